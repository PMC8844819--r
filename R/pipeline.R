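#' End-to-end pipeline orchestration
#'
#' `run_pipeline()` chains the analysis stages —
#' volumes -> growth -> coherence, startle, behavior scoring, and the
#' phenotype concordance map — from a single configuration, writing
#' versioned JSON/CSV reports plus a run log that echoes the seed and
#' configuration hash so identical configs yield byte-identical
#' reports.
#'
#' @name pipeline
NULL

#' Build a pipeline run configuration
#'
#' @param volumes path to a region-volume CSV (or NULL to skip the
#'   volumetric stages).
#' @param startle_trials path to a startle trial CSV (or NULL).
#' @param associations path to a behavior-region association CSV (or NULL).
#' @param out_dir output directory (created if needed).
#' @param basis volume bases to analyze.
#' @param alpha significance level for all stage tests.
#' @param fdr apply BH-FDR across regions in the deviation tests.
#' @param region_manifest allowed region labels, NULL to accept all.
#' @param seed seed echoed into the run log (the analysis stages are
#'   deterministic; the seed matters for `simulate = TRUE`).
#' @param simulate if TRUE, simulate the volume study instead of
#'   reading `volumes` (used for self-contained demo runs).
#' @return a `run_config` list.
#' @export
run_config <- function(volumes = NULL, startle_trials = NULL,
                       associations = NULL, out_dir = "growthpheno_out",
                       basis = c("absolute", "relative"), alpha = 0.05,
                       fdr = FALSE, region_manifest = NULL, seed = 1L,
                       simulate = FALSE) {
  stopifnot(alpha > 0, alpha < 1)
  basis <- match.arg(basis, several.ok = TRUE)
  for (p in c(volumes, startle_trials, associations)) {
    if (!is.null(p) && !file.exists(p)) stop("input not found: ", p)
  }
  structure(list(volumes = volumes, startle_trials = startle_trials,
                 associations = associations, out_dir = out_dir,
                 basis = basis, alpha = alpha, fdr = fdr,
                 region_manifest = region_manifest, seed = seed,
                 simulate = simulate),
            class = "run_config")
}

#' Load a run configuration from a YAML file
#' @param path YAML file whose keys mirror [run_config()] arguments.
#' @export
read_run_config <- function(path) {
  if (!file.exists(path)) stop("config not found: ", path)
  do.call(run_config, yaml::read_yaml(path))
}

config_hash <- function(cfg) {
  # stable short fingerprint of the analysis-relevant configuration
  # (the output directory does not change results and is excluded)
  keep <- unclass(cfg)
  keep$out_dir <- NULL
  txt <- jsonlite::toJSON(keep, auto_unbox = TRUE, digits = NA,
                          null = "null")
  raw <- as.integer(charToRaw(as.character(txt)))
  # small polynomial checksum, enough to identify a config in a log
  h <- 0
  for (b in raw) h <- (h * 131 + b) %% 16777213
  sprintf("%06x", h)
}

#' Run the configured pipeline stages
#'
#' @param cfg a `run_config`.
#' @return invisibly, a list of stage results (deviation objects,
#'   divergence maps, startle fits/thresholds, concordance report).
#' @export
run_pipeline <- function(cfg) {
  stopifnot(inherits(cfg, "run_config"))
  dir.create(cfg$out_dir, showWarnings = FALSE, recursive = TRUE)
  log_lines <- c(sprintf("growthpheno run | seed=%d | config=%s",
                         cfg$seed, config_hash(cfg)))
  say <- function(fmt, ...) {
    log_lines <<- c(log_lines, sprintf(fmt, ...))
  }
  results <- list(config_hash = config_hash(cfg))

  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      stop(sprintf("stage '%s' failed: %s", name, conditionMessage(e)),
           call. = FALSE)
    })
  }

  tab <- NULL
  if (cfg$simulate) {
    tab <- stage("simulate", {
      sim <- simulate_volume_study(volume_sim_config(seed = cfg$seed))
      write_truth_json(sim$truth, file.path(cfg$out_dir, "truth.json"))
      write_volume_table(sim$table, file.path(cfg$out_dir, "volumes.csv"))
      say("simulated volume study: %d rows", nrow(sim$table))
      sim$table
    })
  } else if (!is.null(cfg$volumes)) {
    tab <- stage("volumes", {
      t <- read_volume_table(cfg$volumes, cfg$region_manifest)
      say("read %s: %d rows, %d subjects", cfg$volumes, nrow(t),
          length(unique(t$subject)))
      t
    })
  }

  if (!is.null(tab)) {
    for (b in cfg$basis) {
      dev <- stage(paste0("growth_", b), {
        d <- deviation_from_trajectory(tab, basis = b)
        d <- deviation_tests(d, alpha = cfg$alpha, fdr = cfg$fdr)
        write_deviation_report(
          d, file.path(cfg$out_dir, sprintf("deviation_%s.csv", b)))
        write_deviation_report(
          d, file.path(cfg$out_dir, sprintf("deviation_%s.json", b)))
        say("deviation (%s): %d/%d regions significant", b,
            sum(d$tests$significant), nrow(d$tests))
        d
      })
      results[[paste0("deviation_", b)]] <- dev

      dmap <- stage(paste0("coherence_", b), {
        gim <- growth_index(tab, basis = b)
        dm <- classify_divergence(growth_correlation_matrix(gim, "WT"),
                                  growth_correlation_matrix(gim, "MUT"),
                                  alpha = cfg$alpha)
        write_divergence_report(
          dm,
          csv_path = file.path(cfg$out_dir, sprintf("divergence_%s.csv", b)),
          json_path = file.path(cfg$out_dir, sprintf("divergence_%s.json", b)))
        cc <- dm$class_counts
        say("divergence (%s): shared %d, WT_only %d, MUT_only %d, neither %d",
            b, cc$shared, cc$WT_only, cc$MUT_only, cc$neither)
        dm
      })
      results[[paste0("divergence_", b)]] <- dmap
    }
  }

  if (!is.null(cfg$startle_trials)) {
    results$startle <- stage("startle", {
      trials <- utils::read.csv(cfg$startle_trials, stringsAsFactors = FALSE)
      summ <- summarize_startle(trials)
      fits <- fit_startle_curves(summ)
      utils::write.csv(fits, file.path(cfg$out_dir, "startle_fits.csv"),
                       row.names = FALSE)
      thresholds <- if ("genotype" %in% names(summ)) {
        lapply(split(summ, summ$genotype), detect_group_threshold,
               alpha = cfg$alpha)
      } else list(all = detect_group_threshold(summ, alpha = cfg$alpha))
      jsonlite::write_json(
        lapply(thresholds, function(th) {
          list(threshold = th$threshold,
               monotone_threshold = th$monotone_threshold)
        }),
        file.path(cfg$out_dir, "startle_thresholds.json"),
        auto_unbox = TRUE, digits = NA, pretty = TRUE)
      say("startle: %d mice fitted, %d converged", nrow(fits),
          sum(fits$converged))
      list(summary = summ, fits = fits, thresholds = thresholds)
    })
  }

  if (!is.null(cfg$associations) &&
      !is.null(results[["deviation_relative"]])) {
    results$concordance <- stage("phenomap", {
      assoc <- read_association_table(cfg$associations)
      status <- classify_region_status(results[["deviation_relative"]],
                                       alpha = cfg$alpha)
      rep <- predict_phenotype_concordance(assoc, status)
      write_concordance_report(rep,
                               file.path(cfg$out_dir, "concordance.json"))
      say("concordance: %d behaviors tested", sum(rep$table))
      rep
    })
  }

  writeLines(log_lines, file.path(cfg$out_dir, "run_log.txt"))
  invisible(results)
}
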