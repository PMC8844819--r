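#' Synthetic studies with known ground truth
#'
#' Generators emulating the two study designs the analysis modules
#' consume: a two-genotype x two-age region-volume study with
#' region-specific growth multipliers and latent-factor-correlated
#' growth, and acoustic-startle sessions with per-mouse sigmoid
#' response curves plus trial noise. Every generator returns the data
#' table together with a `truth` record sufficient to score parameter
#' recovery.
#'
#' Volume model: a P7 subject's region volume is lognormal around the
#' genotype baseline (mutant baseline shifted by `p7_offset`); a P60
#' volume is baseline x genotype growth multiplier x
#' exp(factor loadings . latent z + noise). Latent factors shared
#' between genotypes plant correlated growth in both; genotype-specific
#' factors plant divergent correlations. With loading L and log-noise
#' sd s, the induced growth-index correlation between two regions on a
#' common factor is about L^2 / (L^2 + s^2).
#'
#' @name synthetic_data
NULL

default_p7_baselines <- function() {
  # plausible neonatal region volumes (mm3) for the default manifest
  stats::setNames(
    c(12, 6, 22, 7, 10, 2.5, 28, 35, 16, 4, 18, 14),
    DEFAULT_REGIONS)
}

default_wt_multipliers <- function() {
  # P7 -> P60 fold growth, region-specific, brain roughly doubling
  stats::setNames(
    c(2.2, 2.0, 1.9, 2.1, 1.8, 1.9, 2.4, 2.6, 2.3, 2.1, 2.2, 2.0),
    DEFAULT_REGIONS)
}

#' Configuration for a synthetic volume study
#'
#' @param regions named numeric vector of P7 baseline means (mm3).
#' @param cv lognormal coefficient of variation of subject volumes.
#' @param wt_multipliers,mut_multipliers named P7->P60 growth
#'   multipliers per region; mutant defaults to wild type (null study
#'   apart from the baseline offset).
#' @param p7_offset fractional mutant P7 baseline shift (0.10 = +10%).
#' @param factors list of latent growth factors, each
#'   `list(regions = <labels>, loading = <log-scale sd>, genotype =
#'   "both"|"WT"|"MUT")`.
#' @param n_per_group subjects per genotype per age.
#' @param seed RNG seed (NULL = leave the RNG state alone).
#' @return a `volume_sim_config` list.
#' @export
volume_sim_config <- function(regions = default_p7_baselines(),
                              cv = 0.05,
                              wt_multipliers = default_wt_multipliers()[names(regions)],
                              mut_multipliers = wt_multipliers,
                              p7_offset = 0.10,
                              factors = list(),
                              n_per_group = 10,
                              seed = NULL) {
  stopifnot(is.numeric(regions), !is.null(names(regions)), all(regions > 0),
            cv >= 0, all(wt_multipliers > 0), all(mut_multipliers > 0),
            n_per_group >= 2)
  if (is.null(names(wt_multipliers))) names(wt_multipliers) <- names(regions)
  if (is.null(names(mut_multipliers))) names(mut_multipliers) <- names(regions)
  for (f in factors) {
    stopifnot(all(f$regions %in% names(regions)), is.finite(f$loading))
  }
  structure(list(regions = regions, cv = cv,
                 wt_multipliers = wt_multipliers[names(regions)],
                 mut_multipliers = mut_multipliers[names(regions)],
                 p7_offset = p7_offset, factors = factors,
                 n_per_group = n_per_group, seed = seed),
            class = "volume_sim_config")
}

#' Simulate a two-genotype, two-age region-volume study
#'
#' @param cfg a [volume_sim_config()].
#' @return list(table = `region_volume_table` with relative volumes,
#'   truth = list of the planted parameters, including the expected
#'   percent deviation per region
#'   (mut multiplier / wt multiplier - 1) x 100 and the planted
#'   correlated region pairs per factor).
#' @export
simulate_volume_study <- function(cfg) {
  stopifnot(inherits(cfg, "volume_sim_config"))
  if (!is.null(cfg$seed)) set.seed(cfg$seed)
  regions <- names(cfg$regions)
  k <- length(regions)
  sdlog <- sqrt(log(1 + cfg$cv^2))  # lognormal sd matching the CV
  n <- cfg$n_per_group

  mk_subjects <- function(genotype, age) {
    sprintf("%s_%s_%02d", genotype, age, seq_len(n))
  }
  base <- list(WT = cfg$regions, MUT = cfg$regions * (1 + cfg$p7_offset))
  mult <- list(WT = cfg$wt_multipliers, MUT = cfg$mut_multipliers)

  rows <- list()
  for (g in c("WT", "MUT")) {
    for (age in c("P7", "P60")) {
      subjects <- mk_subjects(g, age)
      for (si in seq_along(subjects)) {
        lognoise <- stats::rnorm(k, 0, sdlog)
        if (age == "P60") {
          for (f in cfg$factors) {
            if (f$genotype %in% c("both", g)) {
              z <- stats::rnorm(1)
              ix <- match(f$regions, regions)
              lognoise[ix] <- lognoise[ix] + f$loading * z
            }
          }
          vol <- base[[g]] * mult[[g]] * exp(lognoise)
        } else {
          vol <- base[[g]] * exp(lognoise)
        }
        rows[[length(rows) + 1]] <- data.frame(
          subject = subjects[si], genotype = g, age = age,
          region = c(regions, WHOLE_BRAIN),
          volume_mm3 = c(vol, sum(vol)), stringsAsFactors = FALSE)
      }
    }
  }
  tab <- validate_volume_table(do.call(rbind, rows), region_manifest = regions)
  tab <- compute_relative_volumes(tab)

  planted_pairs <- lapply(cfg$factors, function(f) {
    prs <- t(utils::combn(sort(f$regions), 2))
    data.frame(region_a = prs[, 1], region_b = prs[, 2],
               genotype = f$genotype,
               expected_r = f$loading^2 / (f$loading^2 + sdlog^2),
               stringsAsFactors = FALSE)
  })
  truth <- list(
    regions = cfg$regions,
    wt_multipliers = cfg$wt_multipliers,
    mut_multipliers = cfg$mut_multipliers,
    p7_offset = cfg$p7_offset,
    cv = cfg$cv, sdlog = sdlog,
    expected_deviation_pct =
      (cfg$mut_multipliers / cfg$wt_multipliers - 1) * 100,
    planted_pairs = if (length(planted_pairs)) {
      do.call(rbind, planted_pairs)
    } else NULL,
    n_per_group = n, seed = cfg$seed)
  list(table = tab, truth = truth)
}

#' Configuration for a synthetic startle-threshold study
#'
#' @param groups data frame with one row per group: name, n, m_max,
#'   s0, r (sigmoid truth in log10-amplitude units / dB), and optional
#'   between-mouse sds sd_m_max, sd_s0, sd_r.
#' @param trial_noise_sd Gaussian sd on log10 amplitude per trial.
#' @param trials_per_db presentations per intensity.
#' @param db_set stimulus intensities (dB above background).
#' @param seed RNG seed.
#' @return a `startle_sim_config`.
#' @export
startle_sim_config <- function(groups = data.frame(
                                 name = c("WT", "MUT"), n = 12,
                                 m_max = 2.0, s0 = 25, r = 0.3,
                                 sd_m_max = 0.1, sd_s0 = 2, sd_r = 0.03),
                               trial_noise_sd = 0.1,
                               trials_per_db = 8,
                               db_set = STARTLE_DB_SET,
                               seed = NULL) {
  for (col in c("sd_m_max", "sd_s0", "sd_r")) {
    if (!col %in% names(groups)) groups[[col]] <- 0
  }
  stopifnot(all(groups$r > 0), all(groups$m_max > 0),
            trial_noise_sd >= 0, trials_per_db >= 1,
            all(c(groups$sd_m_max, groups$sd_s0, groups$sd_r) >= 0))
  structure(list(groups = groups, trial_noise_sd = trial_noise_sd,
                 trials_per_db = trials_per_db, db_set = db_set, seed = seed),
            class = "startle_sim_config")
}

#' Simulate a startle-threshold session
#'
#' Each mouse gets sigmoid parameters drawn around its group truth
#' (slope and saturation truncated away from zero); each trial's
#' amplitude is 10^(N(s) + noise).
#'
#' @param cfg a [startle_sim_config()].
#' @return list(trials = data frame subject/genotype/stimulus_db/
#'   trial_index/amplitude, truth = per-mouse parameter data frame).
#' @export
simulate_startle_study <- function(cfg) {
  stopifnot(inherits(cfg, "startle_sim_config"))
  if (!is.null(cfg$seed)) set.seed(cfg$seed)
  trials <- list(); truth <- list()
  for (gi in seq_len(nrow(cfg$groups))) {
    grp <- cfg$groups[gi, ]
    for (mi in seq_len(grp$n)) {
      id <- sprintf("%s_%02d", grp$name, mi)
      m_max <- max(0.1, stats::rnorm(1, grp$m_max, grp$sd_m_max))
      s0 <- stats::rnorm(1, grp$s0, grp$sd_s0)
      r <- max(0.02, stats::rnorm(1, grp$r, grp$sd_r))
      truth[[id]] <- data.frame(subject = id, genotype = grp$name,
                                m_max = m_max, s0 = s0, r = r,
                                stringsAsFactors = FALSE)
      for (db in cfg$db_set) {
        la <- sigmoid_n(db, m_max, s0, r) +
          stats::rnorm(cfg$trials_per_db, 0, cfg$trial_noise_sd)
        trials[[length(trials) + 1]] <- data.frame(
          subject = id, genotype = grp$name, stimulus_db = db,
          trial_index = seq_len(cfg$trials_per_db),
          amplitude = 10^la, session_kind = "threshold",
          stringsAsFactors = FALSE)
      }
    }
  }
  list(trials = do.call(rbind, trials), truth = do.call(rbind, truth))
}

#' Simulate a three-phase habituation / prepulse-inhibition session
#'
#' Pulse-alone trials share a per-mouse log10 startle level; phase III
#' amplitudes are attenuated by the habituation fraction, prepulse
#' trials by the configured inhibition fraction per prepulse intensity.
#'
#' @param n_mice mice per group (single group).
#' @param startle_log10 mean pulse-alone log10 amplitude.
#' @param between_sd between-mouse sd of the log10 level.
#' @param trial_noise_sd per-trial log10 noise sd.
#' @param inhibition named fractions in \[0, 1) per prepulse type.
#' @param habituation fractional phase I -> III amplitude decline.
#' @param seed RNG seed.
#' @return list(trials = data frame with phase and trial_type columns,
#'   truth = list of the planted fractions).
#' @export
simulate_ppi_session <- function(n_mice = 10, startle_log10 = 2.0,
                                 between_sd = 0.15, trial_noise_sd = 0.1,
                                 inhibition = c(prepulse4 = 0.30,
                                                prepulse8 = 0.45,
                                                prepulse16 = 0.60),
                                 habituation = 0.30, seed = NULL) {
  stopifnot(all(inhibition >= 0 & inhibition < 1), habituation < 1)
  if (!is.null(seed)) set.seed(seed)
  rows <- list()
  emit <- function(id, phase, type, n, level) {
    rows[[length(rows) + 1]] <<- data.frame(
      subject = id, phase = phase, trial_type = type,
      trial_index = seq_len(n),
      amplitude = 10^(level + stats::rnorm(n, 0, trial_noise_sd)),
      stringsAsFactors = FALSE)
  }
  for (mi in seq_len(n_mice)) {
    id <- sprintf("M_%02d", mi)
    lev <- stats::rnorm(1, startle_log10, between_sd)
    emit(id, "I", "startle", 6, lev)
    emit(id, "II", "startle", 12, lev)
    emit(id, "II", "control", 10, -1)  # no-stimulus floor
    for (tp in names(inhibition)) {
      emit(id, "II", tp, 10, lev + log10(1 - inhibition[[tp]]))
    }
    emit(id, "III", "startle", 6, lev + log10(1 - habituation))
  }
  list(trials = do.call(rbind, rows),
       truth = list(inhibition = inhibition, habituation = habituation,
                    startle_log10 = startle_log10, n_mice = n_mice,
                    seed = seed))
}

#' Simulate three-chamber times with a planted social preference
#'
#' Mouse-chamber time = `ratio` x empty-chamber time on average, with
#' multiplicative lognormal noise.
#'
#' @param n subjects.
#' @param empty_mean mean empty-chamber time (s).
#' @param ratio mouse-chamber / empty-chamber mean ratio.
#' @param noise_cv coefficient of variation of the noise.
#' @param seed RNG seed.
#' @return data frame subject/time_mouse_tube/time_empty_tube.
#' @export
simulate_chamber_times <- function(n = 10, empty_mean = 100, ratio = 1.5,
                                   noise_cv = 0.10, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  sdlog <- sqrt(log(1 + noise_cv^2))
  data.frame(
    subject = sprintf("S_%02d", seq_len(n)),
    time_mouse_tube = empty_mean * ratio * exp(stats::rnorm(n, 0, sdlog)),
    time_empty_tube = empty_mean * exp(stats::rnorm(n, 0, sdlog)),
    stringsAsFactors = FALSE)
}

#' Write a synthetic truth record as JSON
#' @param truth truth list/data frame from a simulator.
#' @param path output path.
#' @export
write_truth_json <- function(truth, path) {
  jsonlite::write_json(truth, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE, force = TRUE)
  invisible(path)
}
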