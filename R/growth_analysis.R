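#' Growth-trajectory analysis
#'
#' The developmental model: for each brain region, wild-type growth from
#' P7 to P60 defines a trajectory w = mean(P60 WT) / mean(P7 WT). A
#' mutant adult region is predicted to reach y_hat = mean(P7 MUT) x w;
#' each mutant P60 subject's percent deviation from that prediction is
#' x = (y - y_hat) / y_hat x 100. One-sample t tests of x against zero
#' per region identify regions departing from the wild-type trajectory.
#' P7 and P60 animals are independent cohorts, so all baselines are
#' genotype means, never subject-matched values.
#'
#' @name growth_analysis
NULL

basis_column <- function(basis = c("absolute", "relative")) {
  basis <- match.arg(basis)
  c(absolute = "volume_mm3", relative = "rel_volume")[[basis]]
}

#' Per-subject region growth index matrix
#'
#' For every P60 subject and region, (P60 value - genotype mean P7
#' value) / genotype mean P7 value, computed within genotype on the
#' chosen volume basis.
#'
#' @param tab a `region_volume_table` with relative volumes computed.
#' @param basis `"absolute"` (mm3) or `"relative"` (percent of brain).
#' @param include_whole_brain keep the whole-brain row as a column.
#' @return a `growth_index_matrix`: numeric matrix, P60 subjects x
#'   regions, with `attr(, "genotype")` giving each row's genotype and
#'   `attr(, "basis")` the basis.
#' @export
growth_index <- function(tab, basis = c("absolute", "relative"),
                         include_whole_brain = FALSE) {
  basis <- match.arg(basis)
  col <- basis_column(basis)
  stopifnot(inherits(tab, "region_volume_table"), col %in% names(tab))
  regions <- volume_regions(tab)
  if (include_whole_brain) regions <- c(regions, WHOLE_BRAIN)

  for (g in c("WT", "MUT")) {
    if (!any(tab$genotype == g & tab$age == "P7")) {
      stop("no P7 subjects for genotype ", g)
    }
  }
  p7 <- tab[tab$age == "P7", ]
  # genotype x region mean at P7
  p7_mean <- tapply(p7[[col]], list(p7$genotype, p7$region), mean)
  if (any(p7_mean[, regions, drop = FALSE] == 0, na.rm = TRUE)) {
    stop("zero P7 mean volume encountered (division by zero)")
  }
  p60 <- tab[tab$age == "P60" & tab$region %in% regions, ]
  subjects <- sort(unique(p60$subject))
  geno <- vapply(subjects,
                 function(s) p60$genotype[p60$subject == s][1], character(1))
  m <- matrix(NA_real_, length(subjects), length(regions),
              dimnames = list(subjects, regions))
  for (i in seq_len(nrow(p60))) {
    base <- p7_mean[p60$genotype[i], p60$region[i]]
    m[p60$subject[i], p60$region[i]] <- (p60[[col]][i] - base) / base
  }
  structure(m, genotype = geno, basis = basis,
            class = c("growth_index_matrix", class(m)))
}

#' Wild-type growth trajectory per region
#'
#' w = mean(P60 WT) / mean(P7 WT), strictly positive. On the relative
#' basis the whole-brain trajectory is exactly 1 (100 / 100).
#'
#' @inheritParams growth_index
#' @return named numeric vector over regions (whole brain included).
#' @export
wt_trajectory <- function(tab, basis = c("absolute", "relative")) {
  basis <- match.arg(basis)
  col <- basis_column(basis)
  stopifnot(inherits(tab, "region_volume_table"), col %in% names(tab))
  wt <- tab[tab$genotype == "WT", ]
  for (a in c("P7", "P60")) {
    if (!any(wt$age == a)) stop("no WT subjects at age ", a)
  }
  m7 <- tapply(wt[[col]][wt$age == "P7"], wt$region[wt$age == "P7"], mean)
  m60 <- tapply(wt[[col]][wt$age == "P60"], wt$region[wt$age == "P60"], mean)
  regions <- intersect(names(m7), names(m60))
  w <- m60[regions] / m7[regions]
  if (any(!is.finite(w) | w <= 0)) stop("non-positive WT trajectory")
  w
}

#' Percent deviation from the trajectory-predicted volume
#'
#' For the chosen genotype's P60 subjects: predicted region volume
#' y_hat = mean(P7 of that genotype) x w; deviation
#' x = (y - y_hat) / y_hat x 100. Applied to the WT cohort itself the
#' per-region mean deviation is zero by construction, a property used
#' as an internal consistency check.
#'
#' @param tab a `region_volume_table`.
#' @param w named trajectory vector from [wt_trajectory()]; computed
#'   from `tab` if NULL.
#' @param basis volume basis.
#' @param genotype cohort whose P60 subjects are scored (default MUT).
#' @return a `trajectory_deviation` object: list with `deviations`
#'   (long data frame subject/region/x), `predicted` (named y_hat),
#'   `w`, `basis`, `genotype`.
#' @export
deviation_from_trajectory <- function(tab, w = NULL,
                                      basis = c("absolute", "relative"),
                                      genotype = "MUT") {
  basis <- match.arg(basis)
  col <- basis_column(basis)
  stopifnot(inherits(tab, "region_volume_table"), col %in% names(tab))
  if (is.null(w)) w <- wt_trajectory(tab, basis)
  g7 <- tab[tab$genotype == genotype & tab$age == "P7", ]
  g60 <- tab[tab$genotype == genotype & tab$age == "P60", ]
  if (!nrow(g7)) stop("no ", genotype, " P7 subjects (needed for prediction)")
  if (!nrow(g60)) stop("no ", genotype, " P60 subjects")
  m7 <- tapply(g7[[col]], g7$region, mean)
  regions <- intersect(names(w), names(m7))
  y_hat <- m7[regions] * w[regions]
  if (any(y_hat == 0)) stop("predicted volume of zero (division by zero)")
  keep <- g60$region %in% regions
  dev <- data.frame(
    subject = g60$subject[keep],
    region = g60$region[keep],
    y = g60[[col]][keep],
    stringsAsFactors = FALSE)
  dev$y_hat <- y_hat[dev$region]
  dev$x <- (dev$y - dev$y_hat) / dev$y_hat * 100
  structure(list(deviations = dev, predicted = y_hat, w = w[regions],
                 basis = basis, genotype = genotype),
            class = "trajectory_deviation")
}

#' Per-region one-sample tests of trajectory deviation
#'
#' Two-sided one-sample t of the per-subject percent deviations against
#' zero, per region, with the star/trend categories; regions with fewer
#' than two subjects are flagged untestable rather than dropped.
#' Benjamini-Hochberg q values across regions are off by default and
#' filled only when `fdr = TRUE`.
#'
#' @param dev a `trajectory_deviation` from [deviation_from_trajectory()].
#' @param alpha significance level used for the `significant` column.
#' @param fdr compute BH q values across regions.
#' @return the input with a `tests` data frame added: region, n,
#'   mean_x, sem, t, df, p, q, category, untestable, significant.
#' @export
deviation_tests <- function(dev, alpha = 0.05, fdr = FALSE) {
  stopifnot(inherits(dev, "trajectory_deviation"))
  sp <- split(dev$deviations$x, dev$deviations$region)
  rows <- lapply(names(sp), function(r) {
    x <- sp[[r]]
    n <- length(x)
    if (n < 2) {
      return(data.frame(region = r, n = n, mean_x = mean(x), sem = NA_real_,
                        t = NA_real_, df = NA_real_, p = NA_real_,
                        untestable = TRUE, stringsAsFactors = FALSE))
    }
    tt <- t_test(x, kind = "one_sample", mu = 0)
    data.frame(region = r, n = n, mean_x = mean(x),
               sem = stats::sd(x) / sqrt(n),
               t = tt$statistic, df = tt$df, p = tt$p,
               untestable = tt$untestable, stringsAsFactors = FALSE)
  })
  tests <- do.call(rbind, rows)
  tests$q <- if (fdr) bh_fdr(tests$p) else NA_real_
  tests$category <- p_category(tests$p)
  p_eff <- if (fdr) tests$q else tests$p
  tests$significant <- !is.na(p_eff) & p_eff < alpha & !tests$untestable
  tests <- tests[order(tests$region), ]
  rownames(tests) <- NULL
  dev$tests <- tests
  dev$alpha <- alpha
  dev$fdr <- fdr
  dev
}

#' @export
print.trajectory_deviation <- function(x, ...) {
  cat(sprintf("Trajectory deviation (%s basis, %s cohort): %d regions, %d subjects\n",
              x$basis, x$genotype, length(x$predicted),
              length(unique(x$deviations$subject))))
  if (!is.null(x$tests)) {
    cat(sprintf("  %d/%d regions significant at alpha = %g%s\n",
                sum(x$tests$significant), nrow(x$tests), x$alpha,
                if (isTRUE(x$fdr)) " (BH-FDR)" else ""))
  }
  invisible(x)
}

#' Export a deviation report (one row per region) as CSV/JSON
#' @param dev a tested `trajectory_deviation`.
#' @param path output path; format by extension (.json or .csv).
#' @export
write_deviation_report <- function(dev, path) {
  stopifnot(inherits(dev, "trajectory_deviation"), !is.null(dev$tests))
  rep <- dev$tests
  rep$w <- as.numeric(dev$w[rep$region])
  rep$y_hat <- as.numeric(dev$predicted[rep$region])
  rep$basis <- dev$basis
  if (grepl("\\.json$", path, ignore.case = TRUE)) {
    jsonlite::write_json(rep, path, digits = NA, pretty = TRUE)
  } else {
    utils::write.csv(rep, path, row.names = FALSE)
  }
  invisible(path)
}
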