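#' Shared statistical primitives
#'
#' Thin wrappers around classical tests that attach the reporting
#' conventions used throughout the package: two-sided p values, a star
#' category with cuts at 0.001 / 0.01 / 0.05 and a trend band at
#' 0.05 <= p < 0.10, and explicit "untestable" flags instead of silent
#' NA propagation.
#'
#' @name stats_core
NULL

#' Significance category for a p value
#'
#' Cuts: `***` p < 0.001, `**` p < 0.01, `*` p < 0.05, `+` 0.05 <= p < 0.10
#' (trend), `ns` otherwise.
#'
#' @param p numeric vector of p values in \[0, 1\] (NA allowed).
#' @return character vector of categories; NA maps to `NA`.
#' @export
p_category <- function(p) {
  stopifnot(is.numeric(p))
  out <- rep(NA_character_, length(p))
  ok <- !is.na(p)
  if (any(p[ok] < 0 | p[ok] > 1)) stop("p values must lie in [0, 1]")
  out[ok] <- ifelse(p[ok] < 0.001, "***",
             ifelse(p[ok] < 0.01,  "**",
             ifelse(p[ok] < 0.05,  "*",
             ifelse(p[ok] < 0.10,  "+", "ns"))))
  out
}

new_test_result <- function(statistic, df, p, method, untestable = FALSE,
                            estimate = NA_real_) {
  structure(
    list(statistic = statistic, df = df, p = p,
         category = if (is.na(p)) NA_character_ else p_category(p),
         estimate = estimate, method = method, untestable = untestable),
    class = "gp_test")
}

#' @export
print.gp_test <- function(x, ...) {
  cat(sprintf("%s: t = %.4g, df = %.4g, p = %.4g [%s]%s\n",
              x$method, x$statistic, x$df, x$p,
              ifelse(is.na(x$category), "NA", x$category),
              if (isTRUE(x$untestable)) " (untestable)" else ""))
  invisible(x)
}

#' t tests with the package's reporting conventions
#'
#' One-sample, paired, or independent two-sample t test, two-sided.
#' The independent test pools variances by default (`welch = TRUE` for
#' the Welch correction). Degenerate inputs (zero variance in a
#' one-sample test, all-zero paired differences) return an untestable
#' result with the p = 1 convention rather than an error, so that
#' region-wise loops never die on a constant region.
#'
#' @param x numeric vector (first sample, or the only sample).
#' @param y second sample for paired / independent kinds.
#' @param kind one of `"one_sample"`, `"paired"`, `"independent"`.
#' @param mu reference value for the one-sample test (default 0).
#' @param welch use Welch's unequal-variance form for `independent`.
#' @return a `gp_test` list: statistic, df, p, category, estimate,
#'   method, untestable.
#' @export
t_test <- function(x, y = NULL,
                   kind = c("one_sample", "paired", "independent"),
                   mu = 0, welch = FALSE) {
  kind <- match.arg(kind)
  x <- as.numeric(x)
  if (kind == "one_sample") {
    if (length(x) < 2) stop("one-sample t test needs n >= 2")
    if (stats::sd(x) == 0) {
      # constant data: t undefined (0/0); report the degenerate convention
      return(new_test_result(0, length(x) - 1, 1,
                             "one-sample t", untestable = TRUE,
                             estimate = mean(x) - mu))
    }
    ht <- stats::t.test(x, mu = mu)
    return(new_test_result(unname(ht$statistic), unname(ht$parameter),
                           ht$p.value, "one-sample t",
                           estimate = mean(x) - mu))
  }
  y <- as.numeric(y)
  if (kind == "paired") {
    if (length(x) != length(y)) stop("paired samples must have equal length")
    if (length(x) < 2) stop("paired t test needs n >= 2 pairs")
    d <- x - y
    if (stats::sd(d) == 0) {
      return(new_test_result(0, length(d) - 1, 1, "paired t",
                             untestable = TRUE, estimate = mean(d)))
    }
    ht <- stats::t.test(x, y, paired = TRUE)
    return(new_test_result(unname(ht$statistic), unname(ht$parameter),
                           ht$p.value, "paired t", estimate = mean(d)))
  }
  if (length(x) < 2 || length(y) < 2) stop("independent t test needs n >= 2 per arm")
  if (stats::sd(c(x, y)) == 0) {
    return(new_test_result(0, length(x) + length(y) - 2, 1,
                           "independent t", untestable = TRUE,
                           estimate = mean(x) - mean(y)))
  }
  ht <- stats::t.test(x, y, var.equal = !welch)
  new_test_result(unname(ht$statistic), unname(ht$parameter), ht$p.value,
                  if (welch) "Welch t" else "independent t (pooled)",
                  estimate = mean(x) - mean(y))
}

#' Benjamini-Hochberg step-up q values
#'
#' @param p numeric vector of p values; NAs are carried through.
#' @return q values, same length and order as `p`; `q >= p` elementwise
#'   and idempotent under re-application.
#' @export
bh_fdr <- function(p) {
  if (length(p) == 0) return(numeric(0))
  stopifnot(is.numeric(p))
  if (any(p < 0 | p > 1, na.rm = TRUE)) stop("p values must lie in [0, 1]")
  stats::p.adjust(p, method = "BH")
}

#' Sidak adjustment for k post-hoc comparisons
#'
#' p_adj = 1 - (1 - p)^k.
#'
#' @param p numeric vector of raw p values.
#' @param k number of comparisons in the family (default `length(p)`).
#' @return adjusted p values, capped at 1.
#' @export
sidak_adjust <- function(p, k = length(p)) {
  stopifnot(is.numeric(p), k >= 1)
  pmin(1, 1 - (1 - p)^k)
}

#' Pearson correlation with two-sided p
#'
#' Returns an undefined-flagged record (r = NA) if either vector has
#' zero variance, so callers can exclude the pair rather than crash.
#'
#' @param x,y numeric vectors of equal length >= 3.
#' @return list(r, p, n, defined).
#' @export
pearson_r <- function(x, y) {
  x <- as.numeric(x); y <- as.numeric(y)
  if (length(x) != length(y)) stop("x and y must have equal length")
  keep <- stats::complete.cases(x, y)
  x <- x[keep]; y <- y[keep]
  n <- length(x)
  if (n < 3) stop("Pearson correlation needs n >= 3 complete pairs")
  if (stats::sd(x) == 0 || stats::sd(y) == 0) {
    return(list(r = NA_real_, p = NA_real_, n = n, defined = FALSE))
  }
  ht <- stats::cor.test(x, y, method = "pearson")
  list(r = unname(ht$estimate), p = ht$p.value, n = n, defined = TRUE)
}

#' One-sample t of percent time against chance
#'
#' Convenience used for water-maze style quadrant analyses: tests
#' whether percent time in a target quadrant differs from a chance
#' level (25 by default).
#'
#' @param percent_time numeric vector of per-subject percent times.
#' @param chance chance level on the percent scale.
#' @return a `gp_test`.
#' @export
quadrant_vs_chance <- function(percent_time, chance = 25) {
  t_test(percent_time, kind = "one_sample", mu = chance)
}
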