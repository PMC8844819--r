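#' Acoustic startle psychophysics
#'
#' Trials are whole-body flinch amplitudes (accelerometer units) to
#' 40 ms white-noise bursts at 0-50 dB above a 70 dB background, eight
#' presentations per intensity plus eight no-stimulus control trials.
#' Per-mouse analysis: per-intensity trial means are log10-normalized
#' and fitted with a logistic (sigmoid) response curve
#'
#'   N(s) = m_max / (1 + exp(-r (s - s0)))
#'
#' where m_max is the saturation (maximal log-amplitude), s0 the
#' midpoint (intensity at 50 percent of saturation) and r the slope.
#' Derived measures: the 5 percent startle threshold
#' s0 - ln(19)/r, the fit RMSE, and the observed maximum (highest
#' per-intensity mean, since the loudest stimulus may undershoot true
#' saturation). Group-level analyses: the traditional threshold
#' (lowest intensity with a significant paired increase over the
#' no-stimulus baseline), low/high dB-module mixed ANOVAs, and
#' prepulse-inhibition / habituation scores.
#'
#' @name startle
NULL

#' Stimulus intensities (dB above background) used by default
#' @export
STARTLE_DB_SET <- seq(0, 50, by = 5)

sigmoid_n <- function(s, m_max, s0, r) m_max / (1 + exp(-r * (s - s0)))

#' Summarize startle trials per subject and intensity
#'
#' Mean raw amplitude across trials per (subject, dB) plus its
#' log10-normalized value, floored at `eps` to avoid log of zero
#' (floored cells are flagged).
#'
#' @param trials data frame with columns subject, stimulus_db,
#'   amplitude (extra columns such as genotype/sex are carried through
#'   by first value).
#' @param eps floor applied to the mean amplitude before log10.
#' @return data frame: subject, stimulus_db, n_trials, mean_amplitude,
#'   log_amplitude, floored, plus carried grouping columns.
#' @export
summarize_startle <- function(trials, eps = 0.01) {
  need <- c("subject", "stimulus_db", "amplitude")
  miss <- setdiff(need, names(trials))
  if (length(miss)) stop("missing column(s): ", paste(miss, collapse = ", "))
  if (any(!is.finite(trials$amplitude) | trials$amplitude < 0)) {
    stop("amplitudes must be finite and non-negative")
  }
  key <- interaction(trials$subject, trials$stimulus_db, drop = TRUE)
  agg <- do.call(rbind, lapply(split(seq_len(nrow(trials)), key), function(ix) {
    first <- ix[1]
    mn <- mean(trials$amplitude[ix])
    carried <- intersect(c("genotype", "sex", "age_group"), names(trials))
    out <- data.frame(subject = trials$subject[first],
                      stimulus_db = trials$stimulus_db[first],
                      n_trials = length(ix),
                      mean_amplitude = mn,
                      log_amplitude = log10(max(mn, eps)),
                      floored = mn < eps,
                      stringsAsFactors = FALSE)
    for (cc in carried) out[[cc]] <- trials[[cc]][first]
    out
  }))
  agg <- agg[order(agg$subject, agg$stimulus_db), ]
  rownames(agg) <- NULL
  agg
}

startle_rmse <- function(par, s, y) {
  sqrt(mean((y - sigmoid_n(s, par[1], par[2], par[3]))^2))
}

# sum of squares and its analytic gradient (same argmin as the RMSE)
startle_sse <- function(par, s, y) {
  sum((y - sigmoid_n(s, par[1], par[2], par[3]))^2)
}

startle_sse_grad <- function(par, s, y) {
  m <- par[1]; s0 <- par[2]; r <- par[3]
  l <- 1 / (1 + exp(-r * (s - s0)))
  e <- y - m * l
  c(-2 * sum(e * l),
    -2 * sum(e * m * l * (1 - l) * (-r)),
    -2 * sum(e * m * l * (1 - l) * (s - s0)))
}

#' Fit the startle sigmoid to one mouse's log-normalized curve
#'
#' Bounded least-squares fit of (m_max, s0, r) minimizing RMSE over the
#' observed intensities, with multi-start initialization
#' (m_max0 = max of the log data; s0 in 15/25/35; r in 0.1/0.3) and
#' bounds m_max > 0, r in (0, 5], s0 in \[-20, 80\]. A flat curve
#' (log-amplitude range below `flat_tol`) is reported unconverged with
#' the constant-model RMSE.
#'
#' @param stimulus_db intensities (dB above background), length >= 5.
#' @param log_amplitude per-intensity log10 mean amplitudes.
#' @param flat_tol minimum log-amplitude range for a meaningful fit.
#' @return a `startle_fit` list: m_max, s0, r, rmse, threshold5,
#'   max_observed (filled by callers that have raw means), converged.
#' @export
fit_startle_sigmoid <- function(stimulus_db, log_amplitude, flat_tol = 1e-3) {
  keep <- is.finite(stimulus_db) & is.finite(log_amplitude)
  s <- as.numeric(stimulus_db[keep])
  y <- as.numeric(log_amplitude[keep])
  if (length(s) < 5) stop("need >= 5 intensity points to fit the sigmoid")
  const_rmse <- sqrt(mean((y - mean(y))^2))
  if (diff(range(y)) < flat_tol) {
    return(structure(list(m_max = NA_real_, s0 = NA_real_, r = NA_real_,
                          rmse = const_rmse, threshold5 = NA_real_,
                          max_observed = NA_real_, converged = FALSE),
                     class = "startle_fit"))
  }
  lower <- c(1e-6, -20, 1e-4)
  upper <- c(Inf, 80, 5)
  starts <- expand.grid(m_max = max(y), s0 = c(15, 25, 35), r = c(0.1, 0.3))
  best <- NULL
  for (k in seq_len(nrow(starts))) {
    p0 <- pmin(pmax(as.numeric(starts[k, ]), lower), c(1e6, 80, 5))
    fit <- tryCatch(
      stats::optim(p0, startle_sse, gr = startle_sse_grad, s = s, y = y,
                   method = "L-BFGS-B", lower = lower, upper = upper,
                   control = list(maxit = 500, factr = 1e4)),
      error = function(e) NULL)
    if (!is.null(fit) && (is.null(best) || fit$value < best$value)) best <- fit
  }
  if (!is.null(best)) {
    # polish the winning start at tight tolerance
    polish <- tryCatch(
      stats::optim(best$par, startle_sse, gr = startle_sse_grad, s = s, y = y,
                   method = "L-BFGS-B", lower = lower, upper = upper,
                   control = list(maxit = 2000, factr = 1, pgtol = 0)),
      error = function(e) NULL)
    if (!is.null(polish) && polish$value <= best$value) best <- polish
  }
  if (is.null(best)) {
    return(structure(list(m_max = NA_real_, s0 = NA_real_, r = NA_real_,
                          rmse = const_rmse, threshold5 = NA_real_,
                          max_observed = NA_real_, converged = FALSE),
                     class = "startle_fit"))
  }
  p <- best$par
  out <- structure(list(m_max = p[1], s0 = p[2], r = p[3],
                        rmse = sqrt(best$value / length(s)),
                        threshold5 = NA_real_, max_observed = NA_real_,
                        converged = TRUE),
                   class = "startle_fit")
  out$threshold5 <- threshold_at_fraction(out, 0.05)
  out
}

#' @export
print.startle_fit <- function(x, ...) {
  if (isTRUE(x$converged)) {
    cat(sprintf(
      "Startle sigmoid: m_max = %.4g, s0 = %.4g dB, r = %.4g /dB, rmse = %.4g, 5%% threshold = %.4g dB\n",
      x$m_max, x$s0, x$r, x$rmse, x$threshold5))
  } else {
    cat(sprintf("Startle sigmoid: not converged (flat curve), constant rmse = %.4g\n",
                x$rmse))
  }
  invisible(x)
}

#' Stimulus intensity producing a given fraction of saturation
#'
#' Closed form s = s0 - ln((1 - f)/f)/r; f = 0.5 returns the midpoint
#' s0 exactly, f = 0.05 the conventional 5 percent startle threshold.
#'
#' @param fit a converged `startle_fit`.
#' @param f fraction of saturation in (0, 1).
#' @return intensity in dB above background.
#' @export
threshold_at_fraction <- function(fit, f) {
  stopifnot(inherits(fit, "startle_fit"))
  if (!isTRUE(fit$converged)) stop("fit did not converge; no threshold defined")
  if (!(f > 0 && f < 1)) stop("fraction must lie in (0, 1)")
  fit$s0 - log((1 - f) / f) / fit$r
}

#' Observed maximum startle for one mouse
#'
#' Highest per-intensity mean raw amplitude regardless of intensity;
#' ties broken toward the lower dB and flagged.
#'
#' @param stimulus_db intensities.
#' @param mean_amplitude per-intensity mean raw amplitudes.
#' @return list(amplitude, at_db, tie).
#' @export
max_observed <- function(stimulus_db, mean_amplitude) {
  stopifnot(length(stimulus_db) == length(mean_amplitude),
            length(stimulus_db) > 0)
  ord <- order(stimulus_db)
  s <- stimulus_db[ord]; a <- mean_amplitude[ord]
  i <- which.max(a)  # which.max returns the first (lowest-dB) maximum
  list(amplitude = a[i], at_db = s[i], tie = sum(a == a[i]) > 1)
}

#' Fit every mouse in a summarized startle table
#'
#' @param summary output of [summarize_startle()].
#' @return data frame, one row per subject: m_max, s0, r, rmse,
#'   threshold5, max_observed, max_at_db, converged, plus carried
#'   grouping columns.
#' @export
fit_startle_curves <- function(summary) {
  sp <- split(summary, summary$subject)
  out <- do.call(rbind, lapply(sp, function(d) {
    fit <- fit_startle_sigmoid(d$stimulus_db, d$log_amplitude)
    mx <- max_observed(d$stimulus_db, d$mean_amplitude)
    row <- data.frame(subject = d$subject[1], m_max = fit$m_max,
                      s0 = fit$s0, r = fit$r, rmse = fit$rmse,
                      threshold5 = fit$threshold5,
                      max_observed = mx$amplitude, max_at_db = mx$at_db,
                      converged = fit$converged, stringsAsFactors = FALSE)
    for (cc in intersect(c("genotype", "sex", "age_group"), names(d))) {
      row[[cc]] <- d[[cc]][1]
    }
    row
  }))
  rownames(out) <- NULL
  out
}

#' Traditional group startle threshold
#'
#' Per intensity, a paired t test compares the group's per-subject mean
#' amplitudes against their no-stimulus (0 dB) baseline. The threshold
#' is the lowest intensity with p < alpha; because significance need
#' not be monotone in intensity, the monotone threshold (lowest dB from
#' which it and all higher intensities are significant) is reported
#' alongside.
#'
#' @param summary output of [summarize_startle()] for one group, on the
#'   scale to be tested (`value` selects raw or log means).
#' @param alpha significance level.
#' @param value `"mean_amplitude"` or `"log_amplitude"`.
#' @return list(threshold, monotone_threshold, per_db data frame);
#'   thresholds are NA when no intensity is significant.
#' @export
detect_group_threshold <- function(summary, alpha = 0.05,
                                   value = c("mean_amplitude", "log_amplitude")) {
  value <- match.arg(value)
  wide <- split(summary, summary$subject)
  base <- vapply(wide, function(d) {
    b <- d[[value]][d$stimulus_db == 0]
    if (!length(b)) NA_real_ else b[1]
  }, numeric(1))
  if (anyNA(base)) stop("missing 0 dB baseline for subject(s): ",
                        paste(names(base)[is.na(base)], collapse = ", "))
  if (length(base) < 2) stop("need >= 2 subjects for the group threshold")
  dbs <- sort(setdiff(unique(summary$stimulus_db), 0))
  per_db <- do.call(rbind, lapply(dbs, function(db) {
    v <- vapply(wide, function(d) {
      y <- d[[value]][d$stimulus_db == db]
      if (!length(y)) NA_real_ else y[1]
    }, numeric(1))
    keep <- !is.na(v)
    tt <- t_test(v[keep], base[keep], kind = "paired")
    data.frame(stimulus_db = db, n = sum(keep), t = tt$statistic,
               df = tt$df, p = tt$p, category = p_category(tt$p),
               significant = !tt$untestable & tt$p < alpha,
               stringsAsFactors = FALSE)
  }))
  sig <- per_db$significant
  threshold <- if (any(sig)) per_db$stimulus_db[which(sig)[1]] else NA_real_
  mono <- NA_real_
  if (any(sig)) {
    run <- rev(cumprod(rev(sig)))  # 1 where this and all higher dBs significant
    if (any(run == 1)) mono <- per_db$stimulus_db[which(run == 1)[1]]
  }
  list(threshold = threshold, monotone_threshold = mono, per_db = per_db)
}

#' Low/high dB-module mixed ANOVA (genotype x stimulus intensity)
#'
#' The intensity range is split into a low module (0-25 dB above
#' background) and a high module (30-50); within a module a two-way
#' mixed ANOVA is run with genotype between subjects and intensity
#' within subjects. When the interaction is significant at
#' `posthoc_alpha`, Sidak-adjusted pairwise genotype contrasts per
#' intensity are added. Subjects missing any within-subject level are
#' excluded (and listed).
#'
#' @param summary output of [summarize_startle()] with a genotype column.
#' @param module `"low"` or `"high"`.
#' @param value response column.
#' @param posthoc_alpha interaction p threshold for post hocs.
#' @return list(anova = data frame of effect/df/F/p, posthoc or NULL,
#'   excluded_subjects, module).
#' @export
db_module_effect <- function(summary, module = c("low", "high"),
                             value = c("log_amplitude", "mean_amplitude"),
                             posthoc_alpha = 0.05) {
  module <- match.arg(module)
  value <- match.arg(value)
  if (!"genotype" %in% names(summary)) stop("summary must carry a genotype column")
  dbs <- if (module == "low") seq(0, 25, 5) else seq(30, 50, 5)
  d <- summary[summary$stimulus_db %in% dbs, ]
  # complete-case subjects only
  n_levels <- tapply(d$stimulus_db, d$subject, function(v) length(unique(v)))
  complete <- names(n_levels)[n_levels == length(intersect(dbs, unique(d$stimulus_db)))]
  excluded <- setdiff(unique(d$subject), complete)
  d <- d[d$subject %in% complete, ]
  d$subject <- factor(d$subject)
  d$genotype <- factor(d$genotype)
  d$db <- factor(d$stimulus_db)
  d$y <- d[[value]]
  fit <- stats::aov(y ~ genotype * db + Error(subject/db), data = d)
  sm <- summary(fit)
  between <- as.data.frame(sm[["Error: subject"]][[1]])
  within <- as.data.frame(sm[["Error: subject:db"]][[1]])
  pick <- function(tab, label) {
    i <- which(trimws(rownames(tab)) == label)
    data.frame(effect = label, df = tab$Df[i], F = tab$`F value`[i],
               p = tab$`Pr(>F)`[i], stringsAsFactors = FALSE)
  }
  an <- rbind(pick(between, "genotype"), pick(within, "db"),
              pick(within, "genotype:db"))
  an$category <- p_category(an$p)
  posthoc <- NULL
  int_p <- an$p[an$effect == "genotype:db"]
  if (is.finite(int_p) && int_p < posthoc_alpha) {
    lev <- levels(d$db)
    ph <- do.call(rbind, lapply(lev, function(l) {
      dd <- d[d$db == l, ]
      gs <- split(dd$y, droplevels(dd$genotype))
      if (length(gs) != 2) return(NULL)
      tt <- t_test(gs[[1]], gs[[2]], kind = "independent")
      data.frame(stimulus_db = as.numeric(l), t = tt$statistic, df = tt$df,
                 p = tt$p, stringsAsFactors = FALSE)
    }))
    ph$p_sidak <- sidak_adjust(ph$p, k = nrow(ph))
    ph$category <- p_category(ph$p_sidak)
    posthoc <- ph
  }
  list(anova = an, posthoc = posthoc, excluded_subjects = excluded,
       module = module)
}

#' Percent prepulse inhibition
#'
#' \[(phase II startle amplitude - prepulse startle amplitude) /
#' (phase II startle amplitude)\] x 100. At most 100 (full inhibition);
#' negative values indicate facilitation.
#'
#' @param phase2_mean mean startle amplitude to phase II pulse-alone trials.
#' @param prepulse_mean mean amplitude to prepulse trials.
#' @return percent PPI.
#' @export
ppi_percent <- function(phase2_mean, prepulse_mean) {
  if (any(phase2_mean <= 0)) stop("phase II mean amplitude must be > 0")
  (phase2_mean - prepulse_mean) / phase2_mean * 100
}

#' Percent startle habituation
#'
#' Per mouse: \[(phase I amplitude - phase III amplitude) /
#' (denominator phase amplitude)\] x 100. The conventional denominator
#' is phase I; `denominator = "phase3"` is available as an alternative
#' normalization. Negative scores (more startle in phase III) are
#' permitted.
#'
#' @param phase1_mean,phase3_mean per-mouse mean amplitudes.
#' @param denominator `"phase1"` (default) or `"phase3"`.
#' @return percent habituation.
#' @export
habituation_percent <- function(phase1_mean, phase3_mean,
                                denominator = c("phase1", "phase3")) {
  denominator <- match.arg(denominator)
  den <- if (denominator == "phase1") phase1_mean else phase3_mean
  if (any(den <= 0)) stop("denominator phase mean amplitude must be > 0")
  (phase1_mean - phase3_mean) / den * 100
}

#' Group habituation summary: mean of per-mouse scores vs score of means
#'
#' Because individual mice can have negative habituation, the mean of
#' the per-mouse scores generally differs from the score computed on
#' the group-mean phase amplitudes; both are reported.
#'
#' @param phase1_means,phase3_means per-mouse phase mean amplitudes.
#' @inheritParams habituation_percent
#' @return list(mean_of_scores, score_of_means, per_mouse).
#' @export
habituation_group_summary <- function(phase1_means, phase3_means,
                                      denominator = c("phase1", "phase3")) {
  denominator <- match.arg(denominator)
  per <- habituation_percent(phase1_means, phase3_means, denominator)
  list(mean_of_scores = mean(per),
       score_of_means = habituation_percent(mean(phase1_means),
                                            mean(phase3_means), denominator),
       per_mouse = per)
}
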