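make_trials <- function(amplitudes_by_db, subject = "m1") {
  do.call(rbind, lapply(names(amplitudes_by_db), function(db) {
    a <- amplitudes_by_db[[db]]
    data.frame(subject = subject, stimulus_db = as.numeric(db),
               trial_index = seq_along(a), amplitude = a,
               stringsAsFactors = FALSE)
  }))
}

test_that("trial summarization averages and log-normalizes per intensity", {
  tr <- make_trials(list(`0` = rep(50, 8),
                         `5` = c(10, 20, 30, 40, 10, 20, 30, 40)))
  s <- summarize_startle(tr)
  expect_equal(s$mean_amplitude[s$stimulus_db == 0], 50)
  expect_equal(s$log_amplitude[s$stimulus_db == 0], log10(50))
  expect_equal(s$mean_amplitude[s$stimulus_db == 5], 25)
  expect_false(any(s$floored))

  zero <- summarize_startle(make_trials(list(`0` = rep(0, 8))))
  expect_equal(zero$log_amplitude, -2)  # log10 of the 0.01 floor
  expect_true(zero$floored)

  expect_error(summarize_startle(make_trials(list(`0` = c(1, -2)))),
               "non-negative")
})

test_that("noiseless sigmoid curves are recovered essentially exactly", {
  s <- STARTLE_DB_SET
  y <- 2.0 / (1 + exp(-0.3 * (s - 25)))
  fit <- fit_startle_sigmoid(s, y)
  expect_true(fit$converged)
  expect_close(fit$m_max, 2.0, tol = 1e-4)
  expect_close(fit$s0, 25, tol = 1e-4)
  expect_close(fit$r, 0.3, tol = 1e-4)
  expect_lt(fit$rmse, 1e-6)
})

test_that("a flat curve is unconverged with the constant-model RMSE", {
  s <- STARTLE_DB_SET
  fit <- fit_startle_sigmoid(s, rep(1.3, length(s)))
  expect_false(fit$converged)
  expect_equal(fit$rmse, 0)
  expect_true(is.na(fit$m_max))
  expect_error(threshold_at_fraction(fit, 0.05), "converge")
})

test_that("fit RMSE never exceeds the constant-model RMSE", {
  set.seed(41)
  s <- STARTLE_DB_SET
  for (i in 1:10) {
    y <- runif(1, 0.5, 3) / (1 + exp(-runif(1, 0.1, 0.6) * (s - runif(1, 10, 40)))) +
      rnorm(length(s), 0, 0.2)
    fit <- fit_startle_sigmoid(s, y)
    expect_lte(fit$rmse, sqrt(mean((y - mean(y))^2)) + 1e-9)
  }
})

test_that("threshold fractions follow the closed form and its symmetry", {
  fit <- structure(list(m_max = 2, s0 = 25, r = 0.2, converged = TRUE),
                   class = "startle_fit")
  expect_identical(threshold_at_fraction(fit, 0.5), 25)
  expect_close(threshold_at_fraction(fit, 0.05), 25 - log(19) / 0.2, tol = 1e-9)
  expect_close(threshold_at_fraction(fit, 0.95), 25 + log(19) / 0.2, tol = 1e-9)
  for (f in c(0.01, 0.2, 0.37, 0.6)) {
    expect_close(threshold_at_fraction(fit, f) +
                   threshold_at_fraction(fit, 1 - f), 2 * 25, tol = 1e-9)
  }
  expect_error(threshold_at_fraction(fit, 1), "fraction")
})

test_that("the observed maximum picks the highest mean, lower dB on ties", {
  s <- seq(0, 50, 5)
  mono <- seq_along(s)
  expect_equal(max_observed(s, mono)$at_db, 50)
  m <- c(1, 2, 3, 4, 5, 6, 7, 8, 900, 870, 880)
  got <- max_observed(s, m)
  expect_equal(got$amplitude, 900)
  expect_equal(got$at_db, 40)
  expect_false(got$tie)
  tie <- max_observed(s, rep(7, length(s)))
  expect_equal(tie$at_db, 0)
  expect_true(tie$tie)
})

test_that("group threshold handles null, non-monotone, and missing baselines", {
  dbs <- seq(0, 50, 5)
  subjects <- sprintf("s%02d", 1:10)
  # every intensity equals each subject's own baseline exactly: all
  # paired differences are zero -> untestable everywhere -> no threshold
  flat <- matrix(10 + seq_len(10), 10, length(dbs),
                 dimnames = list(subjects, dbs))
  null_res <- detect_group_threshold(make_startle_summary(flat))
  expect_true(is.na(null_res$threshold))
  expect_true(is.na(null_res$monotone_threshold))

  # planted significance at 5 dB only and again from 20 dB upward
  set.seed(42)
  bump <- flat + matrix(rnorm(length(flat), 0, 0.3), nrow = 10)
  bump[, "0"] <- flat[, "0"]
  bump[, "5"] <- flat[, "5"] + 5 + rnorm(10, 0, 0.3)
  for (d in as.character(seq(20, 50, 5))) {
    bump[, d] <- flat[, d] + 5 + rnorm(10, 0, 0.3)
  }
  res <- detect_group_threshold(make_startle_summary(bump))
  expect_false(any(res$per_db$significant[res$per_db$stimulus_db %in% c(10, 15)]))
  expect_equal(res$threshold, 5)
  expect_equal(res$monotone_threshold, 20)
  expect_equal(nrow(res$per_db), length(dbs) - 1)

  nobase <- make_startle_summary(flat)
  nobase <- nobase[nobase$stimulus_db != 0, ]
  expect_error(detect_group_threshold(nobase), "baseline")
})

test_that("mixed ANOVA matches hand-computed sums of squares on a toy table", {
  # 2 genotypes x 3 intensities x 4 subjects, fixed values
  set.seed(43)
  subj <- sprintf("s%d", 1:8)
  geno <- rep(c("WT", "MUT"), each = 4)
  dbs <- c(30, 40, 50)
  y <- round(matrix(rnorm(24, mean = rep(c(1, 2), each = 4) +
                            rep(c(0, 0.5, 1), each = 8), sd = 0.3), 8, 3), 3)
  d <- data.frame(subject = rep(subj, 3), genotype = rep(geno, 3),
                  stimulus_db = rep(dbs, each = 8),
                  mean_amplitude = as.vector(y),
                  log_amplitude = as.vector(y), floored = FALSE,
                  n_trials = 8, stringsAsFactors = FALSE)

  res <- db_module_effect(d, module = "high", value = "log_amplitude")

  # textbook mixed-design decomposition, computed from scratch
  grand <- mean(y)
  n <- 4; a <- 2; b <- 3
  subj_means <- rowMeans(y)
  geno_means <- tapply(subj_means, geno, mean)
  db_means <- colMeans(y)
  cell_means <- rbind(colMeans(y[geno == "MUT", ]), colMeans(y[geno == "WT", ]))
  ss_geno <- n * b * sum((geno_means - grand)^2)
  ss_subj_within <- b * sum((subj_means - geno_means[geno])^2)
  ss_db <- n * a * sum((db_means - grand)^2)
  ss_cells <- n * sum((cell_means - grand)^2)
  ss_int <- ss_cells - ss_geno - ss_db
  ss_tot <- sum((y - grand)^2)
  ss_err <- ss_tot - ss_cells - ss_subj_within
  f_geno <- (ss_geno / (a - 1)) / (ss_subj_within / (a * (n - 1)))
  f_db <- (ss_db / (b - 1)) / (ss_err / (a * (n - 1) * (b - 1)))
  f_int <- (ss_int / ((a - 1) * (b - 1))) / (ss_err / (a * (n - 1) * (b - 1)))

  an <- res$anova
  expect_close(an$F[an$effect == "genotype"], f_geno, tol = 1e-8)
  expect_close(an$F[an$effect == "db"], f_db, tol = 1e-8)
  expect_close(an$F[an$effect == "genotype:db"], f_int, tol = 1e-8)
  expect_close(an$p[an$effect == "genotype"],
               pf(f_geno, a - 1, a * (n - 1), lower.tail = FALSE), tol = 1e-8)
})

test_that("identical genotypes give a near-zero genotype effect", {
  dbs <- seq(30, 50, 5)
  subj <- sprintf("s%d", 1:8)
  # mirrored subject offsets: genotype means identical, subjects vary
  offsets <- rep(c(0.1, 0.2, 0.3, 0.4), 2)
  y <- outer(offsets, seq_along(dbs) * 0.3, `+`)
  d <- data.frame(subject = rep(subj, each = length(dbs)),
                  genotype = rep(rep(c("WT", "MUT"), each = 4), each = length(dbs)),
                  stimulus_db = rep(dbs, 8),
                  log_amplitude = as.vector(t(y)),
                  mean_amplitude = as.vector(t(y)),
                  stringsAsFactors = FALSE)
  res <- db_module_effect(d, module = "high")
  expect_lt(abs(res$anova$F[res$anova$effect == "genotype"]), 1e-10)
})

test_that("subjects missing a within-subject level are excluded and logged", {
  dbs <- seq(0, 25, 5)
  subj <- sprintf("s%d", 1:8)
  set.seed(44)
  d <- expand.grid(subject = subj, stimulus_db = dbs,
                   stringsAsFactors = FALSE)
  d$genotype <- ifelse(d$subject %in% subj[1:4], "WT", "MUT")
  d$log_amplitude <- rnorm(nrow(d), 1)
  d$mean_amplitude <- 10^d$log_amplitude
  d <- d[!(d$subject == "s3" & d$stimulus_db == 10), ]  # incomplete subject
  res <- db_module_effect(d, module = "low")
  expect_equal(res$excluded_subjects, "s3")
})

test_that("PPI and habituation follow the printed formulas", {
  expect_equal(ppi_percent(100, 40), 60)
  expect_equal(ppi_percent(100, 100), 0)
  expect_equal(ppi_percent(100, 0), 100)
  expect_error(ppi_percent(0, 10), "> 0")

  expect_equal(habituation_percent(100, 60), 40)
  expect_equal(habituation_percent(100, 100), 0)
  expect_lt(habituation_percent(100, 130), 0)  # negative habituation allowed
  expect_equal(habituation_percent(100, 60, denominator = "phase3"),
               (100 - 60) / 60 * 100)
  expect_error(habituation_percent(0, 10), "> 0")
})

test_that("PPI and habituation are invariant to amplitude rescaling", {
  for (k in c(0.5, 3, 100)) {
    expect_close(ppi_percent(k * 80, k * 30), ppi_percent(80, 30))
    expect_close(habituation_percent(k * 80, k * 30),
                 habituation_percent(80, 30))
  }
})

test_that("mean-of-scores and score-of-means habituation disagree on heterogeneous groups", {
  p1 <- c(100, 50, 200)
  p3 <- c(60, 70, 100)
  gs <- habituation_group_summary(p1, p3)
  expect_equal(gs$mean_of_scores, mean((p1 - p3) / p1 * 100))
  expect_equal(gs$score_of_means, (mean(p1) - mean(p3)) / mean(p1) * 100)
  expect_false(isTRUE(all.equal(gs$mean_of_scores, gs$score_of_means)))
})

test_that("per-mouse curve fitting propagates grouping and observed maxima", {
  sim <- simulate_startle_study(startle_sim_config(
    groups = data.frame(name = c("WT", "MUT"), n = 3, m_max = 2, s0 = 25,
                        r = 0.3, sd_m_max = 0, sd_s0 = 0, sd_r = 0),
    trial_noise_sd = 0, seed = 45))
  fits <- fit_startle_curves(summarize_startle(sim$trials))
  expect_equal(nrow(fits), 6)
  expect_true(all(fits$converged))
  expect_close(fits$s0, 25, tol = 1e-3)
  expect_equal(fits$genotype, sub("_.*", "", fits$subject))
  expect_close(fits$max_observed, 10^(2 / (1 + exp(-0.3 * 25))), tol = 1e-6)
})
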