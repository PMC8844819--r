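# Hand-arithmetic table: WT P7 mean 8, WT P60 mean 12 (w = 1.5),
# MUT P7 mean 9; MUT P60 subjects placed around the predicted 13.5.
hand_table <- function() {
  dfs <- list(
    make_volume_df(list(w7a = c(pons = 7), w7b = c(pons = 9)),
                   list(w7a = "WT", w7b = "WT"), list(w7a = "P7", w7b = "P7")),
    make_volume_df(list(w60a = c(pons = 10), w60b = c(pons = 14)),
                   list(w60a = "WT", w60b = "WT"),
                   list(w60a = "P60", w60b = "P60")),
    make_volume_df(list(m7a = c(pons = 8), m7b = c(pons = 10)),
                   list(m7a = "MUT", m7b = "MUT"),
                   list(m7a = "P7", m7b = "P7")),
    make_volume_df(list(m60a = c(pons = 14.85), m60b = c(pons = 13.5)),
                   list(m60a = "MUT", m60b = "MUT"),
                   list(m60a = "P60", m60b = "P60")))
  compute_relative_volumes(validate_volume_table(do.call(rbind, dfs)))
}

test_that("growth index is the normalized rise over the genotype P7 mean", {
  tab <- hand_table()
  gim <- growth_index(tab, basis = "absolute")
  # WT subject 12.0 against P7 mean 10.0 -> 0.2 pattern: here w60b = 14
  # against WT P7 mean 8 -> 0.75; m60b = 13.5 against MUT P7 mean 9 -> 0.5
  expect_equal(gim["w60b", "pons"], (14 - 8) / 8)
  expect_equal(gim["m60b", "pons"], (13.5 - 9) / 9)
  expect_equal(attr(gim, "genotype")[rownames(gim) == "m60a"], "MUT",
               ignore_attr = TRUE)

  # value equal to the P7 mean gives exactly zero; shrinkage is allowed
  df <- make_group_table(list(WT_P7 = c(a = 10), WT_P60 = c(a = 10),
                              MUT_P7 = c(a = 8), MUT_P60 = c(a = 6)))
  g2 <- growth_index(df, basis = "absolute")
  expect_equal(unname(g2[grep("WT", rownames(g2)), "a"]), c(0, 0))
  expect_equal(unname(g2[grep("MUT", rownames(g2)), "a"]), c(-0.25, -0.25))
})

test_that("growth index requires P7 subjects of both genotypes", {
  tab <- hand_table()
  no_mut7 <- tab[!(tab$genotype == "MUT" & tab$age == "P7"), ]
  class(no_mut7) <- class(tab)
  expect_error(growth_index(no_mut7, basis = "absolute"), "P7.*MUT")
})

test_that("the WT trajectory is the ratio of WT age means", {
  tab <- hand_table()
  w <- wt_trajectory(tab, basis = "absolute")
  expect_equal(unname(w["pons"]), 12 / 8)  # 1.5

  flat <- make_group_table(list(WT_P7 = c(a = 5), WT_P60 = c(a = 5),
                                MUT_P7 = c(a = 5), MUT_P60 = c(a = 5)))
  expect_equal(unname(wt_trajectory(flat, basis = "absolute")["a"]), 1)
  # relative basis forces the whole-brain trajectory to exactly 1
  expect_identical(unname(wt_trajectory(flat, basis = "relative")["whole_brain"]), 1)
})

test_that("deviation matches the hand-computed prediction", {
  tab <- hand_table()
  dev <- deviation_from_trajectory(tab, basis = "absolute")
  # y_hat = mean P7 MUT (9) x w (1.5) = 13.5
  expect_equal(unname(dev$predicted["pons"]), 13.5)
  x <- dev$deviations[dev$deviations$region == "pons", ]
  expect_equal(x$x[x$subject == "m60a"], 10)   # 14.85 vs 13.5 -> +10%
  expect_equal(x$x[x$subject == "m60b"], 0)    # y = y_hat -> exactly 0
})

test_that("WT cohort deviations have zero mean per region on both bases", {
  sim <- simulate_volume_study(volume_sim_config(seed = 21))
  for (b in c("absolute", "relative")) {
    dev <- deviation_from_trajectory(sim$table, basis = b, genotype = "WT")
    means <- tapply(dev$deviations$x, dev$deviations$region, mean)
    expect_close(means, 0, tol = 1e-9)
  }
})

test_that("deviations are invariant to global volume rescaling", {
  sim <- simulate_volume_study(volume_sim_config(n_per_group = 4, seed = 22))
  tab <- sim$table
  scaled <- tab
  scaled$volume_mm3 <- scaled$volume_mm3 * 1e3
  scaled <- compute_relative_volumes(scaled)
  d1 <- deviation_from_trajectory(tab, basis = "absolute")
  d2 <- deviation_from_trajectory(scaled, basis = "absolute")
  expect_close(d1$deviations$x, d2$deviations$x, tol = 1e-9)
})

test_that("per-region one-sample tests carry stars, FDR, and untestable flags", {
  tab <- hand_table()
  # plant three MUT P60 subjects with deviations {+9, +10, +11}%
  extra <- make_volume_df(
    list(m60c = c(pons = 13.5 * 1.09), m60d = c(pons = 13.5 * 1.10),
         m60e = c(pons = 13.5 * 1.11)),
    list(m60c = "MUT", m60d = "MUT", m60e = "MUT"),
    list(m60c = "P60", m60d = "P60", m60e = "P60"))
  tab2 <- compute_relative_volumes(validate_volume_table(
    rbind(as.data.frame(tab)[names(extra)], extra)))
  dev <- deviation_from_trajectory(tab2, basis = "absolute")
  keep <- dev$deviations$subject %in% c("m60c", "m60d", "m60e")
  dev$deviations <- dev$deviations[keep, ]
  res <- deviation_tests(dev)
  row <- res$tests[res$tests$region == "pons", ]
  expect_equal(row$t, 10 / (1 / sqrt(3)), tolerance = 1e-6)
  expect_equal(row$category, "**")
  expect_true(row$significant)
  expect_true(is.na(row$q))

  withq <- deviation_tests(dev, fdr = TRUE)
  expect_false(any(is.na(withq$tests$q)))
  expect_true(all(withq$tests$q >= withq$tests$p))
})

test_that("all-zero deviations are untestable with the p = 1 convention", {
  flat <- make_group_table(list(WT_P7 = c(a = 5), WT_P60 = c(a = 10),
                                MUT_P7 = c(a = 6), MUT_P60 = c(a = 12)),
                           n = 3)
  res <- deviation_tests(deviation_from_trajectory(flat, basis = "absolute"))
  row <- res$tests[res$tests$region == "a", ]
  expect_true(row$untestable)
  expect_equal(row$p, 1)
  expect_false(row$significant)
})

test_that("a single-subject region is flagged untestable, not dropped", {
  tab <- hand_table()
  dev <- deviation_from_trajectory(tab, basis = "absolute")
  dev$deviations <- dev$deviations[dev$deviations$subject == "m60a", ]
  res <- deviation_tests(dev)
  expect_true("pons" %in% res$tests$region)
  expect_true(res$tests$untestable[res$tests$region == "pons"])
})

test_that("deviation report writes one row per region", {
  sim <- simulate_volume_study(volume_sim_config(n_per_group = 4, seed = 23))
  dev <- deviation_tests(deviation_from_trajectory(sim$table, basis = "relative"))
  path <- tempfile(fileext = ".csv")
  write_deviation_report(dev, path)
  rep <- read.csv(path)
  expect_equal(sort(rep$region),
               sort(c(names(sim$truth$regions), "whole_brain")))
  expect_true(all(c("w", "y_hat", "mean_x", "sem", "t", "p") %in% names(rep)))
})
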