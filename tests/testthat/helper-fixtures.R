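# Fixtures are always built in code.

# Minimal long volume table: values is a list keyed by subject, each a
# named vector of region volumes (whole_brain appended as the sum
# unless provided).
make_volume_df <- function(values, genotype, age) {
  rows <- lapply(names(values), function(s) {
    v <- values[[s]]
    if (!"whole_brain" %in% names(v)) {
      v <- c(v, whole_brain = sum(v))
    }
    data.frame(subject = s, genotype = genotype[[s]], age = age[[s]],
               region = names(v), volume_mm3 = unname(v),
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

# Two-genotype, two-age table from per-group region means with zero
# within-group variation (used for hand-arithmetic checks).
make_group_table <- function(means, n = 2) {
  # means: list like list(WT_P7 = c(a = 8, b = 4), WT_P60 = ..., ...)
  dfs <- list()
  for (key in names(means)) {
    parts <- strsplit(key, "_")[[1]]
    g <- parts[1]; a <- parts[2]
    for (i in seq_len(n)) {
      s <- sprintf("%s_%s_%d", g, a, i)
      dfs[[s]] <- make_volume_df(
        stats::setNames(list(means[[key]]), s),
        stats::setNames(list(g), s), stats::setNames(list(a), s))
    }
  }
  tab <- validate_volume_table(do.call(rbind, dfs))
  compute_relative_volumes(tab)
}

# Per-subject startle summary table from a matrix of means
# (subjects x dB), for group-level threshold tests.
make_startle_summary <- function(mean_matrix, genotype = NULL) {
  dbs <- as.numeric(colnames(mean_matrix))
  out <- do.call(rbind, lapply(seq_len(nrow(mean_matrix)), function(i) {
    data.frame(subject = rownames(mean_matrix)[i], stimulus_db = dbs,
               n_trials = 8, mean_amplitude = mean_matrix[i, ],
               log_amplitude = log10(pmax(mean_matrix[i, ], 0.01)),
               floored = FALSE, stringsAsFactors = FALSE)
  }))
  if (!is.null(genotype)) {
    out$genotype <- genotype[match(out$subject, rownames(mean_matrix))]
  }
  rownames(out) <- NULL
  out
}

expect_close <- function(object, expected, tol = 1e-9) {
  expect_true(all(abs(object - expected) <= tol),
              label = sprintf("max abs diff %g within %g",
                              max(abs(object - expected)), tol))
}
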