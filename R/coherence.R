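#' Growth-correlation divergence between genotypes
#'
#' Within each genotype, per-subject region growth indices are
#' correlated pairwise across regions (Pearson). Comparing the two
#' correlation grids at a significance level alpha classifies each
#' region pair as shared (significant in both genotypes), WT_only,
#' MUT_only, or neither — the coordinated-growth divergence analysis.
#'
#' @name coherence
NULL

#' Pairwise growth-index correlations for one genotype
#'
#' @param gim a `growth_index_matrix` from [growth_index()].
#' @param genotype which rows to use ("WT" or "MUT").
#' @return a `growth_corr` list: `r` and `p` matrices (NA diagonal),
#'   `n`, `genotype`, `basis`, and `defined` logical matrix (FALSE for
#'   zero-variance pairs).
#' @export
growth_correlation_matrix <- function(gim, genotype) {
  stopifnot(inherits(gim, "growth_index_matrix"))
  rows <- attr(gim, "genotype") == genotype
  if (sum(rows) < 3) stop("need >= 3 subjects of genotype ", genotype)
  m <- gim[rows, , drop = FALSE]
  k <- ncol(m)
  regions <- colnames(m)
  r <- p <- matrix(NA_real_, k, k, dimnames = list(regions, regions))
  defined <- matrix(FALSE, k, k, dimnames = list(regions, regions))
  for (i in seq_len(k - 1)) {
    for (j in seq((i + 1), k)) {
      pr <- pearson_r(m[, i], m[, j])
      r[i, j] <- r[j, i] <- pr$r
      p[i, j] <- p[j, i] <- pr$p
      defined[i, j] <- defined[j, i] <- pr$defined
    }
  }
  structure(list(r = r, p = p, defined = defined, n = sum(rows),
                 genotype = genotype, basis = attr(gim, "basis")),
            class = "growth_corr")
}

#' Classify region-pair correlations as shared or genotype-specific
#'
#' A pair is `shared` iff significant (p < alpha) in both genotypes,
#' `WT_only` / `MUT_only` if in exactly one, `neither` otherwise.
#' Pairs undefined in either genotype (zero variance) are excluded
#' from classification. `adjust = "BH"` applies Benjamini-Hochberg
#' across pairs within each genotype before thresholding.
#'
#' @param corr_wt,corr_mut `growth_corr` objects over the same regions.
#' @param alpha per-pair significance level.
#' @param adjust `"none"` (default) or `"BH"`.
#' @return a `divergence_map`: `pairs` data frame (region_a, region_b,
#'   r_wt, p_wt, r_mut, p_mut, class), `class_counts`, `alpha`, `basis`.
#' @export
classify_divergence <- function(corr_wt, corr_mut, alpha = 0.05,
                                adjust = c("none", "BH")) {
  adjust <- match.arg(adjust)
  stopifnot(inherits(corr_wt, "growth_corr"), inherits(corr_mut, "growth_corr"))
  regions <- rownames(corr_wt$r)
  if (!identical(sort(regions), sort(rownames(corr_mut$r)))) {
    stop("correlation grids cover different region sets")
  }
  regions_b <- rownames(corr_mut$r)
  idx <- which(upper.tri(corr_wt$r), arr.ind = TRUE)
  pairs <- data.frame(
    region_a = regions[idx[, 1]], region_b = regions[idx[, 2]],
    r_wt = corr_wt$r[idx], p_wt = corr_wt$p[idx],
    r_mut = corr_mut$r[cbind(match(regions[idx[, 1]], regions_b),
                             match(regions[idx[, 2]], regions_b))],
    p_mut = corr_mut$p[cbind(match(regions[idx[, 1]], regions_b),
                             match(regions[idx[, 2]], regions_b))],
    stringsAsFactors = FALSE)
  pairs$defined <- !is.na(pairs$p_wt) & !is.na(pairs$p_mut)

  p_wt <- pairs$p_wt
  p_mut <- pairs$p_mut
  if (adjust == "BH") {
    p_wt <- bh_fdr(p_wt)
    p_mut <- bh_fdr(p_mut)
  }
  sig_wt <- pairs$defined & p_wt < alpha
  sig_mut <- pairs$defined & p_mut < alpha
  pairs$class <- ifelse(!pairs$defined, NA_character_,
                 ifelse(sig_wt & sig_mut, "shared",
                 ifelse(sig_wt, "WT_only",
                 ifelse(sig_mut, "MUT_only", "neither"))))
  counts <- table(factor(pairs$class,
                         levels = c("shared", "WT_only", "MUT_only", "neither")))
  structure(list(pairs = pairs, class_counts = as.list(counts),
                 alpha = alpha, adjust = adjust, basis = corr_wt$basis),
            class = "divergence_map")
}

#' @export
print.divergence_map <- function(x, ...) {
  cc <- x$class_counts
  cat(sprintf(
    "Divergence map (%s basis, alpha = %g%s): %d pairs | shared %d, WT_only %d, MUT_only %d, neither %d\n",
    x$basis, x$alpha, if (x$adjust == "BH") ", BH" else "",
    nrow(x$pairs), cc$shared, cc$WT_only, cc$MUT_only, cc$neither))
  invisible(x)
}

#' Write divergence pairs CSV and class-count JSON
#' @param dmap a `divergence_map`.
#' @param csv_path,json_path output paths (NULL to skip either).
#' @export
write_divergence_report <- function(dmap, csv_path = NULL, json_path = NULL) {
  stopifnot(inherits(dmap, "divergence_map"))
  if (!is.null(csv_path)) {
    utils::write.csv(dmap$pairs, csv_path, row.names = FALSE)
  }
  if (!is.null(json_path)) {
    jsonlite::write_json(
      list(alpha = dmap$alpha, adjust = dmap$adjust, basis = dmap$basis,
           class_counts = dmap$class_counts),
      json_path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  }
  invisible(dmap)
}

#' Heatmap of the divergence classification
#'
#' Green = shared, purple = genotype-specific, grey = neither; requires
#' ggplot2.
#' @param dmap a `divergence_map`.
#' @return a ggplot object.
#' @export
plot_divergence_map <- function(dmap) {
  if (!requireNamespace("ggplot2", quietly = TRUE)) {
    stop("ggplot2 is required for plotting")
  }
  pp <- dmap$pairs
  both <- rbind(pp, data.frame(region_a = pp$region_b, region_b = pp$region_a,
                               pp[setdiff(names(pp), c("region_a", "region_b"))]))
  ggplot2::ggplot(both, ggplot2::aes(x = .data$region_a, y = .data$region_b,
                                     fill = .data$class)) +
    ggplot2::geom_tile() +
    ggplot2::scale_fill_manual(values = c(
      shared = "#1b9e77", WT_only = "#7b3294", MUT_only = "#c2a5cf",
      neither = "grey85"), na.value = "white") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 45, hjust = 1)) +
    ggplot2::labs(x = NULL, y = NULL, fill = "class")
}
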