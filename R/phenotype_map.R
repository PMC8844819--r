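#' Region-status to behavior concordance mapping
#'
#' Volumetric outcomes per region (increased / decreased / unchanged
#' relative to the trajectory prediction) are joined to a literature
#' behavior-to-region association table to evaluate the predictive
#' claim that behaviors supported by relatively enlarged regions show
#' phenotypes.
#'
#' @name phenotype_map
NULL

#' Classify regions by their trajectory-deviation outcome
#'
#' increased if p < alpha and mean deviation > 0; decreased if p <
#' alpha and mean deviation < 0; unchanged otherwise. Untestable
#' regions are unchanged with a flag.
#'
#' @param dev a tested `trajectory_deviation` (relative basis is the
#'   conventional input).
#' @param alpha significance level.
#' @return data frame: region, mean_x, p, status, untestable.
#' @export
classify_region_status <- function(dev, alpha = 0.05) {
  stopifnot(inherits(dev, "trajectory_deviation"))
  if (is.null(dev$tests)) stop("run deviation_tests() first")
  tt <- dev$tests
  status <- ifelse(tt$untestable | is.na(tt$p) | tt$p >= alpha, "unchanged",
            ifelse(tt$mean_x > 0, "increased", "decreased"))
  data.frame(region = tt$region, mean_x = tt$mean_x, p = tt$p,
             status = status, untestable = tt$untestable,
             stringsAsFactors = FALSE)
}

#' Read a behavior-to-region association table
#'
#' CSV with header `behavior,regions,observed`; `regions` is a
#' semicolon-separated list, `observed` one of abnormal / normal /
#' untested.
#'
#' @param path CSV path.
#' @return data frame with a list-column `regions`.
#' @export
read_association_table <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("behavior", "regions", "observed")
  miss <- setdiff(need, names(df))
  if (length(miss)) stop("missing column(s): ", paste(miss, collapse = ", "))
  bad <- setdiff(unique(tolower(df$observed)), c("abnormal", "normal", "untested"))
  if (length(bad)) stop("unknown observed label(s): ", paste(bad, collapse = ", "))
  df$observed <- tolower(df$observed)
  df$regions <- lapply(strsplit(df$regions, ";"), trimws)
  df
}

#' Predicted-phenotype concordance report
#'
#' Each behavior is predicted abnormal when its associated regions'
#' statuses satisfy `rule` ("any" increased, "majority" increased, or
#' "all" increased); behaviors whose regions all lack a status are
#' excluded and listed. Over tested behaviors a 2x2
#' predicted x observed tally is built, with an exploratory Fisher
#' exact test.
#'
#' @param assoc association table from [read_association_table()] (or a
#'   data frame of the same shape).
#' @param status region-status data frame from
#'   [classify_region_status()], or a named character vector.
#' @param rule prediction rule: `"any"` (default), `"majority"`, `"all"`.
#' @return a `concordance_report`: per_behavior data frame, `table`
#'   (2x2 matrix predicted x observed), `fisher_p`, `excluded`.
#' @export
predict_phenotype_concordance <- function(assoc, status,
                                          rule = c("any", "majority", "all")) {
  rule <- match.arg(rule)
  if (is.data.frame(status)) {
    status <- stats::setNames(status$status, status$region)
  }
  rows <- list(); excluded <- character(0)
  for (i in seq_len(nrow(assoc))) {
    regs <- assoc$regions[[i]]
    st <- status[regs]
    known <- !is.na(st)
    if (!any(known)) {
      excluded <- c(excluded, assoc$behavior[i])
      next
    }
    inc <- st[known] == "increased"
    predicted <- switch(rule,
      any = any(inc),
      majority = mean(inc) > 0.5,
      all = all(inc))
    rows[[length(rows) + 1]] <- data.frame(
      behavior = assoc$behavior[i],
      n_regions = sum(known),
      n_increased = sum(inc),
      predicted = if (predicted) "abnormal" else "unpredicted",
      observed = assoc$observed[i],
      stringsAsFactors = FALSE)
  }
  per <- do.call(rbind, rows)
  tested <- per[per$observed != "untested", , drop = FALSE]
  tab <- table(factor(tested$predicted, levels = c("abnormal", "unpredicted")),
               factor(tested$observed, levels = c("abnormal", "normal")))
  fisher_p <- if (all(dim(tab) == c(2, 2)) && sum(tab) > 0) {
    stats::fisher.test(tab)$p.value
  } else NA_real_
  structure(list(per_behavior = per, table = as.matrix(tab),
                 fisher_p = fisher_p, rule = rule, excluded = excluded),
            class = "concordance_report")
}

#' @export
print.concordance_report <- function(x, ...) {
  cat(sprintf("Concordance (%s-increased rule): %d behaviors tested, %d excluded\n",
              x$rule, sum(x$table), length(x$excluded)))
  print(x$table)
  cat(sprintf("Exploratory Fisher exact p = %.4g\n", x$fisher_p))
  invisible(x)
}

#' Write the concordance report as JSON
#' @param rep a `concordance_report`.
#' @param path output path.
#' @export
write_concordance_report <- function(rep, path) {
  stopifnot(inherits(rep, "concordance_report"))
  jsonlite::write_json(
    list(rule = rep$rule,
         per_behavior = rep$per_behavior,
         table = list(
           predicted_abnormal_observed_abnormal = rep$table["abnormal", "abnormal"],
           predicted_abnormal_observed_normal = rep$table["abnormal", "normal"],
           unpredicted_observed_abnormal = rep$table["unpredicted", "abnormal"],
           unpredicted_observed_normal = rep$table["unpredicted", "normal"]),
         fisher_p = rep$fisher_p,
         excluded = rep$excluded),
    path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}
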