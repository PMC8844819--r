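#' Region-volume table I/O and validation
#'
#' The canonical input is a long (tidy) CSV/TSV with header
#' `subject,genotype,age,region,volume_mm3`, one row per
#' (subject, region), including one reserved `whole_brain` row per
#' subject. Genotype and age labels are normalized case-insensitively to
#' the enums WT/MUT and P7/P60.
#'
#' @name volumetrics_io
NULL

#' Reserved region label for the whole-brain row
#' @export
WHOLE_BRAIN <- "whole_brain"

#' Default region manifest used by the simulators
#'
#' Twelve named gray-matter regions spanning hindbrain, midbrain and
#' forebrain; user-overridable everywhere a manifest is accepted.
#' @export
DEFAULT_REGIONS <- c(
  "pons", "inferior_colliculus", "medulla", "superior_colliculus",
  "hypothalamus", "medial_septum", "frontal_lobe", "cerebellar_cortex",
  "striatum", "nucleus_accumbens", "hippocampus", "thalamus")

norm_genotype <- function(g) {
  g <- toupper(trimws(as.character(g)))
  map <- c("WT" = "WT", "MUT" = "MUT",
           "WILDTYPE" = "WT", "WILD-TYPE" = "WT", "WILD_TYPE" = "WT",
           "HET" = "MUT", "MUTANT" = "MUT")
  out <- unname(map[g])
  if (anyNA(out)) {
    stop("unrecognized genotype label(s): ",
         paste(unique(g[is.na(out)]), collapse = ", "))
  }
  out
}

norm_age <- function(a) {
  a <- toupper(trimws(as.character(a)))
  if (!all(a %in% c("P7", "P60"))) {
    stop("unrecognized age label(s): ",
         paste(setdiff(unique(a), c("P7", "P60")), collapse = ", "))
  }
  a
}

#' Validate a long region-volume data frame
#'
#' Checks column presence, positive volumes, one age and one genotype per
#' subject, at most one row per (subject, region), and a `whole_brain`
#' row for every subject. Returns the table in deterministic
#' (subject, region) order with normalized labels.
#'
#' @param df data frame with columns subject, genotype, age, region,
#'   volume_mm3.
#' @param region_manifest character vector of allowed region labels
#'   (exclusive of `whole_brain`), or NULL to accept all.
#' @param strict if TRUE (default), regions absent from the manifest are
#'   an error; if FALSE they are kept and flagged in
#'   `attr(x, "unknown_regions")`.
#' @return validated data frame of class `region_volume_table`.
#' @export
validate_volume_table <- function(df, region_manifest = NULL, strict = TRUE) {
  need <- c("subject", "genotype", "age", "region", "volume_mm3")
  miss <- setdiff(need, names(df))
  if (length(miss)) stop("missing column(s): ", paste(miss, collapse = ", "))
  df <- as.data.frame(df)[need]
  df$subject <- as.character(df$subject)
  df$region <- trimws(as.character(df$region))
  df$genotype <- norm_genotype(df$genotype)
  df$age <- norm_age(df$age)
  df$volume_mm3 <- as.numeric(df$volume_mm3)

  bad <- which(!is.finite(df$volume_mm3) | df$volume_mm3 <= 0)
  if (length(bad)) {
    stop(sprintf("non-positive or non-finite volume for subject '%s', region '%s'",
                 df$subject[bad[1]], df$region[bad[1]]))
  }
  dup <- duplicated(df[c("subject", "region")])
  if (any(dup)) {
    stop(sprintf("duplicate (subject, region) row: subject '%s', region '%s'",
                 df$subject[which(dup)[1]], df$region[which(dup)[1]]))
  }
  # one genotype and one age per subject
  for (col in c("genotype", "age")) {
    k <- tapply(df[[col]], df$subject, function(v) length(unique(v)))
    if (any(k > 1)) {
      stop(sprintf("subject '%s' has more than one %s label",
                   names(k)[which(k > 1)[1]], col))
    }
  }
  has_wb <- tapply(df$region, df$subject, function(r) WHOLE_BRAIN %in% r)
  if (!all(has_wb)) {
    stop("missing whole_brain row for subject(s): ",
         paste(names(has_wb)[!has_wb], collapse = ", "))
  }
  unknown <- character(0)
  if (!is.null(region_manifest)) {
    unknown <- setdiff(unique(df$region), c(region_manifest, WHOLE_BRAIN))
    if (length(unknown) && strict) {
      stop("region(s) not in manifest: ", paste(unknown, collapse = ", "))
    }
  }
  df <- df[order(df$subject, df$region), , drop = FALSE]
  rownames(df) <- NULL
  class(df) <- c("region_volume_table", "data.frame")
  attr(df, "unknown_regions") <- unknown
  df
}

#' Read a long region-volume CSV/TSV
#'
#' @param path file path; `.tsv`/`.txt` is read tab-separated, else comma.
#' @param region_manifest,strict see [validate_volume_table()].
#' @return validated `region_volume_table` with `rel_volume` populated.
#' @export
read_volume_table <- function(path, region_manifest = NULL, strict = TRUE) {
  if (!file.exists(path)) stop("file not found: ", path)
  sep <- if (grepl("\\.(tsv|txt)$", path, ignore.case = TRUE)) "\t" else ","
  df <- utils::read.table(path, header = TRUE, sep = sep,
                          stringsAsFactors = FALSE)
  tab <- validate_volume_table(df, region_manifest, strict)
  compute_relative_volumes(tab)
}

#' Read a wide region x subject volume matrix
#'
#' Convenience for hand-edited wide tables: first columns
#' `subject,genotype,age`, one further column per region (including
#' `whole_brain`). Converted internally to the canonical long form.
#'
#' @inheritParams read_volume_table
#' @export
read_volume_table_wide <- function(path, region_manifest = NULL, strict = TRUE) {
  if (!file.exists(path)) stop("file not found: ", path)
  sep <- if (grepl("\\.(tsv|txt)$", path, ignore.case = TRUE)) "\t" else ","
  w <- utils::read.table(path, header = TRUE, sep = sep,
                         stringsAsFactors = FALSE, check.names = FALSE)
  id <- c("subject", "genotype", "age")
  miss <- setdiff(id, names(w))
  if (length(miss)) stop("missing column(s): ", paste(miss, collapse = ", "))
  regions <- setdiff(names(w), id)
  long <- do.call(rbind, lapply(regions, function(r) {
    data.frame(subject = w$subject, genotype = w$genotype, age = w$age,
               region = r, volume_mm3 = as.numeric(w[[r]]),
               stringsAsFactors = FALSE)
  }))
  tab <- validate_volume_table(long, region_manifest, strict)
  compute_relative_volumes(tab)
}

#' Compute relative volumes (percent of whole brain)
#'
#' rel_volume = volume_mm3 / whole-brain volume x 100 per subject; the
#' whole-brain row's own relative volume is exactly 100.
#'
#' @param tab a `region_volume_table`.
#' @return the table with a `rel_volume` column added/updated.
#' @export
compute_relative_volumes <- function(tab) {
  stopifnot(inherits(tab, "region_volume_table"))
  wb_rows <- tab$region == WHOLE_BRAIN
  wb <- tab$volume_mm3[wb_rows]
  names(wb) <- tab$subject[wb_rows]
  tab$rel_volume <- tab$volume_mm3 / wb[tab$subject] * 100
  tab$rel_volume[wb_rows] <- 100
  tab
}

#' Write a region-volume table to CSV
#'
#' Only the canonical five columns are written; relative volumes are
#' recomputed on read.
#' @param tab a `region_volume_table`.
#' @param path output path.
#' @export
write_volume_table <- function(tab, path) {
  stopifnot(inherits(tab, "region_volume_table"))
  cols <- c("subject", "genotype", "age", "region", "volume_mm3")
  out <- as.data.frame(tab)[cols]
  # full double precision so a write/read round-trip is bit-exact
  out$volume_mm3 <- sprintf("%.17g", out$volume_mm3)
  utils::write.csv(out, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Export a validated table as JSON
#' @param tab a `region_volume_table`.
#' @param path output path.
#' @export
volume_table_to_json <- function(tab, path) {
  stopifnot(inherits(tab, "region_volume_table"))
  jsonlite::write_json(as.data.frame(tab), path, digits = NA, pretty = TRUE)
  invisible(path)
}

#' Region labels present in a table (excluding whole brain)
#' @param tab a `region_volume_table`.
#' @export
volume_regions <- function(tab) {
  sort(setdiff(unique(tab$region), WHOLE_BRAIN))
}
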