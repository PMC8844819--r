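#' Formula-defined behavioral indices
#'
#' Novel-object recognition, three-chamber social approach, and
#' puzzle-box scores, all simple normalized-time formulas plus their
#' group-level tests.
#'
#' @name behavior_scores
NULL

#' Novel-object discrimination index and percent investigation
#'
#' DI = (novel - familiar) / (novel + familiar) x 100, in
#' \[-100, 100\]; percent investigation of each object sums to 100;
#' percent of trial spent investigating = (novel + familiar) /
#' trial duration x 100 when a duration is supplied.
#'
#' @param time_novel,time_familiar investigation times (s, >= 0).
#' @param trial_duration total trial time (s), optional.
#' @return list(di, pct_novel, pct_familiar, pct_investigating,
#'   defined); zero total investigation yields `defined = FALSE` with
#'   NA scores.
#' @export
discrimination_index <- function(time_novel, time_familiar,
                                 trial_duration = NA_real_) {
  stopifnot(time_novel >= 0, time_familiar >= 0)
  tot <- time_novel + time_familiar
  if (!is.na(trial_duration) && tot > trial_duration) {
    stop("investigation times exceed trial duration")
  }
  if (tot == 0) {
    return(list(di = NA_real_, pct_novel = NA_real_, pct_familiar = NA_real_,
                pct_investigating = 0, defined = FALSE))
  }
  list(di = (time_novel - time_familiar) / tot * 100,
       pct_novel = time_novel / tot * 100,
       pct_familiar = time_familiar / tot * 100,
       pct_investigating = if (is.na(trial_duration)) NA_real_
                           else tot / trial_duration * 100,
       defined = TRUE)
}

#' Three-chamber social preference index
#'
#' (time in mouse+tube chamber - time in empty-tube chamber) /
#' (sum of the two) and, by default, x 100 for comparability with the
#' usual presentation; `scale100 = FALSE` gives the raw -1..1 index.
#'
#' @param time_mouse_tube,time_empty_tube chamber times (s, >= 0).
#' @param scale100 report on the x100 scale (default TRUE).
#' @return list(index, defined).
#' @export
preference_index <- function(time_mouse_tube, time_empty_tube,
                             scale100 = TRUE) {
  stopifnot(time_mouse_tube >= 0, time_empty_tube >= 0)
  tot <- time_mouse_tube + time_empty_tube
  if (tot == 0) return(list(index = NA_real_, defined = FALSE))
  idx <- (time_mouse_tube - time_empty_tube) / tot
  list(index = if (scale100) idx * 100 else idx, defined = TRUE)
}

#' Group-level social-preference dichotomy
#'
#' A group "shows social preference" when the paired t test between
#' the per-subject mouse-chamber and empty-chamber time vectors is
#' significant with more time in the social chamber.
#'
#' @param time_mouse_tube,time_empty_tube per-subject time vectors.
#' @param alpha significance level.
#' @return list(preference, test, mean_index) where `test` is a
#'   `gp_test` and `mean_index` the group mean preference index (x100).
#' @export
social_preference <- function(time_mouse_tube, time_empty_tube, alpha = 0.05) {
  stopifnot(length(time_mouse_tube) == length(time_empty_tube))
  if (length(time_mouse_tube) < 2) stop("need >= 2 subjects")
  tt <- t_test(time_mouse_tube, time_empty_tube, kind = "paired")
  idx <- mapply(function(m, e) preference_index(m, e)$index,
                time_mouse_tube, time_empty_tube)
  list(preference = !tt$untestable && tt$p < alpha &&
                    mean(time_mouse_tube) > mean(time_empty_tube),
       test = tt, mean_index = mean(idx, na.rm = TRUE))
}

#' Puzzle-box percent of maximum time
#'
#' latency / maximum time x 100, in \[0, 100\]. Non-completers
#' (latency above the maximum) are clamped to 100 and flagged.
#'
#' @param latency latency to enter the goal zone (s).
#' @param max_time maximum allowed time (s, > 0).
#' @return list(percent, completed, clamped).
#' @export
percent_max_time <- function(latency, max_time) {
  stopifnot(max_time > 0, latency >= 0)
  clamped <- latency > max_time
  pct <- pmin(latency, max_time) / max_time * 100
  list(percent = pct, completed = latency <= max_time, clamped = clamped)
}

#' Condition-level puzzle-box summary
#'
#' Mean percent-of-maximum-time over a condition's trials, the
#' completion fraction, and (for the habituation condition) the change
#' score between the first two trials.
#'
#' @param latencies per-trial latencies (s) within one condition.
#' @param max_time maximum allowed time (s).
#' @return list(mean_percent, completion_fraction, change_score
#'   (trial1 - trial2 latency, NA with < 2 trials), n_trials).
#' @export
puzzle_condition_score <- function(latencies, max_time) {
  res <- lapply(latencies, percent_max_time, max_time = max_time)
  pct <- vapply(res, `[[`, numeric(1), "percent")
  comp <- vapply(res, `[[`, logical(1), "completed")
  list(mean_percent = mean(pct),
       completion_fraction = mean(comp),
       change_score = if (length(latencies) >= 2) {
         latencies[1] - latencies[2]
       } else NA_real_,
       n_trials = length(latencies))
}
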