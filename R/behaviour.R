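#' Score Go/NoGo trials from stimuli and button presses
#'
#' Each response is assigned to the latest stimulus whose onset precedes it
#' (the response window of a trial closes at the next stimulus onset). Go
#' trials without a response in their window are misses; NoGo trials with a
#' response are false alarms. Reaction times are measured from stimulus
#' onset; trials with RT below 300 ms are marked `excluded` and count
#' towards neither correct nor error tallies.
#'
#' @param stimuli Tibble ordered by onset with `onset_s`, `offset_s`,
#'   `is_nogo` and optionally `task`, `block` (carried through). Stimuli
#'   must not overlap.
#' @param responses Tibble of button presses with `time_s` (same time base).
#' @param rt_exclusion_ms Minimum RT in milliseconds (default 300).
#' @return A tibble of trials: input columns plus `trial` (index),
#'   `response_time_s`, `rt_ms`, and
#'   `outcome` in `correct_go`, `miss`, `correct_nogo`, `false_alarm`,
#'   `excluded`.
#' @export
score_trials <- function(stimuli, responses, rt_exclusion_ms = 300) {
  stopifnot(all(c("onset_s", "offset_s", "is_nogo") %in% names(stimuli)))
  stimuli <- dplyr::arrange(stimuli, .data$onset_s)
  if (nrow(stimuli) > 1 &&
      any(stimuli$offset_s[-nrow(stimuli)] > stimuli$onset_s[-1] + 1e-9)) {
    stop("Overlapping stimuli")
  }
  n <- nrow(stimuli)
  next_onset <- c(stimuli$onset_s[-1], Inf)
  rt_first <- rep(NA_real_, n)
  if (nrow(responses) > 0) {
    rtimes <- sort(responses$time_s)
    idx <- findInterval(rtimes, stimuli$onset_s)
    ok <- idx >= 1
    for (k in which(ok)) {
      i <- idx[k]
      if (rtimes[k] < next_onset[i] && is.na(rt_first[i])) {
        rt_first[i] <- rtimes[k]
      }
    }
  }
  rt_ms <- (rt_first - stimuli$onset_s) * 1000
  outcome <- dplyr::case_when(
    !is.na(rt_ms) & rt_ms < rt_exclusion_ms ~ "excluded",
    stimuli$is_nogo & !is.na(rt_ms) ~ "false_alarm",
    stimuli$is_nogo ~ "correct_nogo",
    !is.na(rt_ms) ~ "correct_go",
    TRUE ~ "miss"
  )
  dplyr::mutate(stimuli,
                trial = dplyr::row_number(),
                response_time_s = rt_first,
                rt_ms = rt_ms,
                outcome = outcome)
}

#' Pre-probe behavioural summaries
#'
#' For each probe, summarizes the scored trials whose onset falls in the
#' window `[probe onset - window_s, probe onset)`, optionally split into
#' `n_subwindows` equal sub-windows (e.g. four 5-s sub-windows of the 20-s
#' window). Excluded trials enter no denominator. Rates are `NA` when their
#' denominator is zero.
#'
#' @param trials Scored trials from [score_trials()] (with `task`, `block`
#'   columns if the probes carry them).
#' @param probes Tibble with `probe_id`, `onset_s` and optionally `task`,
#'   `block`, `mental_state`, `vigilance` (carried through).
#' @param window_s Pre-probe window length in seconds (default 20).
#' @param n_subwindows Number of equal sub-windows (default 1).
#' @return A tibble with one row per probe (by sub-window): probe columns
#'   plus `subwindow`, `window_start_s`, `window_end_s`, `n_go`, `n_nogo`,
#'   `n_miss`, `n_fa`, `n_excluded`, `miss_rate`, `fa_rate`, `mean_rt_ms`.
#' @export
preprobe_summary <- function(trials, probes, window_s = 20,
                             n_subwindows = 1) {
  stopifnot(window_s > 0, n_subwindows >= 1)
  by_cols <- intersect(c("task", "block"), intersect(names(trials),
                                                     names(probes)))
  sub_len <- window_s / n_subwindows
  grid <- tidyr::expand_grid(probes, subwindow = seq_len(n_subwindows)) |>
    dplyr::mutate(
      window_start_s = .data$onset_s - window_s +
        (.data$subwindow - 1) * sub_len,
      window_end_s = .data$window_start_s + sub_len)
  joined <- dplyr::inner_join(
    grid, dplyr::rename(trials, trial_onset_s = "onset_s"),
    by = by_cols, relationship = "many-to-many") |>
    dplyr::filter(.data$trial_onset_s >= .data$window_start_s,
                  .data$trial_onset_s < .data$window_end_s)
  stats_tbl <- joined |>
    dplyr::group_by(.data$probe_id, .data$subwindow) |>
    dplyr::summarise(
      n_go = sum(!.data$is_nogo & .data$outcome != "excluded"),
      n_nogo = sum(.data$is_nogo & .data$outcome != "excluded"),
      n_miss = sum(.data$outcome == "miss"),
      n_fa = sum(.data$outcome == "false_alarm"),
      n_excluded = sum(.data$outcome == "excluded"),
      mean_rt_ms = mean(.data$rt_ms[.data$outcome == "correct_go"]),
      .groups = "drop")
  grid |>
    dplyr::left_join(stats_tbl, by = c("probe_id", "subwindow")) |>
    dplyr::mutate(
      dplyr::across(dplyr::all_of(c("n_go", "n_nogo", "n_miss", "n_fa",
                                    "n_excluded")),
                    ~ dplyr::coalesce(.x, 0L)),
      miss_rate = ifelse(.data$n_go > 0, .data$n_miss / .data$n_go,
                         NA_real_),
      fa_rate = ifelse(.data$n_nogo > 0, .data$n_fa / .data$n_nogo,
                       NA_real_),
      mean_rt_ms = ifelse(is.nan(.data$mean_rt_ms), NA_real_,
                          .data$mean_rt_ms))
}

#' Blink-correct a pupil trace
#'
#' Replaces blink segments, extended by a margin on each side, with linear
#' interpolation between the flanking valid samples (edge blinks are filled
#' with the nearest valid value).
#'
#' @param pupil Tibble with `time_s`, `size` (`NA` during blinks) and
#'   optionally `is_blink` (defaults to `is.na(size)`).
#' @param blink_margin_s Margin in seconds interpolated around each blink
#'   (default 0.1).
#' @return The tibble with `size` cleaned and a `was_interpolated` column.
#' @export
preprocess_pupil <- function(pupil, blink_margin_s = 0.1) {
  stopifnot(all(c("time_s", "size") %in% names(pupil)))
  blink <- if ("is_blink" %in% names(pupil)) pupil$is_blink | is.na(pupil$size)
  else is.na(pupil$size)
  if (all(blink)) stop("Pupil trace is entirely missing")
  if (!any(blink)) {
    return(dplyr::mutate(pupil, was_interpolated = FALSE))
  }
  dt <- stats::median(diff(pupil$time_s))
  margin_n <- round(blink_margin_s / dt)
  mask <- blink
  if (margin_n > 0) {
    idx <- which(blink)
    ext <- unique(pmin(pmax(rep(idx, each = 2 * margin_n + 1) +
                              rep(-margin_n:margin_n, length(idx)), 1),
                       length(mask)))
    mask[ext] <- TRUE
  }
  good <- which(!mask)
  filled <- stats::approx(pupil$time_s[good], pupil$size[good],
                          xout = pupil$time_s, rule = 2)$y
  out <- pupil
  out$size <- ifelse(mask, filled, pupil$size)
  out$was_interpolated <- mask
  out
}

#' Mean pupil size per trial
#'
#' Averages the cleaned pupil trace over each stimulus presentation window
#' `[onset_s, offset_s)`.
#'
#' @param pupil Cleaned pupil tibble ([preprocess_pupil()]).
#' @param trials Tibble with `onset_s`, `offset_s` (and an optional `trial`
#'   index, created if absent).
#' @return `trials` with a `pupil_mean` column.
#' @export
pupil_trial_means <- function(pupil, trials) {
  if (!"trial" %in% names(trials)) {
    trials <- dplyr::mutate(trials, trial = dplyr::row_number())
  }
  means <- vapply(seq_len(nrow(trials)), function(i) {
    sel <- pupil$time_s >= trials$onset_s[i] &
      pupil$time_s < trials$offset_s[i]
    if (!any(sel)) return(NA_real_)
    mean(pupil$size[sel])
  }, numeric(1))
  dplyr::mutate(trials, pupil_mean = means)
}

#' Mean pupil size per probe
#'
#' Averages the per-trial pupil means over the trials within `window_s`
#' seconds before each probe onset.
#'
#' @param trial_means Output of [pupil_trial_means()].
#' @param probes Probe tibble (`probe_id`, `onset_s`, optional `task`,
#'   `block`).
#' @param window_s Pre-probe window (default 20 s).
#' @return `probes` with a `pupil_mean` column.
#' @export
pupil_probe_means <- function(trial_means, probes, window_s = 20) {
  by_cols <- intersect(c("task", "block"),
                       intersect(names(trial_means), names(probes)))
  joined <- dplyr::inner_join(
    probes, dplyr::rename(trial_means, trial_onset_s = "onset_s"),
    by = by_cols, relationship = "many-to-many") |>
    dplyr::filter(.data$trial_onset_s >= .data$onset_s - window_s,
                  .data$trial_onset_s < .data$onset_s) |>
    dplyr::group_by(.data$probe_id) |>
    dplyr::summarise(pupil_mean = mean(.data$pupil_mean, na.rm = TRUE),
                     .groups = "drop")
  dplyr::left_join(probes, joined, by = "probe_id")
}

#' Discretize per-probe pupil size into quantile bins
#'
#' Assigns each probe's mean pupil size to one of `n_bins` quantile bins,
#' separately per participant and task (normalizing pupil size across
#' participants). Bin labels are non-decreasing in pupil size; ties share
#' the lower bin; with distinct values the bin counts differ by at most one.
#' Groups with fewer than `n_bins` non-missing values get `NA` bins with a
#' warning.
#'
#' @param probe_means Tibble with `pupil_mean` and grouping columns.
#' @param n_bins Number of bins (default 5).
#' @param by Grouping columns (default those of `participant`, `task`
#'   present).
#' @return The input with a `pupil_bin` column (integer 1..`n_bins`).
#' @export
discretize_pupil <- function(probe_means, n_bins = 5, by = NULL) {
  if (is.null(by)) {
    by <- intersect(c("participant", "task"), names(probe_means))
  }
  bin_group <- function(x) {
    ok <- !is.na(x)
    out <- rep(NA_integer_, length(x))
    if (sum(ok) < n_bins) {
      warning("Fewer than ", n_bins,
              " non-missing pupil values in a group; bins set to NA")
      return(out)
    }
    r <- rank(x[ok], ties.method = "min")
    out[ok] <- as.integer(floor((r - 1) * n_bins / sum(ok)) + 1)
    out
  }
  probe_means |>
    dplyr::group_by(dplyr::across(dplyr::all_of(by))) |>
    dplyr::mutate(pupil_bin = bin_group(.data$pupil_mean)) |>
    dplyr::ungroup()
}
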