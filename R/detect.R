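#' Extract candidate slow waves from one filtered channel
#'
#' Candidate waves are negative half-waves followed by a positive rebound,
#' delimited by zero-crossings: the wave starts at the last non-negative
#' sample before the negative excursion, has its negative peak at the most
#' negative sample (earliest on exact ties), its positive peak at the maximum
#' of the following positive excursion, and ends at the first non-positive
#' sample after that excursion. Crossing times are sample times (no
#' sub-sample interpolation). Negative excursions without a following
#' positive rebound are not candidates.
#'
#' @param x Numeric vector: one channel of mastoid-referenced, delta-band
#'   filtered EEG, in microvolts.
#' @param fs Sampling rate of `x` in Hz.
#' @param channel Channel label recorded in the output.
#' @return A tibble with one row per candidate wave and columns `channel`,
#'   `start_s`, `neg_peak_s`, `pos_peak_s`, `end_s`, `neg_peak_amp`,
#'   `pos_peak_amp`, `p2p_amp`, `down_slope`, `up_slope`, ordered by
#'   `start_s` and non-overlapping.
#' @export
extract_candidate_waves <- function(x, fs, channel = "chan") {
  stopifnot(is.numeric(x), all(is.finite(x)), fs > 0)
  n <- length(x)
  t <- (seq_len(n) - 1) / fs
  neg <- x < 0
  if (!any(neg)) return(empty_wave_tbl())
  r <- rle(neg)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1
  neg_runs <- which(r$values)
  rows <- vector("list", length(neg_runs))
  k <- 0L
  prev_end_idx <- 0L
  for (ri in neg_runs) {
    i1 <- starts[ri]; i2 <- ends[ri]
    if (i1 == 1L) next                      # no preceding zero-crossing
    start_idx <- max(i1 - 1L, prev_end_idx) # keep waves non-overlapping
    # first positive excursion after the negative run, with no negative
    # sample in between (zeros may intervene)
    j <- i2 + 1L
    while (j <= n && x[j] == 0) j <- j + 1L
    if (j > n || x[j] < 0) next
    j1 <- j
    j2 <- j1
    while (j2 < n && x[j2 + 1L] > 0) j2 <- j2 + 1L
    if (j2 == n) next                       # no closing zero-crossing
    end_idx <- j2 + 1L
    np <- i1 - 1L + which.min(x[i1:i2])     # earliest on ties
    pp <- j1 - 1L + which.max(x[j1:j2])
    if (np <= start_idx) next               # degenerate after overlap trim
    k <- k + 1L
    rows[[k]] <- c(start_idx, np, pp, end_idx)
    prev_end_idx <- end_idx
  }
  if (k == 0L) return(empty_wave_tbl())
  idx <- do.call(rbind, rows[seq_len(k)])
  neg_amp <- x[idx[, 2]]
  pos_amp <- x[idx[, 3]]
  tibble::tibble(
    channel = channel,
    start_s = t[idx[, 1]],
    neg_peak_s = t[idx[, 2]],
    pos_peak_s = t[idx[, 3]],
    end_s = t[idx[, 4]],
    neg_peak_amp = neg_amp,
    pos_peak_amp = pos_amp,
    p2p_amp = pos_amp - neg_amp,
    down_slope = abs(neg_amp) / (t[idx[, 2]] - t[idx[, 1]]),
    up_slope = (pos_amp - neg_amp) / (t[idx[, 3]] - t[idx[, 2]])
  )
}

empty_wave_tbl <- function() {
  tibble::tibble(
    channel = character(), start_s = numeric(), neg_peak_s = numeric(),
    pos_peak_s = numeric(), end_s = numeric(), neg_peak_amp = numeric(),
    pos_peak_amp = numeric(), p2p_amp = numeric(), down_slope = numeric(),
    up_slope = numeric()
  )
}

#' Exclude artifact-like candidate waves
#'
#' Applies the three exclusion rules of the detector, on the same filtered
#' signal the candidates were extracted from: waves with a positive peak
#' above `max_pos_peak` microvolts (blink guard); waves whose span lies
#' within `artifact_margin` seconds of any sample exceeding
#' `artifact_abs_amp` microvolts in absolute amplitude; and waves shorter
#' than `min_duration` seconds.
#'
#' @param candidates Candidate tibble from [extract_candidate_waves()].
#' @param x The filtered channel the candidates came from.
#' @param fs Sampling rate of `x` (Hz).
#' @param params A [detection_params()].
#' @return The retained subset of `candidates` (always a subset, same
#'   columns).
#' @export
filter_waves <- function(candidates, x, fs, params = detection_params()) {
  if (nrow(candidates) == 0) return(candidates)
  keep <- candidates$pos_peak_amp <= params$max_pos_peak
  keep <- keep &
    (candidates$end_s - candidates$start_s) >= params$min_duration
  bad_t <- ((which(abs(x) > params$artifact_abs_amp)) - 1) / fs
  if (length(bad_t) > 0) {
    near <- vapply(seq_len(nrow(candidates)), function(i) {
      any(bad_t >= candidates$start_s[i] - params$artifact_margin &
            bad_t <= candidates$end_s[i] + params$artifact_margin)
    }, logical(1))
    keep <- keep & !near
  }
  candidates[keep, , drop = FALSE]
}

#' Select the highest-amplitude waves per electrode
#'
#' Retains, independently for each channel, the `top_fraction` of candidate
#' waves with the highest peak-to-peak amplitude (count rounded up so a
#' non-empty candidate set always retains at least one wave). The retained
#' amplitudes per channel are all at least as large as any discarded one.
#'
#' @param candidates Candidate tibble (post-exclusion).
#' @param top_fraction Fraction retained per channel (default 0.10).
#' @return The retained waves, with an attribute `thresholds`: a tibble
#'   (`channel`, `threshold`, `n_candidates`, `n_retained`) where `threshold`
#'   is the smallest retained peak-to-peak amplitude in microvolts. See also
#'   [top_amplitude_thresholds()].
#' @export
select_top_amplitude <- function(candidates, top_fraction = 0.10) {
  stopifnot(top_fraction > 0, top_fraction <= 1)
  if (nrow(candidates) == 0) {
    out <- candidates
    attr(out, "thresholds") <- tibble::tibble(
      channel = character(), threshold = numeric(),
      n_candidates = integer(), n_retained = integer())
    return(out)
  }
  out <- candidates |>
    dplyr::group_by(.data$channel) |>
    dplyr::arrange(dplyr::desc(.data$p2p_amp), .data$start_s,
                   .by_group = TRUE) |>
    dplyr::filter(dplyr::row_number() <= ceiling(top_fraction * dplyr::n())) |>
    dplyr::ungroup() |>
    dplyr::arrange(.data$channel, .data$start_s)
  thr <- out |>
    dplyr::group_by(.data$channel) |>
    dplyr::summarise(threshold = min(.data$p2p_amp),
                     n_retained = dplyr::n(), .groups = "drop") |>
    dplyr::left_join(
      candidates |>
        dplyr::count(.data$channel, name = "n_candidates"),
      by = "channel")
  attr(out, "thresholds") <- thr[, c("channel", "threshold",
                                     "n_candidates", "n_retained")]
  out
}

#' Per-channel amplitude-selection thresholds
#'
#' @param waves Output of [select_top_amplitude()] or [detect_slow_waves()].
#' @return Tibble of per-channel thresholds in microvolts.
#' @export
top_amplitude_thresholds <- function(waves) {
  thr <- attr(waves, "thresholds")
  if (is.null(thr)) stop("No thresholds attribute; run select_top_amplitude() first")
  thr
}

#' Detect slow waves in a continuous EEG recording
#'
#' Full detector: mastoid re-referencing, down-sampling and delta-band
#' filtering ([preprocess_for_detection()]), candidate extraction per
#' electrode ([extract_candidate_waves()]), artifact exclusions
#' ([filter_waves()]) and per-electrode amplitude selection
#' ([select_top_amplitude()]). The mastoid channels themselves are not
#' searched for waves.
#'
#' @param eeg An [eeg_recording()] including TP9 and TP10.
#' @param params A [detection_params()].
#' @param channels Channels to search; default all non-mastoid channels.
#' @return A tibble of detected slow waves (one row per wave, columns as in
#'   [extract_candidate_waves()]), with per-channel selection thresholds in
#'   the `thresholds` attribute.
#' @export
detect_slow_waves <- function(eeg, params = detection_params(),
                              channels = NULL) {
  pre <- preprocess_for_detection(eeg, params)
  if (is.null(channels)) {
    channels <- setdiff(pre$channels, c("TP9", "TP10"))
  }
  cands <- purrr::map_dfr(channels, function(ch) {
    x <- pre$data[, ch]
    cand <- extract_candidate_waves(x, pre$fs, channel = ch)
    filter_waves(cand, x, pre$fs, params)
  })
  select_top_amplitude(cands, params$top_fraction)
}

#' Summarize slow waves per analysis window
#'
#' Assigns each wave to a window when its start time lies in the half-open
#' interval `[start_s, end_s)` and reports, per window and channel, the
#' temporal density (waves per minute) and the mean peak-to-peak amplitude,
#' downward slope and upward slope. Property means are `NA` when a window
#' contains no wave for that channel.
#'
#' @param waves Tibble of detected waves.
#' @param windows Tibble with columns `window_id`, `start_s`, `end_s`
#'   (half-open, non-degenerate).
#' @param channels Channels to report; default the channels present in
#'   `waves`.
#' @return A tibble with one row per window by channel: `window_id`,
#'   `channel`, `n_waves`, `density` (waves/min), `mean_p2p_amp`,
#'   `mean_down_slope`, `mean_up_slope`.
#' @export
summarize_waves <- function(waves, windows, channels = NULL) {
  stopifnot(all(c("window_id", "start_s", "end_s") %in% names(windows)))
  if (any(windows$end_s <= windows$start_s)) {
    stop("Windows must have positive length")
  }
  if (is.null(channels)) channels <- sort(unique(waves$channel))
  grid <- tidyr::expand_grid(
    tibble::tibble(window_id = windows$window_id,
                   win_start_s = windows$start_s,
                   win_end_s = windows$end_s),
    channel = channels
  )
  member <- dplyr::inner_join(
    waves,
    grid,
    by = "channel",
    relationship = "many-to-many"
  ) |>
    dplyr::filter(.data$start_s >= .data$win_start_s,
                  .data$start_s < .data$win_end_s) |>
    dplyr::group_by(.data$window_id, .data$channel) |>
    dplyr::summarise(
      n_waves = dplyr::n(),
      mean_p2p_amp = mean(.data$p2p_amp),
      mean_down_slope = mean(.data$down_slope),
      mean_up_slope = mean(.data$up_slope),
      .groups = "drop")
  grid |>
    dplyr::left_join(member, by = c("window_id", "channel")) |>
    dplyr::mutate(
      n_waves = dplyr::coalesce(.data$n_waves, 0L),
      density = .data$n_waves / (.data$win_end_s - .data$win_start_s) * 60
    ) |>
    dplyr::select("window_id", "channel", "n_waves", "density",
                  "mean_p2p_amp", "mean_down_slope", "mean_up_slope")
}

#' Flag trials during which a slow wave started
#'
#' A trial is flagged for a given electrode when at least one slow wave on
#' that electrode has its onset within the stimulus presentation window,
#' half-open `[onset_s, offset_s)` (a wave starting exactly at stimulus onset
#' counts; one starting at offset does not).
#'
#' @param trials Tibble with `onset_s` and `offset_s` (one row per trial).
#' @param waves Tibble of detected waves (`channel`, `start_s`).
#' @param channels Channels to flag; default those present in `waves`.
#' @return A tibble in long form: `trial` (row index into `trials`),
#'   `channel`, `wave_present` (0/1 integer).
#' @export
flag_trial_wave_presence <- function(trials, waves, channels = NULL) {
  stopifnot(all(c("onset_s", "offset_s") %in% names(trials)))
  if (is.null(channels)) channels <- sort(unique(waves$channel))
  eps <- 1e-9
  purrr::map_dfr(channels, function(ch) {
    st <- sort(waves$start_s[waves$channel == ch])
    n_before <- function(x) findInterval(x - eps, st)
    cnt <- n_before(trials$offset_s) - n_before(trials$onset_s)
    tibble::tibble(trial = seq_len(nrow(trials)), channel = ch,
                   wave_present = as.integer(cnt > 0))
  })
}

#' Event-locked average (ERP) of an EEG recording
#'
#' Re-references to the mastoids, band-passes (zero phase) and averages
#' fixed-length epochs locked to the supplied event times (slow-wave starts,
#' stimulus onsets or motor responses).
#'
#' @param eeg An [eeg_recording()] including TP9 and TP10.
#' @param event_times Event times in seconds; events whose epoch would leave
#'   the recording are dropped.
#' @param window Two numbers: epoch span in seconds relative to the event
#'   (default `c(-1, 1)`).
#' @param band Band-pass edges in Hz (default `c(0.1, 30)`), or `NULL` to
#'   skip filtering.
#' @return A tibble `time_s` (relative to event), `channel`, `amplitude`
#'   (mean across epochs, microvolts), with attribute `n_events`.
#' @export
event_locked_average <- function(eeg, event_times, window = c(-1, 1),
                                 band = c(0.1, 30)) {
  stopifnot(inherits(eeg, "eeg_recording"), length(window) == 2,
            window[1] < window[2])
  absent <- setdiff(c("TP9", "TP10"), eeg$channels)
  if (length(absent) > 0) {
    stop("Mastoid channel(s) missing: ", paste(absent, collapse = ", "))
  }
  x <- eeg$data - rowMeans(eeg$data[, c("TP9", "TP10"), drop = FALSE])
  if (!is.null(band)) {
    bf <- signal::butter(2, band / (eeg$fs / 2), type = "pass")
    x <- apply(x, 2, function(ch) signal::filtfilt(bf, ch))
  }
  i0 <- round(window[1] * eeg$fs)
  i1 <- round(window[2] * eeg$fs)
  centers <- round(event_times * eeg$fs) + 1
  ok <- centers + i0 >= 1 & centers + i1 <= nrow(x)
  centers <- centers[ok]
  if (length(centers) == 0) stop("No usable events within the recording")
  rel <- i0:i1
  acc <- matrix(0, length(rel), ncol(x))
  for (c0 in centers) acc <- acc + x[c0 + rel, , drop = FALSE]
  acc <- acc / length(centers)
  out <- tibble::tibble(
    time_s = rep(rel / eeg$fs, times = ncol(x)),
    channel = rep(eeg$channels, each = length(rel)),
    amplitude = as.vector(acc)
  )
  attr(out, "n_events") <- length(centers)
  out
}
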