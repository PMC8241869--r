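# Independent brute-force oracles used to cross-check the implementation.
# These deliberately re-derive everything by plain sample scanning and
# per-probe loops, sharing no code with the package internals.

# wave delimitation oracle: scan every sample, find negative runs, their
# following positive run, and compute all wave quantities directly
oracle_waves <- function(x, fs) {
  n <- length(x)
  t <- (seq_len(n) - 1) / fs
  out <- list()
  i <- 2
  prev_end <- 0
  while (i <= n) {
    if (x[i] < 0 && x[i - 1] >= 0) {
      start_idx <- max(i - 1, prev_end)
      j <- i
      while (j <= n && x[j] < 0) j <- j + 1
      # skip zeros
      k <- j
      while (k <= n && x[k] == 0) k <- k + 1
      if (k > n || x[k] < 0) { i <- j; next }
      l <- k
      while (l < n && x[l + 1] > 0) l <- l + 1
      if (l == n) { i <- j; next }
      end_idx <- l + 1
      neg_seg <- i:(j - 1)
      np <- neg_seg[which.min(x[neg_seg])]
      pos_seg <- k:l
      pp <- pos_seg[which.max(x[pos_seg])]
      if (np > start_idx) {
        out[[length(out) + 1]] <- data.frame(
          start_s = t[start_idx], neg_peak_s = t[np], pos_peak_s = t[pp],
          end_s = t[end_idx],
          neg_peak_amp = x[np], pos_peak_amp = x[pp],
          p2p_amp = x[pp] - x[np],
          down_slope = abs(x[np]) / (t[np] - t[start_idx]),
          up_slope = (x[pp] - x[np]) / (t[pp] - t[np]))
        prev_end <- end_idx
      }
      i <- end_idx
    } else {
      i <- i + 1
    }
  }
  do.call(rbind, out)
}

# per-probe behavioural summary oracle: direct loop over probes and trials
oracle_preprobe <- function(trials, probes, window_s) {
  res <- list()
  for (r in seq_len(nrow(probes))) {
    sel <- trials$task == probes$task[r] &
      trials$block == probes$block[r] &
      trials$onset_s >= probes$onset_s[r] - window_s &
      trials$onset_s < probes$onset_s[r]
    tr <- trials[sel, ]
    keep <- tr$outcome != "excluded"
    n_go <- sum(!tr$is_nogo & keep)
    n_nogo <- sum(tr$is_nogo & keep)
    res[[r]] <- data.frame(
      probe_id = probes$probe_id[r],
      miss_rate = if (n_go > 0) sum(tr$outcome == "miss") / n_go else NA_real_,
      fa_rate = if (n_nogo > 0) sum(tr$outcome == "false_alarm") / n_nogo
      else NA_real_)
  }
  do.call(rbind, res)
}

# long-signal amplitude-ratio measurement of filter gain at one frequency
oracle_filter_gain <- function(filt, freq, fs, dur = 400) {
  t <- seq(0, dur, by = 1 / fs)
  y <- wakewave::apply_zero_phase(filt, sin(2 * pi * freq * t))
  core <- y[t > dur * 0.25 & t < dur * 0.75]
  max(abs(core))
}

# simple deterministic session for behaviour tests: explicit stimuli and
# responses with known outcomes
make_scored_fixture <- function() {
  stimuli <- tibble::tibble(
    onset_s = c(0, 1, 2, 3, 4, 5),
    offset_s = c(1, 2, 3, 4, 5, 6) - 0.05,
    is_nogo = c(FALSE, FALSE, TRUE, FALSE, TRUE, FALSE),
    task = "face", block = 1)
  # stim1: rt 400 ms (correct_go); stim2: no response (miss);
  # stim3 (nogo): rt 500 ms (false_alarm); stim4: rt 250 ms (excluded);
  # stim5 (nogo): no response (correct_nogo); stim6: rt 600 ms (correct_go)
  responses <- tibble::tibble(time_s = c(0.4, 2.5, 3.25, 5.6))
  list(stimuli = stimuli, responses = responses)
}
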