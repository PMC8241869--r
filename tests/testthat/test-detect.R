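test_that("candidate extraction matches analytic sinusoid properties", {
  fs <- 128
  t <- seq(0, 10, by = 1 / fs)
  w <- extract_candidate_waves(40 * sin(2 * pi * 2 * t), fs)
  # 2 Hz, amplitude 40: p2p 80 within sampling granularity, spacing 0.5 s
  expect_true(all(abs(w$p2p_amp - 80) <= 1))
  expect_true(all(abs(diff(w$start_s) - 0.5) <= 1 / fs + 1e-9))
  # a pure negative-first sinusoid starts its first wave at t = 0
  x2 <- -sin(2 * pi * 2 * seq(0, 2, by = 1 / fs))
  x2[abs(x2) < 1e-12] <- 0   # exact zeros at the crossings
  w2 <- extract_candidate_waves(x2, fs)
  expect_equal(w2$start_s[1], 0)
  expect_equal(w2$neg_peak_s[1], 0.125)
  expect_equal(w2$end_s[1], 0.5)
})

test_that("flat and all-positive signals yield no candidates", {
  expect_equal(nrow(extract_candidate_waves(rep(0, 500), 128)), 0)
  expect_equal(nrow(extract_candidate_waves(rep(3.2, 500), 128)), 0)
})

test_that("candidate invariants hold on noisy signals", {
  set.seed(7)
  for (rep in 1:5) {
    x <- as.numeric(stats::filter(rnorm(4000, sd = 20), rep(1 / 8, 8),
                                  sides = 1))
    x[is.na(x)] <- 0
    w <- extract_candidate_waves(x, 128)
    expect_true(all(w$start_s < w$neg_peak_s))
    expect_true(all(w$neg_peak_s < w$pos_peak_s))
    expect_true(all(w$pos_peak_s < w$end_s))
    expect_true(all(w$p2p_amp > 0))
    expect_true(all(w$neg_peak_amp < 0))
    expect_true(all(diff(w$start_s) > 0))
    # non-overlapping spans
    expect_true(all(w$start_s[-1] >= w$end_s[-nrow(w)] - 1e-12))
    # slopes recompute from the delimitation quantities
    expect_equal(w$down_slope,
                 abs(w$neg_peak_amp) / (w$neg_peak_s - w$start_s))
    expect_equal(w$up_slope,
                 (w$pos_peak_amp - w$neg_peak_amp) /
                   (w$pos_peak_s - w$neg_peak_s))
  }
})

test_that("exclusion rules drop high positive peaks, short waves and waves near artifacts", {
  fs <- 128
  t <- seq(0, 30, by = 1 / fs)
  # three clean 1 Hz-ish waves at known spots via templates
  x <- numeric(length(t))
  put <- function(x, onset, dur, p2p) {
    tpl <- wave_template(dur, p2p, fs)
    i0 <- round(onset * fs) + 1
    x[i0:(i0 + length(tpl) - 1)] <- x[i0:(i0 + length(tpl) - 1)] + tpl
    x
  }
  x <- put(x, 2, 1.0, 60)     # kept
  x <- put(x, 6, 0.10, 60)    # too short (0.1 s < 0.143 s)
  x <- put(x, 10, 1.0, 300)   # positive peak 100 > 75, also artifact
  x <- put(x, 20, 1.0, 60)    # kept, far from artifacts
  cand <- extract_candidate_waves(x, fs)
  kept <- filter_waves(cand, x, fs)
  expect_true(all(kept$pos_peak_amp <= 75))
  expect_true(all(kept$end_s - kept$start_s >= 0.143))
  expect_equal(nrow(kept), 2)
  expect_equal(round(kept$start_s), c(2, 20))
  # artifact proximity: a wave ending 0.5 s before a 160 uV spike is
  # excluded; 1.5 s before, retained
  y <- numeric(length(t))
  y <- put(y, 2, 1.0, 60)
  y[round(3.5 * fs)] <- 160
  cy <- filter_waves(extract_candidate_waves(y, fs), y, fs)
  expect_equal(nrow(cy), 0)
  y2 <- numeric(length(t))
  y2 <- put(y2, 2, 1.0, 60)
  y2[round(4.6 * fs)] <- 160
  cy2 <- filter_waves(extract_candidate_waves(y2, fs), y2, fs)
  expect_equal(nrow(cy2), 1)
})

test_that("top-amplitude selection keeps the ceiling fraction per channel", {
  set.seed(11)
  cand <- tibble::tibble(
    channel = rep(c("Fz", "Pz"), c(1000, 57)),
    start_s = c(seq_len(1000), seq_len(57)),
    p2p_amp = c(runif(1000, 10, 80), runif(57, 10, 80)))
  sel <- select_top_amplitude(cand, 0.10)
  expect_equal(sum(sel$channel == "Fz"), 100)
  expect_equal(sum(sel$channel == "Pz"), ceiling(0.1 * 57))
  thr <- top_amplitude_thresholds(sel)
  for (ch in c("Fz", "Pz")) {
    kept <- sel$p2p_amp[sel$channel == ch]
    disc <- setdiff(cand$p2p_amp[cand$channel == ch], kept)
    expect_gte(min(kept), max(disc))
    expect_equal(thr$threshold[thr$channel == ch], min(kept))
  }
  # top_fraction 1 retains everything
  expect_equal(nrow(select_top_amplitude(cand, 1)), nrow(cand))
  # empty input is fine
  expect_equal(nrow(select_top_amplitude(cand[0, ], 0.1)), 0)
})

test_that("window summaries compute density and conserve counts under splits", {
  waves <- tibble::tibble(
    channel = "Cz",
    start_s = c(1, 5, 9, 12, 19.5),
    end_s = start_s + 1, p2p_amp = 50, down_slope = 100, up_slope = 80)
  win <- tibble::tibble(window_id = 1, start_s = 0, end_s = 20)
  s <- summarize_waves(waves, win)
  expect_equal(s$n_waves, 5)
  expect_equal(s$density, 5 / 20 * 60)
  # 3 waves in a 20 s window -> 9 waves/min
  s3 <- summarize_waves(waves[1:3, ], win)
  expect_equal(s3$density, 9)
  # empty window: density 0, null property means
  s0 <- summarize_waves(waves[0, ], win, channels = "Cz")
  expect_equal(s0$density, 0)
  expect_true(is.na(s0$mean_p2p_amp))
  # four 5-s sub-windows partition the count
  sub <- tibble::tibble(window_id = 1:4, start_s = c(0, 5, 10, 15),
                        end_s = c(5, 10, 15, 20))
  ssub <- summarize_waves(waves, sub)
  expect_equal(sum(ssub$n_waves), s$n_waves)
  expect_error(summarize_waves(waves, tibble::tibble(
    window_id = 1, start_s = 3, end_s = 3)), "positive length")
})

test_that("trial wave flags use the half-open stimulus window", {
  trials <- tibble::tibble(onset_s = c(0, 1, 2), offset_s = c(1, 2, 3))
  waves <- tibble::tibble(channel = "Fz",
                          start_s = c(0, 1.01, 2.5, 2.6))
  fl <- flag_trial_wave_presence(trials, waves)
  expect_equal(fl$wave_present, c(1L, 1L, 1L))
  # wave starting 10 ms after stimulus offset does not flag that trial
  w2 <- tibble::tibble(channel = "Fz", start_s = 1.01)
  fl2 <- flag_trial_wave_presence(trials[1, ], w2)
  expect_equal(fl2$wave_present, 0L)
  # wave exactly at onset flags (closed left endpoint)
  w3 <- tibble::tibble(channel = "Fz", start_s = 1)
  fl3 <- flag_trial_wave_presence(trials[2, ], w3)
  expect_equal(fl3$wave_present, 1L)
  # two waves in one stimulus still a binary 1
  w4 <- tibble::tibble(channel = "Fz", start_s = c(0.2, 0.8))
  expect_equal(flag_trial_wave_presence(trials[1, ], w4)$wave_present, 1L)
})

test_that("event-locked averages reduce noise as 1/sqrt(n) and pass identity checks", {
  fs <- 128
  set.seed(21)
  n <- fs * 120
  chans <- c("Cz", "TP9", "TP10")
  dat <- cbind(rnorm(n), 0, 0)
  eeg <- eeg_recording(dat, chans, fs)
  ev <- runif(400, 5, 115)
  erp <- event_locked_average(eeg, ev, window = c(-0.5, 0.5), band = NULL)
  cz <- erp$amplitude[erp$channel == "Cz"]
  expect_lt(sd(cz), 1.5 / sqrt(400))
  expect_gt(sd(cz), 0.5 / sqrt(400))
  # single event: the average is that epoch
  erp1 <- event_locked_average(eeg, 10, window = c(-0.1, 0.1), band = NULL)
  i0 <- round(10 * fs) + 1
  rel <- round(-0.1 * fs):round(0.1 * fs)
  expect_equal(erp1$amplitude[erp1$channel == "Cz"], dat[i0 + rel, 1])
  expect_error(event_locked_average(eeg, numeric(0)), "No usable events")
})

test_that("wave delimitation is identical to the brute-force scan oracle", {
  fs <- 128
  set.seed(31)
  for (rep in 1:8) {
    x <- as.numeric(stats::filter(rnorm(2000, sd = 15), rep(1 / 6, 6),
                                  sides = 1))
    x[is.na(x)] <- 0
    got <- extract_candidate_waves(x, fs)
    want <- oracle_waves(x, fs)
    expect_equal(nrow(got), nrow(want))
    for (col in c("start_s", "neg_peak_s", "pos_peak_s", "end_s",
                  "neg_peak_amp", "pos_peak_amp", "p2p_amp",
                  "down_slope", "up_slope")) {
      expect_equal(got[[col]], want[[col]], tolerance = 1e-12)
    }
  }
})
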