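test_that("trial scoring implements the miss/FA/exclusion rules", {
  fx <- make_scored_fixture()
  tr <- score_trials(fx$stimuli, fx$responses)
  expect_equal(tr$outcome,
               c("correct_go", "miss", "false_alarm", "excluded",
                 "correct_nogo", "correct_go"))
  expect_equal(tr$rt_ms[1], 400)
  expect_equal(tr$rt_ms[3], 500)
  expect_equal(tr$rt_ms[4], 250)
  expect_true(is.na(tr$rt_ms[2]))
  # response after the next onset belongs to the next trial
  resp2 <- tibble::tibble(time_s = 1.2)  # within stim 2 window
  tr2 <- score_trials(fx$stimuli, resp2)
  expect_equal(tr2$outcome[1], "miss")
  expect_equal(tr2$outcome[2], "excluded")  # rt 200 ms
  expect_error(score_trials(tibble::tibble(
    onset_s = c(0, 0.5), offset_s = c(1, 1.5), is_nogo = FALSE),
    fx$responses), "Overlapping")
})

test_that("every Go trial is exactly one of miss/correct/excluded", {
  s <- generate_session(session_config(seed = 6, n_blocks_per_task = 1,
                                       n_probes_per_block = 5))
  tr <- score_session(s)
  go <- tr[!tr$is_nogo, ]
  expect_equal(sum(go$outcome %in% c("miss", "correct_go", "excluded")),
               nrow(go))
  nogo <- tr[tr$is_nogo, ]
  expect_equal(sum(nogo$outcome %in% c("false_alarm", "correct_nogo",
                                       "excluded")), nrow(nogo))
})

test_that("pre-probe summaries match the brute-force oracle and partition", {
  s <- generate_session(session_config(seed = 17, n_blocks_per_task = 1,
                                       n_probes_per_block = 6))
  tr <- score_session(s)
  ps <- preprobe_summary(tr, s$probes, 20)
  want <- oracle_preprobe(tr, s$probes, 20)
  expect_equal(ps$miss_rate, want$miss_rate)
  expect_equal(ps$fa_rate, want$fa_rate)
  # four 5-s sub-windows partition the trials of the 20-s window
  ps4 <- preprobe_summary(tr, s$probes, 20, n_subwindows = 4)
  counts4 <- ps4 |>
    dplyr::group_by(probe_id) |>
    dplyr::summarise(n = sum(n_go + n_nogo + n_excluded), .groups = "drop")
  counts1 <- ps |>
    dplyr::mutate(n = n_go + n_nogo + n_excluded)
  expect_equal(counts4$n, counts1$n)
  # simple rate arithmetic
  ex <- tibble::tibble(onset_s = seq(0.5, 19.5, by = 1) - 0.01,
                       offset_s = seq(0.5, 19.5, by = 1) + 0.9,
                       is_nogo = FALSE, task = "face", block = 1)
  exr <- tibble::tibble(time_s = ex$onset_s[-(1:2)] + 0.4)
  trx <- score_trials(ex, exr)
  prb <- tibble::tibble(probe_id = 1, onset_s = 20, task = "face",
                        block = 1)
  px <- preprobe_summary(trx, prb, 20)
  expect_equal(px$miss_rate, 2 / 20)
  expect_true(is.na(px$fa_rate))
})

test_that("blink interpolation is exact on ramps and idempotent without blinks", {
  t <- seq(0, 10, by = 0.01)
  ramp <- tibble::tibble(time_s = t, size = 2 * t + 1,
                         is_blink = t > 4 & t < 4.5)
  ramp$size[ramp$is_blink] <- NA
  out <- preprocess_pupil(ramp)
  expect_equal(out$size, 2 * t + 1, tolerance = 1e-9)
  clean <- tibble::tibble(time_s = t, size = sin(t))
  expect_equal(preprocess_pupil(clean)$size, clean$size)
  # constant trace with a blink stays constant
  const <- tibble::tibble(time_s = t, size = 5,
                          is_blink = t > 2 & t < 2.2)
  const$size[const$is_blink] <- NA
  expect_equal(unique(preprocess_pupil(const)$size), 5)
  allmiss <- tibble::tibble(time_s = t, size = NA_real_)
  expect_error(preprocess_pupil(allmiss), "entirely missing")
})

test_that("per-trial and per-probe pupil means average the right windows", {
  t <- seq(0, 100, by = 0.01)
  pupil <- tibble::tibble(time_s = t, size = t)  # identity ramp
  trials <- tibble::tibble(onset_s = c(10, 20), offset_s = c(11, 21),
                           task = "face", block = 1)
  tm <- pupil_trial_means(pupil, trials)
  expect_equal(tm$pupil_mean, c(10.495, 20.495), tolerance = 1e-6)
  probes <- tibble::tibble(probe_id = 1, onset_s = 30, task = "face",
                           block = 1)
  pm <- pupil_probe_means(tm, probes, window_s = 20)
  expect_equal(pm$pupil_mean, mean(c(10.495, 20.495)), tolerance = 1e-6)
})

test_that("pupil discretization is a rank-invariant balanced quantile binning", {
  x <- tibble::tibble(participant = 1, task = "face",
                      pupil_mean = c(5, 1, 3, 2, 4))
  b <- discretize_pupil(x)
  expect_equal(b$pupil_bin, c(5L, 1L, 3L, 2L, 4L))
  set.seed(3)
  y <- tibble::tibble(participant = rep(1:2, each = 20), task = "face",
                      pupil_mean = runif(40))
  by <- discretize_pupil(y)
  counts <- table(by$participant, by$pupil_bin)
  expect_true(all(counts == 4))
  # monotone transformation leaves bins unchanged
  y2 <- dplyr::mutate(y, pupil_mean = exp(3 * pupil_mean))
  expect_equal(discretize_pupil(y2)$pupil_bin, by$pupil_bin)
  # bin index non-decreasing in pupil size within group
  g1 <- dplyr::filter(by, participant == 1) |> dplyr::arrange(pupil_mean)
  expect_true(all(diff(g1$pupil_bin) >= 0))
  # too few values: NA bins with warning
  small <- tibble::tibble(participant = 1, task = "face",
                          pupil_mean = c(1, 2, 3))
  expect_warning(bs <- discretize_pupil(small), "Fewer than")
  expect_true(all(is.na(bs$pupil_bin)))
})

test_that("states couple to behaviour in the planted directions", {
  # pooled trial-level rates across sessions: MB raises misses, MW raises
  # false alarms, MB slows reaction times (relative to ON)
  acc <- list()
  for (sd in 1:12) {
    s <- generate_session(session_config(seed = 400 + sd))
    tr <- score_session(s)
    acc[[sd]] <- dplyr::inner_join(
      s$probes,
      dplyr::rename(tr, trial_onset_s = onset_s),
      by = c("task", "block"), relationship = "many-to-many") |>
      dplyr::filter(trial_onset_s >= onset_s - 20, trial_onset_s < onset_s)
  }
  j <- dplyr::bind_rows(acc)
  rates <- j |>
    dplyr::group_by(mental_state) |>
    dplyr::summarise(
      miss = sum(outcome == "miss") / sum(!is_nogo & outcome != "excluded"),
      fa = sum(outcome == "false_alarm") /
        sum(is_nogo & outcome != "excluded"),
      rt = mean(rt_ms[outcome == "correct_go"]), .groups = "drop")
  r <- function(st, col) rates[[col]][rates$mental_state == st]
  expect_gt(r("MB", "miss"), r("ON", "miss"))
  expect_gt(r("MW", "fa"), r("ON", "fa"))
  expect_gt(r("MB", "rt"), r("MW", "rt"))
})
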