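#' Session configuration for the synthetic SART generator
#'
#' Describes a simulated sustained-attention (Go/NoGo) session: two task
#' variants (faces, digits), `n_blocks_per_task` blocks each, a continuous
#' stimulus stream with uniformly jittered durations, one NoGo per permuted
#' block of `nogo_period` stimuli, and experience-sampling probes every
#' `probe_interval_range` seconds, `n_probes_per_block` per block.
#'
#' @param n_blocks_per_task Blocks per task (default 3).
#' @param n_probes_per_block Probes per block (default 10).
#' @param stim_duration_range Stimulus duration range in seconds, uniform
#'   jitter (default 0.75 to 1.25).
#' @param nogo_period Permutation block length; exactly one NoGo per
#'   consecutive `nogo_period` stimuli (default 9).
#' @param probe_interval_range Inter-probe interval range in seconds
#'   (default 30 to 70).
#' @param sampling_rate EEG sampling rate in Hz (default 500).
#' @param montage Montage tibble (default [montage_1010()]).
#' @param seed Integer session seed; all generator randomness derives from
#'   it through fixed per-component offsets.
#' @return A list of class `session_config`.
#' @export
session_config <- function(n_blocks_per_task = 3,
                           n_probes_per_block = 10,
                           stim_duration_range = c(0.75, 1.25),
                           nogo_period = 9,
                           probe_interval_range = c(30, 70),
                           sampling_rate = 500,
                           montage = montage_1010(),
                           seed = 1) {
  stopifnot(n_blocks_per_task >= 1, n_probes_per_block >= 1,
            length(stim_duration_range) == 2,
            stim_duration_range[1] > 0,
            stim_duration_range[1] <= stim_duration_range[2],
            nogo_period >= 2,
            length(probe_interval_range) == 2,
            probe_interval_range[1] > 0,
            probe_interval_range[1] <= probe_interval_range[2],
            sampling_rate > 0,
            !anyDuplicated(montage$channel))
  structure(
    list(n_blocks_per_task = n_blocks_per_task,
         n_probes_per_block = n_probes_per_block,
         stim_duration_range = stim_duration_range,
         nogo_period = nogo_period,
         probe_interval_range = probe_interval_range,
         sampling_rate = sampling_rate,
         montage = montage,
         seed = as.integer(seed)),
    class = "session_config"
  )
}

#' Coupling between latent vigilance, slow waves and behaviour
#'
#' Parameters of the generative coupling used to validate the downstream
#' pipeline: latent vigilance drifts within a block; two partially
#' independent "local sleep" intensities (frontal and posterior) rise as
#' vigilance falls; slow waves arise as an inhomogeneous Poisson process
#' whose channel-wise rate mixes a baseline with the frontal intensity
#' (weighted towards Fp/AF/F rows) and the posterior intensity (weighted
#' towards O/PO/P rows). Probe reports are drawn from a softmax: mind
#' wandering (MW) is driven by the frontal intensity, mind blanking (MB) by
#' the posterior intensity, task focus (ON) by vigilance, with base rates
#' set so the marginal report mix is roughly 48/39/13 percent ON/MW/MB.
#' Trial responses come from the drift-diffusion model: a frontal wave
#' during stimulus presentation shrinks `|v_nogo|` (impulsivity: more false
#' alarms), a posterior wave shrinks `v_go` (sluggishness: more misses and
#' slower responses). The coupling is a validation device, not a mechanistic
#' claim.
#'
#' @param base_rate Baseline slow-wave rate, waves per minute per channel
#'   (independent across channels; the state-independent floor).
#' @param mw_rate Frontal event rate in events per minute at frontal
#'   intensity 1; each event places simultaneous waves over the frontal
#'   channel group.
#' @param mb_rate Posterior event rate, likewise, for the posterior group.
#' @param wave_p2p_range Injected wave peak-to-peak amplitude range, uV.
#' @param wave_duration_range Injected wave duration range, s.
#' @param ddm Baseline [ddm_params()].
#' @param v_nogo_factor Multiplier on `v_nogo` when a frontal wave occurs
#'   during the stimulus (< 1 weakens withholding).
#' @param v_go_factor Multiplier on `v_go` when a posterior wave occurs
#'   during the stimulus (< 1 slows responding).
#' @param state_gain Softmax gain on the intensities for probe reports.
#' @param state_base Named numeric base logits for ON/MW/MB.
#' @param anticipation_rate Fraction of trials with an anticipatory press
#'   (RT uniform 0.15 to 0.30 s), exercising the short-RT exclusion.
#' @return A list of class `coupling_params`.
#' @export
coupling_params <- function(base_rate = 0.5,
                            mw_rate = 30,
                            mb_rate = 30,
                            wave_p2p_range = c(35, 75),
                            wave_duration_range = c(0.8, 1.2),
                            ddm = ddm_params(),
                            v_nogo_factor = 0.25,
                            v_go_factor = 0.5,
                            state_gain = 6,
                            state_base = c(ON = 1.501, MW = 0.125, MB = -2.057),
                            anticipation_rate = 0.01) {
  stopifnot(base_rate >= 0, mw_rate >= 0, mb_rate >= 0,
            v_nogo_factor > 0, v_go_factor > 0,
            all(c("ON", "MW", "MB") %in% names(state_base)),
            anticipation_rate >= 0, anticipation_rate < 1)
  structure(
    list(base_rate = base_rate, mw_rate = mw_rate, mb_rate = mb_rate,
         wave_p2p_range = wave_p2p_range,
         wave_duration_range = wave_duration_range,
         ddm = ddm, v_nogo_factor = v_nogo_factor, v_go_factor = v_go_factor,
         state_gain = state_gain, state_base = state_base,
         anticipation_rate = anticipation_rate),
    class = "coupling_params"
  )
}

# deterministic stream splitting: every generator component draws from
# set.seed(stream_seed(session_seed, component, index)); offsets are fixed
# so adding components never perturbs existing streams
stream_seed <- function(seed, component, index = 0L) {
  offs <- c(stimuli = 11L, probes = 23L, latent = 37L, waves = 51L,
            responses = 67L, pupil = 83L, eeg = 97L)
  as.integer((as.double(seed) * 1009 + offs[[component]] * 131 + index) %%
               2147483647)
}

#' Generate a continuous Go/NoGo stimulus stream
#'
#' Stimulus identities are permuted in blocks of `nogo_period` (so exactly
#' one NoGo -- the designated identity -- appears per consecutive block) and
#' the same identity never appears twice in a row, including across block
#' boundaries. Durations are i.i.d. uniform on `stim_duration_range`; the
#' stream is contiguous (each onset is the previous offset).
#'
#' @param config A [session_config()].
#' @param n_stimuli Number of stimuli (rounded up to a whole number of
#'   permutation blocks).
#' @param seed Integer seed (default derives from the config seed).
#' @param task Task label stored in the output.
#' @return A tibble: `stim_index`, `identity` (1..`nogo_period`; identity
#'   `nogo_period` is the NoGo), `onset_s`, `offset_s`, `is_nogo`, `task`.
#' @export
generate_stimulus_stream <- function(config, n_stimuli,
                                     seed = stream_seed(config$seed, "stimuli"),
                                     task = "face") {
  stopifnot(inherits(config, "session_config"), n_stimuli >= 1)
  m <- config$nogo_period
  n_blocks <- ceiling(n_stimuli / m)
  set.seed(seed)
  ids <- integer(0)
  last <- NA_integer_
  for (b in seq_len(n_blocks)) {
    repeat {
      perm <- sample.int(m)
      if (is.na(last) || perm[1] != last) break
    }
    ids <- c(ids, perm)
    last <- perm[m]
  }
  n_total <- n_blocks * m
  dur <- stats::runif(n_total, config$stim_duration_range[1],
                      config$stim_duration_range[2])
  offset <- cumsum(dur)
  tibble::tibble(
    stim_index = seq_len(n_total),
    identity = ids,
    onset_s = c(0, offset[-n_total]),
    offset_s = offset,
    is_nogo = ids == m,
    task = task
  )
}

# Ornstein-Uhlenbeck-style clamped random walk on a 1 Hz grid
ou_walk <- function(n, x0, mu, theta, sigma, lo = 0, hi = 1) {
  x <- numeric(n)
  x[1] <- x0
  eps <- stats::rnorm(n - 1, 0, sigma)
  for (i in seq_len(n - 1)) {
    x[i + 1] <- min(max(x[i] + theta * (mu - x[i]) + eps[i], lo), hi)
  }
  x
}

# latent vigilance and local-sleep intensities for one block, 1 Hz grid
generate_latent_block <- function(duration_s, seed) {
  n <- ceiling(duration_s) + 1
  set.seed(seed)
  v <- ou_walk(n, x0 = stats::runif(1, 0.55, 0.95), mu = 0.55,
               theta = 0.03, sigma = 0.06)
  # two largely independent local-sleep intensities: a shared pull from low
  # vigilance plus a dominant slow independent fluctuation each (time
  # constant ~50 s), so sustained frontal and posterior episodes occur
  # separately and the 20-s pre-probe means carry most of the variance
  uf <- ou_walk(n, x0 = 0, mu = 0, theta = 0.02, sigma = 0.12,
                lo = -1.5, hi = 1.5)
  up <- ou_walk(n, x0 = 0, mu = 0, theta = 0.02, sigma = 0.12,
                lo = -1.5, hi = 1.5)
  tibble::tibble(
    time_s = seq_len(n) - 1,
    vigilance = v,
    frontal_intensity = pmin(pmax(0.55 * (1 - v) + uf, 0), 1),
    posterior_intensity = pmin(pmax(0.55 * (1 - v) + up, 0), 1)
  )
}

empty_gt_tbl <- function() {
  tibble::tibble(event_id = integer(), event_type = character(),
                 channel = character(), onset_s = numeric(),
                 duration_s = numeric(), p2p_amp = numeric())
}

# inhomogeneous Poisson ground-truth waves for one block. Baseline waves are
# independent per channel at base_rate waves/min; frontal and posterior
# "local sleep" events occur at mw_rate * f(t) and mb_rate * p(t) events/min
# and place simultaneous waves over their channel group (each group channel
# joins the event with probability equal to its topographic weight).
generate_gt_waves <- function(latent, channels, coupling, duration_s, seed) {
  set.seed(seed)
  wf <- frontal_weight(channels)
  wp <- posterior_weight(channels)
  n_bins <- floor(duration_s)
  if (n_bins < 1) return(empty_gt_tbl())
  f <- latent$frontal_intensity[seq_len(n_bins)]
  p <- latent$posterior_intensity[seq_len(n_bins)]
  draw_dur <- function(n) stats::runif(n, coupling$wave_duration_range[1],
                                       coupling$wave_duration_range[2])
  draw_amp <- function(n) stats::runif(n, coupling$wave_p2p_range[1],
                                       coupling$wave_p2p_range[2])
  acc <- list(event_id = list(), event_type = list(), channel = list(),
              onset_s = list(), duration_s = list(), p2p_amp = list())
  push <- function(id, type, ch, on, dur, amp) {
    k <- length(acc$event_id) + 1
    acc$event_id[[k]] <<- id; acc$event_type[[k]] <<- type
    acc$channel[[k]] <<- ch; acc$onset_s[[k]] <<- on
    acc$duration_s[[k]] <<- dur; acc$p2p_amp[[k]] <<- amp
  }
  ev_id <- 0L
  # baseline: per channel, homogeneous
  if (coupling$base_rate > 0) {
    for (ci in seq_along(channels)) {
      counts <- stats::rpois(n_bins, coupling$base_rate / 60)
      tot <- sum(counts)
      if (tot == 0) next
      push(ev_id + seq_len(tot), rep("baseline", tot),
           rep(channels[ci], tot),
           rep(seq_len(n_bins) - 1, counts) + stats::runif(tot),
           draw_dur(tot), draw_amp(tot))
      ev_id <- ev_id + tot
    }
  }
  # localized multi-channel events
  for (kind in c("frontal", "posterior")) {
    rate <- if (kind == "frontal") coupling$mw_rate * f
    else coupling$mb_rate * p
    w <- if (kind == "frontal") wf else wp
    counts <- stats::rpois(n_bins, rate / 60)
    tot <- sum(counts)
    if (tot == 0) next
    onsets <- rep(seq_len(n_bins) - 1, counts) + stats::runif(tot)
    for (k in seq_len(tot)) {
      member <- which(stats::runif(length(channels)) < w)
      if (length(member) == 0) next
      ev_id <- ev_id + 1L
      nm <- length(member)
      push(rep(ev_id, nm), rep(kind, nm), channels[member],
           rep(onsets[k], nm), rep(draw_dur(1), nm), rep(draw_amp(1), nm))
    }
  }
  if (length(acc$event_id) == 0) return(empty_gt_tbl())
  res <- tibble::tibble(
    event_id = as.integer(unlist(acc$event_id)),
    event_type = unlist(acc$event_type),
    channel = unlist(acc$channel),
    onset_s = unlist(acc$onset_s),
    duration_s = unlist(acc$duration_s),
    p2p_amp = unlist(acc$p2p_amp))
  res <- res[res$onset_s + res$duration_s <= duration_s, , drop = FALSE]
  dplyr::arrange(res, .data$onset_s)
}

#' Generate a full synthetic SART session
#'
#' Produces, for every task (`"face"`, `"digit"`) and block: the stimulus
#' stream, probe onsets (inter-probe gaps uniform on the configured range),
#' the latent vigilance/intensity traces, ground-truth slow waves, and
#' drift-diffusion responses whose parameters are modulated trial-by-trial
#' by ground-truth wave presence during stimulus presentation (see
#' [coupling_params()]). Each block has its own time base starting at zero.
#'
#' @param config A [session_config()].
#' @param coupling A [coupling_params()].
#' @param seed Session seed (default `config$seed`).
#' @return A list of class `sart_session` with tibbles `stimuli`,
#'   `responses` (button-press times), `probes`, `latent`,
#'   `ground_truth_waves`, and the `config`/`coupling` used. All tables
#'   carry `task` and `block` columns.
#' @export
generate_session <- function(config = session_config(),
                             coupling = coupling_params(),
                             seed = config$seed) {
  stopifnot(inherits(config, "session_config"),
            inherits(coupling, "coupling_params"))
  channels <- setdiff(config$montage$channel, c("TP9", "TP10"))
  tasks <- c("face", "digit")
  acc <- list(stimuli = list(), responses = list(), probes = list(),
              latent = list(), waves = list())
  probe_id <- 0L
  bi <- 0L
  for (task in tasks) {
    for (block in seq_len(config$n_blocks_per_task)) {
      bi <- bi + 1L
      # probes
      set.seed(stream_seed(seed, "probes", bi))
      gaps <- stats::runif(config$n_probes_per_block,
                           config$probe_interval_range[1],
                           config$probe_interval_range[2])
      probe_onsets <- cumsum(gaps)
      block_end <- max(probe_onsets) + 2
      # stimuli: enough to cover the block
      n_stim <- ceiling(block_end / config$stim_duration_range[1]) +
        config$nogo_period
      stim <- generate_stimulus_stream(
        config, n_stim, seed = stream_seed(seed, "stimuli", bi), task = task)
      stim <- stim[stim$onset_s < block_end, , drop = FALSE]
      stim$block <- block
      # latent state
      latent <- generate_latent_block(block_end,
                                      stream_seed(seed, "latent", bi))
      latent$task <- task; latent$block <- block
      # ground-truth waves
      waves <- generate_gt_waves(latent, channels, coupling, block_end,
                                 stream_seed(seed, "waves", bi))
      if (nrow(waves) > 0) { waves$task <- task; waves$block <- block }
      # per-trial wave modulation of DDM parameters
      wfront <- waves[frontal_weight(waves$channel) >= 0.7, , drop = FALSE]
      wpost <- waves[posterior_weight(waves$channel) >= 0.7, , drop = FALSE]
      in_stim <- function(w) {
        if (nrow(w) == 0) return(rep(FALSE, nrow(stim)))
        st <- sort(w$onset_s)
        findInterval(stim$offset_s - 1e-9, st) -
          findInterval(stim$onset_s - 1e-9, st) > 0
      }
      has_front <- in_stim(wfront)
      has_post <- in_stim(wpost)
      dd <- coupling$ddm
      vtrial <- ifelse(stim$is_nogo,
                       dd$v_nogo * ifelse(has_front, coupling$v_nogo_factor, 1),
                       dd$v_go * ifelse(has_post, coupling$v_go_factor, 1))
      sim <- simulate_ddm_trials(
        tibble::tibble(v = vtrial, a = dd$a, z = dd$z, t_nd = dd$t_nd,
                       deadline_s = stim$offset_s - stim$onset_s),
        seed = stream_seed(seed, "responses", bi))
      set.seed(stream_seed(seed, "responses", bi) + 1L)
      anticip <- stats::runif(nrow(stim)) < coupling$anticipation_rate
      rt <- sim$rt_s
      rt[anticip] <- stats::runif(sum(anticip), 0.15, 0.30)
      responded <- sim$boundary == "respond" | anticip
      resp <- tibble::tibble(
        task = task, block = block,
        time_s = (stim$onset_s + rt)[responded]
      )
      stim$wave_frontal <- has_front
      stim$wave_posterior <- has_post
      # probe reports from the softmax over pre-probe latent summaries
      set.seed(stream_seed(seed, "probes", bi) + 1L)
      states <- character(length(probe_onsets))
      vigilance_rating <- integer(length(probe_onsets))
      vbar_all <- numeric(length(probe_onsets))
      for (k in seq_along(probe_onsets)) {
        win <- latent$time_s >= probe_onsets[k] - 20 &
          latent$time_s < probe_onsets[k]
        fbar <- mean(latent$frontal_intensity[win])
        pbar <- mean(latent$posterior_intensity[win])
        vbar <- mean(latent$vigilance[win])
        logits <- c(
          ON = coupling$state_base[["ON"]] + 2 * vbar,
          MW = coupling$state_base[["MW"]] + coupling$state_gain * fbar,
          MB = coupling$state_base[["MB"]] + coupling$state_gain * pbar)
        pr <- exp(logits - max(logits)); pr <- pr / sum(pr)
        states[k] <- sample(names(pr), 1, prob = pr)
        vigilance_rating[k] <- min(max(round(1 + 3 * (vbar +
          stats::rnorm(1, 0, 0.08))), 1), 4)
        vbar_all[k] <- vbar
      }
      acc$probes[[bi]] <- tibble::tibble(
        probe_id = probe_id + seq_along(probe_onsets),
        task = task, block = block,
        onset_s = probe_onsets,
        mental_state = states,
        vigilance = vigilance_rating,
        vigilance_latent = vbar_all
      )
      probe_id <- probe_id + length(probe_onsets)
      acc$stimuli[[bi]] <- stim
      acc$responses[[bi]] <- resp
      acc$latent[[bi]] <- latent
      acc$waves[[bi]] <- waves
    }
  }
  structure(
    list(config = config, coupling = coupling, seed = seed,
         stimuli = dplyr::bind_rows(acc$stimuli),
         responses = dplyr::bind_rows(acc$responses),
         probes = dplyr::bind_rows(acc$probes),
         latent = dplyr::bind_rows(acc$latent),
         ground_truth_waves = dplyr::bind_rows(acc$waves)),
    class = "sart_session"
  )
}

#' @export
print.sart_session <- function(x, ...) {
  cat(sprintf("<sart_session> %d stimuli, %d probes, %d ground-truth waves (seed %d)\n",
              nrow(x$stimuli), nrow(x$probes), nrow(x$ground_truth_waves),
              x$seed))
  invisible(x)
}

#' Biphasic slow-wave template
#'
#' Half-sine negative lobe followed by a half-sine positive rebound, with
#' the negative amplitude twice the positive one (so the negative peak is
#' `-2/3` and the positive peak `+1/3` of the peak-to-peak amplitude),
#' matching the canonical slow-wave morphology.
#'
#' @param duration_s Total template duration (s).
#' @param p2p_amp Peak-to-peak amplitude (uV).
#' @param fs Sampling rate (Hz).
#' @param neg_fraction Fraction of the duration taken by the negative lobe.
#' @return Numeric vector of `round(duration_s * fs)` samples.
#' @export
wave_template <- function(duration_s, p2p_amp, fs, neg_fraction = 0.45) {
  stopifnot(duration_s > 0, p2p_amp > 0, fs > 0,
            neg_fraction > 0, neg_fraction < 1)
  n <- max(round(duration_s * fs), 4)
  n_neg <- max(round(n * neg_fraction), 2)
  n_pos <- n - n_neg
  a_neg <- 2 / 3 * p2p_amp
  a_pos <- 1 / 3 * p2p_amp
  c(-a_neg * sin(pi * seq(0, 1, length.out = n_neg)),
    a_pos * sin(pi * seq(0, 1, length.out = n_pos)))
}

#' Spectrally shaped background-noise specification
#'
#' @param alpha Spectral exponent of the `1/f^alpha` background (default 1).
#' @param rms Target root-mean-square amplitude in uV (default 10).
#' @return A list of class `noise_spec`.
#' @export
noise_spec <- function(alpha = 1, rms = 10) {
  stopifnot(alpha >= 0, rms >= 0)
  structure(list(alpha = alpha, rms = rms), class = "noise_spec")
}

# one channel of 1/f^alpha Gaussian noise via spectral shaping
onef_noise <- function(n, fs, alpha = 1, rms = 10) {
  if (rms == 0) return(numeric(n))
  nf <- 2^ceiling(log2(n))
  freqs <- seq(0, fs / 2, length.out = nf / 2 + 1)
  amp <- c(0, 1 / freqs[-1]^(alpha / 2))
  phase <- stats::runif(nf / 2 + 1, 0, 2 * pi)
  spec <- amp * exp(1i * phase)
  full <- c(spec, Conj(rev(spec[2:(nf / 2)])))
  x <- Re(stats::fft(full, inverse = TRUE))[seq_len(n)]
  x * rms / stats::sd(x)
}

#' Inject slow-wave templates into an EEG recording
#'
#' Adds biphasic wave templates ([wave_template()]) at the listed onsets and
#' channels, optionally on top of freshly generated `1/f`-type background
#' noise. Channels without waves differ from the input only by that noise.
#'
#' @param eeg An [eeg_recording()].
#' @param waves Tibble with `channel`, `onset_s`, `duration_s`, `p2p_amp`.
#' @param noise A [noise_spec()] to add background noise, or `NULL` to add
#'   none.
#' @param seed Seed for the noise draw (required when `noise` is given).
#' @return A new [eeg_recording()].
#' @export
inject_slow_waves <- function(eeg, waves, noise = NULL, seed = 1) {
  stopifnot(inherits(eeg, "eeg_recording"))
  data <- eeg$data
  if (!is.null(noise)) {
    stopifnot(inherits(noise, "noise_spec"))
    set.seed(seed)
    for (j in seq_len(ncol(data))) {
      data[, j] <- data[, j] +
        onef_noise(nrow(data), eeg$fs, noise$alpha, noise$rms)
    }
  }
  if (nrow(waves) > 0) {
    bad_ch <- setdiff(waves$channel, eeg$channels)
    if (length(bad_ch) > 0) {
      stop("Wave channel(s) not in recording: ",
           paste(unique(bad_ch), collapse = ", "))
    }
    dur_rec <- nrow(data) / eeg$fs
    if (any(waves$onset_s < 0 | waves$onset_s + waves$duration_s > dur_rec)) {
      stop("Wave outside the recording span")
    }
    for (i in seq_len(nrow(waves))) {
      tpl <- wave_template(waves$duration_s[i], waves$p2p_amp[i], eeg$fs)
      i0 <- round(waves$onset_s[i] * eeg$fs) + 1
      idx <- i0:(i0 + length(tpl) - 1)
      j <- match(waves$channel[i], eeg$channels)
      data[idx, j] <- data[idx, j] + tpl
    }
  }
  eeg_recording(data, eeg$channels, eeg$fs, eeg$reference)
}

#' Synthesize the EEG of one session block
#'
#' Builds a block-long multi-channel recording: `1/f`-type background noise
#' on every montage channel plus the block's ground-truth slow-wave
#' templates on their channels. Mastoid channels carry noise only.
#'
#' @param session A `sart_session` from [generate_session()].
#' @param task,block Which block to synthesize.
#' @param noise A [noise_spec()].
#' @return An [eeg_recording()] at the configured sampling rate.
#' @export
synthesize_eeg <- function(session, task = "face", block = 1,
                           noise = noise_spec()) {
  stopifnot(inherits(session, "sart_session"))
  cfg <- session$config
  lat <- session$latent[session$latent$task == task &
                          session$latent$block == block, ]
  if (nrow(lat) == 0) stop("No such task/block in session")
  dur <- max(lat$time_s) + 1
  n <- round(dur * cfg$sampling_rate)
  waves <- session$ground_truth_waves
  waves <- waves[waves$task == task & waves$block == block, , drop = FALSE]
  eeg <- eeg_recording(matrix(0, n, nrow(cfg$montage)),
                       cfg$montage$channel, cfg$sampling_rate,
                       reference = "AFz")
  bi <- match(paste(task, block),
              c(t(outer(c("face", "digit"),
                        seq_len(cfg$n_blocks_per_task), paste))))
  inject_slow_waves(eeg, waves, noise = noise,
                    seed = stream_seed(session$seed, "eeg", bi))
}

#' Simulate a pupil-size trace with blinks
#'
#' Pupil size (arbitrary units) tracks the latent vigilance trace (larger
#' pupil at higher vigilance) plus slow noise; blinks occur as a Poisson
#' process at `blink_rate` events per minute, each blanking 100 to 300 ms of
#' samples to missing values.
#'
#' @param latent Tibble with `time_s` and `vigilance` (1 Hz grid), e.g. one
#'   block of a session's `latent` table.
#' @param blink_rate Blinks per minute (>= 0).
#' @param fs Output sampling rate in Hz (default 1000).
#' @param seed Integer seed.
#' @return A tibble `time_s`, `size` (`NA` during blinks), `is_blink`.
#' @export
simulate_pupil <- function(latent, blink_rate = 15, fs = 1000, seed = 1) {
  stopifnot(blink_rate >= 0, fs > 0,
            all(c("time_s", "vigilance") %in% names(latent)))
  set.seed(seed)
  dur <- max(latent$time_s)
  t <- seq(0, dur, by = 1 / fs)
  v <- stats::approx(latent$time_s, latent$vigilance, xout = t,
                     rule = 2)$y
  slow <- stats::filter(stats::rnorm(length(t), 0, 0.004),
                        0.999, method = "recursive")
  size <- 3 + 1.5 * v + as.numeric(slow)
  is_blink <- rep(FALSE, length(t))
  n_blinks <- stats::rpois(1, blink_rate * dur / 60)
  if (n_blinks > 0) {
    onsets <- stats::runif(n_blinks, 0, dur)
    durs <- stats::runif(n_blinks, 0.1, 0.3)
    for (k in seq_len(n_blinks)) {
      sel <- t >= onsets[k] & t < onsets[k] + durs[k]
      is_blink[sel] <- TRUE
    }
  }
  size[is_blink] <- NA_real_
  tibble::tibble(time_s = t, size = size, is_blink = is_blink)
}
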