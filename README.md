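# wakewave

Local "sleep" doesn't wait for bedtime: during monotonous sustained-attention
tasks, high-amplitude delta-band (~1–4 Hz) **slow waves** — the signature of
NREM sleep — appear transiently in subsets of scalp electrodes while people
are awake and responding. Their location matters: frontal waves tend to
accompany impulsive behaviour and mind wandering, posterior waves sluggish
behaviour and mind blanking. `wakewave` packages the full analysis chain for
studying this phenomenon, for cognitive-neurophysiology researchers who want
a tested, reproducible implementation that runs end-to-end on synthetic data
(no recordings required).

The package provides:

* **Synthetic SART sessions** (`generate_session()`): continuous Go/NoGo
  stimulus streams (one NoGo per permuted block of nine, durations uniform
  0.75–1.25 s), experience-sampling probes every 30–70 s with ON / mind
  wandering (MW) / mind blanking (MB) reports, latent vigilance, ground-truth
  slow waves, drift-diffusion responses, pupil traces with blinks, and
  multi-channel EEG (`synthesize_eeg()`, EDF IO via `write_edf()`).
* **Slow-wave detection** (`detect_slow_waves()`): mastoid re-referencing,
  down-sampling to 128 Hz, a Chebyshev type-II band-pass (≥25 dB attenuation
  in the [0.1, 15] Hz stopband, <3 dB across the [1, 10] Hz passband),
  zero-crossing wave delimitation, artifact exclusions (positive peak
  >75 µV, within 1 s of >150 µV events, shorter than 143 ms), and selection
  of the top 10% of waves by peak-to-peak amplitude per electrode.
* **Behavioural scoring** (`score_trials()`, `preprobe_summary()`): misses,
  false alarms, RTs with the 300 ms exclusion, 20 s / 10 s / 4×5 s pre-probe
  windows, pupil blink-correction and 5-bin discretization.
* **Cluster-based permutation statistics** (`cluster_permutation()`):
  paired-t electrode maps, sign-flip permutation null of the maximal cluster
  mass (cluster-forming alpha 0.025 per tail, Monte Carlo p, Bonferroni
  across map families), montage adjacency from packaged 10-10 positions.
* **Drift-diffusion modelling** (`simulate_ddm_trials()`, `wfpt_density()`,
  `fit_ddm()`): a two-boundary DDM of Go/NoGo decisions with parameters
  v_Go, v_NoGo, a, z, t_nd and the derived drift bias
  v_Bias = |v_Go| − |v_NoGo|, fitted per condition (e.g. slow wave present
  vs absent at an electrode) by maximum likelihood with explicit deadline
  censoring; `tidy()`/`glance()` methods and `autoplot()` included.
* **One-call orchestration** (`run_pipeline()`, YAML configs, TSV + JSON
  manifest outputs) and a CLI wrapper (`inst/cli/wakewave.R`, subcommands
  `simulate | detect | behaviour | all`).

## Worked example

Inject known slow waves into 1/f background noise and detect them:

```r
library(wakewave)

fs <- 500
montage <- c("Fz", "Cz", "Pz", "TP9", "TP10")
truth <- tibble::tibble(channel = "Cz", onset_s = seq(10, 110, by = 10),
                        duration_s = 1.0, p2p_amp = 60)
eeg <- eeg_recording(matrix(0, fs * 120, 5), montage, fs, reference = "AFz")
eeg <- inject_slow_waves(eeg, truth, noise = noise_spec(rms = 10), seed = 2)
waves <- detect_slow_waves(eeg)
top_amplitude_thresholds(waves)
#> # A tibble: 3 × 4
#>   channel threshold n_candidates n_retained
#>   <chr>       <dbl>        <int>      <int>
#> 1 Cz           26.5          286         29
#> 2 Fz           25.7          297         30
#> 3 Pz           23.9          297         30
```

Per electrode, roughly 290 candidate waves survive the exclusions in two
minutes of noisy EEG and the top 10% (29–30 waves) are kept; the selection
threshold lands near 26 µV on 10 µV-RMS noise, and the ten injected 60 µV
waves on Cz all clear it. The designed filter itself reports

```r
f <- design_detection_filter(128)
filter_attenuation_db(f, c(0.1, 15))          # 26.0 26.0  (dB, stopband)
max(filter_attenuation_db(f, seq(1, 10, length.out = 100)))  # 1.75 (dB)
```

Simulate a whole session and score it:

```r
s <- generate_session(session_config(seed = 1))
s
#> <sart_session> 3020 stimuli, 60 probes, 21991 ground-truth waves (seed 1)
trials <- score_session(s)
dplyr::count(trials, outcome)
#> # A tibble: 5 × 2
#>   outcome          n
#> 1 correct_go    2369
#> 2 correct_nogo   271
#> 3 excluded        32
#> 4 false_alarm     63
#> 5 miss           285
```

(The mental-state contrasts — more misses before MB, more false alarms
before MW — are group-level effects; the test suite demonstrates them over
pooled simulated participants, and `run_pipeline()` reproduces the
frontal/posterior cluster dissociation over 16 subjects.)

Fit the drift-diffusion model to simulated Go/NoGo trials:

```r
fit <- fit_ddm(trials_tbl, seed = 7)   # trial_type, responded, rt_s, deadline_s
tidy(fit)
#>   parameter estimate
#> 1 v_go         2.66     # true 2.5
#> 2 v_nogo      -1.28     # true -1.3
#> 3 a            1.32     # true 1.4
#> 4 z            0.497    # true 0.55
#> 5 t_nd         0.299    # true 0.3
#> 6 v_bias       1.37
```

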