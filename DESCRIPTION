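Package: wakewave
Title: Sleep-Like Slow Waves During Wakefulness and Attentional Lapses
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for studying local sleep-like slow waves in waking
    electroencephalography (EEG) and their behavioural consequences during
    sustained-attention (Go/NoGo) tasks. The package generates fully
    synthetic task sessions with ground-truth slow waves, detects
    delta-band slow waves per electrode (Chebyshev type-II band-pass,
    zero-crossing wave delimitation, amplitude-based selection), scores
    trials and experience-sampling probes, runs cluster-based permutation
    statistics over the electrode montage, and simulates and fits a
    two-boundary drift-diffusion model of Go/NoGo decisions so that the
    effect of slow waves on decision sub-components can be mapped across
    the scalp.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    readr,
    rlang,
    signal,
    stats,
    tibble,
    tidyr,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
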