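#' Score all blocks of a synthetic session
#'
#' Applies [score_trials()] within each task and block (each block has its
#' own time base) and binds the results.
#'
#' @param session A `sart_session` from [generate_session()].
#' @return A tibble of scored trials with `task` and `block` columns.
#' @export
score_session <- function(session) {
  stopifnot(inherits(session, "sart_session"))
  session$stimuli |>
    dplyr::group_by(.data$task, .data$block) |>
    dplyr::group_modify(function(g, key) {
      resp <- session$responses[session$responses$task == key$task &
                                  session$responses$block == key$block, ]
      score_trials(g, resp)
    }) |>
    dplyr::ungroup()
}

#' Configuration of a full pipeline run
#'
#' @param n_subjects Number of simulated participants.
#' @param session A [session_config()] (per-subject seeds are derived from
#'   the run seed).
#' @param coupling A [coupling_params()].
#' @param detection A [detection_params()].
#' @param window_s Pre-probe analysis window in seconds (default 20).
#' @param contrasts List of length-2 character vectors of mental states to
#'   contrast (default MW>ON, MB>ON, MB>MW).
#' @param wave_features Wave summary columns mapped per probe window
#'   (default density, amplitude, both slopes).
#' @param cluster List of cluster-permutation settings: `alpha`, `n_perm`,
#'   `mc_threshold`, `n_comparisons` (default 12: three contrasts by four
#'   wave properties).
#' @param ddm_channels Electrodes at which trial-level wave flags condition
#'   the drift-diffusion fits (default `c("Fz", "Pz")`, one frontal and one
#'   posterior site).
#' @param detect_from_eeg If `TRUE`, synthesize block EEG and run the wave
#'   detector; if `FALSE` (default), use the generator's ground-truth wave
#'   table for the map stages, which exercises the identical downstream path
#'   at a fraction of the cost.
#' @param seed Run seed.
#' @return A list of class `run_config`.
#' @export
run_config <- function(n_subjects = 12,
                       session = session_config(),
                       coupling = coupling_params(),
                       detection = detection_params(),
                       window_s = 20,
                       contrasts = list(c("MW", "ON"), c("MB", "ON"),
                                        c("MB", "MW")),
                       wave_features = c("density", "mean_p2p_amp",
                                         "mean_down_slope", "mean_up_slope"),
                       cluster = list(alpha = 0.025, n_perm = 1000,
                                      mc_threshold = 0.05,
                                      n_comparisons = 12),
                       ddm_channels = c("Fz", "Pz"),
                       detect_from_eeg = FALSE,
                       seed = 1) {
  stopifnot(n_subjects >= 1, window_s > 0,
            inherits(session, "session_config"),
            inherits(coupling, "coupling_params"),
            inherits(detection, "detection_params"))
  structure(
    list(n_subjects = n_subjects, session = session, coupling = coupling,
         detection = detection, window_s = window_s, contrasts = contrasts,
         wave_features = wave_features, cluster = cluster,
         ddm_channels = ddm_channels, detect_from_eeg = detect_from_eeg,
         seed = as.integer(seed)),
    class = "run_config"
  )
}

#' Read a pipeline configuration from YAML
#'
#' Top-level keys mirror the arguments of [run_config()]; the nested
#' `session`, `coupling` and `detection` maps mirror [session_config()],
#' [coupling_params()] and [detection_params()]. Missing keys take the
#' defaults. Note that the mental-state label `ON` must be quoted in YAML
#' (`"ON"`), since a bare `ON` parses as a boolean.
#'
#' @param path YAML file path.
#' @return A `run_config`.
#' @export
read_run_config <- function(path) {
  y <- yaml::read_yaml(path)
  args <- list()
  simple <- intersect(names(y), c("n_subjects", "window_s", "ddm_channels",
                                  "detect_from_eeg", "seed",
                                  "wave_features"))
  args[simple] <- y[simple]
  if (!is.null(y$contrasts)) {
    args$contrasts <- lapply(y$contrasts, as.character)
  }
  if (!is.null(y$cluster)) {
    args$cluster <- utils::modifyList(
      list(alpha = 0.025, n_perm = 1000, mc_threshold = 0.05,
           n_comparisons = 12), y$cluster)
  }
  if (!is.null(y$session)) args$session <- do.call(session_config, y$session)
  if (!is.null(y$coupling)) {
    cp <- y$coupling
    if (!is.null(cp$ddm)) cp$ddm <- do.call(ddm_params, cp$ddm)
    if (!is.null(cp$state_base)) cp$state_base <- unlist(cp$state_base)
    args$coupling <- do.call(coupling_params, cp)
  }
  if (!is.null(y$detection)) {
    args$detection <- do.call(detection_params, y$detection)
  }
  do.call(run_config, args)
}

config_hash <- function(config) {
  rlang::hash(config)
}

#' Run the full analysis pipeline on synthetic sessions
#'
#' Simulates `n_subjects` sessions, obtains slow waves (detected from
#' synthesized EEG or taken from the ground-truth table, per the config),
#' scores behaviour, extracts pre-probe wave features per electrode, runs
#' the cluster-permutation contrasts between mental states, and fits the
#' drift-diffusion model by wave presence at the configured electrodes.
#'
#' @param config A [run_config()].
#' @param seed Overrides the config seed when given.
#' @param out_dir If non-`NULL`, writes all result tables as TSV plus a
#'   `manifest.json` into this directory.
#' @return A list of class `result_bundle`: `waves`, `trials`, `probes`,
#'   `summaries` (per probe by channel wave features), `stat_maps`,
#'   `clusters`, `ddm_fits`, `manifest`.
#' @export
run_pipeline <- function(config = run_config(), seed = NULL,
                         out_dir = NULL) {
  stopifnot(inherits(config, "run_config"))
  if (!is.null(seed)) config$seed <- as.integer(seed)
  channels <- setdiff(config$session$montage$channel, c("TP9", "TP10"))

  per_subject <- lapply(seq_len(config$n_subjects), function(s) {
    subj_seed <- as.integer((as.double(config$seed) * 7477 + s * 53) %%
                              2147483647)
    scfg <- config$session
    scfg$seed <- subj_seed
    sess <- generate_session(scfg, config$coupling, seed = subj_seed)
    waves <- if (config$detect_from_eeg) {
      detect_session_waves(sess, config$detection)
    } else {
      # ground-truth waves carry template geometry; derive the delimitation
      # quantities from it (half-sine lobes: negative peak at 0.225 of the
      # duration, positive peak at 0.725)
      sess$ground_truth_waves[, c("task", "block", "channel", "onset_s",
                                  "duration_s", "p2p_amp")] |>
        dplyr::rename(start_s = "onset_s") |>
        dplyr::mutate(
          end_s = .data$start_s + .data$duration_s,
          down_slope = (2 / 3 * .data$p2p_amp) / (0.225 * .data$duration_s),
          up_slope = .data$p2p_amp / (0.5 * .data$duration_s))
    }
    trials <- score_session(sess)
    probes <- sess$probes
    # per-probe wave summaries (pre-probe window), per electrode
    summaries <- probes |>
      dplyr::group_by(.data$task, .data$block) |>
      dplyr::group_modify(function(g, key) {
        w <- waves[waves$task == key$task & waves$block == key$block, ]
        win <- tibble::tibble(window_id = g$probe_id,
                              start_s = g$onset_s - config$window_s,
                              end_s = g$onset_s)
        summarize_waves(w, win, channels = channels) |>
          dplyr::rename(probe_id = "window_id")
      }) |>
      dplyr::ungroup() |>
      dplyr::left_join(
        probes[, c("probe_id", "mental_state", "vigilance")],
        by = "probe_id")
    list(subject = s, session = sess, waves = waves, trials = trials,
         probes = probes, summaries = summaries)
  })

  waves_all <- purrr::map_dfr(per_subject, function(p)
    dplyr::mutate(p$waves, subject = p$subject))
  trials_all <- purrr::map_dfr(per_subject, function(p)
    dplyr::mutate(p$trials, subject = p$subject))
  probes_all <- purrr::map_dfr(per_subject, function(p)
    dplyr::mutate(p$probes, subject = p$subject))
  summaries_all <- purrr::map_dfr(per_subject, function(p)
    dplyr::mutate(p$summaries, subject = p$subject))

  # cluster-permutation contrasts per wave feature
  adjacency <- build_adjacency(config$session$montage, channels = channels)
  stat_maps <- list()
  clusters <- list()
  feature_value <- function(df, feat) {
    v <- df[[feat]]
    if (feat != "density") v[is.na(v)] <- 0  # no-wave windows: property 0
    v
  }
  for (ct in config$contrasts) {
    for (feat in config$wave_features) {
      feats <- tibble::tibble(
        subject = summaries_all$subject,
        channel = summaries_all$channel,
        condition = summaries_all$mental_state,
        value = feature_value(summaries_all, feat))
      res <- tryCatch(
        cluster_permutation(
          feats, ct, adjacency,
          cluster_alpha = config$cluster$alpha,
          n_perm = config$cluster$n_perm,
          mc_threshold = config$cluster$mc_threshold,
          n_comparisons = config$cluster$n_comparisons,
          seed = config$seed),
        error = function(e) NULL)
      if (is.null(res)) next
      label <- paste(ct[1], ">", ct[2])
      sm <- attr(res, "stat_map")
      sm$contrast <- label; sm$feature <- feat
      stat_maps[[length(stat_maps) + 1]] <- sm
      if (nrow(res) > 0) {
        cl <- tibble::as_tibble(res)
        cl$channels <- vapply(cl$channels, paste, character(1),
                              collapse = ",")
        cl$contrast <- label; cl$feature <- feat
        clusters[[length(clusters) + 1]] <- cl
      }
    }
  }
  stat_maps <- dplyr::bind_rows(stat_maps)
  clusters <- if (length(clusters) > 0) dplyr::bind_rows(clusters) else
    tibble::tibble(cluster_id = integer(), channels = character(),
                   n_channels = integer(), mass = numeric(),
                   sign = integer(), p_cluster = numeric(),
                   significant = logical(), contrast = character(),
                   feature = character())

  # DDM by wave presence at selected electrodes (pre-probe trials only)
  ddm_fits <- ddm_by_wave_presence(trials_all, probes_all, waves_all,
                                   config$ddm_channels, config$window_s,
                                   seed = config$seed)

  manifest <- list(
    config_hash = config_hash(config),
    seed = config$seed,
    n_subjects = config$n_subjects,
    detect_from_eeg = config$detect_from_eeg,
    window_s = config$window_s,
    n_comparisons = config$cluster$n_comparisons,
    package_version = as.character(utils::packageVersion("wakewave"))
  )
  bundle <- structure(
    list(waves = waves_all, trials = trials_all, probes = probes_all,
         summaries = summaries_all, stat_maps = stat_maps,
         clusters = clusters, ddm_fits = ddm_fits, manifest = manifest),
    class = "result_bundle")
  if (!is.null(out_dir)) write_result_bundle(bundle, out_dir)
  bundle
}

# run the detector on synthesized EEG for every block of a session
detect_session_waves <- function(sess, detection) {
  blocks <- unique(sess$latent[, c("task", "block")])
  purrr::pmap_dfr(blocks, function(task, block) {
    eeg <- synthesize_eeg(sess, task = task, block = block)
    w <- detect_slow_waves(eeg, detection)
    if (nrow(w) == 0) return(w)
    dplyr::mutate(w, task = task, block = block,
                  duration_s = .data$end_s - .data$start_s)
  })
}

# Fit the DDM separately for wave-present and wave-absent trials at each
# electrode, pooling trials across subjects (trials restricted to the
# pre-probe window, mirroring the map analyses). Cells larger than
# max_trials_per_cell are subsampled (seeded) before fitting: the ML
# estimates are already stable well below that size and the cost of the
# likelihood is linear in the trial count.
ddm_by_wave_presence <- function(trials, probes, waves, channels, window_s,
                                 seed = 1, max_trials_per_cell = 4000,
                                 n_restarts = 2) {
  pre <- dplyr::inner_join(
    probes[, c("subject", "task", "block", "onset_s", "probe_id")] |>
      dplyr::rename(probe_onset_s = "onset_s"),
    trials, by = c("subject", "task", "block"),
    relationship = "many-to-many") |>
    dplyr::filter(.data$onset_s >= .data$probe_onset_s - window_s,
                  .data$onset_s < .data$probe_onset_s) |>
    dplyr::distinct(.data$subject, .data$task, .data$block, .data$trial,
                    .keep_all = TRUE)
  purrr::map_dfr(channels, function(ch) {
    flags <- pre |>
      dplyr::group_by(.data$subject, .data$task, .data$block) |>
      dplyr::group_modify(function(g, key) {
        w <- waves[waves$subject == key$subject & waves$task == key$task &
                     waves$block == key$block & waves$channel == ch, ]
        st <- sort(w$start_s)
        cnt <- findInterval(g$offset_s - 1e-9, st) -
          findInterval(g$onset_s - 1e-9, st)
        dplyr::mutate(g, wave_flag = cnt > 0)
      }) |>
      dplyr::ungroup()
    fit_in <- flags |>
      dplyr::filter(.data$outcome != "excluded") |>
      dplyr::mutate(
        trial_type = ifelse(.data$is_nogo, "nogo", "go"),
        responded = !is.na(.data$rt_ms),
        rt_s = .data$rt_ms / 1000,
        deadline_s = .data$offset_s - .data$onset_s,
        condition = ifelse(.data$wave_flag, "wave", "no_wave"))
    set.seed(seed)
    fit_in <- fit_in |>
      dplyr::group_by(.data$condition, .data$trial_type) |>
      dplyr::slice_sample(n = max_trials_per_cell) |>
      dplyr::ungroup()
    fit <- fit_ddm(fit_in[, c("trial_type", "responded", "rt_s",
                              "deadline_s", "condition")],
                   by = "condition", n_restarts = n_restarts, seed = seed)
    dplyr::mutate(fit, channel = ch)
  })
}

#' Write a result bundle to TSV files plus a JSON manifest
#'
#' @param bundle A `result_bundle` from [run_pipeline()].
#' @param out_dir Output directory (created if needed).
#' @return `out_dir`, invisibly.
#' @export
write_result_bundle <- function(bundle, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  tabs <- c("waves", "trials", "probes", "summaries", "stat_maps",
            "clusters", "ddm_fits")
  for (tb in tabs) {
    readr::write_tsv(bundle[[tb]], file.path(out_dir, paste0(tb, ".tsv")))
  }
  jsonlite::write_json(bundle$manifest,
                       file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE)
  invisible(out_dir)
}

#' @export
print.result_bundle <- function(x, ...) {
  cat(sprintf(paste0("<result_bundle> %d subjects, %d waves, %d probes, ",
                     "%d stat-map rows, %d clusters, %d DDM fits\n"),
              length(unique(x$trials$subject)), nrow(x$waves),
              nrow(x$probes), nrow(x$stat_maps), nrow(x$clusters),
              nrow(x$ddm_fits)))
  invisible(x)
}
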