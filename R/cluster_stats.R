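#' Per-electrode contrast map (paired t across subjects)
#'
#' Aggregates a per-probe (or per-trial) feature to one value per subject,
#' channel and condition level, then computes, for each electrode, the
#' within-subject difference between the two contrast levels divided by its
#' standard error across subjects (a paired t). Subjects missing either
#' level are dropped with a warning. A custom per-electrode statistic can be
#' plugged in via `stat_fn`.
#'
#' @param features Long tibble with columns `subject`, `channel`,
#'   `condition`, `value` (one row per observation; multiple rows per
#'   subject-channel-condition are averaged first).
#' @param contrast Length-2 character vector `c(level_a, level_b)`; the map
#'   tests `level_a - level_b` (positive t means larger under `level_a`).
#' @param stat_fn Optional function(diff_matrix) returning a list with
#'   elements `t` and `p` (vectors over channels); `diff_matrix` is subjects
#'   by channels. Default: paired t.
#' @return A tibble of class `electrode_stat_map`: `channel`, `t`, `p`,
#'   `df`, `n_subjects`, `contrast`.
#' @export
electrode_stat_map <- function(features, contrast, stat_fn = NULL) {
  d <- subject_difference_maps(features, contrast)
  stat <- (stat_fn %||% paired_t_stat)(d)
  tibble::tibble(
    channel = colnames(d),
    t = stat$t,
    p = stat$p,
    df = nrow(d) - 1,
    n_subjects = nrow(d),
    contrast = paste(contrast[1], ">", contrast[2])
  ) |> structure(class = c("electrode_stat_map", class(tibble::tibble())))
}

# subjects x channels matrix of within-subject mean differences
subject_difference_maps <- function(features, contrast) {
  stopifnot(all(c("subject", "channel", "condition", "value") %in%
                  names(features)),
            length(contrast) == 2)
  f <- features[features$condition %in% contrast, , drop = FALSE]
  agg <- f |>
    dplyr::group_by(.data$subject, .data$channel, .data$condition) |>
    dplyr::summarise(value = mean(.data$value, na.rm = TRUE),
                     .groups = "drop")
  wide <- tidyr::pivot_wider(agg, names_from = "condition",
                             values_from = "value")
  ok_subj <- wide |>
    dplyr::group_by(.data$subject) |>
    dplyr::summarise(
      usable = all(!is.na(.data[[contrast[1]]])) &&
        all(!is.na(.data[[contrast[2]]])), .groups = "drop")
  dropped <- ok_subj$subject[!ok_subj$usable]
  if (length(dropped) > 0) {
    warning("Dropping subject(s) lacking a contrast level: ",
            paste(dropped, collapse = ", "))
    wide <- wide[!wide$subject %in% dropped, , drop = FALSE]
  }
  if (length(unique(wide$subject)) < 2) {
    stop("Fewer than 2 usable subjects for contrast ",
         paste(contrast, collapse = " vs "))
  }
  wide$diff <- wide[[contrast[1]]] - wide[[contrast[2]]]
  m <- tidyr::pivot_wider(wide[, c("subject", "channel", "diff")],
                          names_from = "channel", values_from = "diff")
  out <- as.matrix(m[, -1, drop = FALSE])
  rownames(out) <- m$subject
  out
}

paired_t_stat <- function(d) {
  n <- nrow(d)
  m <- colMeans(d)
  se <- apply(d, 2, stats::sd) / sqrt(n)
  t <- unname(ifelse(se > 0, m / se, 0))
  list(t = t, p = 2 * stats::pt(-abs(t), df = n - 1))
}

# connected components of supra-threshold electrodes of one sign;
# neighbour list is a list of integer vectors
components_of <- function(members, nbrs) {
  if (length(members) == 0) return(list())
  in_set <- logical(length(nbrs))
  in_set[members] <- TRUE
  seen <- logical(length(nbrs))
  out <- list()
  for (s in members) {
    if (seen[s]) next
    stack <- s
    comp <- integer(0)
    seen[s] <- TRUE
    while (length(stack) > 0) {
      v <- stack[[length(stack)]]
      stack <- stack[-length(stack)]
      comp <- c(comp, v)
      for (w in nbrs[[v]]) {
        if (in_set[w] && !seen[w]) {
          seen[w] <- TRUE
          stack <- c(stack, w)
        }
      }
    }
    out[[length(out) + 1]] <- sort(comp)
  }
  out
}

# max |cluster mass| over both signs for one t map (for the null)
max_cluster_mass <- function(t, thr, nbrs) {
  best <- 0
  pos <- components_of(which(t > thr), nbrs)
  for (c0 in pos) best <- max(best, sum(t[c0]))
  neg <- components_of(which(t < -thr), nbrs)
  for (c0 in neg) best <- max(best, abs(sum(t[c0])))
  best
}

#' Cluster-based permutation test over the electrode montage
#'
#' Forms clusters of neighbouring electrodes whose per-electrode statistic
#' exceeds the cluster-forming threshold (`cluster_alpha` per tail, i.e.
#' electrodes with one-tailed p below 0.025 in the same direction), scores
#' each cluster by the sum of its member t values (cluster mass), and
#' compares observed masses to the permutation null distribution of the
#' maximal cluster mass obtained by within-subject sign flips of the
#' per-subject difference maps. When all `2^n` sign patterns number no more
#' than `n_perm`, the null is enumerated exhaustively. The Monte Carlo
#' cluster p value is `(1 + #permutations >= observed) / (1 + n_perm)`; a
#' cluster is significant when `p_cluster < mc_threshold / n_comparisons`
#' (Bonferroni across map families).
#'
#' @param features Long tibble as in [electrode_stat_map()].
#' @param contrast Length-2 character vector of condition levels.
#' @param adjacency Logical adjacency matrix from [build_adjacency()]; its
#'   channels must cover the feature channels.
#' @param cluster_alpha Per-tail cluster-forming alpha (default 0.025).
#' @param n_perm Number of permutations (default 1000, minimum 200).
#' @param mc_threshold Monte Carlo significance threshold (default 0.05).
#' @param n_comparisons Number of map families Bonferroni-corrected across
#'   (default 1).
#' @param seed Integer seed for the sign flips.
#' @param stat_fn Optional per-electrode statistic, as in
#'   [electrode_stat_map()]; the permutation null always uses the paired-t
#'   cluster machinery on the sign-flipped difference maps.
#' @return A tibble of class `cluster_result`: one row per cluster with
#'   `cluster_id`, `channels` (list column), `n_channels`, `mass`, `sign`,
#'   `p_cluster`, `significant`. The observed stat map is in the `stat_map`
#'   attribute; the null distribution in `null_max_mass`.
#' @export
cluster_permutation <- function(features, contrast, adjacency,
                                cluster_alpha = 0.025, n_perm = 1000,
                                mc_threshold = 0.05, n_comparisons = 1,
                                seed = 1, stat_fn = NULL) {
  stopifnot(n_perm >= 200, cluster_alpha > 0, cluster_alpha < 0.5,
            isTRUE(all.equal(adjacency, t(adjacency))))
  d <- subject_difference_maps(features, contrast)
  channels <- colnames(d)
  missing <- setdiff(channels, rownames(adjacency))
  if (length(missing) > 0) {
    stop("Channels absent from adjacency: ", paste(missing, collapse = ", "))
  }
  adj <- adjacency[channels, channels]
  nbrs <- lapply(seq_along(channels), function(i) which(adj[i, ]))
  n <- nrow(d)
  df <- n - 1
  thr <- stats::qt(1 - cluster_alpha, df)

  stat <- (stat_fn %||% paired_t_stat)(d)
  tobs <- stat$t

  # observed clusters (per tail, sign-consistent)
  clusters <- c(
    lapply(components_of(which(tobs > thr), nbrs), function(m)
      list(members = m, mass = sum(tobs[m]), sign = 1)),
    lapply(components_of(which(tobs < -thr), nbrs), function(m)
      list(members = m, mass = sum(tobs[m]), sign = -1))
  )

  # permutation null: max |cluster mass| under sign flips
  ss <- colSums(d^2)
  null_from_signs <- function(signs_mat) {
    mm <- signs_mat %*% d / n
    apply(rbind(mm), 1, function(mrow) {
      vr <- (ss - n * mrow^2) / (n - 1)
      tt <- ifelse(vr > 0, mrow / sqrt(vr / n), 0)
      max_cluster_mass(tt, thr, nbrs)
    })
  }
  if (2^n <= n_perm) {
    signs <- as.matrix(expand.grid(rep(list(c(-1, 1)), n)))
    storage.mode(signs) <- "double"
    null_max <- null_from_signs(signs)
    n_eff <- nrow(signs)
  } else {
    set.seed(seed)
    signs <- matrix(sample(c(-1, 1), n_perm * n, replace = TRUE),
                    nrow = n_perm)
    null_max <- null_from_signs(signs)
    n_eff <- n_perm
  }

  if (length(clusters) == 0) {
    out <- tibble::tibble(
      cluster_id = integer(), channels = list(), n_channels = integer(),
      mass = numeric(), sign = integer(), p_cluster = numeric(),
      significant = logical())
  } else {
    out <- purrr::imap_dfr(clusters, function(cl, i) {
      p <- (1 + sum(null_max >= abs(cl$mass))) / (1 + n_eff)
      tibble::tibble(
        cluster_id = i,
        channels = list(channels[cl$members]),
        n_channels = length(cl$members),
        mass = cl$mass,
        sign = cl$sign,
        p_cluster = p,
        significant = p < mc_threshold / n_comparisons)
    })
  }
  attr(out, "stat_map") <- tibble::tibble(channel = channels, t = tobs,
                                          p = stat$p)
  attr(out, "null_max_mass") <- null_max
  class(out) <- c("cluster_result", class(out))
  out
}

#' Family-wise error simulation for the cluster permutation procedure
#'
#' Simulates global-null datasets (per-probe feature values i.i.d. standard
#' normal, condition labels assigned at random within subject), runs the
#' cluster permutation on each, and reports the fraction of datasets with at
#' least one significant cluster -- the empirical family-wise error rate,
#' which should not exceed the Monte Carlo threshold.
#'
#' @param n_datasets Number of simulated null datasets.
#' @param n_subjects Subjects per dataset (default 26).
#' @param n_probes Probes per subject, split randomly between the two
#'   condition levels (default 60).
#' @param adjacency Adjacency matrix (default: full 63-channel montage).
#' @param cluster_alpha,n_perm,mc_threshold,n_comparisons Passed to
#'   [cluster_permutation()].
#' @param seed Integer seed.
#' @return A tibble with one row per dataset: `dataset`, `n_clusters`,
#'   `any_significant`; the empirical FWER is `mean(any_significant)`.
#' @export
cluster_fwer_simulation <- function(n_datasets, n_subjects = 26,
                                    n_probes = 60,
                                    adjacency = build_adjacency(montage_1010()),
                                    cluster_alpha = 0.025, n_perm = 1000,
                                    mc_threshold = 0.05, n_comparisons = 1,
                                    seed = 1) {
  channels <- rownames(adjacency)
  purrr::map_dfr(seq_len(n_datasets), function(ds) {
    set.seed(seed + ds * 7919L)
    feats <- purrr::map_dfr(seq_len(n_subjects), function(s) {
      cond <- sample(rep(c("A", "B"), length.out = n_probes))
      tibble::tibble(
        subject = s,
        probe = rep(seq_len(n_probes), each = length(channels)),
        channel = rep(channels, n_probes),
        condition = rep(cond, each = length(channels)),
        value = stats::rnorm(n_probes * length(channels))
      )
    })
    res <- cluster_permutation(
      feats, c("A", "B"), adjacency, cluster_alpha = cluster_alpha,
      n_perm = n_perm, mc_threshold = mc_threshold,
      n_comparisons = n_comparisons, seed = seed + ds)
    tibble::tibble(dataset = ds, n_clusters = nrow(res),
                   any_significant = any(res$significant))
  })
}
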