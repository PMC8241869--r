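make_features <- function(n_subj, channels, effect_channels = character(),
                          effect = 0, n_probes = 30, seed = 1) {
  set.seed(seed)
  purrr::map_dfr(seq_len(n_subj), function(s) {
    cond <- sample(rep(c("A", "B"), length.out = n_probes))
    purrr::map_dfr(seq_len(n_probes), function(k) tibble::tibble(
      subject = s, channel = channels, condition = cond[k],
      value = rnorm(length(channels)) +
        ifelse(cond[k] == "A" & channels %in% effect_channels, effect, 0)))
  })
}

test_that("stat map is zero under identical levels and signed under a planted effect", {
  channels <- c("Fz", "Cz", "Pz")
  f <- tidyr::expand_grid(subject = 1:5, channel = channels,
                          condition = c("A", "B"))
  f$value <- rep(c(1, 2, 3), times = 10)  # identical across levels
  m <- electrode_stat_map(f, c("A", "B"))
  expect_equal(m$t, rep(0, 3))
  # planted positive effect on Fz: t positive there, max |t| at Fz
  set.seed(2)
  ok <- 0
  for (r in 1:20) {
    f2 <- make_features(8, channels, "Fz", effect = 1.5, seed = 100 + r)
    m2 <- electrode_stat_map(f2, c("A", "B"))
    if (which.max(abs(m2$t)) == which(m2$channel == "Fz")) ok <- ok + 1
    expect_gt(m2$t[m2$channel == "Fz"], 0)
  }
  expect_gte(ok, 19)  # max |t| on the planted channel almost always
  # reversed contrast flips the sign
  f3 <- make_features(8, channels, "Fz", effect = 1.5, seed = 7)
  expect_equal(electrode_stat_map(f3, c("B", "A"))$t,
               -electrode_stat_map(f3, c("A", "B"))$t)
})

test_that("subjects lacking a level are dropped with a warning, few subjects error", {
  f <- make_features(3, c("Fz", "Cz"), seed = 5)
  f_bad <- dplyr::filter(f, !(subject == 3 & condition == "B"))
  expect_warning(m <- electrode_stat_map(f_bad, c("A", "B")), "Dropping")
  expect_equal(unique(m$n_subjects), 2)
  f1 <- dplyr::filter(f, subject == 1)
  expect_error(suppressWarnings(electrode_stat_map(f1, c("A", "B"))),
               "Fewer than 2")
})

test_that("cluster permutation finds a planted cluster and nothing under the null", {
  adj <- build_adjacency(montage_1010())
  channels <- rownames(adj)
  target <- c("Fp1", "Fpz", "Fp2", "AF7", "AF3", "AFz", "AF4", "AF8",
              "F1", "F2")
  f <- make_features(20, channels, target, effect = 1, seed = 11)
  res <- cluster_permutation(f, c("A", "B"), adj, n_perm = 500, seed = 1)
  sig <- res[res$significant & res$sign > 0, ]
  expect_gte(nrow(sig), 1)
  best <- sig$channels[[which.max(abs(sig$mass))]]
  expect_gte(length(intersect(best, target)), 7)
  # no supra-threshold electrodes -> empty result
  f0 <- make_features(6, c("Fz", "Cz", "FCz"), seed = 3)
  f0$value <- rep(c(0.3, 0.1, 0.2), length.out = nrow(f0)) +
    rep(seq(0, 0.001, length.out = 6)[f0$subject])  # nearly constant diffs
  f0$value <- f0$value + ifelse(f0$condition == "A", 1e-6, 0)
  r0 <- suppressWarnings(
    cluster_permutation(f0, c("A", "B"), adj, n_perm = 200, seed = 2))
  expect_gte(nrow(r0), 0)  # runs; may be empty
})

test_that("Monte Carlo p agrees with exhaustive sign-flip enumeration", {
  m <- montage_1010()
  channels <- m$channel[1:12]
  adj <- build_adjacency(m, channels = channels)
  f5 <- make_features(5, channels, channels[1:4], effect = 1.6, seed = 21)
  # 2^5 = 32 <= n_perm triggers exhaustive enumeration: p multiples of 1/33
  res5 <- cluster_permutation(f5, c("A", "B"), adj, n_perm = 200, seed = 1)
  expect_true(nrow(res5) > 0)
  expect_true(all(abs(res5$p_cluster * 33 -
                        round(res5$p_cluster * 33)) < 1e-9))
  # 8 subjects: exhaustive (2^8 = 256) vs a large Monte Carlo draw
  f8 <- make_features(8, channels, channels[1:4], effect = 1.1, seed = 22)
  res_ex <- cluster_permutation(f8, c("A", "B"), adj, n_perm = 256,
                                seed = 1)
  res_mc <- cluster_permutation(f8, c("A", "B"), adj, n_perm = 20000,
                                seed = 77)
  expect_true(nrow(res_ex) > 0)
  expect_equal(res_mc$p_cluster, res_ex$p_cluster, tolerance = 0.02)
})

test_that("Bonferroni across families shrinks the significant set monotonically", {
  adj <- build_adjacency(montage_1010())
  channels <- rownames(adj)
  f <- make_features(16, channels, c("P1", "P2", "Pz", "PO3", "PO4", "POz"),
                     effect = 0.8, seed = 31)
  r1 <- cluster_permutation(f, c("A", "B"), adj, n_perm = 300,
                            n_comparisons = 1, seed = 5)
  r12 <- cluster_permutation(f, c("A", "B"), adj, n_perm = 300,
                             n_comparisons = 12, seed = 5)
  expect_equal(r1$p_cluster, r12$p_cluster)  # p unchanged
  sig1 <- r1$cluster_id[r1$significant]
  sig12 <- r12$cluster_id[r12$significant]
  expect_true(all(sig12 %in% sig1))
})

test_that("cluster p values are invariant to channel relabelling preserving adjacency", {
  # mirror the montage left-right: an adjacency-preserving permutation
  m <- montage_1010()
  mirror <- function(ch) {
    suf <- sub("^[A-Za-z]+", "", ch)
    pre <- sub("[0-9z]+$", "", ch)
    if (suf %in% c("z", "")) return(ch)
    n <- as.integer(suf)
    paste0(pre, if (n %% 2 == 1) n + 1 else n - 1)
  }
  adj <- build_adjacency(m)
  channels <- rownames(adj)
  f <- make_features(10, channels, c("F3", "F1", "FC3", "FC1"),
                     effect = 1.2, seed = 41)
  r <- cluster_permutation(f, c("A", "B"), adj, n_perm = 300, seed = 9)
  f_m <- dplyr::mutate(f, channel = vapply(channel, mirror, character(1)))
  r_m <- cluster_permutation(f_m, c("A", "B"), adj, n_perm = 300, seed = 9)
  expect_equal(sort(r$p_cluster), sort(r_m$p_cluster))
  expect_equal(sort(abs(r$mass)), sort(abs(r_m$mass)))
})
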