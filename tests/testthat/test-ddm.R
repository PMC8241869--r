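test_that("simulator matches the analytic choice probability on a grid", {
  grid <- tidyr::expand_grid(v = c(-1.5, 0, 1.2), a = c(0.8, 1.4),
                             z = c(0.4, 0.55))
  for (i in seq_len(nrow(grid))) {
    g <- grid[i, ]
    tr <- tibble::tibble(v = g$v, a = g$a, z = g$z, t_nd = 0.2,
                         deadline_s = 60)[rep(1, 3000), ]
    sim <- simulate_ddm_trials(tr, seed = 100 + i)
    p_hat <- mean(sim$boundary == "respond")
    p_an <- ddm_choice_probability(g$v, g$a, g$z)
    expect_lt(abs(p_hat - p_an), 3.5 * sqrt(p_an * (1 - p_an) / 3000) + 0.005)
  }
  # symmetric case is exactly 1/2 in expectation
  expect_equal(ddm_choice_probability(0, 1.4, 0.5), 0.5)
  # all response times at least the non-decision time
  tr <- tibble::tibble(v = 1, a = 1, z = 0.5, t_nd = 0.25,
                       deadline_s = 5)[rep(1, 500), ]
  sim <- simulate_ddm_trials(tr, seed = 4)
  expect_true(all(sim$rt_s[!is.na(sim$rt_s)] >= 0.25))
})

test_that("first-passage densities are non-negative and integrate to one", {
  for (pars in list(c(2, 1.4, 0.55, 0.3), c(-0.9, 1.0, 0.5, 0.2),
                    c(0.5, 0.8, 0.4, 0.1))) {
    v <- pars[1]; a <- pars[2]; z <- pars[3]; tnd <- pars[4]
    tg <- seq(tnd + 1e-4, 40, length.out = 10000)
    du <- wfpt_density(tg, v, a, z, tnd, "respond")
    dl <- wfpt_density(tg, v, a, z, tnd, "withhold")
    expect_true(all(du >= 0) && all(dl >= 0))
    h <- diff(tg)[1]
    expect_equal(sum(du + dl) * h, 1, tolerance = 1e-4)
    # respond mass equals the analytic absorption probability
    expect_equal(sum(du) * h, ddm_choice_probability(v, a, z),
                 tolerance = 1e-4)
    # zero density at and before the non-decision time
    expect_equal(wfpt_density(c(0, tnd - 0.01, tnd), v, a, z, tnd,
                              "respond"), c(0, 0, 0))
  }
})

test_that("simulated RT histograms match the density curve", {
  v <- 1.8; a <- 1.2; z <- 0.5; tnd <- 0.25
  n <- 40000
  tr <- tibble::tibble(v = v, a = a, z = z, t_nd = tnd,
                       deadline_s = 30)[rep(1, n), ]
  sim <- simulate_ddm_trials(tr, seed = 8)
  rts <- sim$rt_s[sim$boundary == "respond"]
  breaks <- seq(tnd, 3, by = 0.05)
  counts <- hist(rts[rts < max(breaks)], breaks = breaks,
                 plot = FALSE)$counts
  # expected bin probabilities from the density (fine trapezoid per bin)
  p_bin <- vapply(seq_len(length(breaks) - 1), function(i) {
    tg <- seq(breaks[i], breaks[i + 1], length.out = 50)
    d <- wfpt_density(tg, v, a, z, tnd, "respond")
    sum((d[-1] + d[-50]) / 2) * diff(tg)[1]
  }, numeric(1))
  se <- sqrt(p_bin * (1 - p_bin) / n)
  # sup-norm over well-populated bins (normal approximation valid there);
  # the far tail is covered by the integral checks above
  ok <- n * p_bin >= 20
  dev <- abs(counts / n - p_bin)[ok] / se[ok]
  expect_gt(sum(ok), 25)
  expect_lt(max(dev), 4)
})

test_that("deadline censoring converges to the analytic withhold probability", {
  v <- 0.8; a <- 1.2; z <- 0.5; tnd <- 0.2
  p_lower <- 1 - ddm_choice_probability(v, a, z)
  for (dl in c(1, 3, 20)) {
    tr <- tibble::tibble(v = v, a = a, z = z, t_nd = tnd,
                         deadline_s = dl)[rep(1, 4000), ]
    sim <- simulate_ddm_trials(tr, seed = 40 + dl)
    p_wh <- mean(sim$boundary == "withhold")
    if (dl >= 20) {
      expect_lt(abs(p_wh - p_lower), 3.5 * sqrt(p_lower * (1 - p_lower) /
                                                  4000) + 0.005)
    } else {
      expect_gte(p_wh + 1e-9, p_lower)  # censoring only adds withholds
    }
  }
})

test_that("parameters are recovered within tolerance at 5000 trials per condition", {
  true <- list(v_go = 2.5, v_nogo = -1.3, a = 1.4, z = 0.55, t_nd = 0.3)
  n_go <- 4400; n_nogo <- 600
  set.seed(55)
  dl <- runif(n_go + n_nogo, 0.75, 1.25)
  type <- c(rep("go", n_go), rep("nogo", n_nogo))
  v <- ifelse(type == "go", true$v_go, true$v_nogo)
  sim <- simulate_ddm_trials(
    tibble::tibble(v = v, a = true$a, z = true$z, t_nd = true$t_nd,
                   deadline_s = dl), seed = 56)
  trials <- tibble::tibble(trial_type = type,
                           responded = sim$boundary == "respond",
                           rt_s = sim$rt_s, deadline_s = dl)
  fit <- fit_ddm(trials, n_restarts = 3, seed = 5)
  expect_true(fit$converged)
  expect_lt(abs(fit$v_go - true$v_go) / true$v_go, 0.1)
  expect_lt(abs(fit$v_nogo - true$v_nogo) / abs(true$v_nogo), 0.1)
  expect_lt(abs(fit$a - true$a) / true$a, 0.1)
  expect_lt(abs(fit$z - true$z), 0.05)
  expect_lt(abs(fit$t_nd - true$t_nd), 0.05)
  # v_bias is derived exactly
  expect_equal(fit$v_bias, abs(fit$v_go) - abs(fit$v_nogo))
})

test_that("a planted drift reduction in one condition is recovered", {
  set.seed(66)
  mk <- function(v_nogo, seed) {
    n_go <- 1800; n_nogo <- 450
    dl <- runif(n_go + n_nogo, 0.75, 1.25)
    type <- c(rep("go", n_go), rep("nogo", n_nogo))
    v <- ifelse(type == "go", 2.5, v_nogo)
    sim <- simulate_ddm_trials(
      tibble::tibble(v = v, a = 1.4, z = 0.55, t_nd = 0.3,
                     deadline_s = dl), seed = seed)
    tibble::tibble(trial_type = type,
                   responded = sim$boundary == "respond",
                   rt_s = sim$rt_s, deadline_s = dl)
  }
  wins <- 0
  for (r in 1:5) {
    ta <- dplyr::mutate(mk(-1.3, 200 + r), condition = "A")
    tb <- dplyr::mutate(mk(-0.45, 300 + r), condition = "B")
    fit <- fit_ddm(dplyr::bind_rows(ta, tb), by = "condition",
                   n_restarts = 3, seed = r)
    if (abs(fit$v_nogo[fit$condition == "B"]) <
        abs(fit$v_nogo[fit$condition == "A"])) wins <- wins + 1
  }
  expect_gte(wins, 5 * 0.9 - 1)  # >= 0.9 probability over replicates
})

test_that("ddm_params validates its contracts and single-trial wrapper works", {
  expect_error(ddm_params(v_go = -1), "v_go")
  expect_error(ddm_params(z = 1.2))
  expect_error(ddm_params(a = -0.5))
  p <- ddm_params()
  expect_equal(ddm_v_bias(p), abs(p$v_go) - abs(p$v_nogo))
  out <- simulate_ddm_trial(p, "go", deadline_s = 2, seed = 3)
  expect_equal(nrow(out), 1)
  expect_true(out$boundary %in% c("respond", "withhold"))
})

test_that("tidy and glance methods reshape fits", {
  set.seed(77)
  dl <- runif(800, 0.75, 1.25)
  sim <- simulate_ddm_trials(
    tibble::tibble(v = 2.5, a = 1.4, z = 0.55, t_nd = 0.3,
                   deadline_s = dl), seed = 78)
  trials <- tibble::tibble(trial_type = "go",
                           responded = sim$boundary == "respond",
                           rt_s = sim$rt_s, deadline_s = dl,
                           cond = rep(c("x", "y"), each = 400))
  fit <- fit_ddm(trials, by = "cond", n_restarts = 2, seed = 9)
  td <- tidy(fit)
  expect_equal(nrow(td), 12)  # 2 cells x 6 parameters
  expect_true(all(c("parameter", "estimate") %in% names(td)))
  gl <- glance(fit)
  expect_equal(nrow(gl), 2)
  expect_true(all(c("loglik", "converged") %in% names(gl)))
})

test_that("fitting with no responses at all is an error", {
  trials <- tibble::tibble(trial_type = "go", responded = FALSE,
                           rt_s = NA_real_, deadline_s = 1)[rep(1, 50), ]
  expect_error(fit_ddm(trials), "no responses")
})
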