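#' Drift-diffusion parameters for Go/NoGo decisions
#'
#' The two-boundary drift-diffusion model used throughout: evidence starts at
#' a relative point `z` of the boundary separation `a` and drifts with rate
#' `v_go` (positive-signed, towards the response boundary) on Go trials or
#' `v_nogo` (negative-signed) on NoGo trials, with unit noise scale. Hitting
#' the upper boundary produces a response after the non-decision time `t_nd`;
#' hitting the lower boundary (or reaching the deadline) withholds. The drift
#' bias `v_bias = |v_go| - |v_nogo|` is always derived, never stored.
#'
#' @param v_go Go-trial drift rate (1/s), must be >= 0.
#' @param v_nogo NoGo-trial drift rate (1/s), must be <= 0.
#' @param a Boundary separation (evidence units), > 0.
#' @param z Relative start point in (0, 1).
#' @param t_nd Non-decision time in seconds, >= 0.
#' @return A list of class `ddm_params`.
#' @export
ddm_params <- function(v_go = 2.5, v_nogo = -1.3, a = 1.4, z = 0.55,
                       t_nd = 0.3) {
  stopifnot(is.numeric(v_go), v_go >= 0, is.numeric(v_nogo), v_nogo <= 0,
            a > 0, z > 0, z < 1, t_nd >= 0)
  structure(list(v_go = v_go, v_nogo = v_nogo, a = a, z = z, t_nd = t_nd),
            class = "ddm_params")
}

#' Drift bias of a parameter set
#' @param params A [ddm_params()] or a data frame with `v_go`, `v_nogo`.
#' @return `|v_go| - |v_nogo|`; larger values mean a stronger bias towards
#'   responding.
#' @export
ddm_v_bias <- function(params) abs(params$v_go) - abs(params$v_nogo)

#' Analytic probability of hitting the response boundary
#'
#' Closed-form absorption probability at the upper (response) boundary for a
#' drift-diffusion process with drift `v`, boundary separation `a`, relative
#' start `z` and unit noise, ignoring any deadline:
#' `(exp(-2 v a z) - 1) / (exp(-2 v a) - 1)`, with the limit `z` as `v -> 0`.
#'
#' @param v Drift rate (1/s), any sign.
#' @param a Boundary separation.
#' @param z Relative start point in (0, 1).
#' @return Probability of responding (vectorized over `v`).
#' @export
ddm_choice_probability <- function(v, a, z) {
  stopifnot(a > 0, z > 0, z < 1)
  out <- ifelse(abs(v * a) < 1e-9,
                z,
                expm1(-2 * v * a * z) / expm1(-2 * v * a))
  as.numeric(out)
}

#' Simulate drift-diffusion trials (Euler-Maruyama)
#'
#' Simulates each trial's evidence path from `z * a` with time step `dt` and
#' unit noise until it is absorbed at a boundary or the deadline passes.
#' Upper-boundary absorption is a response with `rt_s` equal to the first
#' passage time plus `t_nd`; lower-boundary absorption and deadline censoring
#' are withholds (`rt_s` is `NA`). Responses whose total RT would exceed the
#' deadline are also censored to withholds.
#'
#' @param trials A tibble with one row per trial and columns `v` (signed
#'   drift for that trial), `a`, `z`, `t_nd`, `deadline_s`. Recycled scalars
#'   are allowed via [tibble::tibble()] rules upstream.
#' @param dt Integration step in seconds (must be <= 1 ms).
#' @param seed Integer seed.
#' @return A tibble with `boundary` (`"respond"`/`"withhold"`) and `rt_s`.
#' @export
simulate_ddm_trials <- function(trials, dt = 5e-4, seed = 1) {
  stopifnot(dt <= 1e-3, all(trials$deadline_s > trials$t_nd))
  n <- nrow(trials)
  set.seed(seed)
  boundary <- rep("withhold", n)
  rt <- rep(NA_real_, n)
  # packed working vectors over the still-active trials, compacted as
  # trials absorb, so each step costs O(active) with small constants
  idx <- seq_len(n)
  x <- trials$z * trials$a
  vdt <- trials$v * dt
  aa <- trials$a
  max_dec <- trials$deadline_s - trials$t_nd
  sdt <- sqrt(dt)
  tcur <- 0
  while (length(idx) > 0) {
    tcur <- tcur + dt
    prev <- x
    x <- x + vdt + sdt * stats::rnorm(length(x))
    hit_up <- x >= aa
    hit_lo <- !hit_up & x <= 0
    # Brownian-bridge correction: probability the path crossed a boundary
    # between checks even though both endpoints are inside (removes the
    # O(sqrt(dt)) first-passage bias of the plain Euler scheme)
    inside <- !hit_up & !hit_lo & prev < aa & prev > 0
    if (any(inside)) {
      p_up <- exp(-2 * (aa[inside] - prev[inside]) * (aa[inside] - x[inside]) / dt)
      p_lo <- exp(-2 * prev[inside] * x[inside] / dt)
      u <- stats::runif(sum(inside))
      hit_up[inside] <- u < p_up
      hit_lo[inside] <- !hit_up[inside] & u < p_up + p_lo
    }
    if (any(hit_up)) {
      won <- idx[hit_up]
      boundary[won] <- "respond"
      rt[won] <- tcur + trials$t_nd[won]
    }
    done <- hit_up | hit_lo | tcur >= max_dec
    if (any(done)) {
      keep <- !done
      idx <- idx[keep]; x <- x[keep]; vdt <- vdt[keep]; aa <- aa[keep]
      max_dec <- max_dec[keep]
    }
  }
  censor <- !is.na(rt) & rt > trials$deadline_s
  boundary[censor] <- "withhold"; rt[censor] <- NA_real_
  tibble::tibble(boundary = boundary, rt_s = rt)
}

#' Simulate a single Go/NoGo drift-diffusion trial
#'
#' @param params A [ddm_params()].
#' @param trial_type `"go"` or `"nogo"`; selects `v_go` or `v_nogo`.
#' @param deadline_s Response deadline in seconds (> `t_nd`).
#' @param dt Integration step (s), <= 1 ms.
#' @param seed Integer seed.
#' @return A one-row tibble with `boundary` and `rt_s`.
#' @export
simulate_ddm_trial <- function(params, trial_type = c("go", "nogo"),
                               deadline_s = 1, dt = 5e-4, seed = 1) {
  stopifnot(inherits(params, "ddm_params"))
  trial_type <- match.arg(trial_type)
  v <- if (trial_type == "go") params$v_go else params$v_nogo
  simulate_ddm_trials(
    tibble::tibble(v = v, a = params$a, z = params$z, t_nd = params$t_nd,
                   deadline_s = deadline_s),
    dt = dt, seed = seed)
}

# Wiener first-passage density at the LOWER boundary for drift v, boundary
# separation a, relative start w, unit noise, at decision times tau > 0.
# Small-time and large-time series with the standard switching rule; both
# truncations chosen for absolute error below 1e-10 in the scaled density.
wfpt_lower_scaled <- function(tau, w) {
  # density in scaled time tau = t / a^2 for a = 1, v = 0 start w
  out <- numeric(length(tau))
  pos <- which(tau > 0)
  if (length(pos) == 0) return(out)
  tt <- tau[pos]
  eps <- 1e-10
  # required terms (Navarro & Fuss 2009 bounds)
  ks <- ceiling(pmax(sqrt(tt) + 1,
                     sqrt(pmax(-2 * tt * log(2 * eps * sqrt(2 * pi * tt)), 0)) /
                       (2 * sqrt(tt)) + 1))
  kl <- ceiling(pmax(1 / (pi * sqrt(tt)),
                     sqrt(pmax(-2 * log(pi * tt * eps), 0) / (pi^2 * tt))))
  use_small <- ks < kl
  f <- numeric(length(tt))
  if (any(use_small)) {
    ts <- tt[use_small]
    K <- max(ks[use_small])
    kk <- seq(-floor((K - 1) / 2), ceiling((K - 1) / 2))
    acc <- 0
    for (k in kk) {
      acc <- acc + (w + 2 * k) * exp(-(w + 2 * k)^2 / (2 * ts))
    }
    f[use_small] <- acc / sqrt(2 * pi * ts^3)
  }
  if (any(!use_small)) {
    tl <- tt[!use_small]
    K <- max(kl[!use_small])
    acc <- 0
    for (k in seq_len(K)) {
      acc <- acc + k * exp(-k^2 * pi^2 * tl / 2) * sin(k * pi * w)
    }
    f[!use_small] <- acc * pi
  }
  out[pos] <- pmax(f, 0)
  out
}

#' First-passage time density of the drift-diffusion model
#'
#' Probability density of absorption at the response (`"respond"`, upper) or
#' withhold (`"withhold"`, lower) boundary at time `t`, for drift `v`,
#' boundary separation `a`, relative start `z`, non-decision time `t_nd` and
#' unit noise. Computed with the standard small-time/large-time series
#' expansions with an automatic switching rule. The density is zero for
#' `t <= t_nd`, and the two boundary densities integrate to one (when no
#' deadline truncates the process).
#'
#' @param t Times in seconds (vectorized).
#' @param v Signed drift rate.
#' @param a Boundary separation.
#' @param z Relative start point in (0, 1).
#' @param t_nd Non-decision time (s).
#' @param boundary `"respond"` (upper) or `"withhold"` (lower).
#' @return Density values (1/s).
#' @export
wfpt_density <- function(t, v, a, z, t_nd = 0,
                         boundary = c("respond", "withhold")) {
  boundary <- match.arg(boundary)
  stopifnot(a > 0, z > 0, z < 1)
  if (boundary == "respond") { v <- -v; w <- 1 - z } else w <- z
  tdec <- t - t_nd
  tau <- tdec / a^2
  dens <- wfpt_lower_scaled(tau, w) / a^2
  dens * exp(-v * a * w - v^2 * tdec / 2) * as.numeric(tdec > 0)
}

# cumulative first-passage probability at the response boundary on a grid,
# by trapezoidal integration of wfpt_density; returns an interpolator
ddm_response_cdf_fun <- function(v, a, z, t_nd, t_max, n_grid = 500) {
  if (t_max <= t_nd) return(function(t) rep(0, length(t)))
  tg <- seq(t_nd, t_max, length.out = n_grid)
  d <- wfpt_density(tg, v, a, z, t_nd, boundary = "respond")
  cdf <- c(0, cumsum((d[-1] + d[-length(d)]) / 2 * diff(tg)))
  function(t) {
    out <- stats::approx(tg, cdf, xout = pmin(pmax(t, t_nd), t_max),
                         rule = 2)$y
    out[t <= t_nd] <- 0
    out
  }
}

#' Fit the Go/NoGo drift-diffusion model by maximum likelihood
#'
#' Non-hierarchical maximum-likelihood fitting per condition cell. Response
#' trials contribute the response-boundary first-passage density at their RT
#' ([wfpt_density()]); withheld trials (misses and correct withholds alike)
#' contribute the probability of not having hit the response boundary by the
#' trial deadline (lower-boundary absorption plus deadline censoring,
#' obtained by integrating the response density tail). `v_go` applies to Go
#' trials, `v_nogo` to NoGo trials; `a`, `z`, `t_nd` are shared within a
#' cell. Optimization is bounded quasi-Newton (L-BFGS-B) from `n_restarts`
#' seeded random starting points; the best converged solution wins.
#'
#' @param trials A tibble with columns `trial_type` (`"go"`/`"nogo"`),
#'   `responded` (logical), `rt_s` (s, `NA` when not responded), `deadline_s`
#'   (s), plus any condition columns.
#' @param by Character vector of condition columns to fit separately
#'   (default none: one fit over all trials).
#' @param n_restarts Number of random restarts.
#' @param seed Integer seed for the restart draws.
#' @return A tibble of class `ddm_fit`: one row per condition cell with
#'   `v_go`, `v_nogo`, `a`, `z`, `t_nd`, `v_bias`, `loglik`, `converged`,
#'   `n_trials`, `n_responses`.
#' @export
fit_ddm <- function(trials, by = character(), n_restarts = 5, seed = 1) {
  stopifnot(all(c("trial_type", "responded", "rt_s", "deadline_s") %in%
                  names(trials)),
            all(trials$trial_type %in% c("go", "nogo")))
  groups <- if (length(by) == 0) {
    list(trials)
  } else {
    split(trials, trials[by], drop = TRUE)
  }
  fits <- purrr::imap_dfr(groups, function(g, key) {
    fit <- fit_ddm_cell(g, n_restarts = n_restarts, seed = seed)
    if (length(by) > 0) {
      fit <- dplyr::bind_cols(g[1, by, drop = FALSE], fit)
    }
    fit
  })
  class(fits) <- c("ddm_fit", class(fits))
  fits
}

fit_ddm_cell <- function(g, n_restarts, seed) {
  if (!any(g$responded)) stop("Cannot fit a DDM with no responses at all")
  rts <- g$rt_s[g$responded]
  min_rt <- min(rts)
  t_max <- max(g$deadline_s)
  types <- unique(g$trial_type)
  resp_rt <- lapply(types, function(ty) g$rt_s[g$trial_type == ty &
                                                 g$responded])
  held_dl <- lapply(types, function(ty) g$deadline_s[g$trial_type == ty &
                                                       !g$responded])
  names(resp_rt) <- names(held_dl) <- types
  nll <- function(th) {
    v_go <- th[1]; v_nogo <- th[2]; a <- th[3]; z <- th[4]; t_nd <- th[5]
    ll <- 0
    for (type in types) {
      v <- if (type == "go") v_go else v_nogo
      if (length(resp_rt[[type]]) > 0) {
        d <- wfpt_density(resp_rt[[type]], v, a, z, t_nd,
                          boundary = "respond")
        ll <- ll + sum(log(pmax(d, 1e-12)))
      }
      if (length(held_dl[[type]]) > 0) {
        cdf <- ddm_response_cdf_fun(v, a, z, t_nd, t_max)
        p_no <- 1 - cdf(held_dl[[type]])
        ll <- ll + sum(log(pmax(p_no, 1e-12)))
      }
    }
    -ll
  }
  lower <- c(0.01, -8, 0.3, 0.05, 0.01)
  upper <- c(8, -0.01, 4, 0.95, max(min_rt - 1e-3, 0.012))
  set.seed(seed)
  starts <- replicate(n_restarts, stats::runif(5, lower, upper * 0.999),
                      simplify = FALSE)
  starts[[1]] <- pmin(pmax(c(2, -1, 1.5, 0.5, 0.8 * min_rt), lower),
                      upper * 0.999)
  best <- NULL
  for (s in starts) {
    res <- tryCatch(
      stats::optim(s, nll, method = "L-BFGS-B", lower = lower, upper = upper,
                   control = list(maxit = 300)),
      error = function(e) NULL)
    if (is.null(res)) next
    if (is.null(best) || res$value < best$value) best <- res
  }
  if (is.null(best)) stop("DDM optimization failed from all starting points")
  th <- best$par
  tibble::tibble(
    v_go = th[1], v_nogo = th[2], a = th[3], z = th[4], t_nd = th[5],
    v_bias = abs(th[1]) - abs(th[2]),
    loglik = -best$value,
    converged = best$convergence == 0,
    n_trials = nrow(g),
    n_responses = sum(g$responded)
  )
}

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' Tidy a fitted drift-diffusion model
#'
#' @param x A `ddm_fit` from [fit_ddm()].
#' @param ... Unused.
#' @return A long tibble: condition columns, `parameter`, `estimate`.
#' @export
tidy.ddm_fit <- function(x, ...) {
  tibble::as_tibble(x) |>
    tidyr::pivot_longer(
      cols = dplyr::all_of(c("v_go", "v_nogo", "a", "z", "t_nd", "v_bias")),
      names_to = "parameter", values_to = "estimate")
}

#' One-row-per-cell summary of a fitted drift-diffusion model
#'
#' @param x A `ddm_fit` from [fit_ddm()].
#' @param ... Unused.
#' @return A tibble with `loglik`, `converged`, `n_trials`, `n_responses`
#'   per condition cell.
#' @export
glance.ddm_fit <- function(x, ...) {
  tibble::as_tibble(x) |>
    dplyr::select(-dplyr::all_of(c("v_go", "v_nogo", "a", "z", "t_nd",
                                   "v_bias")))
}
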