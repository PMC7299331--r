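#' Rescaled analysis of the frustrated feed-forward fiber
#'
#' For the UNSAT-FFF (activator input X, repressor autoregulator Y driving
#' itself and Z) with the drive held above its threshold, the rescaled
#' variable psi_t = y_t / k_y obeys
#'
#'   psi_{t+1} = beta * psi_t + alpha * lambda * theta(1 - psi_t)
#'
#' with beta = 1 - alpha and the dimensionless gain
#' lambda = gamma_x * gamma_y / (k_y * alpha). The map oscillates iff
#' lambda > 1; for lambda < 1 it converges monotonically to the fixed point
#' psi = lambda. The relaxation time is tau = -1 / log(1 - alpha) steps.
#'
#' @param alpha degradation rate in (0, 1).
#' @param gamma_x,gamma_y interaction strengths of X and Y.
#' @param k_y dissociation threshold of Y.
#' @return list with `lambda`, `beta`, `tau`, `phase` ("oscillatory" or
#'   "fixed_point"; "boundary" at lambda == 1) and `fixed_point` (the rescaled
#'   fixed point lambda when lambda < 1, otherwise NA).
#' @export
unsat_fff_analysis <- function(alpha, gamma_x, gamma_y, k_y) {
  stopifnot(alpha > 0, alpha < 1, gamma_x > 0, gamma_y > 0, k_y > 0)
  lam <- gamma_x * gamma_y / (k_y * alpha)
  phase <- if (lam > 1) "oscillatory" else if (lam < 1) "fixed_point" else "boundary"
  list(lambda = lam, beta = 1 - alpha, tau = -1 / log(1 - alpha),
       phase = phase,
       fixed_point = if (lam < 1) lam else NA_real_)
}

#' Iterate the rescaled UNSAT-FFF map
#'
#' The one-dimensional map psi_{t+1} = beta psi_t + alpha lambda theta(1-psi),
#' i.e. the exact dynamics of the frustrated fiber with the drive above
#' threshold. This is the simulation oracle for [unsat_fff_closed_form].
#'
#' @param lambda dimensionless gain.
#' @param alpha degradation rate.
#' @param psi0 initial rescaled level.
#' @param T steps.
#' @param theta_at_zero step-function convention at equality (default 1).
#' @return numeric vector psi_0..psi_T (length T + 1).
#' @export
unsat_fff_map <- function(lambda, alpha, psi0, T, theta_at_zero = 1) {
  beta <- 1 - alpha
  psi <- numeric(T + 1)
  psi[1] <- psi0
  for (t in seq_len(T)) {
    p <- psi[t]
    on <- if (p < 1) 1 else if (p == 1) theta_at_zero else 0
    psi[t + 1] <- beta * p + alpha * lambda * on
  }
  psi
}

#' Piecewise closed-form solution of the UNSAT-FFF map
#'
#' Alternates exponential decay segments psi_t = psi_s e^{-(t-s)/tau} (while
#' psi > 1, production off) with relaxation segments
#' psi_t = psi_s e^{-(t-s)/tau} + lambda (1 - e^{-(t-s)/tau}) (while psi <= 1,
#' production on). Segment lengths are the ceiling switch times
#' t1 = ceil(tau log psi0), t2 = t1 + ceil(tau log((lambda - psi1)/(lambda - 1))),
#' t3 = t2 + ceil(tau log psi2), continued periodically. For lambda < 1 and
#' psi0 < 1 the single monotone segment converges to lambda.
#'
#' @param alpha degradation rate.
#' @param lambda dimensionless gain.
#' @param psi0 initial rescaled level.
#' @param T steps.
#' @return list with `psi` (length T + 1), `switch_times` (t1, t2, ...; the
#'   cumulative regime-change steps within 0..T), `tau` and `lambda`.
#' @export
unsat_fff_closed_form <- function(alpha, lambda, psi0, T) {
  stopifnot(alpha > 0, alpha < 1, psi0 >= 0, T >= 1)
  beta <- 1 - alpha
  tau <- -1 / log(beta)
  psi <- numeric(T + 1)
  psi[1] <- psi0
  switches <- integer(0)
  t_cur <- 0L
  p_cur <- psi0
  if (psi0 <= 1 && lambda <= 1) {
    tt <- seq_len(T)
    psi[tt + 1] <- p_cur * beta^tt + lambda * (1 - beta^tt)
    return(list(psi = psi, switch_times = integer(0), tau = tau, lambda = lambda))
  }
  if (psi0 > 1 && lambda <= 1) {
    # one decay segment, then the monotone branch; no further switches
    d <- ceiling(tau * log(p_cur))
    d <- max(d, 1L)
    n_take <- min(d, T - t_cur)
    if (n_take > 0) {
      tt <- seq_len(n_take)
      psi[t_cur + tt + 1] <- p_cur * beta^tt
    }
    if (d <= T - t_cur) switches <- c(switches, t_cur + d)
    p_cur <- p_cur * beta^d
    t_cur <- t_cur + as.integer(d)
    if (t_cur < T) {
      tt <- seq_len(T - t_cur)
      psi[t_cur + tt + 1] <- p_cur * beta^tt + lambda * (1 - beta^tt)
    }
    return(list(psi = psi, switch_times = switches, tau = tau, lambda = lambda))
  }
  # lambda > 1: alternating decay / relaxation segments
  while (t_cur < T) {
    if (p_cur > 1) {
      d <- max(ceiling(tau * log(p_cur)), 1L)
      seg <- function(tt) p_cur * beta^tt
    } else {
      d <- max(ceiling(tau * log((lambda - p_cur) / (lambda - 1))), 1L)
      seg <- function(tt) p_cur * beta^tt + lambda * (1 - beta^tt)
    }
    n_take <- min(d, T - t_cur)
    tt <- seq_len(n_take)
    psi[t_cur + tt + 1] <- seg(tt)
    if (d <= T - t_cur) switches <- c(switches, t_cur + as.integer(d))
    p_cur <- seg(d)
    t_cur <- t_cur + as.integer(d)
  }
  list(psi = psi, switch_times = switches, tau = tau, lambda = lambda)
}

#' Oscillation phase diagram of the frustrated fiber
#'
#' Classifies each point of a grid over (gamma_x / alpha, gamma_y / k_y) by
#' the analytic condition: oscillatory iff
#' (gamma_y / k_y) * (gamma_x / alpha) > 1, i.e. the phase boundary is
#' gamma_y / k_y = (gamma_x / alpha)^{-1}.
#'
#' @param gx_over_alpha,gy_over_ky positive numeric vectors spanning the grid.
#' @param boundary_tol half-width of the band labelled "boundary" around
#'   lambda = 1.
#' @return data frame with columns `gx_over_alpha`, `gy_over_ky`, `lambda`,
#'   `phase`.
#' @export
phase_diagram <- function(gx_over_alpha, gy_over_ky, boundary_tol = 1e-12) {
  stopifnot(all(gx_over_alpha > 0), all(gy_over_ky > 0))
  grid <- expand.grid(gx_over_alpha = gx_over_alpha,
                      gy_over_ky = gy_over_ky)
  grid$lambda <- grid$gx_over_alpha * grid$gy_over_ky
  grid$phase <- ifelse(abs(grid$lambda - 1) <= boundary_tol, "boundary",
                       ifelse(grid$lambda > 1, "oscillatory", "fixed_point"))
  grid
}

#' Locate the oscillation threshold by bisection on lambda
#'
#' Simulates the rescaled UNSAT-FFF map at each trial gain and classifies the
#' trajectory with [detect_oscillation], bisecting on lambda until the
#' bracketing interval is narrower than `tol`.
#'
#' @param lo,hi initial bracket (lo non-oscillatory, hi oscillatory).
#' @param alpha degradation rate.
#' @param psi0 initial rescaled level.
#' @param T simulation length per trial.
#' @param tol bracket width at which to stop.
#' @param burn_in burn-in passed to the detector (default 0.5 * T).
#' @return the midpoint estimate of the critical lambda.
#' @export
oscillation_threshold <- function(lo = 0.5, hi = 2, alpha = 0.2, psi0 = 0.5,
                                  T = 2000, tol = 1e-3, burn_in = floor(T / 2)) {
  classify <- function(lam) {
    psi <- unsat_fff_map(lam, alpha, psi0, T)
    detect_oscillation(psi, burn_in = burn_in)$oscillating
  }
  if (classify(lo)) stop("lower bracket already oscillates")
  if (!classify(hi)) stop("upper bracket does not oscillate")
  while (hi - lo > tol) {
    mid <- (lo + hi) / 2
    if (classify(mid)) hi <- mid else lo <- mid
  }
  (lo + hi) / 2
}
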