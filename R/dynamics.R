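#' Parameters of the Boolean-threshold dynamics
#'
#' The simulator implements a discrete-time, continuous-state threshold model
#' in the Glass-Kauffman tradition. For a gene g with regulators r_1..r_m the
#' update is
#'
#'   s_g(t+1) = (1 - alpha) * s_g(t) + P_g(t)
#'
#' where the production term P_g combines, under the chosen gate, one factor
#' gamma_r * theta(s_r - k_r) per activator r and gamma_r * theta(k_r - s_r)
#' per repressor r. The AND gate multiplies the factors; the OR gate takes
#' their maximum. theta is the Heaviside step; its value at exactly zero is
#' the convention `theta_at_zero` (default 1, i.e. active at equality).
#'
#' @param alpha degradation rate per step, in (0, 1).
#' @param gamma named numeric vector: interaction strength (maximum expression
#'   rate, expression units/step) per regulator gene.
#' @param k named numeric vector: dissociation threshold (expression units)
#'   per regulator gene.
#' @param gate `"AND"` or `"OR"`: combination rule for multiple regulators.
#' @param theta_at_zero value of the step function at exact threshold (0 or 1).
#' @param undriven `"decay"` (default) or `"hold"`: behaviour of genes with no
#'   regulators and no drive.
#' @return an object of class `dynamics_spec`.
#' @export
dynamics_spec <- function(alpha, gamma, k, gate = c("AND", "OR"),
                          theta_at_zero = 1, undriven = c("decay", "hold")) {
  gate <- match.arg(gate)
  undriven <- match.arg(undriven)
  stopifnot(is.numeric(alpha), length(alpha) == 1, alpha > 0, alpha < 1)
  stopifnot(all(gamma > 0), all(k > 0))
  stopifnot(!is.null(names(gamma)), !is.null(names(k)))
  stopifnot(theta_at_zero %in% c(0, 1))
  structure(list(alpha = alpha, gamma = gamma, k = k, gate = gate,
                 theta_at_zero = theta_at_zero, undriven = undriven),
            class = "dynamics_spec")
}

theta_step <- function(x, at_zero = 1) {
  ifelse(x > 0, 1, ifelse(x == 0, at_zero, 0))
}

#' Drive signals for input genes
#'
#' An input gene's expression is set directly by its drive at every time step
#' (it is held by the environment rather than obeying the decay equation).
#'
#' @param level constant expression level.
#' @return an object of class `drive_signal`.
#' @export
drive_constant <- function(level) {
  stopifnot(level >= 0)
  structure(list(kind = "constant", level = level), class = "drive_signal")
}

#' @rdname drive_constant
#' @param high,low expression levels of the high and low half-waves
#'   (`high > low >= 0`).
#' @param period period in steps (>= 2).
#' @param duty fraction of the period spent high (default 0.5).
#' @param phase phase offset in steps.
#' @export
drive_square <- function(high, low = 0, period = 50, duty = 0.5, phase = 0) {
  stopifnot(high > low, low >= 0, period >= 2, duty > 0, duty < 1)
  structure(list(kind = "square_wave", high = high, low = low,
                 period = period, duty = duty, phase = phase),
            class = "drive_signal")
}

#' @rdname drive_constant
#' @param drive a `drive_signal`.
#' @param t integer time step(s).
#' @export
drive_value <- function(drive, t) {
  stopifnot(inherits(drive, "drive_signal"))
  if (drive$kind == "constant") return(rep(drive$level, length(t)))
  pos <- (t + drive$phase) %% drive$period
  ifelse(pos < drive$duty * drive$period, drive$high, drive$low)
}

# production factor of one regulator edge
production_factor <- function(sign, level, gamma, k, at_zero) {
  arg <- if (sign == "activator") level - k else k - level
  gamma * theta_step(arg, at_zero)
}

#' One step of the threshold dynamics
#'
#' Genes listed in `drive` are pinned to their drive level. Regulated genes
#' follow the decay-plus-production update; unregulated, undriven genes decay
#' by (1 - alpha) (or hold, per the spec).
#'
#' @param net a [regnet]; must have no unknown-sign edge into a regulated gene.
#' @param spec a [dynamics_spec].
#' @param state named numeric vector of current expression levels (all genes).
#' @param drive named numeric vector of drive levels for input genes (may be
#'   empty).
#' @return named numeric vector: the next state.
#' @export
step_state <- function(net, spec, state, drive = numeric(0)) {
  stopifnot(inherits(net, "regnet"), inherits(spec, "dynamics_spec"))
  stopifnot(setequal(names(state), net$genes))
  state <- state[net$genes]
  if (any(state < 0)) stop("state must be non-negative")
  inx <- in_edges_index(net)
  out <- state
  for (g in net$genes) {
    if (g %in% names(drive)) {
      out[g] <- drive[[g]]
      next
    }
    ine <- inx[[g]]
    if (is.null(ine) || nrow(ine) == 0) {
      out[g] <- if (spec$undriven == "decay") (1 - spec$alpha) * state[[g]] else state[[g]]
      next
    }
    if (any(ine$sign == "unknown")) {
      stop("unknown-sign edge into regulated gene ", g,
           "; dynamics require signed regulation")
    }
    miss <- setdiff(ine$source, intersect(names(spec$gamma), names(spec$k)))
    if (length(miss) > 0) {
      stop("missing gamma/k for regulator(s): ", paste(miss, collapse = ", "))
    }
    fac <- mapply(function(src, sgn) {
      production_factor(sgn, state[[src]], spec$gamma[[src]], spec$k[[src]],
                        spec$theta_at_zero)
    }, ine$source, ine$sign)
    prod_term <- if (spec$gate == "AND") prod(fac) else max(fac)
    out[g] <- (1 - spec$alpha) * state[[g]] + prod_term
  }
  out
}

#' Simulate the threshold dynamics
#'
#' Iterates [step_state] for `T` steps. Driven genes take their drive value at
#' every recorded time, including t = 0.
#'
#' @param net a [regnet].
#' @param spec a [dynamics_spec].
#' @param initial named numeric vector of initial levels; genes omitted start
#'   at 0.
#' @param drive named list of [drive_constant]/[drive_square] signals, keyed by
#'   input gene.
#' @param T number of steps (>= 1).
#' @return an object of class `trajectory`: list with `times` (0..T) and
#'   `levels`, a (T+1) x n_genes matrix.
#' @examples
#' ffl <- make_circuit("FFL")
#' spec <- dynamics_spec(alpha = 0.2,
#'                       gamma = c(X = 0.12, Y = 0.7),
#'                       k = c(X = 0.5, Y = 0.1))
#' tr <- simulate_network(ffl, spec, initial = c(Y = 0.7, Z = 0),
#'                        drive = list(X = drive_constant(1)), T = 500)
#' tail(tr$levels[, c("Y", "Z")], 1)  # ~0.6 and ~0.42
#' @export
simulate_network <- function(net, spec, initial = numeric(0), drive = list(), T) {
  stopifnot(T >= 1)
  genes <- net$genes
  state <- stats::setNames(rep(0, length(genes)), genes)
  state[names(initial)] <- unlist(initial)
  levels <- matrix(0, nrow = T + 1, ncol = length(genes),
                   dimnames = list(NULL, genes))
  dr_at <- function(t) {
    if (length(drive) == 0) return(numeric(0))
    vapply(drive, drive_value, numeric(1), t = t)
  }
  d0 <- dr_at(0)
  state[names(d0)] <- d0
  levels[1, ] <- state
  for (t in seq_len(T)) {
    state <- step_state(net, spec, state, dr_at(t - 1))
    dt <- dr_at(t)
    state[names(dt)] <- dt
    levels[t + 1, ] <- state
  }
  structure(list(times = 0:T, levels = levels), class = "trajectory")
}

#' @export
print.trajectory <- function(x, ...) {
  cat(sprintf("trajectory: %d genes over %d steps\n",
              ncol(x$levels), length(x$times) - 1))
  invisible(x)
}

#' Tidy view of a trajectory
#'
#' @param x a `trajectory`.
#' @param ... unused.
#' @return a data frame with columns `time`, `gene`, `level`.
#' @export
as.data.frame.trajectory <- function(x, ...) {
  genes <- colnames(x$levels)
  data.frame(time = rep(x$times, times = length(genes)),
             gene = rep(genes, each = length(x$times)),
             level = as.vector(x$levels),
             stringsAsFactors = FALSE)
}

#' Tail synchronization error between two genes
#'
#' Maximum absolute difference of the two expression series after a burn-in.
#' Zero (to machine precision) iff the tails coincide, the signature of two
#' genes in one fiber.
#'
#' @param traj a `trajectory`.
#' @param gene_a,gene_b gene names.
#' @param burn_in steps to discard.
#' @return non-negative scalar.
#' @export
sync_error <- function(traj, gene_a, gene_b, burn_in = 0) {
  stopifnot(inherits(traj, "trajectory"))
  if (!all(c(gene_a, gene_b) %in% colnames(traj$levels))) {
    stop("unknown gene(s): ",
         paste(setdiff(c(gene_a, gene_b), colnames(traj$levels)), collapse = ", "))
  }
  stopifnot(burn_in < nrow(traj$levels))
  idx <- (burn_in + 1):nrow(traj$levels)
  max(abs(traj$levels[idx, gene_a] - traj$levels[idx, gene_b]))
}

#' Detect sustained oscillation in a trajectory
#'
#' After discarding `burn_in` steps, a series oscillates if it has nonzero
#' amplitude (range above `tol`) and revisits its states with a fixed period:
#' the smallest p with |s(t+p) - s(t)| < tol for all t in the tail window.
#' Constant tails and monotone-convergent tails (which are flat within `tol`
#' after an adequate burn-in for these contracting maps) report
#' non-oscillating.
#'
#' @param x a `trajectory` or a numeric series.
#' @param gene gene name (when `x` is a trajectory).
#' @param burn_in steps to discard; choose at least ~25 relaxation times
#'   (tau = -1/log(1 - alpha)) so convergent transients are flat within `tol`.
#' @param tol absolute tolerance for state recurrence.
#' @return list with `oscillating` (logical), `period` (integer or NA), and
#'   `amplitude` (max - min over the tail).
#' @export
detect_oscillation <- function(x, gene = NULL, burn_in = 0, tol = 1e-9) {
  v <- if (inherits(x, "trajectory")) {
    stopifnot(gene %in% colnames(x$levels))
    x$levels[, gene]
  } else as.numeric(x)
  if (length(v) <= burn_in + 2) stop("series too short for the requested burn-in")
  v <- v[(burn_in + 1):length(v)]
  amp <- max(v) - min(v)
  if (amp < tol) {
    return(list(oscillating = FALSE, period = NA_integer_, amplitude = amp))
  }
  n <- length(v)
  # monotone tail => convergence, not oscillation
  dv <- diff(v)
  if (all(dv >= -tol) || all(dv <= tol)) {
    return(list(oscillating = FALSE, period = NA_integer_, amplitude = amp))
  }
  for (p in seq_len(floor(n / 2))) {
    if (max(abs(v[seq_len(n - p) + p] - v[seq_len(n - p)])) < tol) {
      return(list(oscillating = TRUE, period = p, amplitude = amp))
    }
  }
  # recurrent but no clean period at this length/tolerance
  list(oscillating = FALSE, period = NA_integer_, amplitude = amp)
}
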