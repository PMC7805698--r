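#' Core dynamics parameters
#'
#' Parameters of one attractor network. `beta` is the unit gain
#' (inverse temperature): `Inf` gives deterministic sign dynamics, finite
#' values give a logistic stochastic unit. `sigma` is the SD of additive
#' Gaussian noise on the net input. `U` and `tau_rec` are the
#' Tsodyks-style synaptic-depression parameters: every step an active
#' (`+1`) unit consumes a fraction `U` of its presynaptic resource, which
#' recovers toward 1 with time constant `tau_rec` (steps).
#'
#' @param beta Gain, > 0 (may be `Inf`).
#' @param sigma Input noise SD, >= 0.
#' @param U Resource-use fraction per active step, in `[0, 1]`.
#' @param tau_rec Resource recovery time constant in steps, >= 1.
#' @param update Update scheme, `"asynchronous"` (one unit per step) or
#'   `"synchronous"` (all units).
#' @return List of class `"core_params"`.
#' @export
core_params <- function(beta = Inf, sigma = 0, U = 0, tau_rec = 50,
                        update = c("asynchronous", "synchronous")) {
  update <- match.arg(update)
  if (!(beta > 0)) stop("'beta' must be positive")
  if (sigma < 0) stop("'sigma' must be nonnegative")
  if (U < 0 || U > 1) stop("'U' must be in [0, 1]")
  if (tau_rec < 1) stop("'tau_rec' must be >= 1")
  structure(list(beta = beta, sigma = sigma, U = U, tau_rec = tau_rec,
                 update = update),
            class = "core_params")
}

#' Initial core state
#'
#' @param n Unit count.
#' @return List of class `"core_state"` with activations `s` (all 0,
#'   the empty memory state), resources `r` (all 1, fully recovered) and
#'   step counter `t = 0`.
#' @export
core_state <- function(n) {
  structure(list(s = numeric(n), r = rep(1, n), t = 0L),
            class = "core_state")
}

#' Hebbian / covariance storage
#'
#' Builds the symmetric zero-diagonal weight matrix storing a pattern set.
#' The plain Hebbian rule is `W_ij = (1/N) sum_mu xi_i^mu xi_j^mu` (i != j);
#' the covariance rule subtracts each unit's mean activity across the set
#' before the outer product and normalizes by the mean per-unit variance,
#' which keeps correlated or sparse sets stable as attractors with fields
#' on the same scale as the Hebbian rule.
#'
#' @param patterns List of [pattern()] objects (same N, unique labels).
#' @param rule `"hebbian"` or `"covariance"`.
#' @return `N x N` weight matrix.
#' @examples
#' W <- store_patterns(list(pattern("a", c(1, 1, -1, -1))))
#' W[1, 2]  # +1/4
#' @export
store_patterns <- function(patterns, rule = c("hebbian", "covariance")) {
  rule <- match.arg(rule)
  P <- pattern_matrix(patterns)
  scale <- 1
  if (rule == "covariance") {
    P <- sweep(P, 2, colMeans(P))
    v <- mean(P^2)
    if (v > 0) scale <- 1 / v
  }
  W <- scale * crossprod(P) / ncol(P)
  diag(W) <- 0
  unname(W)
}

#' Net input to every unit
#'
#' `h_i = sum_j W_ij r_j s_j + g_bu * external_i + g_td * topdown_i`.
#' The recurrent term uses the depressed efficacies `W_ij * r_j`: a
#' depleted presynaptic unit contributes less, which is what destabilizes
#' a visited attractor.
#'
#' @param state A [core_state()].
#' @param W Weight matrix.
#' @param external Bottom-up drive vector (or NULL).
#' @param topdown Top-down drive vector (or NULL).
#' @param g_bu,g_td Bottom-up / top-down mode weights, >= 0.
#' @return Net-input vector of length N.
#' @export
net_input <- function(state, W, external = NULL, topdown = NULL,
                      g_bu = 1, g_td = 1) {
  n <- length(state$s)
  h <- as.vector(W %*% (state$r * state$s))
  if (!is.null(external)) {
    if (length(external) != n) stop("'external' has wrong length")
    h <- h + g_bu * external
  }
  if (!is.null(topdown)) {
    if (length(topdown) != n) stop("'topdown' has wrong length")
    h <- h + g_td * topdown
  }
  h
}

# Single-unit activation rule. Deterministic limit: sign with ties keeping
# the previous activation. Finite beta: +1 with probability
# logistic(2 * beta * h).
unit_activation <- function(s_old, h, beta) {
  if (is.infinite(beta)) {
    if (h > 0) 1 else if (h < 0) -1 else s_old
  } else {
    if (stats::runif(1) < stats::plogis(2 * beta * h)) 1 else -1
  }
}

#' One update step
#'
#' Applies the unit rule to the net input plus per-unit Gaussian noise of
#' SD `params$sigma`. The asynchronous scheme updates one randomly chosen
#' unit per call; the synchronous scheme updates all units from the same
#' field. The step counter increments either way. Randomness (noise, unit
#' choice, stochastic units) is drawn from R's global RNG, so trajectories
#' are reproducible under `set.seed()`.
#'
#' @param state A [core_state()].
#' @param h Net-input vector (see [net_input()]).
#' @param params A [core_params()].
#' @return Updated [core_state()] (resources untouched; see
#'   [depression_update()]).
#' @export
core_step <- function(state, h, params) {
  n <- length(state$s)
  if (length(h) != n) stop("'h' has wrong length")
  if (params$update == "asynchronous") {
    i <- sample.int(n, 1L)
    hi <- h[i] + if (params$sigma > 0) stats::rnorm(1, 0, params$sigma) else 0
    state$s[i] <- unit_activation(state$s[i], hi, params$beta)
  } else {
    eps <- if (params$sigma > 0) stats::rnorm(n, 0, params$sigma) else numeric(n)
    hh <- h + eps
    if (is.infinite(params$beta)) {
      new_s <- ifelse(hh > 0, 1, ifelse(hh < 0, -1, state$s))
    } else {
      new_s <- ifelse(stats::runif(n) < stats::plogis(2 * params$beta * hh),
                      1, -1)
    }
    state$s <- new_s
  }
  state$t <- state$t + 1L
  state
}

#' Synaptic depression update
#'
#' `r_j <- r_j + (1 - r_j) / tau_rec - U * r_j * [s_j == +1]`, clipped to
#' `[0, 1]`. Inactive units only recover; a unit held active settles at
#' `r* = (1/tau_rec) / (1/tau_rec + U)`.
#'
#' @param state A [core_state()].
#' @param params A [core_params()].
#' @return Updated resource vector.
#' @export
depression_update <- function(state, params) {
  active <- as.numeric(state$s > 0)
  r <- state$r + (1 - state$r) / params$tau_rec -
    params$U * state$r * active
  pmin(pmax(r, 0), 1)
}

#' Settle into an attractor
#'
#' Runs deterministic asynchronous sweeps (units in fixed index order,
#' each seeing the current state) until no unit changes across a full
#' sweep or `max_sweeps` is exhausted. Depression is frozen during
#' settling: `r` is used but not advanced, so convergence is
#' well-defined; resources only evolve in free-running mode. With zero
#' drive and fresh resources each accepted flip strictly decreases the
#' energy, so convergence is guaranteed.
#'
#' @param state A [core_state()].
#' @param W Weight matrix.
#' @param external,topdown Optional drive vectors.
#' @param params A [core_params()]; only `sigma` is consulted (additive
#'   noise on each unit's field; keep 0 for a convergence guarantee).
#' @param g_bu,g_td Drive weights.
#' @param max_sweeps Sweep budget.
#' @param record_energy If TRUE, return the energy after every unit
#'   update (first element = energy of the initial state).
#' @return List with `state` (settled), `converged` flag, `sweeps` used
#'   and `energy` (numeric vector or NULL).
#' @export
settle <- function(state, W, external = NULL, params = core_params(),
                   topdown = NULL, g_bu = 1, g_td = 1,
                   max_sweeps = 100L, record_energy = FALSE) {
  n <- length(state$s)
  drive <- numeric(n)
  if (!is.null(external)) {
    if (length(external) != n) stop("'external' has wrong length")
    drive <- drive + g_bu * external
  }
  if (!is.null(topdown)) {
    if (length(topdown) != n) stop("'topdown' has wrong length")
    drive <- drive + g_td * topdown
  }
  s <- state$s
  r <- state$r
  h <- as.vector(W %*% (r * s)) + drive
  energies <- if (record_energy) energy_value(s, W) else NULL
  converged <- FALSE
  sweeps <- 0L
  while (sweeps < max_sweeps) {
    sweeps <- sweeps + 1L
    changed <- FALSE
    for (i in seq_len(n)) {
      hi <- h[i] + if (params$sigma > 0) stats::rnorm(1, 0, params$sigma) else 0
      si <- if (hi > 0) 1 else if (hi < 0) -1 else s[i]
      if (si != s[i]) {
        h <- h + W[, i] * r[i] * (si - s[i])
        s[i] <- si
        changed <- TRUE
      }
      if (record_energy) energies <- c(energies, energy_value(s, W))
    }
    if (!changed) {
      converged <- TRUE
      break
    }
  }
  state$s <- s
  state$t <- state$t + sweeps
  list(state = state, converged = converged, sweeps = sweeps,
       energy = energies)
}

energy_value <- function(s, W) {
  -0.5 * sum(s * as.vector(W %*% s))
}

#' Hopfield energy of a state
#'
#' `E = -(1/2) sum_{i != j} W_ij s_i s_j`. A diagnostic of recall
#' progress: it decreases as a pattern is completed. Depression and
#' external drive are deliberately ignored.
#'
#' @param state A [core_state()] or bare activation vector.
#' @param W Weight matrix (zero diagonal).
#' @return Scalar energy.
#' @export
energy <- function(state, W) {
  s <- if (inherits(state, "core_state")) state$s else as.numeric(state)
  energy_value(s, W)
}

#' Overlap with a stored pattern
#'
#' `m = (1/N) sum_i s_i p_i`, in `[-1, 1]`; 1 means perfect recall.
#'
#' @param state A [core_state()] or activation vector.
#' @param p A [pattern()] or bare numeric vector.
#' @return Scalar overlap.
#' @export
overlap <- function(state, p) {
  s <- if (inherits(state, "core_state")) state$s else as.numeric(state)
  v <- if (inherits(p, "pattern")) p$values else as.numeric(p)
  if (length(s) != length(v)) stop("length mismatch")
  sum(s * v) / length(s)
}

#' Nearest stored attractor
#'
#' Label of the stored pattern with the largest overlap with the current
#' state, provided that overlap reaches `threshold`; otherwise
#' `NA_character_` ("no attractor"). Ties break to the first stored
#' pattern.
#'
#' @param state A [core_state()] or activation vector.
#' @param patterns List of [pattern()] objects.
#' @param threshold Overlap threshold (default 0.9).
#' @return Pattern label or `NA_character_`.
#' @export
nearest_attractor <- function(state, patterns, threshold = 0.9) {
  s <- if (inherits(state, "core_state")) state$s else as.numeric(state)
  P <- pattern_matrix(patterns)
  m <- as.vector(P %*% s) / length(s)
  best <- which.max(m)
  if (m[best] >= threshold) rownames(P)[best] else NA_character_
}
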