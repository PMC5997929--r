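#' Leaky integrate-and-fire rate curve
#'
#' Steady-state firing rate of an LIF neuron as a function of its input
#' current, used both to fit gain/bias to a desired tuning curve and to build
#' the activity matrix for decoder optimisation.
#'
#' @param J Input current (dimensionless; threshold at 1).
#' @param tau_rc Membrane time constant in seconds.
#' @param tau_ref Absolute refractory period in seconds.
#' @return Firing rate in Hz (0 below threshold).
#' @export
lif_rate <- function(J, tau_rc = 0.02, tau_ref = 0.002) {
  r <- numeric(length(J))
  on <- J > 1 + 1e-12
  r[on] <- 1 / (tau_ref - tau_rc * log1p(-1 / J[on]))
  r
}

# Gain and bias such that the neuron is silent below its intercept and fires
# at max_rate when driven fully along its encoder.
lif_gain_bias <- function(intercepts, max_rates, tau_rc = 0.02,
                          tau_ref = 0.002) {
  z <- 1 / (1 - exp((tau_ref - 1 / max_rates) / tau_rc))
  gain <- (z - 1) / (1 - intercepts)
  list(gain = gain, bias = 1 - gain * intercepts)
}

#' Specify a one-dimensional LIF ensemble
#'
#' Samples neuron tuning (encoders, intercepts, maximum rates) for a scalar
#' ensemble and converts them to gain/bias current parameters. Buffers in the
#' sequencing model are arrays of these one-dimensional ensembles, one per
#' vector component.
#'
#' @param n_neurons Number of neurons (default 50).
#' @param radius Representational radius; inputs are normalised by it.
#' @param intercepts Length-2 range for firing thresholds along the encoder,
#'   in normalised units within `[-1, 1)`.
#' @param max_rates Length-2 range (Hz) for firing rate at full drive.
#' @param encoders Either `NULL` (random signs) or a vector of +1/-1.
#' @param rng An RNG stream from the network builder (internal); when `NULL` a
#'   fresh stream from `seed` is used.
#' @param seed Seed for the standalone case.
#' @param tau_rc,tau_ref LIF membrane and refractory time constants (s).
#' @return A list with per-neuron `gain` (signed, includes encoder and radius),
#'   `bias`, `enc`, and the scalar parameters.
#' @export
ensemble_spec <- function(n_neurons = 50L, radius = 1, intercepts = c(-1, 1),
                          max_rates = c(200, 400), encoders = NULL,
                          rng = NULL, seed = 1L, tau_rc = 0.02,
                          tau_ref = 0.002) {
  stopifnot(n_neurons >= 1, tau_ref < tau_rc,
            intercepts[1] >= -1, intercepts[2] <= 1)
  if (is.null(rng)) rng <- local_rng(seed)
  ints <- rng$unif(n_neurons, intercepts[1], intercepts[2])
  rates <- rng$unif(n_neurons, max_rates[1], max_rates[2])
  enc <- encoders %||% ifelse(rng$unif(n_neurons) < 0.5, -1, 1)
  enc <- rep_len(enc, n_neurons)
  gb <- lif_gain_bias(ints, rates, tau_rc, tau_ref)
  list(n_neurons = as.integer(n_neurons), radius = radius,
       gain = gb$gain * enc / radius, bias = gb$bias, enc = enc,
       intercepts = ints, max_rates = rates,
       tau_rc = tau_rc, tau_ref = tau_ref)
}

# Static rate matrix over represented values x (columns: neurons).
ensemble_rates <- function(ens, x) {
  J <- outer(x, ens$gain) + rep(ens$bias, each = length(x))
  matrix(lif_rate(J, ens$tau_rc, ens$tau_ref), nrow = length(x))
}

#' Solve decoding weights by regularised least squares
#'
#' Finds the weights that reconstruct `target_fn(x)` from the ensemble's
#' static firing rates over a set of evaluation points, minimising the
#' regularised squared error. The regularisation term also guarantees the
#' normal equations are solvable for any tuning-curve draw.
#'
#' @param ens An [ensemble_spec()].
#' @param target_fn Function of the represented value to decode.
#' @param eval_points Represented values to optimise over; default a uniform
#'   grid of 250 points across `[-radius, radius]`.
#' @param reg Regularisation as a fraction of the maximum firing rate
#'   (default 0.1, i.e. noise std = 10 % of peak rate).
#' @return List with `decoders` (length `n_neurons`, units of value per Hz)
#'   and `rmse`, the residual root-mean-square error over the eval points.
#' @export
solve_decoders <- function(ens, target_fn = identity, eval_points = NULL,
                           reg = 0.1) {
  if (is.null(eval_points)) {
    eval_points <- seq(-ens$radius, ens$radius, length.out = 250L)
  }
  A <- ensemble_rates(ens, eval_points)
  f <- vapply(eval_points, target_fn, numeric(1))
  sigma <- reg * max(A)
  d <- solve_normal_eq(A, f, nrow(A) * sigma^2)
  est <- drop(A %*% d)
  list(decoders = d, rmse = sqrt(mean((est - f)^2)))
}

#' Piecewise-linear (rectified) output nonlinearity
#'
#' The output function of each basal-ganglia population in the Gurney-style
#' action-selection circuit: zero below a threshold, linear above it.
#'
#' @param x Input value(s).
#' @param eps Threshold.
#' @param m Slope.
#' @return `m * pmax(0, x - eps)`.
#' @export
ramp <- function(x, eps, m = 1) m * pmax(0, x - eps)
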