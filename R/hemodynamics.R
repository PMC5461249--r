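# Balloon-model hemodynamics: forward simulation of BOLD from neuronal
# activity, HRF kernel extraction, and convolution of neuronal series with
# an HRF kernel.
#
# The model is the standard 4-state hemodynamic system: a vasodilatory
# signal s drives normalized inflow f, which inflates normalized venous
# volume v and dilutes normalized deoxyhemoglobin q:
#
#   ds/dt = eps * n - kappa * s - gamma * (f - 1)
#   df/dt = s
#   tau dv/dt = f - v^(1/alpha)
#   tau dq/dt = f * E(f, E0) / E0 - v^(1/alpha) * q / v,  E(f,E0) = 1-(1-E0)^(1/f)
#
# with the classic nonlinear BOLD observation in (q, v):
#
#   y = 100 * V0 * (k1 (1 - q) + k2 (1 - q/v) + k3 (1 - v)),
#   k1 = 7 E0, k2 = 2, k3 = 2 E0 - 0.2
#
# in percent signal change relative to rest. Integration is fixed-step RK4
# at the neuronal sampling interval, with neuronal input held constant over
# each step (zero-order hold).

#' Balloon-model hemodynamic parameters
#'
#' @param kappa Vasodilatory signal decay rate (1/s).
#' @param gamma Autoregulatory feedback rate (1/s).
#' @param tau Mean venous transit time (s).
#' @param alpha Vessel stiffness exponent (Grubb exponent, dimensionless).
#' @param E0 Resting oxygen extraction fraction, in (0, 1).
#' @param V0 Resting venous blood volume fraction, in (0, 1).
#' @param epsilon Neuronal efficacy (dimensionless gain from neuronal
#'   activity to the vasodilatory signal).
#' @return A `balloon_params` object (named list).
#' @export
balloon_params <- function(kappa = 0.65, gamma = 0.41, tau = 0.98,
                           alpha = 0.32, E0 = 0.34, V0 = 0.04,
                           epsilon = 0.54) {
  p <- list(kappa = kappa, gamma = gamma, tau = tau, alpha = alpha,
            E0 = E0, V0 = V0, epsilon = epsilon)
  if (!all(vapply(p, function(v) is.numeric(v) && length(v) == 1 && is.finite(v), TRUE)))
    stop("all Balloon parameters must be finite scalars")
  if (p$tau <= 0) stop("tau must be > 0")
  if (p$E0 <= 0 || p$E0 >= 1) stop("E0 must lie in (0, 1)")
  if (p$alpha <= 0 || p$alpha >= 1) stop("alpha must lie in (0, 1)")
  if (p$V0 <= 0 || p$V0 >= 1) stop("V0 must lie in (0, 1)")
  if (p$kappa <= 0 || p$gamma <= 0 || p$epsilon <= 0)
    stop("kappa, gamma and epsilon must be > 0")
  class(p) <- "balloon_params"
  p
}

#' Neuronal activity time series
#'
#' @param values Activity per time step (arbitrary units).
#' @param dt Sampling interval (s).
#' @param space_id Voxel/ROI label.
#' @export
neuronal_ts <- function(values, dt, space_id = "roi1") {
  if (!is.numeric(dt) || length(dt) != 1 || dt <= 0) stop("dt must be a positive scalar")
  if (!all(is.finite(values))) stop("neuronal values must be finite")
  structure(list(values = as.numeric(values), dt = dt, space_id = space_id),
            class = "neuronal_ts")
}

#' BOLD time series (percent signal change)
#'
#' @param values Percent signal change per time step.
#' @param TR Sampling interval (s).
#' @param space_id Voxel/ROI label.
#' @export
bold_ts <- function(values, TR, space_id = "roi1") {
  if (!is.numeric(TR) || length(TR) != 1 || TR <= 0) stop("TR must be a positive scalar")
  if (!all(is.finite(values))) stop("BOLD values must be finite")
  structure(list(values = as.numeric(values), TR = TR, space_id = space_id),
            class = "bold_ts")
}

# Time derivative of the hemodynamic state. `state` is a 4 x m matrix with
# rows (s, f, v, q); `n` is the neuronal drive (length-m); vectorized over
# columns so cubature points / voxels can be propagated together.
balloon_deriv <- function(state, n, p) {
  s <- state[1, ]; f <- state[2, ]; v <- state[3, ]; q <- state[4, ]
  fv <- v^(1 / p$alpha)
  Ef <- 1 - (1 - p$E0)^(1 / f)
  rbind(p$epsilon * n - p$kappa * s - p$gamma * (f - 1),
        s,
        (f - fv) / p$tau,
        (f * Ef / p$E0 - fv * q / v) / p$tau)
}

# One RK4 step with drive held constant; vectorized over columns.
balloon_rk4_step <- function(state, n, p, dt) {
  k1 <- balloon_deriv(state, n, p)
  k2 <- balloon_deriv(state + dt / 2 * k1, n, p)
  k3 <- balloon_deriv(state + dt / 2 * k2, n, p)
  k4 <- balloon_deriv(state + dt * k3, n, p)
  state + dt / 6 * (k1 + 2 * k2 + 2 * k3 + k4)
}

# Integrate many voxels at once: `drives` is V x T (neuronal per voxel),
# `plist` a list of V balloon_params. Elementwise parameter vectors ride
# through balloon_deriv unchanged. Returns V x T percent-signal-change.
simulate_hemodynamics_multi <- function(drives, dt, plist) {
  V <- nrow(drives); nT <- ncol(drives)
  pv <- list(kappa = vapply(plist, `[[`, 0, "kappa"),
             gamma = vapply(plist, `[[`, 0, "gamma"),
             tau = vapply(plist, `[[`, 0, "tau"),
             alpha = vapply(plist, `[[`, 0, "alpha"),
             E0 = vapply(plist, `[[`, 0, "E0"),
             V0 = vapply(plist, `[[`, 0, "V0"),
             epsilon = vapply(plist, `[[`, 0, "epsilon"))
  state <- rbind(rep(0, V), rep(1, V), rep(1, V), rep(1, V))
  out <- matrix(0, V, nT)
  for (t in seq_len(nT)) {
    state <- balloon_rk4_step(state, drives[, t], pv, dt)
    if (any(!is.finite(state))) stop(sprintf("hemodynamic integration diverged at step %d", t))
    out[, t] <- balloon_observe(state, pv)
  }
  out
}

# BOLD observation (percent signal change) from state rows (s, f, v, q).
balloon_observe <- function(state, p) {
  v <- state[3, ]; q <- state[4, ]
  k1 <- 7 * p$E0; k2 <- 2; k3 <- 2 * p$E0 - 0.2
  100 * p$V0 * (k1 * (1 - q) + k2 * (1 - q / v) + k3 * (1 - v))
}

#' Simulate BOLD from neuronal activity via the Balloon model
#'
#' Integrates the 4-state hemodynamic system with fixed-step RK4 at the
#' neuronal sampling interval, starting from the resting fixed point
#' (s = 0, f = v = q = 1), and applies the nonlinear BOLD observation.
#' Optional i.i.d. Gaussian measurement noise is appended after integration.
#'
#' @param neuronal A [neuronal_ts()] (dt of at most ~0.1 s recommended for
#'   accurate integration).
#' @param params A [balloon_params()].
#' @param noise_sd Standard deviation of measurement noise (percent signal
#'   change units), `>= 0`.
#' @param seed Integer seed for the measurement noise.
#' @return A [bold_ts()] at the neuronal dt.
#' @export
simulate_hemodynamics <- function(neuronal, params, noise_sd = 0, seed = 1L) {
  stopifnot(inherits(neuronal, "neuronal_ts"), inherits(params, "balloon_params"))
  if (!is.finite(noise_sd) || noise_sd < 0) stop("noise_sd must be a finite scalar >= 0")
  n <- neuronal$values
  if (!all(is.finite(n))) stop("non-finite neuronal input")
  dt <- neuronal$dt
  state <- matrix(c(0, 1, 1, 1), 4, 1)
  out <- numeric(length(n))
  for (t in seq_along(n)) {
    state <- balloon_rk4_step(state, n[t], params, dt)
    if (!all(is.finite(state)) || state[3, 1] <= 0 || state[2, 1] <= 0) {
      stop(sprintf(paste0("hemodynamic integration diverged at step %d ",
                          "(tau=%.3g, alpha=%.3g): reduce dt or input amplitude"),
                   t, params$tau, params$alpha))
    }
    out[t] <- balloon_observe(state, params)
  }
  if (noise_sd > 0) {
    out <- out + with_seed(seed, stats::rnorm(length(out), sd = noise_sd))
  }
  bold_ts(out, TR = dt, space_id = neuronal$space_id)
}

#' Hemodynamic impulse response (HRF) kernel
#'
#' The noiseless Balloon-model response to a single-sample unit impulse,
#' truncated to `duration`. The kernel is what [convolve_with_hrf()] expects.
#'
#' @param params A [balloon_params()].
#' @param dt Kernel sampling interval (s).
#' @param duration Kernel length (s); at least ~20 s is needed to capture
#'   the post-stimulus undershoot.
#' @return Numeric vector of length `round(duration / dt)`.
#' @export
hrf_impulse_response <- function(params, dt = 0.1, duration = 32) {
  if (duration < dt) stop("duration must be at least dt")
  nsteps <- round(duration / dt)
  drive <- c(1 / dt, numeric(nsteps - 1))  # unit-area impulse
  simulate_hemodynamics(neuronal_ts(drive, dt), params, noise_sd = 0)$values
}

#' Convolve neuronal activity with an HRF kernel and decimate
#'
#' Linear causal convolution of the neuronal series with `kernel` (both on
#' the neuronal dt grid), scaled by dt so the result approximates the
#' continuous convolution integral, then decimated to the output TR.
#'
#' @param neuronal A [neuronal_ts()].
#' @param kernel Numeric HRF kernel sampled at the neuronal dt.
#' @param out_TR Output sampling interval; must be an integer multiple of
#'   the neuronal dt.
#' @return A [bold_ts()] of length `ceiling(length(neuronal) * dt / out_TR)`.
#' @export
convolve_with_hrf <- function(neuronal, kernel, out_TR) {
  stopifnot(inherits(neuronal, "neuronal_ts"))
  dt <- neuronal$dt
  dec <- out_TR / dt
  if (abs(dec - round(dec)) > 1e-8 || dec < 1)
    stop("out_TR must be an integer multiple of the neuronal dt")
  dec <- round(dec)
  x <- neuronal$values
  full <- stats::convolve(x, rev(kernel), type = "open") * dt
  full <- full[seq_along(x)]
  idx <- seq(1, length(x), by = dec)
  bold_ts(full[idx], TR = out_TR, space_id = neuronal$space_id)
}
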