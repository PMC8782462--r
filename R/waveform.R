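#' Oscillatory TF activity waveform parameters
#'
#' Describes a TF whose activity sits at a basal level and oscillates up to a
#' maximum with period \code{T}, optionally perturbed by additive Gaussian
#' noise. The default parameters describe p53 after DNA damage: basal
#' 0.06 uM, peak 0.5 uM, period 5.5 h, noise SD 0.2 x basal.
#'
#' @param A_basal basal TF concentration (uM).
#' @param A_max maximum TF concentration during oscillation (uM).
#' @param T oscillation period (h).
#' @param sigma standard deviation of the additive Gaussian noise (uM).
#' @param noise_enabled logical; when \code{FALSE} the waveform is
#'   deterministic regardless of \code{sigma}.
#'
#' @return An object of class \code{tf_waveform_params}.
#' @export
#' @examples
#' wf <- waveform_params()
#' tf_waveform(wf, c(0, 2.75)) # basal at t = 0, maximal at t = T/2
waveform_params <- function(A_basal = 0.06, A_max = 0.5, T = 5.5,
                            sigma = 0.2 * A_basal, noise_enabled = TRUE) {
  stopifnot(is.numeric(A_basal), is.numeric(A_max), is.numeric(T),
            is.numeric(sigma))
  if (A_basal < 0 || A_max < A_basal)
    stop("waveform requires A_max >= A_basal >= 0")
  if (T <= 0) stop("waveform period T must be positive")
  if (sigma < 0) stop("waveform noise SD must be non-negative")
  structure(list(A_basal = A_basal, A_max = A_max, T = T, sigma = sigma,
                 noise_enabled = isTRUE(noise_enabled)),
            class = "tf_waveform_params")
}

#' Evaluate a TF activity waveform
#'
#' Computes \code{A_basal*(1 + cos(2*pi*t/T))/2 + A_max*(1 - cos(2*pi*t/T))/2}
#' plus, when noise is enabled, an independent Normal(0, sigma^2) perturbation
#' per time point. Because concentrations cannot be negative, noisy values are
#' clipped at zero before use.
#'
#' @param params a \code{\link{waveform_params}} object.
#' @param t numeric vector of non-negative times (h).
#' @param noise logical, whether to add noise; defaults to the
#'   \code{noise_enabled} flag of \code{params}. Uses the current RNG state.
#'
#' @return Numeric vector of TF concentrations (uM), same length as \code{t}.
#' @export
tf_waveform <- function(params, t, noise = params$noise_enabled) {
  stopifnot(inherits(params, "tf_waveform_params"))
  if (any(t < 0)) stop("waveform times must be non-negative")
  ph <- cos(2 * pi * t / params$T)
  x <- params$A_basal * (1 + ph) / 2 + params$A_max * (1 - ph) / 2
  if (isTRUE(noise) && params$sigma > 0)
    x <- pmax(x + stats::rnorm(length(t), 0, params$sigma), 0)
  x
}

#' Simulation time grid
#'
#' @param duration total simulated time (h).
#' @param dt time step (h).
#' @param t0 start time (h).
#'
#' @return An object of class \code{simulation_grid} with the vector of grid
#'   times in \code{$times}.
#' @export
simulation_grid <- function(duration = 20, dt = 0.001, t0 = 0) {
  if (dt <= 0) stop("grid step dt must be positive")
  if (duration <= dt) stop("grid duration must exceed dt")
  n_steps <- round(duration / dt)
  if (abs(n_steps * dt - duration) > 1e-8 * duration)
    stop("duration must be an integer multiple of dt (within rounding)")
  structure(list(duration = duration, dt = dt, t0 = t0, n_steps = n_steps,
                 times = t0 + seq(0, duration, by = dt)),
            class = "simulation_grid")
}
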