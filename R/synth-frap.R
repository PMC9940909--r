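## Synthetic FRAP recovery traces.
##
## Junctional myosin FRAP shows an immediate partial recovery (a fully
## mobile, possibly cytoplasmic pool of about 50 percent), a fast phase
## within the first ~30 s, a slow phase, and complete recovery by ~210 s.
## The phenomenological trace is an immediate-mobile-pool plus
## double-exponential model:
##   I(t) = 1 - (1 - f_mob) * [A_f exp(-t/tau_f) + (1 - A_f) exp(-t/tau_s)]
## with I(0) = f_mob (the first post-bleach frame reflects the mobile
## pool). An optional sinusoidal term emulates myosin oscillations on a
## ~60 s timescale.

#' Generate a synthetic FRAP recovery trace
#'
#' @param mobile_fraction fully mobile pool f_mob in [0, 1]; the
#'   first post-bleach intensity equals f_mob.
#' @param tau_fast,tau_slow fast and slow recovery timescales (s).
#' @param fast_share amplitude share A_f of the fast component in [0, 1].
#' @param dt sampling interval (s); acquisition default 1.5 s.
#' @param duration post-bleach duration (s).
#' @param n_prebleach number of pre-bleach frames (intensity 1).
#' @param noise_sigma additive Gaussian noise sd.
#' @param oscillation_amplitude,oscillation_period optional oscillatory
#'   term (amplitude in intensity units, period in s); off by default.
#' @param seed integer seed for the noise.
#' @return object of class \code{frap_trace}: data.frame with \code{t_s}
#'   (0 = first post-bleach frame; pre-bleach frames at negative times) and
#'   \code{intensity} (pre-bleach mean = 1), with the generating parameters
#'   attached as the \code{params} attribute.
#' @examples
#' tr <- make_frap_trace()
#' tr$intensity[tr$t_s == 0]   # immediate mobile-pool recovery
#' @export
make_frap_trace <- function(mobile_fraction = 0.5, tau_fast = 8,
                            tau_slow = 60, fast_share = 0.6,
                            dt = 1.5, duration = 300, n_prebleach = 5,
                            noise_sigma = 0, oscillation_amplitude = 0,
                            oscillation_period = 60, seed = 1) {
  if (mobile_fraction < 0 || mobile_fraction > 1)
    stop("mobile_fraction must lie in [0, 1]")
  if (tau_fast <= 0 || tau_slow <= 0) stop("timescales must be positive")
  if (fast_share < 0 || fast_share > 1)
    stop("fast_share must lie in [0, 1]")
  if (duration < dt) stop("duration shorter than one sampling interval")
  t_post <- seq(0, duration, by = dt)
  I <- frap_model(t_post, mobile_fraction, tau_fast, tau_slow, fast_share)
  if (oscillation_amplitude > 0)
    I <- I + oscillation_amplitude * (1 - exp(-t_post / tau_fast)) *
      sin(2 * pi * t_post / oscillation_period)
  t_pre <- if (n_prebleach > 0) -rev(seq_len(n_prebleach)) * dt
           else numeric(0)
  t_s <- c(t_pre, t_post)
  intensity <- c(rep(1, length(t_pre)), I)
  if (noise_sigma > 0) {
    set.seed(seed)
    intensity <- intensity + stats::rnorm(length(intensity), 0, noise_sigma)
  }
  structure(data.frame(t_s = t_s, intensity = intensity),
            params = list(mobile_fraction = mobile_fraction,
                          tau_fast = tau_fast, tau_slow = tau_slow,
                          fast_share = fast_share),
            class = c("frap_trace", "data.frame"))
}

## closed-form recovery model (t >= 0)
frap_model <- function(t, f_mob, tau_f, tau_s, A_f) {
  1 - (1 - f_mob) * (A_f * exp(-t / tau_f) + (1 - A_f) * exp(-t / tau_s))
}
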