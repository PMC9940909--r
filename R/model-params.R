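#' Parameters of the static-source myosin recruitment model
#'
#' The model: myosin binds preferentially to junctions parallel to the DV
#' axis (a recruitment source peaked at angle 0, fixed in the embryo frame),
#' unbinds with rate 1/tau, and junctions rotate with the local tissue
#' rotation rate. The source is Gaussian in angle,
#' s(theta) = s0 * exp(-theta^2 / (2 sigma_s^2)), optionally modulated
#' spatially (ventral-maximal, exponential decay in DV distance with length
#' \code{ell_m}). The predicted mean deflection depends only on the source
#' direction and tau, not on the source magnitude, spatial modulation, or
#' functional form.
#'
#' @param tau effective myosin lifetime (min); the model's one free
#'   parameter.
#' @param source_direction angle of maximal recruitment (deg from the DV
#'   axis).
#' @param source_width angular width sigma_s of the source (deg).
#' @param source_amplitude recruitment amplitude s0 (a.u./min).
#' @param ell_m DV decay length of the spatial source modulation
#'   (micrometers); \code{Inf} disables the modulation.
#' @return object of class \code{model_params}.
#' @export
model_params <- function(tau = 5, source_direction = 0, source_width = 15,
                         source_amplitude = 1, ell_m = 76) {
  if (!is.finite(tau) || tau <= 0) stop("tau must be positive")
  if (source_width <= 0) stop("source width must be positive")
  structure(list(tau = tau,
                 source_direction = angle_to_dv(source_direction),
                 source_width = source_width,
                 source_amplitude = source_amplitude,
                 ell_m = ell_m),
            class = "model_params")
}

#' @exportS3Method print model_params
print.model_params <- function(x, ...) {
  cat(sprintf(paste0("static-source model: tau = %g min, source %g deg ",
                     "+- %g deg, amplitude %g, ell_m %g um\n"),
              x$tau, x$source_direction, x$source_width,
              x$source_amplitude, x$ell_m))
  invisible(x)
}
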