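## Synthetic germband-extension tissue flow.
##
## The wild-type flow during GBE is emulated as four Gaussian-core vortices
## mirror-paired across the ventral midline (two strong posterior, two weak
## anterior, giving two hyperbolic fixed points on the midline) plus a weak
## DV-convergent / AP-extending component, all multiplied by a shared
## piecewise-linear time envelope. Only the envelope varies in time, so the
## direction of the flow is stationary -- the structure the analysis relies
## on. Amplitudes are calibrated so the peak local rotation rate is about
## 5 deg/min at the posterior vortices and below 2 deg/min anteriorly.

#' Specify a synthetic GBE tissue flow
#'
#' @param chart a \code{chart_grid}; vortex positions default to fractions
#'   of its extents.
#' @param rot_peak_posterior,rot_peak_anterior peak local rotation rate
#'   (deg/min, at full envelope) of the posterior resp. anterior vortex
#'   pairs.
#' @param sigma_v vortex core radius (micrometers).
#' @param convergence_amplitude rate constant (1/min) of the DV-convergent,
#'   AP-extending component.
#' @param envelope two-column matrix of (time min, value) knots of the
#'   piecewise-linear envelope g(t); the default ramps from 0 at 10 min to
#'   1 at 20 min, plateaus to 25 min, and decays to 0 by 35 min.
#' @param amplitude overall multiplier applied to the whole field (used by
#'   the mutant presets, e.g. 0.5 for twist).
#' @param vortices optional data.frame overriding the default vortex set,
#'   with columns \code{x}, \code{y} (micrometers), \code{sign} (+1
#'   counterclockwise), \code{rot_peak} (deg/min), \code{sigma}.
#' @return object of class \code{flow_spec}.
#' @export
flow_spec <- function(chart,
                      rot_peak_posterior = 5, rot_peak_anterior = 1.5,
                      sigma_v = 55, convergence_amplitude = 0.008,
                      envelope = cbind(time = c(0, 10, 20, 25, 35),
                                       value = c(0, 0, 1, 1, 0)),
                      amplitude = 1, vortices = NULL) {
  stopifnot(inherits(chart, "chart_grid"))
  if (is.null(vortices)) {
    yv <- 0.22 * chart$dv_circumference
    vortices <- data.frame(
      x = c(0.75, 0.75, 0.22, 0.22) * chart$ap_length,
      y = c(yv, -yv, yv, -yv) %% chart$dv_circumference,
      sign = c(1, -1, -1, 1),
      rot_peak = c(rot_peak_posterior, rot_peak_posterior,
                   rot_peak_anterior, rot_peak_anterior),
      sigma = sigma_v)
  }
  if (any(vortices$x < 0 | vortices$x > chart$ap_length))
    stop("vortex center outside chart AP range")
  if (any(vortices$sigma <= 0)) stop("vortex core radius must be positive")
  structure(list(chart = chart, vortices = vortices,
                 convergence_amplitude = convergence_amplitude,
                 envelope = envelope, amplitude = amplitude),
            class = "flow_spec")
}

## envelope g(t), linear between knots, constant outside
flow_envelope <- function(spec, t) {
  stats::approx(spec$envelope[, 1L], spec$envelope[, 2L], xout = t,
                rule = 2)$y
}

## Analytic velocity (um/min) of the spec at points (px, py), time t.
flow_velocity_at <- function(spec, px, py, t) {
  chart <- spec$chart
  vx <- numeric(length(px)); vy <- numeric(length(px))
  for (k in seq_len(nrow(spec$vortices))) {
    v <- spec$vortices[k, ]
    ddx_ <- px - v$x
    ddy_ <- wrap_dy(py - v$y, chart$dv_circumference)
    ## tangential Gaussian-core vortex: peak rotation rate rot_peak at the
    ## center; strength = rot_peak(rad/min) * sigma
    s <- v$sign * deg2rad(v$rot_peak) * v$sigma
    gauss <- exp(-(ddx_^2 + ddy_^2) / (2 * v$sigma^2))
    vx <- vx - s * gauss * ddy_ / v$sigma
    vy <- vy + s * gauss * ddx_ / v$sigma
  }
  ## DV convergence toward the ventral midline, AP extension (area
  ## conserving within the germband, curl-free)
  c0 <- spec$convergence_amplitude
  if (c0 != 0) {
    L <- chart$dv_circumference
    vx <- vx + c0 * (px - chart$ap_length / 2)
    vy <- vy - c0 * (L / (2 * pi)) * sin(2 * pi * py / L)
  }
  g <- spec$amplitude * flow_envelope(spec, t)
  list(vx = g * vx, vy = g * vy)
}

#' Generate a gridded velocity-field time series from a flow specification
#'
#' Evaluates the analytic flow of a \code{flow_spec} on the chart grid at
#' the requested times. The direction pattern is time-independent; only the
#' envelope varies.
#'
#' @param chart a \code{chart_grid}.
#' @param spec a \code{flow_spec}.
#' @param times strictly increasing vector of times (min).
#' @return object of class \code{velocity_field}: 3D arrays \code{vx},
#'   \code{vy} (nx, ny, nt) in um/min, \code{times}, and the \code{chart}.
#' @examples
#' chart <- make_chart(dx = 5, dy = 5)
#' vf <- make_flow_field(chart, flow_spec(chart), times = 0:35)
#' @export
make_flow_field <- function(chart, spec, times) {
  stopifnot(inherits(chart, "chart_grid"), inherits(spec, "flow_spec"))
  if (length(times) < 1L || is.unsorted(times, strictly = TRUE))
    stop("times must be strictly increasing")
  pts <- expand.grid(x = chart$x, y = chart$y)
  nt <- length(times)
  vx <- array(0, c(chart$nx, chart$ny, nt))
  vy <- array(0, c(chart$nx, chart$ny, nt))
  ## direction pattern is static: evaluate the unit-envelope field once
  base <- flow_velocity_at(within_envelope_one(spec), pts$x, pts$y, 0)
  bx <- matrix(base$vx, chart$nx, chart$ny)
  by <- matrix(base$vy, chart$nx, chart$ny)
  g <- spec$amplitude * flow_envelope(spec, times)
  for (k in seq_len(nt)) {
    vx[, , k] <- g[k] * bx
    vy[, , k] <- g[k] * by
  }
  structure(list(vx = vx, vy = vy, times = times, chart = chart),
            class = "velocity_field")
}

## copy of the spec with unit envelope and unit amplitude
within_envelope_one <- function(spec) {
  spec$envelope <- cbind(time = c(0, 1), value = c(1, 1))
  spec$amplitude <- 1
  spec
}

#' @exportS3Method print velocity_field
print.velocity_field <- function(x, ...) {
  cat(sprintf("velocity_field: %d x %d grid, %d time points (%g..%g min)\n",
              x$chart$nx, x$chart$ny, length(x$times),
              min(x$times), max(x$times)))
  invisible(x)
}
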