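## Stochastic junction-ensemble simulation.
##
## Each simulated junction is a persistent record: its midpoint advects
## passively with the tissue flow, its nematic angle integrates
## d theta/dt = local rotation rate, and its myosin level integrates
## dm/dt = source(theta, position) - m / tau. Junction lengths are fixed
## (strain does not rotate or create junctions in this model); only m
## changes, so the number of records is conserved. Fixed-step RK4 with
## dt = 0.1 min.

#' Simulate a junction ensemble under the static-source model
#'
#' @param chart a \code{chart_grid}.
#' @param flow a \code{velocity_field} covering \code{t_span}, or
#'   \code{NULL} for no advection (junctions stay in place).
#' @param params a \code{model_params}.
#' @param n_junctions number of junctions.
#' @param t_span numeric length-2, simulation start and end (min).
#' @param seed integer seed; output is bit-identical for a fixed seed.
#' @param dt integration step (min).
#' @param record_dt interval between recorded frames (min).
#' @param rotation_override if non-NULL, a constant rotation rate
#'   (deg/min) applied to every junction instead of the flow's vorticity
#'   (used for the controlled-rotation experiments).
#' @param lifetime_profile if non-NULL, a function theta -> tau(theta)
#'   (min) implementing the alternative model with uniform recruitment and
#'   angle-modulated detachment; the static source is then angle-independent.
#' @param advect if FALSE, junction positions stay fixed while the angle
#'   still integrates the local rotation rate (a diagnostic separating
#'   rotation from transport).
#' @return object of class \code{junction_sim}: \code{segments}, a
#'   data.frame with columns t_min, id, x_um, y_um, angle_deg, intensity,
#'   length_um; and \code{truth}, the ground-truth record (parameters,
#'   seed, initial state).
#' @export
simulate_junction_ensemble <- function(chart, flow, params,
                                       n_junctions = 1000,
                                       t_span = c(0, 35), seed = 1,
                                       dt = 0.1, record_dt = 1,
                                       rotation_override = NULL,
                                       lifetime_profile = NULL,
                                       advect = TRUE) {
  stopifnot(inherits(chart, "chart_grid"), inherits(params, "model_params"))
  if (length(t_span) != 2L || t_span[2L] <= t_span[1L])
    stop("t_span must be an increasing pair of times")
  has_flow <- !is.null(flow)
  if (has_flow) {
    stopifnot(inherits(flow, "velocity_field"))
    if (t_span[1L] < min(flow$times) - 1e-9 ||
        t_span[2L] > max(flow$times) + 1e-9)
      stop("t_span outside flow coverage")
    rot <- rotation_rate(flow)   # deg/min field series
  }

  set.seed(seed)
  x <- stats::runif(n_junctions, chart$ap_margin,
                    chart$ap_length - chart$ap_margin)
  y <- stats::runif(n_junctions, -chart$germband_halfwidth,
                    chart$germband_halfwidth) %% chart$dv_circumference
  theta <- stats::runif(n_junctions, -90, 90)
  len <- pmax(3, stats::rnorm(n_junctions, 7, 1))

  spatial <- function(yy) {
    if (is.finite(params$ell_m)) exp(-dv_distance(yy, chart) / params$ell_m)
    else rep(1, length(yy))
  }
  source_rate <- function(th, yy) {
    if (is.null(lifetime_profile)) {
      d <- nematic_diff(th, params$source_direction)
      params$source_amplitude *
        exp(-d^2 / (2 * params$source_width^2)) * spatial(yy)
    } else {
      params$source_amplitude * spatial(yy)
    }
  }
  tau_of <- function(th) {
    if (is.null(lifetime_profile)) rep(params$tau, length(th))
    else {
      tv <- lifetime_profile(angle_to_dv(th))
      if (any(tv <= 0)) stop("lifetime profile must be positive")
      tv
    }
  }

  ## initialize myosin at the zero-rotation stationary level
  m <- source_rate(theta, y) * tau_of(theta)

  rot_at <- function(px, py, t) {
    if (!is.null(rotation_override))
      return(rep(rotation_override, length(px)))
    if (!has_flow) return(numeric(length(px)))
    interp_field(frame_at(rot$data, rot$times, t), chart, px, py)
  }
  vel_at <- function(px, py, t) {
    if (!has_flow || !advect) return(list(vx = 0, vy = 0))
    list(vx = interp_field(frame_at(flow$vx, flow$times, t), chart, px, py),
         vy = interp_field(frame_at(flow$vy, flow$times, t), chart, px, py))
  }

  deriv <- function(st, t) {
    v <- vel_at(st$x, st$y, t)
    list(x = v$vx, y = v$vy,
         theta = rot_at(st$x, st$y, t),
         m = source_rate(st$theta, st$y) - st$m / tau_of(st$theta))
  }

  rec_times <- seq(t_span[1L], t_span[2L], by = record_dt)
  records <- vector("list", length(rec_times))
  truth0 <- data.frame(id = seq_len(n_junctions), x0 = x, y0 = y,
                       angle0 = theta, length_um = len)

  snapshot <- function(t, k) {
    records[[k]] <<- data.frame(
      t_min = t, id = seq_len(n_junctions),
      x_um = pmin(pmax(x, 0), chart$ap_length),
      y_um = y %% chart$dv_circumference,
      angle_deg = angle_to_dv(theta), intensity = m, length_um = len)
  }

  t <- t_span[1L]
  next_rec <- 1L
  snapshot(t, next_rec); next_rec <- next_rec + 1L
  nstep <- ceiling((t_span[2L] - t_span[1L]) / dt - 1e-9)
  for (i in seq_len(nstep)) {
    h <- min(dt, t_span[2L] - t)
    st <- list(x = x, y = y, theta = theta, m = m)
    k1 <- deriv(st, t)
    k2 <- deriv(list(x = x + h / 2 * k1$x, y = y + h / 2 * k1$y,
                     theta = theta + h / 2 * k1$theta,
                     m = m + h / 2 * k1$m), t + h / 2)
    k3 <- deriv(list(x = x + h / 2 * k2$x, y = y + h / 2 * k2$y,
                     theta = theta + h / 2 * k2$theta,
                     m = m + h / 2 * k2$m), t + h / 2)
    k4 <- deriv(list(x = x + h * k3$x, y = y + h * k3$y,
                     theta = theta + h * k3$theta,
                     m = m + h * k3$m), t + h)
    x <- x + h / 6 * (k1$x + 2 * k2$x + 2 * k3$x + k4$x)
    y <- y + h / 6 * (k1$y + 2 * k2$y + 2 * k3$y + k4$y)
    theta <- theta + h / 6 * (k1$theta + 2 * k2$theta + 2 * k3$theta +
                              k4$theta)
    m <- pmax(m + h / 6 * (k1$m + 2 * k2$m + 2 * k3$m + k4$m), 0)
    x <- pmin(pmax(x, 0), chart$ap_length)
    t <- t + h
    while (next_rec <= length(rec_times) &&
           t >= rec_times[next_rec] - 1e-9) {
      snapshot(rec_times[next_rec], next_rec)
      next_rec <- next_rec + 1L
    }
  }

  structure(list(segments = do.call(rbind, records),
                 truth = list(params = params, seed = seed,
                              n_junctions = n_junctions, t_span = t_span,
                              initial = truth0,
                              rotation_override = rotation_override,
                              lifetime_modulated =
                                !is.null(lifetime_profile)),
                 chart = chart, times = rec_times),
            class = "junction_sim")
}

## Extract one recorded frame as a plain junction table.
sim_frame <- function(sim, t) {
  seg <- sim$segments
  seg[abs(seg$t_min - t) < 1e-6, , drop = FALSE]
}
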