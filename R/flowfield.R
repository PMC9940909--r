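## Velocity-field analysis: vorticity, rotation rate, Lagrangian advection,
## and temporal autocorrelation of direction fields.

#' Vorticity of a velocity field
#'
#' Curl omega = d vy / dx - d vx / dy via central differences, periodic in
#' DV, one-sided at the AP edges. Positive values are counterclockwise in
#' the chart (x right = posterior, y up). Units 1/min.
#'
#' @param velocity_field a \code{velocity_field}.
#' @return \code{field_series}: list with 3D \code{data} array (1/min),
#'   \code{times}, \code{chart}.
#' @export
vorticity <- function(velocity_field) {
  stopifnot(inherits(velocity_field, "velocity_field"))
  chart <- velocity_field$chart
  if (chart$nx < 2L || chart$ny < 2L)
    stop("vorticity needs at least a 2 x 2 grid")
  nt <- length(velocity_field$times)
  out <- array(0, dim(velocity_field$vx))
  for (k in seq_len(nt)) {
    out[, , k] <- ddx(velocity_field$vy[, , k], chart) -
      ddy(velocity_field$vx[, , k], chart)
  }
  structure(list(data = out, times = velocity_field$times, chart = chart,
                 units = "1/min"),
            class = "field_series")
}

#' Local tissue rotation rate
#'
#' Half the vorticity, converted to deg/min: the angular velocity of a
#' local material element under rigid rotation. This is the rotation rate
#' entering the mean-deflection model.
#'
#' @param velocity_field a \code{velocity_field}.
#' @return \code{field_series} in deg/min.
#' @export
rotation_rate <- function(velocity_field) {
  om <- vorticity(velocity_field)
  om$data <- om$data / 2 * 180 / pi
  om$units <- "deg/min"
  om
}

#' Advect points along the tissue flow
#'
#' RK4 integration of dx/dt = v(x, t) with bilinear interpolation in space
#' and linear interpolation in time; the DV coordinate wraps periodically,
#' points reaching the AP boundary are clamped and flagged. Backward
#' tracing (t1 < t0) is supported.
#'
#' @param points 2-column matrix or data.frame of (x, y) in micrometers.
#' @param velocity_series a \code{velocity_field} covering [t0, t1].
#' @param t0,t1 start and end times (min).
#' @param dt integration step magnitude (min).
#' @return matrix with columns \code{x}, \code{y} and a logical attribute
#'   \code{clamped} marking points that hit the AP boundary.
#' @export
advect_points <- function(points, velocity_series, t0, t1, dt = 0.25) {
  stopifnot(inherits(velocity_series, "velocity_field"))
  if (length(velocity_series$times) < 1L) stop("empty velocity series")
  tr <- range(velocity_series$times)
  if (min(t0, t1) < tr[1L] - 1e-9 || max(t0, t1) > tr[2L] + 1e-9)
    stop("advection interval outside velocity coverage")
  pts <- as.matrix(points)
  if (ncol(pts) != 2L) stop("points must have two columns")
  chart <- velocity_series$chart
  x <- pts[, 1L]; y <- pts[, 2L]
  clamped <- rep(FALSE, length(x))
  vel <- function(px, py, t) {
    list(vx = interp_field(frame_at(velocity_series$vx,
                                    velocity_series$times, t),
                           chart, px, py),
         vy = interp_field(frame_at(velocity_series$vy,
                                    velocity_series$times, t),
                           chart, px, py))
  }
  total <- t1 - t0
  n <- max(1L, ceiling(abs(total) / dt))
  h <- total / n
  t <- t0
  for (i in seq_len(n)) {
    k1 <- vel(x, y, t)
    k2 <- vel(x + h / 2 * k1$vx, y + h / 2 * k1$vy, t + h / 2)
    k3 <- vel(x + h / 2 * k2$vx, y + h / 2 * k2$vy, t + h / 2)
    k4 <- vel(x + h * k3$vx, y + h * k3$vy, t + h)
    x <- x + h / 6 * (k1$vx + 2 * k2$vx + 2 * k3$vx + k4$vx)
    y <- y + h / 6 * (k1$vy + 2 * k2$vy + 2 * k3$vy + k4$vy)
    out <- x < 0 | x > chart$ap_length
    clamped <- clamped | out
    x <- pmin(pmax(x, 0), chart$ap_length)
    t <- t + h
  }
  res <- cbind(x = x, y = y %% chart$dv_circumference)
  attr(res, "clamped") <- clamped
  res
}

#' Advect a polyline along the tissue flow
#'
#' Applies \code{\link{advect_points}} to every vertex; the vertex count is
#' preserved. Used to predict the deformation of inter-stripe lines by
#' tissue flow.
#'
#' @inheritParams advect_points
#' @param polyline 2-column matrix/data.frame of vertices.
#' @return matrix of advected vertices with the \code{clamped} attribute.
#' @export
advect_polyline <- function(polyline, velocity_series, t0, t1, dt = 0.25) {
  advect_points(polyline, velocity_series, t0, t1, dt = dt)
}

## correlation_matrix constructor
correlation_matrix <- function(C, times) {
  dimnames(C) <- list(times, times)
  structure(list(C = C, times = times), class = "correlation_matrix")
}

#' @exportS3Method print correlation_matrix
print.correlation_matrix <- function(x, ...) {
  cat(sprintf("correlation_matrix over %d time points (%g..%g min)\n",
              length(x$times), min(x$times), max(x$times)))
  print(round(x$C, 3))
  invisible(x)
}

#' @exportS3Method plot correlation_matrix
plot.correlation_matrix <- function(x, main = "temporal autocorrelation",
                                    ...) {
  graphics::image(x$times, x$times, x$C, zlim = c(0, 1),
                  xlab = "time (min)", ylab = "time (min)", main = main,
                  col = grDevices::hcl.colors(64, "viridis"), ...)
}

#' Temporal autocorrelation of flow direction
#'
#' For each pair of time points, the mask-averaged inner product of the
#' unit velocity directions, clamped to [0, 1] (anti-aligned maps to 0).
#' Pixels where the speed is below \code{speed_floor} at either time are
#' excluded; a pair with no valid pixels yields NA (flagged, never silently
#' 1). The matrix is symmetric with unit diagonal.
#'
#' @param velocity_series a \code{velocity_field}.
#' @param mask optional logical matrix restricting the average (default:
#'   the chart's germband mask).
#' @param speed_floor minimal speed (um/min) for a pixel to count.
#' @return a \code{correlation_matrix}.
#' @export
direction_autocorrelation <- function(velocity_series, mask = NULL,
                                      speed_floor = 0.1) {
  stopifnot(inherits(velocity_series, "velocity_field"))
  times <- velocity_series$times
  nt <- length(times)
  if (nt < 2L) stop("need at least two time points")
  chart <- velocity_series$chart
  if (is.null(mask)) mask <- chart$germband_mask
  sel <- which(mask)
  ux <- matrix(NA_real_, length(sel), nt)
  uy <- matrix(NA_real_, length(sel), nt)
  for (k in seq_len(nt)) {
    vx <- velocity_series$vx[, , k][sel]
    vy <- velocity_series$vy[, , k][sel]
    sp <- sqrt(vx^2 + vy^2)
    ok <- sp >= speed_floor
    ux[ok, k] <- (vx / sp)[ok]
    uy[ok, k] <- (vy / sp)[ok]
  }
  C <- matrix(NA_real_, nt, nt)
  for (a in seq_len(nt)) for (b in a:nt) {
    ok <- !is.na(ux[, a]) & !is.na(ux[, b])
    C[a, b] <- C[b, a] <- if (!any(ok)) NA_real_
      else clamp0(mean(ux[ok, a] * ux[ok, b] + uy[ok, a] * uy[ok, b]))
  }
  diag(C) <- ifelse(is.na(diag(C)), NA_real_, 1)
  correlation_matrix(C, times)
}
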