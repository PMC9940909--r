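#' Cylindrical pullback chart of the embryo surface
#'
#' Constructs the 2D coordinate system used throughout: an AP x DV grid in
#' micrometers, periodic in the DV (y) direction. By convention the ventral
#' midline sits at y = 0 (equivalently y = dv_circumference) and the dorsal
#' midline at y = dv_circumference / 2; the DV axis is the +y unit vector
#' everywhere, the chart proxy for the direction of maximal surface
#' curvature. Fields on the chart are \code{nx} x \code{ny} matrices with
#' the first index along AP (x, anterior left / posterior right) and the
#' second along DV (y).
#'
#' @param ap_length AP extent in micrometers.
#' @param dv_circumference DV circumference in micrometers.
#' @param dx,dy grid spacing in micrometers.
#' @param germband_halfwidth maximal DV distance from the ventral midline
#'   (micrometers) included in the germband mask.
#' @param ap_margin AP margin (micrometers) excluded from the germband mask
#'   at both poles.
#' @return an object of class \code{chart_grid}: grid dimensions, spacings,
#'   node coordinates \code{x}, \code{y} (micrometers), and the logical
#'   \code{germband_mask}.
#' @examples
#' chart <- make_chart()            # wild-type geometry, 450 x 500 grid
#' chart$ny * chart$dy              # DV circumference
#' @export
make_chart <- function(ap_length = 450, dv_circumference = 500,
                       dx = 1, dy = 1,
                       germband_halfwidth = 175, ap_margin = 25) {
  if (!is.finite(ap_length) || !is.finite(dv_circumference) ||
      ap_length <= 0 || dv_circumference <= 0)
    stop("chart extents must be positive")
  if (!is.finite(dx) || !is.finite(dy) || dx <= 0 || dy <= 0)
    stop("grid spacings must be positive")
  nx <- as.integer(round(ap_length / dx))
  ny <- as.integer(round(dv_circumference / dy))
  if (nx < 2L || ny < 2L) stop("grid must have at least 2 nodes per axis")
  x <- (seq_len(nx) - 1) * dx
  y <- (seq_len(ny) - 1) * dy
  dvdist <- pmin(y, dv_circumference - y)   # distance from ventral midline
  mask <- outer(x >= ap_margin & x <= ap_length - ap_margin,
                dvdist <= germband_halfwidth, `&`)
  structure(list(nx = nx, ny = ny, dx = dx, dy = dy,
                 ap_length = ap_length, dv_circumference = dv_circumference,
                 x = x, y = y,
                 germband_halfwidth = germband_halfwidth,
                 ap_margin = ap_margin,
                 germband_mask = mask),
            class = "chart_grid")
}

#' @exportS3Method print chart_grid
print.chart_grid <- function(x, ...) {
  cat(sprintf("chart_grid: %d x %d nodes, dx = %g um, dy = %g um\n",
              x$nx, x$ny, x$dx, x$dy))
  cat(sprintf("  AP length %g um, DV circumference %g um (periodic)\n",
              x$ap_length, x$dv_circumference))
  cat(sprintf("  germband: |DV| <= %g um, AP margin %g um (%d px)\n",
              x$germband_halfwidth, x$ap_margin, sum(x$germband_mask)))
  invisible(x)
}

## Signed/unsigned DV distance from the ventral midline for y coordinates.
dv_distance <- function(y, chart) {
  yy <- y %% chart$dv_circumference
  pmin(yy, chart$dv_circumference - yy)
}

## Wrap y displacements to the minimal image (-C/2, C/2].
wrap_dy <- function(dy, circumference) {
  ((dy + circumference / 2) %% circumference) - circumference / 2
}

same_grid <- function(a, b) {
  a$nx == b$nx && a$ny == b$ny &&
    isTRUE(all.equal(a$dx, b$dx)) && isTRUE(all.equal(a$dy, b$dy))
}
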