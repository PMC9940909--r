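## Gridded-field primitives shared across modules.
##
## Fields are nx x ny matrices on a chart_grid (first index AP/x, second
## DV/y). All y-operations use the periodic continuation of the cylinder;
## x-operations replicate at the AP boundaries.

## --- separable Gaussian smoothing, periodic in y, replicate in x --------

gauss_kernel <- function(sigma_px) {
  if (sigma_px <= 0) return(1)
  r <- max(1L, ceiling(3 * sigma_px))
  k <- exp(-((-r):r)^2 / (2 * sigma_px^2))
  k / sum(k)
}

## shift a matrix along margin (1 = x, 2 = y) by s nodes; periodic or
## replicate continuation
shift_mat <- function(m, s, margin, periodic) {
  n <- dim(m)[margin]
  idx <- seq_len(n) + s
  idx <- if (periodic) ((idx - 1) %% n) + 1 else pmin(pmax(idx, 1L), n)
  if (margin == 1L) m[idx, , drop = FALSE] else m[, idx, drop = FALSE]
}

conv_margin <- function(m, kernel, margin, periodic) {
  r <- (length(kernel) - 1L) / 2L
  out <- matrix(0, nrow(m), ncol(m))
  for (j in seq_along(kernel))
    out <- out + kernel[j] * shift_mat(m, j - 1L - r, margin, periodic)
  out
}

## Gaussian smoothing of a chart field; sigma in micrometers.
smooth_field <- function(field, chart, sigma_um) {
  if (sigma_um < 0) stop("sigma must be >= 0")
  if (sigma_um == 0) return(field)
  if (sigma_um >= min(chart$ap_length, chart$dv_circumference))
    stop("smoothing scale exceeds the field extent")
  f <- conv_margin(field, gauss_kernel(sigma_um / chart$dx), 1L, FALSE)
  conv_margin(f, gauss_kernel(sigma_um / chart$dy), 2L, TRUE)
}

## --- finite differences -------------------------------------------------

## d/dx, central interior, one-sided at the AP edges
ddx <- function(field, chart) {
  nx <- nrow(field)
  out <- (shift_mat(field, 1L, 1L, FALSE) -
          shift_mat(field, -1L, 1L, FALSE)) / (2 * chart$dx)
  out[1L, ] <- (field[2L, ] - field[1L, ]) / chart$dx
  out[nx, ] <- (field[nx, ] - field[nx - 1L, ]) / chart$dx
  out
}

## d/dy, central with periodic wrap
ddy <- function(field, chart) {
  (shift_mat(field, 1L, 2L, TRUE) -
   shift_mat(field, -1L, 2L, TRUE)) / (2 * chart$dy)
}

## --- interpolation -------------------------------------------------------

## Bilinear interpolation of a chart field at points (px, py) in
## micrometers; y wraps periodically, x clamps to the chart range.
interp_field <- function(field, chart, px, py) {
  fx <- pmin(pmax(px / chart$dx, 0), chart$nx - 1)
  fy <- (py / chart$dy) %% chart$ny
  i0 <- pmin(floor(fx), chart$nx - 2); tx <- fx - i0
  j0 <- floor(fy); ty <- fy - j0
  j1 <- as.integer((j0 + 1) %% chart$ny) + 1L   # 1-based, wrapped
  j0 <- as.integer(j0 %% chart$ny) + 1L
  i0 <- as.integer(i0) + 1L                     # 1-based
  i1 <- i0 + 1L
  nx <- chart$nx
  at <- function(i, j) field[(j - 1L) * nx + i]
  at(i0, j0) * (1 - tx) * (1 - ty) + at(i1, j0) * tx * (1 - ty) +
    at(i0, j1) * (1 - tx) * ty + at(i1, j1) * tx * ty
}

## Linear interpolation between time frames of a 3D field array
## (nx, ny, nt) at scalar time t; clamped at the ends.
frame_at <- function(arr, times, t) {
  nt <- length(times)
  if (t <= times[1L]) return(arr[, , 1L])
  if (t >= times[nt]) return(arr[, , nt])
  k <- findInterval(t, times)
  w <- (t - times[k]) / (times[k + 1L] - times[k])
  arr[, , k] * (1 - w) + arr[, , k + 1L] * w
}

## --- connected components with DV periodicity ----------------------------

## Label connected components of a logical chart field; components touching
## across the y = 0 seam are merged (the chart is a cylinder).
label_components <- function(mask, periodic = TRUE) {
  lab <- EBImage::bwlabel(mask * 1)
  lab <- matrix(as.integer(round(lab)), nrow(mask), ncol(mask))
  if (periodic && max(lab) > 0L) {
    first <- lab[, 1L]; last <- lab[, ncol(lab)]
    touching <- unique(cbind(first, last)[first > 0L & last > 0L, ,
                                          drop = FALSE])
    if (nrow(touching) > 0L) {
      parent <- seq_len(max(lab))
      find <- function(i) { while (parent[i] != i) i <- parent[i]; i }
      for (r in seq_len(nrow(touching))) {
        a <- find(touching[r, 1L]); b <- find(touching[r, 2L])
        if (a != b) parent[max(a, b)] <- min(a, b)
      }
      root <- vapply(seq_len(max(lab)), find, integer(1))
      root <- match(root, sort(unique(root)))
      lab[lab > 0L] <- root[lab[lab > 0L]]
    }
  }
  lab
}

## --- spatial averaging ----------------------------------------------------

#' Spatially averaged time series of a field series
#'
#' Arithmetic mean over a mask, per time point. Used e.g. for the
#' germband-averaged rotation rate and myosin/DV-axis angle versus time.
#'
#' @param field_series a \code{field_series} (list with 3D \code{data} array
#'   and \code{times}) or a 3D array.
#' @param mask logical matrix matching the field grid; must select at least
#'   one pixel.
#' @return data.frame with columns \code{time} and \code{value}.
#' @export
spatial_average <- function(field_series, mask) {
  arr <- if (is.list(field_series)) field_series$data else field_series
  times <- if (is.list(field_series)) field_series$times
           else seq_len(dim(arr)[3L])
  if (!is.array(arr) || length(dim(arr)) != 3L)
    stop("field series must be a 3D array")
  if (!identical(dim(arr)[1:2], dim(mask)))
    stop("mask shape does not match field grid")
  if (!any(mask)) stop("mask selects no pixels")
  vals <- apply(arr, 3L, function(m) mean(m[mask]))
  data.frame(time = times, value = vals)
}
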