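## Nematic angle utilities.
##
## Orientations of undirected line segments (cell-cell junctions, stripe
## normals) are nematic: defined modulo 180 degrees. All angles in this
## package are measured against the DV axis (the +y direction of the chart)
## and stored in the canonical range (-90, 90].

#' Canonicalize an angle to the nematic range relative to the DV axis
#'
#' Maps any angle in degrees to the canonical nematic range (-90, 90],
#' identifying \code{theta} with \code{theta + 180}. The convention follows
#' measurement of undirected junction orientations against the DV axis:
#' 95 maps to -85, -90 maps to +90, 0 stays 0. Idempotent.
#'
#' @param x numeric vector (or an \code{orientation_field}) of angles in
#'   degrees.
#' @return object of the same shape with all angles in (-90, 90].
#' @examples
#' angle_to_dv(c(95, -90, 0, 180))
#' @export
angle_to_dv <- function(x) {
  if (inherits(x, "orientation_field")) {
    x$angle[] <- angle_to_dv(as.numeric(x$angle))
    return(x)
  }
  a <- ((x %% 180) + 180) %% 180   # [0, 180)
  ifelse(a > 90, a - 180, a)
}

## Nematic difference a - b mapped to (-90, 90].
nematic_diff <- function(a, b) angle_to_dv(a - b)

## Intensity-weighted nematic mean via the double-angle representation.
## Returns the mean angle (deg, canonical), the nematic order parameter
## R = |<w e^{2 i theta}>| in [0, 1], the circular (nematic) sd in degrees
## (Mardia's wrapped dispersion, halved back from double-angle space), and
## the total weight.
nematic_mean <- function(theta_deg, w = NULL) {
  if (length(theta_deg) == 0L) {
    return(list(mean = NA_real_, R = NA_real_, sd = NA_real_, weight = 0))
  }
  if (is.null(w)) w <- rep(1, length(theta_deg))
  keep <- is.finite(theta_deg) & is.finite(w) & w > 0
  theta_deg <- theta_deg[keep]; w <- w[keep]
  W <- sum(w)
  if (W <= 0 || length(theta_deg) == 0L) {
    return(list(mean = NA_real_, R = NA_real_, sd = NA_real_, weight = 0))
  }
  phi <- 2 * theta_deg * pi / 180
  C <- sum(w * cos(phi)) / W
  S <- sum(w * sin(phi)) / W
  R <- sqrt(C^2 + S^2)
  m <- atan2(S, C) / 2 * 180 / pi
  sdv <- if (R > 0) 0.5 * sqrt(-2 * log(R)) * 180 / pi else Inf
  list(mean = angle_to_dv(m), R = R, sd = sdv, weight = W)
}

## Weighted nematic median: weighted median of angles unwrapped about the
## nematic mean.
nematic_median <- function(theta_deg, w = NULL) {
  nm <- nematic_mean(theta_deg, w)
  if (!is.finite(nm$mean)) return(NA_real_)
  if (is.null(w)) w <- rep(1, length(theta_deg))
  keep <- is.finite(theta_deg) & is.finite(w) & w > 0
  d <- nematic_diff(theta_deg[keep], nm$mean)
  w <- w[keep]
  o <- order(d)
  d <- d[o]; w <- w[o]
  cw <- cumsum(w) / sum(w)
  med <- d[which(cw >= 0.5)[1L]]
  angle_to_dv(nm$mean + med)
}

deg2rad <- function(x) x * pi / 180
rad2deg <- function(x) x * 180 / pi

## clamp negative correlations to zero (printed correlation range [0, 1])
clamp0 <- function(x) pmax(x, 0)
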