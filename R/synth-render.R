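## Rendering of junction segments into synthetic fluorescence images.

#' Render junction segments as a noisy fluorescence image
#'
#' Draws each segment as an anti-aliased line with Gaussian cross-section
#' (FWHM \code{line_width}) and peak brightness proportional to its myosin
#' intensity, convolves with a Gaussian PSF, and adds Gaussian noise.
#' Deterministic for a fixed seed.
#'
#' @param segments data.frame with columns \code{x_um}, \code{y_um}
#'   (midpoints), \code{angle_deg} (nematic, to the DV axis),
#'   \code{length_um}, \code{intensity}. May be empty.
#' @param chart a \code{chart_grid} defining the image raster.
#' @param line_width line FWHM in micrometers.
#' @param psf_sigma PSF standard deviation in micrometers (0 = none).
#' @param noise_sigma additive Gaussian noise standard deviation.
#' @param seed integer seed for the noise.
#' @return nx x ny intensity matrix.
#' @export
render_junction_image <- function(segments, chart, line_width = 1.2,
                                  psf_sigma = 0.8, noise_sigma = 0,
                                  seed = 1) {
  stopifnot(inherits(chart, "chart_grid"))
  if (line_width < 0 || psf_sigma < 0 || noise_sigma < 0)
    stop("widths and sigmas must be >= 0")
  img <- matrix(0, chart$nx, chart$ny)
  sw <- max(line_width / (2 * sqrt(2 * log(2))), 0.2)  # FWHM -> sigma
  if (!is.null(segments) && nrow(segments) > 0L) {
    for (r in seq_len(nrow(segments))) {
      s <- segments[r, ]
      ## segment direction: nematic angle measured counterclockwise from
      ## the DV (+y) axis (the sign of the rotation rate)
      ux <- -sin(deg2rad(s$angle_deg)); uy <- cos(deg2rad(s$angle_deg))
      hl <- s$length_um / 2
      pad <- 3 * sw + 1
      ix <- which(abs(chart$x - s$x_um) <= hl + pad)
      jy <- which(abs(wrap_dy(chart$y - s$y_um, chart$dv_circumference)) <=
                  hl + pad)
      if (length(ix) == 0L || length(jy) == 0L) next
      rx <- outer(chart$x[ix] - s$x_um, rep(1, length(jy)))
      ry <- outer(rep(1, length(ix)),
                  wrap_dy(chart$y[jy] - s$y_um, chart$dv_circumference))
      along <- pmin(pmax(rx * ux + ry * uy, -hl), hl)
      dx_ <- rx - along * ux
      dy_ <- ry - along * uy
      v <- s$intensity * exp(-(dx_^2 + dy_^2) / (2 * sw^2))
      img[ix, jy] <- pmax(img[ix, jy], v)
    }
  }
  if (psf_sigma > 0) img <- smooth_field(img, chart, psf_sigma)
  if (noise_sigma > 0) {
    set.seed(seed)
    img <- img + matrix(stats::rnorm(length(img), 0, noise_sigma),
                        nrow(img), ncol(img))
  }
  img
}
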