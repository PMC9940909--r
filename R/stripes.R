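## Pair-rule-gene stripe analysis: smoothed gradients, stripe segmentation,
## inter-stripe lines, stripe orientation fields, nematic autocorrelation,
## the PRG-gradient regression, and DV decay profiles.

#' Smoothed gradient of an expression field
#'
#' Gaussian smoothing (DV-periodic) followed by central-difference
#' gradients. The gradient vector points in the direction in which the
#' signal increases most; for striped expression it points towards the
#' stripe centers.
#'
#' @param field nx x ny intensity matrix.
#' @param chart the \code{chart_grid} of the field.
#' @param sigma_um smoothing scale in micrometers (default 10, about 1.5
#'   cell diameters).
#' @return list with matrices \code{gx}, \code{gy} (units of field per um)
#'   and the smoothed field \code{smoothed}.
#' @export
smoothed_gradient <- function(field, chart, sigma_um = 10) {
  stopifnot(inherits(chart, "chart_grid"))
  if (!all(dim(field) == c(chart$nx, chart$ny)))
    stop("field shape does not match chart")
  f <- smooth_field(field, chart, sigma_um)
  list(gx = ddx(f, chart), gy = ddy(f, chart), smoothed = f)
}

#' Gradient magnitude of an expression field
#'
#' For the default seven-stripe pattern this map shows 14 regularly spaced
#' bands along AP (two flanks per stripe), modulated along DV like the
#' expression itself.
#'
#' @inheritParams smoothed_gradient
#' @return nx x ny matrix of |gradient|.
#' @export
gradient_magnitude <- function(field, chart, sigma_um = 10) {
  g <- smoothed_gradient(field, chart, sigma_um)
  sqrt(g$gx^2 + g$gy^2)
}

#' Count AP gradient bands of an expression pattern
#'
#' Thresholds the smoothed gradient-magnitude map at a fraction of its
#' germband maximum and counts connected components (with DV periodicity)
#' that intersect the germband.
#'
#' @inheritParams smoothed_gradient
#' @param threshold_frac fraction of the germband maximum.
#' @return integer band count.
#' @export
count_gradient_bands <- function(field, chart, sigma_um = 10,
                                 threshold_frac = 0.5) {
  gm <- gradient_magnitude(field, chart, sigma_um)
  thr <- threshold_frac * max(gm[chart$germband_mask])
  lab <- label_components(gm >= thr, periodic = TRUE)
  length(setdiff(unique(lab[chart$germband_mask]), 0L))
}

#' Segment expression stripes
#'
#' Threshold at \code{threshold_frac} of the maximum after smoothing;
#' connected components (periodic in DV) spanning at least half of the
#' germband DV extent become stripes, ordered along AP. An empty result is
#' returned with a warning, not an error.
#'
#' @inheritParams smoothed_gradient
#' @param threshold_frac fraction of the smoothed maximum, in (0, 1).
#' @return object of class \code{stripe_set}: label matrix \code{labels}
#'   (0 = background, stripes numbered 1..k along AP), \code{k}, the
#'   smoothed field, and a per-stripe summary data.frame.
#' @export
segment_stripes <- function(field, chart, threshold_frac = 0.5,
                            sigma_um = 5) {
  stopifnot(inherits(chart, "chart_grid"))
  if (threshold_frac <= 0 || threshold_frac >= 1)
    stop("threshold_frac must lie in (0, 1)")
  f <- smooth_field(field, chart, sigma_um)
  mx <- max(f)
  lab <- if (mx > 0) label_components(f >= threshold_frac * mx,
                                      periodic = TRUE)
         else matrix(0L, chart$nx, chart$ny)
  ## keep components spanning >= 50% of the germband DV extent
  need_span <- chart$germband_halfwidth        # half of the 2*hw extent
  gb_rows <- dv_distance(chart$y, chart) <= chart$germband_halfwidth
  keep <- integer(0)
  info <- list()
  for (id in setdiff(unique(as.integer(lab)), 0L)) {
    px <- which(lab == id, arr.ind = TRUE)
    rows <- unique(px[, 2L])
    span <- sum(gb_rows[rows]) * chart$dy
    if (span >= need_span) {
      keep <- c(keep, id)
      info[[length(info) + 1L]] <-
        data.frame(old_id = id, x_center = mean(chart$x[px[, 1L]]),
                   dv_span_um = span, n_px = nrow(px))
    }
  }
  out_lab <- matrix(0L, chart$nx, chart$ny)
  stripes <- data.frame()
  if (length(keep) > 0L) {
    info <- do.call(rbind, info)
    ord <- order(info$x_center)
    info <- info[ord, , drop = FALSE]
    for (i in seq_along(keep))
      out_lab[lab == info$old_id[i]] <- i
    stripes <- data.frame(id = seq_along(keep), x_center = info$x_center,
                          dv_span_um = info$dv_span_um, n_px = info$n_px)
  } else {
    warning("no stripes found")
  }
  structure(list(labels = out_lab, k = nrow(stripes), stripes = stripes,
                 smoothed = f, chart = chart,
                 threshold_frac = threshold_frac),
            class = "stripe_set")
}

#' @exportS3Method print stripe_set
print.stripe_set <- function(x, ...) {
  cat(sprintf("stripe_set: %d stripes\n", x$k))
  if (x$k > 0) print(x$stripes)
  invisible(x)
}

#' Inter-stripe lines of a stripe set
#'
#' For each pair of AP-adjacent stripes, the ridge of minimal smoothed
#' intensity between their AP extents, one polyline spanning the germband
#' DV extent (one vertex per DV row, ordered ventral-to-ventral through the
#' dorsal side if the germband wraps). k stripes yield k - 1 lines.
#'
#' @param stripe_set a \code{stripe_set}.
#' @return list of polylines, each a data.frame with \code{x_um},
#'   \code{y_um}; empty list if fewer than 2 stripes.
#' @export
interstripe_lines <- function(stripe_set) {
  stopifnot(inherits(stripe_set, "stripe_set"))
  chart <- stripe_set$chart
  if (stripe_set$k < 2L) return(list())
  ## germband DV rows ordered by signed distance from the ventral midline
  signed <- wrap_dy(chart$y, chart$dv_circumference)
  rows <- which(abs(signed) <= chart$germband_halfwidth)
  rows <- rows[order(signed[rows])]
  f <- stripe_set$smoothed
  lines <- vector("list", stripe_set$k - 1L)
  for (p in seq_len(stripe_set$k - 1L)) {
    xs <- numeric(length(rows))
    for (ri in seq_along(rows)) {
      j <- rows[ri]
      cols_a <- which(stripe_set$labels[, j] == p)
      cols_b <- which(stripe_set$labels[, j] == p + 1L)
      lo <- if (length(cols_a)) max(cols_a)
            else round(stripe_set$stripes$x_center[p] / chart$dx) + 1L
      hi <- if (length(cols_b)) min(cols_b)
            else round(stripe_set$stripes$x_center[p + 1L] / chart$dx) + 1L
      lo <- max(1L, min(lo, chart$nx)); hi <- max(1L, min(hi, chart$nx))
      if (hi <= lo) { xs[ri] <- chart$x[lo]; next }
      seg <- f[lo:hi, j]
      xs[ri] <- chart$x[lo + which.min(seg) - 1L]
    }
    lines[[p]] <- data.frame(x_um = xs, y_um = chart$y[rows])
  }
  lines
}

#' Nematic orientation field of expression stripes
#'
#' The stripe direction is the direction of the expression gradient rotated
#' by 90 degrees, expressed as a nematic angle against the DV axis and
#' weighted by the gradient magnitude. Stripes parallel to the DV axis give
#' angle 0 wherever the weight is appreciable.
#'
#' @inheritParams smoothed_gradient
#' @return object of class \code{orientation_field}: matrices \code{angle}
#'   (deg in (-90, 90]) and \code{weight} (>= 0), plus the chart.
#' @export
stripe_angle_field <- function(field, chart, sigma_um = 10) {
  g <- smoothed_gradient(field, chart, sigma_um)
  ## gradient perpendicular: (-gy, gx); nematic angle counterclockwise
  ## from the DV (+y) axis
  px <- -g$gy; py <- g$gx
  ang <- angle_to_dv(rad2deg(atan2(-px, py)))
  w <- sqrt(g$gx^2 + g$gy^2)
  ang[w == 0] <- 0
  structure(list(angle = ang, weight = w, chart = chart),
            class = "orientation_field")
}

#' Temporal autocorrelation of a nematic orientation field series
#'
#' C(t1, t2) = clamp0 of the weighted mean of cos 2(theta(t1) - theta(t2)),
#' weights being the product of the per-frame weights. Symmetric with unit
#' diagonal; frames with all-zero weight yield flagged NA entries.
#'
#' @param orientation_series list with 3D arrays \code{angle} (deg) and
#'   \code{weight}, and \code{times}; as built by
#'   \code{\link{orientation_series}}.
#' @param mask optional logical matrix restricting the average.
#' @return a \code{correlation_matrix}.
#' @export
nematic_autocorrelation <- function(orientation_series, mask = NULL) {
  ang <- orientation_series$angle
  w <- orientation_series$weight
  times <- orientation_series$times
  nt <- length(times)
  if (is.null(mask)) mask <- matrix(TRUE, dim(ang)[1L], dim(ang)[2L])
  sel <- which(mask)
  C <- matrix(NA_real_, nt, nt)
  for (a in seq_len(nt)) for (b in a:nt) {
    wa <- w[, , a][sel]; wb <- w[, , b][sel]
    ww <- wa * wb
    W <- sum(ww)
    C[a, b] <- C[b, a] <- if (!is.finite(W) || W <= 0) NA_real_
      else clamp0(sum(ww * cos(2 * deg2rad(ang[, , a][sel] -
                                           ang[, , b][sel]))) / W)
  }
  correlation_matrix(C, times)
}

#' Assemble an orientation-field series
#'
#' @param fields list of \code{orientation_field}s on a common grid.
#' @param times numeric vector of time stamps (min).
#' @return list with 3D arrays \code{angle}, \code{weight}, plus
#'   \code{times} and \code{chart}, accepted by
#'   \code{\link{nematic_autocorrelation}} and \code{\link{fit_tau}}.
#' @export
orientation_series <- function(fields, times) {
  stopifnot(length(fields) == length(times), length(fields) >= 1L)
  d <- dim(fields[[1L]]$angle)
  ang <- array(0, c(d, length(fields)))
  w <- array(0, c(d, length(fields)))
  for (k in seq_along(fields)) {
    ang[, , k] <- fields[[k]]$angle
    w[, , k] <- fields[[k]]$weight
  }
  list(angle = ang, weight = w, times = times, chart = fields[[1L]]$chart)
}

#' Regression of myosin intensity on PRG gradient patterns
#'
#' Ordinary least squares of the myosin map on the gradient-magnitude maps
#' of the PRG expression patterns over the germband pixels, one signed
#' weight per gene, no intercept by default. Rank-deficient regressor sets
#' are reported and resolved by the minimum-norm solution.
#'
#' @param myosin_field nx x ny myosin intensity matrix.
#' @param prg_gradient_fields named list of regressor matrices (typically
#'   gradient magnitudes, one per PRG).
#' @param mask logical matrix of analysis pixels (default: germband of
#'   \code{chart}).
#' @param chart optional \code{chart_grid} (for the default mask).
#' @param intercept include an intercept (default FALSE).
#' @return object of class \code{prg_regression}: \code{weights} (named,
#'   signed), \code{fitted} and \code{residual} maps (fitted = weighted sum
#'   of the regressor maps exactly), \code{r_squared}, and
#'   \code{rank_deficient}.
#' @export
prg_regression <- function(myosin_field, prg_gradient_fields, mask = NULL,
                           chart = NULL, intercept = FALSE) {
  if (length(prg_gradient_fields) < 1L) stop("need at least one regressor")
  if (is.null(mask)) {
    if (is.null(chart)) stop("supply a mask or a chart")
    mask <- chart$germband_mask
  }
  sel <- which(mask)
  X <- vapply(prg_gradient_fields, function(m) m[sel],
              numeric(length(sel)))
  X <- as.matrix(X)
  nm <- names(prg_gradient_fields)
  if (is.null(nm)) nm <- paste0("prg", seq_len(ncol(X)))
  if (intercept) {
    X <- cbind(`(intercept)` = 1, X)
    nm <- c("(intercept)", nm)
  }
  yv <- myosin_field[sel]
  qr_ <- qr(X)
  rank_deficient <- qr_$rank < ncol(X)
  beta <- if (!rank_deficient) qr.coef(qr_, yv) else {
    sv <- svd(X)
    pos <- sv$d > max(sv$d) * 1e-10
    drop(sv$v[, pos, drop = FALSE] %*%
           ((crossprod(sv$u[, pos, drop = FALSE], yv)) / sv$d[pos]))
  }
  beta[!is.finite(beta)] <- 0
  names(beta) <- nm
  fitted_map <- matrix(0, nrow(myosin_field), ncol(myosin_field))
  if (intercept) fitted_map[] <- beta[1L]
  bmap <- if (intercept) beta[-1L] else beta
  for (j in seq_along(prg_gradient_fields))
    fitted_map <- fitted_map + bmap[j] * prg_gradient_fields[[j]]
  resid_map <- myosin_field - fitted_map
  rss <- sum(resid_map[sel]^2)
  tss <- if (intercept) sum((yv - mean(yv))^2) else sum(yv^2)
  structure(list(weights = beta, fitted = fitted_map,
                 residual = resid_map,
                 r_squared = if (tss > 0) 1 - rss / tss else NA_real_,
                 rank_deficient = rank_deficient, mask = mask),
            class = "prg_regression")
}

#' @exportS3Method print prg_regression
print.prg_regression <- function(x, ...) {
  cat("PRG gradient regression\n  weights:\n")
  print(round(x$weights, 4))
  cat(sprintf("  R^2 = %.4f%s\n", x$r_squared,
              if (x$rank_deficient) " (rank deficient, minimum norm)"
              else ""))
  invisible(x)
}

#' DV decay profile of a field
#'
#' Mean intensity versus DV distance from the ventral midline, fold-
#' averaged over the two lateral halves (using DV periodicity), averaged
#' over the germband AP range, and normalized to the ventral maximum. Used
#' to quantify the decay of junctional myosin and of Runt away from the
#' ventral furrow.
#'
#' @param field nx x ny intensity matrix.
#' @param chart the \code{chart_grid}.
#' @param bin_um DV bin width (micrometers).
#' @return data.frame with \code{dv_um} (bin centers) and \code{intensity}
#'   (normalized).
#' @export
dv_profile <- function(field, chart, bin_um = 5) {
  stopifnot(inherits(chart, "chart_grid"))
  if (bin_um <= 0) stop("bin width must be positive")
  d <- dv_distance(chart$y, chart)
  in_ap <- chart$x >= chart$ap_margin &
    chart$x <= chart$ap_length - chart$ap_margin
  colmean <- colMeans(field[in_ap, , drop = FALSE])
  bins <- floor(d / bin_um)
  prof <- tapply(colmean, bins, mean)
  centers <- (as.numeric(names(prof)) + 0.5) * bin_um
  v <- as.numeric(prof)
  if (max(v) > 0) v <- v / max(v)
  data.frame(dv_um = centers, intensity = v)
}
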