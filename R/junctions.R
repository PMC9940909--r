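## Segmentation-free detection of myosin-rich junctions (MRJs) via a
## windowed Radon transform, intensity-weighted nematic orientation
## fields, and circular statistics of junction angles.

#' Parameters of the Radon junction detector
#'
#' @param window_um side of the square analysis window (micrometers).
#' @param overlap fractional overlap between adjacent windows.
#' @param angular_step angular sampling of the transform (degrees).
#' @param threshold_k peak threshold in robust standard deviations above
#'   the window sinogram median.
#' @param merge_angle,merge_dist duplicate-suppression criteria: two
#'   detections closer than \code{merge_dist} (micrometers) with nematic
#'   angle difference below \code{merge_angle} (degrees) are merged.
#' @param min_length_um minimal accepted segment length.
#' @param suppress_crossing_um weaker detections whose midpoint lies
#'   within this distance of a stronger one are treated as angular
#'   sidelobes of the same structure and dropped regardless of angle.
#' @return list of detector parameters.
#' @export
radon_params <- function(window_um = 12, overlap = 0.5, angular_step = 1,
                         threshold_k = 5, merge_angle = 10,
                         merge_dist = 3, min_length_um = 4,
                         suppress_crossing_um = 3) {
  list(window_um = window_um, overlap = overlap,
       angular_step = angular_step, threshold_k = threshold_k,
       merge_angle = merge_angle, merge_dist = merge_dist,
       min_length_um = min_length_um,
       suppress_crossing_um = suppress_crossing_um)
}

## Projection operator of a square window: maps the vectorized window to
## its sinogram (mean intensity per (offset, angle) bin). Cached per
## (wpx, nang) in the package namespace.
.radon_cache <- new.env(parent = emptyenv())

radon_operator <- function(wpx, angles_deg, dx) {
  key <- sprintf("w%d_a%d", wpx, length(angles_deg))
  if (!is.null(.radon_cache[[key]])) return(.radon_cache[[key]])
  half <- (wpx - 1) / 2
  cc <- ((seq_len(wpx)) - 1 - half) * dx     # pixel offsets from center
  px <- rep(cc, times = wpx)                 # x = first index
  py <- rep(cc, each = wpx)
  rmax <- sqrt(2) / 2 * wpx * dx
  nb <- 2L * ceiling(rmax / dx) + 1L
  nang <- length(angles_deg)
  rows <- integer(0); cols <- integer(0)
  for (a in seq_len(nang)) {
    th <- deg2rad(angles_deg[a])
    ## line direction u = (-sin th, cos th): angle measured
    ## counterclockwise from the DV (+y) axis; projection offset along
    ## the normal n = (cos th, sin th)
    rho <- px * cos(th) + py * sin(th)
    b <- pmin(pmax(round(rho / dx) + (nb + 1L) %/% 2L, 1L), nb)
    rows <- c(rows, (a - 1L) * nb + b)
    cols <- c(cols, seq_along(px))
  }
  P <- Matrix::sparseMatrix(i = rows, j = cols, x = 1,
                            dims = c(nb * nang, wpx * wpx))
  cnt <- Matrix::rowSums(P)
  cnt[cnt == 0] <- 1
  P <- Matrix::Diagonal(x = 1 / cnt) %*% P
  op <- list(P = P, nb = nb, nang = nang, angles = angles_deg,
             counts = cnt, rmax = rmax, wpx = wpx)
  .radon_cache[[key]] <- op
  op
}

#' Detect myosin-rich junctions by a windowed Radon transform
#'
#' The image is tiled with overlapping square windows. Per window the
#' median is subtracted, the Radon transform over 0-180 degrees is
#' computed, and sinogram peaks above \code{threshold_k} robust standard
#' deviations (median/MAD) are back-projected to line segments. Each
#' candidate chord is trimmed to the contiguous bright run along it, and
#' duplicates arising from window overlap are merged, keeping the
#' strongest detection. The detector is insensitive to noise and requires
#' no cell segmentation.
#'
#' @param image nx x ny intensity matrix on \code{chart}.
#' @param chart the \code{chart_grid} of the image (needs square pixels).
#' @param params detector parameters, see \code{\link{radon_params}}.
#' @return data.frame of class \code{junction_segments}: columns
#'   \code{x_um}, \code{y_um} (midpoint), \code{x1_um}, \code{y1_um},
#'   \code{x2_um}, \code{y2_um}, \code{angle_deg} (nematic, to the DV
#'   axis), \code{length_um}, \code{intensity}, \code{peak_z}.
#' @export
radon_detect <- function(image, chart, params = radon_params()) {
  stopifnot(inherits(chart, "chart_grid"))
  if (!isTRUE(all.equal(chart$dx, chart$dy)))
    stop("radon_detect requires square pixels")
  dx <- chart$dx
  wpx <- max(6L, round(params$window_um / dx))
  if (wpx > chart$nx || wpx > chart$ny)
    stop("window larger than image")
  angles <- seq(0, 180 - params$angular_step, by = params$angular_step)
  op <- radon_operator(wpx, angles, dx)

  step <- max(1L, round(wpx * (1 - params$overlap)))
  xs <- unique(c(seq(1L, chart$nx - wpx + 1L, by = step),
                 chart$nx - wpx + 1L))
  ys <- unique(c(seq(1L, chart$ny - wpx + 1L, by = step),
                 chart$ny - wpx + 1L))
  starts <- expand.grid(i = xs, j = ys)
  nwin <- nrow(starts)

  ## stack windows into columns, subtract per-window medians
  W <- matrix(0, wpx * wpx, nwin)
  for (k in seq_len(nwin)) {
    W[, k] <- as.numeric(image[starts$i[k] + seq_len(wpx) - 1L,
                               starts$j[k] + seq_len(wpx) - 1L])
  }
  meds <- apply(W, 2L, stats::median)
  W <- sweep(W, 2L, meds)
  S <- as.matrix(op$P %*% W)        # (nb * nang) x nwin sinograms

  half <- (wpx - 1) / 2
  ## variance-stabilized sinogram: each bin is a mean of counts[b] pixels,
  ## so multiplying by sqrt(count) equalizes the noise across bins
  sqrtcnt <- sqrt(op$counts)
  lowcnt <- op$counts < 3          # unreliable corner bins
  ## image-level signal scale: windows whose strongest projection is below
  ## 1% of the brightest window's cannot yield detections (detection floor)
  qall <- S * sqrtcnt
  qall[lowcnt, ] <- NA
  q_global <- max(qall, na.rm = TRUE)
  det_list <- list()
  for (k in seq_len(nwin)) {
    q <- S[, k] * sqrtcnt
    q[lowcnt] <- NA
    med <- stats::median(q, na.rm = TRUE)
    ## noise scale estimated robustly from the window pixels themselves
    ## (variance stabilization makes the per-bin noise equal to the pixel
    ## noise); floored at 5% of the peak excursion so nearly noise-free
    ## windows threshold against their own signal rather than a vanishing
    ## MAD
    sdr <- max(stats::mad(W[, k]),
               0.05 * max(q - med, 0, na.rm = TRUE),
               0.01 * q_global, 1e-12)
    z <- matrix((q - med) / sdr, op$nb, op$nang)
    z[is.na(z)] <- -Inf
    peaks <- which(z >= params$threshold_k, arr.ind = TRUE)
    if (nrow(peaks) == 0L) next
    ## non-maximum suppression over +-1 offset bin and +-5 degrees
    da <- max(1L, round(5 / params$angular_step))
    keep <- logical(nrow(peaks))
    for (p in seq_len(nrow(peaks))) {
      b <- peaks[p, 1L]; a <- peaks[p, 2L]
      nb_b <- unique(pmin(pmax(b + (-1:1), 1L), op$nb))
      nb_a <- unique(((a + (-da:da) - 1L) %% op$nang) + 1L)
      keep[p] <- z[b, a] >= max(z[nb_b, nb_a])
    }
    peaks <- peaks[keep, , drop = FALSE]
    if (nrow(peaks) == 0L) next
    cx <- (starts$i[k] - 1 + half) * dx    # window center, um
    cy <- (starts$j[k] - 1 + half) * dx
    for (p in seq_len(nrow(peaks))) {
      b <- peaks[p, 1L]; a <- peaks[p, 2L]
      ## quadratic sub-bin interpolation along the angle axis
      am <- ((a - 2L) %% op$nang) + 1L; ap <- (a %% op$nang) + 1L
      zm <- z[b, am]; zp <- z[b, ap]; zc <- z[b, a]
      if (!is.finite(zm)) zm <- zc
      if (!is.finite(zp)) zp <- zc
      denom <- zm - 2 * zc + zp
      dtheta <- if (is.finite(denom) && abs(denom) > 1e-12)
        0.5 * (zm - zp) / denom else 0
      theta <- op$angles[a] + pmin(pmax(dtheta, -0.5), 0.5) *
        params$angular_step
      rho <- (b - (op$nb + 1L) %/% 2L) * dx
      seg <- trim_segment(image, chart, cx, cy, theta, rho,
                          half * dx, meds[k], sdr)
      if (is.null(seg) || seg$length_um < params$min_length_um) next
      seg$peak_z <- z[b, a]
      det_list[[length(det_list) + 1L]] <- seg
    }
  }
  if (length(det_list) == 0L) {
    out <- empty_segments()
  } else {
    det <- do.call(rbind, lapply(det_list, as.data.frame))
    out <- merge_detections(det, params$merge_dist, params$merge_angle,
                            params$suppress_crossing_um)
  }
  class(out) <- c("junction_segments", "data.frame")
  out
}

empty_segments <- function() {
  data.frame(x_um = numeric(0), y_um = numeric(0), x1_um = numeric(0),
             y1_um = numeric(0), x2_um = numeric(0), y2_um = numeric(0),
             angle_deg = numeric(0), length_um = numeric(0),
             intensity = numeric(0), peak_z = numeric(0))
}

## Back-project a sinogram peak (theta deg from DV axis, offset rho along
## the normal) to the chord of the window, then trim it to the contiguous
## bright run along the chord.
trim_segment <- function(image, chart, cx, cy, theta_deg, rho, half_um,
                         bg, noise_scale = 0) {
  th <- deg2rad(theta_deg)
  ux <- -sin(th); uy <- cos(th)       # line direction (CCW from +y)
  nx_ <- cos(th); ny_ <- sin(th)      # normal
  p0x <- rho * nx_; p0y <- rho * ny_  # window coords of the line foot
  ## clip s-range to the window square |p0 + s u| <= half
  smin <- -2 * half_um; smax <- 2 * half_um
  for (axis in 1:2) {
    u <- if (axis == 1L) ux else uy
    p0 <- if (axis == 1L) p0x else p0y
    if (abs(u) < 1e-12) {
      if (abs(p0) > half_um) return(NULL)
    } else {
      s1 <- (-half_um - p0) / u; s2 <- (half_um - p0) / u
      smin <- max(smin, min(s1, s2)); smax <- min(smax, max(s1, s2))
    }
  }
  if (smax <= smin) return(NULL)
  s <- seq(smin, smax, by = chart$dx / 2)
  if (length(s) < 3L) return(NULL)
  sx <- cx + p0x + s * ux
  sy <- cy + p0y + s * uy
  prof <- interp_field(image, chart, sx, sy)
  if (length(prof) >= 5L) {
    sm <- stats::filter(prof, rep(1, 3) / 3, sides = 2)
    prof <- ifelse(is.na(sm), prof, as.numeric(sm))
  }
  pk <- which.max(prof)
  if (prof[pk] - bg < 2 * noise_scale) return(NULL)
  lev <- bg + 0.5 * (prof[pk] - bg)
  if (prof[pk] <= bg) return(NULL)
  lo <- pk; while (lo > 1L && prof[lo - 1L] >= lev) lo <- lo - 1L
  hi <- pk; while (hi < length(prof) && prof[hi + 1L] >= lev) hi <- hi + 1L
  x1 <- sx[lo]; y1 <- sy[lo]; x2 <- sx[hi]; y2 <- sy[hi]
  len <- sqrt((x2 - x1)^2 + (y2 - y1)^2)
  mx <- (x1 + x2) / 2; my <- (y1 + y2) / 2
  inten <- mean(prof[lo:hi])
  ## iterate: refine the angle from intensity-weighted second moments in
  ## a narrow tube, then re-trim along the refined direction on the full
  ## image (the initial chord is clipped to the window, which shortens
  ## the run and biases the midpoint)
  theta <- theta_deg
  for (it in 1:3) {
    ref <- refine_angle(image, chart, mx, my, theta,
                        max(len, 7), bg)
    if (!is.finite(ref)) break
    conv <- abs(nematic_diff(ref, theta)) < 0.1
    theta <- ref
    rt <- line_retrim(image, chart, mx, my, theta,
                      span_um = max(len, 7) + 5, bg = bg,
                      noise_scale = noise_scale)
    if (is.null(rt)) break
    mx <- rt$mx; my <- rt$my; len <- rt$len; inten <- rt$intensity
    if (conv) break
  }
  th2 <- deg2rad(theta)
  list(x_um = mx, y_um = my,
       x1_um = mx + len / 2 * sin(th2), y1_um = my - len / 2 * cos(th2),
       x2_um = mx - len / 2 * sin(th2), y2_um = my + len / 2 * cos(th2),
       angle_deg = angle_to_dv(theta), length_um = len,
       intensity = inten)
}

## Re-trim a line through (mx, my) at angle theta on the full image: find
## the contiguous run above the half-level around the profile maximum.
line_retrim <- function(image, chart, mx, my, theta_deg, span_um, bg,
                        noise_scale = 0) {
  th <- deg2rad(theta_deg)
  ux <- -sin(th); uy <- cos(th)
  s <- seq(-span_um / 2, span_um / 2, by = chart$dx / 2)
  sx <- pmin(pmax(mx + s * ux, 0), chart$ap_length - chart$dx)
  sy <- my + s * uy
  prof <- interp_field(image, chart, sx, sy)
  if (length(prof) >= 5L) {
    sm <- stats::filter(prof, rep(1, 3) / 3, sides = 2)
    prof <- ifelse(is.na(sm), prof, as.numeric(sm))
  }
  ## take the run containing the sample closest to the current midpoint
  c0 <- which.min(abs(s))
  win <- abs(s) <= 2
  pk <- which(win)[which.max(prof[win])]
  if (!length(pk) || prof[pk] <= bg ||
      prof[pk] - bg < 2 * noise_scale) return(NULL)
  lev <- bg + 0.5 * (prof[pk] - bg)
  lo <- pk; while (lo > 1L && prof[lo - 1L] >= lev) lo <- lo - 1L
  hi <- pk; while (hi < length(prof) && prof[hi + 1L] >= lev) hi <- hi + 1L
  list(mx = (sx[lo] + sx[hi]) / 2, my = (sy[lo] + sy[hi]) / 2,
       len = sqrt((sx[hi] - sx[lo])^2 + (sy[hi] - sy[lo])^2),
       intensity = mean(prof[lo:hi]))
}

## Principal-axis angle (deg from the DV axis) of the background-
## subtracted intensity in a tube around a candidate segment; NA when the
## moment tensor is degenerate.
refine_angle <- function(image, chart, mx, my, theta_deg, len, bg,
                         tube_um = 2.5) {
  th <- deg2rad(theta_deg)
  ux <- -sin(th); uy <- cos(th)
  hl <- len / 2
  ix <- which(abs(chart$x - mx) <= hl + tube_um)
  jy <- which(abs(wrap_dy(chart$y - my, chart$dv_circumference)) <=
              hl + tube_um)
  if (length(ix) < 2L || length(jy) < 2L) return(NA_real_)
  rx <- outer(chart$x[ix] - mx, rep(1, length(jy)))
  ry <- outer(rep(1, length(ix)),
              wrap_dy(chart$y[jy] - my, chart$dv_circumference))
  along <- rx * ux + ry * uy
  perp <- rx * uy - ry * ux
  w <- pmax(image[ix, jy] - bg, 0)
  w[abs(along) > hl | abs(perp) > tube_um] <- 0
  sw <- sum(w)
  if (sw <= 0) return(NA_real_)
  cx_ <- sum(w * rx) / sw; cy_ <- sum(w * ry) / sw
  sxx <- sum(w * (rx - cx_)^2) / sw
  syy <- sum(w * (ry - cy_)^2) / sw
  sxy <- sum(w * (rx - cx_) * (ry - cy_)) / sw
  if (sxx + syy <= 1e-12) return(NA_real_)
  ## principal axis of the 2x2 tensor; angle from the +x axis, converted
  ## to the CCW-from-DV-axis convention
  ang <- 0.5 * atan2(2 * sxy, sxx - syy)
  out <- angle_to_dv(rad2deg(ang) - 90)
  ## guard: stay close to the Radon estimate
  if (abs(nematic_diff(out, theta_deg)) > 20) return(NA_real_)
  out
}

## Greedy duplicate suppression: strongest peaks first; later detections
## within merge_dist and merge_angle of an accepted one are dropped.
merge_detections <- function(det, merge_dist, merge_angle,
                             suppress_crossing_um = 0) {
  det <- det[order(-det$peak_z), , drop = FALSE]
  n <- nrow(det)
  acc <- logical(n)
  for (i in seq_len(n)) {
    if (!any(acc)) { acc[i] <- TRUE; next }
    j <- which(acc)
    dd <- sqrt((det$x_um[j] - det$x_um[i])^2 +
               (det$y_um[j] - det$y_um[i])^2)
    ## distance from this midpoint to the accepted segments (collinear
    ## duplicates from adjacent windows have shifted midpoints but lie on
    ## the same line)
    ds <- point_segment_distance(det$x_um[i], det$y_um[i],
                                 det$x1_um[j], det$y1_um[j],
                                 det$x2_um[j], det$y2_um[j])
    da <- abs(nematic_diff(det$angle_deg[j], det$angle_deg[i]))
    dup <- any(pmin(dd, ds) < merge_dist & da < merge_angle) ||
      any(dd < suppress_crossing_um)
    acc[i] <- !dup
  }
  out <- det[acc, , drop = FALSE]
  rownames(out) <- NULL
  out
}

## --- orientation fields from segments ------------------------------------

## Accumulate the weighted nematic tensor of segments in disks around
## every chart node. weights = intensity * length.
segment_nematic_disks <- function(segments, chart, radius_um) {
  if (radius_um <= 0) stop("radius must be positive")
  re <- matrix(0, chart$nx, chart$ny)
  im <- matrix(0, chart$nx, chart$ny)
  wt <- matrix(0, chart$nx, chart$ny)
  if (!is.null(segments) && nrow(segments) > 0L) {
    len <- if ("length_um" %in% names(segments)) segments$length_um
           else rep(1, nrow(segments))
    w_all <- segments$intensity * len
    phi <- 2 * deg2rad(segments$angle_deg)
    for (r in seq_len(nrow(segments))) {
      if (!is.finite(w_all[r]) || w_all[r] <= 0) next
      ix <- which(abs(chart$x - segments$x_um[r]) <= radius_um)
      jy <- which(abs(wrap_dy(chart$y - segments$y_um[r],
                              chart$dv_circumference)) <= radius_um)
      if (length(ix) == 0L || length(jy) == 0L) next
      ddx_ <- outer(chart$x[ix] - segments$x_um[r], rep(1, length(jy)))
      ddy_ <- outer(rep(1, length(ix)),
                    wrap_dy(chart$y[jy] - segments$y_um[r],
                            chart$dv_circumference))
      inside <- (ddx_^2 + ddy_^2) <= radius_um^2
      re[ix, jy] <- re[ix, jy] + inside * (w_all[r] * cos(phi[r]))
      im[ix, jy] <- im[ix, jy] + inside * (w_all[r] * sin(phi[r]))
      wt[ix, jy] <- wt[ix, jy] + inside * w_all[r]
    }
  }
  list(re = re, im = im, weight = wt)
}

#' Local myosin anisotropy orientation field
#'
#' Per chart node, the intensity-weighted nematic mean of the orientations
#' of all junction segments whose midpoint lies within \code{radius_um}
#' (default 20 um, about three cell diameters), weights intensity x
#' length. Nodes with no segments get weight 0; degenerate nematic means
#' (order parameter below \code{q_floor}, e.g. equal weight at +45 and -45
#' degrees) are reported as missing (weight 0), never as arbitrary angles.
#'
#' @param segments a junction table (detected or simulated), with columns
#'   \code{x_um}, \code{y_um}, \code{angle_deg}, \code{intensity} and
#'   optionally \code{length_um}.
#' @param chart the \code{chart_grid} on which to evaluate the field.
#' @param radius_um disk radius (micrometers).
#' @param q_floor order-parameter threshold below which the local mean is
#'   flagged degenerate.
#' @return an \code{orientation_field} (angle deg, weight).
#' @export
anisotropy_field <- function(segments, chart, radius_um = 20,
                             q_floor = 0.05) {
  acc <- segment_nematic_disks(segments, chart, radius_um)
  mag <- sqrt(acc$re^2 + acc$im^2)
  q <- ifelse(acc$weight > 0, mag / acc$weight, 0)
  ang <- angle_to_dv(rad2deg(atan2(acc$im, acc$re)) / 2)
  w <- acc$weight
  w[q < q_floor] <- 0
  ang[w == 0] <- 0
  structure(list(angle = ang, weight = w, chart = chart,
                 order_parameter = q),
            class = "orientation_field")
}

#' Local magnitude of myosin anisotropy
#'
#' The nematic order parameter q = |weighted mean of e^{2 i theta}| in
#' [0, 1] per disk: 1 for perfectly parallel junctions, approaching 0 (as
#' n^{-1/2}) for isotropic ensembles.
#'
#' @inheritParams anisotropy_field
#' @return nx x ny matrix of q values (0 where no segments).
#' @export
myosin_anisotropy_magnitude <- function(segments, chart, radius_um = 20) {
  acc <- segment_nematic_disks(segments, chart, radius_um)
  ifelse(acc$weight > 0,
         sqrt(acc$re^2 + acc$im^2) / acc$weight, 0)
}

#' Angular distribution of junction orientations
#'
#' Intensity-weighted histogram of nematic junction angles over bins that
#' divide 180 degrees evenly, with circular (nematic) mean, standard
#' deviation, and median computed in double-angle space and mapped back.
#'
#' @param segments a junction table.
#' @param region_mask optional logical chart matrix; only segments whose
#'   midpoint falls inside are used.
#' @param chart required when \code{region_mask} is given.
#' @param bins number of angular bins (default 18, i.e. 10-degree bins).
#' @return object of class \code{angular_distribution}: \code{breaks},
#'   \code{mids}, weighted \code{counts}, \code{n}, \code{mean}, \code{sd},
#'   \code{median} (all degrees; NA-flagged when the region is empty).
#' @export
angular_distribution <- function(segments, region_mask = NULL,
                                 chart = NULL, bins = 18) {
  if (bins < 1 || 180 %% bins != 0)
    stop("bins must divide 180 degrees evenly")
  seg <- segments
  if (!is.null(region_mask)) {
    if (is.null(chart)) stop("supply the chart with a region mask")
    ii <- pmin(pmax(round(seg$x_um / chart$dx) + 1L, 1L), chart$nx)
    jj <- (round(seg$y_um / chart$dy) %% chart$ny) + 1L
    seg <- seg[region_mask[cbind(ii, jj)], , drop = FALSE]
  }
  breaks <- seq(-90, 90, by = 180 / bins)
  if (nrow(seg) == 0L) {
    return(structure(list(breaks = breaks,
                          mids = (breaks[-1] + breaks[-length(breaks)]) / 2,
                          counts = rep(0, bins), n = 0L,
                          mean = NA_real_, sd = NA_real_,
                          median = NA_real_),
                     class = "angular_distribution"))
  }
  w <- seg$intensity
  ang <- angle_to_dv(seg$angle_deg)
  idx <- pmin(pmax(findInterval(ang, breaks, rightmost.closed = TRUE),
                   1L), bins)
  counts <- vapply(seq_len(bins),
                   function(b) sum(w[idx == b]), numeric(1))
  nm <- nematic_mean(ang, w)
  structure(list(breaks = breaks,
                 mids = (breaks[-1] + breaks[-length(breaks)]) / 2,
                 counts = counts, n = nrow(seg),
                 mean = nm$mean, sd = nm$sd,
                 median = nematic_median(ang, w)),
            class = "angular_distribution")
}

#' @exportS3Method print angular_distribution
print.angular_distribution <- function(x, ...) {
  cat(sprintf(paste0("angular_distribution: n = %d, mean = %.2f deg, ",
                     "sd = %.2f deg, median = %.2f deg\n"),
              x$n, x$mean, x$sd, x$median))
  invisible(x)
}


## vectorized distance from a point to segments (x1,y1)-(x2,y2)
point_segment_distance <- function(px, py, x1, y1, x2, y2) {
  vx <- x2 - x1; vy <- y2 - y1
  l2 <- vx^2 + vy^2
  t <- ifelse(l2 > 0, ((px - x1) * vx + (py - y1) * vy) / l2, 0)
  t <- pmin(pmax(t, 0), 1)
  sqrt((px - (x1 + t * vx))^2 + (py - (y1 + t * vy))^2)
}
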