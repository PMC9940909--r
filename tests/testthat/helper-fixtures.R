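## Shared fixtures: all synthetic, built in code at test time.

## small square chart for detector images (1 um pixels)
image_chart <- function(side = 128) {
  make_chart(ap_length = side, dv_circumference = side, dx = 1, dy = 1,
             germband_halfwidth = side / 2, ap_margin = 0)
}

## well-separated random segments on a jittered grid
test_segments <- function(n, chart, seed = 42, length_um = 7,
                          spacing = 13) {
  set.seed(seed)
  gs <- expand.grid(x = seq(spacing - 1, chart$ap_length - spacing + 1,
                            by = spacing),
                    y = seq(spacing - 1, chart$dv_circumference -
                              spacing + 1, by = spacing))
  stopifnot(nrow(gs) >= n)
  gs <- gs[sample(nrow(gs), n), ]
  data.frame(x_um = gs$x + stats::runif(n, -2, 2),
             y_um = gs$y + stats::runif(n, -2, 2),
             angle_deg = stats::runif(n, -90, 90),
             length_um = length_um, intensity = 1)
}

## render at a given SNR (ridge amplitude / noise sd)
snr_image <- function(segs, chart, snr, seed = 7) {
  amp <- max(render_junction_image(segs, chart, noise_sigma = 0))
  ns <- if (is.finite(snr)) amp / snr else 0
  render_junction_image(segs, chart, noise_sigma = ns, seed = seed)
}

## match detections to ground truth by midpoint distance (< 3 um)
match_detections <- function(det, segs, max_dist = 3) {
  hits <- 0
  errs <- numeric(0)
  for (r in seq_len(nrow(segs))) {
    d <- sqrt((det$x_um - segs$x_um[r])^2 + (det$y_um - segs$y_um[r])^2)
    if (length(d) && min(d) < max_dist) {
      hits <- hits + 1
      j <- which.min(d)
      errs <- c(errs, abs(((det$angle_deg[j] - segs$angle_deg[r] + 90) %%
                             180) - 90))
    }
  }
  list(recall = hits / nrow(segs),
       rmse = if (length(errs)) sqrt(mean(errs^2)) else NA_real_)
}

## intensity-weighted mean deflection of the stationary junction ensemble
## under constant rotation: the exponential-age integral (ages weighted
## exp(-a/tau), angles source + rho * a, wrapped to the nematic range)
exp_age_mean <- function(rho, tau, source_width) {
  th0 <- seq(-89.75, 90, by = 0.25)
  a <- seq(0, 12 * tau, by = 0.05)
  w <- outer(exp(-th0^2 / (2 * source_width^2)), exp(-a / tau))
  phi <- 2 * (outer(th0, rho * a, `+`)) * pi / 180
  ## double-angle (nematic) mean, as computed by the measured statistics
  atan2(sum(w * sin(phi)), sum(w * cos(phi))) / 2 * 180 / pi
}

## default wild-type rotation-rate envelope as a scalar series
wt_rotation_series <- function(peak = 5, dt = 1, t_end = 60) {
  tt <- seq(0, t_end, by = dt)
  env <- stats::approx(c(0, 10, 20, 25, 35), c(0, 0, 1, 1, 0),
                       xout = tt, rule = 2)$y
  data.frame(time = tt, value = peak * env)
}
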