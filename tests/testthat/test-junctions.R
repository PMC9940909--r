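test_that("single rendered segment is detected once, accurately", {
  chartI <- image_chart(64)
  one <- data.frame(x_um = 32, y_um = 32, angle_deg = 30, length_um = 8,
                    intensity = 1)
  det <- radon_detect(render_junction_image(one, chartI, noise_sigma = 0),
                      chartI)
  expect_equal(nrow(det), 1L)
  expect_lt(abs(det$angle_deg - 30), 2)
  expect_lt(sqrt((det$x_um - 32)^2 + (det$y_um - 32)^2), 2)
})

test_that("noise-only images give no detections", {
  chartI <- image_chart(64)
  blank <- render_junction_image(NULL, chartI, noise_sigma = 1, seed = 3)
  expect_equal(nrow(radon_detect(blank, chartI)), 0L)
})

test_that("detector reaches the stated recall and angular accuracy at
           SNR 5", {
  chartI <- image_chart(167)
  segs <- test_segments(100, chartI, seed = 42)
  det <- radon_detect(snr_image(segs, chartI, 5), chartI)
  m <- match_detections(det, segs)
  expect_gte(m$recall, 0.95)
  expect_lte(m$rmse, 5)
})

test_that("recall is monotone in SNR", {
  chartI <- image_chart(128)
  segs <- test_segments(60, chartI, seed = 42)
  recalls <- vapply(c(2, 5, 10), function(snr) {
    det <- radon_detect(snr_image(segs, chartI, snr), chartI)
    match_detections(det, segs)$recall
  }, numeric(1))
  expect_true(all(diff(recalls) >= 0))
})

test_that("detector is intensity-scale equivariant", {
  chartI <- image_chart(64)
  one <- data.frame(x_um = 32, y_um = 32, angle_deg = -40, length_um = 8,
                    intensity = 1)
  img <- render_junction_image(one, chartI, noise_sigma = 0)
  d1 <- radon_detect(img, chartI)
  d3 <- radon_detect(3 * img, chartI)
  expect_equal(nrow(d3), nrow(d1))
  expect_equal(d3$angle_deg, d1$angle_deg, tolerance = 0.01)
  expect_equal(d3$x_um, d1$x_um, tolerance = 0.01)
  expect_equal(d3$intensity, 3 * d1$intensity, tolerance = 0.01)
})

test_that("joint 90-degree rotation maps detected angles accordingly", {
  chartI <- image_chart(128)
  segs <- test_segments(40, chartI, seed = 13)
  img <- snr_image(segs, chartI, 10)
  det <- radon_detect(img, chartI)
  ## rotate image by 90 degrees: (x, y) -> (y, side - x)
  img_rot <- t(img)[, rev(seq_len(nrow(img)))]
  det_rot <- radon_detect(img_rot, chartI)
  segs_rot <- segs
  segs_rot$x_um <- segs$y_um
  segs_rot$y_um <- chartI$ap_length - segs$x_um
  segs_rot$angle_deg <- angle_to_dv(segs$angle_deg - 90)
  m <- match_detections(det, segs)
  m_rot <- match_detections(det_rot, segs_rot)
  expect_lt(abs(m$recall - m_rot$recall), 0.02 + 1e-9)
  expect_lte(m_rot$rmse, 6)
})

test_that("angle canonicalization boundary cases", {
  expect_equal(angle_to_dv(c(95, -90, 0, 90, 180)),
               c(-85, 90, 0, 90, 0))
})

test_that("anisotropy fields take weighted nematic disk means", {
  chart <- make_chart(ap_length = 60, dv_circumference = 60, dx = 2,
                      dy = 2, germband_halfwidth = 30, ap_margin = 0)
  ## all segments parallel: field equals that angle wherever weighted
  par <- data.frame(x_um = c(20, 30, 40), y_um = c(30, 30, 30),
                    angle_deg = 25, length_um = 7, intensity = 1)
  of <- anisotropy_field(par, chart, radius_um = 15)
  expect_equal(unique(of$angle[of$weight > 0]), 25, tolerance = 1e-9)
  ## nematic cancellation: +45 / -45 in one disk flagged as degenerate
  cross <- data.frame(x_um = c(30, 30), y_um = c(30, 32),
                      angle_deg = c(45, -45), length_um = 7,
                      intensity = 1)
  ofc <- anisotropy_field(cross, chart, radius_um = 20)
  ## at nodes whose disk holds both segments the mean is degenerate
  expect_equal(ofc$weight[16, 16], 0)
  expect_equal(ofc$angle[16, 16], 0)
  ## empty segment list: zero weight everywhere
  of0 <- anisotropy_field(par[0, ], chart, radius_um = 15)
  expect_equal(max(of0$weight), 0)
  ## 180-degree shift leaves the field identical
  par2 <- par; par2$angle_deg <- par$angle_deg + 180
  expect_equal(anisotropy_field(par2, chart, 15)$angle, of$angle)
})

test_that("disk means recover the sampling distribution mean", {
  chart <- make_chart(ap_length = 40, dv_circumference = 40, dx = 4,
                      dy = 4, germband_halfwidth = 20, ap_margin = 0)
  set.seed(21)
  n <- 500
  segs <- data.frame(x_um = stats::runif(n, 15, 25),
                     y_um = stats::runif(n, 15, 25),
                     angle_deg = 10 + stats::rnorm(n, 0, 15),
                     length_um = 7, intensity = 1)
  of <- anisotropy_field(segs, chart, radius_um = 18)
  center <- of$angle[chart$nx / 2, chart$ny / 2]
  expect_equal(center, 10, tolerance = 2 / 10)
})

test_that("angular distributions compute nematic circular statistics", {
  seg1 <- data.frame(x_um = 1:20, y_um = 1, angle_deg = 0,
                     length_um = 7, intensity = 1)
  d <- angular_distribution(seg1, bins = 18)
  expect_equal(d$mean, 0)
  expect_equal(d$sd, 0, tolerance = 1e-9)
  expect_equal(sum(d$counts > 0), 1L)
  expect_error(angular_distribution(seg1, bins = 7), "divide")
  ## empty region: flagged, not an error
  chart <- make_chart(ap_length = 40, dv_circumference = 40, dx = 4,
                      dy = 4, germband_halfwidth = 20, ap_margin = 0)
  none <- matrix(FALSE, chart$nx, chart$ny)
  d0 <- angular_distribution(seg1, region_mask = none, chart = chart)
  expect_equal(d0$n, 0L)
  expect_true(is.na(d0$mean))
})

test_that("rotation shifts and widens the simulated distribution", {
  d0 <- simulate_angular_distribution(0, 5, n = 2000, seed = 12)
  d3 <- simulate_angular_distribution(3, 5, n = 2000, seed = 12)
  expect_gt(d3$mean, 10)
  expect_gt(d3$sd, d0$sd)
})

test_that("nematic order parameter behaves at its limits", {
  chart <- make_chart(ap_length = 40, dv_circumference = 40, dx = 4,
                      dy = 4, germband_halfwidth = 20, ap_margin = 0)
  par <- data.frame(x_um = c(18, 20, 22), y_um = 20, angle_deg = -30,
                    length_um = 7, intensity = 2)
  q <- myosin_anisotropy_magnitude(par, chart, radius_um = 15)
  expect_equal(max(q), 1, tolerance = 1e-12)
  ## isotropic ensemble: q ~ n^{-1/2}
  set.seed(33)
  qn <- vapply(c(100, 400), function(n) {
    iso <- data.frame(x_um = stats::runif(n, 18, 22),
                      y_um = stats::runif(n, 18, 22),
                      angle_deg = stats::runif(n, -90, 90),
                      length_um = 7, intensity = 1)
    myosin_anisotropy_magnitude(iso, chart, radius_um = 18)[5, 5]
  }, numeric(1))
  expect_lt(qn[2], 3 * qn[1])          # shrinking with n
  expect_lt(qn[1], 0.3)
})

test_that("reduced source selectivity lowers the order parameter", {
  ## wild-type-like vs eve-like source widths at matched n and rotation
  q_of <- function(sw, seed) {
    d <- simulate_angular_distribution(3, ifelse(sw > 20, 2.5, 5),
                                       source_width = sw, n = 1500,
                                       seed = seed)
    nm <- gbeorient:::nematic_mean(d$mids, d$counts)
    nm$R
  }
  qs <- vapply(1:3, function(s) c(q_of(15, s), q_of(30, s)), numeric(2))
  expect_true(all(qs[2, ] < qs[1, ]))
})
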