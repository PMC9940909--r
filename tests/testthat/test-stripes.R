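chart1 <- make_chart(dx = 1, dy = 1)
runt1 <- make_prg_pattern(chart1, stripe_spec())

test_that("smoothed gradients match analytic fields", {
  chart <- make_chart(ap_length = 100, dv_circumference = 100, dx = 1,
                      dy = 1, germband_halfwidth = 50, ap_margin = 0)
  ## linear AP ramp
  ramp <- outer(0.4 * chart$x, rep(1, chart$ny))
  g <- smoothed_gradient(ramp, chart, sigma_um = 3)
  interior <- 15:85
  expect_equal(max(abs(g$gx[interior, ] - 0.4)), 0, tolerance = 1e-8)
  expect_equal(max(abs(g$gy[interior, ])), 0, tolerance = 1e-8)
  ## constant field
  const <- matrix(2, chart$nx, chart$ny)
  g0 <- smoothed_gradient(const, chart, sigma_um = 3)
  expect_equal(max(abs(g0$gx)), 0)
  expect_equal(max(abs(g0$gy)), 0)
  expect_equal(max(gradient_magnitude(const, chart)), 0)
  ## oversized smoothing scale
  expect_error(smoothed_gradient(ramp, chart, sigma_um = 200), "extent")
})

test_that("gradients point toward the stripe center from both flanks", {
  chart <- make_chart(ap_length = 120, dv_circumference = 60, dx = 1,
                      dy = 1, germband_halfwidth = 30, ap_margin = 0)
  one <- make_prg_pattern(chart, stripe_spec(n_stripes = 1, period = 60,
                                             width = 8, ap_start = 60,
                                             dv_floor = 1))
  g <- smoothed_gradient(one, chart, sigma_um = 5)
  expect_gt(min(g$gx[35:50, ]), 0)    # left flank: increasing toward 60
  expect_lt(max(g$gx[70:85, ]), 0)    # right flank: decreasing
})

test_that("the seven-stripe pattern yields 14 gradient bands", {
  expect_equal(count_gradient_bands(runt1, chart1), 14L)
})

test_that("gradient bands weaken toward the dorsal pole", {
  gm <- gradient_magnitude(runt1, chart1)
  ventral_band <- mean(gm[, chart1$y < 40])
  lateral_band <- mean(gm[, chart1$y > 110 & chart1$y < 150])
  expect_gt(ventral_band, lateral_band)
})

test_that("stripe segmentation and inter-stripe lines are consistent", {
  ss <- segment_stripes(runt1, chart1)
  expect_equal(ss$k, 7L)
  lines <- interstripe_lines(ss)
  expect_length(lines, 6L)
  ## lines are vertical at t = 0 (parallel to the DV axis, within 2 deg)
  for (l in lines) {
    fit <- stats::coef(stats::lm(x_um ~ y_um, data = l))
    expect_lt(abs(atan(fit[2]) * 180 / pi), 2)
  }
  ## symmetric two-stripe fixture: line at the exact midpoint
  chart <- make_chart(ap_length = 120, dv_circumference = 60, dx = 1,
                      dy = 1, germband_halfwidth = 30, ap_margin = 0)
  two <- make_prg_pattern(chart, stripe_spec(n_stripes = 2, period = 50,
                                             width = 8, ap_start = 35,
                                             dv_floor = 1))
  ss2 <- segment_stripes(two, chart)
  expect_equal(ss2$k, 2L)
  l2 <- interstripe_lines(ss2)[[1]]
  expect_equal(mean(l2$x_um), 60, tolerance = 1e-8)
  ## blank field: empty stripe set with a warning, no error
  expect_warning(ss0 <- segment_stripes(matrix(0, chart$nx, chart$ny),
                                        chart), "no stripes")
  expect_equal(ss0$k, 0L)
  expect_length(interstripe_lines(ss0), 0L)
})

test_that("stripe angle fields measure the nematic stripe direction", {
  ## vertical stripes: approximately parallel to the DV axis where the
  ## gradient weight is high (the DV intensity modulation contributes a
  ## small systematic tilt toward the dorsal pole)
  of <- stripe_angle_field(runt1, chart1)
  hi <- of$weight > 0.5 * max(of$weight)
  expect_lt(abs(stats::weighted.mean(of$angle[hi], of$weight[hi])), 1)
  expect_lt(stats::median(abs(of$angle[hi])), 3)
  ## pattern rotated by 20 degrees reads back 20 degrees
  c2 <- make_chart(ap_length = 200, dv_circumference = 500, dx = 2, dy = 2)
  lam <- 500 * sin(pi / 9) / 4      # keeps the tilted wave DV-periodic
  f <- outer(c2$x, c2$y, function(x, y)
    1 + cos(2 * pi * (x * cos(pi / 9) + y * sin(pi / 9)) / lam))
  of2 <- stripe_angle_field(f, c2, sigma_um = 5)
  hw <- of2$weight > 0.5 * max(of2$weight)
  hw[c(1:10, 91:100), ] <- FALSE    # AP edge effects
  ang <- stats::weighted.mean(of2$angle[hw], of2$weight[hw])
  expect_equal(ang, 20, tolerance = 0.5 / 20)
  ## constant field: zero weight everywhere
  of3 <- stripe_angle_field(matrix(1, chart1$nx, chart1$ny), chart1)
  expect_equal(max(of3$weight), 0)
})

test_that("nematic autocorrelation follows the double-angle formula", {
  d <- c(10, 10)
  mk <- function(angles, weights = 1) {
    n <- length(angles)
    list(angle = array(rep(angles, each = prod(d)), c(d, n)),
         weight = array(weights, c(d, n)),
         times = seq_len(n) - 1)
  }
  ## static field
  C <- nematic_autocorrelation(mk(c(17, 17, 17)))
  expect_true(all(C$C == 1))
  ## orthogonal nematic pair
  C2 <- nematic_autocorrelation(mk(c(30, 120)))
  expect_equal(C2$C[1, 2], 0)
  ## rotation at 1 deg/min: C = max(0, cos 2 dt)
  times <- seq(0, 80, by = 20)
  C3 <- nematic_autocorrelation(mk(times))
  for (a in seq_along(times)) for (b in seq_along(times))
    expect_equal(C3$C[a, b],
                 max(0, cos(2 * (times[a] - times[b]) * pi / 180)),
                 tolerance = 1e-8)
  ## nematic invariance: +180 on all angles changes nothing
  s <- mk(c(10, 40, 80))
  s2 <- s; s2$angle <- s$angle + 180
  expect_equal(nematic_autocorrelation(s)$C,
               nematic_autocorrelation(s2)$C)
  ## all-zero-weight frame is flagged
  s3 <- mk(c(0, 10))
  s3$weight[, , 2] <- 0
  expect_true(is.na(nematic_autocorrelation(s3)$C[1, 2]))
})

test_that("PRG regression recovers exact linear relations", {
  chart <- make_chart(ap_length = 120, dv_circumference = 100, dx = 2,
                      dy = 2, germband_halfwidth = 50, ap_margin = 10)
  spec <- stripe_spec(n_stripes = 2, period = 40, width = 8,
                      ap_start = 40)
  g_runt <- gradient_magnitude(make_prg_pattern(chart, spec), chart)
  myo <- 2 * g_runt
  fit <- prg_regression(myo, list(runt = g_runt), chart = chart)
  expect_equal(unname(fit$weights["runt"]), 2, tolerance = 1e-12)
  expect_equal(fit$r_squared, 1, tolerance = 1e-10)
  expect_equal(fit$fitted, 2 * g_runt)
})

test_that("regression residuals satisfy the normal equations", {
  chart <- make_chart(ap_length = 100, dv_circumference = 80, dx = 2,
                      dy = 2, germband_halfwidth = 40, ap_margin = 10)
  set.seed(5)
  X1 <- matrix(stats::runif(chart$nx * chart$ny), chart$nx)
  X2 <- matrix(stats::runif(chart$nx * chart$ny), chart$nx)
  y <- matrix(stats::rnorm(chart$nx * chart$ny), chart$nx)
  fit <- prg_regression(y, list(a = X1, b = X2), chart = chart)
  sel <- which(chart$germband_mask)
  for (X in list(X1, X2)) {
    rel <- abs(sum(X[sel] * fit$residual[sel])) /
      (sqrt(sum(X[sel]^2)) * sqrt(sum(y[sel]^2)))
    expect_lt(rel, 1e-8)
  }
})

test_that("orthogonal targets give zero weights and R^2", {
  chart <- make_chart(ap_length = 100, dv_circumference = 80, dx = 2,
                      dy = 2, germband_halfwidth = 40, ap_margin = 10)
  set.seed(6)
  X <- matrix(stats::runif(chart$nx * chart$ny), chart$nx)
  y0 <- matrix(stats::rnorm(chart$nx * chart$ny), chart$nx)
  ## project the regressor out of y over the mask: exact orthogonality
  sel <- which(chart$germband_mask)
  y <- y0
  y[sel] <- y0[sel] - X[sel] * sum(X[sel] * y0[sel]) / sum(X[sel]^2)
  fit <- prg_regression(y, list(x = X), chart = chart)
  expect_equal(unname(fit$weights["x"]), 0, tolerance = 1e-10)
  expect_equal(fit$r_squared, 0, tolerance = 1e-10)
})

test_that("collinear regressors are flagged and solved minimum-norm", {
  chart <- make_chart(ap_length = 100, dv_circumference = 80, dx = 2,
                      dy = 2, germband_halfwidth = 40, ap_margin = 10)
  set.seed(7)
  X <- matrix(stats::runif(chart$nx * chart$ny), chart$nx)
  y <- 3 * X
  fit <- prg_regression(y, list(a = X, b = X), chart = chart)
  expect_true(fit$rank_deficient)
  ## minimum-norm solution splits the weight equally
  expect_equal(unname(fit$weights), c(1.5, 1.5), tolerance = 1e-6)
  expect_equal(fit$r_squared, 1, tolerance = 1e-8)
})

test_that("DV profiles quantify the myosin recruitment zone", {
  ## constant field: flat profile at 1
  const <- matrix(4, chart1$nx, chart1$ny)
  p <- dv_profile(const, chart1)
  expect_true(all(abs(p$intensity - 1) < 1e-12))
  ## synthetic myosin decays below the 10% floor near 175 um
  myo <- make_myosin_pattern(chart1)
  pm <- dv_profile(myo, chart1)
  drop <- pm$dv_um[which(pm$intensity < 0.1)[1]]
  expect_equal(drop, 175, tolerance = 10 / 175)
  ## Fat2-like geometry: Runt persists where myosin has ended
  fat2 <- make_chart(ap_length = 360, dv_circumference = 650)
  runt_f <- make_prg_pattern(fat2, stripe_spec(period = 34, ap_start = 60))
  myo_f <- make_myosin_pattern(fat2)
  pr <- dv_profile(runt_f, fat2)
  pmf <- dv_profile(myo_f, fat2)
  support <- function(p) max(p$dv_um[p$intensity >= 0.1])
  expect_gt(support(pr), support(pmf) + 50)
})
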