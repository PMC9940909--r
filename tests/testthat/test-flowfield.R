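## analytic velocity fields on a small chart
chartF <- make_chart(ap_length = 100, dv_circumference = 100, dx = 2,
                     dy = 2, germband_halfwidth = 50, ap_margin = 0)

vfield <- function(fun, times = c(0, 1)) {
  nx <- chartF$nx; ny <- chartF$ny
  vx <- array(0, c(nx, ny, length(times)))
  vy <- array(0, c(nx, ny, length(times)))
  for (k in seq_along(times)) {
    for (j in seq_len(ny)) {
      v <- fun(chartF$x, chartF$y[j])
      vx[, j, k] <- v[[1]]; vy[, j, k] <- v[[2]]
    }
  }
  structure(list(vx = vx, vy = vy, times = times, chart = chartF),
            class = "velocity_field")
}

test_that("vorticity matches analytic curls", {
  ## uniform translation: zero curl
  u <- vfield(function(x, y) list(rep(2, length(x)), rep(-1, length(x))))
  expect_equal(max(abs(vorticity(u)$data)), 0)
  ## rigid rotation v = Omega * (-(y - yc), x - xc): curl = 2 Omega
  Om <- 0.05
  r <- vfield(function(x, y) list(-Om * (y - 50), Om * (x - 50)))
  om <- vorticity(r)$data[, , 1]
  interior <- 2:(chartF$nx - 1)
  ## periodic wrap in y corrupts edge rows for a non-periodic test field
  expect_equal(mean(om[interior, 10:40]), 2 * Om, tolerance = 1e-10)
  ## pure shear v = (k y, 0): curl = -k
  sh <- vfield(function(x, y) list(0.3 * y, rep(0, length(x))))
  expect_equal(stats::median(vorticity(sh)$data[, 10:40, 1]), -0.3,
               tolerance = 1e-10)
})

test_that("vorticity is linear in the field", {
  set.seed(4)
  f1 <- vfield(function(x, y) list(sin(x / 9) * cos(y / 11), cos(x / 7)))
  f2 <- vfield(function(x, y) list(cos(x / 13), sin(y / 8) * sin(x / 10)))
  comb <- f1
  comb$vx <- 2 * f1$vx - 3 * f2$vx
  comb$vy <- 2 * f1$vy - 3 * f2$vy
  expect_equal(vorticity(comb)$data,
               2 * vorticity(f1)$data - 3 * vorticity(f2)$data)
})

test_that("rotation rate is half the curl in degrees per minute", {
  Om <- 0.05
  r <- vfield(function(x, y) list(-Om * (y - 50), Om * (x - 50)))
  rr <- rotation_rate(r)$data[, , 1]
  expect_equal(mean(rr[2:(chartF$nx - 1), 10:40]), Om * 180 / pi,
               tolerance = 1e-10)
  z <- vfield(function(x, y) list(rep(0, length(x)), rep(0, length(x))))
  expect_equal(max(abs(rotation_rate(z)$data)), 0)
})

test_that("advection integrates trajectories accurately", {
  ## zero flow: identity
  z <- vfield(function(x, y) list(rep(0, length(x)), rep(0, length(x))),
              times = c(0, 10))
  pts <- cbind(c(20, 50, 80), c(10, 50, 90))
  expect_equal(unclass(advect_points(pts, z, 0, 10))[, ],
               cbind(x = pts[, 1], y = pts[, 2]))
  ## uniform flow: rigid translation
  u <- vfield(function(x, y) list(rep(2, length(x)), rep(0, length(x))),
              times = c(0, 10))
  out <- advect_points(cbind(30, 50), u, 0, 10)
  expect_equal(unname(out[1, "x"]), 50)
  ## uniform flow preserves polyline arc length
  pl <- cbind(c(20, 25, 30), c(40, 50, 60))
  apl <- advect_polyline(pl, u, 0, 10)
  expect_equal(nrow(apl), 3L)
  arc <- function(p) sum(sqrt(diff(p[, 1])^2 + diff(p[, 2])^2))
  expect_equal(arc(apl), arc(pl))
  ## rigid rotation: points rotate by Omega * dt about the center
  Om <- 0.02
  r <- vfield(function(x, y) list(-Om * (y - 50), Om * (x - 50)),
              times = c(0, 10))
  p0 <- cbind(60, 50)
  out <- advect_points(p0, r, 0, 10, dt = 0.25)
  phi <- Om * 10
  expected <- c(50 + 10 * cos(phi), 50 + 10 * sin(phi))
  err_rad <- sqrt(sum((out[1, ] - expected)^2)) / 10
  expect_lt(err_rad, 1e-3)
})

test_that("advection is reversible on smooth flows", {
  chart <- make_chart(dx = 5, dy = 5)
  vf <- make_flow_field(chart, flow_spec(chart), times = 0:30)
  set.seed(8)
  pts <- cbind(stats::runif(40, 60, 390), stats::runif(40, 0, 500))
  fwd <- advect_points(pts, vf, 10, 25)
  back <- advect_points(fwd, vf, 25, 10)
  expect_lt(max(abs(back[, 1] - pts[, 1])), 0.1)
  dy_wrap <- abs(((back[, 2] - pts[, 2] + 250) %% 500) - 250)
  expect_lt(max(dy_wrap), 0.1)
})

test_that("advection rejects intervals outside coverage", {
  z <- vfield(function(x, y) list(rep(0, length(x)), rep(0, length(x))),
              times = c(0, 10))
  expect_error(advect_points(cbind(10, 10), z, 0, 20), "coverage")
})

test_that("direction autocorrelation has the stated structure", {
  ## time-independent field: all entries 1
  u <- vfield(function(x, y) list(rep(2, length(x)), rep(1, length(x))),
              times = c(0, 5, 10))
  C <- direction_autocorrelation(u, speed_floor = 0.1)
  expect_true(all(abs(C$C - 1) < 1e-12))
  ## everywhere-orthogonal frames: 0
  o <- u
  o$vx[, , 2] <- -1; o$vy[, , 2] <- 2
  C2 <- direction_autocorrelation(o)
  expect_equal(C2$C[1, 2], 0)
  ## uniformly rotating direction: C = max(0, cos dt) for 1 deg/min
  times <- seq(0, 150, by = 30)
  rotf <- u
  rotf$vx <- array(0, c(chartF$nx, chartF$ny, length(times)))
  rotf$vy <- array(0, c(chartF$nx, chartF$ny, length(times)))
  rotf$times <- times
  for (k in seq_along(times)) {
    rotf$vx[, , k] <- sin(times[k] * pi / 180)
    rotf$vy[, , k] <- cos(times[k] * pi / 180)
  }
  C3 <- direction_autocorrelation(rotf)
  for (a in seq_along(times)) for (b in seq_along(times)) {
    expect_equal(C3$C[a, b],
                 max(0, cos((times[a] - times[b]) * pi / 180)),
                 tolerance = 1e-8)
  }
  ## matrix properties
  expect_equal(C3$C, t(C3$C))
  expect_true(all(diag(C3$C) == 1))
  expect_true(all(C3$C >= 0 & C3$C <= 1))
  ## all-masked frame yields flagged NA, not 1
  dead <- u
  dead$vx[, , 2] <- 0.01; dead$vy[, , 2] <- 0.01
  dead$vx[, , 2] <- 0; dead$vy[, , 2] <- 0
  C4 <- direction_autocorrelation(dead)
  expect_true(is.na(C4$C[1, 2]))
})

test_that("spatial averaging respects the mask", {
  arr <- array(3, c(chartF$nx, chartF$ny, 2))
  fs <- list(data = arr, times = c(0, 1), chart = chartF)
  mask <- matrix(TRUE, chartF$nx, chartF$ny)
  expect_equal(spatial_average(fs, mask)$value, c(3, 3))
  half <- arr
  half[1:(chartF$nx / 2), , ] <- 0
  expect_equal(spatial_average(list(data = half, times = c(0, 1),
                                    chart = chartF), mask)$value,
               c(1.5, 1.5))
  expect_error(spatial_average(fs, matrix(TRUE, 2, 2)), "shape|match")
  expect_error(spatial_average(fs, mask & FALSE), "no pixels")
})

test_that("germband rotation-rate average peaks inside the plateau", {
  chart <- make_chart(dx = 10, dy = 10)
  vf <- make_flow_field(chart, flow_spec(chart), times = 0:35)
  rr <- rotation_rate(vf)
  rr_abs <- rr; rr_abs$data <- abs(rr$data)
  ts <- spatial_average(rr_abs, chart$germband_mask)
  pk <- ts$time[which.max(ts$value)]
  expect_gte(pk, 20)
  expect_lte(pk, 25)
})
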