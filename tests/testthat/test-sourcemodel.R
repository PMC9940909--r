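test_that("relaxation ODE matches closed forms to 1e-6 degrees", {
  tau <- 5
  tt <- seq(0, 40, by = 0.5)
  ## constant rotation: theta = rho tau (1 - exp(-t/tau))
  d1 <- integrate_mean_deflection(function(t) rep(3, length(t)), tau,
                                  times = tt)
  expect_lt(max(abs(d1$deflection_deg - 15 * (1 - exp(-tt / 5)))), 1e-6)
  expect_equal(tail(d1$deflection_deg, 1), 15, tolerance = 1e-3)
  ## zero rotation stays zero
  d0 <- integrate_mean_deflection(function(t) rep(0, length(t)), tau,
                                  times = tt)
  expect_equal(max(abs(d0$deflection_deg)), 0)
  ## linear ramp rho = a t: theta = a tau (t - tau + tau exp(-t/tau))
  a <- 0.2
  d2 <- integrate_mean_deflection(function(t) a * t, tau, times = tt)
  exact2 <- a * tau * (tt - tau + tau * exp(-tt / tau))
  expect_lt(max(abs(d2$deflection_deg - exact2)), 1e-6)
  ## exponential rho = exp(-t/b)
  b <- 8
  d3 <- integrate_mean_deflection(function(t) exp(-t / b), tau,
                                  times = tt)
  exact3 <- (exp(-tt / b) - exp(-tt / tau)) / (1 / tau - 1 / b)
  expect_lt(max(abs(d3$deflection_deg - exact3)), 1e-6)
  expect_error(integrate_mean_deflection(function(t) t, tau = -1,
                                         times = tt), "tau")
})

test_that("output lags a slowly varying input by tau", {
  ## broad Gaussian rotation pulse (much slower than tau)
  tau <- 4
  tt <- seq(0, 200, by = 1)
  rho <- data.frame(time = tt, value = 3 * exp(-(tt - 80)^2 / (2 * 35^2)))
  d <- integrate_mean_deflection(rho, tau)
  lag <- deflection_lag(rho, d, lag_max = 15)
  expect_equal(lag, tau, tolerance = 1 / tau)
})

test_that("deflection decays exponentially with rate 1/tau after
           rotation stops", {
  tau <- 5
  tt <- seq(0, 80, by = 0.5)
  rho <- function(t) ifelse(t < 30, 3, 0)
  d <- integrate_mean_deflection(rho, tau, times = tt)
  dec <- d[d$time >= 31, ]
  fit <- stats::lm(log(deflection_deg) ~ time, data = dec)
  tau_fit <- -1 / stats::coef(fit)[2]
  expect_equal(unname(tau_fit), tau, tolerance = 0.05)
})

test_that("steady-state ensemble deflection equals rho tau across the
           tested grid", {
  for (rho in c(1, 3)) for (tau in c(2, 5, 8)) {
    d <- simulate_angular_distribution(rho, tau, source_width = 15,
                                       n = 5000, seed = rho * 10 + tau)
    oracle <- exp_age_mean(rho, tau, 15)
    expect_equal(d$mean, oracle, tolerance = 0.8 / max(abs(oracle), 1))
    ## far from the nematic wrap the oracle is rho * tau itself (the
    ## nematic mean of the skewed distribution adds a small offset)
    if (rho * tau <= 8)
      expect_lt(abs(oracle - rho * tau), 0.05 + 0.03 * rho * tau)
  }
})

test_that("predicted deflection fields reduce to the scalar law", {
  chart <- make_chart(ap_length = 60, dv_circumference = 60, dx = 10,
                      dy = 10, germband_halfwidth = 30, ap_margin = 0)
  times <- 0:20
  ## spatially uniform rho(t): every pixel equals the scalar solution
  env <- pmin(times / 10, 1)
  rr <- list(data = array(rep(3 * env, each = chart$nx * chart$ny),
                          c(chart$nx, chart$ny, length(times))),
             times = times, chart = chart, units = "deg/min")
  class(rr) <- "field_series"
  pred_e <- predict_deflection_field(rr, tau = 5, mode = "eulerian")
  scal <- integrate_mean_deflection(data.frame(time = times,
                                               value = 3 * env), tau = 5)
  for (k in c(5, 11, 21))
    expect_equal(unique(round(as.numeric(pred_e$data[, , k]), 8)),
                 round(scal$deflection_deg[k], 8))
  ## zero rotation: zero field, both modes
  rr0 <- rr; rr0$data[] <- 0
  expect_equal(max(abs(predict_deflection_field(rr0, 5)$data)), 0)
  zero_flow <- structure(list(
    vx = array(0, dim(rr$data)), vy = array(0, dim(rr$data)),
    times = times, chart = chart), class = "velocity_field")
  pred_l <- predict_deflection_field(rr, tau = 5, mode = "lagrangian",
                                     flow = zero_flow)
  for (k in c(5, 21))
    expect_equal(max(abs(pred_l$data[, , k] - pred_e$data[, , k])), 0,
                 tolerance = 0.05)
  expect_error(predict_deflection_field(rr, 5, mode = "lagrangian"),
               "velocity")
})

test_that("predicted deflection peaks in the posterior vortex domain", {
  chart <- make_chart(dx = 10, dy = 10)
  vf <- make_flow_field(chart, flow_spec(chart), times = 0:25)
  rot <- rotation_rate(vf)
  pred <- predict_deflection_field(rot, tau = 5)
  pk <- which(pred$data[, , 26] == max(pred$data[, , 26]), arr.ind = TRUE)
  px <- chart$x[pk[1]]; py <- chart$y[pk[2]]
  ## posterior vortex center at (0.75 L, 0.22 C)
  expect_lt(sqrt((px - 0.75 * 450)^2 + (py - 110)^2), 60)
})

## shared wild-type ensemble for the adjusted-angle and fit tests
chartW <- make_chart(dx = 5, dy = 5)
vfW <- make_flow_field(chartW, flow_spec(chartW), times = 0:35)
rotW <- rotation_rate(vfW)
simW <- simulate_junction_ensemble(chartW, vfW, model_params(tau = 5),
                                   n_junctions = 2000, t_span = c(0, 35),
                                   seed = 1)
obsW <- orientation_series(lapply(0:35, function(t)
  anisotropy_field(gbeorient:::sim_frame(simW, t), chartW, 20)), 0:35)

test_that("rotation-adjusted angle is small with the true lifetime and
           large with a wrong one", {
  ## observed = predicted gives exactly zero
  fake <- obsW
  pred5 <- predict_deflection_field(rotW, 5)
  fake$angle <- array(angle_to_dv(pred5$data), dim(pred5$data))
  adj0 <- rotation_adjusted_angle(fake, pred5)
  expect_equal(max(abs(adj0$angle)), 0, tolerance = 1e-9)
  ## posterior-vortex region, signed mean
  reg <- outer(chartW$x > 270 & chartW$x < 390,
               chartW$y > 60 & chartW$y < 160, `&`) & chartW$germband_mask
  rsel <- which(reg)
  regional_mean <- function(adj, k)
    stats::weighted.mean(adj$angle[, , k][rsel], adj$weight[, , k][rsel])
  adj5 <- rotation_adjusted_angle(obsW, pred5)
  m5 <- vapply(11:36, function(k) regional_mean(adj5, k), numeric(1))
  expect_lt(max(abs(m5)), 2)
  adj1 <- rotation_adjusted_angle(obsW, predict_deflection_field(rotW, 1))
  m1 <- vapply(21:31, function(k) regional_mean(adj1, k), numeric(1))
  expect_gt(max(abs(m1)), 5)
  ## grid mismatch is rejected
  small <- predict_deflection_field(
    rotation_rate(make_flow_field(make_chart(dx = 10, dy = 10),
                                  flow_spec(make_chart(dx = 10, dy = 10)),
                                  0:35)), 5)
  expect_error(rotation_adjusted_angle(obsW, small), "match")
})

test_that("the lifetime fit recovers the generating tau", {
  fit <- fit_tau(obsW, rotW, tau_grid = seq(1, 12, 0.5),
                 segments = simW$segments, source_width = 15)
  expect_true(fit$identifiable)
  ## single-ensemble scale: one 2000-junction embryo (the five-embryo
  ## pooled fit in the acceptance tests holds the tighter band)
  expect_equal(fit$tau_hat, 5, tolerance = 1.5 / 5)
  ## objective curve is returned for diagnostics
  expect_equal(nrow(fit$objective_curve), 23L)
})

test_that("a flat rotation history makes tau unidentifiable", {
  rr0 <- rotW; rr0$data[] <- 0
  expect_warning(f <- fit_tau(obsW, rr0), "unidentifiable")
  expect_false(f$identifiable)
  expect_true(is.na(f$tau_hat))
})

test_that("deflection and fit are invariant to source magnitude", {
  sim2 <- simulate_junction_ensemble(chartW, vfW,
                                     model_params(tau = 5,
                                                  source_amplitude = 2.7),
                                     n_junctions = 2000,
                                     t_span = c(0, 35), seed = 1)
  obs2 <- orientation_series(lapply(c(15, 25), function(t)
    anisotropy_field(gbeorient:::sim_frame(sim2, t), chartW, 20)),
    c(15, 25))
  obs_ref <- orientation_series(lapply(c(15, 25), function(t)
    anisotropy_field(gbeorient:::sim_frame(simW, t), chartW, 20)),
    c(15, 25))
  expect_equal(obs2$angle, obs_ref$angle, tolerance = 1e-8)
  expect_equal(obs2$weight, 2.7 * obs_ref$weight, tolerance = 1e-8)
})

test_that("angle-independent lifetime yields a uniform distribution
           under any rotation", {
  for (rho in c(0, 3)) {
    d <- lifetime_modulation_model(rho, function(th) rep(4, length(th)),
                                   n = 3000, duration = 25,
                                   seed = 40 + rho)
    frac <- d$counts / sum(d$counts)
    expect_lt(max(abs(frac - 1 / length(frac))), 0.35 / length(frac))
  }
})

test_that("DV-peaked lifetime modulation deviates from the static-source
           prediction", {
  prof <- function(th) 0.5 + 4.5 * exp(-th^2 / (2 * 25^2))
  d <- lifetime_modulation_model(3, prof, n = 3000, duration = 30,
                                 seed = 44)
  static <- simulate_angular_distribution(3, 5, source_width = 15,
                                          n = 3000, seed = 44)
  ## the two mechanisms predict measurably different mean deflections
  expect_gt(abs(d$mean - static$mean), 2)
})
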