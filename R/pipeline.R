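## End-to-end orchestration: synthetic embryo -> stripe/flow/junction
## analysis -> static-source model fit -> kinetics, for the wild-type and
## mutant-like parameterizations.

#' Build a pipeline run configuration
#'
#' Genotype presets encode only the documented differences from wild type:
#' \code{twist} halves the flow amplitude; \code{eve} reduces the
#' effective lifetime to 2.5 min, reduces flow and source amplitude, and
#' uses a later, steeper flow onset; \code{fat2} shortens the AP axis and
#' extends the DV circumference by 30 percent with reduced flow. All other
#' knobs inherit the wild-type defaults.
#'
#' @param genotype preset name.
#' @param seed integer seed used by every stochastic stage.
#' @param n_junctions ensemble size.
#' @param grid_um analysis grid spacing (micrometers).
#' @param times analysis time stamps (min; t = 0 is ventral-furrow
#'   initiation).
#' @param tau_grid candidate lifetimes for the tau fit (min).
#' @param ... named overrides of individual config entries.
#' @return object of class \code{run_config}.
#' @export
run_config <- function(genotype = c("wt", "twist", "eve", "fat2",
                                    "custom"),
                       seed = 1, n_junctions = 1000, grid_um = 5,
                       times = 0:35, tau_grid = seq(0.5, 20, by = 0.5),
                       ...) {
  genotype <- match.arg(genotype)
  cfg <- list(
    genotype = genotype, seed = seed, n_junctions = n_junctions,
    times = times,
    chart = list(ap_length = 450, dv_circumference = 500,
                 dx = grid_um, dy = grid_um),
    flow = list(amplitude = 1,
                envelope = cbind(time = c(0, 10, 20, 25, 35),
                                 value = c(0, 0, 1, 1, 0)),
                rot_peak_posterior = 5, rot_peak_anterior = 1.5),
    stripes = list(n_stripes = 7, period = 40, width = 8,
                   ap_start = 100, dv_floor = 0.1,
                   phases = c(runt = 0, eve = 13, ftz = 27)),
    model = list(tau = 5, source_width = 15, source_amplitude = 1,
                 ell_m = 76),
    detect = list(radius_um = 20),
    fit = list(tau_grid = tau_grid, window = c(10, 35)),
    frap = list(mobile_fraction = 0.5, tau_fast = 8, tau_slow = 60,
                fast_share = 0.6, noise_sigma = 0.02))
  if (genotype == "twist") {
    cfg$flow$amplitude <- 0.5
  } else if (genotype == "eve") {
    cfg$model$tau <- 2.5
    cfg$model$source_amplitude <- 0.6
    cfg$model$source_width <- 30
    cfg$flow$amplitude <- 0.5
    cfg$flow$envelope <- cbind(time = c(0, 10, 13, 25, 35),
                               value = c(0, 0, 1, 1, 0))
  } else if (genotype == "fat2") {
    cfg$chart$ap_length <- 360
    cfg$chart$dv_circumference <- 650
    cfg$flow$amplitude <- 0.4
    ## the intact AP patterning system compresses onto the shorter egg
    cfg$stripes$period <- 34
    cfg$stripes$ap_start <- 60
  }
  dots <- list(...)
  for (nm in names(dots)) {
    cfg[[nm]] <- if (is.list(cfg[[nm]]) && is.list(dots[[nm]]) &&
                     !is.matrix(dots[[nm]]))
      utils::modifyList(cfg[[nm]], dots[[nm]]) else dots[[nm]]
  }
  structure(cfg, class = "run_config")
}

#' @exportS3Method print run_config
print.run_config <- function(x, ...) {
  cat(sprintf(paste0("run_config: genotype %s, seed %d, %d junctions, ",
                     "t = %g..%g min\n"),
              x$genotype, x$seed, x$n_junctions, min(x$times),
              max(x$times)))
  invisible(x)
}

## run one named stage, tagging errors with the stage name
run_stage <- function(name, expr) {
  tryCatch(expr, error = function(e)
    stop(sprintf("[stage %s] %s", name, conditionMessage(e)),
         call. = FALSE))
}

#' Run the full analysis pipeline on a synthetic embryo
#'
#' Executes generation, stripe/flow/junction analysis, the static-source
#' model fit, and kinetics, and returns a machine-readable report. All
#' randomness derives from \code{config$seed}; the same config yields an
#' identical report.
#'
#' @param config a \code{run_config}.
#' @param out_dir optional directory; when given, junction tables (CSV),
#'   correlation matrices (CSV), key fields (TIFF), the FRAP trace (CSV)
#'   and the report (JSON) are written there.
#' @return object of class \code{run_report}.
#' @export
run_pipeline <- function(config, out_dir = NULL) {
  stopifnot(inherits(config, "run_config"))
  times <- config$times
  t0 <- times[1L]

  chart <- run_stage("chart", do.call(make_chart, config$chart))
  fs <- run_stage("flow", flow_spec(
    chart, amplitude = config$flow$amplitude,
    envelope = config$flow$envelope,
    rot_peak_posterior = config$flow$rot_peak_posterior,
    rot_peak_anterior = config$flow$rot_peak_anterior))
  vf <- run_stage("flow", make_flow_field(chart, fs, times))
  rot <- run_stage("flow", rotation_rate(vf))

  sspec <- run_stage("stripes", stripe_spec(
    n_stripes = config$stripes$n_stripes, period = config$stripes$period,
    width = config$stripes$width, ap_start = config$stripes$ap_start,
    dv_floor = config$stripes$dv_floor))
  prgs <- run_stage("stripes",
                    make_prg_set(chart, sspec, config$stripes$phases))
  runt0 <- prgs[[1L]]

  ## advect the Runt pattern: semi-Lagrangian lookup along back-trajectories
  nodes <- as.matrix(expand.grid(x = chart$x, y = chart$y))
  runt_fields <- run_stage("advection", lapply(times, function(t) {
    if (t <= t0) return(runt0)
    b <- advect_points(nodes, vf, t, t0, dt = 0.5)
    matrix(interp_field(runt0, chart, b[, 1L], b[, 2L]),
           chart$nx, chart$ny)
  }))
  runt_orient <- run_stage("stripes", orientation_series(
    lapply(runt_fields, stripe_angle_field, chart = chart), times))

  params <- run_stage("model", model_params(
    tau = config$model$tau, source_width = config$model$source_width,
    source_amplitude = config$model$source_amplitude,
    ell_m = config$model$ell_m))
  sim <- run_stage("junctions", simulate_junction_ensemble(
    chart, vf, params, n_junctions = config$n_junctions,
    t_span = range(times), seed = config$seed, record_dt = 1))
  myo_orient <- run_stage("junctions", orientation_series(
    lapply(times, function(t)
      anisotropy_field(sim_frame(sim, t), chart,
                       radius_um = config$detect$radius_um)),
    times))

  flow_corr <- run_stage("autocorrelation",
                         direction_autocorrelation(vf))
  runt_corr <- run_stage("autocorrelation", nematic_autocorrelation(
    runt_orient, mask = chart$germband_mask))
  myo_corr <- run_stage("autocorrelation", nematic_autocorrelation(
    myo_orient, mask = chart$germband_mask))

  fit <- run_stage("tau_fit", fit_tau(
    myo_orient, rot, tau_grid = config$fit$tau_grid,
    window = config$fit$window, segments = sim$segments,
    radius_um = config$detect$radius_um,
    source_width = config$model$source_width))
  pred <- run_stage("tau_fit", predict_deflection_field(
    rot, if (is.finite(fit$tau_hat)) fit$tau_hat else config$model$tau))
  adj <- run_stage("tau_fit", rotation_adjusted_angle(myo_orient, pred))

  ## spatial averages are taken over one lateral half (mirror symmetry
  ## across the ventral midline makes whole-germband signed means cancel)
  upper <- outer(rep(TRUE, chart$nx),
                 chart$y > 0 & chart$y < chart$dv_circumference / 2)
  gb <- which(chart$germband_mask & upper)
  mean_signed <- function(series, k)
    stats::weighted.mean(series$angle[, , k][gb],
                         series$weight[, , k][gb] + 1e-12)
  summary_ts <- data.frame(
    time = times,
    rotation = vapply(seq_along(times), function(k)
      mean(rot$data[, , k][gb]), numeric(1)),
    myosin_angle = vapply(seq_along(times), function(k)
      mean_signed(myo_orient, k), numeric(1)),
    adjusted_angle = vapply(seq_along(times), function(k)
      mean_signed(adj, k), numeric(1)))

  ## PRG gradient regression at flow onset against the smoothed myosin map
  myo_map <- run_stage("regression", {
    seg10 <- sim_frame(sim, min(max(times), 10))
    acc <- matrix(0, chart$nx, chart$ny)
    ii <- pmin(pmax(round(seg10$x_um / chart$dx) + 1L, 1L), chart$nx)
    jj <- (round(seg10$y_um / chart$dy) %% chart$ny) + 1L
    for (r in seq_len(nrow(seg10)))
      acc[ii[r], jj[r]] <- acc[ii[r], jj[r]] + seg10$intensity[r]
    smooth_field(acc, chart, 10)
  })
  regression <- run_stage("regression", prg_regression(
    myo_map, lapply(prgs, gradient_magnitude, chart = chart),
    mask = chart$germband_mask))

  myo_profile <- run_stage("profiles", dv_profile(myo_map, chart))
  runt_profile <- run_stage("profiles", dv_profile(runt0, chart))
  support <- function(p, floor = 0.1) {
    ok <- which(p$intensity >= floor)
    if (length(ok) == 0L) 0 else max(p$dv_um[ok])
  }

  frap_trace <- run_stage("kinetics", make_frap_trace(
    mobile_fraction = config$frap$mobile_fraction,
    tau_fast = config$frap$tau_fast, tau_slow = config$frap$tau_slow,
    fast_share = config$frap$fast_share,
    noise_sigma = config$frap$noise_sigma, seed = config$seed))
  frap <- run_stage("kinetics", fit_frap(frap_trace))
  lifetimes <- run_stage("kinetics",
                         reconcile_lifetimes(frap, fit$tau_hat))

  stripes0 <- run_stage("stripes", segment_stripes(runt0, chart))
  stripe_ts <- run_stage("stripe_regions", stripe_region_timeseries(
    stripes0, runt_orient, myo_orient, adj, sim, vf, times))

  nt <- length(times)
  report <- structure(list(
    config = unclass(config),
    tau_hat_min = fit$tau_hat,
    tau_objective = fit$objective_curve,
    tau_identifiable = fit$identifiable,
    autocorrelation = list(
      ## flow direction is undefined while the envelope is zero; compare
      ## the first and last frames with measurable flow
      flow_first_last = {
        ok <- which(!is.na(diag(flow_corr$C)))
        if (length(ok) >= 2L) flow_corr$C[ok[1L], ok[length(ok)]]
        else NA_real_
      },
      runt_first_last = runt_corr$C[1L, nt],
      myosin_first_last = myo_corr$C[1L, nt]),
    regression_weights = as.list(regression$weights),
    regression_r_squared = regression$r_squared,
    summary_timeseries = summary_ts,
    myosin_dv_support_um = support(myo_profile),
    runt_dv_support_um = support(runt_profile),
    frap = list(mobile_fraction = frap$mobile_fraction,
                tau_fast_s = frap$tau_fast, tau_slow_s = frap$tau_slow,
                converged = frap$converged),
    lifetime_ordering = lifetimes$consistent_ordering,
    stripe_timeseries = stripe_ts,
    n_stripes = stripes0$k,
    seed = config$seed), class = "run_report")

  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    write_junction_csv(sim$segments, file.path(out_dir, "junctions.csv"))
    write_correlation_csv(flow_corr,
                          file.path(out_dir, "flow_autocorr.csv"))
    write_correlation_csv(runt_corr,
                          file.path(out_dir, "runt_autocorr.csv"))
    write_correlation_csv(myo_corr,
                          file.path(out_dir, "myosin_autocorr.csv"))
    write_field_tiff(rot, file.path(out_dir, "rotation_rate.tif"))
    write_field_tiff(myo_map, file.path(out_dir, "myosin_map.tif"))
    write_frap_csv(frap_trace, file.path(out_dir, "frap_trace.csv"))
    utils::write.csv(summary_ts,
                     file.path(out_dir, "summary_timeseries.csv"),
                     row.names = FALSE)
    utils::write.csv(stripe_ts,
                     file.path(out_dir, "stripe_timeseries.csv"),
                     row.names = FALSE)
    write_report_json(report[setdiff(names(report),
                                     c("summary_timeseries",
                                       "stripe_timeseries",
                                       "tau_objective"))],
                      file.path(out_dir, "report.json"))
  }
  attr(report, "intermediates") <-
    list(chart = chart, flow = vf, rotation = rot, sim = sim,
         myosin_orientation = myo_orient, runt_orientation = runt_orient,
         adjusted = adj, prediction = pred, stripes = stripes0,
         myosin_map = myo_map, prgs = prgs,
         correlations = list(flow = flow_corr, runt = runt_corr,
                             myosin = myo_corr))
  report
}

#' @exportS3Method print run_report
print.run_report <- function(x, ...) {
  cat(sprintf("run_report (%s, seed %d)\n", x$config$genotype, x$seed))
  cat(sprintf("  tau_hat = %.2f min (identifiable: %s)\n", x$tau_hat_min,
              x$tau_identifiable))
  cat(sprintf(paste0("  autocorrelation C(t_first, t_last): flow %.2f, ",
                     "Runt %.2f, myosin %.2f\n"),
              x$autocorrelation$flow_first_last,
              x$autocorrelation$runt_first_last,
              x$autocorrelation$myosin_first_last))
  cat(sprintf("  regression R^2 = %.3f; stripes found: %d\n",
              x$regression_r_squared, x$n_stripes))
  cat(sprintf("  DV support: myosin %g um, Runt %g um\n",
              x$myosin_dv_support_um, x$runt_dv_support_um))
  invisible(x)
}

#' Per-stripe time series of orientation angles
#'
#' Stripe regions are segmented at the first time point and advected
#' forward with the flow; per region and minute the weighted nematic means
#' of the Runt stripe angle, the myosin angle, the myosin-minus-Runt
#' angle, and the rotation-rate-adjusted myosin angle are reported.
#' Regions that advect off the chart yield NA (flagged) entries.
#'
#' @param stripes0 a \code{stripe_set} segmented at the first time point.
#' @param runt_orient,myo_orient,adjusted orientation series on the same
#'   grid and times (Runt stripe angle, myosin angle, adjusted angle).
#' @param sim the \code{junction_sim} (for per-region myosin from raw
#'   segments).
#' @param flow the \code{velocity_field}.
#' @param times analysis times.
#' @return long data.frame (upper lateral half): stripe, time,
#'   runt_angle, myosin_angle, myosin_vs_runt, adjusted_angle, n_px.
#' @export
stripe_region_timeseries <- function(stripes0, runt_orient, myo_orient,
                                     adjusted, sim, flow, times) {
  chart <- stripes0$chart
  nodes <- as.matrix(expand.grid(x = chart$x, y = chart$y))
  ## restrict to one lateral half: the two halves mirror each other, so
  ## signed angles averaged across both cancel identically
  upper <- outer(rep(TRUE, chart$nx),
                 chart$y > 0 & chart$y < chart$dv_circumference / 2)
  t0 <- times[1L]
  out <- list()
  for (k in seq_along(times)) {
    t <- times[k]
    lab_t <- if (t <= t0) stripes0$labels else {
      b <- advect_points(nodes, flow, t, t0, dt = 0.5)
      ii <- pmin(pmax(round(b[, 1L] / chart$dx) + 1L, 1L), chart$nx)
      jj <- (round(b[, 2L] / chart$dy) %% chart$ny) + 1L
      matrix(stripes0$labels[cbind(ii, jj)], chart$nx, chart$ny)
    }
    for (s in seq_len(stripes0$k)) {
      m <- lab_t == s & upper
      n_px <- sum(m)
      wmean <- function(series) {
        if (n_px == 0L) return(NA_real_)
        nm <- nematic_mean(series$angle[, , k][m],
                           series$weight[, , k][m])
        nm$mean
      }
      ra <- wmean(runt_orient); ma <- wmean(myo_orient)
      out[[length(out) + 1L]] <- data.frame(
        stripe = s, time = t, runt_angle = ra, myosin_angle = ma,
        myosin_vs_runt = if (is.na(ra) || is.na(ma)) NA_real_
                         else nematic_diff(ma, ra),
        adjusted_angle = wmean(adjusted), n_px = n_px)
    }
  }
  do.call(rbind, out)
}
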