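## Synthetic pair-rule-gene expression patterns.
##
## PRGs (Runt, Eve, Ftz, ...) are expressed in seven stripes at regular AP
## intervals, parallel to the DV axis at t = 0, with expression reduced
## towards the dorsal pole. Different genes are slightly out of register,
## modeled as an AP phase offset.

#' Specify a synthetic pair-rule stripe pattern
#'
#' @param n_stripes number of AP stripes (wild type: 7).
#' @param period AP distance between stripe centers (micrometers).
#' @param width Gaussian half-width of each stripe bump (micrometers).
#' @param ap_start AP position of the first stripe center (micrometers).
#' @param dv_floor minimum of the multiplicative DV intensity modulation,
#'   attained at the dorsal pole; 1 disables the modulation.
#' @param amplitude peak intensity (arbitrary units).
#' @return object of class \code{stripe_spec}.
#' @export
stripe_spec <- function(n_stripes = 7, period = 40, width = 8,
                        ap_start = 100, dv_floor = 0.1, amplitude = 1) {
  if (n_stripes < 1) stop("need at least one stripe")
  if (period <= 0 || width <= 0) stop("period and width must be positive")
  if (dv_floor < 0 || dv_floor > 1) stop("dv_floor must lie in [0, 1]")
  structure(list(n_stripes = n_stripes, period = period, width = width,
                 ap_start = ap_start, dv_floor = dv_floor,
                 amplitude = amplitude),
            class = "stripe_spec")
}

## DV modulation profile: expression is roughly uniform across the
## analyzed germband and decreases towards the dorsal pole. Implemented
## as a logistic drop in DV distance from the ventral midline, centered
## at 42% of the circumference with a 30-um width, down to `floor` at
## the pole. (A profile falling already inside the germband would
## contaminate gradient-based stripe angles with its own DV gradient.)
dv_modulation <- function(y, chart, floor) {
  d <- dv_distance(y, chart)
  floor + (1 - floor) *
    stats::plogis((0.42 * chart$dv_circumference - d) / 30)
}

#' Generate a synthetic PRG expression map
#'
#' Non-negative intensity on the chart: Gaussian AP stripe bumps times a DV
#' modulation with its minimum at the dorsal pole. Stripes are parallel to
#' the DV axis (the t = 0 configuration; later times are obtained by
#' advecting this field with the tissue flow).
#'
#' @param chart a \code{chart_grid}.
#' @param spec a \code{stripe_spec}.
#' @param phase AP offset of this gene relative to the spec (micrometers);
#'   genes that are slightly out of register get different phases.
#' @return nx x ny intensity matrix.
#' @examples
#' chart <- make_chart(dx = 2, dy = 2)
#' runt <- make_prg_pattern(chart, stripe_spec())
#' @export
make_prg_pattern <- function(chart, spec, phase = 0) {
  stopifnot(inherits(chart, "chart_grid"), inherits(spec, "stripe_spec"))
  if (spec$n_stripes * spec$period > chart$ap_length)
    stop("stripes do not fit within the AP extent")
  centers <- spec$ap_start + phase + (seq_len(spec$n_stripes) - 1) *
    spec$period
  if (any(centers < 0 | centers > chart$ap_length))
    stop("stripes do not fit within the AP extent")
  ap <- rowSums(vapply(centers,
                       function(c0) exp(-(chart$x - c0)^2 /
                                        (2 * spec$width^2)),
                       numeric(chart$nx)))
  dv <- dv_modulation(chart$y, chart, spec$dv_floor)
  spec$amplitude * outer(ap, dv)
}

#' Generate a registered set of PRG expression maps
#'
#' @param chart a \code{chart_grid}.
#' @param spec a \code{stripe_spec}.
#' @param phases named numeric vector of AP phase offsets (micrometers),
#'   one per gene.
#' @return named list of intensity matrices.
#' @export
make_prg_set <- function(chart, spec,
                         phases = c(runt = 0, eve = 13, ftz = 27)) {
  lapply(phases, function(p) make_prg_pattern(chart, spec, phase = p))
}

#' Generate a synthetic smoothed junctional myosin intensity map
#'
#' The large-scale myosin pattern is a stripe-free band: roughly uniform
#' along AP within the germband (smooth roll-off at the poles) and decaying
#' exponentially with DV distance from the ventral furrow with length scale
#' \code{ell_m}, emulating the ventral-maximal recruitment zone.
#'
#' @param chart a \code{chart_grid}.
#' @param ell_m DV decay length (micrometers); the default puts the
#'   detection floor (10 percent of the ventral maximum) near 175 um from
#'   the furrow.
#' @param ap_rolloff width of the smooth AP roll-off (micrometers).
#' @param amplitude peak intensity.
#' @return nx x ny intensity matrix.
#' @export
make_myosin_pattern <- function(chart, ell_m = 76, ap_rolloff = 30,
                                amplitude = 1) {
  stopifnot(inherits(chart, "chart_grid"))
  lo <- chart$ap_margin; hi <- chart$ap_length - chart$ap_margin
  ap <- stats::plogis((chart$x - lo) / (ap_rolloff / 4)) *
    stats::plogis((hi - chart$x) / (ap_rolloff / 4))
  dv <- exp(-dv_distance(chart$y, chart) / ell_m)
  amplitude * outer(ap, dv)
}
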