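## Reading and writing the exchange formats: multi-page TIFF for gridded
## fields, CSV for junction tables, FRAP traces, velocity fields and
## correlation matrices, JSON for parameter sets and reports.

## chart matrices are (x, y); TIFF pages are row = y, column = x
field_to_page <- function(m) t(m)[, , drop = TRUE]
page_to_field <- function(p) t(p)

#' Write a field or field series as multi-page TIFF
#'
#' One page per time point, 32-bit, row = DV (y), column = AP (x). TIFF
#' samples are stored in [0, 1], so the values are affinely rescaled and
#' the original range is written to a JSON sidecar (\code{<path>.range.json})
#' which \code{\link{read_field_tiff}} uses to restore the physical units.
#'
#' @param x a matrix, a list of matrices, or a \code{field_series}.
#' @param path output file.
#' @export
write_field_tiff <- function(x, path) {
  pages <- if (is.matrix(x)) list(x)
  else if (is.list(x) && !is.null(x$data))
    lapply(seq_len(dim(x$data)[3L]), function(k) x$data[, , k])
  else x
  rng <- range(unlist(lapply(pages, range)), finite = TRUE)
  span <- if (diff(rng) > 0) diff(rng) else 1
  scaled <- lapply(pages, function(p) (p - rng[1L]) / span)
  tiff::writeTIFF(lapply(scaled, field_to_page), path,
                  bits.per.sample = 32L, reduce = FALSE)
  jsonlite::write_json(list(min = rng[1L], max = rng[1L] + span),
                       paste0(path, ".range.json"), auto_unbox = TRUE,
                       digits = NA)
  invisible(path)
}

#' Read a multi-page TIFF as a field series
#'
#' @param path TIFF file.
#' @param chart the \code{chart_grid} the pages live on.
#' @param times optional time stamps (default 0, 1, ...).
#' @return a \code{field_series}.
#' @export
read_field_tiff <- function(path, chart, times = NULL) {
  pages <- tiff::readTIFF(path, all = TRUE)
  if (!is.list(pages)) pages <- list(pages)
  side <- paste0(path, ".range.json")
  rng <- if (file.exists(side)) jsonlite::read_json(side)
         else list(min = 0, max = 1)
  arr <- array(0, c(chart$nx, chart$ny, length(pages)))
  for (k in seq_along(pages)) {
    p <- pages[[k]]
    if (length(dim(p)) == 3L) p <- p[, , 1L]
    arr[, , k] <- page_to_field(p) * (rng$max - rng$min) + rng$min
  }
  structure(list(data = arr,
                 times = if (is.null(times)) seq_along(pages) - 1
                         else times,
                 chart = chart),
            class = "field_series")
}

#' Write a junction table as CSV
#'
#' @param segments junction table (simulated or detected).
#' @param path output file.
#' @export
write_junction_csv <- function(segments, path) {
  utils::write.csv(as.data.frame(segments), path, row.names = FALSE)
  invisible(path)
}

#' Read a junction table from CSV
#' @param path CSV file with the columns written by
#'   \code{\link{write_junction_csv}}.
#' @return data.frame of class \code{junction_segments}.
#' @export
read_junction_csv <- function(path) {
  out <- utils::read.csv(path)
  class(out) <- c("junction_segments", "data.frame")
  out
}

#' Write a FRAP trace as CSV
#' @param trace a \code{frap_trace}.
#' @param path output file.
#' @export
write_frap_csv <- function(trace, path) {
  utils::write.csv(as.data.frame(trace), path, row.names = FALSE)
  invisible(path)
}

#' Read a FRAP trace from CSV
#' @param path CSV with columns \code{t_s}, \code{intensity}.
#' @return a \code{frap_trace}.
#' @export
read_frap_csv <- function(path) {
  out <- utils::read.csv(path)
  structure(out, class = c("frap_trace", "data.frame"))
}

#' Write a velocity field as long-format CSV
#'
#' Columns t_min, x_um, y_um, vx, vy.
#' @param vf a \code{velocity_field}.
#' @param path output file.
#' @export
write_velocity_csv <- function(vf, path) {
  chart <- vf$chart
  grid <- expand.grid(x_um = chart$x, y_um = chart$y)
  rows <- lapply(seq_along(vf$times), function(k) {
    data.frame(t_min = vf$times[k], x_um = grid$x_um, y_um = grid$y_um,
               vx = as.numeric(vf$vx[, , k]),
               vy = as.numeric(vf$vy[, , k]))
  })
  utils::write.csv(do.call(rbind, rows), path, row.names = FALSE)
  invisible(path)
}

#' Read a long-format velocity CSV
#' @param path CSV as written by \code{\link{write_velocity_csv}}.
#' @param chart the \code{chart_grid} of the grid.
#' @return a \code{velocity_field}.
#' @export
read_velocity_csv <- function(path, chart) {
  d <- utils::read.csv(path)
  times <- sort(unique(d$t_min))
  vx <- array(0, c(chart$nx, chart$ny, length(times)))
  vy <- array(0, c(chart$nx, chart$ny, length(times)))
  for (k in seq_along(times)) {
    dk <- d[d$t_min == times[k], ]
    ii <- round(dk$x_um / chart$dx) + 1L
    jj <- round(dk$y_um / chart$dy) + 1L
    vx[, , k][cbind(ii, jj)] <- dk$vx
    vy[, , k][cbind(ii, jj)] <- dk$vy
  }
  structure(list(vx = vx, vy = vy, times = times, chart = chart),
            class = "velocity_field")
}

#' Write a correlation matrix as CSV with time-stamp headers
#' @param cm a \code{correlation_matrix}.
#' @param path output file.
#' @export
write_correlation_csv <- function(cm, path) {
  m <- as.data.frame(cm$C)
  names(m) <- cm$times
  utils::write.csv(cbind(t_min = cm$times, m), path, row.names = FALSE)
  invisible(path)
}

#' Write a pipeline report (or any parameter list) as JSON
#' @param x report or list.
#' @param path output file.
#' @export
write_report_json <- function(x, path) {
  keep <- x[!vapply(x, function(el)
    is.matrix(el) || is.array(el) || is.function(el), logical(1))]
  jsonlite::write_json(keep, path, auto_unbox = TRUE, digits = NA,
                       force = TRUE, pretty = TRUE)
  invisible(path)
}
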