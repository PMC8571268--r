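#' Contour length of a fibril trace
#'
#' Sum of the Euclidean lengths of all line segments of the polygonal
#' chain, reported in micrometres.
#'
#' @param trace A [fibril_trace()].
#' @return Contour length L in um.
#' @examples
#' tr <- fibril_trace("f", rbind(c(0, 0, 0), c(300, 400, 0)))
#' contour_length(tr) # 0.5 um (3-4-5 triangle)
#' @export
contour_length <- function(trace) {
  problem <- trace_problem(trace)
  if (!is.null(problem)) stop("invalid trace: ", problem, call. = FALSE)
  p <- trace$points
  seg <- sqrt(rowSums((p[-1L, , drop = FALSE] -
                         p[-nrow(p), , drop = FALSE])^2))
  sum(seg) / 1000
}

#' End-to-end distance of a fibril trace
#'
#' Euclidean distance between the first and last points of the chain, in
#' micrometres. `mode = "planar_xy"` projects onto the x-y plane first
#' (ignores z), emulating a 2D measurement of a 3D trace.
#'
#' @param trace A [fibril_trace()].
#' @param mode `"spatial3d"` (default) or `"planar_xy"`.
#' @return End-to-end distance R in um.
#' @export
end_to_end <- function(trace, mode = c("spatial3d", "planar_xy")) {
  mode <- match.arg(mode)
  problem <- trace_problem(trace)
  if (!is.null(problem)) stop("invalid trace: ", problem, call. = FALSE)
  d <- trace$points[nrow(trace$points), ] - trace$points[1L, ]
  if (mode == "planar_xy") d <- d[1:2]
  sqrt(sum(d^2)) / 1000
}

#' Measure contour length and end-to-end distance for a cohort
#'
#' Applies [contour_length()] and [end_to_end()] to every trace, excluding
#' (and logging) traces that fail validity checks, have fewer than
#' `min_points` points, or have zero end-to-end distance in the chosen
#' mode. The squared end-to-end distance `r2_um2` is stored redundantly
#' because it is the response variable of the persistence-length
#' regression.
#'
#' @param traces List of [fibril_trace()] objects (or objects that fail
#'   validation, which are logged and dropped).
#' @param mode Passed to [end_to_end()].
#' @param min_points Minimum number of points a trace must have.
#' @return A data frame of class `fibril_geometry` with columns
#'   `fibril_id`, `contour_length_um`, `end_to_end_um`, `r2_um2`, ordered
#'   as the input; attribute `exclusions` is a data frame of dropped
#'   traces with reasons.
#' @examples
#' sim <- simulate_study(simulation_spec(n_fibrils = 5, seed = 1))
#' geom <- measure_all(sim$traces)
#' all(geom$end_to_end_um <= geom$contour_length_um)
#' @export
measure_all <- function(traces, mode = c("spatial3d", "planar_xy"),
                        min_points = 2L) {
  mode <- match.arg(mode)
  stopifnot(is.list(traces), length(traces) >= 1L, min_points >= 2L)
  rows <- list()
  excl <- list()
  for (i in seq_along(traces)) {
    tr <- traces[[i]]
    id <- if (is_fibril_trace(tr)) tr$fibril_id else sprintf("index_%d", i)
    problem <- trace_problem(tr)
    if (is.null(problem) && nrow(tr$points) < min_points) {
      problem <- sprintf("fewer than %d points", min_points)
    }
    if (is.null(problem)) {
      r <- end_to_end(tr, mode)
      if (r == 0) problem <- paste0("zero end-to-end distance (", mode, ")")
    }
    if (!is.null(problem)) {
      excl[[length(excl) + 1L]] <- data.frame(fibril_id = id,
                                              reason = problem)
      next
    }
    rows[[length(rows) + 1L]] <- data.frame(
      fibril_id = id,
      contour_length_um = contour_length(tr),
      end_to_end_um = r,
      r2_um2 = r^2
    )
  }
  if (length(rows) == 0L) {
    stop("all ", length(traces), " traces were excluded", call. = FALSE)
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  exclusions <- if (length(excl)) do.call(rbind, excl) else
    data.frame(fibril_id = character(0), reason = character(0))
  attr(out, "exclusions") <- exclusions
  attr(out, "mode") <- mode
  class(out) <- c("fibril_geometry", "data.frame")
  out
}
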