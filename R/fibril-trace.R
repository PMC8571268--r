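#' Construct a fibril trace
#'
#' A `fibril_trace` is an ordered 3D polygonal chain representing one traced
#' fibril, with coordinates in nanometres. It is the unit of data for all
#' geometry and persistence-length computations.
#'
#' @param fibril_id Character scalar identifying the fibril.
#' @param points Numeric matrix with 3 columns (x, y, z) in nm and at least
#'   2 rows. Consecutive duplicate points are merged with a warning.
#' @param provenance Free-text origin tag, e.g. `"simulated"` or
#'   `"imported"`.
#' @param pixel_size_nm Optional positive scale that was applied to raw
#'   pixel coordinates at import time (recorded, not re-applied).
#'
#' @return An object of class `fibril_trace`: a list with elements
#'   `fibril_id`, `points` (n x 3 matrix, nm), `provenance`,
#'   `pixel_size_nm`.
#'
#' @examples
#' tr <- fibril_trace("f1", rbind(c(0, 0, 0), c(1000, 0, 0)))
#' contour_length(tr)
#' @export
fibril_trace <- function(fibril_id, points, provenance = "imported",
                         pixel_size_nm = NULL) {
  stopifnot(is.character(fibril_id), length(fibril_id) == 1L)
  points <- as.matrix(points)
  if (ncol(points) != 3L) {
    stop("`points` must have 3 columns (x, y, z in nm)", call. = FALSE)
  }
  storage.mode(points) <- "double"
  if (!all(is.finite(points))) {
    stop("trace '", fibril_id, "': non-finite coordinates", call. = FALSE)
  }
  if (nrow(points) >= 2L) {
    seg <- sqrt(rowSums((points[-1L, , drop = FALSE] -
                           points[-nrow(points), , drop = FALSE])^2))
    if (any(seg == 0)) {
      warning("trace '", fibril_id, "': merged ", sum(seg == 0),
              " consecutive duplicate point(s)", call. = FALSE)
      points <- points[c(TRUE, seg > 0), , drop = FALSE]
    }
  }
  if (nrow(points) < 2L) {
    stop("trace '", fibril_id, "': needs at least 2 distinct points",
         call. = FALSE)
  }
  if (!is.null(pixel_size_nm)) {
    stopifnot(is.numeric(pixel_size_nm), length(pixel_size_nm) == 1L,
              pixel_size_nm > 0)
  }
  dimnames(points) <- list(NULL, c("x", "y", "z"))
  structure(
    list(fibril_id = fibril_id, points = points,
         provenance = provenance, pixel_size_nm = pixel_size_nm),
    class = "fibril_trace"
  )
}

#' @export
print.fibril_trace <- function(x, ...) {
  cat(sprintf("<fibril_trace> %s: %d points, %.3f um contour (%s)\n",
              x$fibril_id, nrow(x$points), contour_length(x),
              x$provenance))
  invisible(x)
}

is_fibril_trace <- function(x) inherits(x, "fibril_trace")

# validate without constructing; returns NULL if ok, else a reason string
trace_problem <- function(x) {
  if (!is_fibril_trace(x)) return("not a fibril_trace")
  p <- x$points
  if (!is.matrix(p) || ncol(p) != 3L) return("points not an n x 3 matrix")
  if (nrow(p) < 2L) return("fewer than 2 points")
  if (!all(is.finite(p))) return("non-finite coordinates")
  seg <- sqrt(rowSums((p[-1L, , drop = FALSE] -
                         p[-nrow(p), , drop = FALSE])^2))
  if (any(seg == 0)) return("zero-length segment")
  NULL
}
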