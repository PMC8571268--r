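#' Helical pitch from rise and twist
#'
#' For a helix with axial rise `rise_A` (Angstrom per subunit) and twist
#' `twist_deg` (signed degrees per subunit; negative = left-handed), the
#' pitch is the axial distance per full 360-degree turn:
#' `rise_A * 360 / |twist_deg|`, converted to nm.
#'
#' @param rise_A Rise per subunit in Angstrom (> 0).
#' @param twist_deg Twist per subunit in degrees (non-zero; sign ignored).
#' @return Pitch in nm.
#' @examples
#' pitch_from_rise_twist(4.76, -1.46) # 117.4 nm
#' @export
pitch_from_rise_twist <- function(rise_A, twist_deg) {
  stopifnot(rise_A > 0)
  if (any(twist_deg == 0)) stop("pitch is undefined for zero twist",
                                call. = FALSE)
  rise_A * 360 / abs(twist_deg) / 10
}

#' Crossover distance from pitch (and inverse)
#'
#' In projection, a twisted ribbon-like fibril shows `crossovers_per_turn`
#' apparent width minima per full turn (2 for the single-protofilament
#' morphology treated here), so crossover = pitch / crossovers_per_turn.
#'
#' @param pitch_nm Pitch in nm (> 0).
#' @param crossover_nm Crossover distance in nm (> 0).
#' @param crossovers_per_turn Crossovers per 360-degree turn (default 2).
#' @return Crossover distance (resp. pitch) in nm.
#' @examples
#' crossover_from_pitch(117) # 58.5 nm
#' pitch_from_crossover(55)  # 110 nm
#' @export
crossover_from_pitch <- function(pitch_nm, crossovers_per_turn = 2) {
  stopifnot(pitch_nm > 0, crossovers_per_turn > 0)
  pitch_nm / crossovers_per_turn
}

#' @rdname crossover_from_pitch
#' @export
pitch_from_crossover <- function(crossover_nm, crossovers_per_turn = 2) {
  stopifnot(crossover_nm > 0, crossovers_per_turn > 0)
  crossover_nm * crossovers_per_turn
}

#' Twist implied by a measured crossover distance
#'
#' Inverts the pitch relation: `|twist| = rise_A * 360 /
#' (crossover_nm * crossovers_per_turn * 10)` degrees; the sign is set by
#' the handedness (left-handed helices have negative twist).
#'
#' @param rise_A Rise per subunit in Angstrom (> 0).
#' @param crossover_nm Crossover distance in nm (> 0).
#' @param handedness `"left"` or `"right"`.
#' @param crossovers_per_turn Crossovers per turn (default 2).
#' @return Signed twist in degrees per subunit.
#' @examples
#' twist_from_crossover(4.76, 55, "left") # -1.56 deg
#' @export
twist_from_crossover <- function(rise_A, crossover_nm,
                                 handedness = c("left", "right"),
                                 crossovers_per_turn = 2) {
  handedness <- match.arg(handedness)
  stopifnot(rise_A > 0, crossover_nm > 0)
  mag <- rise_A * 360 / (crossover_nm * crossovers_per_turn * 10)
  if (handedness == "left") -mag else mag
}

#' Helical-parameter consistency report
#'
#' Given a partially specified set of helical parameters (any of `rise_A`,
#' `twist_deg`, `pitch_nm`, `crossover_nm`, plus `handedness` when the
#' twist sign is not supplied), fills in every derivable quantity and
#' reports the relative discrepancy between each supplied value and the
#' value implied by the others, flagging discrepancies above
#' `tolerance_frac`. At least two independent quantities are required
#' (rise and twist jointly determine pitch; pitch and crossover determine
#' each other).
#'
#' @param rise_A,twist_deg,pitch_nm,crossover_nm Optional numeric scalars.
#' @param handedness `"left"`, `"right"`, or NA to infer from `twist_deg`.
#' @param tolerance_frac Relative-discrepancy flag threshold (default 0.10).
#' @param crossovers_per_turn Crossovers per turn (default 2).
#' @return A list of class `helix_report` with `params` (the completed
#'   parameter set), `discrepancies` (data frame: quantity, supplied,
#'   implied, rel_discrepancy, flagged), and `handedness`.
#' @examples
#' helix_consistency(rise_A = 4.76, twist_deg = -1.46, crossover_nm = 55)
#' @export
helix_consistency <- function(rise_A = NULL, twist_deg = NULL,
                              pitch_nm = NULL, crossover_nm = NULL,
                              handedness = NA_character_,
                              tolerance_frac = 0.10,
                              crossovers_per_turn = 2) {
  supplied <- list(rise_A = rise_A, twist_deg = twist_deg,
                   pitch_nm = pitch_nm, crossover_nm = crossover_nm)
  supplied <- supplied[!vapply(supplied, is.null, logical(1))]
  # pitch is derivable from (rise, twist) or from crossover
  n_pitch_sources <- sum(!is.null(pitch_nm),
                         !is.null(rise_A) && !is.null(twist_deg),
                         !is.null(crossover_nm))
  if (length(supplied) < 2L || n_pitch_sources < 1L) {
    stop("under-specified: need at least two of rise_A+twist_deg, ",
         "pitch_nm, crossover_nm (supplied: ",
         paste(names(supplied), collapse = ", "), ")", call. = FALSE)
  }
  if (is.na(handedness) && !is.null(twist_deg)) {
    handedness <- if (twist_deg < 0) "left" else "right"
  }
  # all independent estimates of the pitch, labeled by source
  est <- c(
    if (!is.null(pitch_nm)) c(pitch_nm = pitch_nm),
    if (!is.null(rise_A) && !is.null(twist_deg))
      c(rise_twist = pitch_from_rise_twist(rise_A, twist_deg)),
    if (!is.null(crossover_nm))
      c(crossover = pitch_from_crossover(crossover_nm, crossovers_per_turn))
  )
  pitch_best <- mean(est)
  disc <- list()
  for (nm in names(supplied)) {
    other <- est[setdiff(names(est),
                         switch(nm, pitch_nm = "pitch_nm",
                                crossover_nm = "crossover",
                                rise_A = "rise_twist",
                                twist_deg = "rise_twist"))]
    if (length(other) == 0L) next
    implied_pitch <- mean(other)
    implied <- switch(nm,
      pitch_nm = implied_pitch,
      crossover_nm = crossover_from_pitch(implied_pitch,
                                          crossovers_per_turn),
      rise_A = if (!is.null(twist_deg))
        implied_pitch * 10 * abs(twist_deg) / 360 else NA_real_,
      twist_deg = if (!is.null(rise_A)) {
        mag <- rise_A * 360 / (implied_pitch * 10)
        if (identical(handedness, "left")) -mag else mag
      } else NA_real_)
    if (!is.finite(implied)) next
    val <- supplied[[nm]]
    rel <- abs(abs(implied) - abs(val)) / abs(val)
    disc[[length(disc) + 1L]] <- data.frame(
      quantity = nm, supplied = val, implied = implied,
      rel_discrepancy = rel, flagged = rel > tolerance_frac)
  }
  discrepancies <- if (length(disc)) do.call(rbind, disc) else
    data.frame(quantity = character(0), supplied = numeric(0),
               implied = numeric(0), rel_discrepancy = numeric(0),
               flagged = logical(0))
  params <- list(
    rise_A = rise_A %||% NA_real_,
    twist_deg = twist_deg %||% (
      if (!is.null(rise_A)) {
        mag <- rise_A * 360 / (pitch_best * 10)
        if (identical(handedness, "left")) -mag else mag
      } else NA_real_),
    pitch_nm = pitch_nm %||% pitch_best,
    crossover_nm = crossover_nm %||%
      crossover_from_pitch(pitch_best, crossovers_per_turn),
    handedness = handedness
  )
  structure(list(params = params, discrepancies = discrepancies,
                 tolerance_frac = tolerance_frac,
                 crossovers_per_turn = crossovers_per_turn),
            class = "helix_report")
}

#' @export
print.helix_report <- function(x, ...) {
  p <- x$params
  cat(sprintf(
    "Helical parameters: rise %.3g A, twist %.3g deg (%s-handed),\n  pitch %.4g nm, crossover %.4g nm\n",
    p$rise_A, p$twist_deg,
    if (is.na(p$handedness)) "?" else p$handedness,
    p$pitch_nm, p$crossover_nm))
  d <- x$discrepancies
  if (nrow(d)) {
    for (i in seq_len(nrow(d))) {
      cat(sprintf("  %s: supplied %.4g vs implied %.4g (%.1f%%)%s\n",
                  d$quantity[i], d$supplied[i], d$implied[i],
                  100 * d$rel_discrepancy[i],
                  if (d$flagged[i]) "  ** exceeds tolerance **" else ""))
    }
  } else cat("  no cross-checkable redundancy supplied\n")
  invisible(x)
}
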