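#' Annotate the ordered core and mutations of a fibril protein
#'
#' Represents, for one fibril protein, the residue ranges resolved as the
#' ordered fibril core, the positions of somatic mutations, and optionally
#' the sequence. Coordinates are 1-based inclusive throughout.
#'
#' @param protein_id Character identifier.
#' @param seq_length Residue count of the fibril protein fragment.
#' @param ordered_ranges List of length-2 integer vectors `c(start, end)`
#'   (1-based inclusive); must be within sequence bounds and pairwise
#'   disjoint. Stored sorted by start.
#' @param mutation_positions Integer vector of mutated positions.
#' @param sequence Optional one-letter amino-acid string of length
#'   `seq_length`.
#' @param ptms Optional free-form list of post-translational-modification
#'   annotations (metadata only; no computation).
#' @return An object of class `core_annotation`.
#' @examples
#' ann <- core_annotation("demo", 100, list(c(10, 60)), c(5, 20))
#' ordered_fraction(ann)
#' @export
core_annotation <- function(protein_id, seq_length, ordered_ranges = list(),
                            mutation_positions = integer(0),
                            sequence = NULL, ptms = NULL) {
  stopifnot(is.character(protein_id), length(protein_id) == 1L,
            seq_length >= 1L)
  seq_length <- as.integer(seq_length)
  ordered_ranges <- lapply(ordered_ranges, function(r) {
    r <- as.integer(r)
    if (length(r) != 2L || r[1] > r[2] || r[1] < 1L || r[2] > seq_length) {
      stop("invalid ordered range [", paste(r, collapse = ", "),
           "] for sequence length ", seq_length, call. = FALSE)
    }
    r
  })
  if (length(ordered_ranges) > 1L) {
    ord <- order(vapply(ordered_ranges, `[`, integer(1), 1L))
    ordered_ranges <- ordered_ranges[ord]
    starts <- vapply(ordered_ranges, `[`, integer(1), 1L)
    ends <- vapply(ordered_ranges, `[`, integer(1), 2L)
    if (any(starts[-1L] <= ends[-length(ends)])) {
      stop("ordered ranges overlap", call. = FALSE)
    }
  }
  mutation_positions <- sort(unique(as.integer(mutation_positions)))
  if (length(mutation_positions) &&
      (min(mutation_positions) < 1L || max(mutation_positions) > seq_length)) {
    stop("mutation positions outside [1, ", seq_length, "]", call. = FALSE)
  }
  if (!is.null(sequence)) {
    stopifnot(is.character(sequence), length(sequence) == 1L)
    if (nchar(sequence) != seq_length) {
      stop("sequence length ", nchar(sequence),
           " does not match seq_length ", seq_length, call. = FALSE)
    }
  }
  structure(list(protein_id = protein_id, seq_length = seq_length,
                 ordered_ranges = ordered_ranges,
                 mutation_positions = mutation_positions,
                 sequence = sequence, ptms = ptms),
            class = "core_annotation")
}

#' Published core annotation of the FOR001 fibril protein
#'
#' Convenience constructor for the FOR001 lambda-1 light-chain fibril
#' fragment (Gln1--Ser118, 118 residues): ordered core segments
#' Ser9--Thr52 and Ser68--Thr108, and the six somatic mutations
#' Lys17Asn, Asn52Thr, Asn53Asp, Gly82Ala, Asp93Glu and Xaa99Gly. PTM
#' metadata records the Asn17 N-glycosylation, the Cys22--Cys89 disulfide
#' and the partial N-terminal pyroglutamate.
#'
#' @return A [core_annotation()].
#' @examples
#' mutations_in_ordered(for001_annotation())$count # 5
#' @export
for001_annotation <- function() {
  core_annotation(
    "FOR001", 118L,
    ordered_ranges = list(c(9L, 52L), c(68L, 108L)),
    mutation_positions = c(17L, 52L, 53L, 82L, 93L, 99L),
    ptms = list(n_glycosylation = 17L, disulfide = c(22L, 89L),
                pyroglutamate = 1L)
  )
}

#' Fraction of residues in the ordered fibril core
#'
#' @param annotation A [core_annotation()].
#' @return Sum of ordered-range lengths divided by the sequence length.
#' @examples
#' ordered_fraction(for001_annotation()) # 85/118
#' @export
ordered_fraction <- function(annotation) {
  stopifnot(inherits(annotation, "core_annotation"))
  covered <- sum(vapply(annotation$ordered_ranges,
                        function(r) r[2] - r[1] + 1L, integer(1)))
  covered / annotation$seq_length
}

#' Mutations falling inside the ordered core
#'
#' Counts the mutation positions that lie within any ordered range.
#'
#' @param annotation A [core_annotation()] with at least one mutation.
#' @return List with `count`, `n_total` and `fraction` = count / total.
#' @examples
#' mutations_in_ordered(for001_annotation()) # 5 of 6
#' @export
mutations_in_ordered <- function(annotation) {
  stopifnot(inherits(annotation, "core_annotation"))
  mut <- annotation$mutation_positions
  if (length(mut) == 0L) {
    stop("annotation '", annotation$protein_id,
         "' has no mutations; fraction undefined", call. = FALSE)
  }
  inside <- vapply(mut, function(pos) {
    any(vapply(annotation$ordered_ranges,
               function(r) pos >= r[1] && pos <= r[2], logical(1)))
  }, logical(1))
  list(count = sum(inside), n_total = length(mut),
       fraction = mean(inside))
}

#' Ordered-core statistics across fibril structures
#'
#' For each annotated protein computes the ordered-residue fraction and
#' the fraction of mutations inside the ordered core, then aggregates
#' mean and sample standard deviation (n-1 denominator) of both fractions
#' across proteins. Percent display values are rounded to whole percent;
#' full precision is retained in the fraction columns.
#'
#' @param annotations List of [core_annotation()] objects (>= 1; SD needs
#'   >= 2).
#' @return A list of class `segment_stats` with `per_protein` (data
#'   frame) and `aggregate` (means and SDs of both fractions, plus
#'   percent-scale display values).
#' @examples
#' aggregate_stats(list(for001_annotation(), for001_annotation()))
#' @export
aggregate_stats <- function(annotations) {
  stopifnot(is.list(annotations), length(annotations) >= 1L,
            all(vapply(annotations, inherits, logical(1),
                       "core_annotation")))
  per <- do.call(rbind, lapply(annotations, function(a) {
    mio <- mutations_in_ordered(a)
    data.frame(protein_id = a$protein_id,
               seq_length = a$seq_length,
               ordered_residue_fraction = ordered_fraction(a),
               n_mut_total = mio$n_total,
               n_mut_ordered = mio$count,
               mut_ordered_fraction = mio$fraction)
  }))
  rownames(per) <- NULL
  n <- nrow(per)
  agg <- list(
    n_proteins = n,
    mean_ordered_fraction = mean(per$ordered_residue_fraction),
    sd_ordered_fraction = if (n >= 2L) stats::sd(per$ordered_residue_fraction)
                          else NA_real_,
    mean_mut_ordered_fraction = mean(per$mut_ordered_fraction),
    sd_mut_ordered_fraction = if (n >= 2L) stats::sd(per$mut_ordered_fraction)
                              else NA_real_
  )
  agg$ordered_percent <- round(100 * agg$mean_ordered_fraction)
  agg$ordered_percent_sd <- if (n >= 2L)
    round(100 * agg$sd_ordered_fraction) else NA_integer_
  agg$mut_ordered_percent <- round(100 * agg$mean_mut_ordered_fraction)
  agg$mut_ordered_percent_sd <- if (n >= 2L)
    round(100 * agg$sd_mut_ordered_fraction) else NA_integer_
  structure(list(per_protein = per, aggregate = agg),
            class = "segment_stats")
}

#' @export
print.segment_stats <- function(x, ...) {
  a <- x$aggregate
  cat(sprintf("Ordered-core statistics over %d protein(s):\n", a$n_proteins))
  if (a$n_proteins >= 2L) {
    cat(sprintf("  ordered residues: %d +/- %d %%\n",
                a$ordered_percent, a$ordered_percent_sd))
    cat(sprintf("  mutations in ordered core: %d +/- %d %%\n",
                a$mut_ordered_percent, a$mut_ordered_percent_sd))
  } else {
    cat(sprintf("  ordered residues: %d %% (SD undefined for n = 1)\n",
                a$ordered_percent))
    cat(sprintf("  mutations in ordered core: %d %%\n",
                a$mut_ordered_percent))
  }
  invisible(x)
}

#' Molar extinction coefficient at 280 nm
#'
#' Gill--von Hippel style additive estimate of the molar extinction
#' coefficient of an unfolded protein at 280 nm:
#' `eps = c_W * nTrp + c_Y * nTyr + c_SS * n_disulfides`, with a
#' configurable coefficient table. The default coefficients are the
#' denatured-protein values c_W = 5500, c_Y = 1490 and c_SS = 125
#' M^-1 cm^-1 per cystine.
#'
#' @param sequence One-letter amino-acid string (standard 20 codes).
#' @param n_disulfides Number of disulfide bonds (>= 0).
#' @param coefficients Named numeric vector with elements `W`, `Y`, `SS`
#'   in M^-1 cm^-1.
#' @return Extinction coefficient in M^-1 cm^-1.
#' @examples
#' extinction_coefficient("WYY") # 5500 + 2 * 1490
#' @export
extinction_coefficient <- function(sequence, n_disulfides = 0,
                                   coefficients = c(W = 5500, Y = 1490,
                                                    SS = 125)) {
  stopifnot(is.character(sequence), length(sequence) == 1L,
            n_disulfides >= 0,
            all(c("W", "Y", "SS") %in% names(coefficients)))
  aa <- strsplit(toupper(sequence), "")[[1]]
  valid <- strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]]
  bad <- setdiff(aa, valid)
  if (length(bad)) stop("unknown residue letter(s): ",
                        paste(unique(bad), collapse = ", "), call. = FALSE)
  unname(coefficients["W"] * sum(aa == "W") +
           coefficients["Y"] * sum(aa == "Y") +
           coefficients["SS"] * n_disulfides)
}
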