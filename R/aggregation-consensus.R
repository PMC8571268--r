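#' Default binarization rules for the five aggregation predictors
#'
#' A residue is called aggregation-prone by a predictor when its output
#' value lies strictly on the stated side of the threshold:
#' TANGO beta-aggregation > 0.0; WALTZ score > 0.0; FoldAmyloid
#' triple-hybrid value > 0.062 sustained over at least five successive
#' residues; Aggrescan propensity > -0.02; PASTA energy < -2.8 PEU.
#' These thresholds configure the binarization of the external programs'
#' per-residue outputs; the programs themselves are not run here.
#'
#' @return Data frame with columns `predictor`, `direction`
#'   (`"above"`/`"below"`), `threshold`, `min_run`.
#' @export
default_predictor_rules <- function() {
  data.frame(
    predictor = c("tango", "waltz", "foldamyloid", "aggrescan", "pasta"),
    direction = c("above", "above", "above", "above", "below"),
    threshold = c(0.0, 0.0, 0.062, -0.02, -2.8),
    min_run = c(1L, 1L, 5L, 1L, 1L),
    stringsAsFactors = FALSE
  )
}

#' Binarize one predictor's per-residue values
#'
#' Flags residues whose value is strictly above (or below) the rule's
#' threshold; if `min_run > 1`, flags are then kept only inside maximal
#' runs of at least `min_run` consecutive flagged residues (shorter runs
#' are reset to 0). Values must cover a contiguous residue block.
#'
#' @param values Numeric vector of per-residue predictor output, position
#'   i corresponding to residue i of the block.
#' @param rule One row of a rules data frame (see
#'   [default_predictor_rules()]), or a list with `direction`,
#'   `threshold`, `min_run`.
#' @return Integer vector of 0/1 flags, same length as `values`.
#' @examples
#' rule <- list(direction = "above", threshold = 0.062, min_run = 5)
#' binarize(c(rep(0.07, 4), rep(0.05, 6)), rule) # run of 4 < 5: all zero
#' @export
binarize <- function(values, rule) {
  stopifnot(is.numeric(values))
  if (anyNA(values)) stop("missing predictor values at positions: ",
                          paste(which(is.na(values)), collapse = ", "),
                          call. = FALSE)
  direction <- rule$direction
  if (!direction %in% c("above", "below")) {
    stop("rule direction must be 'above' or 'below'", call. = FALSE)
  }
  flags <- if (direction == "above") values > rule$threshold
           else values < rule$threshold
  min_run <- as.integer(rule$min_run %||% 1L)
  if (min_run > 1L && any(flags)) {
    r <- rle(flags)
    r$values <- r$values & r$lengths >= min_run
    flags <- inverse.rle(r)
  }
  as.integer(flags)
}

#' Consensus aggregation score across predictors
#'
#' Combines binarized per-residue predictions from up to five programs
#' into an integer consensus score: the per-residue count of predictors
#' that flag the residue. A score equal to the number of supplied
#' predictors (5 with the full set) means all programs agree the residue
#' is aggregation-prone; 0 means none does.
#'
#' @param predictions A prediction table: data frame with columns
#'   `protein_id`, `predictor`, `residue_index` (1-based, contiguous per
#'   predictor), `value`.
#' @param rules Rules data frame (default [default_predictor_rules()]).
#' @param waltz_mode `"per_residue"` (default) applies the WALTZ threshold
#'   at each position; `"whole_sequence"` flags every residue iff the
#'   summed WALTZ score exceeds the threshold (an alternative reading of a
#'   total-sequence-score rule).
#' @return A data frame of class `consensus_profile` with columns
#'   `protein_id`, `residue_index`, `score`, plus attributes `predictors`
#'   (those used) and `rules`.
#' @examples
#' tab <- expand.grid(residue_index = 1:6,
#'                    predictor = c("tango", "pasta"), stringsAsFactors = FALSE)
#' tab$protein_id <- "p1"
#' tab$value <- ifelse(tab$predictor == "tango", 0.5, -3)
#' consensus_score(tab)$score # all 2
#' @export
consensus_score <- function(predictions, rules = default_predictor_rules(),
                            waltz_mode = c("per_residue",
                                           "whole_sequence")) {
  waltz_mode <- match.arg(waltz_mode)
  stopifnot(is.data.frame(predictions),
            all(c("protein_id", "predictor", "residue_index", "value")
                %in% names(predictions)))
  bad <- setdiff(unique(predictions$predictor), rules$predictor)
  if (length(bad)) stop("unknown predictor id(s): ",
                        paste(bad, collapse = ", "), call. = FALSE)
  dup <- duplicated(predictions[c("protein_id", "predictor",
                                  "residue_index")])
  if (any(dup)) stop("duplicate (protein, predictor, residue) rows",
                     call. = FALSE)
  out <- list()
  for (prot in unique(predictions$protein_id)) {
    sub <- predictions[predictions$protein_id == prot, ]
    preds <- unique(sub$predictor)
    lens <- integer(0)
    flag_mat <- NULL
    for (pr in preds) {
      block <- sub[sub$predictor == pr, ]
      block <- block[order(block$residue_index), ]
      n <- nrow(block)
      if (!identical(as.integer(block$residue_index), seq_len(n))) {
        gaps <- setdiff(seq_len(max(block$residue_index)),
                        block$residue_index)
        stop("protein '", prot, "', predictor '", pr,
             "': residue indices not a contiguous 1..N block",
             if (length(gaps)) paste0(" (missing: ",
                                      paste(gaps, collapse = ", "), ")"),
             call. = FALSE)
      }
      rule <- as.list(rules[rules$predictor == pr, ])
      if (pr == "waltz" && waltz_mode == "whole_sequence") {
        hit <- sum(block$value) > rule$threshold
        flags <- rep(as.integer(hit), n)
      } else {
        flags <- binarize(block$value, rule)
      }
      lens <- c(lens, n)
      flag_mat <- if (is.null(flag_mat)) matrix(flags, ncol = 1L) else {
        if (n != nrow(flag_mat)) {
          stop("protein '", prot, "': predictors disagree on protein ",
               "length (", paste(unique(c(nrow(flag_mat), n)),
                                 collapse = " vs "), ")", call. = FALSE)
        }
        cbind(flag_mat, flags)
      }
    }
    out[[prot]] <- data.frame(protein_id = prot,
                              residue_index = seq_len(nrow(flag_mat)),
                              score = as.integer(rowSums(flag_mat)))
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  attr(res, "predictors") <- unique(predictions$predictor)
  attr(res, "rules") <- rules
  attr(res, "waltz_mode") <- waltz_mode
  class(res) <- c("consensus_profile", "data.frame")
  res
}

#' Call segments with a given consensus score
#'
#' Returns the maximal runs of consecutive residues whose consensus score
#' equals `target_score`, as 1-based inclusive \[start, end\] ranges,
#' filtered to runs of at least `min_len` residues. With the full
#' five-predictor set, score-5 segments are the aggregation-prone calls
#' and score-0 segments the aggregation-free calls.
#'
#' @param scores Integer vector of per-residue consensus scores (one
#'   protein), or a `consensus_profile` row subset for one protein.
#' @param target_score Score to call segments for, in \[0, 5\].
#' @param min_len Minimum segment length (default 1).
#' @return Integer matrix with columns `start`, `end`; zero rows if no
#'   segment matches.
#' @examples
#' segments_with_score(c(5, 5, 5, 0, 0, 5), 5) # rows (1,3) and (6,6)
#' @export
segments_with_score <- function(scores, target_score, min_len = 1L) {
  if (is.data.frame(scores)) {
    if (length(unique(scores$protein_id)) > 1L) {
      stop("supply scores for a single protein", call. = FALSE)
    }
    scores <- scores$score[order(scores$residue_index)]
  }
  stopifnot(is.numeric(scores), min_len >= 1L)
  if (length(target_score) != 1L || target_score < 0 || target_score > 5) {
    stop("`target_score` must be a single value in [0, 5]", call. = FALSE)
  }
  r <- rle(scores == target_score)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  keep <- r$values & r$lengths >= min_len
  out <- cbind(start = starts[keep], end = ends[keep])
  storage.mode(out) <- "integer"
  out
}
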