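# shared fixture builders; everything is generated in code

# a straight trace along +x with n points spaced `step` nm apart
straight_trace <- function(n = 5, step = 100, id = "straight") {
  fibril_trace(id, cbind(seq(0, by = step, length.out = n), 0, 0))
}

# random rotation matrix (QR of a Gaussian matrix, det forced to +1)
random_rotation <- function() {
  qr_dec <- qr(matrix(rnorm(9), 3, 3))
  q <- qr.Q(qr_dec)
  if (det(q) < 0) q[, 1] <- -q[, 1]
  q
}

# random prediction table for one protein over all five predictors
random_prediction_table <- function(n_res = 20, protein = "p1") {
  rules <- default_predictor_rules()
  do.call(rbind, lapply(rules$predictor, function(pr) {
    data.frame(protein_id = protein, predictor = pr,
               residue_index = seq_len(n_res),
               value = rnorm(n_res))
  }))
}

# brute-force per-residue consensus count, independent of the package path
brute_force_consensus <- function(tab, rules = default_predictor_rules()) {
  n <- max(tab$residue_index)
  score <- integer(n)
  for (i in seq_len(n)) {
    for (pr in unique(tab$predictor)) {
      rule <- rules[rules$predictor == pr, ]
      vals <- tab$value[tab$predictor == pr][order(
        tab$residue_index[tab$predictor == pr])]
      hit <- if (rule$direction == "above") vals > rule$threshold
             else vals < rule$threshold
      if (rule$min_run > 1) {
        ok <- FALSE
        # residue i is kept iff it sits in a run of >= min_run hits
        for (s in max(1, i - rule$min_run + 1):i) {
          e <- s + rule$min_run - 1
          if (e <= n && all(hit[s:e])) { ok <- TRUE; break }
        }
        if (hit[i] && ok) score[i] <- score[i] + 1L
      } else if (hit[i]) {
        score[i] <- score[i] + 1L
      }
    }
  }
  score
}

# brute-force maximal runs of positions where x == target
brute_force_segments <- function(x, target) {
  hits <- which(x == target)
  if (!length(hits)) return(cbind(start = integer(0), end = integer(0)))
  breaks <- c(0, which(diff(hits) > 1), length(hits))
  t(vapply(seq_len(length(breaks) - 1), function(k) {
    c(start = hits[breaks[k] + 1], end = hits[breaks[k + 1]])
  }, integer(2)))
}
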