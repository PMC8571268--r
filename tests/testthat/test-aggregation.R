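test_that("thresholds are strict and run filtering follows the rules", {
  rules <- default_predictor_rules()
  tango <- as.list(rules[rules$predictor == "tango", ])
  # boundary is exclusive: values exactly at the threshold are not flagged
  expect_identical(binarize(rep(0.0, 6), tango), rep(0L, 6))
  expect_identical(binarize(c(-0.1, 0.001, 0), tango), c(0L, 1L, 0L))
  pasta <- as.list(rules[rules$predictor == "pasta", ])
  expect_identical(binarize(c(-2.8, -2.81, -1), pasta), c(0L, 1L, 0L))

  fa <- as.list(rules[rules$predictor == "foldamyloid", ])
  # run of 4 above threshold is below min_run = 5: all reset
  expect_identical(binarize(c(rep(0.07, 4), rep(0.05, 6)), fa), rep(0L, 10))
  # run of exactly 5 is kept whole
  expect_identical(binarize(c(rep(0.07, 5), rep(0.05, 5)), fa),
                   c(rep(1L, 5), rep(0L, 5)))
  expect_error(binarize(c(1, NA, 2), tango), "positions: 2")
})

test_that("binarize is monotone and run filtering never adds flags", {
  set.seed(301)
  rules <- default_predictor_rules()
  for (rep_i in 1:20) {
    vals <- rnorm(30, 0.06, 0.02)
    fa <- as.list(rules[rules$predictor == "foldamyloid", ])
    raw <- as.integer(if (fa$direction == "above") vals > fa$threshold
                      else vals < fa$threshold)
    filtered <- binarize(vals, fa)
    expect_true(all(filtered <= raw))
    # raising one value never lowers any flag before run filtering
    idx <- sample(30, 1)
    bumped <- vals; bumped[idx] <- bumped[idx] + 0.05
    fa1 <- fa; fa1$min_run <- 1L
    expect_true(all(binarize(bumped, fa1) >= binarize(vals, fa1)))
  }
})

test_that("consensus equals the brute-force predictor count", {
  all_zero <- random_prediction_table(10)
  all_zero$value <- ifelse(all_zero$predictor == "pasta", 10, -10)
  expect_identical(consensus_score(all_zero)$score, rep(0L, 10))
  all_one <- random_prediction_table(10)
  all_one$value <- ifelse(all_one$predictor == "pasta", -10, 10)
  expect_identical(consensus_score(all_one)$score, rep(5L, 10))

  set.seed(302)
  for (rep_i in 1:10) {
    tab <- random_prediction_table(25)
    prof <- consensus_score(tab)
    expect_identical(prof$score, brute_force_consensus(tab))
    expect_true(all(prof$score >= 0 & prof$score <= 5))
    expect_equal(nrow(prof), 25)
  }
})

test_that("consensus validates its input table", {
  tab <- random_prediction_table(10)
  tab$predictor[1] <- "zipper"
  expect_error(consensus_score(tab), "unknown predictor")

  tab2 <- random_prediction_table(10)
  tab2 <- tab2[!(tab2$predictor == "tango" & tab2$residue_index == 4), ]
  expect_error(consensus_score(tab2), "contiguous")

  tab3 <- random_prediction_table(10)
  tab3 <- rbind(tab3, tab3[1, ])
  expect_error(consensus_score(tab3), "duplicate")

  tab4 <- random_prediction_table(10)
  tab4 <- tab4[!(tab4$predictor == "waltz" & tab4$residue_index == 10), ]
  expect_error(consensus_score(tab4), "length|contiguous")
})

test_that("whole-sequence WALTZ mode flags all residues or none", {
  tab <- random_prediction_table(8)
  tab$value <- ifelse(tab$predictor == "waltz", -1, 10)
  tab$value[tab$predictor == "pasta"] <- -10
  per_res <- consensus_score(tab)
  expect_identical(per_res$score, rep(4L, 8))
  tab$value[tab$predictor == "waltz"] <- c(5, rep(-0.1, 7))
  whole <- consensus_score(tab, waltz_mode = "whole_sequence")
  expect_identical(whole$score, rep(5L, 8))  # sum 4.3 > 0 flags everything
})

test_that("segment calling matches a brute-force run scan", {
  expect_equal(segments_with_score(c(5, 5, 5, 0, 0, 5), 5),
               cbind(start = c(1L, 6L), end = c(3L, 6L)))
  expect_equal(nrow(segments_with_score(rep(0, 5), 5)), 0)
  expect_equal(segments_with_score(c(0, 0, 1, 0), 0),
               cbind(start = c(1L, 4L), end = c(2L, 4L)))
  expect_equal(segments_with_score(c(5, 0, 5, 5, 5, 0), 5, min_len = 2),
               cbind(start = 3L, end = 5L))
  expect_error(segments_with_score(c(1, 2), 7), "\\[0, 5\\]")

  set.seed(303)
  for (rep_i in 1:20) {
    x <- sample(0:5, 40, replace = TRUE)
    tgt <- sample(0:5, 1)
    got <- segments_with_score(x, tgt)
    want <- brute_force_segments(x, tgt)
    expect_equal(unname(got), unname(want))
    # segments are sorted and non-overlapping
    if (nrow(got) > 1) expect_true(all(diff(got[, "start"]) > 0) &&
                                     all(got[-1, "start"] > got[-nrow(got), "end"]))
  }
})

test_that("score-5 and score-0 segment sets are disjoint", {
  set.seed(304)
  tab <- random_prediction_table(60)
  prof <- consensus_score(tab)
  seg5 <- segments_with_score(prof, 5)
  seg0 <- segments_with_score(prof, 0)
  res5 <- unlist(apply(seg5, 1, function(r) seq(r[1], r[2])))
  res0 <- unlist(apply(seg0, 1, function(r) seq(r[1], r[2])))
  expect_length(intersect(res5, res0), 0)
})
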