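test_that("FOR001 printed annotation yields the published statistics", {
  ann <- for001_annotation()
  # two ordered segments, residues 9-52 and 68-108, of a 118-residue chain
  expect_equal(ordered_fraction(ann), 85 / 118)
  mio <- mutations_in_ordered(ann)
  expect_equal(mio$count, 5)
  expect_equal(mio$n_total, 6)
  expect_equal(mio$fraction, 5 / 6)
})

test_that("ordered fraction handles edge cases and split ranges", {
  expect_equal(ordered_fraction(core_annotation("full", 50,
                                                list(c(1, 50)), 1)), 1)
  expect_equal(ordered_fraction(core_annotation("none", 50,
                                                mutation_positions = 1)), 0)
  # splitting a range into adjacent subranges leaves the fraction unchanged
  whole <- core_annotation("w", 100, list(c(10, 60)), 5)
  split <- core_annotation("s", 100, list(c(10, 30), c(31, 60)), 5)
  expect_equal(ordered_fraction(split), ordered_fraction(whole))
})

test_that("annotation invariants are enforced", {
  expect_error(core_annotation("x", 100, list(c(50, 40))), "invalid")
  expect_error(core_annotation("x", 100, list(c(0, 10))), "invalid")
  expect_error(core_annotation("x", 100, list(c(90, 110))), "invalid")
  expect_error(core_annotation("x", 100, list(c(1, 20), c(15, 30))),
               "overlap")
  expect_error(core_annotation("x", 100, mutation_positions = 101),
               "outside")
  expect_error(core_annotation("x", 5, sequence = "ACDE"),
               "does not match")
  expect_error(mutations_in_ordered(core_annotation("x", 10,
                                                    list(c(1, 5)))),
               "no mutations")
})

test_that("mutation membership equals brute-force counting", {
  set.seed(401)
  for (rep_i in 1:20) {
    n <- 200
    starts <- sort(sample(n, 3))
    ranges <- list()
    prev_end <- 0
    for (s in starts) {
      if (s <= prev_end) next
      e <- min(n, s + sample(0:30, 1))
      ranges[[length(ranges) + 1]] <- c(s, e)
      prev_end <- e
    }
    muts <- sample(n, 8)
    ann <- core_annotation("r", n, ranges, muts)
    inside <- sum(vapply(sort(unique(muts)), function(m) {
      any(vapply(ranges, function(r) m >= r[1] && m <= r[2], logical(1)))
    }, logical(1)))
    expect_equal(mutations_in_ordered(ann)$count, inside)
  }
})

test_that("aggregate statistics use the sample SD and match naive math", {
  a <- core_annotation("a", 10, list(c(1, 5)), c(2, 7))   # of 0.5, mf 0.5
  b <- core_annotation("b", 10, list(c(1, 10)), c(2, 7))  # of 1.0, mf 1.0
  st <- aggregate_stats(list(a, b))
  expect_equal(st$aggregate$mean_ordered_fraction, 0.75)
  expect_equal(st$aggregate$sd_ordered_fraction, sd(c(0.5, 1.0)))
  expect_equal(st$aggregate$sd_ordered_fraction, 0.3536, tolerance = 1e-3)
  expect_equal(st$aggregate$ordered_percent, 75)
  # two identical annotations give SD exactly zero
  st2 <- aggregate_stats(list(for001_annotation(), for001_annotation()))
  expect_equal(st2$aggregate$sd_ordered_fraction, 0)
  expect_equal(st2$aggregate$sd_mut_ordered_fraction, 0)
  expect_equal(st2$aggregate$mut_ordered_percent, 83)
  # single annotation: mean defined, SD flagged undefined
  st1 <- aggregate_stats(list(for001_annotation()))
  expect_equal(st1$aggregate$ordered_percent, 72)
  expect_true(is.na(st1$aggregate$sd_ordered_fraction))
})

test_that("extinction coefficient counts Trp/Tyr/cystine additively", {
  expect_equal(extinction_coefficient("ACDEFG"), 0)
  expect_equal(extinction_coefficient("WYY"), 5500 + 2 * 1490)
  expect_equal(extinction_coefficient("WYY", n_disulfides = 2),
               5500 + 2 * 1490 + 2 * 125)
  coefs <- c(W = 100, Y = 10, SS = 1)
  expect_equal(extinction_coefficient("WWY", coefficients = coefs), 210)
  # additive under concatenation at fixed disulfides
  set.seed(402)
  aa <- strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]]
  for (rep_i in 1:10) {
    s1 <- paste(sample(aa, 15, replace = TRUE), collapse = "")
    s2 <- paste(sample(aa, 9, replace = TRUE), collapse = "")
    expect_equal(extinction_coefficient(paste0(s1, s2)),
                 extinction_coefficient(s1) + extinction_coefficient(s2))
  }
  expect_error(extinction_coefficient("AXZ"), "unknown residue")
})
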