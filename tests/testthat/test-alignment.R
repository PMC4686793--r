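test_that("count-algebra totals are Delannoy numbers", {
  s <- scoring_scheme("count")
  for (n in 0:4) for (m in 0:4) {
    x <- strrep("A", n); y <- strrep("C", m)
    expect_equal(nw_inside_outside(x, y, s)$Z, delannoy(n, m),
                 info = paste(n, m))
    expect_equal(gotoh_inside(x, y, s)$Z, delannoy(n, m),
                 info = paste(n, m))
  }
  expect_equal(nw_inside_outside("AACGTG", "ACGTGA", s)$Z, delannoy(6, 6))
  # empty input: the single eps-parse
  t0 <- nw_inside_outside("", "", s)
  expect_equal(t0$A[1, 1], 1)
  expect_equal(t0$Z, 1)
  expect_equal(gotoh_inside("", "", s)$Z, 1)
})

test_that("outside corner and inside corner agree with the total", {
  s <- scoring_scheme("partition")
  t1 <- nw_inside_outside("GATTACA", "GCATGC", s)
  expect_equal(t1$Astar[1, 1], t1$Z, tolerance = 1e-12)
  gi <- gotoh_inside("GATTACA", "GCATGC", s)
  go <- gotoh_outside("GATTACA", "GCATGC", s, gi)
  # all three states receive the neutral start weight at the (n, m) corner
  expect_equal(go$Mstar[8, 7], 1)
  expect_equal(go$Dstar[8, 7], 1)
  expect_equal(go$Istar[8, 7], 1)
  expect_equal(go$Z_outside, gi$Z, tolerance = 1e-12)
})

test_that("optimize mode reproduces unit-cost edit distance", {
  s <- scoring_scheme("optimize", match = 0, mismatch = 1, gap = 1,
                      objective = "min")
  set.seed(3)
  for (rep in 1:10) {
    x <- paste(sample(c("A", "C", "G", "T"), sample(0:6, 1), TRUE), collapse = "")
    y <- paste(sample(c("A", "C", "G", "T"), sample(1:6, 1), TRUE), collapse = "")
    expect_equal(nw_inside_outside(x, y, s)$Z, edit_distance(x, y),
                 info = paste(x, y))
  }
})

test_that("affine gaps collapse to linear gaps when open equals extend", {
  set.seed(11)
  for (rep in 1:8) {
    x <- paste(sample(c("A", "C", "G", "T"), sample(1:6, 1), TRUE), collapse = "")
    y <- paste(sample(c("A", "C", "G", "T"), sample(1:6, 1), TRUE), collapse = "")
    s_nw <- scoring_scheme("optimize", gap = -2)
    s_go <- scoring_scheme("optimize", gap_open = -2, gap_extend = -2)
    expect_equal(gotoh_inside(x, y, s_go)$Z, nw_inside_outside(x, y, s_nw)$Z,
                 info = paste(x, y))
  }
})

test_that("single-character ensemble matches the three-alignment closed form", {
  s <- scoring_scheme("partition", match = 1, gap_open = -2, gap_extend = -1)
  wm <- exp(1); wg <- exp(-2)
  gi <- gotoh_inside("A", "A", s)
  go <- gotoh_outside("A", "A", s, gi)
  expect_equal(gi$Z, wm + 2 * wg^2, tolerance = 1e-12)
  expect_equal(match_posterior(go)[1, 1], wm / (wm + 2 * wg^2),
               tolerance = 1e-12)
})

test_that("match posteriors equal Boltzmann frequencies from exhaustive enumeration", {
  set.seed(23)
  cases <- list(c("ACG", "AG"), c("GATT", "GAT"), c("ACGTA", "ACG"),
                c("TTT", "TAT"), c("AC", "CA"))
  s <- scoring_scheme("partition", match = 1, mismatch = -1,
                      gap_open = -1.5, gap_extend = -0.5, RT = 1)
  for (cs in cases) {
    oracle <- gotoh_ensemble_oracle(cs[1], cs[2], s)
    expect_equal(oracle$n_alignments, delannoy(nchar(cs[1]), nchar(cs[2])))
    gi <- gotoh_inside(cs[1], cs[2], s)
    go <- gotoh_outside(cs[1], cs[2], s, gi)
    expect_equal(gi$Z, oracle$Z, tolerance = 1e-10)
    P <- match_posterior(go)
    expect_equal(unname(P), oracle$P, tolerance = 1e-10)
    expect_true(all(rowSums(P) <= 1 + 1e-9))
    expect_true(all(colSums(P) <= 1 + 1e-9))
  }
})

test_that("inside-outside sums across every anti-diagonal cut reproduce Z", {
  s <- scoring_scheme("partition", gap_open = -2, gap_extend = -1)
  x <- "GATTA"; y <- "GCAT"
  gi <- gotoh_inside(x, y, s)
  go <- gotoh_outside(x, y, s, gi)
  for (c in 0:(nchar(x) + nchar(y))) {
    expect_equal(antidiagonal_cut_sum(go, c), gi$Z, tolerance = 1e-10,
                 info = paste("cut", c))
  }
  t_nw <- nw_inside_outside(x, y, s)
  for (c in 0:(nchar(x) + nchar(y))) {
    expect_equal(antidiagonal_cut_sum(t_nw, c), t_nw$Z, tolerance = 1e-10,
                 info = paste("nw cut", c))
  }
})

test_that("posterior matrix respects reversal of both sequences", {
  s <- scoring_scheme("partition", gap_open = -2, gap_extend = -1)
  x <- "GATTAC"; y <- "GCAT"
  revs <- function(z) paste(rev(strsplit(z, "")[[1]]), collapse = "")
  gi <- gotoh_inside(x, y, s); go <- gotoh_outside(x, y, s, gi)
  gir <- gotoh_inside(revs(x), revs(y), s)
  gor <- gotoh_outside(revs(x), revs(y), s, gir)
  P <- match_posterior(go); Pr <- match_posterior(gor)
  expect_equal(unname(P), unname(Pr[nrow(Pr):1, ncol(Pr):1]), tolerance = 1e-12)
})

test_that("posteriors concentrate on the diagonal for identical sequences at strong match reward", {
  s <- scoring_scheme("partition", match = 40, mismatch = -40,
                      gap_open = -40, gap_extend = -40)
  P <- match_posterior(gotoh_outside("ACGT", "ACGT", s,
                                     gotoh_inside("ACGT", "ACGT", s)))
  expect_equal(unname(diag(P)), rep(1, 4), tolerance = 1e-10)
})

test_that("non-partition tables are rejected by match_posterior", {
  s <- scoring_scheme("count")
  expect_error(match_posterior(nw_inside_outside("A", "A", s)), "partition")
  gi <- gotoh_inside("A", "A", s)
  expect_error(gotoh_outside("A", "C", s, gi), "different sequences")
})

test_that("the numeric Gotoh outside recursion is the derived outside grammar", {
  # the engine implements exactly the mechanically derived rule set
  go <- derive_outside(grammar_gotoh())
  expected <- sort(c(
    "ee* -> M*", "ee* -> D*", "ee* -> I*",
    "M* -> M* uv", "M* -> D* u-", "M* -> I* -v", "M* -> S*",
    "D* -> M* uv", "D* -> D* u.", "D* -> I* -v", "D* -> S*",
    "I* -> M* uv", "I* -> D* u-", "I* -> I* .v", "I* -> S*"))
  expect_identical(grammar_rules(go), expected)
})
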