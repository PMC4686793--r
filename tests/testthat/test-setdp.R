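test_that("distance matrix validation", {
  m <- matrix(c(0, 1, 1, 0), 2, 2)
  expect_s3_class(distance_matrix(m), "distance_matrix")
  expect_error(distance_matrix(matrix(1:6, 2, 3)), "square")
  expect_error(distance_matrix(matrix(c(0, -1, -1, 0), 2, 2)), "nonnegative")
  bad <- matrix(c(0, 1, 3, 0), 2, 2)
  expect_error(distance_matrix(bad), "asymmetric at")
  expect_silent(distance_matrix(bad, require_symmetric = FALSE))
})

test_that("Held-Karp: two vertices and the brute-force optimum", {
  d2 <- matrix(c(0, 3, 5, 0), 2, 2, byrow = TRUE)
  hk <- held_karp(distance_matrix(d2, require_symmetric = FALSE))
  expect_equal(hk$tour, c(1L, 2L))
  expect_equal(hk$length, 8)
  set.seed(31)
  for (n in c(4, 5, 6, 7, 8, 9)) {
    d <- random_symmetric_d(n)
    hk <- held_karp(d)
    expect_equal(hk$length, brute_force_tour(d), tolerance = 1e-10,
                 info = paste("n =", n))
    expect_setequal(hk$tour, seq_len(n))
    # the reported tour realizes the reported length
    ord <- hk$tour
    expect_equal(sum(d[cbind(ord, c(ord[-1], ord[1]))]), hk$length,
                 tolerance = 1e-10)
  }
  # asymmetric input is allowed for tours
  set.seed(32)
  da <- matrix(runif(25, 1, 9), 5, 5); diag(da) <- 0
  hk <- held_karp(distance_matrix(da, require_symmetric = FALSE))
  perms <- function(v) {
    if (length(v) <= 1) return(matrix(v, 1))
    out <- NULL
    for (k in seq_along(v)) out <- rbind(out, cbind(v[k], perms(v[-k])))
    out
  }
  pp <- perms(2:5)
  lens <- apply(pp, 1, function(r) {
    ord <- c(1, r); sum(da[cbind(ord, c(ord[-1], 1))])
  })
  expect_equal(hk$length, min(lens), tolerance = 1e-10)
})

test_that("Held-Karp ties: uniform distances give length n*c and a deterministic tour", {
  d <- distance_matrix(3 * (matrix(1, 6, 6) - diag(6)))
  hk1 <- held_karp(d)
  hk2 <- held_karp(d)
  expect_equal(hk1$length, 6 * 3)
  expect_identical(hk1$tour, hk2$tour)
  expect_error(held_karp(random_symmetric_d(5), cap = 4), "exceeds the cap")
})

test_that("path enumeration oracle: counts and minima", {
  d3 <- random_symmetric_d(3)
  expect_equal(nrow(enumerate_hamiltonian_paths(d3)$paths), 3L)
  d4 <- random_symmetric_d(4)
  expect_equal(nrow(enumerate_hamiltonian_paths(d4)$paths), 12L)  # 4!/2
  set.seed(37)
  for (n in 4:7) {
    d <- random_symmetric_d(n)
    or <- enumerate_hamiltonian_paths(d)
    opt <- shp_optimal_path(d)
    expect_equal(opt$length, min(or$lengths), tolerance = 1e-10)
    expect_equal(sum(d[cbind(opt$path[-n], opt$path[-1])]), opt$length,
                 tolerance = 1e-10)
  }
})

test_that("count algebra totals the unordered Hamiltonian paths", {
  d4 <- distance_matrix(matrix(1, 4, 4) - diag(4))
  ci <- shp_inside(d4, algebra = "count")
  # (n-2)! paths per endpoint pair; n!/2 in total
  expect_true(all(ci$Z_pq[upper.tri(ci$Z_pq)] == 2))
  expect_equal(ci$Z_total, 12)
  expect_equal(ci$Z_total, nrow(enumerate_hamiltonian_paths(d4)$paths))
})

test_that("three-vertex closed forms", {
  set.seed(41)
  d <- random_symmetric_d(3)
  par <- ensemble_params(d, T = 0.8)
  ins <- shp_inside(d, par, "partition")
  # with endpoints p, q fixed the middle vertex is forced
  full <- 2^3
  expect_equal(ins$Z_pq[1, 3], exp(-par$alpha * (d[1, 2] + d[2, 3])),
               tolerance = 1e-12)
  ens <- shp_ensemble(d, par)
  expect_equal(ens$conditional(1, 3)[1, 2], 1, tolerance = 1e-12)
  expect_equal(ens$conditional(1, 3)[1, 3], 0)
  # uniform distances: every adjacency has unconditional probability 2/3
  du <- distance_matrix(matrix(2, 3, 3) - 2 * diag(3))
  eu <- shp_ensemble(du, ensemble_params(du, T = 1))
  off <- eu$adjacency[upper.tri(eu$adjacency)]
  expect_equal(off, rep(2 / 3, 3), tolerance = 1e-12)
  expect_equal(sum(off), 3 - 1, tolerance = 1e-12)
})

test_that("outside tables: base case and split consistency", {
  set.seed(43)
  d <- random_symmetric_d(6)
  par <- ensemble_params(d, T = 0.5)
  ins <- shp_inside(d, par, "partition")
  outs <- shp_outside(d, par, ins)
  n <- 6
  # base case: a two-element complement is the single closing edge
  for (j in 1:(n - 1)) for (q in (j + 1):n) {
    mask <- bitwOr(bitwShiftL(1L, j - 1L), bitwShiftL(1L, q - 1L))
    expect_equal(outs$Z[mask + 1, j, q], exp(-par$alpha * d[j, q]),
                 tolerance = 1e-12)
  }
  # combining inside [p, A, i] with outside [i, (V \ A) + i, q] at every
  # split cardinality reproduces Z_pq
  masks <- 0:(2^n - 1)
  pc <- vapply(masks, function(m)
    sum(bitwAnd(m, bitwShiftL(1L, 0:(n - 1))) != 0L), numeric(1))
  for (p in c(1, 2)) for (q in c(4, 6)) {
    for (size in 1:n) {
      tot <- 0
      for (mask in masks[pc == size]) {
        if (bitwAnd(mask, bitwShiftL(1L, p - 1L)) == 0L) next
        comp <- 2^n - 1 - mask
        for (i in seq_len(n)) {
          if (bitwAnd(mask, bitwShiftL(1L, i - 1L)) == 0L) next
          omask <- comp + bitwShiftL(1L, i - 1L)
          tot <- tot + ins$Z[mask + 1, p, i] * outs$Z[omask + 1, i, q]
        }
      }
      expect_equal(tot, ins$Z_pq[p, q], tolerance = 1e-10,
                   info = paste("p", p, "q", q, "size", size))
    }
  }
  # count algebra: inside x outside over complementary splits totals the
  # per-endpoint-pair path counts
  insc <- shp_inside(d, par, "count")
  outsc <- shp_outside(d, par, insc)
  expect_equal(insc$Z_pq[1, 2], factorial(n - 2))
  tot <- 0
  half <- masks[pc == 3]
  for (mask in half) {
    if (bitwAnd(mask, 1L) == 0L) next   # p = 1 must lie in A
    comp <- 2^n - 1 - mask
    if (bitwAnd(comp, bitwShiftL(1L, 1L)) == 0L) next  # q = 2 in complement
    for (i in seq_len(n)) {
      if (bitwAnd(mask, bitwShiftL(1L, i - 1L)) == 0L) next
      omask <- comp + bitwShiftL(1L, i - 1L)
      tot <- tot + insc$Z[mask + 1, 1, i] * outsc$Z[omask + 1, i, 2]
    }
  }
  expect_equal(tot, factorial(n - 2))
})

test_that("ensemble posteriors equal enumeration frequencies across temperatures", {
  set.seed(47)
  for (n in c(5, 6, 8)) {
    d <- random_symmetric_d(n)
    for (Tv in c(0.01, 0.1, 1, 10)) {
      par <- ensemble_params(d, T = Tv)
      ens <- shp_ensemble(d, par)
      oracle <- shp_ensemble_oracle(d, par)
      expect_equal(ens$Z_total, oracle$Z, tolerance = 1e-9)
      expect_equal(unname(unclass(ens$adjacency)), oracle$adjacency,
                   tolerance = 1e-9, info = paste("n", n, "T", Tv))
      expect_equal(unname(ens$endpoint), oracle$endpoint, tolerance = 1e-9)
      expect_equal(unname(unclass(ens$endpoint_pair)), oracle$endpoint_pair,
                   tolerance = 1e-9)
      # normalizations
      expect_equal(sum(ens$endpoint_pair[upper.tri(ens$endpoint_pair)]), 1,
                   tolerance = 1e-9)
      expect_equal(sum(ens$endpoint), 2, tolerance = 1e-9)
      expect_equal(sum(ens$adjacency[upper.tri(ens$adjacency)]), n - 1,
                   tolerance = 1e-9)
    }
  }
})

test_that("uniform distances give endpoint probability 2/n for every vertex", {
  for (n in c(4, 6)) {
    du <- distance_matrix(matrix(5, n, n) - 5 * diag(n))
    ens <- shp_ensemble(du, ensemble_params(du, T = 2))
    expect_equal(unname(ens$endpoint), rep(2 / n, n), tolerance = 1e-12)
  }
})

test_that("temperature limits: uniform adjacencies at T -> Inf, concentration at T -> 0", {
  set.seed(53)
  d <- random_symmetric_d(6)
  n <- 6
  # T -> Inf: every pair has adjacency probability (n - 1) / choose(n, 2) = 2/n
  hot <- shp_ensemble(d, ensemble_params(d, T = 1e6))
  off <- hot$adjacency[upper.tri(hot$adjacency)]
  expect_equal(off, rep(2 / n, choose(n, 2)), tolerance = 1e-3)
  # T -> 0: all adjacency mass sits on the optimal path's edges
  cold <- shp_ensemble(d, ensemble_params(d, T = 1e-4))
  opt <- shp_optimal_path(d)
  on_path <- matrix(FALSE, n, n)
  for (t in 1:(n - 1)) {
    on_path[opt$path[t], opt$path[t + 1]] <- TRUE
    on_path[opt$path[t + 1], opt$path[t]] <- TRUE
  }
  expect_equal(unname(unclass(cold$adjacency))[on_path],
               rep(1, 2 * (n - 1)), tolerance = 1e-6)
  expect_true(all(cold$adjacency[!on_path & upper.tri(on_path)] < 1e-6))
  # and the endpoint mass on the optimal endpoints
  ends <- sort(c(opt$path[1], opt$path[n]))
  expect_equal(cold$endpoint_pair[ends[1], ends[2]], 1, tolerance = 1e-6)
})

test_that("Robinson matrices are solved by the identity order", {
  set.seed(59)
  for (n in c(5, 8, 10)) {
    d <- synthesize_cluster(n, noise = 0, seed = n)
    expect_true(is_robinson(d))
    opt <- shp_optimal_path(d)
    expect_identical(opt$path, seq_len(n))
  }
})

test_that("asymmetric input is rejected by the path ensemble", {
  da <- matrix(c(0, 1, 2, 0), 2, 2)
  expect_error(shp_inside(distance_matrix(da, require_symmetric = FALSE)),
               "asymmetric")
  expect_error(shp_inside(random_symmetric_d(5), cap = 4), "exceeds the cap")
})
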