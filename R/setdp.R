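#' Distance (dissimilarity) matrix
#'
#' @param d Square numeric matrix of nonnegative dissimilarities with zero
#'   diagonal.
#' @param labels Optional vertex names (default: rownames or `V1..Vn`).
#' @param require_symmetric Reject asymmetric input (the Hamiltonian-path
#'   ensemble assumes undirected paths; Held-Karp accepts asymmetric input).
#' @param tol Symmetry tolerance.
#' @return A matrix of class `distance_matrix` with `labels` as dimnames.
#' @export
distance_matrix <- function(d, labels = NULL, require_symmetric = TRUE,
                            tol = 1e-8) {
  d <- as.matrix(d)
  n <- nrow(d)
  if (ncol(d) != n) stop("distance matrix must be square")
  if (any(d < 0)) stop("distances must be nonnegative")
  if (any(abs(diag(d)) > tol)) stop("diagonal must be zero")
  diag(d) <- 0
  if (require_symmetric) {
    delta <- abs(d - t(d))
    if (any(delta > tol)) {
      ij <- which(delta == max(delta), arr.ind = TRUE)[1, ]
      stop(sprintf("matrix is asymmetric at (%d, %d): %g vs %g",
                   ij[1], ij[2], d[ij[1], ij[2]], d[ij[2], ij[1]]))
    }
    d <- (d + t(d)) / 2
  }
  if (is.null(labels)) labels <- rownames(d)
  if (is.null(labels)) labels <- paste0("V", seq_len(n))
  dimnames(d) <- list(labels, labels)
  class(d) <- c("distance_matrix", "matrix")
  d
}

#' Boltzmann-ensemble parameters for path statistics
#'
#' Paths `pi` are weighted `exp(-l(pi) / (R T))` where `l` is the path
#' length, `T` a fictitious unitless temperature and `R` a normalization in
#' distance units, by default `R = (n - 1) * dbar` with `dbar` the mean
#' off-diagonal dissimilarity (over distinct unordered pairs). `T -> 0`
#' concentrates the ensemble on the (co)optimal paths; `T -> infinity` makes
#' all paths equally likely.
#'
#' @param d A [distance_matrix()].
#' @param T Temperature (> 0).
#' @param R Normalization constant; default `(n - 1) * dbar`.
#' @return A list of class `ensemble_params` with `T`, `R`, `alpha = 1/(R T)`.
#' @export
ensemble_params <- function(d, T = 1, R = NULL) {
  stopifnot(T > 0)
  n <- nrow(d)
  if (is.null(R)) {
    dbar <- mean(d[upper.tri(d)])
    R <- (n - 1) * dbar
  }
  stopifnot(R > 0)
  structure(list(T = T, R = R, alpha = 1 / (R * T)), class = "ensemble_params")
}

setdp_algebra <- function(algebra) {
  switch(algebra,
    partition = list(zero = 0, one = 1, plus = `+`, times = `*`),
    count = list(zero = 0, one = 1, plus = `+`, times = `*`),
    min = list(zero = Inf, one = 0, plus = pmin, times = `+`))
}

setdp_weights <- function(d, params, algebra) {
  switch(algebra,
    partition = exp(-params$alpha * d),
    count = matrix(1, nrow(d), ncol(d)),
    min = unclass(d))
}

bit <- function(v) bitwShiftL(1L, v - 1L)

mask_members <- function(mask, n) which(bitwAnd(mask, bit(seq_len(n))) != 0L)

masks_by_popcount <- function(n) {
  masks <- 0:(2^n - 1)
  pc <- vapply(masks, function(m) sum(bitwAnd(m, bit(seq_len(n))) != 0L),
               numeric(1))
  split(masks, pc)
}

#' Exact travelling-salesman tour by subset dynamic programming
#'
#' Held-Karp recursion over sets with an interface: `f([A, i])`, the length
#' of the shortest path that starts at vertex 1, visits every vertex of `A`
#' and ends in `i`, satisfies
#' `f([A, i]) = min_j f([A \\ i, j]) + d(j, i)`. The optimal tour closes the
#' best path back to vertex 1. Asymmetric matrices are allowed. Runtime and
#' memory are `O(n^2 2^n)` / `O(n 2^n)`.
#'
#' @param d A square distance matrix (class `distance_matrix` or plain
#'   matrix; asymmetry is permitted here).
#' @param cap Refuse instances larger than this (memory guard).
#' @return List with `tour` (vertex order starting at 1) and `length`.
#' @export
held_karp <- function(d, cap = 20L) {
  d <- as.matrix(d)
  n <- nrow(d)
  if (n < 2) stop("need at least two vertices")
  if (n > cap) stop("instance size ", n, " exceeds the cap (", cap, ")")
  if (n == 2) return(list(tour = c(1L, 2L), length = d[1, 2] + d[2, 1]))
  m <- n - 1L                       # subsets over vertices 2..n
  rest <- 2:n
  f <- matrix(Inf, 2^m, m)          # f[mask + 1, i]: path 1 -> rest[i] via mask
  for (i in seq_len(m)) f[bit(i) + 1L, i] <- d[1, rest[i]]
  groups <- masks_by_popcount(m)
  for (size in 2:m) {
    for (mask in groups[[as.character(size)]]) {
      mem <- mask_members(mask, m)
      for (i in mem) {
        prev <- mask - bit(i)
        pm <- mask_members(prev, m)
        f[mask + 1L, i] <- min(f[prev + 1L, pm] + d[rest[pm], rest[i]])
      }
    }
  }
  full <- 2^m - 1L
  closing <- f[full + 1L, ] + d[rest, 1]
  len <- min(closing)
  # backtrace from the end, preferring the smallest vertex index on ties
  i <- which(closing == len)[1]
  order_rev <- integer(m)
  mask <- full
  for (k in m:1) {
    order_rev[k] <- rest[i]
    prev <- mask - bit(i)
    if (k == 1) break
    pm <- mask_members(prev, m)
    vals <- f[prev + 1L, pm] + d[rest[pm], rest[i]]
    i <- pm[which(abs(vals - f[mask + 1L, i]) <= 1e-9 * max(1, abs(vals)))[1]]
    mask <- prev
  }
  tour <- c(1L, order_rev)
  # canonical orientation: second element smaller than last
  if (tour[2] > tour[n]) tour <- c(1L, rev(tour[-1]))
  list(tour = tour, length = len)
}

#' Inside tables over punctuated sets (Hamiltonian paths)
#'
#' For every reachable punctuated set `[i, A, j]` (a vertex subset `A` with
#' distinguished endpoints `i, j` in `A`) the table evaluates all Hamiltonian
#' paths on `A` from `i` to `j` under the chosen algebra: minimum length,
#' path count, or the Boltzmann sum `sum exp(-alpha * l)`. Singletons
#' `[i, {i}, i]` hold the neutral value; the recursion splits one boundary
#' vertex off the `j` end (`A -> A v`). Paths are undirected: tables are
#' symmetric in `(i, j)` and a symmetric distance matrix is required.
#'
#' @param d A symmetric [distance_matrix()].
#' @param params An [ensemble_params()] (used by the partition algebra).
#' @param algebra `"partition"`, `"count"` or `"min"`.
#' @param cap Size guard: tables take `O(n^2 2^n)` memory.
#' @return A list of class `shp_tables` with the 3-d array
#'   `Z[mask + 1, i, j]`, `Z_pq` (endpoint-pair values on the full set),
#'   `Z_total` (choice over all endpoint pairs), `algebra`, `params`. The
#'   partition algebra is evaluated in log space (robust down to `T -> 0`);
#'   its log tables are attached as `logZ`, `log_Z_pq`, `log_Z_total`, with
#'   `Z` etc. their exponentials.
#' @export
shp_inside <- function(d, params = ensemble_params(d),
                       algebra = c("partition", "count", "min"), cap = 16L) {
  algebra <- match.arg(algebra)
  d <- distance_matrix(d, require_symmetric = TRUE)
  n <- nrow(d)
  if (n < 2) stop("need at least two vertices")
  if (n > cap) stop("instance size ", n, " exceeds the cap (", cap, ")")
  full <- 2^n - 1L
  groups <- masks_by_popcount(n)
  if (algebra == "partition") {
    lw <- -params$alpha * unclass(d)     # log edge weights
    L <- array(-Inf, dim = c(2^n, n, n))
    for (i in seq_len(n)) L[bit(i) + 1L, i, i] <- 0
    for (size in 2:n) {
      for (mask in groups[[as.character(size)]]) {
        mem <- mask_members(mask, n)
        for (j in mem) {
          prev <- mask - bit(j)
          pm <- mask_members(prev, n)
          np <- length(pm)
          X <- matrix(L[prev + 1L, pm, pm], np, np) +
            matrix(lw[pm, j], np, np, byrow = TRUE)
          m <- apply(X, 1, max)
          vals <- m + log(rowSums(exp(X - m)))
          vals[is.infinite(m) & m < 0] <- -Inf
          L[mask + 1L, pm, j] <- vals
        }
      }
    }
    log_Zpq <- L[full + 1L, , ]
    dimnames(log_Zpq) <- dimnames(d)
    lv <- log_Zpq[upper.tri(log_Zpq)]
    m <- max(lv)
    log_Z_total <- m + log(sum(exp(lv - m)))
    return(structure(list(Z = exp(L), logZ = L, Z_pq = exp(log_Zpq),
                          log_Z_pq = log_Zpq, Z_total = exp(log_Z_total),
                          log_Z_total = log_Z_total, algebra = algebra,
                          params = params, d = d, n = n),
                     class = "shp_tables"))
  }
  alg <- setdp_algebra(algebra)
  w <- setdp_weights(d, params, algebra)
  Z <- array(alg$zero, dim = c(2^n, n, n))
  for (i in seq_len(n)) Z[bit(i) + 1L, i, i] <- alg$one
  for (size in 2:n) {
    for (mask in groups[[as.character(size)]]) {
      mem <- mask_members(mask, n)
      for (j in mem) {
        prev <- mask - bit(j)
        pm <- mask_members(prev, n)
        np <- length(pm)
        sub <- matrix(Z[prev + 1L, pm, pm], np, np)   # [i, k]
        vals <- if (algebra == "min") {
          apply(sub + matrix(w[pm, j], np, np, byrow = TRUE), 1, min)
        } else {
          sub %*% w[pm, j]
        }
        Z[mask + 1L, pm, j] <- vals
      }
    }
  }
  Zpq <- Z[full + 1L, , ]
  dimnames(Zpq) <- dimnames(d)
  vals <- Zpq[upper.tri(Zpq)]
  Z_total <- if (algebra == "min") min(vals) else sum(vals)
  structure(list(Z = Z, logZ = NULL, Z_pq = Zpq, Z_total = Z_total,
                 algebra = algebra, params = params, d = d, n = n),
            class = "shp_tables")
}

#' Outside tables over punctuated sets
#'
#' The complement of a path prefix `[p, A, i]` is the punctuated set
#' `[i, A*, q]` on `A* = (V \\ A) + i`, itself a Hamiltonian path sharing the
#' boundary vertex `i`. The outside recursion `A* -> A* v` grows the
#' complement from the far endpoint; numerically the outside table equals the
#' inside table on the complement index set, and combining inside and outside
#' across any fixed split cardinality reproduces `Z_pq`.
#'
#' @inheritParams shp_inside
#' @param inside Tables from [shp_inside()] (checked for consistency).
#' @return A list of class `shp_tables` with array `O[mask + 1, j, q]`.
#' @export
shp_outside <- function(d, params = ensemble_params(d), inside = NULL,
                        algebra = c("partition", "count", "min"), cap = 16L) {
  algebra <- match.arg(algebra)
  if (!is.null(inside)) {
    stopifnot(inherits(inside, "shp_tables"))
    algebra <- inside$algebra
    params <- inside$params
  }
  d <- distance_matrix(d, require_symmetric = TRUE)
  n <- nrow(d)
  if (n > cap) stop("instance size ", n, " exceeds the cap (", cap, ")")
  groups <- masks_by_popcount(n)
  if (algebra == "partition") {
    lw <- -params$alpha * unclass(d)
    L <- array(-Inf, dim = c(2^n, n, n))
    for (q in seq_len(n)) L[bit(q) + 1L, q, q] <- 0
    for (size in 2:n) {
      for (mask in groups[[as.character(size)]]) {
        mem <- mask_members(mask, n)
        for (j in mem) {
          prev <- mask - bit(j)
          pm <- mask_members(prev, n)
          np <- length(pm)
          X <- matrix(L[prev + 1L, pm, pm], np, np) + lw[j, pm]   # [k, q]
          m <- apply(X, 2, max)
          vals <- m + log(colSums(exp(sweep(X, 2, m))))
          vals[is.infinite(m) & m < 0] <- -Inf
          L[mask + 1L, j, pm] <- vals
        }
      }
    }
    return(structure(list(Z = exp(L), logZ = L, algebra = algebra,
                          params = params, d = d, n = n),
                     class = "shp_tables"))
  }
  alg <- setdp_algebra(algebra)
  w <- setdp_weights(d, params, algebra)
  O <- array(alg$zero, dim = c(2^n, n, n))
  for (q in seq_len(n)) O[bit(q) + 1L, q, q] <- alg$one
  for (size in 2:n) {
    for (mask in groups[[as.character(size)]]) {
      mem <- mask_members(mask, n)
      for (j in mem) {
        prev <- mask - bit(j)
        pm <- mask_members(prev, n)
        sub <- matrix(O[prev + 1L, pm, pm], length(pm), length(pm))  # [k, q]
        if (algebra == "min") {
          vals <- apply(sub + matrix(w[j, pm], length(pm), length(pm)), 2, min)
        } else {
          vals <- as.vector(w[j, pm] %*% sub)
        }
        O[mask + 1L, j, pm] <- vals
      }
    }
  }
  structure(list(Z = O, logZ = NULL, algebra = algebra, params = params,
                 d = d, n = n), class = "shp_tables")
}

#' Full Boltzmann ensemble over Hamiltonian paths
#'
#' Computes the partition function restricted to every endpoint pair,
#' endpoint(-pair) probabilities, and adjacency posteriors: the probability
#' of observing the edge `i ~ j` in a path, conditioned on endpoints
#' `(p, q)` via
#' `P(i~j | p,q) = (1/Z_pq) * sum_A Z([p,A,i]) w_ij Z([j, V\\A, q])`,
#' and unconditionally by marginalizing over endpoint pairs with weights
#' `Z_pq / Z_total`.
#'
#' @inheritParams shp_inside
#' @return A list of class `path_ensemble` with `Z_total`, `Z_pq`,
#'   `adjacency` (matrix `P(i~j)`), `endpoint` (vector `P(end = p)`),
#'   `endpoint_pair` (matrix `P(ends = p, q)`), `params`, `labels`, and
#'   `conditional(p, q)`, a function returning the conditional adjacency
#'   matrix for one endpoint pair.
#' @export
shp_ensemble <- function(d, params = ensemble_params(d), cap = 16L) {
  d <- distance_matrix(d, require_symmetric = TRUE)
  n <- nrow(d)
  inside <- shp_inside(d, params, "partition", cap = cap)
  lw <- -params$alpha * unclass(d)       # log edge weights
  L <- inside$logZ
  nm <- 2^n
  log_Zpq <- inside$log_Z_pq
  log_Z_total <- inside$log_Z_total
  lse_vec <- function(v) {
    m <- max(v)
    if (is.infinite(m) && m < 0) return(-Inf)
    m + log(sum(exp(v - m)))
  }
  # log sum_A Z([p, A, i]) Z([j, V \ A, q]) for all (i, j), computed stably
  cond_lognum <- function(p, q) {
    M1 <- matrix(L[, p, ], nm, n)          # log Z[A, p, i]
    M2 <- matrix(L[nm:1, q, ], nm, n)      # log Z[V \ A, q, j]
    Tl <- matrix(-Inf, n, n)
    for (i in seq_len(n)) {
      v1 <- M1[, i]
      if (all(v1 == -Inf)) next
      for (j in seq_len(n)) {
        if (i == j) next
        Tl[i, j] <- lse_vec(v1 + M2[, j])
      }
    }
    # both traversal orientations of the edge i ~ j, plus its weight
    Pl <- lw + pmax(Tl, t(Tl)) +
      log1p(exp(-abs(Tl - t(Tl))))
    Pl[is.infinite(pmax(Tl, t(Tl)))] <- -Inf
    diag(Pl) <- -Inf
    Pl
  }
  adjacency <- matrix(0, n, n)
  for (p in 1:(n - 1)) for (q in (p + 1):n) {
    if (log_Zpq[p, q] == -Inf) next
    adjacency <- adjacency + exp(cond_lognum(p, q) - log_Z_total)
  }
  endpoint_pair <- exp(log_Zpq - log_Z_total)
  diag(endpoint_pair) <- 0
  endpoint <- rowSums(endpoint_pair)
  labels <- rownames(d)
  dimnames(adjacency) <- dimnames(endpoint_pair) <- dimnames(d)
  names(endpoint) <- labels
  structure(list(Z_total = inside$Z_total, log_Z_total = log_Z_total,
                 Z_pq = inside$Z_pq, log_Z_pq = log_Zpq,
                 adjacency = adjacency,
                 endpoint = endpoint, endpoint_pair = endpoint_pair,
                 params = params, labels = labels, n = n,
                 conditional = function(p, q) {
                   P <- exp(cond_lognum(p, q) - log_Zpq[p, q])
                   dimnames(P) <- dimnames(d)
                   P
                 }),
            class = "path_ensemble")
}

#' Adjacency posteriors of the Hamiltonian-path ensemble
#' @inheritParams shp_inside
#' @return A `path_ensemble` (see [shp_ensemble()]); its `adjacency` entry
#'   holds the unconditional `P(i ~ j)` and `conditional(p, q)` the
#'   endpoint-conditioned version.
#' @export
adjacency_posterior <- function(d, params = ensemble_params(d), cap = 16L) {
  shp_ensemble(d, params, cap = cap)
}

#' Endpoint posteriors of the Hamiltonian-path ensemble
#' @inheritParams shp_inside
#' @return A `path_ensemble` (see [shp_ensemble()]); `endpoint_pair[p, q]`
#'   is `Z_pq / Z_total` and `endpoint[p]` its marginal (sums to 2: every
#'   path has two ends).
#' @export
endpoint_posterior <- function(d, params = ensemble_params(d), cap = 16L) {
  shp_ensemble(d, params, cap = cap)
}

#' Shortest Hamiltonian path with backtrace
#'
#' Min-algebra evaluation over all endpoint pairs, with a deterministic
#' backtrace (smallest vertex index preferred on ties; the returned path
#' starts at its smaller endpoint).
#'
#' @inheritParams shp_inside
#' @return List with `path` (vertex order) and `length`.
#' @export
shp_optimal_path <- function(d, cap = 16L) {
  d <- distance_matrix(d, require_symmetric = TRUE)
  n <- nrow(d)
  tabs <- shp_inside(d, ensemble_params(d), "min", cap = cap)
  Zpq <- tabs$Z_pq
  len <- min(Zpq[upper.tri(Zpq)])
  ends <- which(Zpq == len & upper.tri(Zpq), arr.ind = TRUE)
  ends <- ends[order(ends[, 1], ends[, 2]), , drop = FALSE][1, ]
  p <- ends[1]; q <- ends[2]
  # backtrace from q towards p
  path <- integer(n)
  path[n] <- q
  mask <- 2^n - 1L
  j <- q
  for (k in (n - 1):1) {
    prev <- mask - bit(j)
    pm <- mask_members(prev, n)
    vals <- tabs$Z[prev + 1L, p, pm] + d[pm, j]
    tol <- 1e-9 * max(1, abs(tabs$Z[mask + 1L, p, j]))
    cand <- pm[abs(vals - tabs$Z[mask + 1L, p, j]) <= tol]
    j <- min(cand)
    path[k] <- j
    mask <- prev
  }
  list(path = path, length = len)
}

#' Exhaustively enumerate Hamiltonian paths
#'
#' Independent oracle: lists every undirected Hamiltonian path exactly once
#' (each as the vertex order starting at its smaller endpoint) with its exact
#' length.
#'
#' @param d A square distance matrix.
#' @param max_n Size guard (`(n!)/2` paths).
#' @return List with `paths` (matrix, one row per path) and `lengths`.
#' @export
enumerate_hamiltonian_paths <- function(d, max_n = 9L) {
  d <- as.matrix(d)
  n <- nrow(d)
  if (n > max_n) stop("instance size ", n, " exceeds the enumeration guard")
  perms <- function(v) {
    if (length(v) <= 1) return(matrix(v, nrow = 1))
    out <- NULL
    for (k in seq_along(v)) {
      rest <- perms(v[-k])
      out <- rbind(out, cbind(v[k], rest))
    }
    out
  }
  pp <- perms(seq_len(n))
  keep <- pp[, 1] < pp[, n]
  pp <- pp[keep, , drop = FALSE]
  lens <- apply(pp, 1, function(r) sum(d[cbind(r[-n], r[-1])]))
  list(paths = pp, lengths = lens)
}
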