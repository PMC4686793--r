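# Independent brute-force oracles. These deliberately share no code with the
# package's dynamic-programming engines: everything is computed by direct
# enumeration or by an independent textbook recurrence.

## --- HMM ------------------------------------------------------------------

random_hmm_params <- function() {
  rdirichlet_row <- function() { x <- stats::runif(4, 0.05, 1); x / sum(x) }
  a_plus <- t(replicate(4, rdirichlet_row()))
  a_minus <- t(replicate(4, rdirichlet_row()))
  hmm_params(a_plus, a_minus, q_pm = stats::runif(1, 0.05, 0.95),
             q_mp = stats::runif(1, 0.05, 0.95))
}

# enumerate all state sequences sigma_0 .. sigma_n; returns total likelihood
# and the per-position posterior of the "+" state
hmm_enumerate <- function(params, seq) {
  x <- match(strsplit(toupper(seq), "")[[1]], c("A", "C", "G", "T"))
  n <- length(x)
  grid <- as.matrix(expand.grid(rep(list(c("p", "m")), n + 1),
                                stringsAsFactors = FALSE))
  w <- apply(grid, 1, function(st) {
    wt <- if (st[1] == "p") params$start_plus else params$start_minus
    for (i in seq_len(n)) {
      src <- st[i]; dst <- st[i + 1]
      emis <- if (i == 1) {
        if (src == "p") params$init_plus[x[1]] else params$init_minus[x[1]]
      } else {
        if (src == "p") params$a_plus[x[i - 1], x[i]] else
          params$a_minus[x[i - 1], x[i]]
      }
      qf <- if (src == "p") {
        if (dst == "p") 1 - params$q_pm else params$q_pm
      } else {
        if (dst == "m") 1 - params$q_mp else params$q_mp
      }
      wt <- wt * emis * qf
    }
    wt
  })
  total <- sum(w)
  post <- vapply(seq_len(n), function(i)
    sum(w[grid[, i + 1] == "p"]) / total, numeric(1))
  list(total = total, posterior = post)
}

## --- Alignment ------------------------------------------------------------

# Delannoy numbers by their independent recurrence
delannoy <- function(n, m) {
  D <- matrix(1, n + 1, m + 1)
  if (n > 0 && m > 0) for (i in 1:n) for (j in 1:m) {
    D[i + 1, j + 1] <- D[i, j + 1] + D[i + 1, j] + D[i, j]
  }
  D[n + 1, m + 1]
}

# plain recursive unit-cost edit distance (memoized)
edit_distance <- function(x, y) {
  xc <- strsplit(x, "")[[1]]; yc <- strsplit(y, "")[[1]]
  memo <- new.env()
  rec <- function(i, j) {
    if (i == 0) return(j)
    if (j == 0) return(i)
    key <- paste(i, j)
    if (!is.null(memo[[key]])) return(memo[[key]])
    v <- min(rec(i - 1, j - 1) + (xc[i] != yc[j]),
             rec(i - 1, j) + 1, rec(i, j - 1) + 1)
    memo[[key]] <- v
    v
  }
  rec(length(xc), length(yc))
}

# drop the parses that classify the empty prefix as D or I (the engines
# assign the empty alignment to the match class)
gotoh_filter <- function(p, children) !p$attribute %in% c("empty_d", "empty_i")

# Boltzmann weight and matched index pairs of one Gotoh parse tree
gotoh_parse_eval <- function(tree, input, scheme) {
  leaves <- parse_leaves(tree)
  w <- 1
  matches <- NULL
  for (lf in leaves) {
    ch <- leaf_chars(lf, input)
    sc <- switch(lf$symbol,
                 "uv" = if (ch[[1]] == ch[[2]]) scheme$match else scheme$mismatch,
                 "u-" = , "-v" = scheme$gap_open,
                 "u." = , ".v" = scheme$gap_extend,
                 "ee" = 0)
    w <- w * exp(sc / scheme$RT)
    if (lf$symbol == "uv")
      matches <- rbind(matches, c(lf$spans[[1]][2], lf$spans[[2]][2]))
  }
  list(weight = w, matches = matches)
}

# ensemble match frequencies from exhaustive parse enumeration
gotoh_ensemble_oracle <- function(x, y, scheme) {
  parses <- enumerate_parses(grammar_gotoh(), c(x, y),
                             production_filter = gotoh_filter)
  n <- nchar(x); m <- nchar(y)
  P <- matrix(0, max(n, 1), max(m, 1))
  Z <- 0
  for (tr in parses) {
    ev <- gotoh_parse_eval(tr, c(x, y), scheme)
    Z <- Z + ev$weight
    if (!is.null(ev$matches)) for (r in seq_len(nrow(ev$matches))) {
      P[ev$matches[r, 1], ev$matches[r, 2]] <-
        P[ev$matches[r, 1], ev$matches[r, 2]] + ev$weight
    }
  }
  list(Z = Z, P = P / Z, n_alignments = length(parses))
}

## --- RNA ------------------------------------------------------------------

# Boltzmann pair frequencies over the exhaustively enumerated structures
rna_ensemble_oracle <- function(input, RT = 1, E_pair = 1, E_unpaired = 0) {
  ss <- enumerate_structures(input)
  w <- exp(-vapply(ss, structure_energy, numeric(1),
                   E_pair = E_pair, E_unpaired = E_unpaired) / RT)
  n <- input$n
  P <- matrix(0, n, n)
  for (k in seq_along(ss)) {
    pr <- dotbracket_pairs(ss[k])
    if (nrow(pr)) for (r in seq_len(nrow(pr))) {
      P[pr[r, 1], pr[r, 2]] <- P[pr[r, 1], pr[r, 2]] + w[k]
    }
  }
  list(Z = sum(w), P = (P + t(P)) / sum(w), n_structures = length(ss),
       max_pairs = max(vapply(ss, function(s) nrow(dotbracket_pairs(s)),
                              numeric(1))))
}

random_rna <- function(len) {
  paste(sample(c("A", "C", "G", "U"), len, replace = TRUE), collapse = "")
}

## --- Set DP ---------------------------------------------------------------

random_symmetric_d <- function(n, lo = 1, hi = 10) {
  m <- matrix(stats::runif(n * n, lo, hi), n, n)
  m <- (m + t(m)) / 2
  diag(m) <- 0
  distance_matrix(m)
}

brute_force_tour <- function(d) {
  n <- nrow(d)
  perms <- function(v) {
    if (length(v) <= 1) return(matrix(v, 1))
    out <- NULL
    for (k in seq_along(v)) out <- rbind(out, cbind(v[k], perms(v[-k])))
    out
  }
  pp <- perms(2:n)
  lens <- apply(pp, 1, function(r) {
    ord <- c(1, r)
    sum(d[cbind(ord, c(ord[-1], 1))])
  })
  min(lens)
}

# Boltzmann adjacency / endpoint statistics over all enumerated paths
shp_ensemble_oracle <- function(d, params) {
  or <- enumerate_hamiltonian_paths(d)
  n <- nrow(d)
  w <- exp(-params$alpha * or$lengths)
  Z <- sum(w)
  A <- matrix(0, n, n)
  E <- numeric(n)
  EP <- matrix(0, n, n)
  for (k in seq_along(w)) {
    r <- or$paths[k, ]
    for (t in 1:(n - 1)) A[r[t], r[t + 1]] <- A[r[t], r[t + 1]] + w[k]
    E[r[1]] <- E[r[1]] + w[k]
    E[r[n]] <- E[r[n]] + w[k]
    EP[r[1], r[n]] <- EP[r[1], r[n]] + w[k]
  }
  list(Z = Z, adjacency = (A + t(A)) / Z, endpoint = E / Z,
       endpoint_pair = (EP + t(EP)) / Z)
}
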