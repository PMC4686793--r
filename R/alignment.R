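#' Scoring scheme for pairwise alignment
#'
#' Bundles substitution and affine-gap parameters with the evaluation mode.
#' In `optimize` mode the parameters are scores combined additively and the
#' choice function is `max` (or `min`, for cost schemes such as edit
#' distance). In `count` mode every column has weight 1 and the total counts
#' alignments. In `partition` mode each parameter score `s` becomes the
#' Boltzmann weight `exp(s / RT)` and the total is the partition function
#' over all alignments.
#'
#' @param mode `"partition"`, `"optimize"` or `"count"`.
#' @param match,mismatch Substitution scores (ignored if `submat` given).
#' @param gap Linear gap score (Needleman-Wunsch engine).
#' @param gap_open,gap_extend Affine gap scores: opening a gap (the `-`
#'   column) and extending one (the `.` column); Gotoh engine.
#' @param RT Temperature-like scale of the Boltzmann weights in partition
#'   mode.
#' @param objective `"max"` or `"min"`, used in optimize mode only.
#' @param submat Optional `function(u, v)` returning the substitution score
#'   for a character pair.
#' @return A list of class `scoring_scheme`.
#' @export
scoring_scheme <- function(mode = c("partition", "optimize", "count"),
                           match = 1, mismatch = -1, gap = -2,
                           gap_open = -2, gap_extend = -1, RT = 1,
                           objective = c("max", "min"), submat = NULL) {
  mode <- match.arg(mode)
  objective <- match.arg(objective)
  stopifnot(RT > 0)
  structure(list(mode = mode, match = match, mismatch = mismatch, gap = gap,
                 gap_open = gap_open, gap_extend = gap_extend, RT = RT,
                 objective = objective, submat = submat),
            class = "scoring_scheme")
}

# evaluation algebra: (zero, one, plus = choice, times = combination)
scheme_algebra <- function(s) {
  switch(s$mode,
    count = list(zero = 0, one = 1, plus = `+`, times = `*`),
    partition = list(zero = 0, one = 1, plus = `+`, times = `*`),
    optimize = if (s$objective == "max")
      list(zero = -Inf, one = 0, plus = pmax, times = `+`)
    else
      list(zero = Inf, one = 0, plus = pmin, times = `+`))
}

sub_score <- function(s, u, v) {
  if (!is.null(s$submat)) return(s$submat(u, v))
  if (u == v) s$match else s$mismatch
}

# terminal weight under the scheme's algebra
term_weight <- function(s, score) {
  switch(s$mode, count = 1, partition = exp(score / s$RT), optimize = score)
}

split_chars <- function(x) if (nchar(x)) strsplit(x, "")[[1]] else character(0)

#' Needleman-Wunsch inside and outside tables
#'
#' The inside table `A[i, j]` evaluates all alignments of the prefixes
#' `x[1..i]`, `y[1..j]`; the outside table `Astar[i, j]` evaluates all
#' alignments of the complementary suffixes `x[i+1..n]`, `y[j+1..m]` (the
#' "hole" left by the prefix pair). Both are filled under the scheme's
#' algebra; in partition mode `A[n, m] = Astar[0, 0] = Z`, the partition
#' function over all global alignments.
#'
#' @param x,y Input sequences (strings).
#' @param scheme A [scoring_scheme()].
#' @return A list of class `alignment_tables` with `A`, `Astar`
#'   (`(n+1) x (m+1)` matrices, row/column 1 = prefix length 0), `Z`, the
#'   inputs and the scheme. Table kind is `"nw"`.
#' @export
nw_inside_outside <- function(x, y, scheme = scoring_scheme()) {
  alg <- scheme_algebra(scheme)
  xc <- split_chars(x); yc <- split_chars(y)
  n <- length(xc); m <- length(yc)
  wsub <- function(i, j) term_weight(scheme, sub_score(scheme, xc[i], yc[j]))
  wgap <- term_weight(scheme, scheme$gap)
  A <- matrix(alg$zero, n + 1, m + 1)
  A[1, 1] <- alg$one
  for (i in 0:n) for (j in 0:m) {
    if (i == 0 && j == 0) next
    acc <- alg$zero
    if (i > 0 && j > 0) acc <- alg$plus(acc, alg$times(A[i, j], wsub(i, j)))
    if (i > 0) acc <- alg$plus(acc, alg$times(A[i, j + 1], wgap))
    if (j > 0) acc <- alg$plus(acc, alg$times(A[i + 1, j], wgap))
    A[i + 1, j + 1] <- acc
  }
  As <- matrix(alg$zero, n + 1, m + 1)
  As[n + 1, m + 1] <- alg$one
  for (i in n:0) for (j in m:0) {
    if (i == n && j == m) next
    acc <- alg$zero
    if (i < n && j < m)
      acc <- alg$plus(acc, alg$times(As[i + 2, j + 2], wsub(i + 1, j + 1)))
    if (i < n) acc <- alg$plus(acc, alg$times(As[i + 2, j + 1], wgap))
    if (j < m) acc <- alg$plus(acc, alg$times(As[i + 1, j + 2], wgap))
    As[i + 1, j + 1] <- acc
  }
  structure(list(kind = "nw", A = A, Astar = As, Z = A[n + 1, m + 1],
                 x = x, y = y, n = n, m = m, scheme = scheme),
            class = "alignment_tables")
}

#' Gotoh affine-gap inside tables
#'
#' Prefix alignments classified by their last column: `M[i, j]` ends in a
#' (mis)match, `D[i, j]` in a gap in `y` (deletion), `I[i, j]` in a gap in
#' `x` (insertion). Gap opening is scored on entry from a different class,
#' extension on staying within `D` or `I`. The empty alignment is assigned to
#' `M` (so `M[0,0]` holds the neutral value and totals are not
#' triple-counted). The total combines the three classes at `(n, m)`.
#'
#' @inheritParams nw_inside_outside
#' @return A list of class `alignment_tables` (kind `"gotoh"`) with `M`,
#'   `D`, `I` and `Z`.
#' @export
gotoh_inside <- function(x, y, scheme = scoring_scheme()) {
  alg <- scheme_algebra(scheme)
  xc <- split_chars(x); yc <- split_chars(y)
  n <- length(xc); m <- length(yc)
  wsub <- function(i, j) term_weight(scheme, sub_score(scheme, xc[i], yc[j]))
  wopen <- term_weight(scheme, scheme$gap_open)
  wext <- term_weight(scheme, scheme$gap_extend)
  M <- D <- I <- matrix(alg$zero, n + 1, m + 1)
  M[1, 1] <- alg$one
  for (i in 0:n) for (j in 0:m) {
    if (i == 0 && j == 0) next
    if (i > 0 && j > 0) {
      w <- wsub(i, j)
      M[i + 1, j + 1] <- alg$times(alg$plus(alg$plus(M[i, j], D[i, j]), I[i, j]), w)
    }
    if (i > 0) {
      D[i + 1, j + 1] <- alg$plus(
        alg$times(alg$plus(M[i, j + 1], I[i, j + 1]), wopen),
        alg$times(D[i, j + 1], wext))
    }
    if (j > 0) {
      I[i + 1, j + 1] <- alg$plus(
        alg$times(alg$plus(M[i + 1, j], D[i + 1, j]), wopen),
        alg$times(I[i + 1, j], wext))
    }
  }
  Z <- alg$plus(alg$plus(M[n + 1, m + 1], D[n + 1, m + 1]), I[n + 1, m + 1])
  structure(list(kind = "gotoh", M = M, D = D, I = I, Z = Z,
                 x = x, y = y, n = n, m = m, scheme = scheme),
            class = "alignment_tables")
}

#' Gotoh affine-gap outside tables (gap-closing recursion)
#'
#' The outside table `Mstar[i, j]` evaluates suffix complements of prefix
#' alignments ending in class `M` at `(i, j)` -- the alignments of
#' `x[i+1..n]` with `y[j+1..m]` scored so that a gap is charged its *closing*
#' rather than its opening, the recursion obtained mechanically from the
#' inside grammar. Attribute functions are shared with the inside recursion
#' by signature isomorphism: the weight of the inside rule `D -> I (u-)`
#' attaches to the outside rule `I* -> D* (u-)`, and so on. All three state
#' tables receive the neutral start weight at the `(n, m)` corner.
#'
#' @param x,y Input sequences; must match those of `inside`.
#' @param scheme A [scoring_scheme()]; must match that of `inside`.
#' @param inside Tables from [gotoh_inside()].
#' @return A list of class `alignment_tables` (kind `"gotoh"`) containing
#'   the inside tables plus `Mstar`, `Dstar`, `Istar` and `Z_outside`.
#' @export
gotoh_outside <- function(x, y, scheme, inside) {
  stopifnot(inherits(inside, "alignment_tables"), inside$kind == "gotoh")
  if (!identical(inside$x, x) || !identical(inside$y, y))
    stop("inside tables were computed for different sequences")
  if (!identical(inside$scheme, scheme))
    stop("inside tables were computed under a different scheme")
  alg <- scheme_algebra(scheme)
  xc <- split_chars(x); yc <- split_chars(y)
  n <- length(xc); m <- length(yc)
  wsub <- function(i, j) term_weight(scheme, sub_score(scheme, xc[i], yc[j]))
  wopen <- term_weight(scheme, scheme$gap_open)
  wext <- term_weight(scheme, scheme$gap_extend)
  Ms <- Ds <- Is <- matrix(alg$zero, n + 1, m + 1)
  Ms[n + 1, m + 1] <- Ds[n + 1, m + 1] <- Is[n + 1, m + 1] <- alg$one
  for (i in n:0) for (j in m:0) {
    if (i == n && j == m) next
    msub <- if (i < n && j < m)
      alg$times(Ms[i + 2, j + 2], wsub(i + 1, j + 1)) else alg$zero
    dgap <- if (i < n) Ds[i + 2, j + 1] else alg$zero
    igap <- if (j < m) Is[i + 1, j + 2] else alg$zero
    Ms[i + 1, j + 1] <- alg$plus(msub, alg$plus(alg$times(dgap, wopen),
                                                alg$times(igap, wopen)))
    Ds[i + 1, j + 1] <- alg$plus(msub, alg$plus(alg$times(dgap, wext),
                                                alg$times(igap, wopen)))
    Is[i + 1, j + 1] <- alg$plus(msub, alg$plus(alg$times(dgap, wopen),
                                                alg$times(igap, wext)))
  }
  out <- inside
  out$Mstar <- Ms; out$Dstar <- Ds; out$Istar <- Is
  out$Z_outside <- Ms[1, 1]   # inside corner holds M only: empty prefix is class M
  structure(out, class = "alignment_tables")
}

#' Posterior probability of matching each character pair
#'
#' In partition mode, `P(i, j) = M[i, j] * Mstar[i, j] / Z`: the Boltzmann
#' probability that the ensemble of global alignments matches `x[i]` with
#' `y[j]`. For Needleman-Wunsch tables the match weight enters through the
#' three-way split `A (uv) A*`. Rows and columns each sum to at most 1.
#'
#' @param tables For the Gotoh engine, the output of [gotoh_outside()]
#'   (inside + outside); for the NW engine, the output of
#'   [nw_inside_outside()] with a partition-mode scheme.
#' @return An `n x m` matrix of match probabilities.
#' @export
match_posterior <- function(tables) {
  stopifnot(inherits(tables, "alignment_tables"))
  if (tables$scheme$mode != "partition")
    stop("match posteriors require partition-mode tables")
  n <- tables$n; m <- tables$m
  P <- matrix(0, n, m)
  if (tables$kind == "gotoh") {
    if (is.null(tables$Mstar)) stop("outside tables missing; run gotoh_outside()")
    P <- tables$M[2:(n + 1), 2:(m + 1), drop = FALSE] *
      tables$Mstar[2:(n + 1), 2:(m + 1), drop = FALSE] / tables$Z
  } else {
    xc <- split_chars(tables$x); yc <- split_chars(tables$y)
    for (i in seq_len(n)) for (j in seq_len(m)) {
      w <- term_weight(tables$scheme, sub_score(tables$scheme, xc[i], yc[j]))
      P[i, j] <- tables$A[i, j] * w * tables$Astar[i + 1, j + 1] / tables$Z
    }
  }
  dimnames(P) <- list(split_chars(tables$x), split_chars(tables$y))
  P
}

#' Inside-outside consistency sum across an anti-diagonal cut
#'
#' Every alignment crosses the anti-diagonal `i + j = c` exactly once:
#' either at a cell on the cut or by a match column jumping over it. The
#' corresponding sum of inside-outside products therefore reproduces the
#' total `Z` for every `c`; this is the numeric form of summing the start
#' rule `S -> A A*` over an anti-chain of complementary splits.
#'
#' @param tables Output of [gotoh_outside()] or [nw_inside_outside()]
#'   (partition or count mode).
#' @param c Anti-diagonal index in `0 .. n + m`.
#' @return The cut sum (equal to `Z` up to rounding).
#' @export
antidiagonal_cut_sum <- function(tables, c) {
  stopifnot(inherits(tables, "alignment_tables"))
  n <- tables$n; m <- tables$m
  stopifnot(c >= 0, c <= n + m)
  xc <- split_chars(tables$x); yc <- split_chars(tables$y)
  wsub <- function(i, j) term_weight(tables$scheme,
                                     sub_score(tables$scheme, xc[i], yc[j]))
  total <- 0
  for (i in 0:n) {
    j <- c - i
    if (j >= 0 && j <= m) {
      total <- total + if (tables$kind == "gotoh")
        tables$M[i + 1, j + 1] * tables$Mstar[i + 1, j + 1] +
          tables$D[i + 1, j + 1] * tables$Dstar[i + 1, j + 1] +
          tables$I[i + 1, j + 1] * tables$Istar[i + 1, j + 1]
      else tables$A[i + 1, j + 1] * tables$Astar[i + 1, j + 1]
    }
    j2 <- c + 1 - i   # match columns jumping the cut: (i-1, j2-1) -> (i, j2)
    if (i >= 1 && j2 >= 1 && j2 <= m) {
      total <- total + if (tables$kind == "gotoh")
        tables$M[i + 1, j2 + 1] * tables$Mstar[i + 1, j2 + 1]
      else tables$A[i, j2] * wsub(i, j2) * tables$Astar[i + 1, j2 + 1]
    }
  }
  total
}
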