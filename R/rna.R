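RNA_BASES <- c("A", "C", "G", "U")
CANONICAL_PAIRS <- c("GC", "CG", "AU", "UA", "GU", "UG")

#' RNA folding input
#'
#' @param seq RNA sequence over A, C, G, U (T is accepted and converted).
#' @param pair_rules Character vector of allowed ordered pairs (default: the
#'   six canonical pairs GC, CG, AU, UA, GU, UG).
#' @param min_hairpin Minimum number of unpaired positions enclosed by a base
#'   pair. The default 0 matches the bare decomposition grammar; physically
#'   realistic folding uses 3.
#' @return A list of class `rna_input`.
#' @export
rna_input <- function(seq, pair_rules = CANONICAL_PAIRS, min_hairpin = 0L) {
  x <- strsplit(toupper(gsub("T", "U", toupper(seq))), "")[[1]]
  bad <- setdiff(unique(x), RNA_BASES)
  if (length(bad)) stop("invalid nucleotide(s): ", paste(bad, collapse = ", "))
  stopifnot(min_hairpin >= 0)
  structure(list(seq = paste(x, collapse = ""), chars = x, n = length(x),
                 pair_rules = pair_rules, min_hairpin = as.integer(min_hairpin)),
            class = "rna_input")
}

can_pair <- function(input, i, j) {
  paste0(input$chars[i], input$chars[j]) %in% input$pair_rules &&
    (j - i - 1) >= input$min_hairpin
}

rna_algebra <- function(mode) {
  switch(mode,
    count = list(zero = 0, one = 1, plus = `+`, times = `*`),
    partition = list(zero = 0, one = 1, plus = `+`, times = `*`),
    maxpair = list(zero = -Inf, one = 0, plus = pmax, times = `+`))
}

rna_weights <- function(mode, RT, E_pair, E_unpaired) {
  switch(mode,
    count = list(pair = 1, unpaired = 1),
    partition = list(pair = exp(-E_pair / RT), unpaired = exp(-E_unpaired / RT)),
    maxpair = list(pair = 1, unpaired = 0))  # maximize the number of pairs
}

#' Inside recursion of the toy RNA folding grammar
#'
#' Fills `U[i, j]` (all non-crossing structures on the substring `i..j`) and
#' `B[i, j]` (structures on `i..j` whose outermost feature is the closing
#' pair `<i, j>`; the pair's weight is charged here) bottom-up under the
#' selected algebra: structure counting, maximum number of base pairs, or the
#' Boltzmann partition function with per-terminal energies `E_pair` /
#' `E_unpaired` at scale `RT`. Empty substrings (`i > j`) hold the neutral
#' value (the empty parse). The total is `Z = U[1, n]`.
#'
#' @param input An [rna_input()].
#' @param mode `"count"`, `"maxpair"` or `"partition"`.
#' @param RT Boltzmann scale (partition mode).
#' @param E_pair,E_unpaired Terminal energies: default 1 per base pair and 0
#'   per unpaired position.
#' @return A list of class `rna_tables` with `U`, `B` (stored in
#'   `(n+1) x (n+1)` matrices; `U[i, j]` at row `i`, column `j + 1`), `Z`,
#'   the input and mode.
#' @export
rna_inside <- function(input, mode = c("partition", "count", "maxpair"),
                       RT = 1, E_pair = 1, E_unpaired = 0) {
  mode <- match.arg(mode)
  alg <- rna_algebra(mode)
  w <- rna_weights(mode, RT, E_pair, E_unpaired)
  n <- input$n
  # U[i, j] at [i, j + 1], 1 <= i <= n + 1, i - 1 <= j <= n
  U <- matrix(alg$zero, n + 1, n + 1)
  B <- matrix(alg$zero, n + 1, n + 1)
  for (i in 1:(n + 1)) U[i, i] <- alg$one        # j = i - 1: empty parse
  for (span in 1:n) {
    if (span > n) break
    for (i in 1:(n - span + 1)) {
      j <- i + span - 1
      # B[i, j]: closing pair <i, j> around U[i+1, j-1]
      if (span >= 2 && can_pair(input, i, j))
        B[i, j + 1] <- alg$times(w$pair, U[i + 1, j])
      # U[i, j] = c_i U[i+1, j]  |  B[i, k] U[k+1, j]
      acc <- alg$times(w$unpaired, U[i + 1, j + 1])
      if (span >= 2) for (k in (i + 1):j) {
        acc <- alg$plus(acc, alg$times(B[i, k + 1], U[k + 1, j + 1]))
      }
      U[i, j + 1] <- acc
    }
  }
  structure(list(U = U, B = B, Z = U[1, n + 1], input = input, mode = mode,
                 RT = RT, E_pair = E_pair, E_unpaired = E_unpaired),
            class = "rna_tables")
}

#' Outside recursion of the toy RNA folding grammar
#'
#' Fills `Ustar[i, j]` (weight of all structure contexts of the substring
#' `i..j`, i.e. structures on `[1..i-1] + [j+1..n]` compatible with a `U`
#' slot at `i..j`) and `Bstar[i, j]` (contexts of a helix closed by
#' `<i, j>`; the shared closing pair is charged on the inside table only, so
#' products `B * Bstar` count it exactly once). Initialization is
#' `Ustar[1, n] = one`; the context of the empty slot at the right end,
#' `Ustar[n+1, n]`, reproduces the inside total.
#'
#' @param input The [rna_input()] used for `inside`.
#' @param inside Tables from [rna_inside()].
#' @return `inside` extended with `Ustar`, `Bstar` and `Z_outside`.
#' @export
rna_outside <- function(input, inside) {
  stopifnot(inherits(inside, "rna_tables"))
  if (!identical(input$seq, inside$input$seq))
    stop("inside tables were computed for a different sequence")
  alg <- rna_algebra(inside$mode)
  w <- rna_weights(inside$mode, inside$RT, inside$E_pair, inside$E_unpaired)
  n <- input$n
  U <- inside$U; B <- inside$B
  Us <- matrix(alg$zero, n + 1, n + 1)
  Bs <- matrix(alg$zero, n + 1, n + 1)
  Us[1, n + 1] <- alg$one
  # decreasing hole size; at each size U* first, then B* (B*[i,j] uses U*[i,j])
  for (span in n:0) {
    starts <- 1:(n - span + 1)
    for (i in starts) {
      j <- i + span - 1
      acc <- Us[i, j + 1]   # keeps the initialization at (1, n)
      # U*[i,j] <- c_{i-1} U*[i-1, j]
      if (i >= 2) acc <- alg$plus(acc, alg$times(w$unpaired, Us[i - 1, j + 1]))
      # U*[i,j] <- c_{i-1} B*[i-1, j+1] c'_{j+1}: the enclosing pair's weight
      # belongs to the context
      if (i >= 2 && j <= n - 1 && can_pair(input, i - 1, j + 1))
        acc <- alg$plus(acc, alg$times(w$pair, Bs[i - 1, j + 2]))
      # U*[i,j] <- B[k, i-1] U*[k, j], k < i
      if (i >= 3) for (k in 1:(i - 2)) {
        acc <- alg$plus(acc, alg$times(B[k, i], Us[k, j + 1]))
      }
      Us[i, j + 1] <- acc
    }
    for (i in starts) {
      j <- i + span - 1
      if (j < i || span < 2 || !can_pair(input, i, j)) next
      # B*[i,j] <- U*[i,k] U[j+1,k], k >= j (k = j: empty trailing parse)
      acc <- alg$zero
      for (k in j:n) acc <- alg$plus(acc, alg$times(Us[i, k + 1], U[j + 1, k + 1]))
      Bs[i, j + 1] <- acc
    }
  }
  out <- inside
  out$Ustar <- Us; out$Bstar <- Bs
  out$Z_outside <- Us[n + 1, n + 1]   # context of the final empty slot
  out
}

#' Base-pair probability matrix
#'
#' `P(i, j) = B[i, j] * Bstar[i, j] / Z`: the Boltzmann frequency of the pair
#' `<i, j>` over all structures. Because inside and outside helices share the
#' closing pair as their common boundary, the pair weight (charged on the
#' inside table only) enters each product exactly once. The matrix is
#' symmetric and each row sums to at most 1.
#'
#' @param input An [rna_input()].
#' @param RT,E_pair,E_unpaired Partition-function parameters, as in
#'   [rna_inside()].
#' @return An `n x n` symmetric matrix of pair probabilities.
#' @export
basepair_probabilities <- function(input, RT = 1, E_pair = 1, E_unpaired = 0) {
  inside <- rna_inside(input, "partition", RT = RT, E_pair = E_pair,
                       E_unpaired = E_unpaired)
  tabs <- rna_outside(input, inside)
  n <- input$n
  P <- matrix(0, n, n)
  if (n >= 2) for (i in 1:(n - 1)) for (j in (i + 1):n) {
    if (!can_pair(input, i, j)) next
    p <- tabs$B[i, j + 1] * tabs$Bstar[i, j + 1] / tabs$Z
    P[i, j] <- P[j, i] <- p
  }
  P
}

#' Exhaustively enumerate secondary structures
#'
#' Independent oracle: lists every non-crossing set of allowed base pairs
#' (respecting `min_hairpin`) exactly once, in dot-bracket notation.
#'
#' @param input An [rna_input()].
#' @param max_n Length guard; enumeration is exponential.
#' @return Character vector of dot-bracket strings.
#' @export
enumerate_structures <- function(input, max_n = 20L) {
  n <- input$n
  if (n > max_n) stop("sequence longer than the enumeration guard (", max_n, ")")
  rec <- function(i, j) {
    if (i > j) return("")
    out <- paste0(".", rec(i + 1, j))
    for (k in (i + 1):j) {
      if (j < i + 1) break
      if (!can_pair(input, i, k)) next
      for (inner in rec(i + 1, k - 1)) for (rest in rec(k + 1, j)) {
        out <- c(out, paste0("(", inner, ")", rest))
      }
    }
    out
  }
  rec(1, n)
}

#' Pairs of a dot-bracket string
#' @param db Dot-bracket string.
#' @return Two-column matrix of paired positions (i < j).
#' @export
dotbracket_pairs <- function(db) {
  x <- strsplit(db, "")[[1]]
  stack <- integer(0)
  out <- matrix(integer(0), ncol = 2)
  for (i in seq_along(x)) {
    if (x[i] == "(") stack <- c(stack, i)
    else if (x[i] == ")") {
      j <- stack[length(stack)]
      stack <- stack[-length(stack)]
      out <- rbind(out, c(j, i))
    }
  }
  out
}

#' Boltzmann energy of a structure under the toy model
#' @param db Dot-bracket string.
#' @param E_pair,E_unpaired Per-terminal energies.
#' @return Total energy (pairs count once; unpaired positions once).
#' @export
structure_energy <- function(db, E_pair = 1, E_unpaired = 0) {
  pr <- dotbracket_pairs(db)
  npair <- nrow(pr)
  nunp <- nchar(db) - 2 * npair
  npair * E_pair + nunp * E_unpaired
}
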