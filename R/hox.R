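AA20 <- c("A", "R", "N", "D", "C", "Q", "E", "G", "H", "I",
          "L", "K", "M", "F", "P", "S", "T", "W", "Y", "V")

check_cluster_input <- function(sequences) {
  if (is.list(sequences)) sequences <- unlist(sequences)
  stopifnot(is.character(sequences), length(sequences) >= 2)
  if (is.null(names(sequences)))
    names(sequences) <- paste0("gene", seq_along(sequences))
  lens <- nchar(sequences)
  if (length(unique(lens)) != 1)
    stop("sequences must be aligned to equal length; got lengths ",
         paste(unique(lens), collapse = ", "))
  toupper(sequences)
}

#' Hamming distance matrix of aligned sequences
#'
#' `d[a, b]` is the number of positions at which sequences `a` and `b`
#' differ. Gene order (the order of `sequences`) is preserved in the labels.
#'
#' @param sequences Named character vector of aligned, equal-length
#'   amino-acid sequences in genomic order.
#' @return A [distance_matrix()].
#' @export
hamming_matrix <- function(sequences) {
  sequences <- check_cluster_input(sequences)
  chars <- do.call(rbind, strsplit(sequences, ""))
  n <- nrow(chars)
  d <- matrix(0, n, n)
  for (a in seq_len(n)) for (b in seq_len(n)) {
    if (b > a) d[a, b] <- d[b, a] <- sum(chars[a, ] != chars[b, ])
  }
  distance_matrix(d, labels = names(sequences))
}

#' BLOSUM45-derived distance matrix of aligned sequences
#'
#' Converts similarity scores into a squared-metric-like dissimilarity via
#' `d_ab = s(a, a) + s(b, b) - 2 s(a, b)`, where `s(a, b)` is the summed
#' BLOSUM45 score over alignment columns. The standard published BLOSUM45
#' half-bit matrix shipped with Biostrings is used. Columns containing a
#' residue outside the 20-letter alphabet (gaps, X, ...) are dropped pairwise
#' by default.
#'
#' @inheritParams hamming_matrix
#' @param on_unknown `"drop"` (skip offending columns pairwise) or `"error"`.
#' @return A [distance_matrix()].
#' @export
blosum_distance_matrix <- function(sequences, on_unknown = c("drop", "error")) {
  on_unknown <- match.arg(on_unknown)
  sequences <- check_cluster_input(sequences)
  blosum <- get_blosum45()
  chars <- do.call(rbind, strsplit(sequences, ""))
  known <- matrix(chars %in% AA20, nrow(chars), ncol(chars))
  if (on_unknown == "error" && !all(known))
    stop("unknown residue(s): ",
         paste(unique(chars[!known]), collapse = ", "))
  n <- nrow(chars)
  d <- matrix(0, n, n)
  for (a in seq_len(n)) for (b in a:n) {
    use <- known[a, ] & known[b, ]   # pairwise-shared scorable columns
    saa <- sum(blosum[cbind(chars[a, use], chars[a, use])])
    sbb <- sum(blosum[cbind(chars[b, use], chars[b, use])])
    sab <- sum(blosum[cbind(chars[a, use], chars[b, use])])
    d[a, b] <- d[b, a] <- saa + sbb - 2 * sab
  }
  d[d < 0 & d > -1e-9] <- 0
  distance_matrix(d, labels = names(sequences))
}

get_blosum45 <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      e <- new.env()
      utils::data("BLOSUM45", package = "Biostrings", envir = e)
      cache <<- e$BLOSUM45
    }
    cache
  }
})

#' Hamiltonian-path ensemble analysis of a gene cluster
#'
#' The full application pipeline: build genetic-distance matrices from
#' aligned homeodomain sequences (both Hamming and BLOSUM45-derived metrics
#' are reported side by side; a precomputed matrix may be supplied instead),
#' set the Boltzmann normalization `R = (n - 1) * dbar`, and evaluate the
#' Hamiltonian-path ensemble at each requested temperature: adjacency
#' posteriors, endpoint(-pair) posteriors, plus the optimal (shortest) path.
#' On a matrix with the Robinson property (`d_ik >= max(d_ij, d_jk)` for
#' genes in genomic order) the shortest path follows the genomic gene order,
#' and at low temperature the endpoint probabilities peak at the cluster
#' ends.
#'
#' @param input Named character vector of aligned sequences in genomic
#'   order, or a precomputed [distance_matrix()].
#' @param temperatures Numeric vector of ensemble temperatures.
#' @param metrics Which distance transforms to apply to sequence input
#'   (ignored for matrix input).
#' @param cap Subset-DP size guard, passed through to [shp_ensemble()].
#' @return A list of class `cluster_report`: per metric, the distance
#'   matrix, `dbar`, `R`, the optimal path and length, and one
#'   `path_ensemble` per temperature.
#' @export
run_cluster_analysis <- function(input, temperatures = c(0.1, 0.5, 1, 10),
                                 metrics = c("hamming", "blosum45"),
                                 cap = 16L) {
  stopifnot(length(temperatures) >= 1, all(temperatures > 0))
  mats <- if (inherits(input, "distance_matrix") ||
              (is.matrix(input) && is.numeric(input))) {
    list(precomputed = distance_matrix(input))
  } else {
    res <- list()
    if ("hamming" %in% metrics) res$hamming <- hamming_matrix(input)
    if ("blosum45" %in% metrics) res$blosum45 <- blosum_distance_matrix(input)
    res
  }
  n <- nrow(mats[[1]])
  if (n < 3) stop("need at least 3 genes")
  report <- list(temperatures = temperatures, n = n,
                 labels = rownames(mats[[1]]), metrics = list())
  for (metric in names(mats)) {
    d <- mats[[metric]]
    dbar <- mean(d[upper.tri(d)])
    R <- (n - 1) * dbar
    opt <- shp_optimal_path(d, cap = cap)
    per_T <- lapply(temperatures, function(Tv)
      shp_ensemble(d, ensemble_params(d, T = Tv, R = R), cap = cap))
    names(per_T) <- as.character(temperatures)
    report$metrics[[metric]] <- list(distance = d, dbar = dbar, R = R,
                                     optimal_path = opt$path,
                                     optimal_length = opt$length,
                                     ensembles = per_T)
  }
  structure(report, class = "cluster_report")
}

#' @export
print.cluster_report <- function(x, ...) {
  cat("<cluster_report>", x$n, "genes:", paste(x$labels, collapse = ", "), "\n")
  for (metric in names(x$metrics)) {
    m <- x$metrics[[metric]]
    cat(sprintf("  %s: dbar = %.4g, R = %.4g, optimal path: %s (length %.4g)\n",
                metric, m$dbar, m$R,
                paste(x$labels[m$optimal_path], collapse = " - "),
                m$optimal_length))
    for (Tv in names(m$ensembles)) {
      ep <- m$ensembles[[Tv]]$endpoint
      top <- order(ep, decreasing = TRUE)[1:2]
      cat(sprintf("    T = %s: most probable endpoints %s (%.3f), %s (%.3f)\n",
                  Tv, x$labels[top[1]], ep[top[1]], x$labels[top[2]], ep[top[2]]))
    }
  }
  invisible(x)
}

#' Synthesize a serial-duplication gene cluster
#'
#' Emulates a cluster that arose by successive local duplication: genetic
#' distance grows monotonically with genomic distance. Divergence increments
#' `u_k > 0` between adjacent genes are drawn once and accumulated, giving
#' `d0[i, j] = sum(u[i..j-1])`; at `noise = 0` this satisfies the Robinson
#' property `d_ik >= max(d_ij, d_jk)` (for `i < j < k`) exactly. Positive
#' `noise` adds seeded symmetric Gaussian perturbations (standard deviation
#' `noise`, clipped at 0).
#'
#' With `emit = "sequences"`, integer increments are realized as mutations at
#' fresh alignment positions of a length-`n_positions` amino-acid sequence,
#' so the Hamming distances reproduce the additive matrix exactly (each
#' position is mutated at most once); sequence-mode noise mutates
#' `rpois(1, noise)` additional random positions per gene.
#'
#' @param n Number of genes (>= 3).
#' @param noise Nonnegative noise scale.
#' @param seed Optional integer seed; identical seeds give identical output.
#' @param emit `"matrix"` for a [distance_matrix()], `"sequences"` for a
#'   named vector of aligned amino-acid sequences.
#' @param n_positions Alignment length in sequence mode (60 for
#'   homeodomains).
#' @param increment_range Range of per-duplication divergence increments
#'   (continuous for matrix mode; rounded up to >= 1 integers in sequence
#'   mode).
#' @return A [distance_matrix()] or a named character vector of sequences,
#'   with labels `g01 .. gNN` in genomic order.
#' @export
synthesize_cluster <- function(n, noise = 0, seed = NULL,
                               emit = c("matrix", "sequences"),
                               n_positions = 60L, increment_range = c(2, 6)) {
  emit <- match.arg(emit)
  stopifnot(n >= 3, noise >= 0)
  if (!is.null(seed)) set.seed(seed)
  labels <- sprintf("g%02d", seq_len(n))
  if (emit == "matrix") {
    u <- stats::runif(n - 1, increment_range[1], increment_range[2])
    cum <- c(0, cumsum(u))
    d <- abs(outer(cum, cum, `-`))
    if (noise > 0) {
      eps <- matrix(stats::rnorm(n * n, sd = noise), n, n)
      eps[lower.tri(eps, diag = TRUE)] <- 0
      d <- pmax(d + eps + t(eps), 0)
      diag(d) <- 0
    }
    return(distance_matrix(d, labels = labels))
  }
  k <- pmax(1L, round(stats::runif(n - 1, increment_range[1], increment_range[2])))
  if (sum(k) > n_positions)
    stop("total divergence ", sum(k), " exceeds the alignment length ",
         n_positions, "; reduce n or the increments")
  seqs <- matrix("", n, n_positions)
  seqs[1, ] <- sample(AA20, n_positions, replace = TRUE)
  avail <- seq_len(n_positions)
  for (i in 2:n) {
    seqs[i, ] <- seqs[i - 1, ]
    pos <- sample(avail, k[i - 1])
    avail <- setdiff(avail, pos)
    for (p in pos) seqs[i, p] <- sample(setdiff(AA20, seqs[i, p]), 1)
  }
  if (noise > 0) {
    for (i in seq_len(n)) {
      extra <- stats::rpois(1, noise)
      if (extra > 0) {
        pos <- sample(n_positions, min(extra, n_positions))
        for (p in pos) seqs[i, p] <- sample(setdiff(AA20, seqs[i, p]), 1)
      }
    }
  }
  out <- apply(seqs, 1, paste, collapse = "")
  names(out) <- labels
  out
}

#' Check the Robinson property of a matrix in label order
#' @param d A square dissimilarity matrix.
#' @param tol Tolerance.
#' @return `TRUE` iff `d[i, k] >= max(d[i, j], d[j, k]) - tol` for all
#'   `i < j < k`.
#' @export
is_robinson <- function(d, tol = 1e-9) {
  d <- as.matrix(d)
  n <- nrow(d)
  for (i in 1:(n - 2)) for (j in (i + 1):(n - 1)) for (k in (j + 1):n) {
    if (d[i, k] < max(d[i, j], d[j, k]) - tol) return(FALSE)
  }
  TRUE
}

#' Serialize a cluster report to JSON
#'
#' Numeric content is written at full precision so that reading the file back
#' reproduces the report ([read_cluster_report()]).
#'
#' @param report A `cluster_report`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_cluster_report <- function(report, path) {
  obj <- list(temperatures = report$temperatures, n = report$n,
              labels = report$labels, metrics = list())
  for (metric in names(report$metrics)) {
    m <- report$metrics[[metric]]
    obj$metrics[[metric]] <- list(
      distance = unclass(m$distance), dbar = m$dbar, R = m$R,
      optimal_path = m$optimal_path, optimal_length = m$optimal_length,
      ensembles = lapply(m$ensembles, function(e)
        list(Z_total = e$Z_total, Z_pq = unclass(e$Z_pq),
             adjacency = unclass(e$adjacency), endpoint = unname(e$endpoint),
             endpoint_pair = unclass(e$endpoint_pair))))
  }
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Read back a serialized cluster report
#' @param path File written by [write_cluster_report()].
#' @return A list mirroring the report structure (matrices restored).
#' @export
read_cluster_report <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  for (metric in names(obj$metrics)) {
    m <- obj$metrics[[metric]]
    obj$metrics[[metric]]$distance <- as.matrix(m$distance)
    for (Tv in names(m$ensembles)) {
      e <- obj$metrics[[metric]]$ensembles[[Tv]]
      obj$metrics[[metric]]$ensembles[[Tv]]$Z_pq <- as.matrix(e$Z_pq)
      obj$metrics[[metric]]$ensembles[[Tv]]$adjacency <- as.matrix(e$adjacency)
      obj$metrics[[metric]]$ensembles[[Tv]]$endpoint_pair <-
        as.matrix(e$endpoint_pair)
    }
  }
  obj
}
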