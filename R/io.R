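#' Read a FASTA file
#'
#' Thin wrapper around Biostrings preserving record order (genomic order
#' matters for cluster analysis). Empty files and duplicated labels are
#' errors.
#'
#' @param path FASTA file.
#' @return Named character vector of sequences, in file order.
#' @export
read_fasta <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  set <- Biostrings::readBStringSet(path)
  if (length(set) == 0) stop("no FASTA records in ", path)
  labels <- sub("\\s.*$", "", names(set))
  if (anyDuplicated(labels))
    stop("duplicate FASTA labels: ",
         paste(unique(labels[duplicated(labels)]), collapse = ", "))
  out <- as.character(set)
  names(out) <- labels
  out
}

#' Write sequences to FASTA
#' @param sequences Named character vector.
#' @param path Output file.
#' @return `path`, invisibly.
#' @export
write_fasta <- function(sequences, path) {
  stopifnot(!is.null(names(sequences)))
  set <- Biostrings::BStringSet(sequences)
  Biostrings::writeXStringSet(set, path)
  invisible(path)
}

#' Read a PHYLIP-style square distance matrix
#'
#' Dialect: first line the vertex count `n`, then `n` rows of
#' `label value_1 ... value_n` (whitespace-separated).
#'
#' @param path Input file.
#' @param require_symmetric Passed to [distance_matrix()]; with the default
#'   `TRUE`, asymmetric input is rejected naming the offending cell.
#' @return A [distance_matrix()].
#' @export
read_distance_matrix <- function(path, require_symmetric = TRUE) {
  if (!file.exists(path)) stop("file not found: ", path)
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines))]
  if (!length(lines)) stop("empty distance matrix file: ", path)
  n <- suppressWarnings(as.integer(trimws(lines[1])))
  if (is.na(n) || n < 2) stop("first line must be the vertex count")
  if (length(lines) < n + 1) stop("expected ", n, " matrix rows, found ",
                                  length(lines) - 1)
  labels <- character(n)
  d <- matrix(NA_real_, n, n)
  for (i in seq_len(n)) {
    parts <- strsplit(trimws(lines[i + 1]), "\\s+")[[1]]
    if (length(parts) != n + 1)
      stop("row ", i, ": expected a label and ", n, " values, got ",
           length(parts) - 1)
    labels[i] <- parts[1]
    d[i, ] <- as.numeric(parts[-1])
  }
  if (anyNA(d)) stop("non-numeric entries in the distance matrix")
  distance_matrix(d, labels = labels, require_symmetric = require_symmetric)
}

#' Write a PHYLIP-style square distance matrix
#' @param d A [distance_matrix()] (or plain square matrix).
#' @param path Output file.
#' @param digits Significant digits for the values.
#' @return `path`, invisibly.
#' @export
write_distance_matrix <- function(d, path, digits = 6) {
  d <- as.matrix(d)
  labels <- rownames(d)
  if (is.null(labels)) labels <- paste0("V", seq_len(nrow(d)))
  lines <- c(as.character(nrow(d)),
             vapply(seq_len(nrow(d)), function(i)
               paste(c(format(labels[i], width = 10),
                       format(signif(d[i, ], digits))), collapse = " "),
               character(1)))
  writeLines(lines, path)
  invisible(path)
}

#' Write a matrix as TSV with row and column headers
#' @param m Matrix.
#' @param path Output file.
#' @param row_label Header of the first (row-name) column.
#' @return `path`, invisibly.
#' @export
write_tsv_matrix <- function(m, path, row_label = "id") {
  df <- data.frame(rownames(m), signif(m, 6), check.names = FALSE)
  colnames(df) <- c(row_label, colnames(m))
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
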