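DNA <- c("A", "C", "G", "T")

#' Parameters of the two-state CpG-island HMM
#'
#' The model tracks, per position, whether it lies inside (`+`) or outside
#' (`-`) a CpG island. The probability that nucleotide `b` follows `a`
#' depends on the state and is given by the row-stochastic dinucleotide
#' matrices `a_plus` / `a_minus` (rows index the previous nucleotide, columns
#' the next; rows sum to 1). `q_pm` is the per-step probability of switching
#' `+ -> -`, `q_mp` of switching `- -> +`. The factor for the step
#' `i-1 -> i` uses the *source* state's dinucleotide table and switch
#' probability. Because position 1 has no predecessor nucleotide, its factor
#' uses a per-state initial emission weight (`init_plus` / `init_minus`,
#' default: the column marginal of the corresponding dinucleotide matrix)
#' while keeping the start values at 1 per state; `start_plus` /
#' `start_minus` weight (or forbid) the two possible start states.
#'
#' @param a_plus,a_minus 4x4 numeric matrices with rows/columns in order
#'   A, C, G, T; each row sums to 1 (tolerance `tol`).
#' @param q_pm,q_mp State-switch probabilities in `[0, 1]`.
#' @param init_plus,init_minus Optional length-4 initial emission weights.
#' @param start_plus,start_minus Start-state weights (default 1 each).
#' @param tol Row-sum validation tolerance.
#' @return A list of class `hmm_params`.
#' @export
hmm_params <- function(a_plus, a_minus, q_pm, q_mp,
                       init_plus = NULL, init_minus = NULL,
                       start_plus = 1, start_minus = 1, tol = 1e-9) {
  chk <- function(a, what) {
    a <- as.matrix(a)
    if (!all(dim(a) == c(4L, 4L))) stop(what, " must be 4x4")
    if (any(a < 0 | a > 1)) stop(what, " entries must be in [0, 1]")
    if (any(abs(rowSums(a) - 1) > tol))
      stop(what, " rows must sum to 1 (tolerance ", tol, ")")
    dimnames(a) <- list(DNA, DNA)
    a
  }
  a_plus <- chk(a_plus, "a_plus"); a_minus <- chk(a_minus, "a_minus")
  stopifnot(q_pm >= 0, q_pm <= 1, q_mp >= 0, q_mp <= 1,
            start_plus >= 0, start_minus >= 0)
  if (is.null(init_plus)) init_plus <- colMeans(a_plus)
  if (is.null(init_minus)) init_minus <- colMeans(a_minus)
  names(init_plus) <- names(init_minus) <- DNA
  structure(list(a_plus = a_plus, a_minus = a_minus, q_pm = q_pm, q_mp = q_mp,
                 init_plus = init_plus, init_minus = init_minus,
                 start_plus = start_plus, start_minus = start_minus),
            class = "hmm_params")
}

encode_dna <- function(seq) {
  x <- strsplit(toupper(seq), "")[[1]]
  if (!length(x)) stop("sequence must be nonempty")
  bad <- setdiff(unique(x), DNA)
  if (length(bad)) stop("non-ACGT character(s): ", paste(bad, collapse = ", "))
  match(x, DNA)
}

# step factors for the transition (i-1 -> i); source state's table applies
hmm_step <- function(p, a, b) {
  list(pp = (1 - p$q_pm) * p$a_plus[a, b],   # + stays +
       pm = p$q_pm       * p$a_plus[a, b],   # + switches to -
       mm = (1 - p$q_mp) * p$a_minus[a, b],  # - stays -
       mp = p$q_mp       * p$a_minus[a, b])  # - switches to +
}

hmm_step1 <- function(p, b) {                 # virtual step 0 -> 1
  list(pp = (1 - p$q_pm) * p$init_plus[b],
       pm = p$q_pm       * p$init_plus[b],
       mm = (1 - p$q_mp) * p$init_minus[b],
       mp = p$q_mp       * p$init_minus[b])
}

lse2 <- function(a, b) {
  m <- pmax(a, b)
  ifelse(is.infinite(m) & m < 0, -Inf, m + log(exp(a - m) + exp(b - m)))
}

#' Forward recursion of the CpG-island HMM
#'
#' Fills the prefix tables `f_plus[i]`, `f_minus[i]` (probability mass of all
#' state paths for the first `i` positions ending in state `+` / `-`) left to
#' right, starting from `f_plus[0] = f_minus[0] = 1`. The sequence
#' likelihood is `f_plus[n] + f_minus[n]`. For `n > 64` the computation runs
#' in log space to avoid underflow (log tables are then attached and used by
#' downstream posteriors).
#'
#' @param params An [hmm_params()] object.
#' @param seq Nonempty nucleotide string over A, C, G, T.
#' @param logspace `"auto"` (log space for `n > 64`), `"never"`, `"always"`.
#' @return A list of class `hmm_tables` with `f_plus`, `f_minus` (length
#'   `n + 1`, entry 1 = position 0), `total`, `log_total`, the input and, in
#'   log mode, `log_f_plus` / `log_f_minus`.
#' @export
hmm_forward <- function(params, seq, logspace = c("auto", "never", "always")) {
  logspace <- match.arg(logspace)
  x <- encode_dna(seq)
  n <- length(x)
  use_log <- switch(logspace, auto = n > 64L, never = FALSE, always = TRUE)
  fp <- fm <- numeric(n + 1)
  if (!use_log) {
    fp[1] <- fm[1] <- 1
    s <- hmm_step1(params, x[1])
    fp[2] <- params$start_plus * s$pp + params$start_minus * s$mp
    fm[2] <- params$start_minus * s$mm + params$start_plus * s$pm
    if (n >= 2) for (i in 2:n) {
      s <- hmm_step(params, x[i - 1], x[i])
      fp[i + 1] <- fp[i] * s$pp + fm[i] * s$mp
      fm[i + 1] <- fm[i] * s$mm + fp[i] * s$pm
    }
    total <- fp[n + 1] + fm[n + 1]
    out <- list(f_plus = fp, f_minus = fm, total = total,
                log_total = log(total), seq = seq, n = n, logspace = FALSE)
  } else {
    lfp <- lfm <- numeric(n + 1)
    s <- hmm_step1(params, x[1])
    lfp[2] <- lse2(log(params$start_plus) + log(s$pp),
                   log(params$start_minus) + log(s$mp))
    lfm[2] <- lse2(log(params$start_minus) + log(s$mm),
                   log(params$start_plus) + log(s$pm))
    if (n >= 2) for (i in 2:n) {
      s <- hmm_step(params, x[i - 1], x[i])
      lfp[i + 1] <- lse2(lfp[i] + log(s$pp), lfm[i] + log(s$mp))
      lfm[i + 1] <- lse2(lfm[i] + log(s$mm), lfp[i] + log(s$pm))
    }
    log_total <- lse2(lfp[n + 1], lfm[n + 1])
    out <- list(f_plus = exp(lfp), f_minus = exp(lfm), total = exp(log_total),
                log_total = log_total, log_f_plus = lfp, log_f_minus = lfm,
                seq = seq, n = n, logspace = TRUE)
  }
  structure(out, class = "hmm_tables")
}

#' Backward (outside) recursion of the CpG-island HMM
#'
#' Fills the suffix tables `b_plus[i]`, `b_minus[i]` right to left from
#' `b_plus[n] = b_minus[n] = 1`. Entry `i = 0` folds in the position-1
#' initial factors and start weights, so the backward total
#' `b_plus[0] + b_minus[0]` equals the forward likelihood.
#'
#' @inheritParams hmm_forward
#' @return A list of class `hmm_tables` with `b_plus`, `b_minus` (length
#'   `n + 1`, entry 1 = position 0), `total` and `log_total`.
#' @export
hmm_backward <- function(params, seq, logspace = c("auto", "never", "always")) {
  logspace <- match.arg(logspace)
  x <- encode_dna(seq)
  n <- length(x)
  use_log <- switch(logspace, auto = n > 64L, never = FALSE, always = TRUE)
  if (!use_log) {
    bp <- bm <- numeric(n + 1)
    bp[n + 1] <- bm[n + 1] <- 1
    if (n >= 2) for (i in (n - 1):1) {
      s <- hmm_step(params, x[i], x[i + 1])
      bp[i + 1] <- s$pp * bp[i + 2] + s$pm * bm[i + 2]
      bm[i + 1] <- s$mm * bm[i + 2] + s$mp * bp[i + 2]
    }
    s <- hmm_step1(params, x[1])
    bp[1] <- params$start_plus * (s$pp * bp[2] + s$pm * bm[2])
    bm[1] <- params$start_minus * (s$mm * bm[2] + s$mp * bp[2])
    total <- bp[1] + bm[1]
    out <- list(b_plus = bp, b_minus = bm, total = total,
                log_total = log(total), seq = seq, n = n, logspace = FALSE)
  } else {
    lbp <- lbm <- numeric(n + 1)
    if (n >= 2) for (i in (n - 1):1) {
      s <- hmm_step(params, x[i], x[i + 1])
      lbp[i + 1] <- lse2(log(s$pp) + lbp[i + 2], log(s$pm) + lbm[i + 2])
      lbm[i + 1] <- lse2(log(s$mm) + lbm[i + 2], log(s$mp) + lbp[i + 2])
    }
    s <- hmm_step1(params, x[1])
    lbp[1] <- log(params$start_plus) + lse2(log(s$pp) + lbp[2],
                                            log(s$pm) + lbm[2])
    lbm[1] <- log(params$start_minus) + lse2(log(s$mm) + lbm[2],
                                             log(s$mp) + lbp[2])
    log_total <- lse2(lbp[1], lbm[1])
    out <- list(b_plus = exp(lbp), b_minus = exp(lbm), total = exp(log_total),
                log_total = log_total, log_b_plus = lbp, log_b_minus = lbm,
                seq = seq, n = n, logspace = TRUE)
  }
  structure(out, class = "hmm_tables")
}

check_same_run <- function(fwd, bwd) {
  if (is.null(fwd$f_plus) || is.null(bwd$b_plus))
    stop("pass forward tables first, backward tables second")
  if (fwd$n != bwd$n || fwd$seq != bwd$seq)
    stop("forward and backward tables come from different inputs")
}

#' Per-position posterior probability of the `+` state
#'
#' Combines forward and backward tables: the probability that position `i`
#' lies in a CpG island is `f_plus[i] * b_plus[i] / Z`, with `Z` the forward
#' total. The normalization makes `P(+) + P(-) = 1` at every position; the
#' raw inside-outside products are available via [hmm_joint_product()].
#'
#' @param fwd,bwd Tables from [hmm_forward()] and [hmm_backward()] for the
#'   same parameters and sequence.
#' @return A data frame with columns `position` (1-based), `base`, `p_plus`,
#'   `p_minus`.
#' @export
hmm_posterior <- function(fwd, bwd) {
  check_same_run(fwd, bwd)
  n <- fwd$n
  i <- 2:(n + 1)
  if (isTRUE(fwd$logspace) && !is.null(fwd$log_f_plus) &&
      !is.null(bwd$log_b_plus)) {
    pp <- exp(fwd$log_f_plus[i] + bwd$log_b_plus[i] - fwd$log_total)
    pm <- exp(fwd$log_f_minus[i] + bwd$log_b_minus[i] - fwd$log_total)
  } else {
    pp <- fwd$f_plus[i] * bwd$b_plus[i] / fwd$total
    pm <- fwd$f_minus[i] * bwd$b_minus[i] / fwd$total
  }
  data.frame(position = seq_len(n), base = strsplit(toupper(fwd$seq), "")[[1]],
             p_plus = pp, p_minus = pm)
}

#' Unnormalized inside-outside products of the HMM
#'
#' Returns the raw products `f_sigma[i] * b_sigma[i]` for both states at
#' positions `0..n`. Their sum across states is constant over `i` and equals
#' the sequence likelihood.
#'
#' @inheritParams hmm_posterior
#' @return Matrix with rows `plus`, `minus` and `n + 1` columns (position
#'   `0..n`).
#' @export
hmm_joint_product <- function(fwd, bwd) {
  check_same_run(fwd, bwd)
  rbind(plus = fwd$f_plus * bwd$b_plus,
        minus = fwd$f_minus * bwd$b_minus)
}
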