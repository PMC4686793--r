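#' Exhaustively enumerate derivations of an input
#'
#' Brute-force yield parser for small inputs: enumerates every derivation of
#' the full input from the start symbol by trying all productions and all
#' ways of splitting the covered intervals among the right-hand-side symbols.
#' This is the independent oracle against which the dynamic-programming
#' engines are checked; it shares no code with them.
#'
#' Works for ordered (string-like) grammars on one or two tapes. Set-like
#' grammars (multiset right-hand sides) have their own dedicated enumerator,
#' [enumerate_hamiltonian_paths()].
#'
#' @param g An ordered [adp_grammar()].
#' @param input Character vector of length `g$tapes`: the tape contents.
#' @param limit Abort (with an error) when more than this many parses are
#'   generated; guards against using the oracle on inputs that are too large.
#' @param production_filter Optional `function(production, children)`
#'   returning `FALSE` to veto a candidate derivation step; used e.g. to
#'   enforce base-pair complementarity between the two pair terminals of the
#'   RNA grammar. `children` is the list of already-built child nodes.
#' @return List of parse trees. Each internal node is
#'   `list(symbol, production, attribute, children)`; each leaf is
#'   `list(symbol, spans)` where `spans[[t]] = c(lo, hi)` delimits the
#'   consumed characters `lo+1 .. hi` on tape `t` (0-based, half-open).
#' @export
enumerate_parses <- function(g, input, limit = 100000L,
                             production_filter = NULL) {
  stopifnot(inherits(g, "adp_grammar"))
  if (!g$ordered)
    stop("enumerate_parses handles ordered (string) tapes; ",
         "use enumerate_hamiltonian_paths() for punctuated-set grammars")
  if (length(input) != g$tapes)
    stop("expected ", g$tapes, " tape(s), got ", length(input))
  tapes <- lapply(input, function(s) strsplit(s, "")[[1]])
  lens <- vapply(tapes, length, integer(1))
  count <- 0L

  by_lhs <- split(g$productions,
                  vapply(g$productions, function(p) p$lhs, character(1)))

  # all ways to cut the interval [lo, hi] into `parts` consecutive pieces
  cuts <- function(lo, hi, parts) {
    if (parts == 1L) return(list(c(lo, hi)))
    out <- list()
    for (c1 in lo:hi) {
      for (rest in cuts(c1, hi, parts - 1L)) {
        out[[length(out) + 1L]] <- c(lo, rest)
      }
    }
    out
  }

  derive <- function(symname, spans, stack) {
    sym <- g$symbols[[symname]]
    widths <- vapply(spans, function(sp) sp[2] - sp[1], numeric(1))
    if (sym$role %in% c("terminal", "stop")) {
      if (!all(widths == sym$consumes)) return(list())
      return(list(list(symbol = symname, spans = spans)))
    }
    key <- paste(symname, paste(unlist(spans), collapse = ","))
    if (key %in% stack) return(list())  # cycle on identical spans: no new parses
    stack <- c(stack, key)
    prods <- by_lhs[[symname]]
    if (is.null(prods)) return(list())
    results <- list()
    for (p in prods) {
      r <- length(p$rhs)
      # candidate cut sequences per tape
      tape_cuts <- lapply(seq_len(g$tapes), function(t)
        cuts(spans[[t]][1], spans[[t]][2], r))
      idx <- rep(1L, g$tapes)
      repeat {
        # assemble per-child spans for this combination of cuts
        ok <- TRUE
        child_spans <- vector("list", r)
        for (k in seq_len(r)) child_spans[[k]] <- vector("list", g$tapes)
        for (t in seq_len(g$tapes)) {
          cc <- tape_cuts[[t]][[idx[t]]]
          for (k in seq_len(r)) child_spans[[k]][[t]] <- c(cc[k], cc[k + 1])
        }
        # prune on fixed terminal widths
        for (k in seq_len(r)) {
          s <- g$symbols[[p$rhs[k]]]
          if (s$role %in% c("terminal", "stop")) {
            w <- vapply(child_spans[[k]], function(sp) sp[2] - sp[1], numeric(1))
            if (!all(w == s$consumes)) { ok <- FALSE; break }
          }
        }
        if (ok) {
          kid_lists <- vector("list", r)
          for (k in seq_len(r)) {
            kid_lists[[k]] <- derive(p$rhs[k], child_spans[[k]], stack)
            if (!length(kid_lists[[k]])) { ok <- FALSE; break }
          }
          if (ok) {
            combos <- expand.grid(lapply(kid_lists, seq_along))
            for (row in seq_len(nrow(combos))) {
              children <- lapply(seq_len(r), function(k)
                kid_lists[[k]][[combos[row, k]]])
              if (!is.null(production_filter) &&
                  !isTRUE(production_filter(p, children))) next
              count <<- count + 1L
              if (count > limit)
                stop("oracle too large: more than ", limit, " parses")
              results[[length(results) + 1L]] <-
                list(symbol = symname, production = prod_string(p),
                     attribute = p$attribute, children = children)
            }
          }
        }
        # advance multi-tape cut index
        t <- 1L
        while (t <= g$tapes) {
          idx[t] <- idx[t] + 1L
          if (idx[t] <= length(tape_cuts[[t]])) break
          idx[t] <- 1L
          t <- t + 1L
        }
        if (t > g$tapes) break
      }
    }
    results
  }

  spans0 <- lapply(lens, function(n) c(0, n))
  derive(g$start, spans0, character(0))
}

#' Flatten a parse tree into its terminal leaves
#'
#' @param tree A parse tree from [enumerate_parses()].
#' @return List of leaves, each `list(symbol, spans)`, in left-to-right
#'   derivation order.
#' @export
parse_leaves <- function(tree) {
  if (is.null(tree$children)) return(list(tree))
  out <- list()
  for (ch in tree$children) out <- c(out, parse_leaves(ch))
  out
}

#' Characters consumed by a leaf
#' @param leaf A leaf from [parse_leaves()].
#' @param input The tape contents passed to [enumerate_parses()].
#' @return List (per tape) of character vectors consumed by the leaf.
#' @export
leaf_chars <- function(leaf, input) {
  tapes <- lapply(input, function(s) strsplit(s, "")[[1]])
  lapply(seq_along(tapes), function(t) {
    sp <- leaf$spans[[t]]
    if (sp[2] > sp[1]) tapes[[t]][(sp[1] + 1):sp[2]] else character(0)
  })
}

#' Render a grammar as index-explicit recursions
#'
#' Produces a human-readable listing of the production rules with explicit
#' index handling: string nonterminals become interval-indexed tables, and
#' each rule is shown as the table update it induces.
#'
#' @param g An [adp_grammar()].
#' @return Character vector, one line per production.
#' @export
render_recursions <- function(g) {
  idx <- function(name) {
    role <- symbol_role(g, name)
    if (role %in% c("terminal")) return(name)
    if (role == "stop") return(paste0(name, "[empty]"))
    paste0(name, "[i..j]")
  }
  vapply(g$productions, function(p) {
    paste0(idx(p$lhs), "  <-  ",
           paste(vapply(p$rhs, idx, character(1)), collapse = " . "),
           "   {", p$attribute, "}")
  }, character(1))
}
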