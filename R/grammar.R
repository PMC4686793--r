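#' Declare a grammar symbol
#'
#' Symbols are the vocabulary of a decomposition grammar: terminals that
#' consume input, nonterminals (syntactic variables) that stand for
#' sub-objects, the unique start and stop symbols, and -- in derived outside
#' grammars -- starred outside nonterminals that stand for the complement of
#' an inside object relative to the full input.
#'
#' @param name Symbol identifier (a string). By convention outside
#'   nonterminals carry a trailing `"*"`.
#' @param role One of `"terminal"`, `"nonterminal"`, `"start"`, `"stop"`,
#'   `"outside-nonterminal"`.
#' @param boundary What the boundary of an object of this symbol is:
#'   `"empty"` (object and complement are disjoint), `"left-right-points"`
#'   (a prefix/suffix boundary position), `"point-pair"` (e.g. the closing
#'   base pair of a helix) or `"endpoint-set"` (distinguished vertices of a
#'   punctuated set).
#' @param consumes Integer vector, one entry per tape: how many input
#'   characters a terminal consumes on each tape. Ignored for syntactic
#'   variables. Stop symbols consume nothing.
#' @param inside For outside nonterminals, the name of the inside
#'   nonterminal they complement.
#' @return A list of class `adp_symbol`.
#' @export
adp_symbol <- function(name,
                       role = c("nonterminal", "terminal", "start", "stop",
                                "outside-nonterminal"),
                       boundary = c("empty", "left-right-points",
                                    "point-pair", "endpoint-set"),
                       consumes = NULL, inside = NULL) {
  role <- match.arg(role)
  boundary <- match.arg(boundary)
  stopifnot(is.character(name), length(name) == 1L, nzchar(name))
  if (role == "outside-nonterminal" && is.null(inside)) {
    stop("outside nonterminal '", name, "' must reference its inside nonterminal")
  }
  structure(list(name = name, role = role, boundary = boundary,
                 consumes = consumes, inside = inside),
            class = "adp_symbol")
}

#' Declare a production rule
#'
#' @param lhs Name of the symbol on the left-hand side (a nonterminal or the
#'   start symbol).
#' @param rhs Character vector of symbol names on the right-hand side. For
#'   ordered (string) grammars the order is the order of sub-objects on the
#'   input; for multiset (set) grammars it is immaterial.
#' @param attribute Name of the attribute-function slot evaluating this rule.
#'   Defaults to a string rendering of the rule.
#' @return A list of class `adp_production`.
#' @export
adp_production <- function(lhs, rhs, attribute = NULL) {
  stopifnot(is.character(lhs), length(lhs) == 1L, is.character(rhs))
  if (is.null(attribute)) attribute <- paste(lhs, "->", paste(rhs, collapse = " "))
  structure(list(lhs = lhs, rhs = rhs, attribute = attribute),
            class = "adp_production")
}

#' Assemble a decomposition grammar
#'
#' A grammar bundles symbols and productions together with the unique start
#' and stop symbols, the number of input tapes (1 for HMM/RNA, 2 for
#' pairwise alignment) and whether right-hand sides are ordered lists
#' (strings) or multisets (sets).
#'
#' @param symbols List of [adp_symbol()] objects.
#' @param productions List of [adp_production()] objects.
#' @param start,stop Names of the start and stop symbols.
#' @param tapes Number of input tapes.
#' @param ordered `TRUE` for string-like (totally ordered) data, `FALSE` for
#'   set-like data where the right-hand side is a multiset.
#' @return A list of class `adp_grammar`.
#' @export
adp_grammar <- function(symbols, productions, start, stop, tapes = 1L,
                        ordered = TRUE) {
  nms <- vapply(symbols, function(s) s$name, character(1))
  if (anyDuplicated(nms)) stop("duplicate symbol names: ",
                               paste(unique(nms[duplicated(nms)]), collapse = ", "))
  names(symbols) <- nms
  if (!start %in% nms) stop("start symbol '", start, "' not declared")
  if (!stop %in% nms) stop("stop symbol '", stop, "' not declared")
  if (symbols[[start]]$role != "start") stop("symbol '", start, "' must have role 'start'")
  if (symbols[[stop]]$role != "stop") stop("symbol '", stop, "' must have role 'stop'")
  if (sum(vapply(symbols, function(s) s$role == "start", logical(1))) != 1L)
    stop("grammar must have exactly one start symbol")
  if (sum(vapply(symbols, function(s) s$role == "stop", logical(1))) != 1L)
    stop("grammar must have exactly one stop symbol")
  for (p in productions) {
    if (!p$lhs %in% nms) stop("production lhs '", p$lhs, "' not declared")
    miss <- setdiff(p$rhs, nms)
    if (length(miss)) stop("production '", prod_string(p),
                           "' uses undeclared symbols: ", paste(miss, collapse = ", "))
    lrole <- symbols[[p$lhs]]$role
    if (!lrole %in% c("nonterminal", "start", "outside-nonterminal"))
      stop("production lhs '", p$lhs, "' must be a syntactic variable or the start symbol")
  }
  # default terminal consumption: one character per tape
  for (i in seq_along(symbols)) {
    s <- symbols[[i]]
    if (s$role == "terminal" && is.null(s$consumes))
      symbols[[i]]$consumes <- rep(1L, tapes)
    if (s$role == "stop") symbols[[i]]$consumes <- rep(0L, tapes)
  }
  structure(list(symbols = symbols, productions = productions, start = start,
                 stop = stop, tapes = as.integer(tapes), ordered = ordered),
            class = "adp_grammar")
}

prod_string <- function(p) paste(p$lhs, "->", paste(p$rhs, collapse = " "))

symbol_role <- function(g, name) g$symbols[[name]]$role

is_variable_role <- function(role) role %in% c("nonterminal", "start", "outside-nonterminal")

#' @export
print.adp_grammar <- function(x, ...) {
  cat("<adp_grammar> tapes:", x$tapes,
      if (x$ordered) "(ordered rhs)" else "(multiset rhs)", "\n")
  cat("  start:", x$start, "  stop:", x$stop, "\n")
  for (p in x$productions) cat("  ", prod_string(p), "\n")
  invisible(x)
}

#' Check whether a grammar is normalized
#'
#' A grammar is normalized if (1) every production with the start symbol on
#' the left has a single syntactic variable as its right-hand side, and
#' (2) every production whose right-hand side contains only terminal material
#' is exactly the epsilon rule `lhs -> stop`. Normalized grammars are closed
#' under the outside transformation.
#'
#' @param g An [adp_grammar()].
#' @return A list with elements `ok` (logical) and `violations` (character
#'   vector of offending rules, empty when `ok`).
#' @export
check_normalized <- function(g) {
  stopifnot(inherits(g, "adp_grammar"))
  viol <- character(0)
  for (p in g$productions) {
    if (p$lhs == g$start) {
      ok <- length(p$rhs) == 1L && is_variable_role(symbol_role(g, p$rhs)) &&
        symbol_role(g, p$rhs) != "start"
      if (!ok) viol <- c(viol, paste0(prod_string(p),
                                      " [start rule rhs is not a single nonterminal]"))
      next
    }
    roles <- vapply(p$rhs, function(s) symbol_role(g, s), character(1))
    if (all(roles %in% c("terminal", "stop"))) {
      if (!(length(p$rhs) == 1L && p$rhs == g$stop))
        viol <- c(viol, paste0(prod_string(p),
                               " [terminal-only rhs must be the single stop symbol]"))
    }
  }
  list(ok = length(viol) == 0L, violations = viol)
}

#' Normalize a grammar
#'
#' Introduces a fresh start symbol (when a start rule has a compound
#' right-hand side) and replaces terminal-only right-hand sides by a chain
#' through a fresh nonterminal ending in the stop rule, so that both
#' normalization conditions of [check_normalized()] hold. Grammars that are
#' already normalized are returned unchanged.
#'
#' @param g An [adp_grammar()].
#' @return A normalized [adp_grammar()].
#' @export
normalize_grammar <- function(g) {
  chk <- check_normalized(g)
  if (chk$ok) return(g)
  symbols <- g$symbols
  prods <- list()
  fresh <- function(base) {
    nm <- base
    while (nm %in% names(symbols)) nm <- paste0(nm, "'")
    nm
  }
  for (p in g$productions) {
    if (p$lhs == g$start &&
        !(length(p$rhs) == 1L && is_variable_role(symbol_role(g, p$rhs)))) {
      # S -> alpha  becomes  S -> A', A' -> alpha
      nm <- fresh("A")
      symbols[[nm]] <- adp_symbol(nm, "nonterminal",
                                  boundary = symbols[[g$start]]$boundary)
      prods <- c(prods, list(adp_production(g$start, nm,
                                            attribute = paste0(p$attribute, ":start")),
                             adp_production(nm, p$rhs, attribute = p$attribute)))
      next
    }
    roles <- vapply(p$rhs, function(s) symbol_role(g, s), character(1))
    if (p$lhs != g$start && all(roles %in% c("terminal", "stop")) &&
        !(length(p$rhs) == 1L && p$rhs == g$stop)) {
      # A -> t1 .. tk  becomes  A -> t1 .. tk E', E' -> eps
      nm <- fresh("E")
      symbols[[nm]] <- adp_symbol(nm, "nonterminal")
      prods <- c(prods, list(adp_production(p$lhs, c(p$rhs[p$rhs != g$stop], nm),
                                            attribute = p$attribute),
                             adp_production(nm, g$stop,
                                            attribute = paste0(p$attribute, ":stop"))))
      next
    }
    prods <- c(prods, list(p))
  }
  adp_grammar(unname(symbols), prods, g$start, g$stop, g$tapes, g$ordered)
}

outside_name <- function(x) paste0(x, "*")

#' Mechanically derive the outside grammar
#'
#' For every inside production `A -> alpha B beta` and every syntactic
#' variable `B` on its right-hand side, the outside grammar receives the
#' production `B* -> alpha A* beta`: the complement of `B` consists of the
#' complement of `A` plus the siblings of `B`. Start and stop exchange roles:
#' each inside start rule `S -> A` yields the outside termination rule
#' `A* -> S*`, and each inside epsilon rule `A -> eps` yields the outside
#' start rule `eps* -> A*`. Every outside rule inherits the attribute slot of
#' the inside rule it was generated from, so inside and outside grammars are
#' isomorphic with respect to their signature and evaluation algebras can be
#' reused unchanged.
#'
#' @param g A normalized [adp_grammar()].
#' @param auto_normalize If `TRUE`, a non-normalized input is first passed
#'   through [normalize_grammar()]; otherwise (default) it is rejected with
#'   the violating rules named.
#' @return The outside [adp_grammar()]; its productions are sorted
#'   lexicographically so that comparisons are deterministic.
#' @export
derive_outside <- function(g, auto_normalize = FALSE) {
  stopifnot(inherits(g, "adp_grammar"))
  chk <- check_normalized(g)
  if (!chk$ok) {
    if (auto_normalize) {
      g <- normalize_grammar(g)
    } else {
      stop("grammar is not normalized; violating rules:\n  ",
           paste(chk$violations, collapse = "\n  "))
    }
  }
  ostart <- outside_name(g$stop)   # eps*  -- start of the outside grammar
  ostop <- outside_name(g$start)   # S*    -- stop of the outside grammar
  symbols <- list(adp_symbol(ostart, "start",
                             boundary = g$symbols[[g$stop]]$boundary),
                  adp_symbol(ostop, "stop"))
  for (s in g$symbols) {
    if (s$role == "nonterminal") {
      symbols <- c(symbols,
                   list(adp_symbol(outside_name(s$name), "outside-nonterminal",
                                   boundary = s$boundary, inside = s$name)),
                   list(s))  # inside nonterminals act as syntactic terminals
    } else if (s$role == "terminal") {
      symbols <- c(symbols, list(s))
    }
  }
  prods <- list()
  for (p in g$productions) {
    if (p$lhs == g$start) {
      # S -> A  ~~>  A* -> S*
      prods <- c(prods, list(adp_production(outside_name(p$rhs), ostop,
                                            attribute = p$attribute)))
      next
    }
    if (length(p$rhs) == 1L && p$rhs == g$stop) {
      # A -> eps  ~~>  eps* -> A*
      prods <- c(prods, list(adp_production(ostart, outside_name(p$lhs),
                                            attribute = p$attribute)))
      next
    }
    for (k in seq_along(p$rhs)) {
      if (symbol_role(g, p$rhs[k]) != "nonterminal") next
      rhs <- p$rhs
      b <- rhs[k]
      rhs[k] <- outside_name(p$lhs)
      prods <- c(prods, list(adp_production(outside_name(b), rhs,
                                            attribute = p$attribute)))
    }
  }
  prods <- prods[order(vapply(prods, prod_string, character(1)))]
  adp_grammar(symbols, prods, ostart, ostop, g$tapes, g$ordered)
}

#' Attribute-function signature of a production
#'
#' The signature records, position by position, the type of each
#' right-hand-side element: `"V"` for a syntactic variable (inside or
#' outside -- complements share the evaluation type) and the per-tape
#' consumption pattern for a terminal. Epsilon rules have the empty
#' signature. The outside transformation preserves these signatures rule by
#' rule.
#'
#' @param g An [adp_grammar()].
#' @param p An [adp_production()] belonging to `g`.
#' @return A character string encoding the signature.
#' @export
production_signature <- function(g, p) {
  parts <- character(0)
  for (s in p$rhs) {
    role <- symbol_role(g, s)
    if (is_variable_role(role)) {
      parts <- c(parts, "V")
    } else if (role == "stop") {
      # consumes nothing; contributes no argument
    } else {
      parts <- c(parts, paste0("t", paste(g$symbols[[s]]$consumes, collapse = ",")))
    }
  }
  paste(parts, collapse = "|")
}

#' Signatures of all productions, keyed by attribute slot
#' @param g An [adp_grammar()].
#' @return Named character vector: `attribute -> signature`, one entry per
#'   production (attributes repeated across productions give repeated names).
#' @export
grammar_signatures <- function(g) {
  sig <- vapply(g$productions, function(p) production_signature(g, p), character(1))
  names(sig) <- vapply(g$productions, function(p) p$attribute, character(1))
  sig
}

#' Canonical rule strings of a grammar (sorted)
#' @param g An [adp_grammar()].
#' @return Sorted character vector, one `"lhs -> rhs"` string per production.
#' @export
grammar_rules <- function(g) sort(vapply(g$productions, prod_string, character(1)))

#' Sanity-check reachability and productivity of a grammar
#'
#' Checks that every syntactic variable is reachable from the start symbol
#' and can derive terminal material. In an outside grammar the inside
#' nonterminals appearing on right-hand sides behave as syntactic terminals
#' (their derivations never reach an outside variable), so variables without
#' productions are treated as terminal-like rather than flagged.
#'
#' @param g An [adp_grammar()].
#' @return Invisibly `TRUE`; warns about unreachable or unproductive
#'   variables.
#' @export
validate_grammar <- function(g) {
  has_prod <- unique(vapply(g$productions, function(p) p$lhs, character(1)))
  vars <- names(g$symbols)[vapply(g$symbols, function(s)
    is_variable_role(s$role) && s$role != "start", logical(1))]
  vars <- intersect(vars, has_prod)
  # reachability
  reach <- g$start
  repeat {
    new <- reach
    for (p in g$productions) if (p$lhs %in% reach) new <- union(new, p$rhs)
    if (length(new) == length(reach)) break
    reach <- new
  }
  unreachable <- setdiff(vars, reach)
  if (length(unreachable))
    warning("unreachable variables: ", paste(unreachable, collapse = ", "))
  # productivity (variables without productions count as terminal-like)
  productive <- names(g$symbols)[vapply(g$symbols, function(s)
    s$role %in% c("terminal", "stop") || !(s$name %in% has_prod), logical(1))]
  repeat {
    new <- productive
    for (p in g$productions) {
      if (!(p$lhs %in% new) && all(p$rhs %in% new)) new <- c(new, p$lhs)
    }
    if (length(new) == length(productive)) break
    productive <- new
  }
  unproductive <- setdiff(vars, productive)
  if (length(unproductive))
    warning("unproductive variables: ", paste(unproductive, collapse = ", "))
  invisible(TRUE)
}

## ------------------------------------------------------------------------
## Bundled grammars: the inside decomposition schemes used by the engines.

#' Two-state HMM (forward) grammar
#'
#' `S -> P | M;  P -> P c | M c | eps;  M -> P c | M c | eps`. The
#' nonterminals `P` and `M` stand for prefixes whose last position is in the
#' `+` (CpG island) or `-` state; the terminal `c` is a transition between
#' adjacent positions, so the boundary of `P`/`M` is the prefix end point.
#' @return An [adp_grammar()].
#' @export
grammar_hmm <- function() {
  syms <- list(
    adp_symbol("S", "start"),
    adp_symbol("eps", "stop"),
    adp_symbol("P", "nonterminal", boundary = "left-right-points"),
    adp_symbol("M", "nonterminal", boundary = "left-right-points"),
    adp_symbol("c", "terminal", consumes = 1L))
  prods <- list(
    adp_production("S", "P", "start_plus"),
    adp_production("S", "M", "start_minus"),
    adp_production("P", c("P", "c"), "stay_plus"),
    adp_production("P", c("M", "c"), "switch_to_plus"),
    adp_production("P", "eps", "init_plus"),
    adp_production("M", c("P", "c"), "switch_to_minus"),
    adp_production("M", c("M", "c"), "stay_minus"),
    adp_production("M", "eps", "init_minus"))
  adp_grammar(syms, prods, "S", "eps", tapes = 1L)
}

#' Needleman-Wunsch alignment grammar (two tapes, linear gap cost)
#'
#' `S -> A;  A -> A uv | A u- | A -v | ee` where `uv` consumes one character
#' on both tapes, `u-`/`-v` consume on a single tape and `ee` is the paired
#' stop symbol. `A` is boundary-free: a prefix-pair alignment.
#' @return An [adp_grammar()].
#' @export
grammar_nw <- function() {
  syms <- list(
    adp_symbol("S", "start"),
    adp_symbol("ee", "stop"),
    adp_symbol("A", "nonterminal"),
    adp_symbol("uv", "terminal", consumes = c(1L, 1L)),
    adp_symbol("u-", "terminal", consumes = c(1L, 0L)),
    adp_symbol("-v", "terminal", consumes = c(0L, 1L)))
  prods <- list(
    adp_production("S", "A", "start"),
    adp_production("A", c("A", "uv"), "subst"),
    adp_production("A", c("A", "u-"), "delete"),
    adp_production("A", c("A", "-v"), "insert"),
    adp_production("A", "ee", "empty"))
  adp_grammar(syms, prods, "S", "ee", tapes = 2L)
}

#' Gotoh affine-gap alignment grammar (two tapes)
#'
#' Three boundary-free nonterminals classify a prefix alignment by its last
#' column: `M` (match/mismatch), `D` (gap in the second sequence), `I` (gap
#' in the first). `u-`/`-v` are gap openings, `u.`/`.v` gap extensions.
#' @return An [adp_grammar()].
#' @export
grammar_gotoh <- function() {
  syms <- list(
    adp_symbol("S", "start"),
    adp_symbol("ee", "stop"),
    adp_symbol("M", "nonterminal"),
    adp_symbol("D", "nonterminal"),
    adp_symbol("I", "nonterminal"),
    adp_symbol("uv", "terminal", consumes = c(1L, 1L)),
    adp_symbol("u-", "terminal", consumes = c(1L, 0L)),
    adp_symbol("u.", "terminal", consumes = c(1L, 0L)),
    adp_symbol("-v", "terminal", consumes = c(0L, 1L)),
    adp_symbol(".v", "terminal", consumes = c(0L, 1L)))
  prods <- list(
    adp_production("S", "M", "start_m"),
    adp_production("S", "D", "start_d"),
    adp_production("S", "I", "start_i"),
    adp_production("M", c("M", "uv"), "subst_mm"),
    adp_production("M", c("D", "uv"), "subst_dm"),
    adp_production("M", c("I", "uv"), "subst_im"),
    adp_production("M", "ee", "empty_m"),
    adp_production("D", c("M", "u-"), "open_md"),
    adp_production("D", c("D", "u."), "extend_dd"),
    adp_production("D", c("I", "u-"), "open_id"),
    adp_production("D", "ee", "empty_d"),
    adp_production("I", c("M", "-v"), "open_mi"),
    adp_production("I", c("D", "-v"), "open_di"),
    adp_production("I", c("I", ".v"), "extend_ii"),
    adp_production("I", "ee", "empty_i"))
  adp_grammar(syms, prods, "S", "ee", tapes = 2L)
}

#' Toy RNA secondary-structure grammar
#'
#' `S -> U;  U -> c U | B U | eps;  B -> c U c'`. `U` is boundary-free; `B`
#' carries the closing base pair as its boundary (the pair is shared with the
#' outside object `B*`).
#' @return An [adp_grammar()].
#' @export
grammar_rna <- function() {
  syms <- list(
    adp_symbol("S", "start"),
    adp_symbol("eps", "stop"),
    adp_symbol("U", "nonterminal"),
    adp_symbol("B", "nonterminal", boundary = "point-pair"),
    adp_symbol("c", "terminal", consumes = 1L),
    adp_symbol("c'", "terminal", consumes = 1L))
  prods <- list(
    adp_production("S", "U", "start"),
    adp_production("U", c("c", "U"), "unpaired"),
    adp_production("U", c("B", "U"), "paired_prefix"),
    adp_production("U", "eps", "empty"),
    adp_production("B", c("c", "U", "c'"), "pair"))
  adp_grammar(syms, prods, "S", "eps", tapes = 1L)
}

#' Hamiltonian-path grammar over punctuated sets
#'
#' `S -> A; A -> A v; A -> eps` with a multiset right-hand side: `A` is a
#' punctuated vertex set (a set with distinguished endpoints) and the
#' terminal `v` is the edge joining the split-off endpoint to the new one.
#' The outside transform yields the complement-growing rule `A* -> A* v`.
#' @return An [adp_grammar()].
#' @export
grammar_shp <- function() {
  syms <- list(
    adp_symbol("S", "start"),
    adp_symbol("eps", "stop"),
    adp_symbol("A", "nonterminal", boundary = "endpoint-set"),
    adp_symbol("v", "terminal", consumes = 1L))
  prods <- list(
    adp_production("S", "A", "anchor_endpoints"),
    adp_production("A", c("A", "v"), "extend_path"),
    adp_production("A", "eps", "singleton"))
  adp_grammar(syms, prods, "S", "eps", tapes = 1L, ordered = FALSE)
}

## ------------------------------------------------------------------------
## JSON round trip

#' Write a grammar to JSON
#'
#' The JSON dialect has keys `tapes`, `ordered`, `start`, `stop`,
#' `symbols` (name/role/boundary/consumes/inside) and `productions`
#' (lhs/rhs/attribute). Reading back a written file reproduces the grammar
#' exactly.
#'
#' @param g An [adp_grammar()].
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_grammar_json <- function(g, path) {
  obj <- list(
    tapes = g$tapes, ordered = g$ordered, start = g$start, stop = g$stop,
    symbols = lapply(unname(g$symbols), function(s) {
      out <- list(name = s$name, role = s$role, boundary = s$boundary)
      if (!is.null(s$consumes)) out$consumes <- as.integer(s$consumes)
      if (!is.null(s$inside)) out$inside <- s$inside
      out
    }),
    productions = lapply(g$productions, function(p)
      list(lhs = p$lhs, rhs = as.list(p$rhs), attribute = p$attribute)))
  jsonlite::write_json(obj, path, auto_unbox = TRUE, pretty = TRUE)
  invisible(path)
}

#' Read a grammar from JSON
#' @param path File written by [write_grammar_json()] (or hand-authored in
#'   the same dialect).
#' @return An [adp_grammar()].
#' @export
read_grammar_json <- function(path) {
  obj <- jsonlite::read_json(path)
  syms <- lapply(obj$symbols, function(s)
    adp_symbol(s$name, s$role,
               boundary = if (is.null(s$boundary)) "empty" else s$boundary,
               consumes = if (is.null(s$consumes)) NULL else
                 as.integer(unlist(s$consumes)),
               inside = s$inside))
  prods <- lapply(obj$productions, function(p)
    adp_production(p$lhs, as.character(unlist(p$rhs)), attribute = p$attribute))
  adp_grammar(syms, prods, obj$start, obj$stop, tapes = as.integer(obj$tapes),
              ordered = isTRUE(obj$ordered))
}
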