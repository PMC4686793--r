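test_that("normalization check accepts the bundled grammars and flags violations", {
  expect_true(check_normalized(grammar_rna())$ok)
  expect_true(check_normalized(grammar_hmm())$ok)
  expect_true(check_normalized(grammar_nw())$ok)
  # Gotoh: the paired stop symbol ee counts as the stop, not as a terminal
  expect_true(check_normalized(grammar_gotoh())$ok)

  # the same rule set with (ee) declared a plain terminal is not normalized
  g_bad <- adp_grammar(
    list(adp_symbol("S", "start"), adp_symbol("eps", "stop"),
         adp_symbol("M", "nonterminal"),
         adp_symbol("ee", "terminal", consumes = c(0L, 0L)),
         adp_symbol("uv", "terminal", consumes = c(1L, 1L))),
    list(adp_production("S", "M"),
         adp_production("M", c("M", "uv")),
         adp_production("M", "ee")),
    "S", "eps", tapes = 2L)
  chk <- check_normalized(g_bad)
  expect_false(chk$ok)
  expect_match(chk$violations, "M -> ee", all = FALSE)

  # start rule with terminal material violates condition (1)
  g_start <- adp_grammar(
    list(adp_symbol("S", "start"), adp_symbol("eps", "stop"),
         adp_symbol("P", "nonterminal"), adp_symbol("c", "terminal")),
    list(adp_production("S", c("P", "c")), adp_production("P", "eps")),
    "S", "eps")
  chk <- check_normalized(g_start)
  expect_false(chk$ok)
  expect_match(chk$violations, "S -> P c", all = FALSE)

  # normalize_grammar repairs both kinds of violation
  expect_true(check_normalized(normalize_grammar(g_start))$ok)
  expect_true(check_normalized(normalize_grammar(g_bad))$ok)
  expect_error(derive_outside(g_start), "not normalized")
  expect_silent(derive_outside(g_start, auto_normalize = TRUE))
})

test_that("derive_outside yields the known backward grammar of the HMM", {
  go <- derive_outside(grammar_hmm())
  expect_identical(
    grammar_rules(go),
    sort(c("eps* -> P*", "eps* -> M*",
           "P* -> P* c", "P* -> M* c", "P* -> S*",
           "M* -> P* c", "M* -> M* c", "M* -> S*")))
  expect_identical(go$start, "eps*")
  expect_identical(go$stop, "S*")
})

test_that("derive_outside reproduces the suffix-style outside grammar of NW", {
  go <- derive_outside(grammar_nw())
  expect_identical(
    grammar_rules(go),
    sort(c("ee* -> A*",
           "A* -> A* uv", "A* -> A* u-", "A* -> A* -v", "A* -> S*")))
})

test_that("derive_outside turns the affine-gap grammar into its gap-closing variant", {
  go <- derive_outside(grammar_gotoh())
  expect_identical(
    grammar_rules(go),
    sort(c("ee* -> M*", "ee* -> D*", "ee* -> I*",
           "M* -> M* uv", "M* -> D* u-", "M* -> I* -v", "M* -> S*",
           "D* -> M* uv", "D* -> D* u.", "D* -> I* -v", "D* -> S*",
           "I* -> M* uv", "I* -> D* u-", "I* -> I* .v", "I* -> S*")))
  # the weight of the inside rule D -> I (u-) attaches to I* -> D* (u-)
  open_id <- Filter(function(p) p$attribute == "open_id", go$productions)
  expect_length(open_id, 1L)
  expect_identical(open_id[[1]]$lhs, "I*")
  expect_identical(open_id[[1]]$rhs, c("D*", "u-"))
})

test_that("derive_outside yields the known outside RNA grammar", {
  go <- derive_outside(grammar_rna())
  expect_identical(
    grammar_rules(go),
    sort(c("eps* -> U*",
           "U* -> c U*", "U* -> B U*", "U* -> c B* c'", "U* -> S*",
           "B* -> U* U")))
})

test_that("derive_outside of the punctuated-set grammar grows the complement", {
  go <- derive_outside(grammar_shp())
  expect_identical(grammar_rules(go),
                   sort(c("eps* -> A*", "A* -> A* v", "A* -> S*")))
  expect_false(go$ordered)
})

test_that("outside productions carry exactly one outside nonterminal", {
  for (g in list(grammar_hmm(), grammar_nw(), grammar_gotoh(), grammar_rna(),
                 grammar_shp())) {
    go <- derive_outside(g)
    for (p in go$productions) {
      n_out <- sum(vapply(p$rhs, function(s)
        go$symbols[[s]]$role %in% c("outside-nonterminal", "stop"), logical(1)))
      expect_equal(n_out, 1L,
                   info = paste(p$lhs, "->", paste(p$rhs, collapse = " ")))
    }
  }
})

test_that("the outside variant of a normalized grammar is normalized", {
  for (g in list(grammar_hmm(), grammar_nw(), grammar_gotoh(), grammar_rna(),
                 grammar_shp())) {
    expect_true(check_normalized(derive_outside(g))$ok)
  }
})

test_that("outside rules keep the attribute signature of their inside generator", {
  for (g in list(grammar_hmm(), grammar_nw(), grammar_gotoh(), grammar_rna(),
                 grammar_shp())) {
    go <- derive_outside(g)
    inside_sig <- grammar_signatures(g)
    # every body rule keeps the signature of the inside rule it came from;
    # the start/stop exchange swaps the (normalized) seed and start types
    start_attrs <- vapply(
      Filter(function(p) p$lhs == g$start, g$productions),
      function(p) p$attribute, character(1))
    eps_attrs <- vapply(
      Filter(function(p) length(p$rhs) == 1 && p$rhs == g$stop, g$productions),
      function(p) p$attribute, character(1))
    for (p in go$productions) {
      expect_true(p$attribute %in% names(inside_sig))
      sig <- production_signature(go, p)
      if (p$attribute %in% start_attrs) {
        # inside S -> A (one variable) became the termination rule A* -> S*
        expect_identical(sig, "")
      } else if (p$attribute %in% eps_attrs) {
        # inside A -> eps (seed) became the outside start rule eps* -> A*
        expect_identical(sig, "V")
      } else {
        expect_identical(sig, unname(inside_sig[[p$attribute]]),
                         info = p$attribute)
      }
    }
    # normalization makes the exchange type-safe: all inside start rules have
    # the single-variable type and all eps rules the seed type, so the
    # signature multisets of the two grammars coincide for linear grammars
    linear <- all(vapply(g$productions, function(p)
      sum(vapply(p$rhs, function(s)
        g$symbols[[s]]$role == "nonterminal", logical(1))) <= 1, logical(1)))
    if (linear) expect_identical(sort(unname(grammar_signatures(go))),
                                 sort(unname(inside_sig)))
  }
})

test_that("grammar JSON round trip is lossless", {
  for (g in list(grammar_rna(), grammar_gotoh(), grammar_shp())) {
    path <- withr::local_tempfile(fileext = ".json")
    write_grammar_json(g, path)
    g2 <- read_grammar_json(path)
    expect_identical(grammar_rules(g2), grammar_rules(g))
    expect_identical(g2$start, g$start)
    expect_identical(g2$stop, g$stop)
    expect_identical(g2$tapes, g$tapes)
    expect_identical(g2$ordered, g$ordered)
    expect_identical(lapply(g2$symbols, unclass), lapply(g$symbols, unclass))
  }
})

test_that("parse enumeration matches hand counts on small alignments", {
  g <- grammar_nw()
  expect_length(enumerate_parses(g, c("A", "B")), 3L)          # match, DI, ID
  expect_length(enumerate_parses(g, c("AB", "CD")), 13L)        # Delannoy(2,2)
  expect_length(enumerate_parses(g, c("", "")), 1L)             # the eps-parse
  expect_length(enumerate_parses(g, c("ABC", "DE")), delannoy(3, 2))
  # Gotoh with the empty-prefix convention: one parse per alignment
  expect_length(enumerate_parses(grammar_gotoh(), c("AB", "CD"),
                                 production_filter = gotoh_filter), 13L)
  expect_error(enumerate_parses(g, c("ABCD", "ABCD"), limit = 10L),
               "oracle too large")
  expect_error(enumerate_parses(grammar_shp(), "x"), "punctuated-set")
})

test_that("grammar reachability validation treats inside symbols in outside grammars as terminals", {
  expect_silent(validate_grammar(grammar_rna()))
  expect_silent(validate_grammar(derive_outside(grammar_rna())))
  g_dead <- adp_grammar(
    list(adp_symbol("S", "start"), adp_symbol("eps", "stop"),
         adp_symbol("P", "nonterminal"), adp_symbol("Q", "nonterminal"),
         adp_symbol("c", "terminal")),
    list(adp_production("S", "P"), adp_production("P", "eps"),
         adp_production("Q", "eps")),
    "S", "eps")
  expect_warning(validate_grammar(g_dead), "unreachable")
})
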