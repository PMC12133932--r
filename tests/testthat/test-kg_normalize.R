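test_that("locate_symptom_spans resolves overlaps longest-first", {
  expect_equal(nrow(locate_symptom_spans("nothing here", "zzz")), 0)
  sp <- locate_symptom_spans("fatigue later", "fatigue")
  expect_equal(sp$start, 0)
  expect_equal(sp$end, 7)
  # overlapping candidates: longest wins
  sp2 <- locate_symptom_spans("severe fatigue", c("fatigue", "severe fatigue"))
  expect_equal(sp2, data.frame(start = 0L, end = 14L))
  expect_error(locate_symptom_spans("x", "(unclosed"), "bad pattern")
})

test_that("split_composite_label splits on the connective lexicon", {
  expect_identical(split_composite_label("fatigue"), "fatigue")
  expect_identical(split_composite_label("fatigue and poor appetite"),
                   c("fatigue", "poor appetite"))
  expect_identical(split_composite_label("a, b and c"), c("a", "b", "c"))
  expect_identical(split_composite_label("口苦和失眠、乏力"),
                   c("口苦", "失眠", "乏力"))
  expect_error(split_composite_label("   "), "empty label")
  # naive delimiter-split oracle on random compositions
  set.seed(42)
  atoms_pool <- c("aching head", "night sweats", "dry mouth", "chills")
  for (i in 1:25) {
    atoms <- sample(atoms_pool, sample(1:4, 1))
    joins <- sample(c(" and ", ", ", " or ", " with "),
                    length(atoms) - 1, replace = TRUE)
    lab <- atoms[1]
    if (length(atoms) > 1)
      for (k in 2:length(atoms)) lab <- paste0(lab, joins[k - 1], atoms[k])
    expect_identical(split_composite_label(lab), atoms)
  }
})

test_that("normalize_term follows the dictionary and is idempotent", {
  d <- term_dictionary(c("fatigue", "poor appetite"),
                       data.frame(surface = c("tiredness", "appetite loss"),
                                  canonical = c("fatigue", "poor appetite")))
  r <- normalize_term("tiredness", d)
  expect_identical(r$output_terms, "fatigue")
  expect_true(r$matched)
  expect_match(r$rule_trace[1], "tiredness->fatigue")
  r2 <- normalize_term("fatigue", d)
  expect_identical(r2$output_terms, "fatigue")
  expect_true(r2$matched)
  r3 <- normalize_term("qqq", d)
  expect_identical(r3$output_terms, "qqq")
  expect_false(r3$matched)
  # idempotence over assorted inputs
  for (x in c("tiredness", "mild tiredness all day", "fatigue", "zz"))
    expect_identical(normalize_term(normalize_term(x, d)$output_terms, d)$output_terms,
                     normalize_term(x, d)$output_terms)
  expect_error(normalize_term("x", term_dictionary(character())),
               "empty dictionary")
  expect_error(term_dictionary("a", data.frame(surface = c("s", "s"),
                                               canonical = c("a", "a"))),
               "two canonicals")
})

test_that("Aho-Corasick equals brute-force scan on exhaustive small cases", {
  set.seed(7)
  alphabet <- c("a", "b", "c")
  for (trial in 1:60) {
    n_pat <- sample(1:8, 1)
    pats <- unique(vapply(seq_len(n_pat), function(i)
      paste(sample(alphabet, sample(1:4, 1), replace = TRUE), collapse = ""),
      ""))
    text <- paste(sample(alphabet, sample(1:30, 1), replace = TRUE),
                  collapse = "")
    ac <- ac_automaton(pats)
    hits <- ac_find(ac, text)
    # brute force: every pattern at every position
    brute <- do.call(rbind, lapply(seq_along(pats), function(p) {
      L <- nchar(pats[p]); starts <- integer()
      if (L <= nchar(text))
        for (s in 1:(nchar(text) - L + 1))
          if (substr(text, s, s + L - 1) == pats[p]) starts <- c(starts, s)
      if (length(starts))
        data.frame(pattern = p, start = starts, end = starts + L - 1L)
    }))
    key <- function(df) sort(paste(df$pattern, df$start, df$end))
    expect_identical(key(hits), if (is.null(brute)) character() else key(brute))
  }
})

test_that("normalizer agrees with the brute-force dictionary-scan oracle", {
  set.seed(11)
  canon <- c("fatigue", "insomnia", "vertigo")
  syn <- data.frame(surface = c("tiredness", "sleepless", "fa", "dizzy spell"),
                    canonical = c("fatigue", "insomnia", "fatigue", "vertigo"))
  d <- term_dictionary(canon, syn)
  surfaces <- c(canon, syn$surface)
  targets <- c(canon, syn$canonical)
  pieces <- c(surfaces, "x", "yz", " ", "qq")
  for (i in 1:300) {
    term <- paste(sample(pieces, sample(1:4, 1), replace = TRUE),
                  collapse = "")
    got <- normalize_term(term, d)
    want <- oracle_normalize(term, surfaces, targets)
    expect_identical(got$output_terms, want$text)
    expect_identical(got$matched, want$matched)
  }
})

test_that("merge_duplicate_nodes unifies synonym nodes per the oracle", {
  g <- tiny_kg()
  # no duplicates -> structurally identical
  d0 <- term_dictionary(c("fatigue", "insomnia", "dizziness"))
  m0 <- merge_duplicate_nodes(g, list(Symptoms = d0))
  expect_equal(nrow(m0$nodes), nrow(g$nodes))
  expect_equal(nrow(m0$triples), nrow(g$triples))
  # tiredness/fatigue collapse into one node with the union of triples
  kg <- kg_new()
  res <- kg_add_nodes(kg, "Syndrome", c("s1", "s2"))
  kg <- res$kg; syn <- res$ids
  res <- kg_add_nodes(kg, "Symptoms", c("tiredness", "fatigue"))
  kg <- res$kg; sym <- res$ids
  kg <- kg_add_triples(kg, syn, "Has_symptom", sym)
  d <- term_dictionary("fatigue",
                       data.frame(surface = "tiredness",
                                  canonical = "fatigue"))
  m <- merge_duplicate_nodes(kg, list(Symptoms = d))
  expect_equal(sum(m$nodes$type == "Symptoms"), 1)
  expect_equal(nrow(m$triples), 2)   # both syndromes point at the merged node
  expect_true(all(m$triples$tail == m$nodes$id[m$nodes$type == "Symptoms"]))
  # chain of three same-canonical nodes -> single node, deduplicated triples
  kg3 <- kg_new()
  res <- kg_add_nodes(kg3, "Syndrome", "s")
  kg3 <- res$kg; s <- res$ids
  res <- kg_add_nodes(kg3, "Symptoms", c("fatigue", "tiredness", "fatiguex"))
  kg3 <- res$kg
  kg3 <- kg_add_triples(kg3, rep(s, 3), "Has_symptom", res$ids)
  d3 <- term_dictionary("fatigue",
                        data.frame(surface = c("tiredness", "fatiguex"),
                                   canonical = c("fatigue", "fatigue")))
  m3 <- merge_duplicate_nodes(kg3, list(Symptoms = d3))
  expect_equal(sum(m3$nodes$type == "Symptoms"), 1)
  expect_equal(nrow(m3$triples), 1)
  # counts never increase
  expect_lte(nrow(m3$nodes), nrow(kg3$nodes))
  expect_lte(nrow(m3$triples), nrow(kg3$triples))
})
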