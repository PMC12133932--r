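test_that("default schema matches the reference entity/relation layout", {
  s <- default_schema()
  expect_identical(s$attributes$Syndrome,
                   c("Syndrome_name", "Syndrome_English", "Syndrome_PinYin",
                     "Syndrome_definition"))
  expect_length(s$attributes$Symptoms, 5)
  expect_length(s$attributes$Herb, 5)
  expect_equal(nrow(s$relations), 9)
  expect_true(any(s$relations$head_type == "Syndrome" &
                    s$relations$relation == "Has_symptom" &
                    s$relations$tail_type == "Symptoms"))
})

test_that("schema validation rejects malformed documents and signatures", {
  expect_error(kg_schema(c("A", "A"), list(A = "x"), data.frame(
    head_type = "A", relation = "r", tail_type = "A")), "duplicate entity")
  expect_error(kg_schema("A", list(A = "x"), data.frame(
    head_type = "A", relation = "r", tail_type = "B")), "unknown entity")
  expect_error(kg_schema("A", list(A = character()), data.frame(
    head_type = character(), relation = character(),
    tail_type = character())), "empty attribute")
  # a round-trip through JSON
  p <- withr::local_tempfile(fileext = ".json")
  s <- default_schema()
  jsonlite::write_json(list(entity_types = s$attributes,
                            relations = s$relations), p)
  s2 <- load_schema(p)
  expect_identical(s2$relations, s$relations)
})

test_that("triples outside the declared signatures are rejected", {
  kg <- kg_new()
  res <- kg_add_nodes(kg, "Symptoms", c("a", "b"))
  expect_error(kg_add_triples(res$kg, res$ids[1], "Has_symptom", res$ids[2]),
               "signature")
  res2 <- kg_add_nodes(res$kg, "Syndrome", "s")
  expect_error(kg_add_triples(res2$kg, res2$ids, "Has_symptom", res2$ids),
               "self-loop")
  expect_error(kg_add_nodes(kg, "Ghost", "x"), "unknown entity type")
  expect_error(kg_add_nodes(kg, "Symptoms", "a",
                            list(c(Bogus_attr = "v"))), "not declared")
})

test_that("kg_fuse is idempotent and unions disjoint graphs", {
  g <- tiny_kg()
  f <- kg_fuse(list(g, g))
  expect_equal(nrow(f$nodes), nrow(g$nodes))
  expect_equal(nrow(f$triples), nrow(g$triples))
  g2 <- kg_new()
  res <- kg_add_nodes(g2, "Symptoms", c("cough", "fever"))
  g2 <- res$kg
  u <- kg_fuse(list(g, g2))
  expect_equal(nrow(u$nodes), nrow(g$nodes) + 2)
})

test_that("kg_fuse merges equal (type, name) nodes per the union-find oracle", {
  mk <- function(defn) {
    kg <- kg_new()
    res <- kg_add_nodes(kg, "Syndrome", "X",
                        list(c(Syndrome_name = "X",
                               Syndrome_definition = defn)))
    kg <- res$kg
    r2 <- kg_add_nodes(kg, "Symptoms", paste0("sym-", defn))
    kg_add_triples(r2$kg, res$ids, "Has_symptom", r2$ids)
  }
  g1 <- mk("first"); g2 <- mk("second")
  f <- kg_fuse(list(g1, g2))
  expect_equal(nrow(f$nodes), length(oracle_merged_node_keys(list(g1, g2))))
  x <- f$nodes$id[f$nodes$type == "Syndrome"]
  expect_length(x, 1)
  # keep-first attribute resolution, discarded value recorded
  expect_equal(unname(f$node_attrs[[as.character(x)]]["Syndrome_definition"]),
               "first")
  expect_equal(attr(f, "conflicts")$discarded, "second")
  # both incident triples survive, re-pointed to the merged id
  expect_equal(sum(f$triples$head == x), 2)
  # associativity up to relabeling: same node/triple multisets
  f2 <- kg_fuse(list(kg_fuse(list(g1)), g2))
  expect_equal(nrow(f2$nodes), nrow(f$nodes))
  expect_equal(nrow(f2$triples), nrow(f$triples))
  # schema mismatch refused
  other <- kg_schema("A", list(A = "x"),
                     data.frame(head_type = character(),
                                relation = character(),
                                tail_type = character()))
  expect_error(kg_fuse(list(g1, kg_new(other))), "schema")
})

test_that("adjacency matches the brute-force undirected oracle", {
  g <- tiny_kg()
  expect_identical(kg_adjacency(g), oracle_adjacency(g))
  # symmetry: v in A(u) <=> u in A(v)
  adj <- kg_adjacency(g)
  for (u in names(adj)) for (v in adj[[u]])
    expect_true(as.integer(u) %in% adj[[as.character(v)]])
  # directed option keeps only head -> tail
  dadj <- kg_adjacency(g, directed = TRUE)
  tr <- g$triples
  expect_true(all(vapply(seq_len(nrow(tr)), function(r)
    tr$tail[r] %in% dadj[[as.character(tr$head[r])]], TRUE)))
  expect_identical(kg_adjacency(kg_new()), stats::setNames(list(), character()))
})

test_that("graph IO round-trips across formats", {
  g <- tiny_kg()
  g$embeddings[["1"]] <- c(0.25, -1.5, 3.125)
  g$embeddings[["3"]] <- c(1, 2, 3)
  g$embedding_dim <- 3L
  for (fmt in c("jsonl", "graphml")) {
    p <- withr::local_tempfile()
    write_kg(g, p, fmt)
    r <- read_kg(p, fmt)
    expect_identical(r$nodes[order(r$nodes$id), ]$name,
                     g$nodes[order(g$nodes$id), ]$name)
    expect_equal(nrow(r$triples), nrow(g$triples))
    expect_identical(r$node_attrs[["1"]], g$node_attrs[["1"]])
    expect_equal(r$embeddings[["1"]], g$embeddings[["1"]], tolerance = 1e-12)
  }
  # csv carries the node/edge shape for bulk import
  p <- withr::local_tempfile()
  write_kg(g, p, "csv")
  r <- read_kg(p, "csv")
  expect_identical(r$nodes, g$nodes[order(g$nodes$id), ])
  # cross-format comparison: csv and graphml agree on node/edge multisets
  p2 <- withr::local_tempfile()
  write_kg(g, p2, "graphml")
  r2 <- read_kg(p2, "graphml")
  expect_identical(sort(paste(r$triples$head, r$triples$relation,
                              r$triples$tail)),
                   sort(paste(r2$triples$head, r2$triples$relation,
                              r2$triples$tail)))
})

test_that("jsonl reader reports schema and parse errors with line numbers", {
  p <- withr::local_tempfile()
  writeLines(c('{"head": "a", "relation": "No_such_rel", "tail": "b"}'), p)
  expect_error(read_kg(p, "jsonl"), "unknown relation")
  writeLines(c('{"bogus": 1}'), p)
  expect_error(read_kg(p, "jsonl"), "line 1")
  # triples-only files infer endpoint types from the relation signature
  writeLines(c('{"head": "alpha syndrome", "relation": "Has_symptom", "tail": "fatigue"}'), p)
  kg <- read_kg(p, "jsonl")
  expect_identical(sort(kg$nodes$type), c("Symptoms", "Syndrome"))
})
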