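test_that("random walks truncate, follow forced paths, and are seeded", {
  # isolated node: walk of length 1 regardless of walk_length
  adj <- list(`1` = integer())
  w <- generate_walks(adj, walk_config(walk_length = 20, walks_per_node = 3,
                                       seed = 1))
  expect_length(w, 3)
  expect_true(all(vapply(w, length, 1L) == 1))
  # forced chain a -> b -> c under a directed adjacency restriction
  chain <- list(`1` = 2L, `2` = 3L, `3` = integer())
  w2 <- generate_walks(chain, walk_config(walk_length = 3, walks_per_node = 1,
                                          seed = 1))
  expect_identical(w2[[1]], c(1L, 2L, 3L))
  # reproducibility
  adj3 <- list(`1` = c(2L, 3L), `2` = c(1L, 3L), `3` = c(1L, 2L))
  expect_identical(generate_walks(adj3, walk_config(seed = 9)),
                   generate_walks(adj3, walk_config(seed = 9)))
  expect_identical(generate_walks(list(), walk_config()), list())
})

test_that("first transition is uniform over neighbors (Monte Carlo)", {
  adj <- list(`1` = c(2L, 3L), `2` = integer(), `3` = integer())
  w <- generate_walks(adj, walk_config(walk_length = 2,
                                       walks_per_node = 10000, seed = 4))
  first <- vapply(w[vapply(w, function(x) x[1] == 1L, TRUE)],
                  function(x) x[2], 0L)
  freq <- mean(first == 2L)
  expect_gt(freq, 0.48)   # 0.5 +/- 0.02 covers a ~4-sigma binomial band
  expect_lt(freq, 0.52)
})

test_that("walk visit frequencies track the degree distribution", {
  # star + triangle: stationary visit frequency of a random walk on an
  # undirected graph is proportional to degree
  g <- tiny_kg()
  adj <- kg_adjacency(g)
  adj <- adj[vapply(adj, length, 1L) > 0]
  w <- generate_walks(adj, walk_config(walk_length = 200,
                                       walks_per_node = 80, seed = 2))
  visits <- table(factor(unlist(w), levels = names(adj)))
  deg <- vapply(adj, length, 1L)
  # chi-square against the degree-proportional stationary distribution
  expected <- deg / sum(deg) * length(unlist(w))
  chi <- sum((as.numeric(visits) - expected)^2 / expected)
  expect_gt(stats::cor(as.numeric(visits), deg), 0.9)
  expect_lt(chi / length(unlist(w)), 0.05)   # small relative misfit
})

test_that("skip-gram probabilities normalize and gradients match finite differences", {
  walks <- list(c(1L, 2L, 3L), c(3L, 2L, 1L), c(2L, 1L, 3L))
  tb <- train_skipgram(walks, skipgram_config(dimension = 3, window = 2,
                                              epochs = 3, seed = 1))
  for (wd in c(1L, 2L, 3L))
    expect_equal(sum(skipgram_prob(tb, wd)), 1, tolerance = 1e-12)
  set.seed(5)
  Win <- matrix(stats::rnorm(12, sd = 0.4), 4, 3)
  Cout <- matrix(stats::rnorm(12, sd = 0.4), 4, 3)
  g <- kgfuse:::skipgram_logprob_grad(Win, Cout, 2L, 4L)
  for (d in 1:3) {
    fd <- finite_diff(function(v) {
      W2 <- Win; W2[2, d] <- v
      kgfuse:::skipgram_logprob_grad(W2, Cout, 2L, 4L)$logprob
    }, Win[2, d])
    expect_lt(abs(fd - g$dWin_w[d]), 1e-5)
  }
  for (i in 1:4) for (d in 1:3) {
    fd <- finite_diff(function(v) {
      C2 <- Cout; C2[i, d] <- v
      kgfuse:::skipgram_logprob_grad(Win, C2, 2L, 4L)$logprob
    }, Cout[i, d])
    expect_lt(abs(fd - g$dCout[i, d]), 1e-5)
  }
})

test_that("full-batch training does not decrease the objective", {
  walks <- list(c(1L, 2L, 3L, 4L), c(4L, 3L, 2L, 1L), c(1L, 3L, 2L, 4L))
  pairs <- kgfuse:::walk_pairs(walks, 2L)
  vocab <- sort(unique(unlist(walks)))
  idx <- cbind(match(pairs[, 1], vocab), match(pairs[, 2], vocab))
  objs <- vapply(1:6, function(ep) {
    tb <- train_skipgram(walks, skipgram_config(dimension = 4, window = 2,
                                                epochs = ep,
                                                learning_rate = 0.1,
                                                batch_size = Inf, seed = 3))
    kgfuse:::skipgram_objective(tb$vectors, tb$context, idx)
  }, 0)
  expect_true(all(diff(objs) > -1e-8))
})

test_that("two joined cliques separate in embedding space", {
  adj <- list()
  for (i in 1:6) adj[[as.character(i)]] <- setdiff(1:6, i)
  for (i in 7:12) adj[[as.character(i)]] <- setdiff(7:12, i)
  adj[["6"]] <- sort(c(adj[["6"]], 7L)); adj[["7"]] <- sort(c(adj[["7"]], 6L))
  w <- generate_walks(adj, walk_config(walk_length = 10, walks_per_node = 20,
                                       seed = 5))
  tb <- train_skipgram(w, skipgram_config(dimension = 16, window = 3,
                                          epochs = 8, seed = 5))
  V <- tb$vectors
  cs <- function(i, j) {
    a <- V[as.character(i), ]; b <- V[as.character(j), ]
    sum(a * b) / sqrt(sum(a * a) * sum(b * b))
  }
  intra <- c(); inter <- c()
  for (i in 1:12) for (j in 1:12) if (i < j) {
    if ((i <= 6) == (j <= 6)) intra <- c(intra, cs(i, j))
    else inter <- c(inter, cs(i, j))
  }
  expect_gt(mean(intra), mean(inter))
})

test_that("embed_graph attaches seeded vectors, restricted to requested types", {
  g <- tiny_kg()
  e1 <- embed_graph(g, walk_config(seed = 3),
                    skipgram_config(dimension = 8, epochs = 2, seed = 3))
  expect_equal(length(e1$embeddings), nrow(g$nodes))
  expect_true(all(vapply(e1$embeddings, length, 1L) == 8))
  e2 <- embed_graph(g, walk_config(seed = 3),
                    skipgram_config(dimension = 8, epochs = 2, seed = 3))
  expect_identical(e1$embeddings, e2$embeddings)
  # subgraph restriction leaves other node types untouched
  e3 <- embed_graph(g, walk_config(seed = 3),
                    skipgram_config(dimension = 8, epochs = 2, seed = 3),
                    types = c("Syndrome", "Symptoms"))
  treat <- g$nodes$id[g$nodes$type == "Treatment"]
  expect_null(e3$embeddings[[as.character(treat)]])
  expect_false(is.null(e3$embeddings[["1"]]))
  expect_error(train_skipgram(list()), "empty walk")
  expect_error(embed_graph(kg_new()), "empty graph")
})
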