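# Shared fixtures and independent oracles used across the suite.

# A tiny hand-built graph: 2 syndromes, 3 symptoms, one treatment chain.
tiny_kg <- function() {
  kg <- kg_new(default_schema())
  res <- kg_add_nodes(kg, "Syndrome", c("alpha syndrome", "beta syndrome"),
                      list(c(Syndrome_name = "alpha syndrome",
                             Syndrome_definition = "marked by fatigue"),
                           c(Syndrome_name = "beta syndrome")))
  kg <- res$kg; syn <- res$ids
  res <- kg_add_nodes(kg, "Symptoms", c("fatigue", "insomnia", "dizziness"))
  kg <- res$kg; sym <- res$ids
  kg <- kg_add_triples(kg, c(syn[1], syn[1], syn[2]), "Has_symptom",
                       c(sym[1], sym[2], sym[3]))
  res <- kg_add_nodes(kg, "Treatment", "soothe method")
  kg <- res$kg
  kg_add_triples(kg, syn[1], "Has_treatment", res$ids)
}

# Brute-force adjacency under the undirected convention.
oracle_adjacency <- function(kg) {
  ids <- sort(kg$nodes$id)
  out <- stats::setNames(rep(list(integer()), length(ids)), as.character(ids))
  for (r in seq_len(nrow(kg$triples))) {
    h <- kg$triples$head[r]; t <- kg$triples$tail[r]
    out[[as.character(h)]] <- sort(unique(c(out[[as.character(h)]], t)))
    out[[as.character(t)]] <- sort(unique(c(out[[as.character(t)]], h)))
  }
  out
}

# Union-find merge oracle: expected node count after merging equal
# (type, name) keys across a list of graphs.
oracle_merged_node_keys <- function(graphs) {
  keys <- unlist(lapply(graphs, function(g)
    paste0(g$nodes$type, "\r", g$nodes$name)))
  unique(keys)
}

# Brute-force dictionary scan: leftmost-longest replacement of surfaces by
# canonicals, scanning positions left to right.
oracle_normalize <- function(term, surfaces, targets) {
  chars <- strsplit(term, "", fixed = TRUE)[[1]]
  out <- character(); pos <- 1L; matched <- FALSE
  while (pos <= length(chars)) {
    best_len <- 0L; best <- NA_integer_
    for (p in seq_along(surfaces)) {
      sc <- strsplit(surfaces[p], "", fixed = TRUE)[[1]]
      L <- length(sc)
      if (L > best_len && pos + L - 1L <= length(chars) &&
          identical(chars[pos:(pos + L - 1L)], sc)) {
        best_len <- L; best <- p
      }
    }
    if (!is.na(best)) {
      out <- c(out, targets[best]); pos <- pos + best_len; matched <- TRUE
    } else {
      out <- c(out, chars[pos]); pos <- pos + 1L
    }
  }
  list(text = paste(out, collapse = ""), matched = matched)
}

# All-paths CRF enumeration oracle.
oracle_crf <- function(emissions, transitions) {
  n <- nrow(emissions); L <- ncol(emissions)
  paths <- as.matrix(expand.grid(rep(list(seq_len(L)), n)))
  scores <- apply(paths, 1L, function(y) crf_score(emissions, transitions, y))
  m <- max(scores)
  list(partition = m + log(sum(exp(scores - m))),
       best = as.integer(paths[which.max(scores), ]),
       scores = scores, paths = paths)
}

random_crf_instance <- function(n, L, seed) {
  set.seed(seed)
  list(emissions = matrix(stats::rnorm(n * L), n, L),
       transitions = matrix(stats::rnorm((L + 2)^2), L + 2, L + 2))
}

# Brute-force confusion-matrix metrics oracle.
oracle_metrics <- function(y_true, y_pred, K) {
  prec <- rec <- f1 <- numeric(K)
  for (k in seq_len(K) - 1L) {
    tp <- sum(y_true == k & y_pred == k)
    fp <- sum(y_true != k & y_pred == k)
    fn <- sum(y_true == k & y_pred != k)
    prec[k + 1] <- if (tp + fp > 0) tp / (tp + fp) else 0
    rec[k + 1] <- if (tp + fn > 0) tp / (tp + fn) else 0
    f1[k + 1] <- if (prec[k + 1] + rec[k + 1] > 0)
      2 * prec[k + 1] * rec[k + 1] / (prec[k + 1] + rec[k + 1]) else 0
  }
  list(acc = mean(y_true == y_pred), macro_precision = mean(prec),
       macro_recall = mean(rec), macro_f1 = mean(f1))
}

finite_diff <- function(f, x, eps = 1e-6) (f(x + eps) - f(x - eps)) / (2 * eps)
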