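#' Random-walk configuration
#'
#' @param walk_length maximum walk length `T` (default 20, the pipeline's
#'   maximum step length).
#' @param walks_per_node walks started from every node (default 10).
#' @param seed RNG seed (mandatory for reproducible corpora).
#' @return a `walk_config`.
#' @export
walk_config <- function(walk_length = 20L, walks_per_node = 10L, seed = 1L) {
  stopifnot(walk_length >= 1, walks_per_node >= 1)
  structure(list(walk_length = as.integer(walk_length),
                 walks_per_node = as.integer(walks_per_node),
                 seed = as.integer(seed)),
            class = "walk_config")
}

#' Skip-gram configuration
#'
#' @param dimension embedding dimension (default 384, the best-performing
#'   knowledge-embedding size; configurable).
#' @param window context window half-width (default 5).
#' @param epochs passes over the pair corpus.
#' @param learning_rate SGD step size.
#' @param batch_size minibatch size (pairs); `Inf` trains full-batch.
#' @param seed RNG seed.
#' @return a `skipgram_config`.
#' @export
skipgram_config <- function(dimension = 384L, window = 5L, epochs = 5L,
                            learning_rate = 0.05, batch_size = 256L,
                            seed = 1L) {
  stopifnot(dimension >= 1, window >= 1, epochs >= 1, learning_rate > 0)
  structure(list(dimension = as.integer(dimension), window = as.integer(window),
                 epochs = as.integer(epochs), learning_rate = learning_rate,
                 batch_size = batch_size, seed = as.integer(seed)),
            class = "skipgram_config")
}

#' Generate truncated random walks over an adjacency list
#'
#' Starts `walks_per_node` walks from every node (sorted id order). At each
#' step the next node is drawn uniformly from the current node's neighbors;
#' a walk truncates early at a node with no neighbors. Identical inputs and
#' seed yield identical walks.
#'
#' @param adj adjacency list from [kg_adjacency()].
#' @param cfg a [walk_config()].
#' @return list of integer node-id vectors (possibly shorter than
#'   `walk_length`).
#' @export
generate_walks <- function(adj, cfg = walk_config()) {
  stopifnot(inherits(cfg, "walk_config"))
  ids <- as.integer(names(adj))
  ord <- order(ids)
  if (!length(ids)) return(list())
  with_seed(cfg$seed, {
    walks <- vector("list", length(ids) * cfg$walks_per_node)
    k <- 0L
    for (i in ord) {
      for (r in seq_len(cfg$walks_per_node)) {
        w <- integer(cfg$walk_length)
        w[1] <- ids[i]
        len <- 1L
        while (len < cfg$walk_length) {
          nbrs <- adj[[as.character(w[len])]]
          if (!length(nbrs)) break
          w[len + 1L] <- nbrs[sample.int(length(nbrs), 1L)]
          len <- len + 1L
        }
        k <- k + 1L
        walks[[k]] <- w[seq_len(len)]
      }
    }
    walks
  })
}

# (center, context) pair corpus from walks under a window.
walk_pairs <- function(walks, window) {
  centers <- integer(); contexts <- integer()
  for (w in walks) {
    n <- length(w)
    if (n < 2) next
    for (t in seq_len(n)) {
      lo <- max(1L, t - window); hi <- min(n, t + window)
      ctx <- w[setdiff(lo:hi, t)]
      centers <- c(centers, rep(w[t], length(ctx)))
      contexts <- c(contexts, ctx)
    }
  }
  cbind(center = centers, context = contexts)
}

#' Train skip-gram embeddings with a full-softmax objective
#'
#' Maximizes `sum_w sum_{u in N(w)} log P(u | w)` with
#' `P(u|w) = exp(V_u . V_w) / sum_v exp(V_v . V_w)` over the whole
#' vocabulary (full softmax, no negative sampling) by minibatch stochastic
#' gradient ascent on separate input/context matrices. The returned table
#' holds the input vectors for every node appearing in the walks.
#'
#' @param walks list of node-id vectors from [generate_walks()].
#' @param cfg a [skipgram_config()].
#' @return an `embedding_table`: list with `dimension`, `vectors` (matrix,
#'   rownames = node ids), `context` (output matrix) and `loss_history`
#'   (mean negative log-likelihood per epoch).
#' @export
train_skipgram <- function(walks, cfg = skipgram_config()) {
  if (!length(walks)) stopf("value error: empty walk corpus")
  vocab <- sort(unique(unlist(walks)))
  V <- length(vocab); d <- cfg$dimension
  pairs <- walk_pairs(walks, cfg$window)
  with_seed(cfg$seed, {
    Win <- matrix(stats::runif(V * d, -0.5, 0.5) / d, V, d)
    Cout <- matrix(stats::runif(V * d, -0.5, 0.5) / d, V, d)
    loss_hist <- numeric(cfg$epochs)
    if (nrow(pairs)) {
      ci <- match(pairs[, "center"], vocab)
      ui <- match(pairs[, "context"], vocab)
      bs <- if (is.finite(cfg$batch_size)) as.integer(cfg$batch_size)
            else nrow(pairs)
      for (ep in seq_len(cfg$epochs)) {
        perm <- sample.int(nrow(pairs))
        total <- 0
        for (s in seq(1L, nrow(pairs), by = bs)) {
          sel <- perm[s:min(s + bs - 1L, nrow(pairs))]
          B <- length(sel)
          H <- Win[ci[sel], , drop = FALSE]              # B x d
          scores <- H %*% t(Cout)                        # B x V
          P <- row_softmax(scores)
          total <- total - sum(log(P[cbind(seq_len(B), ui[sel])] + 1e-300))
          G <- P
          G[cbind(seq_len(B), ui[sel])] <- G[cbind(seq_len(B), ui[sel])] - 1
          dC <- crossprod(G, H)                          # V x d
          dH <- G %*% Cout                               # B x d
          dW <- rowsum(dH, group = ci[sel])
          rows <- as.integer(rownames(dW))
          Win[rows, ] <- Win[rows, ] - (cfg$learning_rate / B) * dW
          Cout <- Cout - (cfg$learning_rate / B) * dC
        }
        loss_hist[ep] <- total / nrow(pairs)
      }
    }
    rownames(Win) <- rownames(Cout) <- as.character(vocab)
    structure(list(dimension = d, vectors = Win, context = Cout,
                   loss_history = loss_hist),
              class = "embedding_table")
  })
}

#' Softmax context distribution of a trained table
#'
#' `P(. | w)` over the whole vocabulary; sums to 1 exactly up to floating
#' point.
#' @param table an `embedding_table`.
#' @param w node id (must be in the table).
#' @return named probability vector over vocabulary.
#' @export
skipgram_prob <- function(table, w) {
  i <- match(as.character(w), rownames(table$vectors))
  if (is.na(i)) stopf("value error: node %s not in table", w)
  s <- drop(table$context %*% table$vectors[i, ])
  stats::setNames(softmax(s), rownames(table$vectors))
}

# log P(u|w) and its analytic gradients wrt Win[w,] and all Cout rows.
# Used by the finite-difference oracle tests.
skipgram_logprob_grad <- function(Win, Cout, w, u) {
  s <- drop(Cout %*% Win[w, ])
  p <- softmax(s)
  lp <- s[u] - logsumexp(s)
  dWin_w <- Cout[u, ] - drop(t(Cout) %*% p)
  dCout <- -outer(p, Win[w, ])
  dCout[u, ] <- dCout[u, ] + Win[w, ]
  list(logprob = lp, dWin_w = dWin_w, dCout = dCout)
}

# Full-corpus objective sum log P(u|w) (full batch; monotonicity checks).
skipgram_objective <- function(Win, Cout, pairs_idx) {
  scores <- Win[pairs_idx[, 1], , drop = FALSE] %*% t(Cout)
  lse <- apply(scores, 1L, logsumexp)
  sum(scores[cbind(seq_len(nrow(pairs_idx)), pairs_idx[, 2])] - lse)
}

#' Learn DeepWalk embeddings and attach them to node attributes
#'
#' Runs random walks over the (optionally type-restricted) graph, trains the
#' skip-gram model, and stores each node's vector on the graph so linking can
#' retrieve it by node id.
#'
#' @param kg a `knowledge_graph`.
#' @param walk_cfg a [walk_config()].
#' @param sg_cfg a [skipgram_config()].
#' @param types optional entity types; when given, walks run on the induced
#'   subgraph and only those nodes receive embeddings.
#' @return the graph with embeddings attached.
#' @export
embed_graph <- function(kg, walk_cfg = walk_config(),
                        sg_cfg = skipgram_config(), types = NULL) {
  stopifnot(inherits(kg, "knowledge_graph"))
  if (!nrow(kg$nodes)) stopf("value error: empty graph")
  g <- if (is.null(types)) kg else kg_subgraph_types(kg, types)
  adj <- kg_adjacency(g)
  walks <- generate_walks(adj, walk_cfg)
  table <- train_skipgram(walks, sg_cfg)
  for (id in rownames(table$vectors))
    kg$embeddings[[id]] <- unname(table$vectors[id, ])
  kg$embedding_dim <- table$dimension
  kg
}
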