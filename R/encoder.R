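#' Text encoder contract and the small trainable test encoder
#'
#' The classification model treats the text encoder as a contract: an object
#' with a `hidden_size`, a tokenizer, parameter initialization, and
#' forward/backward functions. In production the contract is meant to be
#' backed by a pretrained transformer (hidden size 768, fine-tuned jointly);
#' the package ships a desk-scale trainable encoder — a bag-of-embeddings
#' network `h = tanh(A . mean(E[tokens]) + a)` — so the full pipeline trains
#' in seconds on one CPU. The method under study is the fusion, not the
#' encoder weights.
#'
#' @param hidden_size output dimension of the text representation
#'   (default 64 for the test encoder; 768 mirrors the production setting).
#' @param embed_dim token-embedding size.
#' @return a `text_encoder` contract object.
#' @export
bow_encoder <- function(hidden_size = 64L, embed_dim = 32L) {
  structure(list(
    hidden_size = as.integer(hidden_size),
    embed_dim = as.integer(embed_dim),
    tokenize = function(text, max_len = 128L) {
      toks <- strsplit(tolower(text), "[^[:alnum:]_]+")[[1]]
      toks <- toks[nzchar(toks)]
      utils::head(toks, max_len)
    },
    init_params = function(vocab_size) {
      ru <- function(n, m) matrix(stats::runif(n * m, -0.1, 0.1), n, m)
      list(enc_E = ru(vocab_size, embed_dim),
           enc_A = ru(hidden_size, embed_dim),
           enc_a = numeric(hidden_size))
    },
    forward = function(params, tok_idx) {
      m <- if (length(tok_idx))
        colMeans(params$enc_E[tok_idx, , drop = FALSE]) else
          numeric(ncol(params$enc_E))
      u <- drop(params$enc_A %*% m + params$enc_a)
      h <- tanh(u)
      list(h = h, cache = list(tok = tok_idx, m = m, h = h))
    },
    backward = function(params, cache, dh) {
      du <- dh * (1 - cache$h^2)
      dA <- tcrossprod(du, cache$m)
      dm <- drop(crossprod(params$enc_A, du))
      dE <- matrix(0, nrow(params$enc_E), ncol(params$enc_E))
      if (length(cache$tok)) {
        contrib <- dm / length(cache$tok)
        for (t in cache$tok) dE[t, ] <- dE[t, ] + contrib
      }
      list(enc_E = dE, enc_A = dA, enc_a = du)
    }),
    class = "text_encoder")
}
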