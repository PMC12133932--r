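#' LSTM-CRF sequence tagger
#'
#' Entity recognition for structured clinical records: tokens are embedded,
#' encoded with a single-direction LSTM, projected to per-label emission
#' scores, and decoded with a linear-chain CRF (`Y = CRF(LSTM(X))`). Tags
#' follow the BIO scheme over the mention types used by the pipeline
#' (symptom, disease, syndrome, chief complaint).
#'
#' @param hidden_size LSTM hidden units (default 64).
#' @param embed_dim token embedding size (default 32).
#' @param epochs training epochs (default 20).
#' @param learning_rate Adam step size (default 1e-2).
#' @param seed RNG seed.
#' @return a `tagger_config`.
#' @export
tagger_config <- function(hidden_size = 64L, embed_dim = 32L, epochs = 20L,
                          learning_rate = 1e-2, seed = 1L) {
  structure(list(hidden_size = as.integer(hidden_size),
                 embed_dim = as.integer(embed_dim),
                 epochs = as.integer(epochs),
                 learning_rate = learning_rate, seed = as.integer(seed)),
            class = "tagger_config")
}

#' A BIO-tagged token sequence
#'
#' @param tokens character vector.
#' @param tags BIO tags, same length, well-formed (`I-X` only after `B-X` or
#'   `I-X`).
#' @return a `tagged_sequence`.
#' @export
tagged_sequence <- function(tokens, tags) {
  if (length(tokens) != length(tags))
    stopf("value error: |tokens| != |tags|")
  validate_bio(tags)
  structure(list(tokens = tokens, tags = tags), class = "tagged_sequence")
}

#' Validate BIO well-formedness
#' @param tags character vector of BIO tags.
#' @return invisibly `TRUE`; errors on malformed input.
#' @export
validate_bio <- function(tags) {
  prev <- "O"
  for (tg in tags) {
    if (tg != "O" && !grepl("^[BI]-", tg))
      stopf("data error: tag '%s' is not BIO", tg)
    if (startsWith(tg, "I-")) {
      ty <- substring(tg, 3)
      ok <- prev %in% c(paste0("B-", ty), paste0("I-", ty))
      if (!ok) stopf("data error: '%s' without preceding B-/I-%s", tg, ty)
    }
    prev <- tg
  }
  invisible(TRUE)
}

# Extract (type, start, end) entity spans from BIO tags.
bio_spans <- function(tags) {
  spans <- list(); start <- NA_integer_; ty <- NA_character_
  flush <- function(i) {
    if (!is.na(start))
      spans[[length(spans) + 1L]] <<- c(ty, start, i - 1L)
    start <<- NA_integer_; ty <<- NA_character_
  }
  for (i in seq_along(tags)) {
    tg <- tags[i]
    if (startsWith(tg, "B-")) { flush(i); start <- i; ty <- substring(tg, 3) }
    else if (startsWith(tg, "I-")) { if (is.na(start)) { start <- i; ty <- substring(tg, 3) } }
    else flush(i)
  }
  flush(length(tags) + 1L)
  spans
}

#' Entity-level micro F1 between gold and predicted BIO taggings
#' @param gold,pred lists of BIO tag vectors (aligned).
#' @return list with `precision`, `recall`, `f1`.
#' @export
entity_f1 <- function(gold, pred) {
  tp <- 0L; n_gold <- 0L; n_pred <- 0L
  for (i in seq_along(gold)) {
    gs <- vapply(bio_spans(gold[[i]]), paste, "", collapse = "|")
    ps <- vapply(bio_spans(pred[[i]]), paste, "", collapse = "|")
    tp <- tp + length(intersect(gs, ps))
    n_gold <- n_gold + length(gs); n_pred <- n_pred + length(ps)
  }
  p <- if (n_pred) tp / n_pred else 0
  r <- if (n_gold) tp / n_gold else 0
  f <- if (p + r > 0) 2 * p * r / (p + r) else 0
  list(precision = p, recall = r, f1 = f)
}

tagger_init_params <- function(V, L, cfg) {
  h <- cfg$hidden_size; e <- cfg$embed_dim
  ru <- function(n, m) matrix(stats::runif(n * m, -0.1, 0.1), n, m)
  list(E = ru(V, e),
       Wx = ru(4 * h, e), Wh = ru(4 * h, h), b = numeric(4 * h),
       Wout = ru(L, h), bout = numeric(L),
       trans = matrix(0, L + 2L, L + 2L))
}

sigm <- function(x) 1 / (1 + exp(-x))

# LSTM forward over a token-index sequence; returns hidden states + cache.
lstm_forward <- function(params, tok) {
  h <- ncol(params$Wh); n <- length(tok)
  H <- matrix(0, n, h)
  cache <- vector("list", n)
  hprev <- numeric(h); cprev <- numeric(h)
  for (t in seq_len(n)) {
    x <- params$E[tok[t], ]
    z <- drop(params$Wx %*% x + params$Wh %*% hprev + params$b)
    i <- sigm(z[1:h]); f <- sigm(z[(h + 1):(2 * h)])
    o <- sigm(z[(2 * h + 1):(3 * h)]); g <- tanh(z[(3 * h + 1):(4 * h)])
    c_t <- f * cprev + i * g
    h_t <- o * tanh(c_t)
    cache[[t]] <- list(x = x, i = i, f = f, o = o, g = g,
                       c = c_t, cprev = cprev, hprev = hprev)
    H[t, ] <- h_t
    hprev <- h_t; cprev <- c_t
  }
  list(H = H, cache = cache)
}

# NLL and full gradients for one sentence (tok, lab are index vectors).
tagger_sentence_grad <- function(params, tok, lab) {
  h <- ncol(params$Wh); n <- length(tok)
  fw <- lstm_forward(params, tok)
  emis <- fw$H %*% t(params$Wout) +
    matrix(params$bout, n, length(params$bout), byrow = TRUE)
  cg <- crf_nll_grad(emis, params$trans, lab)
  dWout <- crossprod(cg$d_emissions, fw$H)
  dbout <- colSums(cg$d_emissions)
  dH <- cg$d_emissions %*% params$Wout                 # n x h
  dE <- matrix(0, nrow(params$E), ncol(params$E))
  dWx <- matrix(0, 4 * h, ncol(params$Wx))
  dWh <- matrix(0, 4 * h, h); db <- numeric(4 * h)
  dh_next <- numeric(h); dc_next <- numeric(h)
  for (t in rev(seq_len(n))) {
    cc <- fw$cache[[t]]
    dh <- dH[t, ] + dh_next
    tc <- tanh(cc$c)
    do <- dh * tc
    dc <- dh * cc$o * (1 - tc * tc) + dc_next
    di <- dc * cc$g; dg <- dc * cc$i; df <- dc * cc$cprev
    dz <- c(di * cc$i * (1 - cc$i),
            df * cc$f * (1 - cc$f),
            do * cc$o * (1 - cc$o),
            dg * (1 - cc$g * cc$g))
    dWx <- dWx + tcrossprod(dz, cc$x)
    dWh <- dWh + tcrossprod(dz, cc$hprev)
    db <- db + dz
    dE[tok[t], ] <- dE[tok[t], ] + drop(crossprod(params$Wx, dz))
    dh_next <- drop(crossprod(params$Wh, dz))
    dc_next <- dc * cc$f
  }
  list(nll = cg$nll,
       grads = list(E = dE, Wx = dWx, Wh = dWh, b = db,
                    Wout = dWout, bout = dbout,
                    trans = cg$d_transitions))
}

#' Train the LSTM-CRF tagger
#'
#' Minimizes the per-sentence CRF negative log-likelihood with Adam;
#' seeded and fully deterministic on CPU.
#'
#' @param corpus list of [tagged_sequence()]s (or lists with `tokens`,
#'   `tags`).
#' @param config a [tagger_config()].
#' @return a `tagger_model` with the vocabulary, label set, parameters, and
#'   per-epoch mean loss in `$loss_history`.
#' @export
train_tagger <- function(corpus, config = tagger_config()) {
  if (!length(corpus)) stopf("value error: empty corpus")
  for (s in corpus) validate_bio(s$tags)
  vocab <- sort(unique(unlist(lapply(corpus, `[[`, "tokens"))))
  vocab <- c(vocab, "<unk>")
  labels <- sort(unique(unlist(lapply(corpus, `[[`, "tags"))))
  toks <- lapply(corpus, function(s) match(s$tokens, vocab))
  labs <- lapply(corpus, function(s) match(s$tags, labels))
  with_seed(config$seed, {
    params <- tagger_init_params(length(vocab), length(labels), config)
    st <- adam_init(params)
    loss_hist <- numeric(config$epochs)
    for (ep in seq_len(config$epochs)) {
      perm <- sample.int(length(corpus))
      total <- 0
      for (s in perm) {
        sg <- tagger_sentence_grad(params, toks[[s]], labs[[s]])
        total <- total + sg$nll
        upd <- adam_step(params, sg$grads, st, config$learning_rate)
        params <- upd$params; st <- upd$state
      }
      loss_hist[ep] <- total / length(corpus)
    }
    structure(list(vocab = vocab, labels = labels, params = params,
                   config = config, loss_history = loss_hist),
              class = "tagger_model")
  })
}

#' Decode BIO tags for a token sequence
#' @param model a trained `tagger_model`.
#' @param tokens character vector; unseen tokens map to `<unk>`.
#' @return character vector of BIO tags.
#' @export
predict_tags <- function(model, tokens) {
  stopifnot(inherits(model, "tagger_model"))
  tok <- match(tokens, model$vocab)
  tok[is.na(tok)] <- match("<unk>", model$vocab)
  fw <- lstm_forward(model$params, tok)
  emis <- fw$H %*% t(model$params$Wout) +
    matrix(model$params$bout, length(tok), length(model$labels), byrow = TRUE)
  model$labels[viterbi_decode(emis, model$params$trans)]
}

#' Read a CoNLL-style two-column (token TAB tag) annotated corpus
#' @param path text file; blank lines separate sentences.
#' @return list of [tagged_sequence()]s.
#' @export
read_conll <- function(path) {
  lines <- readLines(path, encoding = "UTF-8", warn = FALSE)
  out <- list(); toks <- character(); tags <- character()
  flush <- function() {
    if (length(toks))
      out[[length(out) + 1L]] <<- tagged_sequence(toks, tags)
    toks <<- character(); tags <<- character()
  }
  for (ln in lines) {
    if (!nzchar(trimws(ln))) { flush(); next }
    parts <- strsplit(ln, "[\t ]+")[[1]]
    toks <- c(toks, parts[1]); tags <- c(tags, parts[2])
  }
  flush()
  out
}
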