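#' An electronic-medical-record classification record
#'
#' @param disease_name,chief_complaint,history text fields (at least one
#'   non-empty).
#' @param label integer class id in `[0, K)`, or `NA` at inference.
#' @return an `emr_record`.
#' @export
emr_record <- function(disease_name = "", chief_complaint = "", history = "",
                       label = NA_integer_) {
  if (!nzchar(disease_name) && !nzchar(chief_complaint) && !nzchar(history))
    stopf("value error: all EMR text fields empty")
  structure(list(disease_name = disease_name,
                 chief_complaint = chief_complaint,
                 history = history, label = label),
            class = "emr_record")
}

#' Format an EMR record into the encoder input template
#'
#' `"[CLS] {disease_name}, {chief_complaint} [SEP] {history} [SEP]"`, with
#' empty fields rendered as empty strings (no separator is dropped or
#' doubled by the formatter itself).
#'
#' @param record an [emr_record()].
#' @return formatted string.
#' @export
format_emr <- function(record) {
  stopifnot(inherits(record, "emr_record"))
  sprintf("[CLS] %s, %s [SEP] %s [SEP]",
          record$disease_name, record$chief_complaint, record$history)
}

#' Training configuration for the fusion classifier
#'
#' Defaults mirror the reference training setup: cross-entropy loss,
#' Adam-with-weight-decay, batch 16, learning rate 2e-5, weight decay 0.02,
#' max sequence length 128, 10 epochs. The desk-scale test encoder needs a
#' larger learning rate than a pretrained transformer; pass it explicitly.
#'
#' @param batch_size,learning_rate,weight_decay,max_seq_length,epochs,seed
#'   training hyper-parameters.
#' @param freeze_encoder if `TRUE`, encoder parameters receive no updates.
#' @param use_text,use_kg ablation switches: disable the text or the
#'   knowledge branch (the remaining branch feeds the label head alone).
#' @return a `fusion_config`.
#' @export
fusion_config <- function(batch_size = 16L, learning_rate = 2e-5,
                          weight_decay = 0.02, max_seq_length = 128L,
                          epochs = 10L, seed = 1L, freeze_encoder = FALSE,
                          use_text = TRUE, use_kg = TRUE) {
  if (!use_text && !use_kg)
    stopf("value error: at least one of use_text/use_kg must be TRUE")
  structure(list(batch_size = as.integer(batch_size),
                 learning_rate = learning_rate, weight_decay = weight_decay,
                 max_seq_length = as.integer(max_seq_length),
                 epochs = as.integer(epochs), seed = as.integer(seed),
                 freeze_encoder = freeze_encoder,
                 use_text = use_text, use_kg = use_kg),
            class = "fusion_config")
}

#' Build an (untrained) fusion classification model
#'
#' The knowledge vector is linearly projected, combined with the text
#' representation by one of three fusion methods, and mapped to class
#' logits:
#' \describe{
#'   \item{CONCAT}{`S_w = concat(P V_kg, V_emrs)`; projection keeps the
#'     knowledge dimension.}
#'   \item{AVG}{`S_w = (P V_kg + V_emrs) / 2`; projection maps to the
#'     encoder's hidden size.}
#'   \item{WEIGHTED}{`S_w = alpha P V_kg + beta V_emrs` with learnable
#'     non-negative weights normalized to sum 1.}
#' }
#'
#' @param encoder a [bow_encoder()]-style contract.
#' @param n_classes number of syndrome classes `K` (>= 2).
#' @param kg_dim knowledge-embedding dimension (default 384).
#' @param fusion_method `"CONCAT"` (default, the best-performing variant),
#'   `"AVG"`, or `"WEIGHTED"`.
#' @param config a [fusion_config()].
#' @return an untrained `fusion_model`.
#' @export
fusion_model <- function(encoder, n_classes, kg_dim = 384L,
                         fusion_method = c("CONCAT", "AVG", "WEIGHTED"),
                         config = fusion_config()) {
  fusion_method <- match.arg(fusion_method)
  if (n_classes < 2) stopf("value error: need at least 2 classes")
  proj_dim <- if (fusion_method == "CONCAT") as.integer(kg_dim)
              else encoder$hidden_size
  fused_dim <- if (!config$use_text) proj_dim
    else if (!config$use_kg) encoder$hidden_size
    else if (fusion_method == "CONCAT") proj_dim + encoder$hidden_size
    else encoder$hidden_size
  structure(list(encoder = encoder, n_classes = as.integer(n_classes),
                 kg_dim = as.integer(kg_dim), fusion_method = fusion_method,
                 proj_dim = proj_dim, fused_dim = fused_dim,
                 config = config, params = NULL, vocab = NULL,
                 fusion_weights = c(0.5, 0.5), trained = FALSE),
            class = "fusion_model")
}

fusion_init_params <- function(model, vocab_size) {
  ru <- function(n, m) matrix(stats::runif(n * m, -0.1, 0.1), n, m)
  p <- model$encoder$init_params(vocab_size)
  p$P <- ru(model$proj_dim, model$kg_dim)
  p$W <- ru(model$n_classes, model$fused_dim)
  p$b <- numeric(model$n_classes)
  if (model$fusion_method == "WEIGHTED") p$fw_logits <- c(0, 0)
  p
}

#' Fuse a knowledge vector with a text representation
#'
#' Applies the model's current projection and fusion method (see
#' [fusion_model()]). For WEIGHTED, `model$fusion_weights` holds
#' `(alpha, beta)`.
#'
#' @param v_kg knowledge vector of length `kg_dim`.
#' @param v_emrs text vector of length `hidden_size`.
#' @param model a `fusion_model` with initialized parameters.
#' @return fused vector `S_w` of length `fused_dim`.
#' @export
fuse_vectors <- function(v_kg, v_emrs, model) {
  if (is.null(model$params)) stopf("state error: model has no parameters")
  if (length(v_kg) != model$kg_dim)
    stopf("value error: v_kg has length %d, expected %d",
          length(v_kg), model$kg_dim)
  if (length(v_emrs) != model$encoder$hidden_size)
    stopf("value error: v_emrs has length %d, expected %d",
          length(v_emrs), model$encoder$hidden_size)
  pv <- drop(model$params$P %*% v_kg)
  switch(model$fusion_method,
         CONCAT = c(pv, v_emrs),
         AVG = (pv + v_emrs) / 2,
         WEIGHTED = model$fusion_weights[1] * pv +
           model$fusion_weights[2] * v_emrs)
}

# forward+backward for one record; returns loss, probs and gradients.
fusion_record_grad <- function(model, params, tok_idx, v_kg, label1) {
  cfg <- model$config
  enc <- model$encoder
  fw <- NULL; h <- numeric(enc$hidden_size)
  if (cfg$use_text) { fw <- enc$forward(params, tok_idx); h <- fw$h }
  pv <- if (cfg$use_kg) drop(params$P %*% v_kg) else NULL
  alpha <- beta <- NA_real_
  if (!cfg$use_kg) s <- h
  else if (!cfg$use_text) s <- pv
  else s <- switch(model$fusion_method,
                   CONCAT = c(pv, h),
                   AVG = (pv + h) / 2,
                   WEIGHTED = {
                     w <- softmax(params$fw_logits)
                     alpha <- w[1]; beta <- w[2]
                     alpha * pv + beta * h
                   })
  logits <- drop(params$W %*% s + params$b)
  p <- softmax(logits)
  loss <- -log(p[label1] + 1e-300)
  dl <- p; dl[label1] <- dl[label1] - 1
  grads <- list(W = tcrossprod(dl, s), b = dl)
  ds <- drop(crossprod(params$W, dl))
  dpv <- NULL; dh <- NULL
  if (!cfg$use_kg) dh <- ds
  else if (!cfg$use_text) dpv <- ds
  else switch(model$fusion_method,
              CONCAT = { dpv <- ds[seq_len(model$proj_dim)]
                         dh <- ds[-seq_len(model$proj_dim)] },
              AVG = { dpv <- ds / 2; dh <- ds / 2 },
              WEIGHTED = {
                dpv <- alpha * ds; dh <- beta * ds
                dalpha <- sum(ds * pv); dbeta <- sum(ds * h)
                # softmax jacobian on the two logits
                grads$fw_logits <- c(
                  alpha * (dalpha - (alpha * dalpha + beta * dbeta)),
                  beta * (dbeta - (alpha * dalpha + beta * dbeta)))
              })
  if (!is.null(dpv)) grads$P <- tcrossprod(dpv, v_kg)
  if (cfg$use_text && !cfg$freeze_encoder && !is.null(dh))
    grads <- c(grads, enc$backward(params, fw$cache, dh))
  list(loss = loss, probs = p, grads = grads)
}

#' Train the fusion classifier
#'
#' Minimizes the cross-entropy of `softmax(head(S_w))` with Adam plus weight
#' decay; the encoder is fine-tuned jointly unless
#' `config$freeze_encoder = TRUE`. Every record must come with a precomputed
#' knowledge vector (the zero vector is a valid "no link" value). Seeded and
#' deterministic on CPU.
#'
#' @param model an untrained [fusion_model()].
#' @param records list of [emr_record()]s with labels in `[0, K)`.
#' @param vkg numeric matrix `length(records) x kg_dim` of knowledge
#'   vectors.
#' @return the trained model; `$loss_history` holds per-epoch mean loss.
#' @export
train_fusion <- function(model, records, vkg) {
  stopifnot(inherits(model, "fusion_model"))
  cfg <- model$config
  n <- length(records)
  if (!n) stopf("value error: no records")
  if (!is.matrix(vkg) || nrow(vkg) != n || ncol(vkg) != model$kg_dim)
    stopf("state error: vkg must be a %d x %d matrix", n, model$kg_dim)
  labels <- vapply(records, function(r) as.integer(r$label), 0L)
  if (anyNA(labels)) stopf("value error: record with missing label")
  if (any(labels < 0 | labels >= model$n_classes))
    stopf("value error: label outside [0, K)")
  texts <- vapply(records, format_emr, "")
  tok_lists <- lapply(texts, model$encoder$tokenize, cfg$max_seq_length)
  vocab <- sort(unique(unlist(tok_lists)))
  vocab <- c(vocab, "<unk>")
  toks <- lapply(tok_lists, function(tk) {
    i <- match(tk, vocab); i[is.na(i)] <- length(vocab); i })
  with_seed(cfg$seed, {
    params <- fusion_init_params(model, length(vocab))
    st <- adam_init(params)
    loss_hist <- numeric(cfg$epochs)
    for (ep in seq_len(cfg$epochs)) {
      perm <- sample.int(n)
      total <- 0
      for (s0 in seq(1L, n, by = cfg$batch_size)) {
        sel <- perm[s0:min(s0 + cfg$batch_size - 1L, n)]
        acc <- NULL
        for (i in sel) {
          rg <- fusion_record_grad(model, params, toks[[i]], vkg[i, ],
                                   labels[i] + 1L)
          total <- total + rg$loss
          if (is.null(acc)) acc <- rg$grads
          else for (nm in names(rg$grads))
            acc[[nm]] <- (acc[[nm]] %||% 0) + rg$grads[[nm]]
        }
        for (nm in names(acc)) acc[[nm]] <- acc[[nm]] / length(sel)
        upd <- adam_step(params, acc, st, cfg$learning_rate,
                         weight_decay = cfg$weight_decay)
        params <- upd$params; st <- upd$state
      }
      loss_hist[ep] <- total / n
    }
    model$params <- params
    model$vocab <- vocab
    if (model$fusion_method == "WEIGHTED")
      model$fusion_weights <- softmax(params$fw_logits)
    model$trained <- TRUE
    model$loss_history <- loss_hist
    model
  })
}

#' Predict the syndrome class of one record
#'
#' @param model a trained `fusion_model`.
#' @param record an [emr_record()].
#' @param v_kg knowledge vector for the record (zero vector if no link).
#' @return list with `label` (0-based class id, lowest-index tie-break) and
#'   `probs` (probability vector summing to 1).
#' @export
predict_fusion <- function(model, record, v_kg) {
  if (!isTRUE(model$trained)) stopf("state error: model is not trained")
  tk <- model$encoder$tokenize(format_emr(record), model$config$max_seq_length)
  i <- match(tk, model$vocab); i[is.na(i)] <- length(model$vocab)
  rg <- fusion_record_grad(model, model$params, i, v_kg, 1L)
  list(label = which.max(rg$probs) - 1L, probs = unname(rg$probs))
}
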