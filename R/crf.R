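# Linear-chain CRF primitives. Transition matrices are (L+2) x (L+2) with
# rows = from-state, cols = to-state; state L+1 is START, state L+2 is STOP.
# Emissions are n x L score matrices.

check_crf_shapes <- function(emissions, transitions) {
  if (!is.matrix(emissions) || !is.matrix(transitions))
    stopf("value error: emissions and transitions must be matrices")
  L <- ncol(emissions)
  if (nrow(transitions) != L + 2 || ncol(transitions) != L + 2)
    stopf("value error: transitions must be (L+2) x (L+2), L = %d", L)
  L
}

#' Score of a specific label path
#'
#' `score = trans[START, y1] + sum_t emis[t, y_t] + sum_t trans[y_t, y_t+1]
#'  + trans[y_n, STOP]`.
#'
#' @param emissions n x L matrix of per-token label scores.
#' @param transitions (L+2) x (L+2) transition score matrix (START = L+1,
#'   STOP = L+2).
#' @param labels integer label path of length n (values in 1..L).
#' @return scalar path score.
#' @export
crf_score <- function(emissions, transitions, labels) {
  L <- check_crf_shapes(emissions, transitions)
  n <- nrow(emissions)
  if (length(labels) != n || any(labels < 1 | labels > L))
    stopf("value error: labels must be length n in 1..L")
  s <- transitions[L + 1L, labels[1]] + emissions[1, labels[1]]
  if (n > 1) for (t in 2:n)
    s <- s + transitions[labels[t - 1L], labels[t]] + emissions[t, labels[t]]
  s + transitions[labels[n], L + 2L]
}

#' Log-partition function by the forward recursion
#'
#' Log-sum-exp over all `L^n` label paths; `crf_score(y) -
#' crf_partition(...)` is the log-probability of path `y` and is always
#' `<= 0`.
#' @inheritParams crf_score
#' @return scalar log-partition value.
#' @export
crf_partition <- function(emissions, transitions) {
  L <- check_crf_shapes(emissions, transitions)
  n <- nrow(emissions)
  alpha <- transitions[L + 1L, 1:L] + emissions[1, ]
  if (n > 1) for (t in 2:n) {
    alpha <- vapply(1:L, function(j)
      logsumexp(alpha + transitions[1:L, j]) + emissions[t, j], 0)
  }
  logsumexp(alpha + transitions[1:L, L + 2L])
}

# forward/backward tables in log space; used for training gradients.
crf_forward_backward <- function(emissions, transitions) {
  L <- check_crf_shapes(emissions, transitions)
  n <- nrow(emissions)
  alpha <- matrix(0, n, L); beta <- matrix(0, n, L)
  alpha[1, ] <- transitions[L + 1L, 1:L] + emissions[1, ]
  if (n > 1) for (t in 2:n)
    alpha[t, ] <- vapply(1:L, function(j)
      logsumexp(alpha[t - 1L, ] + transitions[1:L, j]) + emissions[t, j], 0)
  beta[n, ] <- transitions[1:L, L + 2L]
  if (n > 1) for (t in (n - 1L):1)
    beta[t, ] <- vapply(1:L, function(i)
      logsumexp(transitions[i, 1:L] + emissions[t + 1L, ] + beta[t + 1L, ]), 0)
  logZ <- logsumexp(alpha[n, ] + beta[n, ])
  list(alpha = alpha, beta = beta, logZ = logZ)
}

#' Viterbi decoding
#'
#' Returns the argmax-score label path. Ties are broken toward the lowest
#' label index (at the final state and at every backpointer).
#' @inheritParams crf_score
#' @return integer label path of length `nrow(emissions)`.
#' @export
viterbi_decode <- function(emissions, transitions) {
  L <- check_crf_shapes(emissions, transitions)
  n <- nrow(emissions)
  dp <- matrix(-Inf, n, L); ptr <- matrix(0L, n, L)
  dp[1, ] <- transitions[L + 1L, 1:L] + emissions[1, ]
  if (n > 1) for (t in 2:n) for (j in 1:L) {
    cand <- dp[t - 1L, ] + transitions[1:L, j]
    ptr[t, j] <- which.max(cand)      # first (= lowest-index) maximum
    dp[t, j] <- cand[ptr[t, j]] + emissions[t, j]
  }
  fin <- dp[n, ] + transitions[1:L, L + 2L]
  y <- integer(n)
  y[n] <- which.max(fin)
  if (n > 1) for (t in n:2) y[t - 1L] <- ptr[t, y[t]]
  y
}

# Gradient of the negative log-likelihood wrt emissions and transitions:
# expected feature counts minus observed ones.
crf_nll_grad <- function(emissions, transitions, labels) {
  L <- ncol(emissions); n <- nrow(emissions)
  fb <- crf_forward_backward(emissions, transitions)
  nll <- fb$logZ - crf_score(emissions, transitions, labels)
  marg <- exp(fb$alpha + fb$beta - fb$logZ)            # n x L unary marginals
  d_emis <- marg
  d_emis[cbind(seq_len(n), labels)] <- d_emis[cbind(seq_len(n), labels)] - 1
  d_trans <- matrix(0, L + 2L, L + 2L)
  d_trans[L + 1L, 1:L] <- marg[1, ]
  d_trans[L + 1L, labels[1]] <- d_trans[L + 1L, labels[1]] - 1
  d_trans[1:L, L + 2L] <- marg[n, ]
  d_trans[labels[n], L + 2L] <- d_trans[labels[n], L + 2L] - 1
  if (n > 1) for (t in 2:n) {
    pair <- exp(outer(fb$alpha[t - 1L, ], emissions[t, ] + fb$beta[t, ], "+") +
                  transitions[1:L, 1:L] - fb$logZ)
    d_trans[1:L, 1:L] <- d_trans[1:L, 1:L] + pair
    d_trans[labels[t - 1L], labels[t]] <-
      d_trans[labels[t - 1L], labels[t]] - 1
  }
  list(nll = nll, d_emissions = d_emis, d_transitions = d_trans)
}
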