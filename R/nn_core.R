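# Numerical core shared by the language model, the transfer classifier and
# the CNN baseline: parameter initialization, activations, losses and the
# AdamW / AdaMax optimizers. All gradients in this package are hand-written
# reverse-mode; every routine here therefore has a matching backward rule at
# its call sites.

sigmoid <- function(x) 1 / (1 + exp(-x))

softmax_rows <- function(z) {
  z <- z - apply(z, 1, max)
  e <- exp(z)
  e / rowSums(e)
}

log_softmax_rows <- function(z) {
  z <- z - apply(z, 1, max)
  z - log(rowSums(exp(z)))
}

# Uniform init in [-k, k], the scheme used by standard LSTM implementations
# (k = 1/sqrt(hidden)).
init_uniform <- function(nr, nc, k) {
  matrix(stats::runif(nr * nc, -k, k), nr, nc)
}

# --- AdamW -------------------------------------------------------------

#' @keywords internal
adamw_state <- function() {
  e <- new.env(parent = emptyenv())
  e$m <- list(); e$v <- list(); e$t <- 0L
  e
}

# One AdamW step over the named parameter list. `lr_of(name)` supplies the
# per-parameter learning rate (discriminative rates across layer groups);
# decoupled weight decay is applied to matrices only.
adamw_step <- function(params, grads, state, lr_of, beta1 = 0.9,
                       beta2 = 0.99, eps = 1e-8, weight_decay = 0.01) {
  state$t <- state$t + 1L
  t <- state$t
  for (nm in names(grads)) {
    g <- grads[[nm]]
    if (is.null(g)) next
    lr <- lr_of(nm)
    if (lr == 0) next
    if (is.null(state$m[[nm]])) {
      state$m[[nm]] <- g * 0
      state$v[[nm]] <- g * 0
    }
    state$m[[nm]] <- beta1 * state$m[[nm]] + (1 - beta1) * g
    state$v[[nm]] <- beta2 * state$v[[nm]] + (1 - beta2) * g * g
    mhat <- state$m[[nm]] / (1 - beta1^t)
    vhat <- state$v[[nm]] / (1 - beta2^t)
    upd <- mhat / (sqrt(vhat) + eps)
    if (weight_decay > 0 && !is.null(dim(params[[nm]])))
      upd <- upd + weight_decay * params[[nm]]
    params[[nm]] <- params[[nm]] - lr * upd
  }
  params
}

# --- AdaMax (used by the CNN baseline) ---------------------------------

adamax_state <- adamw_state

adamax_step <- function(params, grads, state, lr = 0.002, beta1 = 0.9,
                        beta2 = 0.999, eps = 1e-8) {
  state$t <- state$t + 1L
  t <- state$t
  for (nm in names(grads)) {
    g <- grads[[nm]]
    if (is.null(g)) next
    if (is.null(state$m[[nm]])) {
      state$m[[nm]] <- g * 0
      state$v[[nm]] <- g * 0
    }
    state$m[[nm]] <- beta1 * state$m[[nm]] + (1 - beta1) * g
    state$v[[nm]] <- pmax(beta2 * state$v[[nm]], abs(g))
    params[[nm]] <- params[[nm]] -
      (lr / (1 - beta1^t)) * state$m[[nm]] / (state$v[[nm]] + eps)
  }
  params
}

# --- losses ------------------------------------------------------------

# Categorical cross-entropy over logit rows; y is an integer class vector.
# Returns loss and dlogits (already divided by the number of rows).
xent_loss_grad <- function(logits, y) {
  n <- nrow(logits)
  ls <- log_softmax_rows(logits)
  loss <- -mean(ls[cbind(seq_len(n), y)])
  p <- exp(ls)
  d <- p
  d[cbind(seq_len(n), y)] <- d[cbind(seq_len(n), y)] - 1
  list(loss = loss, dlogits = d / n)
}

# Binary cross-entropy over logit matrix; y is a 0/1 matrix of equal shape.
bce_loss_grad <- function(logits, y) {
  p <- sigmoid(logits)
  eps <- 1e-12
  loss <- -mean(y * log(p + eps) + (1 - y) * log(1 - p + eps))
  list(loss = loss, dlogits = (p - y) / length(y))
}

# --- dropout masks (inverted dropout: mask / (1 - p)) ------------------

dropout_mask <- function(nr, nc, p) {
  if (p <= 0) return(NULL)
  matrix((stats::runif(nr * nc) >= p) / (1 - p), nr, nc)
}

apply_mask <- function(x, mask) if (is.null(mask)) x else x * mask
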