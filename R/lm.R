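# Regularized LSTM language model over amino-acid tokens.
#
# Architecture: tied input/output embedding, three stacked LSTM layers
# (embedding_dim -> hidden_dim -> hidden_dim -> embedding_dim) and a
# softmax decoder sharing the embedding matrix. Regularization follows the
# AWD-LSTM taxonomy: embedding dropout (whole token rows), input dropout,
# weight dropout (DropConnect on the recurrent matrices), hidden-state
# dropout between layers and output dropout before the decoder.

#' Language-model configuration
#'
#' @param embedding_dim embedding width (also the final LSTM layer's width,
#'   required by weight tying).
#' @param hidden_dim width of the intermediate LSTM layers.
#' @param n_layers number of LSTM layers (3 by default; overridable for
#'   ablations).
#' @param dropout named list with elements `embedding`, `input`, `weight`,
#'   `hidden`, `output`, each a probability in [0, 1).
#' @param tie_weights share the decoder weight with the embedding matrix
#'   (default `TRUE`).
#' @param bptt_mean mean truncated-backpropagation window length (~70).
#' @param batch_size number of parallel token streams during training.
#' @param lr base learning rate for AdamW.
#' @param seed integer seed for weight initialization.
#' @return list of class `lm_config`.
#' @export
lm_config <- function(embedding_dim = 32, hidden_dim = 64, n_layers = 3,
                      dropout = list(embedding = 0, input = 0, weight = 0,
                                     hidden = 0, output = 0),
                      tie_weights = TRUE, bptt_mean = 70, batch_size = 16,
                      lr = 3e-2, seed = 1L) {
  dp <- utils::modifyList(list(embedding = 0, input = 0, weight = 0,
                               hidden = 0, output = 0), dropout)
  stopifnot(all(unlist(dp) >= 0), all(unlist(dp) < 1), n_layers >= 1)
  structure(list(embedding_dim = embedding_dim, hidden_dim = hidden_dim,
                 n_layers = as.integer(n_layers), dropout = dp,
                 tie_weights = isTRUE(tie_weights), bptt_mean = bptt_mean,
                 batch_size = as.integer(batch_size), lr = lr,
                 seed = as.integer(seed)),
            class = "lm_config")
}

# layer input/output widths for a given config
lm_layer_dims <- function(config) {
  de <- config$embedding_dim; h <- config$hidden_dim; n <- config$n_layers
  d_in <- c(de, rep(h, n - 1))
  d_out <- c(rep(h, n - 1), de)
  if (n == 1) { d_in <- de; d_out <- de }
  list(d_in = d_in, d_out = d_out)
}

#' Build a language model
#'
#' @param config an [lm_config()].
#' @param vocab an [aa_vocabulary()] (size >= 2).
#' @return mutable model handle (environment) of class `aa_lm` holding
#'   `params`, `config` and `vocab`.
#' @export
build_lm <- function(config, vocab) {
  if (vocab$size < 2) stop("vocabulary must have at least 2 tokens")
  dims <- lm_layer_dims(config)
  params <- with_seed(config$seed, {
    p <- list(E = init_uniform(vocab$size, config$embedding_dim, 0.1),
              b_dec = rep(0, vocab$size))
    for (l in seq_len(config$n_layers)) {
      lay <- init_lstm_layer(dims$d_in[l], dims$d_out[l])
      p[[paste0("W", l)]] <- lay$W
      p[[paste0("U", l)]] <- lay$U
      p[[paste0("b", l)]] <- lay$b
    }
    if (!config$tie_weights)
      p$D <- init_uniform(vocab$size, config$embedding_dim, 0.1)
    p
  })
  model <- new.env(parent = emptyenv())
  model$params <- params
  model$config <- config
  model$vocab <- vocab
  class(model) <- "aa_lm"
  model
}

# fresh all-zero hidden state: list per layer of list(h, c), B rows
lm_init_state <- function(config, batch_size) {
  dims <- lm_layer_dims(config)
  lapply(seq_len(config$n_layers), function(l)
    list(h = matrix(0, batch_size, dims$d_out[l]),
         c = matrix(0, batch_size, dims$d_out[l])))
}

# Forward (and optionally backward) pass over one BPTT window.
# xb, yb: T x B integer id matrices (yb may be NULL for inference).
# Returns loss, per-position log-probabilities (optional), parameter
# gradients (when compute_grads) and the detached final state.
lm_window_pass <- function(model, xb, yb = NULL, state = NULL,
                           train = FALSE, compute_grads = FALSE,
                           return_probs = FALSE) {
  cfg <- model$config; p <- model$params
  Tn <- nrow(xb); B <- ncol(xb)
  if (is.null(state)) state <- lm_init_state(cfg, B)
  dp <- if (train) cfg$dropout else
    list(embedding = 0, input = 0, weight = 0, hidden = 0, output = 0)

  # embedding dropout zeroes whole token rows
  rmask <- if (dp$embedding > 0)
    (stats::runif(model$vocab$size) >= dp$embedding) / (1 - dp$embedding) else NULL
  E_in <- if (is.null(rmask)) p$E else p$E * rmask
  ids_flat <- as.integer(t(xb))              # row-major: t-blocks of B
  Xmat <- E_in[ids_flat, , drop = FALSE]
  mi <- dropout_mask(B, cfg$embedding_dim, dp$input)   # variational in time
  X <- lapply(seq_len(Tn), function(t)
    apply_mask(Xmat[(t - 1L) * B + seq_len(B), , drop = FALSE], mi))

  n_lay <- cfg$n_layers
  fw <- vector("list", n_lay)
  hmask <- vector("list", n_lay)   # hidden dropout after layers 1..n-1
  umask <- vector("list", n_lay)
  inp <- X
  for (l in seq_len(n_lay)) {
    Wl <- p[[paste0("W", l)]]; Ul <- p[[paste0("U", l)]]; bl <- p[[paste0("b", l)]]
    umask[l] <- list(if (dp$weight > 0)
      dropout_mask(nrow(Ul), ncol(Ul), dp$weight) else NULL)
    fw[[l]] <- lstm_forward(inp, Wl, Ul, bl, state[[l]]$h, state[[l]]$c,
                            umask = umask[[l]], keep_cache = compute_grads)
    if (l < n_lay) {
      hmask[l] <- list(dropout_mask(B, ncol(fw[[l]]$h), dp$hidden))
      inp <- lapply(fw[[l]]$H, apply_mask, mask = hmask[[l]])
    }
  }
  mo <- dropout_mask(B, cfg$embedding_dim, dp$output)
  Hout <- lapply(fw[[n_lay]]$H, apply_mask, mask = mo)
  M <- do.call(rbind, Hout)                    # (T*B) x de, t-major
  Dw <- if (cfg$tie_weights) p$E else p$D
  logits <- M %*% t(Dw) + matrix(p$b_dec, nrow(M), length(p$b_dec), byrow = TRUE)

  out <- list(state = lapply(fw, function(f) list(h = f$h, c = f$c)))
  if (return_probs) out$log_probs <- log_softmax_rows(logits)
  if (!is.null(yb)) {
    y_flat <- as.integer(t(yb))
    lg <- xent_loss_grad(logits, y_flat)
    out$loss <- lg$loss
    out$n_tokens <- length(y_flat)
    out$correct <- sum(max.col(logits, ties.method = "first") == y_flat)
    if (compute_grads) {
      dlog <- lg$dlogits
      g <- list(b_dec = colSums(dlog))
      dM <- dlog %*% Dw
      dDw <- crossprod(dlog, M)
      if (!is.null(mo)) dM <- dM * mo[rep(seq_len(B), times = Tn), , drop = FALSE]
      # split dM back into per-timestep blocks (t-major, B rows each)
      dAbove <- lapply(seq_len(Tn), function(t)
        dM[(t - 1L) * B + seq_len(B), , drop = FALSE])
      dX_below <- NULL
      for (l in rev(seq_len(n_lay))) {
        Wl <- p[[paste0("W", l)]]; Ul <- p[[paste0("U", l)]]
        bw <- lstm_backward(Wl, Ul, fw[[l]]$cache, dAbove)
        g[[paste0("W", l)]] <- bw$dW
        g[[paste0("U", l)]] <- bw$dU
        g[[paste0("b", l)]] <- bw$db
        if (l > 1) {
          dAbove <- if (is.null(hmask[[l - 1]])) bw$dX else
            lapply(bw$dX, function(m) m * hmask[[l - 1]])
        } else dX_below <- bw$dX
      }
      dXmat <- do.call(rbind, dX_below)
      if (!is.null(mi)) dXmat <- dXmat * mi[rep(seq_len(B), times = Tn), , drop = FALSE]
      dE_rows <- rowsum(dXmat, group = ids_flat)
      dE <- p$E * 0
      dE[as.integer(rownames(dE_rows)), ] <- dE_rows
      if (!is.null(rmask)) dE <- dE * rmask
      if (cfg$tie_weights) {
        g$E <- dE + dDw
      } else {
        g$E <- dE
        g$D <- dDw
      }
      out$grads <- g
    }
  }
  out
}

#' Build a variable-length BPTT stream from tokenized sequences
#'
#' Token sequences are concatenated (in a seed-shuffled order) into
#' `batch_size` parallel streams; training windows are drawn with a
#' variable length: the window mean is `bptt_mean` with probability 0.95
#' and `bptt_mean / 2` otherwise, perturbed by Gaussian noise of standard
#' deviation 5 and clamped to `[5, 2 * bptt_mean]`. Each window's targets
#' are its inputs shifted by one position; together the windows tile each
#' stream, so every token except each stream's first appears exactly once
#' as a target. The learning-rate scale `length / bptt_mean` accompanies
#' each window.
#'
#' @param token_sequences list of integer token-id vectors (from
#'   [tokenize()]).
#' @param batch_size number of parallel streams.
#' @param bptt_mean mean window length (~70 tokens).
#' @param seed integer seed fixing the concatenation order and the window
#'   lengths.
#' @return list of class `bptt_stream` with `windows` (each: `input`,
#'   `target` as T x B id matrices, `lr_scale`), `batch_size`, `n_tokens`.
#' @export
make_bptt_stream <- function(token_sequences, batch_size, bptt_mean = 70,
                             seed = 1L) {
  stopifnot(length(token_sequences) >= 1)
  with_seed(seed, {
    order_ <- sample(length(token_sequences))
    flat <- unlist(token_sequences[order_], use.names = FALSE)
    if (length(flat) < batch_size * 2)
      stop("corpus too small for one BPTT window at this batch size")
    n_per <- length(flat) %/% batch_size
    S <- matrix(flat[seq_len(n_per * batch_size)], nrow = n_per)
    windows <- list()
    pos <- 1L
    while (pos < n_per) {
      base <- if (stats::runif(1) < 0.95) bptt_mean else bptt_mean / 2
      len <- round(stats::rnorm(1, base, 5))
      len <- max(5, min(len, 2 * bptt_mean))
      len <- min(len, n_per - pos)           # final window may be shorter
      rows <- pos + seq_len(len) - 1L
      windows[[length(windows) + 1L]] <-
        list(input = S[rows, , drop = FALSE],
             target = S[rows + 1L, , drop = FALSE],
             lr_scale = len / bptt_mean)
      pos <- pos + len
    }
    structure(list(windows = windows, batch_size = batch_size,
                   bptt_mean = bptt_mean, n_tokens = length(flat),
                   seed = seed),
              class = "bptt_stream")
  })
}

#' Train the language model
#'
#' AdamW on cross-entropy over BPTT windows; the hidden state persists
#' (detached) across windows within an epoch and is reset at epoch
#' boundaries. The learning rate of each step is scaled by the window
#' length relative to `bptt_mean`.
#'
#' @param model an `aa_lm` from [build_lm()].
#' @param stream a `bptt_stream` (training data).
#' @param epochs number of passes over the stream.
#' @param valid_stream optional held-out `bptt_stream` evaluated each
#'   epoch.
#' @param seed seed for dropout noise during training.
#' @param verbose print per-epoch losses.
#' @return the model handle, with `model$history` (data.frame: epoch,
#'   train_loss, valid_loss, valid_accuracy) updated in place.
#' @export
train_lm <- function(model, stream, epochs = 5, valid_stream = NULL,
                     seed = model$config$seed, verbose = FALSE) {
  cfg <- model$config
  opt <- adamw_state()
  history <- data.frame()
  with_seed(derive_seed(seed, "train_lm"), {
    for (ep in seq_len(epochs)) {
      state <- NULL
      tot_loss <- 0; tot_n <- 0
      for (w in stream$windows) {
        res <- lm_window_pass(model, w$input, w$target, state,
                              train = TRUE, compute_grads = TRUE)
        if (!is.finite(res$loss))
          stop(sprintf("non-finite training loss at epoch %d", ep))
        lr <- cfg$lr * w$lr_scale
        model$params <- adamw_step(model$params, res$grads, opt,
                                   lr_of = function(nm) lr)
        state <- res$state
        tot_loss <- tot_loss + res$loss * res$n_tokens
        tot_n <- tot_n + res$n_tokens
      }
      row <- data.frame(epoch = ep, train_loss = tot_loss / tot_n,
                        valid_loss = NA_real_, valid_accuracy = NA_real_)
      if (!is.null(valid_stream)) {
        ev <- evaluate_lm(model, valid_stream)
        row$valid_loss <- log(ev$perplexity)
        row$valid_accuracy <- ev$next_token_accuracy
      }
      history <- rbind(history, row)
      if (verbose)
        message(sprintf("epoch %d: train loss %.4f", ep, row$train_loss))
    }
  })
  model$history <- history
  invisible(model)
}

#' Evaluate a language model on a held-out stream
#'
#' @param model an `aa_lm`.
#' @param stream a `bptt_stream` over held-out sequences.
#' @return list of class `lm_eval` with `perplexity` (exp of the mean
#'   per-token negative log-likelihood) and `next_token_accuracy`.
#' @export
evaluate_lm <- function(model, stream) {
  if (length(stream$windows) == 0) stop("empty evaluation stream")
  state <- NULL
  nll <- 0; n <- 0; correct <- 0
  for (w in stream$windows) {
    res <- lm_window_pass(model, w$input, w$target, state, train = FALSE)
    nll <- nll + res$loss * res$n_tokens
    n <- n + res$n_tokens
    correct <- correct + res$correct
    state <- res$state
  }
  structure(list(perplexity = exp(nll / n),
                 next_token_accuracy = correct / n,
                 n_tokens = n),
            class = "lm_eval")
}

#' Save / load model weights
#'
#' Checkpoints are written as an RDS archive of the parameter list plus a
#' JSON manifest (config, vocabulary, class) alongside it.
#'
#' @param model an `aa_lm` or `aa_classifier` handle.
#' @param path output path (the manifest is written at `<path>.json`).
#' @export
save_model <- function(model, path) {
  saveRDS(list(params = model$params, config = model$config,
               lm_config = model$lm_config, classes = model$classes,
               class = class(model)), path)
  manifest <- list(class = class(model),
                   params = names(model$params),
                   vocab = model$vocab$tokens,
                   saved = format(Sys.time(), "%Y-%m-%dT%H:%M:%S"))
  jsonlite::write_json(manifest, paste0(path, ".json"), auto_unbox = TRUE)
  invisible(path)
}

#' @rdname save_model
#' @param vocab vocabulary to attach on load.
#' @export
load_model <- function(path, vocab = aa_vocabulary()) {
  x <- readRDS(path)
  model <- new.env(parent = emptyenv())
  model$params <- x$params
  model$config <- x$config
  for (f in c("lm_config", "classes"))
    if (!is.null(x[[f]])) model[[f]] <- x[[f]]
  model$vocab <- vocab
  class(model) <- x$class
  model
}
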