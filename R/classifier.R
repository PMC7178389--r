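# Transfer classifier: pre-trained LSTM encoder + concat-pooling head,
# fine-tuned with gradual unfreezing, discriminative per-group learning
# rates and a one-cycle schedule.

#' Classifier configuration
#'
#' @param n_outputs number of output units (>= 2 for categorical loss; 1
#'   allowed for binary detection tasks).
#' @param head_hidden width of the head's hidden dense layer (default 256;
#'   the gene-ontology configuration uses 1024, see [go_classifier_config()]).
#' @param loss `"categorical"` (softmax + categorical cross-entropy) or
#'   `"binary"` (per-output sigmoid + binary cross-entropy).
#' @param max_context maximum number of timesteps gradients are
#'   backpropagated through (default 1024); longer sequences are still
#'   encoded in full, with the hidden state carried forward, but earlier
#'   positions receive no gradient.
#' @param base_lr learning rate of the head layer group; deeper groups get
#'   half the rate of the group above them.
#' @param epochs_final epochs of the final fine-tuning stage (default 30).
#' @param batch_size minibatch size.
#' @param head_dropout dropout probability inside the head.
#' @param direction `"forward"` or `"backward"` token direction.
#' @param seed integer seed (head init, minibatch order, dropout noise).
#' @return list of class `clf_config`.
#' @export
classifier_config <- function(n_outputs, head_hidden = 256,
                              loss = c("categorical", "binary"),
                              max_context = 1024, base_lr = 4e-3,
                              epochs_final = 30, batch_size = 32,
                              head_dropout = 0,
                              direction = c("forward", "backward"),
                              seed = 1L) {
  loss <- match.arg(loss)
  direction <- match.arg(direction)
  if (loss == "categorical" && n_outputs < 2)
    stop("categorical loss needs n_outputs >= 2")
  stopifnot(max_context >= 1)
  structure(list(n_outputs = as.integer(n_outputs), head_hidden = head_hidden,
                 loss = loss, max_context = as.integer(max_context),
                 n_layer_groups = 4L, base_lr = base_lr,
                 epochs_final = as.integer(epochs_final),
                 batch_size = as.integer(batch_size),
                 head_dropout = head_dropout, direction = direction,
                 seed = as.integer(seed)),
            class = "clf_config")
}

#' Gene-ontology task configuration
#'
#' Same as [classifier_config()] but with the multi-label defaults the GO
#' protocol uses: binary cross-entropy and a head hidden width of 1024.
#'
#' @param n_outputs number of GO terms after filtering.
#' @param ... passed to [classifier_config()].
#' @export
go_classifier_config <- function(n_outputs, ...) {
  classifier_config(n_outputs = n_outputs, head_hidden = 1024,
                    loss = "binary", ...)
}

# parameter name -> layer group (1 = embedding, 2 = LSTM layer 1,
# 3 = LSTM layers 2+3, 4 = head)
param_group <- function(name) {
  if (name %in% c("E")) return(1L)
  if (name %in% c("W1", "U1", "b1")) return(2L)
  if (grepl("^[WUb][2-9]$", name)) return(3L)
  4L
}

#' Build a classifier from language-model weights
#'
#' Replaces the language model's decoder with a concat-pooling layer and
#' two dense layers (hidden + output). The embedding and all LSTM weights
#' are copied from the pre-trained model; the head is freshly initialized.
#' `from_scratch = TRUE` instead initializes the whole network randomly
#' (same architecture, same seed-controlled init), for the
#' no-pretraining comparison.
#'
#' @param lm an `aa_lm` handle (pre-trained or not).
#' @param config a [classifier_config()].
#' @param from_scratch ignore the language-model weights.
#' @return mutable handle (environment) of class `aa_classifier`.
#' @export
build_classifier <- function(lm, config, from_scratch = FALSE) {
  lm_cfg <- lm$config
  de <- lm_cfg$embedding_dim
  encoder_names <- c("E", unlist(lapply(seq_len(lm_cfg$n_layers), function(l)
    paste0(c("W", "U", "b"), l))))
  if (from_scratch) {
    fresh <- build_lm(utils::modifyList(lm_cfg, list(seed = config$seed)),
                      lm$vocab)
    enc <- fresh$params[encoder_names]
  } else {
    enc <- lm$params[encoder_names]
  }
  head <- with_seed(derive_seed(config$seed, "head"), {
    k1 <- sqrt(6 / (3 * de))
    k2 <- sqrt(3 / config$head_hidden)
    list(ln_g = rep(1, 3 * de),            # layer norm on pooled features
         ln_b = rep(0, 3 * de),
         Wh = init_uniform(3 * de, config$head_hidden, k1),
         bh = rep(0, config$head_hidden),
         Wo = init_uniform(config$head_hidden, config$n_outputs, k2),
         bo = rep(0, config$n_outputs))
  })
  clf <- new.env(parent = emptyenv())
  clf$params <- c(enc, head)
  clf$config <- config
  clf$lm_config <- lm_cfg
  clf$vocab <- lm$vocab
  class(clf) <- "aa_classifier"
  clf
}

#' Concat pooling of a hidden-state sequence
#'
#' Concatenates the final hidden state, the elementwise maximum over time
#' and the elementwise mean over time of a `T x d` state matrix into a
#' `3d` vector. Padding positions must be removed before calling.
#'
#' @param H numeric matrix, timesteps x hidden-dim, `T >= 1`.
#' @return numeric vector of length `3 * ncol(H)`.
#' @export
concat_pool <- function(H) {
  stopifnot(is.matrix(H), nrow(H) >= 1)
  c(H[nrow(H), ], apply(H, 2, max), colMeans(H))
}

# Encoder + head forward (and optional backward) for a padded batch.
#   ids: T x B id matrix (pad_id beyond each sequence's length), or NULL
#        when X_override supplies embeddings directly (attribution path).
#   lengths: true sequence lengths (tokens incl. <BOS>).
#   y: labels (integer vector for categorical, 0/1 matrix for binary).
# Returns probs, loss, grads (params), dX (when input_grads = TRUE).
clf_batch_pass <- function(clf, ids = NULL, lengths, y = NULL,
                           train = FALSE, compute_grads = FALSE,
                           input_grads = FALSE, X_override = NULL,
                           target_class = NULL, target_on = "prob") {
  cfg <- clf$config; lcfg <- clf$lm_config; p <- clf$params
  de <- lcfg$embedding_dim
  if (is.null(X_override)) {
    Tn <- nrow(ids); B <- ncol(ids)
    ids_flat <- as.integer(t(ids))
    Xmat <- p$E[ids_flat, , drop = FALSE]
    X <- lapply(seq_len(Tn), function(t)
      Xmat[(t - 1L) * B + seq_len(B), , drop = FALSE])
  } else {
    X <- X_override
    Tn <- length(X); B <- nrow(X[[1]])
  }
  n_lay <- lcfg$n_layers
  mc <- cfg$max_context

  # sequences longer than max_context: encode the prefix without caching
  # (state carried, gradients truncated), then the cached tail
  state <- lm_init_state(lcfg, B)
  prefix_H <- list()
  tail_start <- 1L
  if (Tn > mc) {
    tail_start <- Tn - mc + 1L
    inp <- X[seq_len(tail_start - 1L)]
    for (l in seq_len(n_lay)) {
      fwp <- lstm_forward(inp, p[[paste0("W", l)]], p[[paste0("U", l)]],
                          p[[paste0("b", l)]], state[[l]]$h, state[[l]]$c,
                          keep_cache = FALSE)
      state[[l]] <- list(h = fwp$h, c = fwp$c)
      if (l < n_lay) inp <- fwp$H else prefix_H <- fwp$H
    }
  }
  fw <- vector("list", n_lay)
  inp <- X[tail_start:Tn]
  for (l in seq_len(n_lay)) {
    fw[[l]] <- lstm_forward(inp, p[[paste0("W", l)]], p[[paste0("U", l)]],
                            p[[paste0("b", l)]], state[[l]]$h, state[[l]]$c,
                            keep_cache = compute_grads || input_grads)
    inp <- fw[[l]]$H
  }
  H3 <- c(prefix_H, fw[[n_lay]]$H)          # full-sequence final-layer states
  M <- do.call(rbind, H3)                   # (T*B) x de, t-major

  # masked concat pooling
  pooled <- matrix(0, B, 3L * de)
  amax <- matrix(0L, B, de)                 # time index of per-dim max
  for (b in seq_len(B)) {
    len <- lengths[b]
    idx <- seq(b, by = B, length.out = len)
    Mb <- M[idx, , drop = FALSE]
    am <- max.col(t(Mb), ties.method = "first")
    amax[b, ] <- am
    pooled[b, ] <- c(Mb[len, ], Mb[cbind(am, seq_len(de))], colMeans(Mb))
  }

  # layer normalization of the pooled features stabilizes the head against
  # the scale of the encoder states; deterministic at train and inference
  eps_ln <- 1e-5
  D <- ncol(pooled)
  mu_r <- rowMeans(pooled)
  va_r <- rowMeans((pooled - mu_r)^2)
  inv_sd <- 1 / sqrt(va_r + eps_ln)        # per-row
  xhat <- (pooled - mu_r) * inv_sd
  pn <- sweep(sweep(xhat, 2, p$ln_g, "*"), 2, p$ln_b, "+")

  hd <- if (train && cfg$head_dropout > 0)
    dropout_mask(B, cfg$head_hidden, cfg$head_dropout) else NULL
  Z1 <- pn %*% p$Wh + matrix(p$bh, B, cfg$head_hidden, byrow = TRUE)
  A1 <- apply_mask(pmax(Z1, 0), hd)
  logits <- A1 %*% p$Wo + matrix(p$bo, B, cfg$n_outputs, byrow = TRUE)
  probs <- if (cfg$loss == "categorical") softmax_rows(logits) else sigmoid(logits)

  out <- list(probs = probs, logits = logits)
  if (is.null(y) && !input_grads) return(out)

  if (!is.null(y)) {
    lg <- if (cfg$loss == "categorical") xent_loss_grad(logits, y)
          else bce_loss_grad(logits, y)
    out$loss <- lg$loss
    dlogits <- lg$dlogits
  } else {
    # attribution: gradient of the target-class output (post-softmax
    # probability by default, raw logit when target_on = "logit")
    stopifnot(!is.null(target_class))
    dlogits <- matrix(0, B, cfg$n_outputs)
    if (target_on == "logit") {
      dlogits[, target_class] <- 1
    } else if (cfg$loss == "categorical") {
      for (b in seq_len(B))
        dlogits[b, ] <- probs[b, target_class] *
          ((seq_len(cfg$n_outputs) == target_class) - probs[b, ])
    } else {
      dlogits[, target_class] <- probs[, target_class] *
        (1 - probs[, target_class])
    }
  }
  if (!compute_grads && !input_grads) return(out)

  g <- list()
  dA1 <- dlogits %*% t(p$Wo)
  g$Wo <- crossprod(A1, dlogits)
  g$bo <- colSums(dlogits)
  dZ1 <- apply_mask(dA1, hd) * (Z1 > 0)
  g$Wh <- crossprod(pn, dZ1)
  g$bh <- colSums(dZ1)
  dpn <- dZ1 %*% t(p$Wh)
  g$ln_g <- colSums(dpn * xhat)
  g$ln_b <- colSums(dpn)
  dxhat <- sweep(dpn, 2, p$ln_g, "*")
  dpool <- (dxhat - rowMeans(dxhat) - xhat * rowMeans(dxhat * xhat)) * inv_sd

  dM <- matrix(0, nrow(M), de)
  for (b in seq_len(B)) {
    len <- lengths[b]
    idx <- seq(b, by = B, length.out = len)
    dlast <- dpool[b, seq_len(de)]
    dmax <- dpool[b, de + seq_len(de)]
    dmean <- dpool[b, 2L * de + seq_len(de)]
    dM[idx[len], ] <- dM[idx[len], ] + dlast
    pos <- cbind(idx[amax[b, ]], seq_len(de))
    dM[pos] <- dM[pos] + dmax
    dM[idx, ] <- dM[idx, ] + matrix(dmean / len, len, de, byrow = TRUE)
  }
  # gradients flow only through the cached tail
  tail_T <- Tn - tail_start + 1L
  dH <- lapply(seq_len(tail_T), function(t) {
    tt <- tail_start + t - 1L
    dM[(tt - 1L) * B + seq_len(B), , drop = FALSE]
  })
  dAbove <- dH
  dX_tail <- NULL
  for (l in rev(seq_len(n_lay))) {
    bw <- lstm_backward(p[[paste0("W", l)]], p[[paste0("U", l)]],
                        fw[[l]]$cache, dAbove)
    g[[paste0("W", l)]] <- bw$dW
    g[[paste0("U", l)]] <- bw$dU
    g[[paste0("b", l)]] <- bw$db
    dAbove <- bw$dX
    if (l == 1) dX_tail <- bw$dX
  }
  if (input_grads) {
    dX <- c(rep(list(matrix(0, B, de)), tail_start - 1L), dX_tail)
    out$dX <- dX
  }
  if (compute_grads && is.null(X_override)) {
    dXmat <- do.call(rbind, dX_tail)
    flat_tail <- as.integer(t(ids[tail_start:Tn, , drop = FALSE]))
    dE_rows <- rowsum(dXmat, group = flat_tail)
    dE <- p$E * 0
    dE[as.integer(rownames(dE_rows)), ] <- dE_rows
    g$E <- dE
    out$grads <- g
  } else if (compute_grads) {
    out$grads <- g
  }
  out
}

# gradients with frozen layer groups zeroed; used by finetune and exposed
# to tests through the package namespace
classifier_gradients <- function(clf, ids, lengths, y, trainable_groups) {
  res <- clf_batch_pass(clf, ids, lengths, y, train = TRUE,
                        compute_grads = TRUE)
  g <- res$grads
  for (nm in names(g))
    if (!param_group(nm) %in% trainable_groups) g[[nm]] <- g[[nm]] * 0
  res$grads <- g
  res
}

#' Gradual-unfreezing schedule with discriminative learning rates
#'
#' Stage `k` trains the last `k` layer groups (head first); the final stage
#' trains all four groups for `epochs_final` epochs. Within every stage,
#' each trainable group `g` uses the one-cycle schedule peaking at its own
#' rate: the head group peaks at `base_lr` and each group toward the input
#' at half the rate of the group above it.
#'
#' @param base_lr peak learning rate of the head group.
#' @param n_groups number of layer groups (4).
#' @param stage_epochs epochs for stages 1..(n_groups-1) (recycled).
#' @param epochs_final epochs of the final all-groups stage (default 30).
#' @return list of class `unfreeze_schedule` with `stages` (each:
#'   `trainable_groups`, `epochs`) and `group_lrs` (named vector, group 1 =
#'   input/embedding ... group `n_groups` = head).
#' @examples
#' s <- unfreeze_schedule(0.008)
#' s$group_lrs  # 0.001 0.002 0.004 0.008 from input to output group
#' @export
unfreeze_schedule <- function(base_lr, n_groups = 4, stage_epochs = 1,
                              epochs_final = 30) {
  group_lrs <- base_lr / 2^((n_groups - 1):0)
  names(group_lrs) <- paste0("group", seq_len(n_groups))
  stage_epochs <- rep_len(stage_epochs, n_groups - 1)
  stages <- lapply(seq_len(n_groups), function(k)
    list(trainable_groups = seq(n_groups - k + 1, n_groups),
         epochs = if (k < n_groups) stage_epochs[k] else epochs_final))
  structure(list(stages = stages, group_lrs = group_lrs,
                 n_groups = n_groups, base_lr = base_lr),
            class = "unfreeze_schedule")
}

#' One-cycle learning-rate schedule
#'
#' Cosine warmup from `max_lr / div_factor` to `max_lr` over the first
#' `pct_start` of the steps, then cosine annealing down to
#' `max_lr / final_div_factor`.
#'
#' @param step step index, 1..total_steps.
#' @param total_steps total optimizer steps in the stage.
#' @param max_lr peak learning rate.
#' @param pct_start fraction of steps spent warming up.
#' @param div_factor initial divisor.
#' @param final_div_factor final divisor.
#' @return learning rate at `step` (vectorized over `step`).
#' @export
one_cycle_lr <- function(step, total_steps, max_lr, pct_start = 0.25,
                         div_factor = 25, final_div_factor = 1e4) {
  warm <- max(1, round(pct_start * total_steps))
  lo <- max_lr / div_factor
  fin <- max_lr / final_div_factor
  vapply(step, function(s) {
    if (s <= warm) {
      frac <- if (warm > 1) (s - 1) / (warm - 1) else 1
      lo + (max_lr - lo) * (1 - cos(pi * frac)) / 2
    } else {
      frac <- (s - warm) / max(1, total_steps - warm)
      fin + (max_lr - fin) * (1 + cos(pi * frac)) / 2
    }
  }, numeric(1))
}

# tokenize + pad a set of sequences into (ids matrix, lengths)
encode_batch <- function(sequences, vocab, direction) {
  toks <- lapply(sequences, tokenize, vocab = vocab, direction = direction)
  lens <- lengths(toks)
  Tn <- max(lens)
  ids <- matrix(vocab$pad_id, Tn, length(toks))
  for (b in seq_along(toks)) ids[seq_len(lens[b]), b] <- toks[[b]]
  list(ids = ids, lengths = lens)
}

#' Fine-tune a classifier with gradual unfreezing
#'
#' Runs the unfreezing stages of `schedule`; each stage applies AdamW under
#' a one-cycle learning-rate schedule with per-group discriminative rates.
#' Frozen layer groups receive zero gradient. After every epoch the
#' validation metric is computed and the best-scoring weights are retained
#' (ties resolved toward the earliest epoch).
#'
#' @param clf an `aa_classifier` from [build_classifier()].
#' @param train list with `sequences` (character) and `y` (integer class
#'   vector for categorical loss, or 0/1 matrix for binary loss).
#' @param valid like `train`; must be non-empty.
#' @param schedule an [unfreeze_schedule()]; default derives from the
#'   classifier config.
#' @param selection_metric `"accuracy"` (single-label), `"auc"` (binary
#'   detection) or `"loss"`.
#' @param seed seed for minibatch order and dropout.
#' @param verbose print per-epoch progress.
#' @return `clf`, updated in place, with `clf$history` (data.frame) and
#'   `clf$best` (list: stage, epoch, metric).
#' @export
finetune <- function(clf, train, valid, schedule = NULL,
                     selection_metric = c("accuracy", "auc", "loss"),
                     seed = clf$config$seed, verbose = FALSE) {
  selection_metric <- match.arg(selection_metric)
  cfg <- clf$config
  if (is.null(schedule))
    schedule <- unfreeze_schedule(cfg$base_lr, cfg$n_layer_groups,
                                  epochs_final = cfg$epochs_final)
  if (length(valid$sequences) == 0) stop("validation set must be non-empty")
  n <- length(train$sequences)
  bs <- cfg$batch_size
  categorical <- cfg$loss == "categorical"
  best_metric <- -Inf; best_params <- clf$params; best_at <- NULL
  history <- data.frame()

  eval_metric <- function() {
    pv <- predict_proba(clf, valid$sequences)
    if (selection_metric == "accuracy") {
      mean(max.col(pv, ties.method = "first") == valid$y)
    } else if (selection_metric == "auc") {
      sc <- if (ncol(pv) == 1) pv[, 1] else pv[, 2]
      yv <- if (is.matrix(valid$y)) valid$y[, 1] else valid$y
      if (length(unique(yv)) < 2) return(NA_real_)
      auc_score(yv, sc)
    } else {
      pv <- pmin(pmax(pv, 1e-12), 1 - 1e-12)
      if (categorical) mean(log(pv[cbind(seq_along(valid$y), valid$y)]))
      else -mean((valid$y - pv)^2)
    }
  }

  with_seed(derive_seed(seed, "finetune"), {
    for (si in seq_along(schedule$stages)) {
      stage <- schedule$stages[[si]]
      opt <- adamw_state()                 # fresh optimizer per stage
      steps_per_epoch <- max(1L, ceiling(n / bs))
      total_steps <- steps_per_epoch * stage$epochs
      step <- 0L
      for (ep in seq_len(stage$epochs)) {
        ord <- sample(n)
        # sort within chunks by length to limit padding, keep stochasticity
        batches <- split(ord, ceiling(seq_along(ord) / bs))
        ep_loss <- 0; ep_n <- 0
        for (bidx in batches) {
          step <- step + 1L
          eb <- encode_batch(train$sequences[bidx], clf$vocab, cfg$direction)
          yb <- if (categorical) train$y[bidx] else train$y[bidx, , drop = FALSE]
          res <- classifier_gradients(clf, eb$ids, eb$lengths, yb,
                                      stage$trainable_groups)
          if (!is.finite(res$loss)) stop("non-finite fine-tuning loss")
          lr_scale <- one_cycle_lr(step, total_steps, 1)
          lrs <- schedule$group_lrs * lr_scale
          clf$params <- adamw_step(clf$params, res$grads, opt,
                                   lr_of = function(nm) lrs[[param_group(nm)]])
          ep_loss <- ep_loss + res$loss * length(bidx); ep_n <- ep_n + length(bidx)
        }
        m <- eval_metric()
        history <- rbind(history,
                         data.frame(stage = si, epoch = ep,
                                    train_loss = ep_loss / ep_n,
                                    valid_metric = m))
        if (!is.na(m) && m > best_metric) {
          best_metric <- m; best_params <- clf$params
          best_at <- list(stage = si, epoch = ep, metric = m)
        }
        if (verbose)
          message(sprintf("stage %d epoch %d: loss %.4f valid %.4f",
                          si, ep, ep_loss / ep_n, m))
      }
    }
  })
  clf$params <- best_params
  clf$history <- history
  clf$best <- best_at
  invisible(clf)
}

#' Predict class probabilities
#'
#' Inference with dropout off; deterministic under fixed weights.
#' Sequences containing residues outside the vocabulary yield an `NA` row
#' and an entry in the `errors` attribute; the rest of the batch proceeds.
#'
#' @param clf an `aa_classifier`.
#' @param sequences character vector of residue strings.
#' @return numeric matrix, one row per sequence, one column per output;
#'   rows sum to 1 for categorical classifiers. Attribute `errors` is a
#'   named character vector of per-sequence failures (empty when clean).
#' @export
predict_proba <- function(clf, sequences) {
  cfg <- clf$config
  out <- matrix(NA_real_, length(sequences), cfg$n_outputs)
  ok <- vapply(sequences, function(s)
    !inherits(try(tokenize(s, clf$vocab, cfg$direction), silent = TRUE),
              "try-error"), logical(1))
  errs <- character(0)
  if (any(!ok))
    errs <- stats::setNames(
      vapply(sequences[!ok], function(s)
        attr(try(tokenize(s, clf$vocab, cfg$direction), silent = TRUE),
             "condition")$message %||% "tokenization failed", character(1)),
      which(!ok))
  if (any(ok)) {
    idx <- which(ok)
    # process in length-sorted chunks for padding efficiency
    ord <- idx[order(nchar(sequences[idx]))]
    for (chunk in split(ord, ceiling(seq_along(ord) / cfg$batch_size))) {
      eb <- encode_batch(sequences[chunk], clf$vocab, cfg$direction)
      res <- clf_batch_pass(clf, eb$ids, eb$lengths)
      out[chunk, ] <- res$probs
    }
  }
  attr(out, "errors") <- errs
  out
}

#' Ensemble forward and backward classifier probabilities
#'
#' Elementwise arithmetic mean of the two probability matrices.
#'
#' @param p_forward,p_backward numeric matrices of identical shape (rows =
#'   records, columns = classes/terms).
#' @return their elementwise mean.
#' @export
ensemble_proba <- function(p_forward, p_backward) {
  if (!identical(dim(p_forward), dim(p_backward)))
    stop("forward and backward probability matrices must have equal shape")
  (p_forward + p_backward) / 2
}
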