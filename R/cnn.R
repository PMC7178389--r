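# Convolutional baseline over one-hot + PSSM input matrices: seven
# convolution blocks (kernel 3, valid padding, ReLU, max-pool 2) followed
# by three dense layers with dropout and a softmax output, trained with
# AdaMax on categorical cross-entropy.

#' CNN baseline architecture specification
#'
#' The canonical architecture uses filter counts 1024, 512, 512, 512, 256,
#' 256, 256 (kernel size 3, valid padding), dense widths 512, 256, 128 and
#' 25% dropout after each dense layer. `width_scale` shrinks all widths
#' proportionally (layer structure preserved) for a CPU-sized test
#' profile.
#'
#' @param n_outputs number of softmax output units (e.g. 6 for Level-1
#'   enzyme-class prediction).
#' @param filters conv filter counts (7 layers).
#' @param kernel convolution kernel size.
#' @param dense dense-layer widths (3 layers).
#' @param dropout dropout rate after each dense layer.
#' @param max_len padded input length.
#' @param in_channels input width (26 one-hot + 20 PSSM).
#' @param width_scale multiplier applied to `filters` and `dense`.
#' @return list of class `cnn_spec`.
#' @export
cnn_spec <- function(n_outputs, filters = c(1024, 512, 512, 512, 256, 256, 256),
                     kernel = 3, dense = c(512, 256, 128), dropout = 0.25,
                     max_len = 1024, in_channels = 46, width_scale = 1) {
  filters <- pmax(1L, as.integer(round(filters * width_scale)))
  dense <- pmax(1L, as.integer(round(dense * width_scale)))
  stopifnot(length(filters) == 7, length(dense) == 3)
  # check the sequence length survives 7 conv+pool stages
  L <- max_len
  for (i in seq_along(filters)) {
    L <- L - (kernel - 1)
    if (L < 1) stop("max_len too short for 7 convolution blocks")
    L <- L %/% 2L
    if (L < 1 && i < length(filters)) stop("max_len too short for 7 convolution blocks")
  }
  if (L < 1) stop("max_len too short for 7 convolution blocks")
  structure(list(n_outputs = as.integer(n_outputs), filters = filters,
                 kernel = as.integer(kernel), dense = dense,
                 dropout = dropout, max_len = as.integer(max_len),
                 in_channels = as.integer(in_channels), final_len = L),
            class = "cnn_spec")
}

#' Build (initialize) a CNN baseline model
#'
#' @param spec a [cnn_spec()].
#' @param seed integer seed for initialization.
#' @return mutable handle (environment) of class `aa_cnn` with `params`,
#'   `spec`.
#' @export
build_cnn <- function(spec, seed = 1L) {
  params <- with_seed(seed, {
    p <- list()
    in_ch <- spec$in_channels
    for (l in seq_along(spec$filters)) {
      fan_in <- spec$kernel * in_ch
      p[[paste0("convW", l)]] <- init_uniform(fan_in, spec$filters[l],
                                              sqrt(6 / fan_in))
      p[[paste0("convb", l)]] <- rep(0, spec$filters[l])
      in_ch <- spec$filters[l]
    }
    d_in <- spec$final_len * in_ch
    for (l in seq_along(spec$dense)) {
      p[[paste0("denseW", l)]] <- init_uniform(d_in, spec$dense[l],
                                               sqrt(6 / d_in))
      p[[paste0("denseb", l)]] <- rep(0, spec$dense[l])
      d_in <- spec$dense[l]
    }
    p$outW <- init_uniform(d_in, spec$n_outputs, sqrt(3 / d_in))
    p$outb <- rep(0, spec$n_outputs)
    p
  })
  m <- new.env(parent = emptyenv())
  m$params <- params
  m$spec <- spec
  class(m) <- "aa_cnn"
  m
}

#' Describe a CNN model's layer structure
#'
#' @param model an `aa_cnn`.
#' @return data.frame with one row per layer (`type`, `width`,
#'   `n_params`); attribute `total_params` carries the parameter count.
#' @export
cnn_describe <- function(model) {
  sp <- model$spec; p <- model$params
  rows <- list()
  for (l in seq_along(sp$filters))
    rows[[length(rows) + 1]] <- data.frame(
      type = "conv", width = sp$filters[l],
      n_params = length(p[[paste0("convW", l)]]) + length(p[[paste0("convb", l)]]))
  for (l in seq_along(sp$dense))
    rows[[length(rows) + 1]] <- data.frame(
      type = "dense", width = sp$dense[l],
      n_params = length(p[[paste0("denseW", l)]]) + length(p[[paste0("denseb", l)]]))
  rows[[length(rows) + 1]] <- data.frame(type = "softmax", width = sp$n_outputs,
                                         n_params = length(p$outW) + length(p$outb))
  out <- do.call(rbind, rows)
  attr(out, "total_params") <- sum(out$n_params)
  out
}

# im2col for kernel-3 valid convolution
im2col3 <- function(X) {
  L <- nrow(X)
  cbind(X[1:(L - 2), , drop = FALSE],
        X[2:(L - 1), , drop = FALSE],
        X[3:L, , drop = FALSE])
}

# single-sample forward; returns logits (and caches when compute_grads)
cnn_forward_one <- function(params, spec, X, dmasks = NULL,
                            compute_grads = FALSE) {
  caches <- list()
  A <- X
  for (l in seq_along(spec$filters)) {
    Xcol <- im2col3(A)
    Z <- Xcol %*% params[[paste0("convW", l)]] +
      matrix(params[[paste0("convb", l)]], nrow(Xcol),
             spec$filters[l], byrow = TRUE)
    R <- pmax(Z, 0)
    Lp <- nrow(R) %/% 2L
    odd <- R[2 * seq_len(Lp) - 1, , drop = FALSE]
    even <- R[2 * seq_len(Lp), , drop = FALSE]
    P <- pmax(odd, even)
    if (compute_grads)
      caches[[l]] <- list(Xcol = Xcol, Z = Z, odd_sel = odd >= even, Lr = nrow(R))
    A <- P
  }
  flat <- as.vector(t(A))                  # position-major flatten
  caches$conv_out_dim <- dim(A)
  h <- flat
  for (l in seq_along(spec$dense)) {
    Z <- drop(h %*% params[[paste0("denseW", l)]]) + params[[paste0("denseb", l)]]
    R <- pmax(Z, 0)
    if (!is.null(dmasks)) R <- R * dmasks[[l]]
    if (compute_grads) caches[[paste0("dense", l)]] <- list(h = h, Z = Z)
    h <- R
  }
  logits <- drop(h %*% params$outW) + params$outb
  if (compute_grads) caches$head_h <- h
  list(logits = logits, caches = caches)
}

# single-sample backward from dlogits; returns gradient list
cnn_backward_one <- function(params, spec, fwd, dlogits, dmasks = NULL) {
  g <- list()
  caches <- fwd$caches
  h <- caches$head_h
  g$outW <- outer(h, dlogits)
  g$outb <- dlogits
  dh <- drop(params$outW %*% dlogits)
  for (l in rev(seq_along(spec$dense))) {
    cc <- caches[[paste0("dense", l)]]
    if (!is.null(dmasks)) dh <- dh * dmasks[[l]]
    dZ <- dh * (cc$Z > 0)
    g[[paste0("denseW", l)]] <- outer(cc$h, dZ)
    g[[paste0("denseb", l)]] <- dZ
    dh <- drop(params[[paste0("denseW", l)]] %*% dZ)
  }
  od <- caches$conv_out_dim
  dA <- matrix(dh, od[1], od[2], byrow = TRUE)
  for (l in rev(seq_along(spec$filters))) {
    cc <- caches[[l]]
    Lp <- nrow(dA)
    dR <- matrix(0, cc$Lr, ncol(dA))
    sel <- cc$odd_sel[seq_len(Lp), , drop = FALSE]
    dR[2 * seq_len(Lp) - 1, ] <- dA * sel
    dR[2 * seq_len(Lp), ] <- dR[2 * seq_len(Lp), ] + dA * !sel
    dZ <- dR[seq_len(nrow(cc$Z)), , drop = FALSE] * (cc$Z > 0)
    g[[paste0("convW", l)]] <- crossprod(cc$Xcol, dZ)
    g[[paste0("convb", l)]] <- colSums(dZ)
    if (l > 1) {
      dXcol <- dZ %*% t(params[[paste0("convW", l)]])
      C <- ncol(dXcol) / 3L
      Lout <- nrow(dXcol)
      dX <- matrix(0, Lout + 2L, C)
      dX[1:Lout, ] <- dXcol[, 1:C, drop = FALSE]
      dX[2:(Lout + 1), ] <- dX[2:(Lout + 1), ] + dXcol[, C + 1:C, drop = FALSE]
      dX[3:(Lout + 2), ] <- dX[3:(Lout + 2), ] + dXcol[, 2 * C + 1:C, drop = FALSE]
      dA <- dX
    }
  }
  g
}

#' Train the CNN baseline
#'
#' Minimizes categorical cross-entropy with AdaMax over encoded inputs
#' (see [encode_input()]).
#'
#' @param model an `aa_cnn` from [build_cnn()].
#' @param inputs list of `max_len x 46` input matrices.
#' @param y integer class labels (1-based).
#' @param epochs training epochs.
#' @param batch_size minibatch size (gradients averaged over the batch).
#' @param lr AdaMax learning rate.
#' @param valid optional list(inputs, y) evaluated per epoch.
#' @param seed seed for minibatch order and dropout.
#' @param verbose print progress.
#' @return `model` updated in place; `model$history` holds per-epoch loss
#'   and validation accuracy.
#' @export
train_cnn <- function(model, inputs, y, epochs = 5, batch_size = 16,
                      lr = 2e-3, valid = NULL, seed = 1L, verbose = FALSE) {
  sp <- model$spec
  opt <- adamax_state()
  history <- data.frame()
  with_seed(derive_seed(seed, "train_cnn"), {
    for (ep in seq_len(epochs)) {
      ord <- sample(length(inputs))
      ep_loss <- 0
      for (bidx in split(ord, ceiling(seq_along(ord) / batch_size))) {
        acc <- NULL
        bloss <- 0
        for (i in bidx) {
          dmasks <- if (sp$dropout > 0)
            lapply(sp$dense, function(w)
              (stats::runif(w) >= sp$dropout) / (1 - sp$dropout)) else NULL
          fwd <- cnn_forward_one(model$params, sp, inputs[[i]], dmasks,
                                 compute_grads = TRUE)
          lg <- xent_loss_grad(matrix(fwd$logits, 1), y[i])
          if (!is.finite(lg$loss)) stop("non-finite CNN training loss")
          bloss <- bloss + lg$loss
          g <- cnn_backward_one(model$params, sp, fwd, drop(lg$dlogits), dmasks)
          if (is.null(acc)) acc <- g
          else for (nm in names(g)) acc[[nm]] <- acc[[nm]] + g[[nm]]
        }
        for (nm in names(acc)) acc[[nm]] <- acc[[nm]] / length(bidx)
        model$params <- adamax_step(model$params, acc, opt, lr = lr)
        ep_loss <- ep_loss + bloss
      }
      row <- data.frame(epoch = ep, train_loss = ep_loss / length(inputs),
                        valid_accuracy = NA_real_)
      if (!is.null(valid)) {
        pv <- predict_cnn(model, valid$inputs)
        row$valid_accuracy <- mean(max.col(pv, ties.method = "first") == valid$y)
      }
      history <- rbind(history, row)
      if (verbose) message(sprintf("epoch %d: loss %.4f", ep, row$train_loss))
    }
  })
  model$history <- history
  invisible(model)
}

#' Predict class probabilities with the CNN baseline
#'
#' @param model an `aa_cnn`.
#' @param inputs list of encoded input matrices.
#' @return probability matrix (rows sum to 1).
#' @export
predict_cnn <- function(model, inputs) {
  t(vapply(inputs, function(X) {
    lg <- cnn_forward_one(model$params, model$spec, X)$logits
    drop(softmax_rows(matrix(lg, 1)))
  }, numeric(model$spec$n_outputs)))
}
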