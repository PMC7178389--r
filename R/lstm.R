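# LSTM layer with hand-written backward pass.
#
# A layer's parameters are W (input x 4*hidden), U (hidden x 4*hidden) and
# b (4*hidden), with gate columns ordered i | f | g | o. Weight dropout
# (DropConnect) is realized as an elementwise mask on U, drawn once per
# forward pass and shared across timesteps.

init_lstm_layer <- function(d_in, d_hidden) {
  k <- 1 / sqrt(d_hidden)
  b <- rep(0, 4 * d_hidden)
  b[d_hidden + seq_len(d_hidden)] <- 1   # forget-gate bias at 1 (standard)
  list(W = init_uniform(d_in, 4 * d_hidden, k),
       U = init_uniform(d_hidden, 4 * d_hidden, k),
       b = b)
}

# X: list of T matrices (B x d_in); h0, c0: B x h. Returns hidden states
# for all timesteps plus the cache needed for backward. umask is the
# DropConnect mask on U (NULL when weight dropout is off).
lstm_forward <- function(X, W, U, b, h0, c0, umask = NULL,
                         keep_cache = TRUE) {
  Tn <- length(X)
  h <- ncol(U) / 4L
  Ueff <- apply_mask(U, umask)
  ii <- seq_len(h); fi <- h + ii; gi <- 2L * h + ii; oi <- 3L * h + ii
  H <- vector("list", Tn)
  cache <- if (keep_cache)
    list(i = vector("list", Tn), f = vector("list", Tn),
         g = vector("list", Tn), o = vector("list", Tn),
         tc = vector("list", Tn), cprev = vector("list", Tn),
         hprev = vector("list", Tn), X = X, umask = umask) else NULL
  ht <- h0; ct <- c0
  bmat <- matrix(b, nrow(h0), 4L * h, byrow = TRUE)
  for (t in seq_len(Tn)) {
    A <- X[[t]] %*% W + ht %*% Ueff + bmat
    i_g <- sigmoid(A[, ii, drop = FALSE])
    f_g <- sigmoid(A[, fi, drop = FALSE])
    g_g <- tanh(A[, gi, drop = FALSE])
    o_g <- sigmoid(A[, oi, drop = FALSE])
    cnew <- f_g * ct + i_g * g_g
    tc <- tanh(cnew)
    hnew <- o_g * tc
    if (keep_cache) {
      cache$i[[t]] <- i_g; cache$f[[t]] <- f_g; cache$g[[t]] <- g_g
      cache$o[[t]] <- o_g; cache$tc[[t]] <- tc
      cache$cprev[[t]] <- ct; cache$hprev[[t]] <- ht
    }
    ht <- hnew; ct <- cnew
    H[[t]] <- hnew
  }
  list(H = H, h = ht, c = ct, cache = cache)
}

# dH: list of T matrices (B x h) of loss gradients w.r.t. each hidden
# state (zero matrices where unused); dh_last/dc_last: gradients flowing
# into the final state from outside the window. Returns parameter
# gradients, input gradients and the gradients w.r.t. the initial state.
lstm_backward <- function(W, U, cache, dH, dh_last = NULL, dc_last = NULL) {
  Tn <- length(cache$i)
  h <- ncol(U) / 4L
  B <- nrow(cache$i[[1]])
  Ueff <- apply_mask(U, cache$umask)
  dW <- W * 0; dU <- U * 0; db <- rep(0, 4L * h)
  dX <- vector("list", Tn)
  dh <- if (is.null(dh_last)) matrix(0, B, h) else dh_last
  dc <- if (is.null(dc_last)) matrix(0, B, h) else dc_last
  for (t in rev(seq_len(Tn))) {
    dht <- dh + dH[[t]]
    o_g <- cache$o[[t]]; tc <- cache$tc[[t]]
    i_g <- cache$i[[t]]; f_g <- cache$f[[t]]; g_g <- cache$g[[t]]
    dct <- dc + dht * o_g * (1 - tc * tc)
    do_ <- dht * tc * o_g * (1 - o_g)
    di <- dct * g_g * i_g * (1 - i_g)
    df <- dct * cache$cprev[[t]] * f_g * (1 - f_g)
    dg <- dct * i_g * (1 - g_g * g_g)
    dA <- cbind(di, df, dg, do_)
    dW <- dW + crossprod(cache$X[[t]], dA)
    dU <- dU + crossprod(cache$hprev[[t]], dA)
    db <- db + colSums(dA)
    dX[[t]] <- dA %*% t(W)
    dh <- dA %*% t(Ueff)
    dc <- dct * f_g
  }
  if (!is.null(cache$umask)) dU <- dU * cache$umask
  list(dW = dW, dU = dU, db = db, dX = dX, dh0 = dh, dc0 = dc)
}
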