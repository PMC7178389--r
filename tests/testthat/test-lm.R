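tiny_lm_cfg <- function(...) {
  lm_config(embedding_dim = 8, hidden_dim = 12, batch_size = 2,
            bptt_mean = 10, seed = 21, ...)
}

test_that("forward pass is deterministic with dropout off and outputs normalized distributions", {
  v <- aa_vocabulary()
  m <- build_lm(tiny_lm_cfg(), v)
  xb <- matrix(sample(3:28, 12, TRUE), 6, 2)
  a <- protlm:::lm_window_pass(m, xb, return_probs = TRUE)
  b <- protlm:::lm_window_pass(m, xb, return_probs = TRUE)
  expect_identical(a$log_probs, b$log_probs)
  expect_equal(rowSums(exp(a$log_probs)), rep(1, nrow(a$log_probs)),
               tolerance = 1e-6)
})

test_that("vocabulary of fewer than 2 tokens is rejected", {
  fake <- list(size = 1)
  expect_error(build_lm(tiny_lm_cfg(), fake), "at least 2")
})

test_that("weight tying keeps decoder and embedding shared through optimization", {
  v <- aa_vocabulary()
  m <- build_lm(tiny_lm_cfg(tie_weights = TRUE), v)
  expect_null(m$params$D)          # no separate decoder weight exists
  seqs <- replicate(6, paste(sample(v$residues, 20, TRUE), collapse = ""))
  st <- make_bptt_stream(lapply(seqs, tokenize, vocab = v), 2, 10, seed = 1)
  E_before <- m$params$E
  train_lm(m, st, epochs = 1)
  expect_false(identical(E_before, m$params$E))  # embedding trained
  # untied model carries (and trains) its own decoder matrix
  m2 <- build_lm(tiny_lm_cfg(tie_weights = FALSE), v)
  expect_false(is.null(m2$params$D))
})

test_that("BPTT stream windows have ~bptt_mean length and are reproducible", {
  v <- aa_vocabulary()
  long_seq <- list(c(2L, sample(3:28, 800000, TRUE)))
  st <- make_bptt_stream(long_seq, batch_size = 1, bptt_mean = 70, seed = 5)
  lens <- vapply(st$windows, function(w) nrow(w$input), numeric(1))
  expect_gt(length(lens), 10000)
  expect_lt(abs(mean(lens) - 70), 3)
  expect_true(all(lens >= 1 & lens <= 140))
  st2 <- make_bptt_stream(long_seq, batch_size = 1, bptt_mean = 70, seed = 5)
  expect_identical(st$windows[[1]]$input, st2$windows[[1]]$input)
  expect_identical(lens, vapply(st2$windows, function(w) nrow(w$input),
                                numeric(1)))
})

test_that("window targets tile each stream: every token except the first appears once", {
  v <- aa_vocabulary()
  toks <- lapply(1:4, function(i)
    tokenize(paste(sample(v$residues, 25, TRUE), collapse = ""), v))
  st <- make_bptt_stream(toks, batch_size = 2, bptt_mean = 8, seed = 3)
  n_per <- st$n_tokens %/% 2
  # reconstruct the streams from the windows themselves
  for (b in 1:2) {
    inputs <- unlist(lapply(st$windows, function(w) w$input[, b]))
    targets <- unlist(lapply(st$windows, function(w) w$target[, b]))
    expect_identical(targets[-length(targets)], inputs[-1])
    expect_length(targets, n_per - 1L)   # all tokens except the stream's first
  }
  expect_error(make_bptt_stream(list(c(2L, 5L)), batch_size = 4, seed = 1),
               "too small")
})

test_that("initial loss is close to log(vocab size) and training is deterministic", {
  v <- aa_vocabulary()
  seqs <- replicate(8, paste(sample(v$residues, 30, TRUE), collapse = ""))
  st <- make_bptt_stream(lapply(seqs, tokenize, vocab = v), 2, 10, seed = 2)
  m <- build_lm(tiny_lm_cfg(), v)
  first <- protlm:::lm_window_pass(m, st$windows[[1]]$input,
                                   st$windows[[1]]$target)
  expect_lt(abs(first$loss - log(v$size)) / log(v$size), 0.1)
  m1 <- build_lm(tiny_lm_cfg(), v); train_lm(m1, st, epochs = 3, seed = 9)
  m2 <- build_lm(tiny_lm_cfg(), v); train_lm(m2, st, epochs = 3, seed = 9)
  expect_identical(m1$history$train_loss, m2$history$train_loss)
})

test_that("a fully predictable corpus is learned to high next-token accuracy", {
  v <- aa_vocabulary()
  seqs <- rep(paste(rep("ACDE", 25), collapse = ""), 16)
  st <- make_bptt_stream(lapply(seqs, tokenize, vocab = v), 2, 20, seed = 1)
  cfg <- lm_config(embedding_dim = 12, hidden_dim = 16, batch_size = 2,
                   bptt_mean = 20, lr = 3e-2, seed = 1)
  m <- build_lm(cfg, v)
  train_lm(m, st, epochs = 20)
  ev <- evaluate_lm(m, st)
  expect_gt(ev$next_token_accuracy, 0.95)
  expect_lt(ev$perplexity, 1.5)
  expect_true(all(diff(m$history$train_loss[c(1, 10, 20)]) < 0))
})

test_that("zero-weight model scores uniform: perplexity equals vocabulary size", {
  v <- aa_vocabulary()
  m <- build_lm(tiny_lm_cfg(), v)
  for (nm in names(m$params)) m$params[[nm]] <- m$params[[nm]] * 0
  seqs <- replicate(6, paste(sample(v$residues, 20, TRUE), collapse = ""))
  st <- make_bptt_stream(lapply(seqs, tokenize, vocab = v), 2, 10, seed = 4)
  ev <- evaluate_lm(m, st)
  expect_equal(ev$perplexity, v$size, tolerance = 1e-9)
})

test_that("reported perplexity equals an independently accumulated NLL", {
  v <- aa_vocabulary()
  m <- build_lm(tiny_lm_cfg(), v)
  seqs <- replicate(6, paste(sample(v$residues, 20, TRUE), collapse = ""))
  st <- make_bptt_stream(lapply(seqs, tokenize, vocab = v), 2, 10, seed = 8)
  ev <- evaluate_lm(m, st)
  # second pass: accumulate NLL directly from the emitted log-probabilities
  nll <- 0; n <- 0; state <- NULL
  for (w in st$windows) {
    res <- protlm:::lm_window_pass(m, w$input, state = state,
                                   return_probs = TRUE)
    y <- as.integer(t(w$target))
    nll <- nll - sum(res$log_probs[cbind(seq_along(y), y)])
    n <- n + length(y)
    state <- res$state
  }
  expect_equal(ev$perplexity, exp(nll / n), tolerance = 1e-6)
})

test_that("dropout masks perturb training but keep the pass finite", {
  v <- aa_vocabulary()
  cfg <- tiny_lm_cfg(dropout = list(embedding = 0.1, input = 0.1,
                                    weight = 0.2, hidden = 0.1,
                                    output = 0.1))
  m <- build_lm(cfg, v)
  xb <- matrix(sample(3:28, 20, TRUE), 10, 2)
  yb <- matrix(sample(3:28, 20, TRUE), 10, 2)
  set.seed(1)
  r <- protlm:::lm_window_pass(m, xb, yb, train = TRUE, compute_grads = TRUE)
  expect_true(is.finite(r$loss))
  expect_true(all(vapply(r$grads, function(g) all(is.finite(g)), logical(1))))
})

test_that("model checkpoints round-trip through save_model/load_model", {
  v <- aa_vocabulary()
  m <- build_lm(tiny_lm_cfg(), v)
  path <- withr::local_tempfile(fileext = ".rds")
  save_model(m, path)
  expect_true(file.exists(paste0(path, ".json")))
  back <- load_model(path)
  expect_identical(back$params, m$params)
  expect_s3_class(back, "aa_lm")
})
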