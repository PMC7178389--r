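tiny_clf_setup <- function(n_outputs = 3, seed = 31, ...) {
  lm <- build_lm(lm_config(embedding_dim = 8, hidden_dim = 12, seed = 31),
                 aa_vocabulary())
  cfg <- classifier_config(n_outputs = n_outputs, head_hidden = 10,
                           seed = seed, ...)
  list(lm = lm, cfg = cfg, clf = build_classifier(lm, cfg))
}

test_that("classifier encoder is initialized from the language-model weights", {
  s <- tiny_clf_setup()
  for (nm in c("E", "W1", "U1", "b1", "W2", "U2", "b2", "W3", "U3", "b3"))
    expect_identical(s$clf$params[[nm]], s$lm$params[[nm]])
  # head is fresh: not present in the LM at all
  expect_false(is.null(s$clf$params$Wh))
  expect_false(is.null(s$clf$params$Wo))
})

test_that("from-scratch mode is reproducible and independent of the LM weights", {
  s <- tiny_clf_setup(seed = 55)                # config seed differs from LM seed
  lm2 <- build_lm(lm_config(embedding_dim = 8, hidden_dim = 12, seed = 99),
                  aa_vocabulary())
  a <- build_classifier(s$lm, s$cfg, from_scratch = TRUE)
  b <- build_classifier(lm2, s$cfg, from_scratch = TRUE)
  expect_identical(a$params, b$params)          # same config seed, same init
  expect_false(identical(a$params$E, s$lm$params$E))
})

test_that("a Level-1 enzyme-class configuration has six output units", {
  s <- tiny_clf_setup(n_outputs = 6)
  expect_length(s$clf$params$bo, 6)
  expect_identical(ncol(s$clf$params$Wo), 6L)
})

test_that("concat pooling concatenates last, max and mean states", {
  h <- c(1, -2, 3)
  H <- matrix(h, 4, 3, byrow = TRUE)
  expect_equal(concat_pool(H), c(h, h, h))       # constant case
  H1 <- matrix(c(5, 6), 1, 2)
  expect_equal(concat_pool(H1), c(5, 6, 5, 6, 5, 6))  # T = 1 degenerate
  set.seed(41)
  Hr <- matrix(rnorm(15), 5, 3)
  expect_equal(concat_pool(Hr),
               c(Hr[5, ], apply(Hr, 2, max), colMeans(Hr)))
  expect_error(concat_pool(matrix(numeric(0), 0, 3)), "nrow")
})

test_that("batched pooled forward matches concat_pool on each unpadded sequence", {
  s <- tiny_clf_setup()
  seqs <- c("MSLRACD", "WYV", "ACDEFGHIK")
  eb <- protlm:::encode_batch(seqs, s$clf$vocab, "forward")
  res <- protlm:::clf_batch_pass(s$clf, eb$ids, eb$lengths)
  for (b in seq_along(seqs)) {
    one <- protlm:::encode_batch(seqs[b], s$clf$vocab, "forward")
    single <- protlm:::clf_batch_pass(s$clf, one$ids, one$lengths)
    expect_equal(res$probs[b, ], single$probs[1, ], tolerance = 1e-10)
  }
})

test_that("frozen layer groups receive zero gradient, trainable groups do not", {
  s <- tiny_clf_setup()
  eb <- protlm:::encode_batch(c("MSLR", "ACDEF"), s$clf$vocab, "forward")
  res <- protlm:::classifier_gradients(s$clf, eb$ids, eb$lengths,
                                       c(1L, 2L), trainable_groups = 4L)
  groups <- vapply(names(res$grads), protlm:::param_group, integer(1))
  for (nm in names(res$grads)) {
    if (groups[nm] == 4L) expect_gt(max(abs(res$grads[[nm]])), 0)
    else expect_true(all(res$grads[[nm]] == 0))
  }
  # stage 3: groups 2,3,4 trainable, embedding still frozen
  res2 <- protlm:::classifier_gradients(s$clf, eb$ids, eb$lengths,
                                        c(1L, 2L), trainable_groups = 2:4)
  expect_true(all(res2$grads$E == 0))
  expect_gt(max(abs(res2$grads$W1)), 0)
})

test_that("discriminative learning rates halve per group toward the input", {
  sched <- unfreeze_schedule(0.008)
  expect_equal(unname(sched$group_lrs),
               c(0.001, 0.002, 0.004, 0.008))   # input -> output group
  expect_length(sched$stages, 4)
  expect_identical(sched$stages[[1]]$trainable_groups, 4L)
  expect_identical(sched$stages[[4]]$trainable_groups, 1:4)
  expect_equal(sched$stages[[4]]$epochs, 30)    # default final stage length
})

test_that("one-cycle schedule rises then falls with its maximum at the peak", {
  total <- 300
  lr <- one_cycle_lr(1:total, total, max_lr = 0.01)
  peak <- which.max(lr)
  expect_equal(max(lr), 0.01, tolerance = 1e-12)
  expect_true(all(diff(lr[1:peak]) >= 0))
  expect_true(all(diff(lr[peak:total]) <= 0))
  expect_lt(lr[1], 0.01 / 2)
  expect_lt(lr[total], lr[1])
})

test_that("categorical predictions are normalized, deterministic and order-equivariant", {
  s <- tiny_clf_setup()
  seqs <- c("MSLRACD", "WYV", "ACDEFGHIK", "MMMM")
  p1 <- predict_proba(s$clf, seqs)
  expect_equal(rowSums(p1), rep(1, 4), tolerance = 1e-6)
  expect_identical(p1, predict_proba(s$clf, seqs))
  perm <- c(3, 1, 4, 2)
  p2 <- predict_proba(s$clf, seqs[perm])
  expect_equal(p2[, ], p1[perm, ], tolerance = 1e-12)
})

test_that("sequences with unknown residues get an error entry, batch continues", {
  s <- tiny_clf_setup()
  p <- predict_proba(s$clf, c("MSLR", "MS1R", "ACDE"))
  expect_true(all(is.na(p[2, ])))
  expect_false(anyNA(p[c(1, 3), ]))
  expect_match(attr(p, "errors")[["2"]], "position 3")
})

test_that("forward/backward ensembling is the elementwise mean", {
  f <- matrix(c(0.2, 0.8), 1)
  b <- matrix(c(0.4, 0.6), 1)
  expect_equal(ensemble_proba(f, b), matrix(c(0.3, 0.7), 1))
  expect_equal(ensemble_proba(f, f), f)              # idempotent
  expect_equal(rowSums(ensemble_proba(f, b)), 1)     # convexity
  expect_error(ensemble_proba(f, matrix(0.5, 1, 3)), "equal shape")
})

test_that("fine-tuning improves a separable toy task and records best epoch", {
  v <- aa_vocabulary()
  lm <- build_lm(lm_config(embedding_dim = 8, hidden_dim = 12, seed = 43), v)
  cfg <- classifier_config(n_outputs = 2, head_hidden = 8, batch_size = 8,
                           base_lr = 2e-2, seed = 43)
  clf <- build_classifier(lm, cfg, from_scratch = TRUE)
  set.seed(6)
  mk <- function(n, cls) {
    vapply(seq_len(n), function(i) {
      base <- sample(v$standard, 12, TRUE)
      if (cls == 1) base[4:6] <- c("W", "W", "W") else base[4:6] <- c("D", "D", "D")
      paste(base, collapse = "")
    }, character(1))
  }
  tr <- list(sequences = c(mk(24, 1), mk(24, 2)), y = rep(1:2, each = 24))
  va <- list(sequences = c(mk(6, 1), mk(6, 2)), y = rep(1:2, each = 6))
  sched <- unfreeze_schedule(cfg$base_lr, stage_epochs = 1, epochs_final = 12)
  finetune(clf, tr, va, schedule = sched, seed = 43)
  expect_false(is.null(clf$best))
  expect_equal(clf$best$metric, max(clf$history$valid_metric))
  # ties toward the earliest epoch: no strictly earlier epoch has the max
  first_hit <- which(clf$history$valid_metric == clf$best$metric)[1]
  expect_equal(clf$history$stage[first_hit], clf$best$stage)
  expect_equal(clf$history$epoch[first_hit], clf$best$epoch)
  p <- predict_proba(clf, va$sequences)
  expect_gt(mean(max.col(p, ties.method = "first") == va$y), 0.8)
  expect_error(finetune(clf, tr, list(sequences = character(0), y = integer(0)),
                        schedule = sched), "non-empty")
})

test_that("long sequences are encoded in full with gradients truncated at max_context", {
  lm <- build_lm(lm_config(embedding_dim = 6, hidden_dim = 8, seed = 47),
                 aa_vocabulary())
  cfg_short <- classifier_config(n_outputs = 2, head_hidden = 6,
                                 max_context = 10, seed = 47)
  clf <- build_classifier(lm, cfg_short)
  long_seq <- paste(rep("ACDEFGHIKL", 4), collapse = "")   # 40 residues
  eb <- protlm:::encode_batch(long_seq, clf$vocab, "forward")
  res <- protlm:::clf_batch_pass(clf, eb$ids, eb$lengths, y = 1L,
                                 compute_grads = TRUE)
  # same forward probabilities as an unlimited-context classifier
  cfg_full <- classifier_config(n_outputs = 2, head_hidden = 6,
                                max_context = 1024, seed = 47)
  clf_full <- build_classifier(lm, cfg_full)
  res_full <- protlm:::clf_batch_pass(clf_full, eb$ids, eb$lengths, y = 1L,
                                      compute_grads = TRUE)
  expect_equal(res$probs, res_full$probs, tolerance = 1e-12)
  # truncated gradients differ from full-context gradients but are finite
  expect_true(all(is.finite(res$grads$W1)))
  expect_false(isTRUE(all.equal(res$grads$W1, res_full$grads$W1)))
})
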