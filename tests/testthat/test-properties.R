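# Directional properties of the protocols, tested at small scale:
# split-construction effects on language-model evaluation, redundancy in
# classifier training, forward/backward ensembling, and PSSM leakage.

test_that("random-split LM evaluation is easier than cluster-split evaluation", {
  # near-duplicate cluster members span train/test under a random split, so
  # held-out perplexity drops; cluster-aware splits remove that shortcut
  ppl <- matrix(NA_real_, 3, 2, dimnames = list(NULL, c("random", "cluster")))
  for (s in 1:3) {
    cc <- synth_config(n_families = 2, clusters_per_family = 20,
                       members_per_cluster = 4, length_range = c(30, 40),
                       mutation_rate = 0.05, background_model = "markov",
                       seed = 40 + s)
    corpus <- generate_corpus(cc)
    seq_of <- stats::setNames(corpus$records$sequence, corpus$records$id)
    for (mode in c("random", "cluster")) {
      sp <- make_split(corpus$clusters, c(0.8, 0.1, 0.1), mode, seed = s)
      lm <- pretrain_lm(unname(seq_of[sp$train]), epochs = 15,
                        config = lm_config(batch_size = 8, seed = s),
                        seed = s)
      toks <- lapply(unname(seq_of[sp$test]), tokenize, vocab = lm$vocab)
      stream <- make_bptt_stream(toks, batch_size = 4, bptt_mean = 70,
                                 seed = s)
      ppl[s, mode] <- evaluate_lm(lm, stream)$perplexity
    }
  }
  expect_lt(mean(ppl[, "random"]), mean(ppl[, "cluster"]))
})

test_that("training on all cluster members beats representatives only", {
  cc <- synth_config(n_families = 2, motifs = c("WWHKW", "DEDCY"),
                     clusters_per_family = 25, members_per_cluster = 4,
                     length_range = c(30, 40), mutation_rate = 0.1,
                     background_model = "markov", seed = 51)
  corpus <- generate_corpus(cc)
  sp <- make_split(corpus$clusters, c(0.7, 0.1, 0.2), "cluster", seed = 5)
  seq_of <- stats::setNames(corpus$records$sequence, corpus$records$id)
  fam_of <- stats::setNames(corpus$records$family, corpus$records$id)
  lm <- build_lm(lm_config(seed = 51), aa_vocabulary())
  accs <- c()
  for (mode in c("all_members", "representatives_only")) {
    parts <- expand_members(sp, corpus$clusters, mode)
    cfg <- classifier_config(n_outputs = 2, head_hidden = 32,
                             epochs_final = 10, base_lr = 2e-2,
                             batch_size = 16, head_dropout = 0.2, seed = 51)
    clf <- build_classifier(lm, cfg, from_scratch = TRUE)
    finetune(clf,
             list(sequences = unname(seq_of[parts$train]),
                  y = unname(fam_of[parts$train])),
             list(sequences = unname(seq_of[parts$valid]),
                  y = unname(fam_of[parts$valid])),
             schedule = unfreeze_schedule(2e-2, stage_epochs = 1,
                                          epochs_final = 10),
             seed = 51)
    p <- predict_proba(clf, unname(seq_of[parts$test]))
    accs[mode] <- mean(max.col(p, ties.method = "first") ==
                         unname(fam_of[parts$test]))
  }
  expect_gte(accs[["all_members"]], accs[["representatives_only"]])
})

test_that("the forward/backward ensemble is at least as accurate as its weaker member", {
  fx <- get_motif_fixture()
  parts <- fx$parts
  cfg_b <- classifier_config(n_outputs = 2, head_hidden = 32,
                             epochs_final = 8, base_lr = 2e-2,
                             batch_size = 16, direction = "backward",
                             seed = 7)
  clf_b <- build_classifier(fx$lm, cfg_b, from_scratch = TRUE)
  finetune(clf_b,
           list(sequences = unname(fx$seq_of[parts$train]),
                y = unname(fx$fam_of[parts$train])),
           list(sequences = unname(fx$seq_of[parts$valid]),
                y = unname(fx$fam_of[parts$valid])),
           schedule = unfreeze_schedule(2e-2, stage_epochs = 1,
                                        epochs_final = 8),
           seed = 7)
  te <- unname(fx$seq_of[parts$test]); y <- unname(fx$fam_of[parts$test])
  p_f <- predict_proba(fx$clf, te)
  p_b <- predict_proba(clf_b, te)
  acc <- function(p) mean(max.col(p[, , drop = FALSE],
                                  ties.method = "first") == y)
  acc_e <- acc(ensemble_proba(p_f[, ], p_b[, ]))
  expect_gte(acc_e, min(acc(p_f), acc(p_b)))
})

test_that("leaky PSSM profiles do not hurt, and profile features help the CNN", {
  # within-cluster alignment profiles: clean mode sees only the training
  # clusters, so a held-out sequence gets a self-profile; leaky mode aligns
  # it with its own cluster members (test information leaks into features)
  cc <- synth_config(n_families = 2, motifs = c("WWHKW", "DEDCY"),
                     clusters_per_family = 25, members_per_cluster = 3,
                     length_range = c(60, 80), mutation_rate = 0.15,
                     seed = 61)
  corpus <- generate_corpus(cc)
  sp <- make_split(corpus$clusters, c(0.7, 0.0, 0.3), "cluster", seed = 6)
  rec <- corpus$records
  fam_of <- stats::setNames(rec$family, rec$id)
  cl_of <- corpus$clusters$member_of
  profile_for <- function(id, leaky) {
    own <- names(cl_of)[cl_of == cl_of[[id]]]
    in_db <- if (leaky) own else intersect(own, sp$train)
    if (!length(in_db)) in_db <- id          # self-profile fallback
    seqs <- rec$sequence[rec$id %in% unique(c(id, in_db))]
    L <- nchar(rec$sequence[rec$id == id])
    seqs <- seqs[nchar(seqs) == L]           # cluster members share length
    pssm_from_alignment(seqs)
  }
  enc <- function(ids, mode) lapply(ids, function(id)
    encode_input(rec$sequence[rec$id == id],
                 pssm = if (mode == "seq") NULL else
                   profile_for(id, leaky = mode == "leaky"),
                 max_len = 384))
  spec <- cnn_spec(n_outputs = 2, width_scale = 1 / 16, max_len = 384)
  accs <- c()
  for (mode in c("seq", "clean", "leaky")) {
    model <- build_cnn(spec, seed = 61)
    train_cnn(model, enc(sp$train, mode), unname(fam_of[sp$train]),
              epochs = 12, batch_size = 8, lr = 5e-3, seed = 61)
    p <- predict_cnn(model, enc(sp$test, mode))
    accs[mode] <- mean(max.col(p, ties.method = "first") ==
                         unname(fam_of[sp$test]))
  }
  expect_gte(accs[["leaky"]], accs[["clean"]] - 0.05)  # leakage helps or ties
  expect_gte(accs[["leaky"]], accs[["seq"]] - 0.05)    # profiles carry signal
})
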