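# Desk-scale end-to-end pipeline: synthetic corpus -> language-model
# pre-training -> fine-tuning (pre-trained vs from-scratch) -> evaluation.
# These are the study conditions the package's benchmark tests and the
# acceptance script run; sizes are chosen to exercise every stage on a
# single CPU in minutes.

#' Default study conditions for the synthetic transfer benchmark
#'
#' Six motif families, 25 clusters per family, 4 members per cluster
#' (600 sequences of length 40-60), 10% per-residue substitution rate,
#' first-order Markov background (so next-token prediction has learnable
#' structure, as in real protein sequences).
#'
#' @param seed integer seed.
#' @return a [synth_config()].
#' @export
benchmark_corpus_config <- function(seed) {
  synth_config(n_families = 6, length_range = c(40, 60),
               clusters_per_family = 25, members_per_cluster = 4,
               mutation_rate = 0.1, background_model = "markov",
               seed = seed)
}

#' Pre-train a language model on a set of sequences
#'
#' @param sequences character vector of residue strings.
#' @param direction `"forward"` or `"backward"`.
#' @param epochs training epochs.
#' @param config optional [lm_config()] (tiny test profile by default:
#'   embedding 32, hidden 64).
#' @param valid_sequences optional held-out sequences for per-epoch
#'   evaluation.
#' @param seed integer seed.
#' @return trained `aa_lm`.
#' @export
pretrain_lm <- function(sequences, direction = "forward", epochs = 6,
                        config = NULL, valid_sequences = NULL, seed = 1L) {
  vocab <- aa_vocabulary()
  if (is.null(config)) config <- lm_config(seed = seed)
  toks <- lapply(sequences, tokenize, vocab = vocab, direction = direction)
  stream <- make_bptt_stream(toks, config$batch_size, config$bptt_mean,
                             seed = derive_seed(seed, "stream"))
  vstream <- NULL
  if (!is.null(valid_sequences)) {
    vtoks <- lapply(valid_sequences, tokenize, vocab = vocab,
                    direction = direction)
    vstream <- make_bptt_stream(vtoks, min(config$batch_size, length(vtoks)),
                                config$bptt_mean,
                                seed = derive_seed(seed, "vstream"))
  }
  model <- build_lm(config, vocab)
  model$direction <- direction
  train_lm(model, stream, epochs = epochs, valid_stream = vstream, seed = seed)
  model
}

#' Run the synthetic transfer-learning benchmark for one seed
#'
#' Generates the motif-family corpus, makes a cluster-mode 70:10:20 split,
#' pre-trains a tiny language model on the train+validation sequences,
#' fine-tunes (a) a pre-trained and (b) an identically budgeted
#' from-scratch classifier on at most `n_train` training sequences, and
#' returns their test accuracies on cluster-held-out representatives.
#'
#' @param seed integer seed for this replicate.
#' @param n_train maximum number of labeled training sequences (200).
#' @param lm_epochs pre-training epochs.
#' @param epochs_final final fine-tuning stage epochs (shared by both
#'   models).
#' @param direction token direction.
#' @param include_scratch also train the from-scratch comparison model
#'   (default `TRUE`).
#' @param corpus_config optional [synth_config()] override.
#' @return list with `acc_pretrained`, `acc_scratch`, `lm`, `clf`,
#'   `clf_scratch`, `test` (data.frame of test sequences and labels),
#'   `probs_pretrained`.
#' @export
run_transfer_benchmark <- function(seed, n_train = 200, lm_epochs = 30,
                                   epochs_final = 30, direction = "forward",
                                   include_scratch = TRUE,
                                   corpus_config = NULL) {
  cc <- corpus_config %||% benchmark_corpus_config(seed = derive_seed(seed, "corpus"))
  corpus <- generate_corpus(cc)
  rec <- corpus$records
  split <- make_split(corpus$clusters, c(0.7, 0.1, 0.2), mode = "cluster",
                      seed = derive_seed(seed, "split"))
  parts <- expand_members(split, corpus$clusters, "all_members")

  fam_of <- stats::setNames(rec$family, rec$id)
  seq_of <- stats::setNames(rec$sequence, rec$id)

  # unlabeled pre-training corpus: train + validation sequences only
  lm <- pretrain_lm(unname(seq_of[c(parts$train, parts$valid)]),
                    direction = direction, epochs = lm_epochs,
                    seed = derive_seed(seed, "lm"))

  train_ids <- parts$train
  if (length(train_ids) > n_train)
    train_ids <- with_seed(derive_seed(seed, "sub"),
                           sample(train_ids, n_train))
  tr <- list(sequences = unname(seq_of[train_ids]),
             y = unname(fam_of[train_ids]))
  va <- list(sequences = unname(seq_of[parts$valid]),
             y = unname(fam_of[parts$valid]))
  te <- list(sequences = unname(seq_of[parts$test]),
             y = unname(fam_of[parts$test]))

  cfg <- classifier_config(n_outputs = cc$n_families, head_hidden = 64,
                           epochs_final = epochs_final, base_lr = 2e-2,
                           batch_size = 16, head_dropout = 0.2,
                           direction = direction,
                           seed = derive_seed(seed, "clf"))
  sched <- unfreeze_schedule(cfg$base_lr, stage_epochs = 2,
                             epochs_final = epochs_final)

  clf <- build_classifier(lm, cfg)
  finetune(clf, tr, va, schedule = sched, seed = derive_seed(seed, "ft"))
  p_pre <- predict_proba(clf, te$sequences)
  acc_pre <- mean(max.col(p_pre, ties.method = "first") == te$y)

  clf_s <- NULL; acc_scr <- NA_real_
  if (include_scratch) {
    clf_s <- build_classifier(lm, cfg, from_scratch = TRUE)
    finetune(clf_s, tr, va, schedule = sched, seed = derive_seed(seed, "ft"))
    p_scr <- predict_proba(clf_s, te$sequences)
    acc_scr <- mean(max.col(p_scr, ties.method = "first") == te$y)
  }

  list(acc_pretrained = acc_pre, acc_scratch = acc_scr, lm = lm,
       clf = clf, clf_scratch = clf_s,
       test = data.frame(sequence = te$sequences, y = te$y),
       probs_pretrained = p_pre)
}
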