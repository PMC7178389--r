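#' Read a protein corpus: sequences, cluster assignments and labels
#'
#' Sequences come from FASTA; cluster assignments from a tab-separated table
#' with header `seq_id`, `cluster_id`, `is_representative`; labels from a
#' tab-separated table with header `seq_id` followed by one or more label
#' columns. Cluster and label files are optional (a language-model-only
#' corpus needs neither). Lowercase residues are normalized to uppercase;
#' symbols outside the 26-letter alphabet are rejected unless
#' `permissive = TRUE`, in which case they are mapped to X.
#'
#' @param fasta_path path to a FASTA file of amino-acid sequences.
#' @param cluster_path optional path to the cluster TSV.
#' @param label_path optional path to the label TSV.
#' @param vocab an [aa_vocabulary()].
#' @param permissive map unknown symbols to X instead of rejecting.
#' @return a list of class `aa_corpus` with elements `records` (data.frame
#'   with columns `id`, `sequence`), `clusters` (a `cluster_table` or
#'   `NULL`) and `labels` (data.frame keyed by `seq_id`, or `NULL`).
#' @export
read_corpus <- function(fasta_path, cluster_path = NULL, label_path = NULL,
                        vocab = aa_vocabulary(), permissive = FALSE) {
  if (!file.exists(fasta_path))
    stop("FASTA file not found: ", fasta_path)
  seqs <- Biostrings::readAAStringSet(fasta_path)
  ids <- sub("\\s.*$", "", names(seqs))
  if (anyDuplicated(ids)) {
    dup <- ids[duplicated(ids)][1]
    stop(sprintf("duplicate sequence id '%s' in %s", dup, fasta_path))
  }
  seq_chr <- toupper(as.character(seqs))
  alphabet <- paste(vocab$residues, collapse = "")
  bad <- grepl(sprintf("[^%s]", alphabet), seq_chr)
  if (any(bad)) {
    if (permissive) {
      seq_chr[bad] <- gsub(sprintf("[^%s]", alphabet), "X", seq_chr[bad])
    } else {
      stop(sprintf("sequence '%s' contains symbols outside the %d-letter alphabet (set permissive = TRUE to map them to X)",
                   ids[which(bad)[1]], length(vocab$residues)))
    }
  }
  if (any(nchar(seq_chr) == 0L))
    stop(sprintf("sequence '%s' is empty", ids[which(nchar(seq_chr) == 0L)[1]]))
  records <- data.frame(id = ids, sequence = unname(seq_chr),
                        stringsAsFactors = FALSE)

  clusters <- NULL
  if (!is.null(cluster_path)) {
    clusters <- read_cluster_table(cluster_path, known_ids = ids)
  }
  labels <- NULL
  if (!is.null(label_path)) {
    if (!file.exists(label_path)) stop("label file not found: ", label_path)
    labels <- utils::read.delim(label_path, stringsAsFactors = FALSE,
                                check.names = FALSE)
    if (!"seq_id" %in% names(labels))
      stop("label table must have a 'seq_id' column: ", label_path)
    unknown <- setdiff(labels$seq_id, ids)
    if (length(unknown))
      stop(sprintf("label table references unknown sequence id '%s'", unknown[1]))
  }
  structure(list(records = records, clusters = clusters, labels = labels),
            class = "aa_corpus")
}

#' Read a cluster assignment table
#'
#' @param path TSV with header `seq_id`, `cluster_id`, `is_representative`
#'   (logical or 0/1).
#' @param known_ids optional character vector; every `seq_id` must be in it.
#' @return a `cluster_table`: list with `member_of` (named character vector,
#'   sequence id -> cluster id) and `representative` (named character
#'   vector, cluster id -> representative sequence id).
#' @export
read_cluster_table <- function(path, known_ids = NULL) {
  if (!file.exists(path)) stop("cluster file not found: ", path)
  tab <- utils::read.delim(path, stringsAsFactors = FALSE)
  need <- c("seq_id", "cluster_id", "is_representative")
  if (!all(need %in% names(tab)))
    stop("cluster table must have columns seq_id, cluster_id, is_representative: ", path)
  if (!is.null(known_ids)) {
    unknown <- setdiff(tab$seq_id, known_ids)
    if (length(unknown))
      stop(sprintf("cluster table row references unknown sequence id '%s' (%s)",
                   unknown[1], path))
  }
  cluster_table(member_of = stats::setNames(as.character(tab$cluster_id), tab$seq_id),
                representative = {
                  rep_rows <- tab[as.logical(tab$is_representative), , drop = FALSE]
                  stats::setNames(rep_rows$seq_id, as.character(rep_rows$cluster_id))
                })
}

#' Construct and validate a cluster table
#'
#' @param member_of named character vector: sequence id -> cluster id.
#' @param representative named character vector: cluster id -> sequence id.
#' @return validated object of class `cluster_table`.
#' @export
cluster_table <- function(member_of, representative) {
  stopifnot(length(member_of) > 0)
  cl_ids <- unique(unname(member_of))
  missing_rep <- setdiff(cl_ids, names(representative))
  # representatives are optional at construction; expand_members enforces them
  for (cl in names(representative)) {
    rep_id <- representative[[cl]]
    if (is.na(member_of[rep_id]) || member_of[[rep_id]] != cl)
      stop(sprintf("representative '%s' of cluster '%s' is not a member of it",
                   rep_id, cl))
  }
  structure(list(member_of = member_of, representative = representative,
                 clusters = cl_ids, missing_representative = missing_rep),
            class = "cluster_table")
}

#' Members of one cluster
#' @param clusters a `cluster_table`.
#' @param cluster_id cluster id.
#' @return character vector of member sequence ids.
#' @export
cluster_members <- function(clusters, cluster_id) {
  names(clusters$member_of)[clusters$member_of == cluster_id]
}

#' Write sequences as FASTA
#' @param records data.frame with `id`, `sequence`.
#' @param path output path.
#' @export
write_fasta <- function(records, path) {
  x <- Biostrings::AAStringSet(records$sequence)
  names(x) <- records$id
  Biostrings::writeXStringSet(x, path)
  invisible(path)
}

#' Write a cluster table as TSV
#' @param clusters a `cluster_table`.
#' @param path output path.
#' @export
write_cluster_table <- function(clusters, path) {
  tab <- data.frame(seq_id = names(clusters$member_of),
                    cluster_id = unname(clusters$member_of),
                    stringsAsFactors = FALSE)
  reps <- clusters$representative
  tab$is_representative <- as.integer(tab$seq_id %in% unname(reps))
  utils::write.table(tab, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
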