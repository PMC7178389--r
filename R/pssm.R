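# PSSM handling: an internal alignment-based provider, an adapter for an
# external PSI-BLAST-compatible profile search, leakage-controlled PSSM
# database construction, and the one-hot + PSSM input encoding of the CNN
# baseline.

#' PSSM from an alignment (internal provider)
#'
#' Per-column log-odds of pseudocount-smoothed residue frequencies against
#' a background distribution, over the 20 standard amino acids. Columns of
#' the returned matrix follow the package's standard residue order
#' (alphabetical).
#'
#' @param aligned_sequences character vector of equal-length sequences
#'   (>= 1); gap characters (`-`, `.`) and non-standard residues are
#'   ignored in the counts.
#' @param background probability vector over the 20 standard residues
#'   (default uniform).
#' @param pseudocount additive smoothing count per residue (default 1).
#' @param log_base base of the log-odds (default 2).
#' @return numeric matrix `L x 20` of class `pssm`, column names the
#'   standard residues.
#' @export
pssm_from_alignment <- function(aligned_sequences, background = rep(1/20, 20),
                                pseudocount = 1, log_base = 2) {
  if (length(aligned_sequences) == 0) stop("empty alignment")
  L <- unique(nchar(aligned_sequences))
  if (length(L) != 1) stop("aligned sequences must have equal length")
  standard <- aa_vocabulary()$standard
  stopifnot(length(background) == 20, abs(sum(background) - 1) < 1e-8)
  chars <- do.call(rbind, strsplit(aligned_sequences, ""))
  scores <- matrix(0, L, 20, dimnames = list(NULL, standard))
  for (j in seq_len(L)) {
    col <- chars[, j]
    counts <- table(factor(col[col %in% standard], levels = standard))
    n <- sum(counts)
    freq <- (as.numeric(counts) + pseudocount) / (n + 20 * pseudocount)
    scores[j, ] <- log(freq / background, base = log_base)
  }
  structure(scores, class = c("pssm", "matrix"))
}

#' Build a leakage-controlled PSSM search database
#'
#' Writes the FASTA database a profile search runs against. In `"clean"`
#' mode the database contains only members of training clusters, so no
#' validation/test information can leak into the profiles; in `"leaky"`
#' mode it contains the full corpus (the common, leakage-prone practice).
#'
#' @param records data.frame with `id`, `sequence`.
#' @param split a cluster-mode `dataset_split`.
#' @param clusters the `cluster_table` the split was made from.
#' @param mode `"clean"` or `"leaky"`.
#' @param path output FASTA path.
#' @return list of class `pssm_database`: `path`, `mode`, `member_ids`,
#'   `md5` (content hash of the database file).
#' @export
build_pssm_database <- function(records, split, clusters,
                                mode = c("clean", "leaky"), path) {
  mode <- match.arg(mode)
  ids <- if (mode == "clean") {
    names(clusters$member_of)[clusters$member_of %in% split$train_clusters]
  } else {
    records$id
  }
  sel <- records[records$id %in% ids, , drop = FALSE]
  write_fasta(sel, path)
  structure(list(path = path, mode = mode, member_ids = sel$id,
                 md5 = unname(tools::md5sum(path))),
            class = "pssm_database")
}

#' Construct the external profile-search command
#'
#' Pure helper building the argument vector for a PSI-BLAST-compatible
#' executable: 3 search iterations, e-value threshold 0.001, ASCII PSSM
#' output.
#'
#' @param query_fasta query sequence FASTA path.
#' @param database_path path of the (formatted) search database.
#' @param out_pssm output path for the ASCII PSSM.
#' @param n_iterations,evalue search parameters.
#' @param exe executable name.
#' @return list with `exe` and `args` (character vector).
#' @export
psiblast_command <- function(query_fasta, database_path, out_pssm,
                             n_iterations = 3, evalue = 0.001,
                             exe = "psiblast") {
  list(exe = exe,
       args = c("-query", query_fasta, "-db", database_path,
                "-num_iterations", as.character(n_iterations),
                "-evalue", format(evalue, scientific = FALSE),
                "-out_ascii_pssm", out_pssm, "-out", "/dev/null"))
}

#' Run an external profile search and parse its PSSM
#'
#' Invokes a PSI-BLAST-compatible executable (3 iterations, e-value 0.001)
#' and parses the ASCII PSSM it writes. If the search finds no hits and no
#' PSSM is produced, a zero matrix is returned with a warning.
#'
#' @param record list/row with `id` and `sequence`.
#' @param database a `pssm_database` (or a database path).
#' @param mode recorded in the result's provenance metadata.
#' @param exe executable name (must be on the PATH).
#' @param workdir scratch directory for query/output files.
#' @return a `pssm` matrix (`L x 20`, standard residue order) with
#'   attributes `mode` and `command`.
#' @export
psiblast_pssm <- function(record, database, mode = c("clean", "leaky"),
                          exe = "psiblast", workdir = tempdir()) {
  mode <- match.arg(mode)
  if (Sys.which(exe) == "")
    stop(sprintf("profile-search executable '%s' not found on PATH", exe))
  db_path <- if (inherits(database, "pssm_database")) database$path else database
  qf <- file.path(workdir, paste0(record$id, ".fasta"))
  writeLines(c(paste0(">", record$id), record$sequence), qf)
  outp <- file.path(workdir, paste0(record$id, ".pssm"))
  cmd <- psiblast_command(qf, db_path, outp)
  status <- system2(cmd$exe, cmd$args, stdout = FALSE, stderr = FALSE)
  if (status != 0)
    stop(sprintf("'%s' exited with status %d for query '%s'",
                 exe, status, record$id))
  if (!file.exists(outp)) {
    warning(sprintf("no PSSM produced for '%s' (no significant hits); returning zero matrix",
                    record$id))
    L <- nchar(record$sequence)
    m <- matrix(0, L, 20, dimnames = list(NULL, aa_vocabulary()$standard))
    return(structure(m, class = c("pssm", "matrix"), mode = mode,
                     command = paste(c(cmd$exe, cmd$args), collapse = " ")))
  }
  m <- parse_ascii_pssm(outp)
  structure(m, mode = mode,
            command = paste(c(cmd$exe, cmd$args), collapse = " "))
}

#' Parse an ASCII PSSM file
#'
#' Reads the ASCII PSSM dialect written by PSI-BLAST (`-out_ascii_pssm`):
#' a header naming the 20 standard residues in the order
#' `A R N D C Q E G H I L K M F P S T W Y V`, then one row per position
#' with the 20 log-odds scores first. Columns are remapped to the
#' package's alphabetical residue order.
#'
#' @param path PSSM file path.
#' @return a `pssm` matrix (`L x 20`).
#' @export
parse_ascii_pssm <- function(path) {
  lines <- readLines(path)
  header_i <- grep("^\\s*A\\s+R\\s+N\\s+D\\s+C", lines)[1]
  if (is.na(header_i)) stop("unparsable ASCII PSSM (no residue header): ", path)
  blast_order <- strsplit(trimws(lines[header_i]), "\\s+")[[1]][1:20]
  rows <- list()
  for (ln in lines[-seq_len(header_i)]) {
    f <- strsplit(trimws(ln), "\\s+")[[1]]
    if (length(f) < 22 || is.na(suppressWarnings(as.integer(f[1])))) break
    rows[[length(rows) + 1L]] <- as.numeric(f[3:22])
  }
  if (!length(rows)) stop("unparsable ASCII PSSM (no score rows): ", path)
  m <- do.call(rbind, rows)
  colnames(m) <- blast_order
  standard <- aa_vocabulary()$standard
  m <- m[, standard, drop = FALSE]
  structure(m, class = c("pssm", "matrix"))
}

#' Encode a sequence as the CNN baseline input
#'
#' Concatenates the `L x 26` one-hot encoding with the `L x 20` PSSM into
#' an `L x 46` matrix, zero-padded (or truncated at the N-terminal side)
#' to `max_len` rows. In sequence-only mode (`pssm = NULL`) the PSSM block
#' is identically zero.
#'
#' @param sequence residue string.
#' @param pssm optional `pssm` matrix with `nchar(sequence)` rows.
#' @param max_len padded length (default 1024).
#' @param vocab an [aa_vocabulary()].
#' @return numeric matrix `max_len x 46`.
#' @export
encode_input <- function(sequence, pssm = NULL, max_len = 1024,
                         vocab = aa_vocabulary()) {
  L <- nchar(sequence)
  if (!is.null(pssm) && nrow(pssm) != L)
    stop(sprintf("PSSM has %d rows but sequence has length %d", nrow(pssm), L))
  if (L > max_len) {             # keep the N-terminal max_len residues
    sequence <- substr(sequence, 1, max_len)
    if (!is.null(pssm)) pssm <- pssm[seq_len(max_len), , drop = FALSE]
    L <- max_len
  }
  oh <- one_hot(sequence, vocab)
  out <- matrix(0, max_len, 26 + 20)
  out[seq_len(L), seq_len(26)] <- oh
  if (!is.null(pssm)) out[seq_len(L), 26 + seq_len(20)] <- unclass(pssm)
  out
}
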