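#' @title Read classification
#' @description Each read is scored against every species class with the
#'   log-space likelihood L(x|y) = sum_j log P(x_j|y) over the read's k-mers
#'   (distinct k-mers by default; optionally weighted by multiplicity) and
#'   assigned to the argmax class. The species prior is uniform and dropped,
#'   as is the class-independent posterior denominator. Every read receives a
#'   label -- there is no "unclassified" call. Batching and threading are
#'   pure scheduling: predictions are bit-identical for every choice of
#'   thread count and batch layout.
#' @name classify
NULL

match_mode <- function(mode) match.arg(mode, c("unique", "multiplicity"))

#' Log-likelihood of a read's k-mers under one class
#'
#' @param model A `class_model`.
#' @param read_kmers A `kmer_table` of the read (same spec as the model).
#' @param mode `"unique"` (default): each distinct k-mer of the read
#'   contributes once; `"multiplicity"`: each occurrence contributes.
#' @return The natural-log likelihood (a non-positive number; 0 for a read
#'   with no valid k-mers).
#' @export
score_read <- function(model, read_kmers, mode = "unique") {
  mode <- match_mode(mode)
  if (!spec_equal(model$spec, read_kmers$spec))
    stop("read k-mer table spec does not match model spec", call. = FALSE)
  if (length(read_kmers$counts) == 0L) return(0)
  lp <- log_smoothed_prob(model, names(read_kmers$counts))
  if (mode == "unique") sum(lp) else sum(unname(read_kmers$counts) * lp)
}

#' Classify a single read against a model store
#'
#' Scores the read against every class and returns the argmax; ties are
#' broken by the smallest taxid (in particular, a read with no valid k-mers
#' scores 0 everywhere and is assigned the smallest taxid).
#'
#' @param store A non-empty `model_store` (or a list of `class_model`s).
#' @param read Nucleotide string.
#' @param mode Scoring mode, see [score_read()].
#' @param read_id Identifier carried into the output.
#' @return A one-row data.frame: `read_id`, `predicted_species`,
#'   `log_likelihood`.
#' @export
classify_read <- function(store, read, mode = "unique", read_id = "read") {
  models <- if (inherits(store, "model_store")) {
    if (length(store$index) == 0L) stop("model store is empty", call. = FALSE)
    lapply(sort(store$index), function(t) load_class(store, t))
  } else store
  spec <- models[[1L]]$spec
  rk <- count_kmers(read, spec)
  scores <- vapply(models, score_read, numeric(1), read_kmers = rk, mode = mode)
  taxids <- vapply(models, `[[`, integer(1), "species_taxid")
  o <- order(taxids)
  scores <- scores[o]; taxids <- taxids[o]
  best <- which.max(scores) # first maximum = smallest taxid on ties
  data.frame(read_id = read_id, predicted_species = taxids[best],
             log_likelihood = scores[best], stringsAsFactors = FALSE)
}

#' Plan read batches under a memory cap or a fixed batch size
#'
#' Greedy in input order: reads accumulate until adding the next read would
#' exceed `memory_cap_bytes`, then the batch is released. A single read
#' larger than the cap forms a singleton batch (with a warning). With
#' `n_per_batch`, fixed-size chunks are cut instead. The concatenation of the
#' returned batches always reproduces the input order exactly.
#'
#' @param sizes Integer vector of read sizes in bytes (sequence lengths).
#' @param memory_cap_bytes Byte cap per batch; mutually exclusive with
#'   `n_per_batch`.
#' @param n_per_batch Fixed number of reads per batch.
#' @return A list of integer index vectors into the input order.
#' @export
plan_batches <- function(sizes, memory_cap_bytes = NULL, n_per_batch = NULL) {
  n <- length(sizes)
  if (is.null(memory_cap_bytes) == is.null(n_per_batch))
    stop("give exactly one of memory_cap_bytes or n_per_batch", call. = FALSE)
  if (n == 0L) return(list())
  if (!is.null(n_per_batch)) {
    if (n_per_batch <= 0) stop("n_per_batch must be positive", call. = FALSE)
    return(unname(split(seq_len(n), (seq_len(n) - 1L) %/% n_per_batch)))
  }
  if (memory_cap_bytes <= 0) stop("memory cap must be positive", call. = FALSE)
  batches <- list()
  cur <- integer(0); cur_bytes <- 0
  for (i in seq_len(n)) {
    if (length(cur) > 0L && cur_bytes + sizes[i] > memory_cap_bytes) {
      batches[[length(batches) + 1L]] <- cur
      cur <- integer(0); cur_bytes <- 0
    }
    if (sizes[i] > memory_cap_bytes)
      warning(sprintf("read %d (%d bytes) exceeds the memory cap; forming a singleton batch",
                      i, sizes[i]))
    cur <- c(cur, i); cur_bytes <- cur_bytes + sizes[i]
  }
  batches[[length(batches) + 1L]] <- cur
  batches
}

# Score one batch of reads against one class in a single vectorised pass.
# kmer_list: per-read character vectors (distinct kmers, sorted);
# weight_list: matching per-read counts (multiplicity mode). Per-read sums are
# accumulated in each read's own kmer order, so results do not depend on how
# reads were grouped into batches.
score_batch_class <- function(model, kmer_list, weight_list, mode) {
  nk <- lengths(kmer_list)
  all_kmers <- unlist(kmer_list, use.names = FALSE)
  if (length(all_kmers) == 0L) return(numeric(length(kmer_list)))
  f <- model$counts[all_kmers]
  f[is.na(f)] <- 0
  lp <- log((f + 1) / (model$total + 4^model$spec$k))
  if (mode == "multiplicity") lp <- lp * unlist(weight_list, use.names = FALSE)
  grp <- rep.int(seq_along(kmer_list), nk)
  out <- numeric(length(kmer_list))
  sums <- rowsum(lp, grp, reorder = FALSE)
  out[unique(grp)] <- sums[, 1L]
  out
}

#' Classify reads batchwise under memory/thread contracts
#'
#' For each batch, every class savefile is loaded exactly once, all reads of
#' the batch are scored against it, and the batch's best scores are folded in
#' taxid order before the next class is touched; the batch is then released.
#' With `threads > 1` the per-class scoring is distributed over worker
#' processes, but the fold is always performed in ascending taxid order, so
#' predictions (scores bit-equal, labels equal) are identical for every
#' combination of `threads`, `memory_cap_bytes` and `n_per_batch`.
#'
#' @param store A non-empty `model_store`.
#' @param reads Named character vector of sequences, or a
#'   [Biostrings::DNAStringSet]; names are the read ids.
#' @param threads Worker processes for per-class scoring (default 1).
#' @param memory_cap_bytes,n_per_batch Batch layout, see [plan_batches()];
#'   if neither is given all reads form one batch.
#' @param mode Scoring mode, see [score_read()].
#' @param all_scores Keep the full read x class score matrix
#'   (attribute `"scores"` of the result).
#' @return A data.frame with one row per read in input order: `read_id`,
#'   `predicted_species`, `log_likelihood`.
#' @export
classify_batchwise <- function(store, reads, threads = 1L,
                               memory_cap_bytes = NULL, n_per_batch = NULL,
                               mode = "unique", all_scores = FALSE) {
  mode <- match_mode(mode)
  if (threads < 1L) stop("threads must be >= 1", call. = FALSE)
  if (inherits(reads, "XStringSet")) reads <- setNames(as.character(reads), names(reads))
  n <- length(reads)
  if (n == 0L)
    return(data.frame(read_id = character(0), predicted_species = integer(0),
                      log_likelihood = numeric(0), stringsAsFactors = FALSE))
  if (length(store$index) == 0L) stop("model store is empty", call. = FALSE)
  ids <- names(reads)
  if (is.null(ids)) ids <- sprintf("read_%d", seq_len(n))
  if (anyDuplicated(ids)) stop("read ids must be unique within a run", call. = FALSE)

  batches <- if (is.null(memory_cap_bytes) && is.null(n_per_batch)) list(seq_len(n))
             else plan_batches(nchar(reads), memory_cap_bytes, n_per_batch)

  taxids <- sort(store$index)
  best_tax <- integer(n); best_score <- numeric(n)
  score_mat <- if (all_scores) matrix(NA_real_, n, length(taxids),
                                      dimnames = list(ids, taxids))

  for (batch in batches) {
    tabs <- lapply(reads[batch], count_kmers, spec = store$spec)
    kmer_list <- lapply(tabs, function(t) names(t$counts))
    weight_list <- lapply(tabs, function(t) unname(t$counts))
    score_one <- function(taxid) {
      model <- load_class(store, taxid)
      score_batch_class(model, kmer_list, weight_list, mode)
    }
    per_class <- if (threads > 1L)
      parallel::mclapply(taxids, score_one, mc.cores = threads)
    else lapply(taxids, score_one)
    # fold in ascending taxid order; strict > keeps the smallest taxid on ties
    bt <- rep(taxids[1L], length(batch)); bs <- per_class[[1L]]
    for (j in seq_along(taxids)[-1L]) {
      s <- per_class[[j]]
      better <- s > bs
      bs[better] <- s[better]; bt[better] <- taxids[j]
    }
    best_tax[batch] <- bt; best_score[batch] <- bs
    if (all_scores)
      score_mat[batch, ] <- do.call(cbind, per_class)
  }
  out <- data.frame(read_id = ids, predicted_species = best_tax,
                    log_likelihood = best_score, stringsAsFactors = FALSE)
  if (all_scores) attr(out, "scores") <- score_mat
  out
}

#' Write predictions as TSV
#'
#' Columns `read_id`, `predicted_species_taxid`, `log_likelihood` (natural
#' log, 6 decimal places), reads in input order.
#'
#' @param predictions Output of [classify_batchwise()] or rows of
#'   [classify_read()].
#' @param path Output file path.
#' @export
write_predictions <- function(predictions, path) {
  df <- data.frame(read_id = predictions$read_id,
                   predicted_species_taxid = predictions$predicted_species,
                   log_likelihood = sprintf("%.6f", predictions$log_likelihood),
                   stringsAsFactors = FALSE)
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a predictions TSV written by [write_predictions()]
#'
#' @param path TSV file path.
#' @return A data.frame with `read_id`, `predicted_species`, `log_likelihood`.
#' @export
read_predictions <- function(path) {
  df <- read.table(path, sep = "\t", header = TRUE, stringsAsFactors = FALSE)
  data.frame(read_id = as.character(df$read_id),
             predicted_species = as.integer(df$predicted_species_taxid),
             log_likelihood = as.numeric(df$log_likelihood),
             stringsAsFactors = FALSE)
}
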