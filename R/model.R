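#' @title Incremental per-species model store
#' @description One class per species, one savefile per class. A class holds
#'   the raw k-mer counts f(x|y) summed over every training genome of that
#'   species plus the total T = sum_x f(x|y). Because these are plain integer
#'   sums, adding genomes to a class, creating a new class, or merging one
#'   class into another touches only the affected savefiles and reproduces the
#'   batch-trained model exactly -- there is nothing to approximate and no
#'   catastrophic forgetting. Smoothing is applied at query time:
#'   P(x|y) = (f(x|y) + 1) / (T + 4^k).
#' @name model-store
NULL

STORE_FORMAT_VERSION <- 1L

#' Construct an in-memory class model
#'
#' @param species_taxid Integer species taxid (the class label).
#' @param table A `kmer_table` of raw counts pooled over the class's genomes.
#' @param n_genomes Number of genomes absorbed into the counts.
#' @return A `class_model`.
#' @export
class_model <- function(species_taxid, table, n_genomes = 1L) {
  structure(list(species_taxid = as.integer(species_taxid),
                 spec = table$spec,
                 counts = table$counts,
                 total = table$total,
                 n_genomes = as.integer(n_genomes)),
            class = "class_model")
}

#' @export
print.class_model <- function(x, ...) {
  cat(sprintf("<class_model> species %d: %d distinct %d-mers, total %.0f, %d genome(s)\n",
              x$species_taxid, length(x$counts), x$spec$k, x$total, x$n_genomes))
  invisible(x)
}

#' Laplace-smoothed log-probability of k-mers under a class
#'
#' Natural log of (f + 1) / (T + K) with f the stored count of the k-mer
#' (0 if unseen), T the class total and K = 4^k. Add-one smoothing keeps the
#' probability strictly positive, so the log is never -Inf, and forces the
#' distribution over all 4^k words to sum to exactly 1.
#'
#' @param model A `class_model`.
#' @param kmer Character vector of k-mers, each of length `model$spec$k`.
#' @return Numeric vector of natural-log probabilities.
#' @export
#' @examples
#' m <- class_model(1, count_kmers("AAA", kmer_spec(1)))
#' log_smoothed_prob(m, "A")  # log((3+1)/(3+4))
log_smoothed_prob <- function(model, kmer) {
  if (any(nchar(kmer) != model$spec$k))
    stop(sprintf("k-mer length must be %d", model$spec$k), call. = FALSE)
  f <- model$counts[kmer]
  f[is.na(f)] <- 0
  unname(log((f + 1) / (model$total + 4^model$spec$k)))
}

## ---- store ----------------------------------------------------------------

store_manifest_path <- function(store) file.path(store$root, "store.json")
class_file <- function(store, taxid) file.path(store$root, sprintf("%d.nbc", as.integer(taxid)))

write_manifest <- function(store) {
  idx <- sort(store$index)
  jsonlite::write_json(
    list(format_version = STORE_FORMAT_VERSION,
         k = store$spec$k,
         canonical = store$spec$canonical,
         classes = as.integer(idx)),
    store_manifest_path(store), auto_unbox = TRUE, digits = NA)
  invisible(store)
}

#' Create a new (empty) model store
#'
#' A store is a directory holding one `<species_taxid>.nbc` savefile per
#' class plus a `store.json` manifest recording k, strand handling and the
#' class index.
#'
#' @param root Directory path; created if absent. Must not already contain a
#'   manifest.
#' @param spec The [kmer_spec()] shared by every class in the store.
#' @return A `model_store` handle.
#' @export
create_store <- function(root, spec) {
  stopifnot_spec(spec)
  dir.create(root, recursive = TRUE, showWarnings = FALSE)
  if (file.exists(file.path(root, "store.json")))
    stop(sprintf("'%s' already contains a model store", root), call. = FALSE)
  store <- structure(list(root = root, spec = spec, index = integer(0)),
                     class = "model_store")
  write_manifest(store)
  store
}

#' Open an existing model store
#'
#' @param root Directory containing `store.json`.
#' @return A `model_store` handle with the on-disk class index.
#' @export
open_store <- function(root) {
  mp <- file.path(root, "store.json")
  if (!file.exists(mp))
    stop(sprintf("'%s' is not a model store (no store.json)", root), call. = FALSE)
  m <- jsonlite::read_json(mp, simplifyVector = TRUE)
  if (is.null(m$format_version) || m$format_version != STORE_FORMAT_VERSION)
    stop("unsupported model store format version", call. = FALSE)
  store <- structure(list(root = root,
                          spec = kmer_spec(m$k, isTRUE(m$canonical)),
                          index = sort(as.integer(m$classes))),
                     class = "model_store")
  on_disk <- sort(as.integer(sub("\\.nbc$", "", basename(
    list.files(root, pattern = "^[0-9]+\\.nbc$")))))
  if (!identical(on_disk, store$index))
    stop("model store index does not match directory contents", call. = FALSE)
  store
}

#' @export
print.model_store <- function(x, ...) {
  cat(sprintf("<model_store> %s: %d class(es), k = %d, canonical = %s\n",
              x$root, length(x$index), x$spec$k, x$spec$canonical))
  invisible(x)
}

#' Save a class model into a store
#'
#' Savefiles are plain text and byte-deterministic: "#"-prefixed header lines
#' (taxid, k, canonical flag, genome tally, total), then one
#' `<kmer>\t<count>` line per observed k-mer, keys sorted lexicographically.
#'
#' @param model A `class_model` whose spec matches the store's.
#' @param store A `model_store`.
#' @return The updated `model_store` handle, invisibly the model's taxid is
#'   added to the index.
#' @export
save_class <- function(model, store) {
  if (!spec_equal(model$spec, store$spec))
    stop("class model spec does not match store spec", call. = FALSE)
  keys <- names(model$counts) # already sorted by construction
  lines <- c(sprintf("# species_taxid: %d", model$species_taxid),
             sprintf("# k: %d", model$spec$k),
             sprintf("# canonical: %s", if (model$spec$canonical) "true" else "false"),
             sprintf("# n_genomes: %d", model$n_genomes),
             sprintf("# total: %.0f", model$total),
             if (length(keys)) sprintf("%s\t%.0f", keys, unname(model$counts)))
  writeLines(lines, class_file(store, model$species_taxid))
  store$index <- sort(union(store$index, model$species_taxid))
  write_manifest(store)
  store
}

parse_header_num <- function(lines, field) {
  ln <- grep(sprintf("^# %s:", field), lines, value = TRUE)
  if (length(ln) != 1L)
    stop(sprintf("savefile integrity error: missing header '%s'", field), call. = FALSE)
  trimws(sub(sprintf("^# %s:", field), "", ln))
}

#' Load a class model from a store
#'
#' Validates the header against the store spec and checks that the recorded
#' total equals the sum of the counts (truncated or corrupted savefiles fail).
#'
#' @param store A `model_store`.
#' @param taxid Species taxid of the class.
#' @return A `class_model`.
#' @export
load_class <- function(store, taxid) {
  path <- class_file(store, taxid)
  if (!file.exists(path))
    stop(sprintf("no class %s in store '%s'", taxid, store$root), call. = FALSE)
  lines <- readLines(path)
  hdr <- startsWith(lines, "#")
  h_taxid <- as.integer(parse_header_num(lines[hdr], "species_taxid"))
  h_k <- as.integer(parse_header_num(lines[hdr], "k"))
  h_canon <- identical(parse_header_num(lines[hdr], "canonical"), "true")
  h_ng <- as.integer(parse_header_num(lines[hdr], "n_genomes"))
  h_total <- as.numeric(parse_header_num(lines[hdr], "total"))
  if (h_taxid != as.integer(taxid))
    stop("savefile integrity error: header taxid does not match filename", call. = FALSE)
  if (h_k != store$spec$k || h_canon != store$spec$canonical)
    stop("savefile spec (k/canonical) does not match store", call. = FALSE)
  body <- lines[!hdr & nzchar(lines)]
  if (length(body)) {
    parts <- strsplit(body, "\t", fixed = TRUE)
    if (any(lengths(parts) != 2L))
      stop("savefile integrity error: malformed count line", call. = FALSE)
    flat <- unlist(parts, use.names = FALSE)
    kmers <- flat[c(TRUE, FALSE)]
    counts <- as.numeric(flat[c(FALSE, TRUE)])
  } else {
    kmers <- character(0); counts <- numeric(0)
  }
  if (anyNA(counts) || any(counts <= 0) || abs(sum(counts) - h_total) > 0)
    stop("savefile integrity error: total does not equal sum of counts", call. = FALSE)
  class_model(h_taxid, new_kmer_table(setNames(counts, kmers), store$spec), h_ng)
}

#' Add genomes to a class (creating it if absent)
#'
#' The incremental update: if the class exists, its counts become the
#' key-wise sum of the old counts and the new genome tables and its genome
#' tally grows; if the class is new, it is created from the tables alone. No
#' other class's savefile is read or written, so updating with new data never
#' disturbs existing classes, and any sequence of updates yields integer-
#' exactly the batch-trained model.
#'
#' @param store A `model_store`.
#' @param species_taxid Class label.
#' @param genome_tables A list of `kmer_table`s, one per genome (a single
#'   `kmer_table` is accepted).
#' @return The updated `model_store` handle.
#' @export
update_class <- function(store, species_taxid, genome_tables) {
  if (inherits(genome_tables, "kmer_table")) genome_tables <- list(genome_tables)
  if (length(genome_tables) == 0L) return(store)
  for (tab in genome_tables)
    if (!spec_equal(tab$spec, store$spec))
      stop("genome table spec does not match store spec", call. = FALSE)
  acc <- Reduce(merge_tables, genome_tables)
  n_new <- length(genome_tables)
  if (species_taxid %in% store$index) {
    old <- load_class(store, species_taxid)
    model <- class_model(species_taxid,
                         merge_tables(new_kmer_table(old$counts, store$spec), acc),
                         old$n_genomes + n_new)
  } else {
    model <- class_model(species_taxid, acc, n_new)
  }
  save_class(model, store)
}

#' Merge one class into another
#'
#' Applies the taxonomy-revision rule: the receiving class's counts become
#' the key-wise sum of both classes (genome tallies summed) and the source
#' savefile is removed -- identical to having trained the receiving species
#' on both classes' genomes from scratch.
#'
#' @param store A `model_store`.
#' @param from_taxid Class to be absorbed and deleted.
#' @param into_taxid Receiving class.
#' @return The updated `model_store` handle.
#' @export
merge_classes <- function(store, from_taxid, into_taxid) {
  if (!(from_taxid %in% store$index) || !(into_taxid %in% store$index))
    stop("both classes must exist in the store to merge", call. = FALSE)
  if (from_taxid == into_taxid) {
    warning("merging a class into itself: no-op")
    return(store)
  }
  a <- load_class(store, from_taxid)
  b <- load_class(store, into_taxid)
  merged <- class_model(into_taxid,
                        merge_tables(new_kmer_table(a$counts, store$spec),
                                     new_kmer_table(b$counts, store$spec)),
                        a$n_genomes + b$n_genomes)
  store <- save_class(merged, store)
  delete_class(store, from_taxid)
}

#' Remove a class from a store
#'
#' Maintenance complement to class creation: deletes the savefile and drops
#' the taxid from the manifest.
#'
#' @param store A `model_store`.
#' @param taxid Class to delete.
#' @return The updated `model_store` handle.
#' @export
delete_class <- function(store, taxid) {
  if (!(taxid %in% store$index))
    stop(sprintf("no class %s in store", taxid), call. = FALSE)
  file.remove(class_file(store, taxid))
  store$index <- setdiff(store$index, as.integer(taxid))
  write_manifest(store)
  store
}

#' Train a store from genome k-mer tables
#'
#' Convenience batch trainer: groups tables by species and updates each class
#' once. Equivalent to any sequence of per-genome [update_class()] calls.
#'
#' @param store A `model_store`.
#' @param tables List of `kmer_table`s, one per genome.
#' @param species_taxids Integer vector parallel to `tables`.
#' @return The updated `model_store` handle.
#' @export
train_store <- function(store, tables, species_taxids) {
  stopifnot(length(tables) == length(species_taxids))
  for (sp in sort(unique(as.integer(species_taxids)))) {
    store <- update_class(store, sp, tables[species_taxids == sp])
  }
  store
}
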