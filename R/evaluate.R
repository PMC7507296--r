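#' @title Evaluation harness
#' @description Genome-level k-fold cross-validation, known/unknown read
#'   accounting, per-rank trace-back accuracy, the yearly incremental-
#'   snapshot experiment, and the k-mer size sweep.
#' @name evaluate
NULL

#' Read a genome metadata table
#'
#' Accepts either a plain TSV with columns `genome_id`, `species_taxid`,
#' `release_date` (and optionally `fasta_path`), or an NCBI
#' assembly-summary-style table ("#"-prefixed header lines, tab-separated,
#' with `assembly_accession`/`species_taxid`/`seq_rel_date`/`assembly_level`/
#' `version_status` columns) to which the filters `assembly_level ==
#' "Complete Genome"` and `version_status == "latest"` are applied.
#'
#' @param path Path to the table.
#' @return A data.frame with `genome_id`, `species_taxid`, `release_date`,
#'   `release_year` (and `fasta_path` when present).
#' @export
read_genome_metadata <- function(path) {
  lines <- readLines(path)
  hdr_idx <- grep("^#", lines)
  if (length(hdr_idx) > 0L) {
    # assembly-summary dialect: last "#" line is the column header
    header <- sub("^#\\s*", "", lines[max(hdr_idx)])
    cols <- strsplit(header, "\t", fixed = TRUE)[[1L]]
    body <- lines[-hdr_idx]
    df <- read.table(text = body, sep = "\t", quote = "", comment.char = "",
                     stringsAsFactors = FALSE, col.names = make.names(cols))
    names(df) <- cols
    df <- df[df$assembly_level == "Complete Genome" & df$version_status == "latest", ]
    out <- data.frame(genome_id = as.character(df$assembly_accession),
                      species_taxid = as.integer(df$species_taxid),
                      release_date = as.character(df$seq_rel_date),
                      stringsAsFactors = FALSE)
    if ("fasta_path" %in% names(df)) out$fasta_path <- as.character(df$fasta_path)
  } else {
    df <- read.table(path, sep = "\t", header = TRUE, stringsAsFactors = FALSE)
    out <- data.frame(genome_id = as.character(df$genome_id),
                      species_taxid = as.integer(df$species_taxid),
                      release_date = as.character(df$release_date),
                      stringsAsFactors = FALSE)
    if ("fasta_path" %in% names(df)) out$fasta_path <- as.character(df$fasta_path)
  }
  out$release_year <- as.integer(sub("^([0-9]{4}).*$", "\\1", out$release_date))
  if (any(!is.na(out$release_year) & out$release_year < 1995))
    warning("some release years precede 1995; check the release_date column")
  out
}

#' Split genomes into cross-validation folds
#'
#' Uniform random genome-level partition into `n_folds` balanced folds
#' (sizes differ by at most one); species may straddle folds, so held-out
#' strains of a trained species test generalisation while species entirely
#' in the held-out fold are "unknown" to the classifier. Deterministic for a
#' fixed seed.
#'
#' @param genome_ids Character vector of genome identifiers.
#' @param n_folds Number of folds (default 5).
#' @param seed Integer seed (required; recorded on the result).
#' @return Named integer vector genome_id -> fold, with attribute `seed`.
#' @export
split_folds <- function(genome_ids, n_folds = 5L, seed) {
  n <- length(genome_ids)
  if (n < n_folds)
    stop(sprintf("need at least %d genomes for %d folds", n_folds, n_folds), call. = FALSE)
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old))
  set.seed(seed)
  folds <- sample(rep_len(seq_len(n_folds), n))
  structure(setNames(folds, genome_ids), seed = seed)
}

.Random.seed_save <- function() {
  if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
}
.Random.seed_restore <- function(old) {
  if (is.null(old)) {
    if (exists(".Random.seed", globalenv())) rm(".Random.seed", envir = globalenv())
  } else assign(".Random.seed", old, envir = globalenv())
}

#' Species known to a training set
#'
#' A test read is "known" iff its true species has at least one genome in
#' training; unknown reads cannot be labelled correctly at species rank.
#'
#' @param training_species Integer vector of species taxids of the training
#'   genomes (one entry per genome; duplicates fine).
#' @return Sorted integer vector of distinct known species taxids.
#' @export
known_species <- function(training_species) {
  sort(unique(as.integer(training_species)))
}

#' Trace-back accuracy at the six named ranks
#'
#' At each rank a read is correct iff the predicted and true species share
#' the same ancestor at that rank and both lineages resolve there. Reads
#' whose true lineage has no node at a rank are excluded from that rank's
#' denominator and reported as unresolved. Accuracy is reported for all
#' reads and for the subset whose true species was in training ("known").
#'
#' @param predictions Data.frame with `read_id`, `predicted_species`.
#' @param truth Named integer vector read_id -> true species taxid.
#' @param tree A `taxonomy_tree`.
#' @param known_set Integer vector of known species taxids
#'   (see [known_species()]).
#' @param ranks Ranks to evaluate (default species through phylum).
#' @return Data.frame with one row per rank: `rank`, `accuracy_all`,
#'   `accuracy_known`, `fraction_known`, `n_reads`, `unresolved_fraction`.
#' @export
accuracy_at_levels <- function(predictions, truth, tree, known_set,
                               ranks = TRACE_RANKS) {
  if (!all(predictions$read_id %in% names(truth)))
    stop("every read needs a truth label", call. = FALSE)
  true_sp <- unname(truth[predictions$read_id])
  pred_sp <- predictions$predicted_species
  known <- true_sp %in% known_set
  fraction_known <- mean(known)
  n <- length(true_sp)
  rows <- lapply(ranks, function(r) {
    ta <- ancestors_at_rank(tree, true_sp, r)
    pa <- ancestors_at_rank(tree, pred_sp, r)
    resolved <- !is.na(ta)
    correct <- resolved & !is.na(pa) & ta == pa
    acc_all <- if (any(resolved)) sum(correct) / sum(resolved) else NA_real_
    rk <- resolved & known
    acc_known <- if (any(rk)) sum(correct & known) / sum(rk) else NA_real_
    data.frame(rank = r, accuracy_all = acc_all, accuracy_known = acc_known,
               fraction_known = fraction_known, n_reads = n,
               unresolved_fraction = mean(!resolved), stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

# Count each genome's FASTA once; returns a named list of kmer_tables.
genome_tables <- function(genomes, spec) {
  tabs <- lapply(genomes$fasta_path, count_fasta, spec = spec)
  setNames(tabs, genomes$genome_id)
}

#' Yearly incremental-snapshot experiment
#'
#' Starting from an empty store, each year's training genomes are folded in
#' incrementally (each genome processed exactly once); after each year the
#' fixed held-out read set is classified and a per-rank accuracy report
#' emitted. At the final year the incrementally built store is compared
#' file-by-file against a scratch-trained store on all years -- byte
#' identity is the incremental-equals-batch guarantee. Cumulative
#' genomes-processed counters contrast the incremental cost (each genome
#' once) with yearly retraining from scratch (everything up to that year,
#' re-processed every year).
#'
#' @param genomes Training-genome data.frame with `genome_id`,
#'   `species_taxid`, `release_year`, `fasta_path`.
#' @param reads Named character vector (or DNAStringSet) of test reads.
#' @param truth Named integer vector read_id -> true species taxid.
#' @param tree A `taxonomy_tree`.
#' @param spec A [kmer_spec()].
#' @param years Ordered year vector; defaults to the sorted distinct release
#'   years. Years with no genomes are allowed (no-op updates).
#' @param dir Working directory for the stores (default a fresh tempdir).
#' @param mode Scoring mode.
#' @return List: `reports` (tidy data.frame with a `year` column), `cost`
#'   (data.frame `year`, `incremental_cumulative`, `scratch_cumulative`),
#'   `identical` (logical: incremental final store byte-equals scratch
#'   store), `store_dir`.
#' @export
snapshot_experiment <- function(genomes, reads, truth, tree, spec,
                                years = NULL, dir = tempfile("snapshot"),
                                mode = "unique") {
  if (is.null(years)) years <- sort(unique(genomes$release_year))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  tabs <- genome_tables(genomes, spec)
  inc <- create_store(file.path(dir, "incremental"), spec)

  reports <- list()
  cost <- data.frame(year = years, incremental_cumulative = NA_real_,
                     scratch_cumulative = NA_real_)
  seen <- 0; scratch_cum <- 0
  for (i in seq_along(years)) {
    yr <- years[i]
    sel <- genomes$release_year == yr
    inc <- train_store(inc, tabs[genomes$genome_id[sel]], genomes$species_taxid[sel])
    seen <- seen + sum(sel)
    scratch_cum <- scratch_cum + seen # scratch retrains on everything each year
    cost$incremental_cumulative[i] <- seen
    cost$scratch_cumulative[i] <- scratch_cum
    known <- known_species(genomes$species_taxid[genomes$release_year <= yr])
    if (length(inc$index) > 0L) {
      preds <- classify_batchwise(inc, reads, mode = mode)
      rep_y <- accuracy_at_levels(preds, truth, tree, known)
      rep_y$year <- yr
      reports[[length(reports) + 1L]] <- rep_y
    }
  }

  scratch <- create_store(file.path(dir, "scratch"), spec)
  scratch <- train_store(scratch, tabs[genomes$genome_id], genomes$species_taxid)
  identical_stores <- stores_identical(inc$root, scratch$root)

  list(reports = do.call(rbind, reports), cost = cost,
       identical = identical_stores, store_dir = inc$root)
}

#' Byte-level comparison of two model stores
#'
#' @param a,b Store directories.
#' @return TRUE iff both stores contain the same file names with identical
#'   bytes (manifest included).
#' @export
stores_identical <- function(a, b) {
  fa <- sort(list.files(a)); fb <- sort(list.files(b))
  if (!identical(fa, fb)) return(FALSE)
  ha <- unname(tools::md5sum(file.path(a, fa)))
  hb <- unname(tools::md5sum(file.path(b, fb)))
  all(ha == hb)
}

# One cross-validated run at a fixed k: train on all folds but f, classify
# the held-out fold's reads, report per-rank accuracy.
run_cv <- function(genomes, reads, read_genome, truth, tree, spec,
                   n_folds = 5L, seed = 1L, mode = "unique",
                   dir = tempfile("cv")) {
  folds <- split_folds(genomes$genome_id, n_folds, seed)
  tabs <- genome_tables(genomes, spec)
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  reports <- lapply(seq_len(n_folds), function(f) {
    train <- genomes[folds[genomes$genome_id] != f, ]
    store <- create_store(file.path(dir, sprintf("fold%d", f)), spec)
    store <- train_store(store, tabs[train$genome_id], train$species_taxid)
    test_reads <- reads[read_genome %in% genomes$genome_id[folds[genomes$genome_id] == f]]
    preds <- classify_batchwise(store, test_reads, mode = mode)
    rep_f <- accuracy_at_levels(preds, truth, tree, known_species(train$species_taxid))
    rep_f$fold <- f
    rep_f
  })
  list(reports = do.call(rbind, reports), folds = folds)
}

#' Mean species-level accuracy as a function of k-mer size
#'
#' Runs genome-level cross-validation once per requested k and reports the
#' mean species-rank accuracy (all test reads) across folds.
#'
#' @param genomes Genome data.frame (`genome_id`, `species_taxid`,
#'   `fasta_path`).
#' @param reads Named character vector of test reads (all genomes' reads;
#'   each fold classifies only its held-out genomes' reads).
#' @param read_genome Named character vector read_id -> genome_id.
#' @param truth Named integer vector read_id -> true species taxid.
#' @param tree A `taxonomy_tree`.
#' @param k_values Integer vector of k-mer sizes (each in \[1, 31\]).
#' @param n_folds,seed Cross-validation layout.
#' @param canonical Strand handling for all k.
#' @param mode Scoring mode.
#' @return Named numeric vector k -> mean species accuracy.
#' @export
kmer_size_sweep <- function(genomes, reads, read_genome, truth, tree,
                            k_values, n_folds = 5L, seed = 1L,
                            canonical = FALSE, mode = "unique") {
  res <- vapply(k_values, function(k) {
    cv <- run_cv(genomes, reads, read_genome, truth, tree,
                 kmer_spec(k, canonical), n_folds, seed, mode)
    sp <- cv$reports[cv$reports$rank == "species", ]
    mean(sp$accuracy_all)
  }, numeric(1))
  setNames(res, as.character(k_values))
}

#' Write a tidy evaluation report as TSV
#'
#' Long format: one row per (fold/year, rank, metric).
#'
#' @param reports Data.frame as produced by the evaluation functions.
#' @param path Output TSV path.
#' @export
write_report <- function(reports, path) {
  id_cols <- intersect(c("fold", "year", "rank"), names(reports))
  metric_cols <- setdiff(names(reports), id_cols)
  long <- do.call(rbind, lapply(metric_cols, function(m) {
    cbind(reports[id_cols],
          data.frame(metric = m, value = reports[[m]], stringsAsFactors = FALSE))
  }))
  write.table(long, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
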