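# Shared fixtures, built in code at test time.

# Construct a kmer_table directly from a named count vector (bypasses
# counting; for hand-built oracle inputs).
make_table <- function(counts, spec) {
  kmernb:::new_kmer_table(counts, spec)
}

# Independent naive k-mer counter: plain per-window R loop.
naive_count <- function(sequence, k, canonical = FALSE) {
  sequence <- toupper(sequence)
  out <- list()
  n <- nchar(sequence)
  if (n >= k) {
    for (i in 1:(n - k + 1)) {
      w <- substr(sequence, i, i + k - 1)
      if (grepl("^[ACGT]+$", w)) {
        if (canonical) {
          rc <- revcomp(w)
          if (rc < w) w <- rc
        }
        out[[w]] <- (out[[w]] %||% 0) + 1
      }
    }
  }
  unlist(out) %||% setNames(numeric(0), character(0))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# A small hand-built taxdump fixture:
#   root(1) -> phylum(10) -> class(20) -> order(30) -> family(40)
#     -> genus(50) -> species(100), species(101); strain(1000) under 100
#   second genus(51) under family(40) -> species(102)
# merged.dmp: 999 -> 100
write_toy_taxdump <- function(dir = tempfile("taxdump")) {
  dir.create(dir, showWarnings = FALSE)
  nodes <- c(
    "1\t|\t1\t|\tno rank\t|",
    "10\t|\t1\t|\tphylum\t|",
    "20\t|\t10\t|\tclass\t|",
    "30\t|\t20\t|\torder\t|",
    "40\t|\t30\t|\tfamily\t|",
    "50\t|\t40\t|\tgenus\t|",
    "51\t|\t40\t|\tgenus\t|",
    "100\t|\t50\t|\tspecies\t|",
    "101\t|\t50\t|\tspecies\t|",
    "102\t|\t51\t|\tspecies\t|",
    "1000\t|\t100\t|\tno rank\t|")
  nm <- c(
    "1\t|\troot\t|\t\t|\tscientific name\t|",
    "10\t|\tToyphyla\t|\t\t|\tscientific name\t|",
    "100\t|\tToyspecies prima\t|\t\t|\tscientific name\t|",
    "100\t|\tsome synonym\t|\t\t|\tsynonym\t|")
  writeLines(nodes, file.path(dir, "nodes.dmp"))
  writeLines(nm, file.path(dir, "names.dmp"))
  writeLines("999\t|\t100\t|", file.path(dir, "merged.dmp"))
  dir
}

toy_tree <- function() {
  d <- write_toy_taxdump()
  load_taxdump(file.path(d, "nodes.dmp"), file.path(d, "names.dmp"),
               file.path(d, "merged.dmp"))
}

# Tiny random DNA string.
rand_dna <- function(n) paste(sample(c("A", "C", "G", "T"), n, replace = TRUE),
                              collapse = "")

# Memoised synthetic datasets so expensive fixtures are built once per run.
.fixture_env <- new.env(parent = emptyenv())

# Small dataset for module-level tests: fast but structurally complete.
small_dataset <- function() {
  if (is.null(.fixture_env$small)) {
    .fixture_env$small <- simulate_dataset(
      sim_config(genome_length = 3000L, reads_per_genome = 20L, seed = 42L))
  }
  .fixture_env$small
}

# Full default-condition dataset for the acceptance checks.
default_dataset <- function() {
  if (is.null(.fixture_env$default)) {
    .fixture_env$default <- simulate_dataset(sim_config())
  }
  .fixture_env$default
}

# k-mer tables of a genome set, counted once per (dataset, k).
dataset_tables <- function(ds, spec) {
  key <- sprintf("tabs_%s_%d_%s", ds$dir, spec$k, spec$canonical)
  if (is.null(.fixture_env[[key]])) {
    .fixture_env[[key]] <- setNames(
      lapply(ds$genomes$fasta_path, count_fasta, spec = spec),
      ds$genomes$genome_id)
  }
  .fixture_env[[key]]
}
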