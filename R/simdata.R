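#' @title Synthetic taxonomy, genomes and reads
#' @description A fixture generator that emulates the structure of the real
#'   training problem at desk scale: a small multi-rank taxonomy; per-genus
#'   ancestral sequences mutated at a species-level divergence and again at a
#'   smaller strain-level divergence, so species form separable k-mer
#'   classes with within-species strain variation; release years attached to
#'   every genome; and error-free fixed-length shotgun reads with truth
#'   labels in their headers. Everything is deterministic in the seed and
#'   emitted in standard formats (taxdump-dialect dmp files, FASTA, TSV), so
#'   the parsing, training, classification and evaluation code paths run on
#'   synthetic data exactly as they would on real data.
#' @name simdata
NULL

#' Simulation configuration
#'
#' Defaults give 2 phyla x 2 genera x 3 species x 2 strains = 24 genomes of
#' 20 kb, species diverged 10% per base from their genus ancestor and
#' strains 1% from their species sequence (so strains cluster tightly within
#' well-separated species), release years spread round-robin over 2016-2019,
#' and 100 error-free 150 bp reads per genome.
#'
#' @param n_phyla,genera_per_phylum,species_per_genus,strains_per_species
#'   Taxonomy/genome layout (all >= 1).
#' @param genome_length Genome length in bp.
#' @param species_divergence,strain_divergence Per-base substitution
#'   fractions in \[0, 0.75\]; strain divergence must be below species
#'   divergence.
#' @param years Ordered vector of release years.
#' @param reads_per_genome Reads simulated per genome.
#' @param read_length Read length in bp.
#' @param seed Integer master seed.
#' @return A `sim_config` list.
#' @export
sim_config <- function(n_phyla = 2L, genera_per_phylum = 2L,
                       species_per_genus = 3L, strains_per_species = 2L,
                       genome_length = 20000L,
                       species_divergence = 0.10, strain_divergence = 0.01,
                       years = 2016:2019, reads_per_genome = 100L,
                       read_length = 150L, seed = 1L) {
  cfg <- list(n_phyla = as.integer(n_phyla),
              genera_per_phylum = as.integer(genera_per_phylum),
              species_per_genus = as.integer(species_per_genus),
              strains_per_species = as.integer(strains_per_species),
              genome_length = as.integer(genome_length),
              species_divergence = species_divergence,
              strain_divergence = strain_divergence,
              years = as.integer(years),
              reads_per_genome = as.integer(reads_per_genome),
              read_length = as.integer(read_length),
              seed = as.integer(seed))
  counts <- unlist(cfg[c("n_phyla", "genera_per_phylum", "species_per_genus",
                         "strains_per_species", "genome_length",
                         "reads_per_genome", "read_length")])
  if (any(counts < 1L)) stop("all counts and lengths must be >= 1", call. = FALSE)
  if (species_divergence < 0 || species_divergence > 0.75 ||
      strain_divergence < 0 || strain_divergence > 0.75)
    stop("divergences must lie in [0, 0.75]", call. = FALSE)
  if (strain_divergence >= species_divergence)
    stop("strain_divergence must be smaller than species_divergence", call. = FALSE)
  structure(cfg, class = "sim_config")
}

# Deterministic taxid layout: root = 1, then one block per rank level in
# breadth-first order.
sim_structure <- function(config) {
  np <- config$n_phyla; ng <- config$genera_per_phylum; ns <- config$species_per_genus
  n_gen <- np * ng
  n_sp <- n_gen * ns
  phyla <- 1L + seq_len(np)
  classes <- max(phyla) + seq_len(np)       # one class per phylum
  orders <- max(classes) + seq_len(np)      # one order per class
  families <- max(orders) + seq_len(n_gen)  # one family per genus
  genera <- max(families) + seq_len(n_gen)
  species <- max(genera) + seq_len(n_sp)
  genus_of_species <- rep(genera, each = ns)
  phylum_of_genus <- rep(phyla, each = ng)
  list(phyla = phyla, classes = classes, orders = orders,
       families = families, genera = genera, species = species,
       genus_of_species = genus_of_species, phylum_of_genus = phylum_of_genus)
}

#' Simulate a six-rank taxonomy and write taxdump-dialect files
#'
#' Builds full chains root -> phylum -> class -> order -> family -> genus ->
#' species with deterministic taxids and writes `nodes.dmp` / `names.dmp` in
#' the NCBI dump dialect, so [load_taxdump()] parses them unmodified.
#'
#' @param config A [sim_config()].
#' @param dir Output directory for the dmp files (created); `NULL` skips
#'   writing.
#' @return List: `tree` (a parsed `taxonomy_tree`), `species` (data.frame
#'   `species_taxid`, `genus_taxid`, `phylum_taxid`), and the file paths
#'   (when written).
#' @export
simulate_taxonomy <- function(config, dir = NULL) {
  st <- sim_structure(config)
  taxid <- c(1L, st$phyla, st$classes, st$orders, st$families, st$genera, st$species)
  parent <- c(1L,
              rep(1L, length(st$phyla)),
              st$phyla,                              # class under its phylum
              st$classes,                            # order under its class
              st$orders[st$phylum_of_genus - 1L],    # family under its phylum's order
              st$families,                           # genus under its family (parallel)
              st$genus_of_species)                   # species under its genus
  rank <- c("no rank",
            rep("phylum", length(st$phyla)), rep("class", length(st$classes)),
            rep("order", length(st$orders)), rep("family", length(st$families)),
            rep("genus", length(st$genera)), rep("species", length(st$species)))
  name <- c("root",
            sprintf("Phylum_%d", seq_along(st$phyla)),
            sprintf("Class_%d", seq_along(st$classes)),
            sprintf("Order_%d", seq_along(st$orders)),
            sprintf("Family_%d", seq_along(st$families)),
            sprintf("Genus_%d", seq_along(st$genera)),
            sprintf("Species_%d", seq_along(st$species)))

  paths <- NULL
  if (!is.null(dir)) {
    dir.create(dir, recursive = TRUE, showWarnings = FALSE)
    nodes_path <- file.path(dir, "nodes.dmp")
    names_path <- file.path(dir, "names.dmp")
    writeLines(sprintf("%d\t|\t%d\t|\t%s\t|", taxid, parent, rank), nodes_path)
    writeLines(sprintf("%d\t|\t%s\t|\t\t|\tscientific name\t|", taxid, name), names_path)
    paths <- list(nodes = nodes_path, names = names_path)
    tree <- load_taxdump(nodes_path, names_path)
  } else {
    key <- as.character(taxid)
    tree <- structure(list(parent = setNames(parent, key),
                           rank = setNames(rank, key),
                           name = setNames(name, key),
                           merged = setNames(integer(0), character(0)),
                           root_taxid = 1L),
                      class = "taxonomy_tree")
  }
  species_df <- data.frame(species_taxid = st$species,
                           genus_taxid = st$genus_of_species,
                           phylum_taxid = st$phylum_of_genus[match(st$genus_of_species, st$genera)],
                           stringsAsFactors = FALSE)
  c(list(tree = tree, species = species_df), paths)
}

random_dna <- function(n) {
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}

# Substitute each base independently with probability d, drawing the
# replacement uniformly from the three other bases.
mutate_seq <- function(seq, d) {
  if (d == 0) return(seq)
  bases <- strsplit(seq, "", fixed = TRUE)[[1L]]
  hit <- which(runif(length(bases)) < d)
  if (length(hit) > 0L) {
    alt <- list(A = c("C", "G", "T"), C = c("A", "G", "T"),
                G = c("A", "C", "T"), T = c("A", "C", "G"))
    bases[hit] <- vapply(bases[hit], function(b) sample(alt[[b]], 1L), "")
  }
  paste(bases, collapse = "")
}

#' Simulate genomes and a metadata table
#'
#' One random ancestral sequence per genus; each species is the ancestor
#' mutated at `species_divergence`, each strain (genome) is its species
#' sequence mutated at `strain_divergence`. Strains are assigned round-robin
#' to `config$years`. FASTA files (one per genome) and a metadata TSV in the
#' evaluation dialect are written under `dir`.
#'
#' @param taxonomy Output of [simulate_taxonomy()] for the same config.
#' @param config A [sim_config()].
#' @param dir Output directory.
#' @return Data.frame: `genome_id`, `species_taxid`, `release_date`,
#'   `release_year`, `fasta_path`; attribute `metadata_path`.
#' @export
simulate_genomes <- function(taxonomy, config, dir) {
  dir.create(file.path(dir, "genomes"), recursive = TRUE, showWarnings = FALSE)
  old <- .Random.seed_save(); on.exit(.Random.seed_restore(old))
  set.seed(config$seed)
  sp <- taxonomy$species
  genus_seq <- lapply(unique(sp$genus_taxid), function(g) random_dna(config$genome_length))
  names(genus_seq) <- unique(sp$genus_taxid)
  species_seq <- lapply(seq_len(nrow(sp)), function(i)
    mutate_seq(genus_seq[[as.character(sp$genus_taxid[i])]], config$species_divergence))

  rows <- list()
  g_idx <- 0L
  for (i in seq_len(nrow(sp))) {
    for (s in seq_len(config$strains_per_species)) {
      g_idx <- g_idx + 1L
      genome_id <- sprintf("G%d.%d", sp$species_taxid[i], s)
      strain <- mutate_seq(species_seq[[i]], config$strain_divergence)
      path <- file.path(dir, "genomes", paste0(genome_id, ".fasta"))
      writeLines(c(sprintf(">%s species_taxid=%d", genome_id, sp$species_taxid[i]),
                   strain), path)
      year <- config$years[(g_idx - 1L) %% length(config$years) + 1L]
      rows[[g_idx]] <- data.frame(genome_id = genome_id,
                                  species_taxid = sp$species_taxid[i],
                                  release_date = sprintf("%d/01/01", year),
                                  release_year = year,
                                  fasta_path = path, stringsAsFactors = FALSE)
    }
  }
  genomes <- do.call(rbind, rows)
  meta_path <- file.path(dir, "metadata.tsv")
  write.table(genomes[c("genome_id", "species_taxid", "release_date", "fasta_path")],
              meta_path, sep = "\t", quote = FALSE, row.names = FALSE)
  attr(genomes, "metadata_path") <- meta_path
  genomes
}

#' Simulate error-free reads from a genome
#'
#' Fixed-length substrings at uniform random start positions, no errors.
#' Headers carry the genome id and true species taxid for evaluation. By
#' default reads come from the forward strand only; `random_strand = TRUE`
#' reverse-complements each read with probability 1/2 (useful together with
#' canonical counting).
#'
#' @param genome Nucleotide string, or path to a genome FASTA (records are
#'   concatenated conceptually: reads are drawn from the first record).
#' @param n_reads Number of reads.
#' @param read_length Read length (must not exceed the genome length).
#' @param seed Integer seed.
#' @param genome_id,species_taxid Labels written into the headers.
#' @param random_strand Draw the strand uniformly instead of forward-only.
#' @param fasta_path If non-NULL, write the reads as FASTA here.
#' @return Named character vector of read sequences; names are read ids.
#'   Attributes `genome_id` and `species_taxid` map reads to their truth.
#' @export
simulate_reads <- function(genome, n_reads, read_length, seed,
                           genome_id = "genome", species_taxid = NA_integer_,
                           random_strand = FALSE, fasta_path = NULL) {
  if (file.exists(genome))
    genome <- as.character(Biostrings::readDNAStringSet(genome)[[1L]])
  L <- nchar(genome)
  if (read_length > L)
    stop(sprintf("read_length %d exceeds genome length %d", read_length, L), call. = FALSE)
  old <- .Random.seed_save(); on.exit(.Random.seed_restore(old))
  set.seed(seed)
  starts <- sample.int(L - read_length + 1L, n_reads, replace = TRUE)
  reads <- substring(genome, starts, starts + read_length - 1L)
  if (random_strand) {
    flip <- runif(n_reads) < 0.5
    if (any(flip)) reads[flip] <- revcomp(reads[flip])
  }
  ids <- sprintf("%s_r%04d", genome_id, seq_len(n_reads))
  names(reads) <- ids
  if (!is.null(fasta_path))
    writeLines(rbind(sprintf(">%s genome_id=%s species_taxid=%d",
                             ids, genome_id, species_taxid), reads),
               fasta_path)
  attr(reads, "genome_id") <- genome_id
  attr(reads, "species_taxid") <- species_taxid
  reads
}

#' Simulate a complete dataset
#'
#' Taxonomy + genomes + reads in one call: the one-stop fixture for the
#' evaluation experiments. Per-genome read seeds are derived from the master
#' seed, so the whole dataset is reproducible byte-for-byte.
#'
#' @param config A [sim_config()].
#' @param dir Output directory (default a fresh tempdir).
#' @param random_strand Passed to [simulate_reads()].
#' @return List: `config`, `dir`, `tree`, `species`, `genomes` (metadata
#'   data.frame), `reads` (named character vector over all genomes),
#'   `read_genome` (read_id -> genome_id), `truth` (read_id -> species
#'   taxid), `taxdump` (dmp paths).
#' @export
simulate_dataset <- function(config = sim_config(), dir = tempfile("simdata"),
                             random_strand = FALSE) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  tax <- simulate_taxonomy(config, file.path(dir, "taxdump"))
  genomes <- simulate_genomes(tax, config, dir)
  dir.create(file.path(dir, "reads"), showWarnings = FALSE)
  all_reads <- list(); read_genome <- list(); truth <- list()
  for (i in seq_len(nrow(genomes))) {
    r <- simulate_reads(genomes$fasta_path[i], config$reads_per_genome,
                        config$read_length, seed = config$seed + i,
                        genome_id = genomes$genome_id[i],
                        species_taxid = genomes$species_taxid[i],
                        random_strand = random_strand,
                        fasta_path = file.path(dir, "reads",
                                               paste0(genomes$genome_id[i], ".fasta")))
    all_reads[[i]] <- r
    read_genome[[i]] <- setNames(rep(genomes$genome_id[i], length(r)), names(r))
    truth[[i]] <- setNames(rep(genomes$species_taxid[i], length(r)), names(r))
  }
  list(config = config, dir = dir, tree = tax$tree, species = tax$species,
       genomes = genomes,
       reads = unlist(all_reads),
       read_genome = unlist(read_genome),
       truth = unlist(truth),
       taxdump = list(nodes = tax$nodes, names = tax$names))
}
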