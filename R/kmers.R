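#' Define a k-mer feature specification
#'
#' The feature space of the classifier: nucleotide words of length `k` over
#' A/C/G/T, so the total alphabet size is `K = 4^k`. With `canonical = TRUE`
#' a k-mer and its reverse complement are pooled under the lexicographically
#' smaller string (Jellyfish's `-C` behaviour); the default counts strands
#' separately.
#'
#' @param k Integer k-mer length, between 1 and 31.
#' @param canonical Logical; pool each k-mer with its reverse complement.
#' @return An object of class `kmer_spec`.
#' @export
#' @examples
#' kmer_spec(8)
kmer_spec <- function(k, canonical = FALSE) {
  if (length(k) != 1L || is.na(k) || k != as.integer(k) || k < 1L || k > 31L)
    stop("k must be a single integer in [1, 31]", call. = FALSE)
  structure(list(k = as.integer(k), canonical = isTRUE(canonical)),
            class = "kmer_spec")
}

#' @export
print.kmer_spec <- function(x, ...) {
  cat(sprintf("<kmer_spec> k = %d, canonical = %s\n", x$k, x$canonical))
  invisible(x)
}

spec_equal <- function(a, b) {
  a$k == b$k && a$canonical == b$canonical
}

stopifnot_spec <- function(spec) {
  if (!inherits(spec, "kmer_spec")) stop("not a kmer_spec", call. = FALSE)
}

new_kmer_table <- function(counts, spec) {
  counts <- counts[order(names(counts))]
  structure(list(spec = spec, counts = counts, total = sum(counts)),
            class = "kmer_table")
}

#' Count k-mers in nucleotide sequences
#'
#' Slides a window of length `spec$k` over each sequence and counts every
#' window consisting solely of A/C/G/T (input is uppercased first). Windows
#' containing any other character -- N, IUPAC ambiguity codes, gaps --
#' contribute nothing, so for a clean sequence of length L the total count is
#' exactly L - k + 1. Several sequences (e.g. the records of one genome
#' assembly) are pooled into a single table.
#'
#' @param sequence Character vector of nucleotide sequences, or a
#'   [Biostrings::DNAStringSet].
#' @param spec A [kmer_spec()].
#' @return A `kmer_table`: list with `spec`, a named numeric vector `counts`
#'   (keys sorted, all positive), and `total`, the sum of counts.
#' @export
#' @examples
#' count_kmers("ACGTA", kmer_spec(3))
count_kmers <- function(sequence, spec) {
  stopifnot_spec(spec)
  if (inherits(sequence, "XStringSet") || inherits(sequence, "XString"))
    sequence <- as.character(sequence)
  counts <- cpp_count_kmers(as.character(sequence), spec$k, spec$canonical)
  new_kmer_table(counts, spec)
}

#' @export
print.kmer_table <- function(x, ...) {
  cat(sprintf("<kmer_table> k = %d, canonical = %s, %d distinct k-mers, total %d\n",
              x$spec$k, x$spec$canonical, length(x$counts), as.integer(x$total)))
  invisible(x)
}

#' Merge two k-mer count tables
#'
#' Key-wise sum of two tables sharing the same spec; the algebraic primitive
#' behind incremental class updates. Commutative and associative.
#'
#' @param a,b `kmer_table` objects with identical specs.
#' @return A `kmer_table` with summed counts.
#' @export
merge_tables <- function(a, b) {
  if (!spec_equal(a$spec, b$spec))
    stop("incompatible k-mer tables: specs differ (k or canonical)", call. = FALSE)
  keys <- union(names(a$counts), names(b$counts))
  if (length(keys) == 0L) return(new_kmer_table(setNames(numeric(0), character(0)), a$spec))
  keys <- sort(keys)
  ca <- a$counts[keys]; ca[is.na(ca)] <- 0
  cb <- b$counts[keys]; cb[is.na(cb)] <- 0
  new_kmer_table(setNames(as.numeric(ca + cb), keys), a$spec)
}

#' Count k-mers shared between a read and a reference k-mer set
#'
#' The number of distinct valid k-mers of `read` that also occur in
#' `reference_kmers` -- the quantity used to dissect individual
#' classification calls (how many words of the read the class has seen).
#'
#' @param read A nucleotide string.
#' @param reference_kmers Character vector (or set) of k-mers, all of length
#'   `spec$k`.
#' @param spec A [kmer_spec()].
#' @return Integer cardinality of the intersection.
#' @export
shared_kmers <- function(read, reference_kmers, spec) {
  tab <- count_kmers(read, spec)
  length(intersect(names(tab$counts), as.character(reference_kmers)))
}

#' Count k-mers in a FASTA file
#'
#' Reads a (possibly multi-record) FASTA file with Biostrings and pools all
#' records into one table. Description lines are ignored for counting.
#'
#' @param path Path to a FASTA file.
#' @param spec A [kmer_spec()].
#' @return A `kmer_table`.
#' @export
count_fasta <- function(path, spec) {
  seqs <- Biostrings::readDNAStringSet(path)
  count_kmers(seqs, spec)
}

#' Import pre-computed k-mer counts (Jellyfish text-dump dialects)
#'
#' Accepts both text dump flavours: column format, lines of
#' `"<kmer> <count>"`, and FASTA-like format, `">count"` header lines each
#' followed by the k-mer.
#'
#' @param path Path to a text dump.
#' @param spec A [kmer_spec()]; k must match the dump's k-mer length.
#' @return A `kmer_table`.
#' @export
read_kmer_dump <- function(path, spec) {
  stopifnot_spec(spec)
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  if (length(lines) == 0L)
    return(new_kmer_table(setNames(numeric(0), character(0)), spec))
  if (startsWith(lines[[1L]], ">")) {
    if (length(lines) %% 2L != 0L)
      stop("malformed FASTA-like k-mer dump: odd number of lines", call. = FALSE)
    counts <- as.numeric(sub("^>", "", lines[c(TRUE, FALSE)]))
    kmers <- toupper(lines[c(FALSE, TRUE)])
  } else {
    parts <- strsplit(trimws(lines), "[ \t]+")
    kmers <- toupper(vapply(parts, `[[`, "", 1L))
    counts <- as.numeric(vapply(parts, `[[`, "", 2L))
  }
  if (anyNA(counts) || any(counts <= 0))
    stop("malformed k-mer dump: non-positive or unparseable counts", call. = FALSE)
  if (any(nchar(kmers) != spec$k))
    stop(sprintf("k-mer dump contains words of length != %d", spec$k), call. = FALSE)
  if (any(grepl("[^ACGT]", kmers)))
    stop("k-mer dump contains non-ACGT characters", call. = FALSE)
  if (anyDuplicated(kmers)) {
    counts <- tapply(counts, kmers, sum)
    kmers <- names(counts)
    counts <- as.numeric(counts)
  }
  new_kmer_table(setNames(counts, kmers), spec)
}

#' Reverse complement of nucleotide strings
#'
#' @param x Character vector of A/C/G/T strings.
#' @return Character vector of reverse complements.
#' @export
revcomp <- function(x) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAStringSet(x)))
}
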