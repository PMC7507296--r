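#' @title Rank-level abundance profiling
#' @description Species-level predictions are traced back to a chosen rank
#'   and turned into a relative-abundance vector; successive model versions
#'   of the same sample are compared with Bray-Curtis dissimilarity, and low
#'   abundance taxa can be pooled into "Others: Old" / "Others: New" bins for
#'   display.
#' @name profile
NULL

#' Relative-abundance profile at a taxonomic rank
#'
#' Each prediction's species taxid is traced to its ancestor at `rank`; the
#' abundance of a taxon is its read count divided by the total number of
#' reads. Reads whose lineage has no node at `rank` pool into
#' `unresolved_fraction`, so abundances + unresolved always sum to 1.
#'
#' @param predictions Data.frame with a `predicted_species` column (as
#'   returned by [classify_batchwise()]).
#' @param tree A `taxonomy_tree`.
#' @param rank Rank string, e.g. `"genus"`.
#' @return An `abundance_profile`: list with `rank`, named numeric
#'   `abundances` (taxid -> fraction), `n_reads`, `unresolved_fraction`.
#' @export
profile_from_predictions <- function(predictions, tree, rank) {
  if (nrow(predictions) == 0L) stop("no predictions to profile", call. = FALSE)
  anc <- ancestors_at_rank(tree, predictions$predicted_species, rank)
  n <- length(anc)
  unresolved <- sum(is.na(anc)) / n
  tab <- table(anc[!is.na(anc)])
  ab <- setNames(as.numeric(tab) / n, names(tab))
  structure(list(rank = rank, abundances = ab, n_reads = n,
                 unresolved_fraction = unresolved),
            class = "abundance_profile")
}

#' @export
print.abundance_profile <- function(x, ...) {
  cat(sprintf("<abundance_profile> rank %s: %d taxa over %d reads (%.1f%% unresolved)\n",
              x$rank, length(x$abundances), x$n_reads, 100 * x$unresolved_fraction))
  invisible(x)
}

#' Pool low-abundance taxa into "Others: Old" / "Others: New" bins
#'
#' Taxa with relative abundance strictly below `threshold` (default 5%) are
#' moved to the bin `"Others: New"` when they first appeared in the most
#' recent training division (`new_taxa`), else to `"Others: Old"`; taxa at or
#' above the threshold are kept verbatim. Total mass is conserved.
#'
#' @param profile An `abundance_profile`.
#' @param threshold Fraction in (0, 1]; default 0.05.
#' @param new_taxa Integer taxids first added in the latest training
#'   division.
#' @return The binned `abundance_profile`; the two bins appear under the
#'   names `"Others: Old"` and `"Others: New"` (present even when empty of
#'   mass only if they received any taxa).
#' @export
bin_others <- function(profile, threshold = 0.05, new_taxa = integer(0)) {
  if (length(threshold) != 1L || is.na(threshold) || threshold <= 0 || threshold > 1)
    stop("threshold must lie in (0, 1]", call. = FALSE)
  ab <- profile$abundances
  low <- ab < threshold
  kept <- ab[!low]
  if (any(low)) {
    is_new <- names(ab)[low] %in% as.character(new_taxa)
    if (any(is_new)) kept["Others: New"] <- sum(ab[low][is_new])
    if (any(!is_new)) kept["Others: Old"] <- sum(ab[low][!is_new])
  }
  out <- profile
  out$abundances <- kept
  out
}

#' Bray-Curtis dissimilarity between two profiles
#'
#' BC(p, q) = sum_t |p_t - q_t| / sum_t (p_t + q_t) over the union of the two
#' profiles' taxa (absent taxa count 0); all taxon labels enter, none are
#' pooled. For unit-sum relative-abundance vectors this equals half the L1
#' distance: 0 for identical composition, 1 for disjoint support. The
#' unresolved fraction is not a taxon and is excluded.
#'
#' @param p,q `abundance_profile`s at the same rank.
#' @return Dissimilarity in \[0, 1\].
#' @export
bray_curtis <- function(p, q) {
  if (!identical(p$rank, q$rank))
    stop("profiles are at different ranks", call. = FALSE)
  taxa <- union(names(p$abundances), names(q$abundances))
  if (length(taxa) == 0L) return(0)
  pv <- p$abundances[taxa]; pv[is.na(pv)] <- 0
  qv <- q$abundances[taxa]; qv[is.na(qv)] <- 0
  denom <- sum(pv + qv)
  if (denom == 0) return(0)
  sum(abs(pv - qv)) / denom
}

#' Write a profile as TSV
#'
#' Columns `rank`, `taxid`, `name`, `abundance`; taxa sorted by decreasing
#' abundance. Synthetic "Others" bins carry their bin label as both taxid and
#' name.
#'
#' @param profile An `abundance_profile`.
#' @param path Output TSV path.
#' @param tree Optional `taxonomy_tree` used to fill scientific names.
#' @export
write_profile <- function(profile, path, tree = NULL) {
  ab <- sort(profile$abundances, decreasing = TRUE)
  nm <- names(ab)
  sci <- if (!is.null(tree)) {
    vapply(nm, function(t) {
      if (t %in% names(tree$name)) tree$name[[t]] else t
    }, "")
  } else nm
  df <- data.frame(rank = profile$rank, taxid = nm, name = sci,
                   abundance = ab, stringsAsFactors = FALSE)
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
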