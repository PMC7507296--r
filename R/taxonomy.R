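#' @title NCBI-taxdump taxonomy handling
#' @description Parse nodes.dmp/names.dmp/merged.dmp and resolve ancestors at
#'   named ranks. Classification is done at species level only; genus, family,
#'   order, class and phylum results are obtained by tracing each species
#'   label back up this tree.
#' @name taxonomy
NULL

# The six ranks evaluated downstream, finest first.
TRACE_RANKS <- c("species", "genus", "family", "order", "class", "phylum")

split_dmp <- function(lines) {
  # NCBI dump dialect: fields delimited by "\t|\t", records end with "\t|"
  lines <- sub("\t\\|$", "", lines)
  strsplit(lines, "\t\\|\t")
}

#' Load an NCBI taxonomy dump
#'
#' Reads `nodes.dmp` (taxid, parent, rank), `names.dmp` (scientific names
#' only) and optionally `merged.dmp` (old taxid -> new taxid) in the exact
#' dialect of NCBI's taxdump.tar.gz. The tree is validated: every parent must
#' exist and every node's parent chain must terminate at the root.
#'
#' @param nodes_path,names_path,merged_path Paths to the dump files;
#'   `merged_path` may be `NULL`.
#' @return A `taxonomy_tree`: named vectors `parent`, `rank`, `name` keyed by
#'   taxid, `merged` (old -> new), and `root_taxid`.
#' @export
load_taxdump <- function(nodes_path, names_path, merged_path = NULL) {
  nf <- split_dmp(readLines(nodes_path))
  taxid <- as.integer(vapply(nf, `[[`, "", 1L))
  parent <- as.integer(vapply(nf, `[[`, "", 2L))
  rank <- vapply(nf, `[[`, "", 3L)
  if (anyNA(taxid) || anyNA(parent))
    stop("nodes.dmp: unparseable taxid fields", call. = FALSE)
  if (anyDuplicated(taxid))
    stop("nodes.dmp: duplicated taxid", call. = FALSE)

  key <- as.character(taxid)
  parent_map <- setNames(parent, key)
  rank_map <- setNames(rank, key)

  missing_parent <- setdiff(parent, taxid)
  if (length(missing_parent) > 0L)
    stop(sprintf("nodes.dmp: parent taxid %s not present in tree",
                 paste(missing_parent, collapse = ", ")), call. = FALSE)

  # root: the (unique) node that is its own parent
  root <- taxid[taxid == parent]
  if (length(root) != 1L)
    stop(sprintf("nodes.dmp: expected exactly one self-parent root, found %d",
                 length(root)), call. = FALSE)

  # cycle check: walk each chain; chains longer than the node count loop
  n <- length(taxid)
  for (t in taxid) {
    cur <- t
    steps <- 0L
    while (cur != root) {
      cur <- parent_map[[as.character(cur)]]
      steps <- steps + 1L
      if (steps > n)
        stop(sprintf("nodes.dmp: cycle detected at taxid %d", t), call. = FALSE)
    }
  }

  name_map <- setNames(character(length(taxid)), key)
  if (!is.null(names_path)) {
    lf <- split_dmp(readLines(names_path))
    cls <- vapply(lf, function(x) if (length(x) >= 4L) x[[4L]] else "", "")
    sci <- lf[trimws(cls) == "scientific name"]
    if (length(sci) > 0L) {
      ids <- vapply(sci, `[[`, "", 1L)
      nm <- vapply(sci, `[[`, "", 2L)
      keep <- ids %in% key
      name_map[ids[keep]] <- nm[keep]
    }
  }

  merged <- setNames(integer(0), character(0))
  if (!is.null(merged_path) && file.exists(merged_path)) {
    mf <- split_dmp(readLines(merged_path))
    if (length(mf) > 0L) {
      old <- as.integer(vapply(mf, `[[`, "", 1L))
      new <- as.integer(vapply(mf, `[[`, "", 2L))
      # resolve transitively so every merged value is a live node
      for (i in seq_along(new)) {
        seen <- integer(0)
        while (!(new[i] %in% taxid)) {
          j <- match(new[i], old)
          if (is.na(j) || new[i] %in% seen)
            stop(sprintf("merged.dmp: %d merges into missing taxid %d",
                         old[i], new[i]), call. = FALSE)
          seen <- c(seen, new[i])
          new[i] <- new[j]
        }
      }
      merged <- setNames(new, as.character(old))
    }
  }

  structure(list(parent = parent_map, rank = rank_map, name = name_map,
                 merged = merged, root_taxid = root),
            class = "taxonomy_tree")
}

#' @export
print.taxonomy_tree <- function(x, ...) {
  cat(sprintf("<taxonomy_tree> %d nodes, %d merged ids, root %d\n",
              length(x$parent), length(x$merged), x$root_taxid))
  invisible(x)
}

#' Resolve a taxid through the merged-id map
#'
#' @param tree A `taxonomy_tree`.
#' @param taxid Integer taxid, possibly an old merged-away id.
#' @return The live taxid.
#' @export
resolve_taxid <- function(tree, taxid) {
  key <- as.character(taxid)
  if (key %in% names(tree$parent)) return(as.integer(taxid))
  if (key %in% names(tree$merged)) return(unname(tree$merged[[key]]))
  stop(sprintf("taxid %s is absent from the taxonomy (neither a node nor a merged id)",
               key), call. = FALSE)
}

#' Ancestor of a taxid at a named rank
#'
#' Walks the parent chain (after merged-id resolution) and returns the first
#' node whose rank equals `rank`; a node queried at its own rank returns
#' itself. Returns `NA` if the chain reaches the root without a match --
#' NCBI lineages are rank-sparse, and downstream evaluation counts such reads
#' as unresolved at that rank.
#'
#' @param tree A `taxonomy_tree`.
#' @param taxid Integer taxid.
#' @param rank Rank string (e.g. "genus").
#' @return Integer taxid or `NA_integer_`.
#' @export
ancestor_at_rank <- function(tree, taxid, rank) {
  cur <- resolve_taxid(tree, taxid)
  repeat {
    key <- as.character(cur)
    if (tree$rank[[key]] == rank) return(cur)
    if (cur == tree$root_taxid) return(NA_integer_)
    cur <- unname(tree$parent[[key]])
  }
}

#' Species-rank taxid of a node
#'
#' Returns `taxid` itself when it is species-rank, its species ancestor when
#' it sits below species (strains, "no rank" children), and `NA` when no
#' species ancestor exists.
#'
#' @inheritParams ancestor_at_rank
#' @return Integer species taxid or `NA_integer_`.
#' @export
species_of <- function(tree, taxid) {
  ancestor_at_rank(tree, taxid, "species")
}

# Vectorised trace-back used by evaluation/profiling; taxids may repeat, so
# look each distinct id up once.
ancestors_at_rank <- function(tree, taxids, rank) {
  u <- unique(taxids)
  anc <- vapply(u, function(t) ancestor_at_rank(tree, t, rank), integer(1))
  anc[match(taxids, u)]
}
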