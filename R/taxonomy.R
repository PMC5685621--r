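## Gold-standard tree generation from rank-string taxonomy tables.

#' Build the taxonomy gold-standard tree
#'
#' Walks the taxonomy level by level (domain, phylum, ...), grouping
#' sequences that share the same label path. Every distinct named taxon
#' becomes an internal node (keyed by its full path, so an identical genus
#' name under two families yields two nodes); empty rank labels create no
#' node, so sequences attach at their deepest named ancestor; unary chains
#' (nodes with a single child and no directly attached leaves) are
#' collapsed. Child order is lexicographic, making the output
#' deterministic. The tree carries no branch lengths.
#'
#' @param tax Named list of rank-label character vectors (see
#'   [read_taxonomy()]); >= 2 sequences.
#' @return Rooted multifurcating `ape::phylo`; leaves are the sequence IDs,
#'   internal node labels the taxon names.
#' @export
taxonomy_to_tree <- function(tax) {
  ids <- names(tax)
  if (is.null(ids) || length(ids) < 2L) stop("need >= 2 sequences with IDs")
  if (anyDuplicated(ids)) stop("duplicate sequence ID(s): ",
                               paste(unique(ids[duplicated(ids)]), collapse = ", "))
  depth <- max(lengths(tax))
  tax <- lapply(tax, function(r) c(r, rep("", depth - length(r))))

  quote_lab <- function(x) {
    if (grepl("[ ()\\[\\]:;,']", x)) paste0("'", gsub("'", "''", x), "'") else x
  }

  # returns list(text = newick fragment or leaf, n_items): renders the
  # subtree for `idx` sequences from rank `level` under an already-named node
  render <- function(idx, level) {
    if (level > depth) {
      return(vapply(sort(ids[idx], method = "radix"), quote_lab, "",
                    USE.NAMES = FALSE))
    }
    labels_here <- vapply(idx, function(i) tax[[i]][level], "")
    parts <- character(0)
    # empty label at this level: descend without creating a node
    empty <- idx[labels_here == ""]
    if (length(empty) > 0L) parts <- c(parts, render(empty, level + 1L))
    for (lab in sort(unique(labels_here[labels_here != ""]), method = "radix")) {
      sub <- idx[labels_here == lab]
      kids <- render(sub, level + 1L)
      if (length(kids) == 1L) {
        # unary chain: collapse the named node
        parts <- c(parts, kids)
      } else {
        parts <- c(parts, paste0("(", paste(kids, collapse = ","), ")", quote_lab(lab)))
      }
    }
    parts
  }

  top <- render(seq_along(ids), 1L)
  nwk <- if (length(top) == 1L) {
    frag <- top[[1L]]
    if (!startsWith(frag, "(")) stop("degenerate taxonomy: single leaf")
    paste0(frag, ";")
  } else {
    paste0("(", paste(top, collapse = ","), ");")
  }
  read_newick(nwk)
}

#' Distance of an inferred tree from the taxonomy gold standard
#'
#' Builds the taxonomy tree with [taxonomy_to_tree()] and compares the
#' inferred tree to it; smaller values indicate better recovery of the
#' taxonomic structure.
#'
#' @param inferred `ape::phylo` tree whose leaves are the sequence IDs.
#' @param tax Taxonomy table (same IDs).
#' @param metric `"rf"` (Robinson-Foulds count, default), `"rfn"`
#'   (normalized RF) or `"bs"` (branch score).
#' @return Numeric distance.
#' @export
gold_standard_distance <- function(inferred, tax, metric = c("rf", "rfn", "bs")) {
  metric <- match.arg(metric)
  gold <- taxonomy_to_tree(tax)
  switch(metric,
    rf  = robinson_foulds(inferred, gold),
    rfn = robinson_foulds(inferred, gold, normalized = TRUE),
    bs  = branch_score(inferred, gold))
}
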