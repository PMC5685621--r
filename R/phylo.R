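## Tree machinery: deterministic neighbor joining, bipartition views, and
## tree-to-tree distances (Robinson-Foulds, branch score).

fmt_len <- function(x) sprintf("%.10g", x)

#' Neighbor joining with deterministic tie-breaking
#'
#' Standard Saitou-Nei agglomeration with the Studier-Keppler Q criterion.
#' Ties in the Q matrix are broken by the lexicographically smallest
#' (row label, column label) pair (cluster label = smallest leaf label it
#' contains), so the output is bit-reproducible. Negative intermediate
#' branch lengths are clamped to 0.
#'
#' @param dm Distance matrix over >= 3 taxa (see [as_distance_matrix()]).
#' @return Unrooted `ape::phylo` tree with branch lengths.
#' @export
neighbor_joining <- function(dm) {
  dm <- as_distance_matrix(dm)
  if (!all(is.finite(dm))) stop("non-finite entries in distance matrix")
  n <- nrow(dm)
  if (n < 3L) stop("neighbor joining requires >= 3 taxa")
  labs <- rownames(dm)
  frag <- labs          # newick fragment per active cluster
  cname <- labs         # smallest leaf label per cluster (tie-breaking key)
  d <- unname(dm)
  while (n > 3L) {
    r <- rowSums(d)
    Q <- (n - 2) * d - outer(r, r, `+`)
    diag(Q) <- Inf
    qmin <- min(Q)
    cand <- which(Q <= qmin + 1e-12, arr.ind = TRUE)
    cand <- cand[cand[, 1L] < cand[, 2L], , drop = FALSE]
    pick <- order(cname[cand[, 1L]], cname[cand[, 2L]], method = "radix")[1L]
    i <- cand[pick, 1L]; j <- cand[pick, 2L]
    bi <- d[i, j] / 2 + (r[i] - r[j]) / (2 * (n - 2))
    bj <- d[i, j] - bi
    bi <- max(0, bi); bj <- max(0, bj)
    newfrag <- paste0("(", frag[i], ":", fmt_len(bi), ",", frag[j], ":", fmt_len(bj), ")")
    dnew <- (d[i, ] + d[j, ] - d[i, j]) / 2
    keep <- setdiff(seq_len(n), c(i, j))
    d2 <- rbind(cbind(d[keep, keep, drop = FALSE], dnew[keep]), c(dnew[keep], 0))
    frag <- c(frag[keep], newfrag)
    cname <- c(cname[keep], min(cname[c(i, j)]))
    d <- d2
    n <- n - 1L
  }
  b1 <- max(0, (d[1, 2] + d[1, 3] - d[2, 3]) / 2)
  b2 <- max(0, (d[1, 2] + d[2, 3] - d[1, 3]) / 2)
  b3 <- max(0, (d[1, 3] + d[2, 3] - d[1, 2]) / 2)
  nwk <- paste0("(", frag[1], ":", fmt_len(b1), ",", frag[2], ":", fmt_len(b2),
                ",", frag[3], ":", fmt_len(b3), ");")
  read_newick(nwk)
}

## edges x leaves logical matrix: TRUE if the leaf lies below the edge
## (on the child side); rows follow tree$edge order
edge_leaf_matrix <- function(tree) {
  nt <- length(tree$tip.label)
  nn <- max(tree$edge)
  below <- matrix(FALSE, nn, nt)
  below[cbind(seq_len(nt), seq_len(nt))] <- TRUE
  eo <- stats::reorder(tree, "postorder")$edge
  for (e in seq_len(nrow(eo))) {
    below[eo[e, 1L], ] <- below[eo[e, 1L], ] | below[eo[e, 2L], ]
  }
  m <- below[tree$edge[, 2L], , drop = FALSE]
  colnames(m) <- tree$tip.label
  m
}

bip_key <- function(labels) paste(sort(labels), collapse = "\r")

## per-edge bipartition table of the unrooted tree: canonical side is the
## one NOT containing the lexicographically smallest leaf. Lengths are
## aggregated by bipartition (the two root edges of a rooted tree merge).
bipartition_table <- function(tree) {
  tree <- ape::unroot(tree)
  labs <- tree$tip.label
  nt <- length(labs)
  B <- edge_leaf_matrix(tree)
  ref <- sort(labs)[1L]
  refcol <- match(ref, labs)
  lens <- tree$edge.length
  if (is.null(lens)) lens <- rep(0, nrow(B))
  lens[is.na(lens)] <- 0
  keys <- character(nrow(B))
  sizes <- integer(nrow(B))
  for (e in seq_len(nrow(B))) {
    side <- B[e, ]
    if (side[refcol]) side <- !side
    keys[e] <- bip_key(labs[side])
    sizes[e] <- sum(side)
  }
  agg <- tapply(lens, keys, sum)
  key <- names(agg)
  size <- sizes[match(key, keys)]
  data.frame(key = key, length = as.numeric(agg),
             trivial = size < 2L | size > nt - 2L,
             stringsAsFactors = FALSE)
}

#' Non-trivial bipartitions of a tree
#'
#' One bipartition per internal branch of the unrooted tree; trivial
#' bipartitions (splitting off a single leaf) are excluded. Each
#' bipartition is represented canonically by the leaf set on the side not
#' containing the lexicographically smallest leaf, encoded as a sorted,
#' `"\r"`-joined label string.
#'
#' @param tree An `ape::phylo` tree.
#' @return Character vector of canonical bipartition keys.
#' @export
bipartitions <- function(tree) {
  bt <- bipartition_table(tree)
  bt$key[!bt$trivial]
}

#' Decode a bipartition key back to its leaf labels
#' @param key Canonical key as produced by [bipartitions()].
#' @return Character vector of leaf labels.
#' @export
bipartition_leaves <- function(key) strsplit(key, "\r", fixed = TRUE)[[1L]]

check_same_leaves <- function(t1, t2) {
  l1 <- sort(t1$tip.label); l2 <- sort(t2$tip.label)
  if (!identical(l1, l2)) {
    only1 <- setdiff(l1, l2); only2 <- setdiff(l2, l1)
    stop("leaf sets differ; only in tree 1: {",
         paste(only1, collapse = ", "), "}; only in tree 2: {",
         paste(only2, collapse = ", "), "}")
  }
}

#' Robinson-Foulds distance
#'
#' Size of the symmetric difference of the two trees' non-trivial
#' bipartition sets. `normalized = TRUE` divides by `2(N - 3)`, the maximum
#' for two binary trees on `N` leaves.
#'
#' @param t1,t2 `ape::phylo` trees on the same leaf set.
#' @param normalized Report the normalized variant.
#' @return Non-negative count (or fraction if normalized).
#' @export
robinson_foulds <- function(t1, t2, normalized = FALSE) {
  check_same_leaves(t1, t2)
  b1 <- bipartitions(t1); b2 <- bipartitions(t2)
  rf <- length(setdiff(b1, b2)) + length(setdiff(b2, b1))
  if (normalized) {
    nt <- length(t1$tip.label)
    if (nt <= 3L) return(0)
    rf <- rf / (2 * (nt - 3))
  }
  rf
}

#' Branch-score distance
#'
#' Square root of the sum over the union of the two trees' bipartitions
#' (trivial ones included, since pendant branches carry length) of the
#' squared difference in branch length; a bipartition absent from a tree
#' contributes that tree's length as 0, and missing lengths count as 0.
#'
#' @inheritParams robinson_foulds
#' @return Non-negative numeric distance.
#' @export
branch_score <- function(t1, t2) {
  check_same_leaves(t1, t2)
  bt1 <- bipartition_table(t1); bt2 <- bipartition_table(t2)
  keys <- union(bt1$key, bt2$key)
  l1 <- bt1$length[match(keys, bt1$key)]; l1[is.na(l1)] <- 0
  l2 <- bt2$length[match(keys, bt2$key)]; l2[is.na(l2)] <- 0
  sqrt(sum((l1 - l2)^2))
}
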