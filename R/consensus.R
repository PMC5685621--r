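## Consensus ensemble: majority-rule (extended) consensus, deterministic
## multifurcation resolution, weighted non-negative least-squares branch
## fitting, and branch-length averaging across methods.

## clades are leaf-label character vectors, all excluding the global
## smallest leaf (canonical bipartition sides), so two clades are
## compatible iff disjoint or nested
clades_compatible <- function(a, b) {
  inter <- length(intersect(a, b))
  inter == 0L || inter == length(a) || inter == length(b)
}

## build a rooted multifurcating tree from a laminar family of clades,
## rooted at the lexicographically smallest leaf's side
build_tree_from_clades <- function(labs, clades, support = NULL) {
  nt <- length(labs)
  ord <- order(lengths(clades), decreasing = TRUE)
  clades <- clades[ord]
  if (!is.null(support)) support <- support[ord]
  nclade <- length(clades)
  parent_of_clade <- integer(nclade)   # 0 = root
  for (i in seq_len(nclade)) {
    parent_of_clade[i] <- 0L
    if (i > 1L) for (j in (i - 1L):1L) {
      if (all(clades[[i]] %in% clades[[j]])) { parent_of_clade[i] <- j; break }
    }
  }
  parent_of_leaf <- integer(nt)        # 0 = root
  for (t in seq_len(nt)) {
    parent_of_leaf[t] <- 0L
    if (nclade > 0L) for (j in nclade:1L) {
      if (labs[t] %in% clades[[j]]) { parent_of_leaf[t] <- j; break }
    }
  }
  render <- function(node) {
    kids_c <- which(parent_of_clade == node)
    if (node > 0L) kids_c <- kids_c[kids_c != node]
    kids_l <- which(parent_of_leaf == node)
    parts <- c(
      vapply(kids_l, function(t) labs[t], ""),
      vapply(kids_c, render, "")
    )
    # deterministic order: by smallest descendant label
    first_lab <- c(labs[kids_l], vapply(kids_c, function(j) min(clades[[j]]), ""))
    parts <- parts[order(first_lab, method = "radix")]
    lab <- if (node > 0L && !is.null(support)) sprintf("%.4g", support[node]) else ""
    paste0("(", paste(parts, collapse = ","), ")", lab)
  }
  read_newick(paste0(render(0L), ";"))
}

#' Majority-rule (extended) consensus tree
#'
#' Bipartitions occurring in more than `threshold` of the input trees are
#' retained; with `extended = TRUE` (the PHYLIP CONSENSE default behaviour)
#' the remaining bipartitions are then added greedily in order of
#' decreasing frequency (ties broken by canonical bipartition key) whenever
#' compatible with the set built so far. The result may be multifurcating.
#'
#' @param trees List of >= 2 `ape::phylo` trees on the same leaf set.
#' @param threshold Retention frequency threshold (strict; default 0.5).
#' @param extended Greedily add compatible minority bipartitions.
#' @return Object of class `consensus_tree`: list with `tree` (`phylo`,
#'   support values as internal node labels) and `support` (named numeric,
#'   frequency per retained bipartition key).
#' @export
majority_consensus <- function(trees, threshold = 0.5, extended = TRUE) {
  if (length(trees) < 2L) stop("need >= 2 trees")
  labs <- sort(trees[[1L]]$tip.label)
  for (t in trees[-1L]) check_same_leaves(trees[[1L]], t)
  ntree <- length(trees)
  all_bips <- unlist(lapply(trees, bipartitions))
  if (length(all_bips) == 0L) {
    tree <- build_tree_from_clades(labs, list())
    return(structure(list(tree = tree, support = numeric(0)), class = "consensus_tree"))
  }
  tab <- table(all_bips)
  freq <- as.numeric(tab) / ntree
  keys <- names(tab)
  ord <- order(-freq, keys, method = "radix")
  keys <- keys[ord]; freq <- freq[ord]
  keep <- freq > threshold
  retained <- keys[keep]
  ret_freq <- freq[keep]
  if (extended) {
    ret_clades <- lapply(retained, bipartition_leaves)
    for (idx in which(!keep)) {
      cl <- bipartition_leaves(keys[idx])
      if (all(vapply(ret_clades, clades_compatible, TRUE, b = cl))) {
        retained <- c(retained, keys[idx])
        ret_freq <- c(ret_freq, freq[idx])
        ret_clades <- c(ret_clades, list(cl))
      }
    }
  }
  clades <- lapply(retained, bipartition_leaves)
  tree <- build_tree_from_clades(labs, clades, support = ret_freq)
  support <- ret_freq
  names(support) <- retained
  structure(list(tree = tree, support = support), class = "consensus_tree")
}

#' @export
print.consensus_tree <- function(x, ...) {
  cat("Consensus tree with", length(x$tree$tip.label), "leaves and",
      length(x$support), "retained bipartitions\n")
  if (length(x$support) > 0L)
    cat("support range:", min(x$support), "-", max(x$support), "\n")
  invisible(x)
}

## smallest leaf label below each node (for deterministic child ordering)
min_desc_label <- function(tree) {
  nt <- length(tree$tip.label)
  nn <- max(tree$edge)
  md <- rep(NA_character_, nn)
  md[seq_len(nt)] <- tree$tip.label
  eo <- stats::reorder(tree, "postorder")$edge
  for (e in seq_len(nrow(eo))) {
    p <- eo[e, 1L]; ch <- eo[e, 2L]
    md[p] <- if (is.na(md[p])) md[ch] else min(md[p], md[ch])
  }
  md
}

#' Resolve multifurcations into zero-length binary branches
#'
#' Every polytomy is replaced by a deterministic caterpillar over its
#' children, ordered by smallest descendant leaf label; all inserted
#' branches have length 0, so patristic distances and positive-length
#' bipartitions are unchanged. The `seed` argument is accepted for API
#' stability but ignored: the resolution is deterministic.
#'
#' @param tree An `ape::phylo` tree (rooted or unrooted, any degree).
#' @param seed Ignored (resolution is deterministic).
#' @return A strictly binary rooted `ape::phylo` tree.
#' @export
resolve_multifurcations <- function(tree, seed = NULL) {
  nt <- length(tree$tip.label)
  if (nt < 2L) stop("tree must have >= 2 leaves")
  root <- unique(tree$edge[!(tree$edge[, 1L] %in% tree$edge[, 2L]), 1L])
  kids <- split(seq_len(nrow(tree$edge)), tree$edge[, 1L])
  md <- min_desc_label(tree)
  has_len <- !is.null(tree$edge.length)
  render <- function(node, blen) {
    suffix <- if (is.na(blen)) "" else paste0(":", fmt_len(blen))
    if (node <= nt) return(paste0(tree$tip.label[node], suffix))
    erows <- kids[[as.character(node)]]
    ch <- tree$edge[erows, 2L]
    lens <- if (has_len) tree$edge.length[erows] else rep(NA_real_, length(erows))
    ord <- order(md[ch], method = "radix")
    ch <- ch[ord]; lens <- lens[ord]
    parts <- mapply(render, ch, lens)
    zero <- if (has_len) ":0" else ""   # inserted branches are zero-length
    while (length(parts) > 2L) {
      joined <- paste0("(", parts[1L], ",", parts[2L], ")", zero)
      parts <- c(joined, parts[-(1:2)])
    }
    paste0("(", paste(parts, collapse = ","), ")", suffix)
  }
  read_newick(paste0(render(root, NA_real_), ";"))
}

## Lawson-Hanson non-negative least squares on precomputed normal
## equations: min ||A x - b||, x >= 0. The active-set subproblems are small
## (one linear solve on the passive set), so large path-incidence systems
## stay tractable.
nnls_solve <- function(A, b, tol = 1e-10) {
  AtA <- crossprod(A)
  Atb <- drop(crossprod(A, b))
  p <- length(Atb)
  x <- numeric(p)
  passive <- logical(p)
  wtol <- tol * max(1, max(abs(Atb)))
  w <- Atb
  iter <- 0L
  while (any(!passive & w > wtol) && iter < 10L * p) {
    iter <- iter + 1L
    j <- which(!passive)[which.max(w[!passive])]
    passive[j] <- TRUE
    repeat {
      z <- numeric(p)
      fit <- tryCatch(
        solve(AtA[passive, passive, drop = FALSE], Atb[passive]),
        error = function(e) stop("singular least-squares system"))
      z[passive] <- fit
      if (all(z[passive] > tol)) { x <- z; break }
      neg <- passive & z <= tol
      alpha <- min(x[neg] / (x[neg] - z[neg]))
      x <- x + alpha * (z - x)
      passive[passive & x <= tol] <- FALSE
      x[!passive] <- 0
    }
    w <- Atb - drop(AtA %*% x)
  }
  x
}

## path incidence: pairs (i<j in labs order) x edges of the unrooted tree;
## an edge lies on the path between i and j iff exactly one of them is
## below it
path_incidence <- function(tree, labs) {
  B <- edge_leaf_matrix(tree)
  idx <- match(labs, colnames(B))
  pairs <- which(upper.tri(diag(length(labs))), arr.ind = TRUE)
  Bt <- t(B) * 1
  A <- abs(Bt[idx[pairs[, 1L]], , drop = FALSE] -
           Bt[idx[pairs[, 2L]], , drop = FALSE])
  list(A = A, pairs = pairs)
}

#' Weighted least-squares branch lengths on a fixed topology
#'
#' Estimates branch lengths minimising
#' `sum_{i<j} (d_ij - p_ij)^2 / d_ij^power` (with `p` the patristic
#' distance) subject to non-negativity, via non-negative least squares on
#' the path-incidence system — the Fitch-Margoliash criterion at
#' `power = 2`. Pairs with `d = 0` take their weight from the smallest
#' positive distance instead.
#'
#' @param topology `ape::phylo` tree; internally unrooted. Leaves must match
#'   `dm` labels.
#' @param dm Distance matrix on the same labels.
#' @param power Weighting exponent, one of 0, 1, 2 (default 2).
#' @return The unrooted topology with fitted `edge.length`.
#' @export
ls_branch_lengths <- function(topology, dm, power = 2) {
  dm <- as_distance_matrix(dm)
  tree <- ape::unroot(topology)
  if (!setequal(tree$tip.label, rownames(dm)))
    stop("tree leaves and distance matrix labels differ")
  if (!(power %in% c(0, 1, 2))) stop("power must be 0, 1 or 2")
  labs <- rownames(dm)
  pi <- path_incidence(tree, labs)
  d <- dm[pi$pairs]
  wbase <- d
  if (any(wbase <= 0)) {
    pos <- wbase[wbase > 0]
    if (length(pos) == 0L) pos <- 1
    wbase[wbase <= 0] <- min(pos)
  }
  w <- wbase^(-power)
  sw <- sqrt(w)
  lens <- nnls_solve(pi$A * sw, d * sw)
  tree$edge.length <- lens
  tree
}

#' Consensus ensemble with averaged branch lengths
#'
#' The full ensemble pipeline: majority-rule (extended) consensus of the
#' method trees, deterministic resolution of multifurcations with
#' zero-length branches, a weighted least-squares branch-length fit of the
#' common topology against each method's distance matrix, and per-branch
#' arithmetic averaging of the fitted lengths.
#'
#' @param trees List of `ape::phylo` trees (one per method).
#' @param dms List of distance matrices, one per method, same leaf sets.
#' @param threshold,extended Passed to [majority_consensus()].
#' @param power Passed to [ls_branch_lengths()].
#' @return Unrooted `ape::phylo` tree with averaged branch lengths.
#' @export
ensemble_consensus <- function(trees, dms, threshold = 0.5, extended = TRUE,
                               power = 2) {
  if (length(trees) != length(dms))
    stop("need one distance matrix per tree")
  cons <- majority_consensus(trees, threshold = threshold, extended = extended)
  bin <- resolve_multifurcations(cons$tree)
  fits <- lapply(dms, function(dm) ls_branch_lengths(bin, dm, power = power))
  out <- fits[[1L]]
  lens <- vapply(fits, function(t) t$edge.length, numeric(length(out$edge.length)))
  out$edge.length <- rowMeans(as.matrix(lens))
  out
}
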