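# Independent oracles, deliberately naive: they share no code path with the
# package implementations they check.

# O(n^2 * m) matching statistics by per-position extension
ms_brute <- function(x, y) {
  xc <- strsplit(toupper(x), "")[[1]]
  yc <- strsplit(toupper(y), "")[[1]]
  xc[!xc %in% c("A", "C", "G", "T")] <- "N"
  yc[!yc %in% c("A", "C", "G", "T")] <- "N"
  n <- length(xc); m <- length(yc)
  vapply(seq_len(n), function(i) {
    best <- 0L
    for (j in seq_len(m)) {
      t <- 0L
      while (i + t <= n && j + t <= m &&
             xc[i + t] != "N" && xc[i + t] == yc[j + t]) {
        t <- t + 1L
      }
      if (t > best) best <- t
    }
    best
  }, integer(1))
}

random_dna <- function(len, alphabet = c("A", "C", "G", "T")) {
  paste(sample(alphabet, len, replace = TRUE), collapse = "")
}

random_seq_set <- function(n, len, prefix = "s") {
  out <- vapply(seq_len(n), function(i) random_dna(len), "")
  names(out) <- paste0(prefix, seq_len(n))
  out
}

# random tree with positive branch lengths; its cophenetic matrix is additive
random_additive <- function(n_taxa) {
  tree <- ape::rtree(n_taxa)
  tree$edge.length <- runif(nrow(tree$edge), 0.1, 2)
  dm <- as_distance_matrix(stats::cophenetic(tree))
  list(tree = tree, dm = dm)
}

# brute-force non-trivial bipartitions: drop each internal edge of the
# unrooted tree and collect the two leaf components by BFS on an adjacency
# list (canonicalized the same way as the package: side without the
# lexicographically smallest leaf, sorted, "\r"-joined)
bips_oracle <- function(tree) {
  tree <- ape::unroot(tree)
  nt <- length(tree$tip.label)
  edges <- tree$edge
  adj <- vector("list", max(edges))
  for (e in seq_len(nrow(edges))) {
    a <- edges[e, 1]; b <- edges[e, 2]
    adj[[a]] <- c(adj[[a]], b)
    adj[[b]] <- c(adj[[b]], a)
  }
  ref <- sort(tree$tip.label)[1]
  keys <- character(0)
  for (e in seq_len(nrow(edges))) {
    a <- edges[e, 1]; b <- edges[e, 2]
    if (b <= nt) next                      # pendant edge: trivial
    # BFS from b avoiding the dropped edge (a, b)
    seen <- b; queue <- b
    while (length(queue) > 0) {
      v <- queue[1]; queue <- queue[-1]
      for (w in adj[[v]]) {
        if ((v == b && w == a) || (v == a && w == b)) next
        if (!(w %in% seen)) { seen <- c(seen, w); queue <- c(queue, w) }
      }
    }
    side <- tree$tip.label[seen[seen <= nt]]
    if (length(side) < 2 || length(side) > nt - 2) next
    if (ref %in% side) side <- setdiff(tree$tip.label, side)
    keys <- c(keys, paste(sort(side), collapse = "\r"))
  }
  unique(keys)
}

patristic <- function(tree) as_distance_matrix(stats::cophenetic(tree))

expect_same_matrix <- function(a, b, tol = 1e-9) {
  labs <- rownames(a)
  expect_true(setequal(labs, rownames(b)))
  expect_lt(max(abs(a[labs, labs] - b[labs, labs])), tol)
}
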