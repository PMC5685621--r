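## Phylogeny-aware community statistics: weighted UniFrac, PCoA,
## group-centering, and PERMANOVA (one-factor, strata, sequential).

root_for_unifrac <- function(tree) {
  if (is.null(tree$edge.length)) stop("weighted UniFrac requires branch lengths")
  if (!ape::is.rooted(tree)) tree <- phangorn::midpoint(tree)
  tree
}

unifrac_fractions <- function(tree, x) {
  tips <- tree$tip.label
  bad <- setdiff(names(x), tips)
  if (length(bad) > 0L)
    stop("abundance label(s) not in tree: ", paste(bad, collapse = ", "))
  tot <- sum(x)
  if (!is.finite(tot) || tot <= 0) stop("abundance vector must have positive total")
  v <- numeric(length(tips)); names(v) <- tips
  v[names(x)] <- x / tot
  v
}

#' Weighted UniFrac distance between two communities
#'
#' `raw = sum_b l_b * |p_A(b) - p_B(b)|` over the branches of the rooted
#' tree, where `p_X(b)` is the fraction of community X's total abundance on
#' the leaves below branch `b`. The normalized variant divides by
#' `sum_b l_b * (p_A(b) + p_B(b))`. Unrooted trees are midpoint-rooted
#' first (root placement affects the raw value, so the rule is fixed).
#' Leaves absent from an abundance vector count as zero.
#'
#' @param tree `ape::phylo` with branch lengths.
#' @param a,b Named non-negative abundance vectors; names must be leaf
#'   labels; positive totals.
#' @param normalized Return the normalized variant.
#' @return Non-negative numeric distance.
#' @export
weighted_unifrac <- function(tree, a, b, normalized = FALSE) {
  tree <- root_for_unifrac(tree)
  B <- edge_leaf_matrix(tree)
  pa <- drop(B %*% unifrac_fractions(tree, a))
  pb <- drop(B %*% unifrac_fractions(tree, b))
  lens <- tree$edge.length
  raw <- sum(lens * abs(pa - pb))
  if (!normalized) return(raw)
  denom <- sum(lens * (pa + pb))
  if (denom == 0) return(0)
  raw / denom
}

#' Pairwise weighted UniFrac matrix over an abundance table
#'
#' @param tree `ape::phylo` with branch lengths.
#' @param table Sample-by-OTU abundance matrix (see [as_abundance_table()]).
#' @param normalized Use the normalized variant.
#' @return A validated distance matrix over the samples.
#' @export
unifrac_matrix <- function(tree, table, normalized = FALSE) {
  table <- as_abundance_table(table)
  tree <- root_for_unifrac(tree)
  B <- edge_leaf_matrix(tree)
  P <- vapply(rownames(table),
              function(s) drop(B %*% unifrac_fractions(tree, table[s, ])),
              numeric(nrow(B)))
  lens <- tree$edge.length
  n <- ncol(P)
  m <- matrix(0, n, n, dimnames = list(colnames(P), colnames(P)))
  for (i in seq_len(n - 1L)) for (j in (i + 1L):n) {
    raw <- sum(lens * abs(P[, i] - P[, j]))
    if (normalized) {
      denom <- sum(lens * (P[, i] + P[, j]))
      raw <- if (denom == 0) 0 else raw / denom
    }
    m[i, j] <- m[j, i] <- raw
  }
  as_distance_matrix(m, tol = 1e-9)
}

gower_matrix <- function(dm) {
  dm <- as_distance_matrix(dm)
  n <- nrow(dm)
  D2 <- dm^2
  J <- diag(n) - matrix(1 / n, n, n)
  G <- -0.5 * J %*% D2 %*% J
  (G + t(G)) / 2
}

#' Principal coordinates analysis (classical MDS)
#'
#' Gower double-centering `G = -1/2 J D^(2) J` followed by
#' eigendecomposition; coordinates are eigenvectors scaled by the square
#' roots of positive eigenvalues, sorted in decreasing order. Negative
#' eigenvalues are reported but their axes dropped.
#'
#' @param dm Distance matrix.
#' @return List with `coordinates` (samples x positive axes) and
#'   `eigenvalues` (all, descending).
#' @export
pcoa <- function(dm) {
  dm <- as_distance_matrix(dm)
  G <- gower_matrix(dm)
  eig <- eigen(G, symmetric = TRUE)
  vals <- eig$values
  tol <- max(abs(vals)) * 1e-9
  pos <- which(vals > tol)
  coords <- eig$vectors[, pos, drop = FALSE] %*% diag(sqrt(vals[pos]), length(pos))
  rownames(coords) <- rownames(dm)
  colnames(coords) <- paste0("PCo", seq_along(pos))
  list(coordinates = coords, eigenvalues = vals)
}

#' Center ordination coordinates by group
#'
#' Subtracts each group's centroid from its members, removing a nuisance
#' location effect before visualising a second factor.
#'
#' @param coordinates Numeric matrix, samples in rows.
#' @param groups Factor/character vector, one entry per sample.
#' @return Matrix of the same shape with per-group column means 0.
#' @export
center_by_group <- function(coordinates, groups) {
  if (length(groups) != nrow(coordinates)) stop("one group per sample required")
  groups <- as.factor(groups)
  if (anyNA(groups)) stop("every sample needs a group")
  out <- coordinates
  for (g in levels(groups)) {
    idx <- which(groups == g)
    out[idx, ] <- sweep(coordinates[idx, , drop = FALSE], 2,
                        colMeans(coordinates[idx, , drop = FALSE]))
  }
  out
}

align_groups <- function(dm, groups) {
  labs <- rownames(dm)
  if (!is.null(names(groups))) {
    missing <- setdiff(labs, names(groups))
    if (length(missing) > 0L)
      stop("no group for sample(s): ", paste(missing, collapse = ", "))
    groups <- groups[labs]
  } else if (length(groups) != nrow(dm)) {
    stop("groups must be named or match the distance matrix order")
  }
  as.factor(as.vector(groups))
}

## between/within sums of squares from squared distances and a grouping
ss_decompose <- function(D2, groups) {
  n <- nrow(D2)
  ss_total <- sum(D2[upper.tri(D2)]) / n
  ss_within <- 0
  for (g in levels(groups)) {
    idx <- which(groups == g)
    ng <- length(idx)
    ss_within <- ss_within + sum(D2[idx, idx]) / (2 * ng)
  }
  c(total = ss_total, within = ss_within, effect = ss_total - ss_within)
}

permute_within <- function(n, strata = NULL) {
  if (is.null(strata)) return(sample.int(n))
  perm <- seq_len(n)
  for (s in unique(strata)) {
    idx <- which(strata == s)
    perm[idx] <- idx[sample.int(length(idx))]
  }
  perm
}

permanova_result <- function(factor_name, df_effect, df_residual, ss_effect,
                             ss_residual, ss_total, n_permutations, exceed,
                             seed) {
  ms_res <- ss_residual / df_residual
  f <- (ss_effect / df_effect) / ms_res
  structure(list(
    factor = factor_name,
    df_effect = df_effect,
    df_residual = df_residual,
    ss_effect = ss_effect,
    ss_residual = ss_residual,
    ss_total = ss_total,
    pseudo_f = f,
    r2 = ss_effect / ss_total,
    omega2 = (ss_effect - df_effect * ms_res) / (ss_total + ms_res),
    p_value = (exceed + 1) / (n_permutations + 1),
    n_permutations = n_permutations,
    seed = seed
  ), class = "permanova_result")
}

#' @export
print.permanova_result <- function(x, ...) {
  cat(sprintf(
    "PERMANOVA (%s): pseudo-F(%d, %d) = %.4g, R2 = %.4g, omega2 = %.4g, p = %.4g (%d permutations)\n",
    x$factor, x$df_effect, x$df_residual, x$pseudo_f, x$r2, x$omega2,
    x$p_value, x$n_permutations))
  invisible(x)
}

#' One-factor PERMANOVA with omega-squared effect size
#'
#' Permutational multivariate analysis of variance on a distance matrix:
#' `SS_total = sum_{i<j} d_ij^2 / N`, `SS_within` summed per group, pseudo-F
#' the ratio of between/within mean squares. Significance is assessed by
#' permuting group labels (within `strata` if given); the add-one estimator
#' `p = (exceedances + 1)/(B + 1)` never returns 0. The omega-squared
#' effect size `(SS_A - df_A MS_W) / (SS_T + MS_W)` is reported unclamped
#' (it can be negative under the null).
#'
#' @param dm Distance matrix over samples.
#' @param groups Factor (named by sample or in matrix order); >= 2 levels,
#'   each with >= 2 samples.
#' @param n_permutations Number of label permutations (default 10000).
#' @param seed Integer seed for the permutations (reproducible p-values).
#' @param strata Optional sample partition; permutations stay within strata.
#' @return A `permanova_result`.
#' @export
permanova <- function(dm, groups, n_permutations = 10000L, seed = NULL,
                      strata = NULL) {
  dm <- as_distance_matrix(dm)
  groups <- align_groups(dm, groups)
  if (!is.null(strata)) strata <- as.vector(align_groups(dm, strata))
  sizes <- table(groups)
  if (length(sizes) < 2L) stop("need >= 2 groups")
  if (any(sizes < 2L)) stop("every group needs >= 2 samples")
  n <- nrow(dm)
  a <- length(sizes)
  D2 <- dm^2
  obs <- ss_decompose(D2, groups)
  df_e <- a - 1L
  df_r <- n - a
  f_obs <- (obs["effect"] / df_e) / (obs["within"] / df_r)
  if (!is.null(seed)) set.seed(seed)
  exceed <- 0L
  for (b in seq_len(n_permutations)) {
    gp <- groups[permute_within(n, strata)]
    ss <- ss_decompose(D2, gp)
    fp <- (ss["effect"] / df_e) / (ss["within"] / df_r)
    if (fp >= f_obs - 1e-12) exceed <- exceed + 1L
  }
  permanova_result(
    factor_name = "groups",
    df_effect = df_e, df_residual = df_r,
    ss_effect = unname(obs["effect"]),
    ss_residual = unname(obs["within"]),
    ss_total = unname(obs["total"]),
    n_permutations = n_permutations, exceed = exceed,
    seed = if (is.null(seed)) NA_integer_ else seed)
}

## trace-based model SS on the Gower matrix for a dummy-coded design
model_ss <- function(G, factors) {
  cols <- lapply(factors, function(f) {
    f <- droplevels(as.factor(f))
    if (nlevels(f) < 2L) return(NULL)   # constant factor adds nothing
    stats::model.matrix(~ f)[, -1L, drop = FALSE]
  })
  X <- cbind(rep(1, nrow(G)), do.call(cbind, cols))
  qrX <- qr(X)
  Q1 <- qr.Q(qrX)[, seq_len(qrX$rank), drop = FALSE]
  list(ss = sum(Q1 * (G %*% Q1)), rank = qrX$rank)
}

#' Sequential (conditional) PERMANOVA: factor B given factor A
#'
#' Uses the Gower inner-product formulation: `SS(model) = trace(H G)` with
#' `H` the projection onto the dummy-coded design. `SS(B|A)` is the
#' increase from the A-only model to the A+B model; the residual comes from
#' the full model. Permutations shuffle samples within levels of A, keeping
#' the conditioning structure intact.
#'
#' @param dm Distance matrix over samples.
#' @param factor_a Conditioning factor (named or in matrix order).
#' @param factor_b Factor of interest.
#' @param n_permutations,seed As in [permanova()].
#' @return A `permanova_result` for B conditioned on A.
#' @export
permanova_sequential <- function(dm, factor_a, factor_b,
                                 n_permutations = 10000L, seed = NULL) {
  dm <- as_distance_matrix(dm)
  fa <- align_groups(dm, factor_a)
  fb <- align_groups(dm, factor_b)
  n <- nrow(dm)
  G <- gower_matrix(dm)
  ss_total <- sum(diag(G))
  mA <- model_ss(G, list(fa))
  mAB <- model_ss(G, list(fa, fb))
  df_b <- mAB$rank - mA$rank
  if (df_b < 1L) stop("factors are confounded: B adds no rank beyond A")
  ss_b <- mAB$ss - mA$ss
  ss_res <- ss_total - mAB$ss
  df_res <- n - mAB$rank
  f_obs <- (ss_b / df_b) / (ss_res / df_res)
  if (!is.null(seed)) set.seed(seed)
  strata <- as.vector(fa)
  exceed <- 0L
  for (b in seq_len(n_permutations)) {
    perm <- permute_within(n, strata)
    mABp <- model_ss(G, list(fa, fb[perm]))
    ss_bp <- mABp$ss - mA$ss
    ss_resp <- ss_total - mABp$ss
    df_bp <- max(1L, mABp$rank - mA$rank)
    fp <- (ss_bp / df_bp) / (ss_resp / (n - mABp$rank))
    if (fp >= f_obs - 1e-12) exceed <- exceed + 1L
  }
  permanova_result(
    factor_name = "B | A",
    df_effect = df_b, df_residual = df_res,
    ss_effect = ss_b, ss_residual = ss_res, ss_total = ss_total,
    n_permutations = n_permutations, exceed = exceed,
    seed = if (is.null(seed)) NA_integer_ else seed)
}
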