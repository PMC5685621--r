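make_labels <- function(n) paste0("s", seq_len(n))

random_euclid_dm <- function(n, p = 4) {
  x <- matrix(rnorm(n * p), n)
  m <- as.matrix(dist(x))
  dimnames(m) <- list(make_labels(n), make_labels(n))
  as_distance_matrix(m)
}

test_that("weighted UniFrac: identity, two-leaf hand example, linearity", {
  tree <- read_newick("((A:1,B:2):0.5,(C:1,D:1):0.5);")
  a <- c(A = 3, B = 1, C = 2, D = 0.5)
  expect_equal(weighted_unifrac(tree, a, a), 0)

  two <- read_newick("(A:1,B:1);")
  expect_equal(weighted_unifrac(two, c(A = 7), c(B = 2)), 2)
  expect_equal(weighted_unifrac(two, c(A = 7), c(B = 2), normalized = TRUE), 1)

  b <- c(A = 1, B = 1, C = 4, D = 1)
  raw <- weighted_unifrac(tree, a, b)
  scaled <- tree; scaled$edge.length <- tree$edge.length * 3
  expect_equal(weighted_unifrac(scaled, a, b), 3 * raw)
  expect_equal(weighted_unifrac(scaled, a, b, normalized = TRUE),
               weighted_unifrac(tree, a, b, normalized = TRUE))

  expect_error(weighted_unifrac(tree, c(A = 1, Z = 2), b), "Z")
})

test_that("weighted UniFrac is a semimetric on random instances", {
  set.seed(501)
  tree <- ape::rtree(8)
  tips <- tree$tip.label
  for (i in 1:10) {
    a <- setNames(runif(8), tips); b <- setNames(runif(8), tips)
    c_ <- setNames(runif(8), tips)
    dab <- weighted_unifrac(tree, a, b)
    expect_equal(dab, weighted_unifrac(tree, b, a))
    expect_gte(dab, 0)
    expect_lte(dab, weighted_unifrac(tree, a, c_) +
                    weighted_unifrac(tree, c_, b) + 1e-12)
  }
})

test_that("unifrac_matrix matches the per-pair op and is equivariant", {
  set.seed(502)
  tree <- ape::rtree(6)
  tab <- matrix(rexp(5 * 6), 5, 6,
                dimnames = list(make_labels(5), tree$tip.label))
  tab[2, ] <- tab[1, ]                               # duplicate sample
  dm <- unifrac_matrix(tree, tab)
  expect_equal(dm["s1", "s2"], 0)
  expect_equal(dm["s3", "s5"],
               weighted_unifrac(tree, tab["s3", ], tab["s5", ]))
  perm <- c("s4", "s1", "s5", "s3", "s2")
  dm2 <- unifrac_matrix(tree, tab[perm, ])
  expect_equal(dm2[perm, perm], dm[perm, perm])
})

test_that("pcoa: rank, exactness and trace conservation", {
  # 4 collinear points
  x <- matrix(c(0, 1, 3, 7), 4)
  m <- as.matrix(dist(x)); dimnames(m) <- list(make_labels(4), make_labels(4))
  res <- pcoa(m)
  expect_equal(sum(res$eigenvalues > 1e-9 * max(res$eigenvalues)), 1L)

  set.seed(503)
  dm <- random_euclid_dm(7)
  res <- pcoa(dm)
  expect_lt(max(abs(as.matrix(dist(res$coordinates)) - dm)), 1e-6)
  G <- -0.5 * (diag(7) - 1 / 7) %*% dm^2 %*% (diag(7) - 1 / 7)
  expect_equal(sum(res$eigenvalues), sum(diag(G)), tolerance = 1e-9)
})

test_that("center_by_group removes group offsets and is idempotent", {
  set.seed(504)
  base <- matrix(rnorm(12 * 2), 12)
  groups <- rep(c("u", "v"), each = 6)
  shifted <- base
  shifted[groups == "v", ] <- shifted[groups == "v", ] + 10
  cent <- center_by_group(shifted, groups)
  for (g in c("u", "v")) {
    expect_lt(max(abs(colMeans(cent[groups == g, ]))), 1e-12)
  }
  expect_equal(center_by_group(cent, groups), cent)
  one <- center_by_group(shifted, rep("w", 12))
  expect_equal(one, sweep(shifted, 2, colMeans(shifted)))
})

test_that("permanova: hand-computable 4-sample case", {
  m <- matrix(2, 4, 4); m[1, 2] <- m[2, 1] <- 1; m[3, 4] <- m[4, 3] <- 1
  diag(m) <- 0
  dimnames(m) <- list(make_labels(4), make_labels(4))
  res <- permanova(m, c(s1 = "a", s2 = "a", s3 = "b", s4 = "b"),
                   n_permutations = 99, seed = 1)
  expect_equal(res$ss_total, 4.5)
  expect_equal(res$ss_residual, 1)
  expect_equal(res$ss_effect, 3.5)
  expect_equal(res$pseudo_f, 7)
  expect_equal(res$r2, 3.5 / 4.5)
  ms_w <- 1 / 2
  expect_equal(res$omega2, (3.5 - 1 * ms_w) / (4.5 + ms_w))
  expect_lt(res$omega2, res$r2)
})

test_that("permanova agrees with vegan::adonis2", {
  set.seed(505)
  for (i in 1:5) {
    n <- 18
    dm <- random_euclid_dm(n)
    g <- sample(rep(c("a", "b", "c"), each = 6))
    res <- permanova(dm, setNames(g, rownames(dm)), n_permutations = 99, seed = 2)
    ref <- vegan::adonis2(as.dist(dm) ~ g, permutations = 99)
    expect_equal(res$pseudo_f, ref$F[1], tolerance = 1e-9)
    expect_equal(res$r2, ref$R2[1], tolerance = 1e-9)
    expect_equal(res$ss_effect, ref$SumOfSqs[1], tolerance = 1e-9)
  }
})

test_that("permanova separated clusters: minimal p, R2 near 1", {
  set.seed(506)
  x <- rbind(matrix(rnorm(10 * 2, 0, 0.05), 10),
             matrix(rnorm(10 * 2, 50, 0.05), 10))
  m <- as.matrix(dist(x)); dimnames(m) <- list(make_labels(20), make_labels(20))
  g <- rep(c("a", "b"), each = 10)
  res <- permanova(as_distance_matrix(m), setNames(g, rownames(m)),
                   n_permutations = 199, seed = 3)
  expect_equal(res$p_value, 1 / 200)
  expect_gt(res$r2, 0.99)
})

test_that("permanova p-values are reproducible bit-for-bit given a seed", {
  set.seed(507)
  dm <- random_euclid_dm(16)
  g <- setNames(rep(c("a", "b"), each = 8), rownames(dm))
  r1 <- permanova(dm, g, n_permutations = 199, seed = 42)
  r2 <- permanova(dm, g, n_permutations = 199, seed = 42)
  expect_identical(r1$p_value, r2$p_value)
})

test_that("permanova validates groups and strata", {
  dm <- random_euclid_dm(6)
  expect_error(permanova(dm, setNames(rep("a", 6), rownames(dm)), 9), "2 groups")
  expect_error(permanova(dm, setNames(c("a", rep("b", 5)), rownames(dm)), 9),
               ">= 2 samples")
  # strata restrict permutations: labels never leave their stratum, so a
  # perfectly stratum-confounded factor keeps its observed F in every perm
  g <- setNames(rep(c("a", "b"), each = 3), rownames(dm))
  res <- permanova(dm, g, n_permutations = 99, seed = 5, strata = g)
  expect_equal(res$p_value, 1)
})

test_that("one-factor SS from the group formula equals trace(H G)", {
  set.seed(508)
  for (i in 1:5) {
    dm <- random_euclid_dm(15)
    g <- sample(rep(c("a", "b", "c"), each = 5))
    res <- permanova(dm, setNames(g, rownames(dm)), n_permutations = 9, seed = 1)
    seq_res <- permanova_sequential(dm, rep("const", 15),
                                    setNames(g, rownames(dm)),
                                    n_permutations = 9, seed = 1)
    expect_equal(res$ss_effect, seq_res$ss_effect, tolerance = 1e-9)
    expect_equal(res$pseudo_f, seq_res$pseudo_f, tolerance = 1e-9)
    expect_equal(res$ss_total, seq_res$ss_total, tolerance = 1e-9)
  }
})

test_that("sequential permanova: decomposition identity and confounding error", {
  set.seed(509)
  dm <- random_euclid_dm(24)
  A <- rep(c("x", "y"), each = 12)
  B <- rep(rep(c("p", "q"), each = 6), 2)
  res <- permanova_sequential(dm, A, B, n_permutations = 49, seed = 7)
  G <- -0.5 * (diag(24) - 1 / 24) %*% dm^2 %*% (diag(24) - 1 / 24)
  ssA <- aftree:::model_ss(G, list(factor(A)))$ss
  expect_equal(ssA + res$ss_effect + res$ss_residual, res$ss_total,
               tolerance = 1e-9)
  expect_lt(res$omega2, res$r2)
  expect_error(permanova_sequential(dm, A, A, n_permutations = 9), "confounded")
})

test_that("sequential permanova agrees with vegan's sequential adonis2", {
  set.seed(510)
  x <- matrix(rnorm(24 * 3), 24)
  A <- rep(c("x", "y"), each = 12)
  B <- sample(rep(c("p", "q", "r"), 8))
  x[A == "y", ] <- x[A == "y", ] + 1
  dm <- as.matrix(dist(x))
  dimnames(dm) <- list(make_labels(24), make_labels(24))
  res <- permanova_sequential(as_distance_matrix(dm), A, B,
                              n_permutations = 99, seed = 11)
  ref <- vegan::adonis2(as.dist(dm) ~ A + B, permutations = 99, by = "terms")
  expect_equal(res$ss_effect, ref["B", "SumOfSqs"], tolerance = 1e-9)
  expect_equal(res$pseudo_f, ref["B", "F"], tolerance = 1e-9)
  expect_equal(res$df_effect, ref["B", "Df"])
})
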