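# The matching-statistics engine and the three distances. Expected values
# for the worked examples were computed by hand from the definitions and by
# the brute-force oracle in helper-oracles.R.

test_that("matching statistics: worked example, self-statistics, disjoint", {
  expect_identical(matching_statistics("TCTGA", "CCTGT"), c(1L, 3L, 2L, 1L, 0L))
  expect_identical(max(matching_statistics("TCTGA", "CCTGT")), 3L)
  expect_identical(matching_statistics("AAA", "AAA"), c(3L, 2L, 1L))
  expect_identical(matching_statistics("ACG", "TTT"), c(0L, 0L, 0L))
})

test_that("N matches nothing, in the query or the subject", {
  expect_identical(matching_statistics("ANA", "AAA"), c(1L, 0L, 1L))
  expect_identical(matching_statistics("AA", "ANA"), c(1L, 1L))
  expect_identical(matching_statistics("N", "N"), 0L)
})

test_that("engine equals brute force on random ACGTN pairs", {
  set.seed(101)
  for (i in 1:60) {
    x <- random_dna(sample(1:60, 1), alphabet = c("A", "C", "G", "T", "N"))
    y <- random_dna(sample(1:60, 1), alphabet = c("A", "C", "G", "T", "N"))
    expect_identical(matching_statistics(x, y), ms_brute(x, y))
  }
})

test_that("matching statistics invariants hold on random pairs", {
  set.seed(102)
  for (i in 1:25) {
    x <- random_dna(40); y <- random_dna(30)
    l <- matching_statistics(x, y)
    n <- nchar(x)
    expect_true(all(l >= 0 & l <= n - seq_len(n) + 1))
    expect_true(all(diff(l) >= -1))               # suffix-extension property
    expect_identical(shustring_stats(x, y)$sl, l + 1L)
  }
})

test_that("shustring statistics: worked example and sentinels", {
  s <- shustring_stats("TCTGA", "TCGGT")
  expect_identical(s$sl, c(3L, 2L, 2L, 2L, 1L))
  expect_identical(s$witness[1], "TCT")
  expect_identical(shustring_stats("ACGT", "ACGT")$sl, c(5L, 4L, 3L, 2L))
  expect_identical(shustring_stats("A", "C")$sl, 1L)
})

test_that("ACS distance: identity, worked value, symmetry", {
  expect_equal(acs_distance("ACGTACGT", "ACGTACGT"), 0)
  # hand evaluation: L(X,Y) = 1.4, L(Y,X) = 1.6, L(self) = 3, n = m = 5
  expected <- ((log(5) / 1.4 - log(5) / 3) + (log(5) / 1.6 - log(5) / 3)) / 2
  expect_equal(acs_distance("TCTGA", "CCTGT"), expected, tolerance = 1e-12)
  expect_equal(round(expected, 3), 0.541)
  set.seed(103)
  for (i in 1:25) {
    x <- random_dna(50); y <- random_dna(45)
    expect_identical(acs_distance(x, y), acs_distance(y, x))
    expect_gte(acs_distance(x, y), 0)
  }
})

test_that("Kr distance: identity, worked value, symmetry", {
  expect_equal(kr_distance("ACGTAC", "ACGTAC"), 0)
  # independent arithmetic from the sl vectors [3,2,2,2,1] and [3,2,2,2,2]
  pi_xy <- 1 / mean(c(3, 2, 2, 2, 1)) - 1 / mean(c(6, 5, 4, 3, 2))
  pi_yx <- 1 / mean(c(3, 2, 2, 2, 2)) - 1 / mean(c(6, 5, 4, 3, 2))
  expected <- -0.75 * log(1 - 4 / 3 * (pi_xy + pi_yx) / 2)
  expect_equal(kr_distance("TCTGA", "TCGGT"), expected, tolerance = 1e-12)
  expect_gt(expected, 0)
  set.seed(104)
  for (i in 1:25) {
    x <- random_dna(50); y <- random_dna(45)
    expect_identical(kr_distance(x, y), kr_distance(y, x))
    expect_gte(kr_distance(x, y), 0)
  }
})

test_that("composition vector matches a direct-count evaluation", {
  # homopolymer: perfectly Markov-predicted, all components zero
  cv <- composition_vector("AAAA", 3)
  expect_length(cv$a, 0)

  x <- "ACGTACGTAA"
  cv <- composition_vector(x, 3)
  # independent direct-count oracle
  words <- function(s, k) {
    n <- nchar(s)
    substring(s, 1:(n - k + 1), k:n)
  }
  pfun <- function(s, k) {
    w <- words(s, k); tab <- table(w); as.numeric(tab[names(tab)]) -> cnt
    p <- cnt / length(w); names(p) <- names(tab); p
  }
  p3 <- pfun(x, 3); p2 <- pfun(x, 2); p1 <- pfun(x, 1)
  expect_equal(sum(p3), 1)                       # probability normalization
  for (w in names(cv$a)) {
    p0 <- p2[substr(w, 1, 2)] * p2[substr(w, 2, 3)] / p1[substr(w, 2, 2)]
    expect_equal(unname(cv$a[w]), unname((p3[w] - p0) / p0), tolerance = 1e-12)
  }
  expect_error(composition_vector("AC", 3), "shorter")
})

test_that("composition vector skips N windows and reduces the denominator", {
  cv <- composition_vector("AANCC", 3)   # no valid 3-window at all
  expect_length(cv$a, 0)
  # valid windows for k=3 in "AAANCCC": AAA and CCC only
  cv2 <- composition_vector("AAANCCC", 3)
  expect_true(all(names(cv2$a) %in% c("AAA", "CCC")))
})

test_that("cvtree distance: cosine limits", {
  mk <- function(a) structure(list(k = 3L, a = a), class = "composition_vector")
  u <- mk(c(AAA = 1, CCC = -2))
  expect_equal(cvtree_distance(u, u), 0)
  v <- mk(c(GGG = 1, TTT = 3))
  expect_equal(cvtree_distance(u, v), 0.5)
  w <- mk(c(AAA = -1, CCC = 2))
  expect_equal(cvtree_distance(u, w), 1)
  z <- mk(numeric(0))
  expect_equal(cvtree_distance(u, z), 0.5)       # all-zero convention
  expect_error(cvtree_distance(u, structure(list(k = 4L, a = c(AAAA = 1)),
                                            class = "composition_vector")),
               "different k")
})

test_that("distance_matrix is consistent with per-pair ops and equivariant", {
  set.seed(105)
  same <- c(a = "ACGTACGTAC", b = "ACGTACGTAC", c = "ACGTACGTAC")
  for (m in c("acs", "cv", "kr")) {
    expect_true(all(distance_matrix(same, m, k = 3) == 0))
  }
  seqs <- random_seq_set(5, 60)
  dm <- distance_matrix(seqs, "acs")
  expect_equal(dm["s1", "s3"], acs_distance(seqs["s1"], seqs["s3"]))
  dm_kr <- distance_matrix(seqs, "kr")
  expect_equal(dm_kr["s2", "s5"], kr_distance(seqs["s2"], seqs["s5"]))
  perm <- c("s3", "s1", "s5", "s2", "s4")
  dm2 <- distance_matrix(seqs[perm], "acs")
  expect_equal(dm2[perm, perm], dm[perm, perm])
})

test_that("all three distances increase with true JC divergence", {
  set.seed(106)
  divs <- rep(seq(0.01, 0.3, length.out = 10), 2)
  d_acs <- d_cv <- d_kr <- numeric(length(divs))
  for (i in seq_along(divs)) {
    tree <- read_newick(sprintf("(a:%f,b:%f);", divs[i] / 2, divs[i] / 2))
    seqs <- evolve_sequences(tree, 2000, 1, seed = 9000 + i)
    d_acs[i] <- acs_distance(seqs["a"], seqs["b"])
    d_cv[i] <- cvtree_distance(composition_vector(seqs["a"], 6),
                               composition_vector(seqs["b"], 6))
    d_kr[i] <- kr_distance(seqs["a"], seqs["b"])
  }
  expect_gt(cor(divs, d_acs, method = "spearman"), 0.9)
  expect_gt(cor(divs, d_cv, method = "spearman"), 0.9)
  expect_gt(cor(divs, d_kr, method = "spearman"), 0.9)
})
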