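## Synthetic data: Yule trees, Jukes-Cantor sequence evolution,
## tree-consistent taxonomies, two-group community tables with a
## label-permutation effect, and the end-to-end evaluation harnesses.

#' Simulation configuration
#'
#' Bundles and validates the knobs of the community simulator. Defaults are
#' desk-scale: they mirror the shape of stool 16S surveys (long-tailed OTU
#' abundances, two groups of equal size) at a size a laptop can iterate on.
#'
#' @param n_otus Number of OTUs (default 200).
#' @param n_samples Samples per group (default 10).
#' @param n_permuted_labels OTU labels permuted in group 2's baseline to
#'   inject a between-group effect (0 = null; must be `<= n_otus`).
#' @param baseline_sigma Log-normal sigma of the per-OTU baseline mean
#'   abundances (default 1.5, a long-tailed stool-like profile).
#' @param noise_sigma Log-normal sigma of per-sample noise around the
#'   baseline (default 0.5).
#' @param seed Mandatory integer seed.
#' @param n_taxa,sequence_length,scale,cut_depths Tree/sequence/taxonomy
#'   knobs used by [run_evaluation()]: number of taxa (default 64), sites
#'   (default 500), expected root-to-tip substitutions per site (default
#'   0.3), and taxonomy cut depths (`NULL` = evenly spaced).
#' @return Validated list of class `sim_config`.
#' @export
sim_config <- function(n_otus = 200L, n_samples = 10L, n_permuted_labels = 0L,
                       baseline_sigma = 1.5, noise_sigma = 0.5, seed,
                       n_taxa = 64L, sequence_length = 500L, scale = 0.3,
                       cut_depths = NULL) {
  if (missing(seed) || is.null(seed)) stop("seed is mandatory")
  stopifnot(n_otus >= 1L, n_samples >= 1L, n_taxa >= 3L,
            sequence_length >= 1L, scale >= 0, baseline_sigma > 0,
            noise_sigma >= 0)
  if (n_permuted_labels < 0L || n_permuted_labels > n_otus)
    stop("n_permuted_labels must lie in [0, n_otus]")
  structure(list(n_otus = as.integer(n_otus), n_samples = as.integer(n_samples),
                 n_permuted_labels = as.integer(n_permuted_labels),
                 baseline_sigma = baseline_sigma, noise_sigma = noise_sigma,
                 seed = as.integer(seed), n_taxa = as.integer(n_taxa),
                 sequence_length = as.integer(sequence_length), scale = scale,
                 cut_depths = cut_depths),
            class = "sim_config")
}

#' Simulate a Yule (pure-birth) tree
#'
#' Pure-birth topology with fresh i.i.d. exponential branch lengths, rescaled
#' so the mean root-to-tip depth is 1 (so `scale` in [evolve_sequences()]
#' reads directly as expected root-to-tip substitutions per site).
#'
#' @param n_taxa Number of leaves (>= 3).
#' @param seed Integer seed.
#' @return Rooted binary `ape::phylo` with tip labels `t1..tn`.
#' @export
simulate_tree <- function(n_taxa, seed) {
  if (n_taxa < 3L) stop("n_taxa must be >= 3")
  set.seed(seed)
  tree <- ape::rphylo(n_taxa, birth = 1, death = 0)
  tree$edge.length <- rexp(nrow(tree$edge))
  depths <- ape::node.depth.edgelength(tree)
  tree$edge.length <- tree$edge.length / mean(depths[seq_len(n_taxa)])
  tree$tip.label <- paste0("t", seq_len(n_taxa))
  tree
}

#' Evolve sequences along a tree under Jukes-Cantor
#'
#' The root sequence is i.i.d. uniform over ACGT; along each branch of
#' length `l` every site substitutes independently with probability
#' `3/4 (1 - exp(-4 l scale / 3))`, the JC69 site-difference probability at
#' `l * scale` expected substitutions per site, choosing uniformly among the
#' three other bases.
#'
#' @param tree `ape::phylo` with branch lengths.
#' @param length Number of sites.
#' @param scale Expected substitutions per site per unit branch length.
#' @param seed Integer seed.
#' @return Named character vector of leaf sequences.
#' @export
evolve_sequences <- function(tree, length, scale, seed) {
  if (is.null(tree$edge.length)) stop("tree needs branch lengths")
  set.seed(seed)
  nt <- length(tree$tip.label)
  nn <- max(tree$edge)
  root <- unique(tree$edge[!(tree$edge[, 1L] %in% tree$edge[, 2L]), 1L])
  seqs <- matrix(NA_integer_, nn, length)
  seqs[root, ] <- sample.int(4L, length, replace = TRUE)
  eo <- stats::reorder(tree, "cladewise")   # parents before children
  for (e in seq_len(nrow(eo$edge))) {
    p <- eo$edge[e, 1L]; ch <- eo$edge[e, 2L]
    d <- eo$edge.length[e] * scale
    psub <- 0.75 * (1 - exp(-4 * d / 3))
    s <- seqs[p, ]
    hit <- which(runif(length) < psub)
    if (length(hit) > 0L) {
      s[hit] <- ((s[hit] - 1L + sample.int(3L, length(hit), replace = TRUE)) %% 4L) + 1L
    }
    seqs[ch, ] <- s
  }
  bases <- c("A", "C", "G", "T")
  out <- vapply(seq_len(nt),
                function(i) paste(bases[seqs[i, ]], collapse = ""), "")
  names(out) <- tree$tip.label
  out
}

#' Derive a taxonomy table from a tree by depth cuts
#'
#' Rank `r` of a leaf is the identifier of the lineage (tree edge) crossing
#' depth `cut_depths[r]` on the root-to-leaf path; leaves deeper cuts cannot
#' reach get their own label. Labels are synthesized as
#' `"r<rank>_<cluster>"`. By construction the taxonomy is consistent with
#' the tree: rebuilding via [taxonomy_to_tree()] recovers the cut-induced
#' bipartitions.
#'
#' @param tree Rooted `ape::phylo` with branch lengths.
#' @param cut_depths Strictly increasing depths; default: 7 evenly spaced
#'   cuts at `(1:7)/8` of the maximum tip depth.
#' @param seed Ignored (derivation is deterministic); kept for a uniform
#'   simulator API.
#' @return Named list of rank-label character vectors.
#' @export
derive_taxonomy <- function(tree, cut_depths = NULL, seed = NULL) {
  nt <- length(tree$tip.label)
  depths <- ape::node.depth.edgelength(tree)
  if (is.null(cut_depths)) cut_depths <- (1:7) / 8 * max(depths[seq_len(nt)])
  if (is.unsorted(cut_depths, strictly = TRUE)) stop("cut_depths must be strictly increasing")
  parent <- integer(max(tree$edge))
  parent[tree$edge[, 2L]] <- tree$edge[, 1L]
  root <- unique(tree$edge[!(tree$edge[, 1L] %in% tree$edge[, 2L]), 1L])
  paths <- lapply(seq_len(nt), function(tip) {
    path <- tip
    while (path[1L] != root) path <- c(parent[path[1L]], path)
    path
  })
  tax <- vector("list", nt)
  for (tip in seq_len(nt)) {
    path <- paths[[tip]]
    labs <- character(length(cut_depths))
    for (r in seq_along(cut_depths)) {
      cd <- cut_depths[r]
      # deepest ancestor on the path not deeper than the cut (root depth 0
      # always qualifies); cuts at/below the leaf give the leaf itself
      anc <- path[depths[path] <= cd]
      node <- if (length(anc) == 0L) root else anc[length(anc)]
      labs[r] <- sprintf("r%d_%d", r, node)
    }
    tax[[tip]] <- labs
  }
  names(tax) <- tree$tip.label
  tax
}

#' Simulate two-group community abundance tables
#'
#' Per-OTU baseline mean abundances are log-normal; group 1 samples are
#' drawn around this baseline with multiplicative log-normal noise. Group 2
#' samples are drawn around a second baseline in which the abundances of a
#' uniformly chosen set of `n_permuted_labels` OTUs have been permuted
#' among themselves — an effect injection that leaves the phylogenetic
#' structure of the OTUs untouched. The permuted OTU set is returned for
#' diagnostics.
#'
#' @param cfg A [sim_config()].
#' @param otu_ids Optional OTU identifiers (default `otu1..otuN`).
#' @return List with `group1`, `group2` (sample-by-OTU matrices) and
#'   `permuted_otus` (character vector).
#' @export
simulate_communities <- function(cfg, otu_ids = NULL) {
  stopifnot(inherits(cfg, "sim_config"))
  set.seed(cfg$seed)
  n <- cfg$n_otus
  if (is.null(otu_ids)) otu_ids <- paste0("otu", seq_len(n))
  if (length(otu_ids) != n) stop("need exactly n_otus OTU ids")
  baseline <- rlnorm(n, 0, cfg$baseline_sigma)
  baseline2 <- baseline
  permuted <- character(0)
  if (cfg$n_permuted_labels > 0L) {
    sel <- sample.int(n, cfg$n_permuted_labels)
    baseline2[sel] <- baseline[sel][sample.int(length(sel))]
    permuted <- otu_ids[sel]
  }
  draw <- function(base, prefix) {
    m <- t(vapply(seq_len(cfg$n_samples),
                  function(i) base * rlnorm(n, 0, cfg$noise_sigma),
                  numeric(n)))
    dimnames(m) <- list(paste0(prefix, seq_len(cfg$n_samples)), otu_ids)
    as_abundance_table(m)
  }
  list(group1 = draw(baseline, "g1_s"),
       group2 = draw(baseline2, "g2_s"),
       permuted_otus = permuted)
}

#' End-to-end method evaluation harness
#'
#' Per replicate: simulate a Yule tree, evolve sequences, derive the
#' taxonomy, compute the alignment-free distance matrices, build NJ trees,
#' form the ensemble consensus, and score every tree (and the consensus)
#' against the taxonomy gold standard. Sub-seeds are derived from `seed`
#' so the whole report is reproducible.
#'
#' @param cfg A [sim_config()] (uses `n_taxa`, `sequence_length`, `scale`,
#'   `cut_depths`, `seed`).
#' @param methods Distance methods to run.
#' @param replicates Number of replicates (default 10).
#' @param k Composition-vector word length.
#' @param metric Gold-standard metric (see [gold_standard_distance()]).
#' @return `data.frame` with columns replicate, method, distance_to_gold.
#' @export
run_evaluation <- function(cfg, methods = c("acs", "cv", "kr"),
                           replicates = 10L, k = 6L, metric = "rf") {
  stopifnot(inherits(cfg, "sim_config"))
  rows <- list()
  for (r in seq_len(replicates)) {
    seed_r <- cfg$seed + r
    tree <- simulate_tree(cfg$n_taxa, seed = seed_r)
    seqs <- evolve_sequences(tree, cfg$sequence_length, cfg$scale,
                             seed = seed_r + 10000L)
    tax <- derive_taxonomy(tree, cut_depths = cfg$cut_depths)
    dms <- lapply(methods, function(m) distance_matrix(seqs, method = m, k = k))
    njs <- lapply(dms, neighbor_joining)
    gold <- taxonomy_to_tree(tax)
    for (i in seq_along(methods)) {
      rows[[length(rows) + 1L]] <- data.frame(
        replicate = r, method = methods[i],
        distance_to_gold = robinson_foulds_metric(njs[[i]], gold, metric),
        stringsAsFactors = FALSE)
    }
    if (length(methods) >= 2L) {
      cons <- ensemble_consensus(njs, dms)
      rows[[length(rows) + 1L]] <- data.frame(
        replicate = r, method = "consensus",
        distance_to_gold = robinson_foulds_metric(cons, gold, metric),
        stringsAsFactors = FALSE)
    }
  }
  do.call(rbind, rows)
}

robinson_foulds_metric <- function(tree, gold, metric) {
  switch(metric,
    rf  = robinson_foulds(tree, gold),
    rfn = robinson_foulds(tree, gold, normalized = TRUE),
    bs  = branch_score(tree, gold),
    stop("unknown metric: ", metric))
}

#' Label-permutation power study
#'
#' For each effect level (number of permuted OTU labels) and simulation:
#' simulate two-group communities over the leaves of `tree`, compute
#' weighted UniFrac distance matrices under the reference tree and
#' (optionally) an alternative tree, and run one-factor PERMANOVA on each,
#' recording omega-squared and the p-value in long format.
#'
#' @param tree Reference `ape::phylo`; its leaves are the OTU ids.
#' @param levels Integer vector of `n_permuted_labels` values.
#' @param n_sims Simulations per level.
#' @param seed Master seed.
#' @param alt_tree Optional second tree (e.g. an ensemble consensus) on the
#'   same leaves.
#' @param n_samples Samples per group.
#' @param n_permutations PERMANOVA permutations per test (default 999).
#' @param normalized Use normalized weighted UniFrac.
#' @return Long `data.frame`: level, sim, tree (`"reference"`/`"alternative"`),
#'   omega2, p_value.
#' @export
run_power_study <- function(tree, levels = c(0L, 10L, 25L, 50L, 100L),
                            n_sims = 20L, seed, alt_tree = NULL,
                            n_samples = 10L, n_permutations = 999L,
                            normalized = FALSE) {
  otus <- tree$tip.label
  trees <- list(reference = tree)
  if (!is.null(alt_tree)) {
    check_same_leaves(tree, alt_tree)
    trees$alternative <- alt_tree
  }
  rows <- list()
  for (li in seq_along(levels)) {
    for (s in seq_len(n_sims)) {
      sim_seed <- seed + 1000L * li + s
      cfg <- sim_config(n_otus = length(otus), n_samples = n_samples,
                        n_permuted_labels = levels[li], seed = sim_seed)
      com <- simulate_communities(cfg, otu_ids = otus)
      tab <- rbind(com$group1, com$group2)
      grp <- rep(c("g1", "g2"), each = n_samples)
      names(grp) <- rownames(tab)
      for (tn in names(trees)) {
        dm <- unifrac_matrix(trees[[tn]], tab, normalized = normalized)
        res <- permanova(dm, grp, n_permutations = n_permutations,
                         seed = sim_seed + 500000L)
        rows[[length(rows) + 1L]] <- data.frame(
          level = levels[li], sim = s, tree = tn,
          omega2 = res$omega2, p_value = res$p_value,
          stringsAsFactors = FALSE)
      }
    }
  }
  do.call(rbind, rows)
}
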