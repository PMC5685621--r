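#' Read a DNA FASTA file into a sequence set
#'
#' Sequences are uppercased and any character outside `A`, `C`, `G`, `T`
#' (ambiguity codes, gaps, stray symbols) is mapped to `N`. `N` is treated
#' as matching nothing by every downstream statistic, so this mapping is a
#' conservative handling of ambiguity, not an imputation. Whitespace in
#' record identifiers is replaced by underscores.
#'
#' @param path Path to a FASTA file.
#' @return Named character vector of sequences (a "sequence set"); names are
#'   record identifiers in file order.
#' @export
read_fasta <- function(path) {
  if (!file.exists(path)) stop("FASTA file not found: ", path)
  set <- Biostrings::readBStringSet(path)
  if (length(set) == 0L) stop("empty FASTA file: ", path)
  ids <- sub("\\s.*$", "", names(set))
  ids <- gsub("\\s+", "_", ids)
  dup <- ids[duplicated(ids)]
  if (length(dup) > 0L)
    stop("duplicate sequence ID(s) in FASTA: ", paste(unique(dup), collapse = ", "))
  seqs <- toupper(as.character(set))
  seqs <- gsub("[^ACGT]", "N", seqs)
  if (any(nchar(seqs) == 0L)) stop("zero-length sequence in FASTA: ", path)
  names(seqs) <- ids
  seqs
}

#' Validate (and symmetrize) a distance matrix
#'
#' Enforces the container invariants used throughout the package: square,
#' labelled, symmetric within `tol`, zero diagonal, finite and non-negative.
#' Small asymmetries (below `tol`) are averaged away; larger ones are errors.
#'
#' @param m Numeric matrix with identical row/column names, or an object
#'   coercible to one (e.g. `dist`).
#' @param tol Symmetry tolerance (default `1e-9`).
#' @return The validated symmetric matrix.
#' @export
as_distance_matrix <- function(m, tol = 1e-9) {
  if (inherits(m, "dist")) m <- as.matrix(m)
  if (!is.matrix(m) || !is.numeric(m)) stop("distance matrix must be a numeric matrix")
  if (nrow(m) != ncol(m)) stop("distance matrix must be square")
  labs <- rownames(m)
  if (is.null(labs)) stop("distance matrix must have row names")
  if (anyDuplicated(labs)) stop("duplicate labels in distance matrix")
  if (is.null(colnames(m))) colnames(m) <- labs
  if (!identical(colnames(m), labs)) stop("row and column names differ")
  if (!all(is.finite(m))) stop("non-finite entries in distance matrix")
  if (max(abs(m - t(m))) > tol) stop("distance matrix not symmetric within tolerance ", tol)
  m <- (m + t(m)) / 2
  if (any(abs(diag(m)) > tol)) stop("distance matrix diagonal not zero")
  diag(m) <- 0
  if (any(m < 0)) {
    if (min(m) < -tol) stop("negative entries in distance matrix")
    m[m < 0] <- 0
  }
  m
}

#' Write a distance matrix in PHYLIP square format
#'
#' The `"relaxed"` dialect (default) separates the taxon name from the values
#' with tabs and places no limit on name length; the `"strict"` dialect pads
#' names to the classic 10 characters and errors on longer names. Both write
#' the full square matrix, as consumed by PHYLIP NEIGHBOR and FITCH.
#'
#' @param dm Distance matrix (see [as_distance_matrix()]).
#' @param path Output path.
#' @param dialect `"relaxed"` or `"strict"`.
#' @return `path`, invisibly.
#' @export
write_phylip_distances <- function(dm, path, dialect = c("relaxed", "strict")) {
  dm <- as_distance_matrix(dm)
  dialect <- match.arg(dialect)
  labs <- rownames(dm)
  if (dialect == "strict") {
    too_long <- labs[nchar(labs) > 10L]
    if (length(too_long) > 0L)
      stop("strict PHYLIP dialect limits names to 10 characters: ",
           paste(too_long, collapse = ", "))
  }
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(format(nrow(dm)), con)
  for (i in seq_len(nrow(dm))) {
    vals <- sprintf("%.9f", dm[i, ])
    line <- if (dialect == "strict") {
      paste0(formatC(labs[i], width = -10L), paste(vals, collapse = "  "))
    } else {
      paste(c(labs[i], vals), collapse = "\t")
    }
    writeLines(line, con)
  }
  invisible(path)
}

#' Read a PHYLIP square distance matrix
#'
#' Accepts both dialects written by [write_phylip_distances()] (names must
#' not contain whitespace).
#'
#' @param path Path to a PHYLIP square distance file.
#' @return A validated distance matrix.
#' @export
read_phylip_distances <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines))]
  n <- suppressWarnings(as.integer(trimws(lines[1L])))
  if (is.na(n) || n < 1L) stop("invalid PHYLIP header in ", path)
  if (length(lines) != n + 1L) stop("expected ", n, " rows in ", path)
  labs <- character(n)
  m <- matrix(NA_real_, n, n)
  for (i in seq_len(n)) {
    toks <- strsplit(trimws(lines[i + 1L]), "[ \t]+")[[1L]]
    if (length(toks) != n + 1L)
      stop("row ", i, " of ", path, " has ", length(toks) - 1L, " values, expected ", n)
    labs[i] <- toks[1L]
    m[i, ] <- as.numeric(toks[-1L])
  }
  dimnames(m) <- list(labs, labs)
  as_distance_matrix(m, tol = 1e-6)
}

#' Parse / serialize Newick trees
#'
#' Thin wrappers over `ape` adding the validation this toolkit relies on:
#' a parse error (e.g. unbalanced parentheses) and duplicate leaf labels are
#' errors, not warnings. Branch lengths, internal labels, multifurcations
#' and quoted labels are supported.
#'
#' @param text A Newick string (single tree, trailing semicolon).
#' @return `read_newick`: an `ape::phylo`; `write_newick`: a Newick string.
#' @export
read_newick <- function(text) {
  n_open <- lengths(regmatches(text, gregexpr("(", text, fixed = TRUE)))
  n_close <- lengths(regmatches(text, gregexpr(")", text, fixed = TRUE)))
  if (n_open != n_close) stop("unbalanced parentheses in Newick string")
  tree <- tryCatch(
    suppressWarnings(ape::read.tree(text = text)),
    error = function(e) stop("failed to parse Newick: ", conditionMessage(e))
  )
  if (is.null(tree)) stop("failed to parse Newick string")
  if (inherits(tree, "multiPhylo")) stop("expected a single Newick tree")
  dup <- tree$tip.label[duplicated(tree$tip.label)]
  if (length(dup) > 0L)
    stop("duplicate leaf label(s): ", paste(unique(dup), collapse = ", "))
  tree
}

#' @rdname read_newick
#' @param tree An `ape::phylo` tree.
#' @export
write_newick <- function(tree) {
  stopifnot(inherits(tree, "phylo"))
  ape::write.tree(tree)
}

#' Read a Greengenes-style taxonomy table
#'
#' Two-column TSV: sequence ID, then a semicolon-separated rank string such
#' as `"k__Bacteria; p__Firmicutes; c__"`. Rank labels are trimmed but kept
#' verbatim (prefixes like `k__` are not stripped); rank depth is positional.
#' Empty slots (e.g. `"g__"` or a missing trailing rank) are recorded as
#' empty strings; all entries are padded to the deepest rank present.
#'
#' @param path Path to the TSV file (no header).
#' @return Named list of character rank vectors, one per sequence ID.
#' @export
read_taxonomy <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines))]
  if (length(lines) == 0L) stop("empty taxonomy file: ", path)
  parts <- strsplit(lines, "\t", fixed = TRUE)
  bad <- which(lengths(parts) != 2L)
  if (length(bad) > 0L)
    stop("taxonomy rows must have exactly 2 tab-separated fields (row ",
         bad[1L], ")")
  ids <- vapply(parts, `[[`, "", 1L)
  if (anyDuplicated(ids)) stop("duplicate sequence ID(s) in taxonomy")
  ranks <- lapply(parts, function(p) {
    r <- trimws(strsplit(p[[2L]], ";", fixed = TRUE)[[1L]])
    # "k__" style empties stay as-is; depth is positional
    r
  })
  depth <- max(lengths(ranks))
  ranks <- lapply(ranks, function(r) c(r, rep("", depth - length(r))))
  tax <- lapply(ranks, function(r) {
    # a bare prefix like "g__" counts as empty
    r[grepl("^[a-zA-Z]__$", r)] <- ""
    r
  })
  names(tax) <- ids
  tax
}

#' Read a sample-by-OTU abundance table
#'
#' TSV with a header row of OTU identifiers; first column holds sample
#' identifiers. Values must parse as non-negative reals and every sample
#' must have at least one positive entry.
#'
#' @param path Path to the TSV file.
#' @return Numeric matrix, samples in rows, OTUs in columns.
#' @export
read_abundance <- function(path) {
  df <- read.table(path, sep = "\t", header = TRUE, check.names = FALSE,
                   stringsAsFactors = FALSE, comment.char = "")
  if (ncol(df) < 2L) stop("abundance table needs a sample column and >= 1 OTU column")
  ids <- as.character(df[[1L]])
  if (anyDuplicated(ids)) stop("duplicate sample ID(s) in abundance table")
  m <- as.matrix(df[, -1L, drop = FALSE])
  storage.mode(m) <- "double"
  rownames(m) <- ids
  as_abundance_table(m)
}

#' Validate an abundance table
#'
#' @param m Numeric matrix, samples in rows, OTUs in columns.
#' @return The validated matrix.
#' @export
as_abundance_table <- function(m) {
  if (!is.matrix(m) || !is.numeric(m)) stop("abundance table must be a numeric matrix")
  if (is.null(rownames(m)) || is.null(colnames(m)))
    stop("abundance table needs sample (row) and OTU (column) names")
  if (anyDuplicated(rownames(m))) stop("duplicate sample IDs")
  if (anyDuplicated(colnames(m))) stop("duplicate OTU IDs")
  if (any(!is.finite(m)) || any(m < 0)) stop("abundance values must be non-negative reals")
  zero <- rownames(m)[rowSums(m) <= 0]
  if (length(zero) > 0L)
    stop("sample(s) with no positive abundance: ", paste(zero, collapse = ", "))
  m
}

#' Read a sample metadata table
#'
#' TSV with a header; first column holds sample identifiers, remaining
#' columns are factors/covariates.
#'
#' @param path Path to the TSV file.
#' @return `data.frame` with sample IDs as row names.
#' @export
read_metadata <- function(path) {
  df <- read.table(path, sep = "\t", header = TRUE, check.names = FALSE,
                   stringsAsFactors = FALSE, comment.char = "")
  ids <- as.character(df[[1L]])
  if (anyDuplicated(ids)) stop("duplicate sample ID(s) in metadata")
  out <- df[, -1L, drop = FALSE]
  rownames(out) <- ids
  out
}
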