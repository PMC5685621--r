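## Alignment-free pairwise distances: matching statistics (ACS), shortest
## unique substrings (Kr), and Markov-corrected composition vectors (CVTree).

BASE_CODES <- c(A = 1L, C = 2L, G = 3L, T = 4L)

encode_dna <- function(seq) {
  if (length(seq) != 1L || !is.character(seq)) stop("sequence must be a single string")
  if (nchar(seq) < 1L) stop("sequence must have length >= 1")
  chars <- strsplit(toupper(seq), "", fixed = TRUE)[[1L]]
  codes <- BASE_CODES[chars]
  codes[is.na(codes)] <- 0L
  as.integer(codes)
}

revcomp <- function(seq) {
  chartr("ACGTN", "TGCAN", paste(rev(strsplit(toupper(seq), "")[[1L]]), collapse = ""))
}

#' Matching statistics between two sequences
#'
#' For each position `i` of the query `x`, the matching statistic `l[i]` is
#' the length of the longest substring of `x` starting at `i` that occurs
#' anywhere in the subject `y`. Positions holding `N` yield 0 and substrings
#' of `y` containing `N` never match (ambiguity codes match nothing).
#'
#' @param x,y DNA strings over `{A,C,G,T,N}` (case-insensitive).
#' @return Integer vector of length `nchar(x)`.
#' @export
matching_statistics <- function(x, y) {
  matching_stats_cpp(encode_dna(x), encode_dna(y))
}

#' Shortest-unique-substring (shustring) statistics
#'
#' `sl[i]` is the length of the shortest prefix of the suffix `x[i..n]` that
#' is absent from `y`; when every prefix of the suffix occurs in `y` the
#' sentinel value (suffix length + 1) is used. By construction
#' `sl = matching_statistics(x, y) + 1` element-wise, including the sentinel
#' case. The witness substrings (truncated at the sequence end in the
#' sentinel case) are returned alongside.
#'
#' @inheritParams matching_statistics
#' @return List with `sl` (integer vector) and `witness` (character vector).
#' @export
shustring_stats <- function(x, y) {
  l <- matching_statistics(x, y)
  sl <- l + 1L
  n <- nchar(x)
  i <- seq_len(n)
  witness <- substr(rep(toupper(x), n), i, pmin(i + sl - 1L, n))
  list(sl = sl, witness = witness)
}

## mean matching statistic; the directed ACS similarity denominator
acs_L <- function(x, y) mean(matching_stats_cpp(x, y))

#' Average common substring (ACS) distance
#'
#' The directed similarity `L(X,Y)` is the mean matching statistic of `X`
#' against `Y`. It is turned into a directed distance by inverting and
#' subtracting the self-similarity baseline,
#' `d(X->Y) = log(m)/L(X,Y) - log(n)/L(X,X)` with the closed form
#' `L(X,X) = (n+1)/2`, so identical sequences are at distance 0. The
#' reported distance is the average of the two directions; tiny negative
#' values from finite-length noise (>= -1e-9) are clamped to 0.
#'
#' @inheritParams matching_statistics
#' @return Non-negative numeric distance.
#' @export
acs_distance <- function(x, y) {
  acs_distance_enc(encode_dna(x), encode_dna(y))
}

acs_distance_enc <- function(xe, ye) {
  n <- length(xe); m <- length(ye)
  if (n < 2L || m < 2L) stop("ACS distance requires sequences of length >= 2")
  Lxy <- acs_L(xe, ye)
  Lyx <- acs_L(ye, xe)
  if (Lxy == 0) { warning("no common substring; capping L(X,Y) at 1/(2n)"); Lxy <- 1 / (2 * n) }
  if (Lyx == 0) { warning("no common substring; capping L(Y,X) at 1/(2m)"); Lyx <- 1 / (2 * m) }
  dxy <- log(m) / Lxy - log(n) / ((n + 1) / 2)
  dyx <- log(n) / Lyx - log(m) / ((m + 1) / 2)
  d <- (dxy + dyx) / 2
  if (d < 0 && d >= -1e-9) d <- 0
  d
}

#' Kr distance from shortest-unique-substring lengths
#'
#' A mismatch-probability estimator built on shustring lengths: the mean
#' shustring length against the subject is compared with the self baseline,
#' `pi(X->Y) = max(0, 1/mean(sl(X,Y)) - 1/mean(sl(X,X)))`, the two
#' directions are averaged, capped at 0.74, and mapped through the
#' Jukes-Cantor correction `-(3/4) log(1 - (4/3) pi)`. Identical sequences
#' are at distance 0 exactly. This is a simplified stand-in for the original
#' coalescent-corrected Kr estimator (see the methods vignette).
#'
#' @inheritParams matching_statistics
#' @return Non-negative numeric distance.
#' @export
kr_distance <- function(x, y) {
  kr_distance_enc(encode_dna(x), encode_dna(y))
}

kr_distance_enc <- function(xe, ye) {
  n <- length(xe); m <- length(ye)
  if (n < 2L || m < 2L) stop("Kr distance requires sequences of length >= 2")
  # self baseline: sl[i] = n - i + 2, mean = (n + 3) / 2
  pi_xy <- max(0, 1 / mean(matching_stats_cpp(xe, ye) + 1L) - 2 / (n + 3))
  pi_yx <- max(0, 1 / mean(matching_stats_cpp(ye, xe) + 1L) - 2 / (m + 3))
  pi_sym <- (pi_xy + pi_yx) / 2
  if (pi_sym > 0.74) {
    warning("mismatch estimate ", format(pi_sym), " capped at 0.74")
    pi_sym <- 0.74
  }
  -0.75 * log(1 - 4 * pi_sym / 3)
}

count_kmers <- function(chars, k) {
  n <- length(chars)
  if (n < k) return(numeric(0))
  starts <- seq_len(n - k + 1L)
  words <- substring(paste(chars, collapse = ""), starts, starts + k - 1L)
  words <- words[!grepl("N", words, fixed = TRUE)]
  if (length(words) == 0L) return(numeric(0))
  tab <- table(words)
  p <- as.numeric(tab) / sum(tab)
  names(p) <- names(tab)
  p
}

#' Markov-corrected k-mer composition vector
#'
#' Empirical k-word probabilities are compared with the prediction of a
#' (k-2)-order Markov background estimated from the (k-1)- and (k-2)-word
#' frequencies of the same sequence:
#' `p0(a1..ak) = p(a1..a_{k-1}) p(a2..ak) / p(a2..a_{k-1})`. The component
#' for word `w` is the relative deviation `(p(w) - p0(w)) / p0(w)` (0 when
#' `p0(w) = 0`). Windows containing `N` are skipped and the denominators
#' reduced accordingly. The vector is stored sparsely.
#'
#' @param x DNA string.
#' @param k Word length, 3-9 (default 6).
#' @return Object of class `composition_vector`: list with `k` and the named
#'   numeric component vector `a`.
#' @export
composition_vector <- function(x, k = 6L) {
  k <- as.integer(k)
  if (k < 3L) stop("composition vector requires k >= 3")
  chars <- strsplit(gsub("[^ACGT]", "N", toupper(x)), "", fixed = TRUE)[[1L]]
  if (length(chars) < k) stop("sequence shorter than k = ", k)
  p_k  <- count_kmers(chars, k)
  p_k1 <- count_kmers(chars, k - 1L)
  p_k2 <- count_kmers(chars, k - 2L)
  words <- names(p_k)
  pref <- substr(words, 1L, k - 1L)        # a1..a_{k-1}
  suff <- substr(words, 2L, k)             # a2..ak
  mid  <- substr(words, 2L, k - 1L)        # a2..a_{k-1}
  p0 <- unname(p_k1[pref]) * unname(p_k1[suff]) / unname(p_k2[mid])
  p0[!is.finite(p0)] <- 0
  a <- ifelse(p0 > 0, (as.numeric(p_k) - p0) / p0, 0)
  names(a) <- words
  a <- a[a != 0]
  structure(list(k = k, a = a), class = "composition_vector")
}

#' Cosine dissimilarity between composition vectors
#'
#' `(1 - C)/2` where `C` is the cosine of the two sparse component vectors
#' over the union of their supports, giving a distance in `[0, 1]`. If
#' either vector is identically zero the conventional value 0.5 (cosine 0)
#' is returned.
#'
#' @param u,v `composition_vector` objects with equal `k`.
#' @return Numeric distance in `[0, 1]`.
#' @export
cvtree_distance <- function(u, v) {
  stopifnot(inherits(u, "composition_vector"), inherits(v, "composition_vector"))
  if (u$k != v$k) stop("composition vectors have different k (", u$k, " vs ", v$k, ")")
  nu <- sqrt(sum(u$a^2)); nv <- sqrt(sum(v$a^2))
  if (nu == 0 || nv == 0) return(0.5)
  common <- intersect(names(u$a), names(v$a))
  C <- sum(u$a[common] * v$a[common]) / (nu * nv)
  C <- min(1, max(-1, C))
  (1 - C) / 2
}

#' Pairwise alignment-free distance matrix
#'
#' Computes all pairwise distances over a sequence set with one of the three
#' methods. With `rc = TRUE` each pair's distance is the minimum over the
#' subject's two orientations (same-strand amplicons do not need this, so
#' the default is `FALSE`).
#'
#' @param seqs Named character vector of DNA sequences (>= 3).
#' @param method `"acs"`, `"cv"` or `"kr"`.
#' @param k Word length for `method = "cv"`.
#' @param rc Also consider the reverse complement and keep the smaller
#'   distance.
#' @return A validated [as_distance_matrix()] matrix.
#' @export
distance_matrix <- function(seqs, method = c("acs", "cv", "kr"), k = 6L, rc = FALSE) {
  method <- match.arg(method)
  n <- length(seqs)
  if (n < 3L) stop("need at least 3 sequences")
  if (is.null(names(seqs)) || anyDuplicated(names(seqs)))
    stop("sequences must have unique names")
  pairfun <- switch(method,
    acs = acs_distance_enc,
    kr  = kr_distance_enc,
    cv  = NULL)
  m <- matrix(0, n, n, dimnames = list(names(seqs), names(seqs)))
  if (method == "cv") {
    cvs <- lapply(seqs, composition_vector, k = k)
    cvs_rc <- if (rc) lapply(seqs, function(s) composition_vector(revcomp(s), k = k))
    for (i in seq_len(n - 1L)) for (j in (i + 1L):n) {
      d <- cvtree_distance(cvs[[i]], cvs[[j]])
      if (rc) d <- min(d, cvtree_distance(cvs[[i]], cvs_rc[[j]]))
      m[i, j] <- m[j, i] <- d
    }
  } else {
    enc <- lapply(seqs, encode_dna)
    enc_rc <- if (rc) lapply(seqs, function(s) encode_dna(revcomp(s)))
    for (i in seq_len(n - 1L)) for (j in (i + 1L):n) {
      d <- pairfun(enc[[i]], enc[[j]])
      if (rc) d <- min(d, pairfun(enc[[i]], enc_rc[[j]]))
      m[i, j] <- m[j, i] <- d
    }
  }
  as_distance_matrix(m, tol = 1e-9)
}
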