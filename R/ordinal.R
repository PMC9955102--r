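# Bandt-Pompe ordinal symbolization, permutation entropy and missing
# (forbidden) pattern counting.
#
# Patterns are ranked lexicographically via the Lehmer code so that the
# fully ascending pattern has rank 1 and the fully descending pattern has
# rank m!.  Permutation entropy and the missing-pattern count depend only
# on the multiset of pattern probabilities, so the interior labelling is a
# bookkeeping convention; only rank 1 (ascending) and rank m! (descending)
# carry physiological meaning downstream.

.MAX_M <- 10L  # m! must stay integer-representable; 10! = 3,628,800

.check_m <- function(m) {
  if (!is.numeric(m) || length(m) != 1L || is.na(m) || m != as.integer(m))
    stop("`m` must be a single integer", call. = FALSE)
  m <- as.integer(m)
  if (m < 2L) stop("embedding dimension `m` must be >= 2", call. = FALSE)
  if (m > .MAX_M)
    stop("embedding dimension `m` is capped at ", .MAX_M,
         " (m! grows intractably)", call. = FALSE)
  m
}

.check_tau <- function(tau) {
  if (!is.numeric(tau) || length(tau) != 1L || is.na(tau) ||
      tau != as.integer(tau) || tau < 1)
    stop("embedding delay `tau` must be a positive integer", call. = FALSE)
  as.integer(tau)
}

#' Embedding configuration
#'
#' Bundles the embedding dimension `m` and delay `tau` used for
#' Bandt-Pompe symbolization. The defaults (`m = 6`, `tau = 1`) are the
#' parameters used for the 200 Hz ICP analysis: 6! = 720 possible patterns
#' and windows of 5 * 6! = 3600 samples.
#'
#' @param m Embedding dimension (pattern length), an integer in 2..10.
#' @param tau Embedding delay in samples, a positive integer.
#' @return A list of class `"embedding_config"` with elements `m` and `tau`.
#' @examples
#' embedding_config(3, 1)
#' @export
embedding_config <- function(m = 6L, tau = 1L) {
  structure(list(m = .check_m(m), tau = .check_tau(tau)),
            class = "embedding_config")
}

#' @export
print.embedding_config <- function(x, ...) {
  cat(sprintf("Embedding: m = %d (%d patterns), tau = %d\n",
              x$m, factorial(x$m), x$tau))
  invisible(x)
}

#' Ordinal pattern of a single embedded vector
#'
#' Maps a length-`m` window to its Bandt-Pompe ordinal pattern: the
#' permutation listing, in ascending order of value, the 1-based original
#' indices. Ties are broken by the earlier index (stable ordering), so
#' e.g. `c(5, 5, 7)` maps to `(1, 2, 3)`.
#'
#' @param window Numeric vector of length `m` (m >= 2), no NAs.
#' @return Integer vector: a permutation of `1:m`.
#' @examples
#' ordinal_pattern(c(8, 9, 5))  # 3 1 2: value 5 (index 3) is smallest
#' @export
ordinal_pattern <- function(window) {
  if (!is.numeric(window) || anyNA(window))
    stop("`window` must be a numeric vector without NAs", call. = FALSE)
  .check_m(length(window))
  order(window)  # order() is stable: ties resolve to the earlier index
}

#' Lexicographic rank of an ordinal pattern
#'
#' Computes the 1-based lexicographic rank of a permutation of `1:m` via
#' its Lehmer code. The ascending pattern `(1, ..., m)` has rank 1 and the
#' descending pattern `(m, ..., 1)` has rank `m!`.
#'
#' @param pattern Integer vector: a permutation of `1:m`.
#' @return Integer rank in `1..m!`.
#' @seealso [unrank_pattern()] for the inverse.
#' @examples
#' pattern_rank(c(3, 1, 2))  # 5
#' @export
pattern_rank <- function(pattern) {
  m <- .check_m(length(pattern))
  if (!is.numeric(pattern) || anyNA(pattern) ||
      !identical(as.integer(sort(pattern)), seq_len(m)))
    stop("`pattern` must be a permutation of 1..m", call. = FALSE)
  pattern <- as.integer(pattern)
  r <- 0
  for (i in seq_len(m - 1L))
    r <- r + sum(pattern[(i + 1L):m] < pattern[i]) * factorial(m - i)
  as.integer(r + 1)
}

#' Ordinal pattern with a given lexicographic rank
#'
#' Inverse of [pattern_rank()]: decodes a 1-based lexicographic rank into
#' the corresponding permutation of `1:m`.
#'
#' @param rank Integer in `1..factorial(m)`.
#' @param m Embedding dimension.
#' @return Integer vector: a permutation of `1:m`.
#' @examples
#' unrank_pattern(5, 3)  # 3 1 2
#' @export
unrank_pattern <- function(rank, m) {
  m <- .check_m(m)
  N <- factorial(m)
  if (!is.numeric(rank) || length(rank) != 1L || is.na(rank) ||
      rank != as.integer(rank) || rank < 1 || rank > N)
    stop("`rank` must be an integer in 1..m!", call. = FALSE)
  r <- as.integer(rank) - 1L
  avail <- seq_len(m)
  out <- integer(m)
  for (i in seq_len(m)) {
    f <- factorial(m - i)
    k <- r %/% f
    r <- r %% f
    out[i] <- avail[k + 1L]
    avail <- avail[-(k + 1L)]
  }
  out
}

#' Bandt-Pompe symbolization of a time series
#'
#' Slides an embedding window of dimension `m` and delay `tau` along the
#' series and maps each embedded vector `(x_j, x_{j+tau}, ...,
#' x_{j+(m-1)tau})` to the lexicographic rank of its ordinal pattern.
#'
#' Ranks are computed fully vectorized: column-wise stable value ranks are
#' converted to pattern digits and then to Lehmer-code ranks, so the cost
#' is `O(m^2)` vectorized passes over the series.
#'
#' @param x Numeric series of length `T >= (m-1)*tau + 1`.
#' @param m Embedding dimension (2..10), default 6.
#' @param tau Embedding delay in samples, default 1.
#' @param strict If `TRUE` (default) a series too short for a single
#'   embedded vector is an error; if `FALSE`, an empty integer vector is
#'   returned with a warning.
#' @return Integer vector of pattern ranks, length `T - (m-1)*tau`.
#' @examples
#' symbolize(c(3, 6, 8, 9, 5, 10, 2), m = 3)  # 1 1 5 3 5
#' @export
symbolize <- function(x, m = 6L, tau = 1L, strict = TRUE) {
  m <- .check_m(m)
  tau <- .check_tau(tau)
  if (!is.numeric(x) || anyNA(x))
    stop("`x` must be a numeric vector without NAs", call. = FALSE)
  n <- length(x) - (m - 1L) * tau
  if (n < 1L) {
    msg <- sprintf("series of length %d too short for m = %d, tau = %d",
                   length(x), m, tau)
    if (strict) stop(msg, call. = FALSE)
    warning(msg, "; returning empty symbolization", call. = FALSE)
    return(integer(0))
  }
  # embedding matrix: row j = (x_j, x_{j+tau}, ..., x_{j+(m-1)tau})
  E <- matrix(0, n, m)
  for (k in seq_len(m)) E[, k] <- x[(k - 1L) * tau + seq_len(n)]
  # stable value ranks per row: R[,j] = rank of x at slot j, ties to the
  # earlier slot
  R <- matrix(1L, n, m)
  for (j in seq_len(m)) for (k in seq_len(m)) {
    if (k == j) next
    R[, j] <- R[, j] + if (k < j) (E[, k] <= E[, j]) else (E[, k] < E[, j])
  }
  # pattern digits: d[,k] = original slot of the k-th smallest value
  d <- matrix(0L, n, m)
  idx <- seq_len(n)
  for (j in seq_len(m)) d[cbind(idx, R[, j])] <- j
  # Lehmer code -> lexicographic rank
  ranks <- rep.int(1, n)
  for (i in seq_len(m - 1L)) {
    ci <- 0L
    for (j in (i + 1L):m) ci <- ci + (d[, j] < d[, i])
    ranks <- ranks + ci * factorial(m - i)
  }
  as.integer(ranks)
}

#' Ordinal-pattern probability distribution
#'
#' Tabulates a rank sequence produced by [symbolize()] into counts and
#' relative frequencies over all `m!` patterns.
#'
#' @param ranks Integer vector of pattern ranks in `1..m!` (non-empty).
#' @param m Embedding dimension the ranks were computed with.
#' @return An object of class `"pattern_distribution"`: list with `m`,
#'   `counts` (length `m!`), `probs` (length `m!`, sums to 1) and
#'   `n_vectors`.
#' @examples
#' d <- pattern_distribution(symbolize(c(3, 6, 8, 9, 5, 10, 2), m = 3), m = 3)
#' d$probs[d$probs > 0]  # 0.4 0.2 0.4
#' @export
pattern_distribution <- function(ranks, m) {
  m <- .check_m(m)
  N <- factorial(m)
  if (length(ranks) == 0L)
    stop("cannot form a pattern distribution from an empty rank sequence",
         call. = FALSE)
  if (!is.numeric(ranks) || anyNA(ranks) || any(ranks != as.integer(ranks)) ||
      any(ranks < 1) || any(ranks > N))
    stop("`ranks` must be integers in 1..m!", call. = FALSE)
  counts <- tabulate(as.integer(ranks), nbins = N)
  structure(list(m = m, counts = counts, probs = counts / length(ranks),
                 n_vectors = length(ranks)),
            class = "pattern_distribution")
}

#' @export
print.pattern_distribution <- function(x, ...) {
  cat(sprintf(
    "Ordinal-pattern distribution: m = %d, %d patterns, %d vectors\n",
    x$m, factorial(x$m), x$n_vectors))
  cat(sprintf("  observed %d patterns, missing %d; PE = %.4f\n",
              sum(x$counts > 0L), sum(x$counts == 0L),
              permutation_entropy(x)))
  invisible(x)
}

#' Normalized permutation entropy
#'
#' Shannon entropy of the ordinal-pattern probabilities, normalized by its
#' maximum `ln(m!)` (attained by the uniform distribution), so the value
#' lies in `[0, 1]`. Zero-probability patterns contribute nothing
#' (`0 * ln 0 := 0`); natural logarithms throughout.
#'
#' @param dist A `"pattern_distribution"` from [pattern_distribution()].
#' @return Normalized permutation entropy in `[0, 1]`.
#' @examples
#' d <- pattern_distribution(symbolize(sin(1:100), m = 4), m = 4)
#' permutation_entropy(d)
#' @export
permutation_entropy <- function(dist) {
  if (!inherits(dist, "pattern_distribution"))
    stop("`dist` must be a pattern_distribution", call. = FALSE)
  p <- dist$probs[dist$probs > 0]
  h <- -sum(p * log(p)) / log(factorial(dist$m))
  # clamp float dust so the [0, 1] contract is exact
  min(max(h, 0), 1)
}

#' Missing (forbidden) ordinal patterns
#'
#' Counts the patterns that never occur in the analyzed series: those with
#' zero probability. The normalized value divides by `m!`, giving the
#' fraction of pattern space left unvisited -- the quantity tracked as a
#' surrogate for intracranial compliance.
#'
#' @param dist A `"pattern_distribution"`.
#' @return List with `count` (integer, `0..m!`) and `normalized`
#'   (`count / m!`, in `[0, 1]`).
#' @examples
#' d <- pattern_distribution(symbolize(c(3, 6, 8, 9, 5, 10, 2), m = 3), m = 3)
#' missing_patterns(d)$count  # 2
#' @export
missing_patterns <- function(dist) {
  if (!inherits(dist, "pattern_distribution"))
    stop("`dist` must be a pattern_distribution", call. = FALSE)
  cnt <- sum(dist$counts == 0L)
  list(count = as.integer(cnt), normalized = cnt / factorial(dist$m))
}
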