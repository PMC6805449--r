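#' Transform a similarity matrix into a distance matrix
#'
#' Converts normalized similarities s in \[0, 1\] into distances with one of
#' four monotonically decreasing transforms, all satisfying d(s = 1) = 0:
#' \describe{
#'   \item{one_minus}{d = 1 - s}
#'   \item{inverse}{d = 1/s - 1 (the inverse pair of s = 1/(1 + d))}
#'   \item{neglog}{d = -ln(s)}
#'   \item{convex}{d = 1 - k s / (1 + k - s), convexity controlled by k > 0}
#' }
#' The convex transform (the default, with k = 0.382, approximately the
#' Golden Ratio minus one) inflates distances between very similar molecules
#' — where activity conservation is actually decided — while compressing the
#' uninformative low-similarity range; as k grows it approaches 1 - s.
#' For \code{inverse} and \code{neglog}, s = 0 implies infinite distance, so
#' similarities below \code{clamp_sim} are clamped to \code{clamp_sim}
#' before transforming (tying the clamp to a floor similarity keeps the
#' maximum distance on the transform's own scale).
#'
#' @param S similarity matrix (see [similarity_matrix()]).
#' @param method one of "convex", "one_minus", "inverse", "neglog".
#' @param k convexity parameter, > 0 (convex method only; default 0.382).
#' @param clamp_sim similarity floor for inverse/neglog (default 1e-6).
#' @return distance matrix: symmetric, zero diagonal, non-negative, with a
#'   \code{"transform"} attribute recording method and parameters.
#' @export
similarity_to_distance <- function(S,
                                   method = c("convex", "one_minus",
                                              "inverse", "neglog"),
                                   k = 0.382, clamp_sim = 1e-6) {
  method <- match.arg(method)
  s <- unclass(S)
  if (method == "convex" && k <= 0) stop("k must be > 0, got ", k)
  if (method %in% c("inverse", "neglog")) {
    stopifnot(clamp_sim > 0)
    s <- pmax(s, clamp_sim)
  }
  d <- switch(method,
    one_minus = 1 - s,
    inverse   = 1 / s - 1,
    neglog    = -log(s),
    convex    = 1 - (k * s) / (1 + k - s)
  )
  diag(d) <- 0
  attr(d, "transform") <- list(method = method, k = k, clamp_sim = clamp_sim)
  class(d) <- c("psma_distance", "matrix", "array")
  d
}

# apply the recorded transform to raw similarity values (vector or matrix);
# used when embedding new molecules with the training transform.
apply_transform <- function(s, tag) {
  k <- tag$k
  if (tag$method %in% c("inverse", "neglog")) s <- pmax(s, tag$clamp_sim)
  switch(tag$method,
    one_minus = 1 - s,
    inverse   = 1 / s - 1,
    neglog    = -log(s),
    convex    = 1 - (k * s) / (1 + k - s),
    stop("unknown transform method ", tag$method)
  )
}

#' Triangle-inequality diagnostics for a distance matrix
#'
#' The convex transform is not guaranteed to yield a metric, and the
#' projection methods consume the distances as-is; this reports (never
#' repairs) how non-metric a matrix is.  All point triples are checked
#' exhaustively when M <= 60, otherwise \code{n_triples} triples are sampled
#' uniformly with the given seed.
#'
#' @param D distance matrix.
#' @param n_triples number of sampled triples for large M (default 10000).
#' @param seed RNG seed for the sampling.
#' @return list with n_checked, n_violations, fraction, max_violation,
#'   symmetric and zero_diagonal flags.
#' @export
metric_diagnostics <- function(D, n_triples = 10000L, seed = 1L) {
  d <- unclass(D)
  m <- nrow(d)
  if (m < 3L) stop("need >=3 points for triangle diagnostics, got ", m)
  if (m <= 60L) {
    triples <- t(utils::combn(m, 3L))
  } else {
    set.seed(seed)
    triples <- matrix(0L, n_triples, 3L)
    for (i in seq_len(n_triples)) triples[i, ] <- sample.int(m, 3L)
  }
  ab <- d[cbind(triples[, 1], triples[, 2])]
  ac <- d[cbind(triples[, 1], triples[, 3])]
  bc <- d[cbind(triples[, 2], triples[, 3])]
  # worst excess over the three orientations of each triple
  excess <- pmax(ab - (ac + bc), ac - (ab + bc), bc - (ab + ac))
  viol <- excess > 1e-12
  list(
    n_checked = nrow(triples),
    n_violations = sum(viol),
    fraction = mean(viol),
    max_violation = if (any(viol)) max(excess) else 0,
    symmetric = max(abs(d - t(d))) <= 1e-12,
    zero_diagonal = all(diag(d) == 0)
  )
}

#' Mean and standard deviation of pairwise distances
#'
#' Summary over the M(M-1)/2 strictly-upper-triangular entries: each
#' unordered pair counted once, self-distances excluded (they are trivially
#' zero and would bias the mean).  The standard deviation is the sample
#' (n - 1) flavour.
#'
#' @param D distance matrix, M >= 2.
#' @return named numeric vector c(mean = , sd = ).
#' @export
distance_summary <- function(D) {
  d <- unclass(D)
  if (nrow(d) < 2L) stop("need >=2 molecules, got ", nrow(d))
  v <- d[upper.tri(d)]
  c(mean = mean(v), sd = stats::sd(v))
}

# pairwise Euclidean distances of a coordinate matrix, as a full matrix,
# so upper.tri() indexing lines up with the distance matrix
coord_dist <- function(coords) as.matrix(stats::dist(coords))
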