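# Per-point precision search: find beta_i so that the conditional
# distribution p_{j|i} ∝ exp(-beta_i * d_ij^2) has the requested perplexity
# (2^H).  Binary search on beta, 50 iterations.
perplexity_probs <- function(d2row, perplexity, tol = 1e-5) {
  target <- log(perplexity)
  beta <- 1
  betamin <- -Inf
  betamax <- Inf
  for (it in 1:50) {
    p <- exp(-d2row * beta)
    sump <- sum(p)
    if (sump == 0) { h <- 0; p[] <- 0 }
    else {
      h <- log(sump) + beta * sum(d2row * p) / sump
      p <- p / sump
    }
    diff <- h - target
    if (abs(diff) < tol) break
    if (diff > 0) {
      betamin <- beta
      beta <- if (is.finite(betamax)) (beta + betamax) / 2 else beta * 2
    } else {
      betamax <- beta
      beta <- if (is.finite(betamin)) (beta + betamin) / 2 else beta / 2
    }
  }
  p
}

#' t-distributed Stochastic Neighbor Embedding on a distance matrix
#'
#' Exact (O(M^2)) t-SNE consuming a precomputed distance matrix directly:
#' per-point Gaussian bandwidths are calibrated so each conditional
#' neighbour distribution has the requested perplexity, affinities are
#' symmetrized, and the Kullback-Leibler divergence to a Student-t (one
#' degree of freedom) output kernel is minimized by gradient descent with
#' momentum, adaptive gains and early exaggeration.  The heavy-tailed output
#' kernel relieves the crowding effect of projecting to 2D.  The result is
#' deterministic given \code{seed}; different seeds generally give different
#' (but comparable-quality) maps.
#'
#' @param D distance matrix (used as-is; affinities use squared distances).
#' @param perplexity effective neighbourhood size (default 30); requires
#'   M >= 3 * perplexity + 1.
#' @param seed RNG seed for the random initialization (default 1).
#' @param max_iter gradient-descent iterations (default 1000).
#' @param dims output dimensionality (default 2).
#' @param eta learning rate (default 200).
#' @return a \code{psma_projection} with the final KL divergence in
#'   \code{$kl}.
#' @export
tsne <- function(D, perplexity = 30, seed = 1L, max_iter = 1000L,
                 dims = 2L, eta = 200) {
  d <- unclass(D)
  m <- nrow(d)
  if (m < 3 * perplexity + 1)
    stop("perplexity ", perplexity, " too large: need M >= ",
         3 * perplexity + 1, ", got ", m)
  d2 <- d^2
  P <- matrix(0, m, m)
  for (i in seq_len(m)) {
    pr <- perplexity_probs(d2[i, -i], perplexity)
    P[i, -i] <- pr
  }
  P <- (P + t(P)) / (2 * m)
  P <- pmax(P, 1e-12)

  set.seed(seed)
  Y <- matrix(stats::rnorm(m * dims, sd = 1e-4), m, dims)
  dY <- matrix(0, m, dims)
  gains <- matrix(1, m, dims)
  exag_iter <- min(250L, max_iter)
  Pe <- P * 12          # early exaggeration
  momentum <- 0.5
  for (it in seq_len(max_iter)) {
    if (it == exag_iter + 1L) Pe <- P
    if (it == 251L) momentum <- 0.8
    sumY <- rowSums(Y^2)
    num <- 1 / (1 + outer(sumY, sumY, "+") - 2 * tcrossprod(Y))
    diag(num) <- 0
    Q <- pmax(num / sum(num), 1e-12)
    L <- (Pe - Q) * num
    grad <- 4 * (rowSums(L) * Y - L %*% Y)
    gains <- ifelse(sign(grad) != sign(dY), gains + 0.2, gains * 0.8)
    gains[gains < 0.01] <- 0.01
    dY <- momentum * dY - eta * gains * grad
    Y <- Y + dY
    Y <- sweep(Y, 2L, colMeans(Y))
  }
  kl <- sum(P * log(P / Q))
  ids <- rownames(d)
  if (is.null(ids)) ids <- paste0("mol", seq_len(m))
  new_projection(ids, Y, "tsne", seed = seed, iterations = max_iter,
                 converged = TRUE, extra = list(kl = kl, perplexity = perplexity))
}

#' Run a projection method by name
#'
#' Dispatcher used by the pipeline: "pcooa", "kmds", "sammon" or "tsne"
#' with each method's own defaults.
#'
#' @param D distance matrix.
#' @param method projection method name.
#' @param dims output dimensionality.
#' @param seed seed (t-SNE only).
#' @param perplexity perplexity (t-SNE only).
#' @param max_iter iteration cap (iterative methods).
#' @param ... passed through to the method.
#' @return a \code{psma_projection}.
#' @export
project <- function(D, method = c("pcooa", "kmds", "sammon", "tsne"),
                    dims = 2L, seed = 1L, perplexity = 30,
                    max_iter = NULL, ...) {
  method <- match.arg(method)
  switch(method,
    pcooa  = pcooa(D, dims = dims),
    kmds   = kruskal_mds(D, dims = dims,
                         max_iter = if (is.null(max_iter)) 50L else max_iter, ...),
    sammon = sammon(D, dims = dims,
                    max_iter = if (is.null(max_iter)) 100L else max_iter, ...),
    tsne   = tsne(D, dims = dims, seed = seed, perplexity = perplexity,
                  max_iter = if (is.null(max_iter)) 1000L else max_iter, ...)
  )
}
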