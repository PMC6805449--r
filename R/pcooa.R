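new_projection <- function(ids, coords, method, stress = NULL,
                           eigenvalues = NULL, seed = NULL,
                           iterations = NULL, converged = NA, trace = NULL,
                           extra = list()) {
  rownames(coords) <- ids
  structure(c(list(ids = ids, coords = coords, method = method,
                   stress = stress, eigenvalues = eigenvalues, seed = seed,
                   iterations = iterations, converged = converged,
                   trace = trace), extra),
            class = "psma_projection")
}

#' @export
print.psma_projection <- function(x, ...) {
  cat(sprintf("PSMA projection: %s, %d molecules, %d dims\n",
              x$method, nrow(x$coords), ncol(x$coords)))
  if (!is.null(x$stress)) cat(sprintf("  final stress: %.6g\n", x$stress))
  if (!is.null(x$eigenvalues)) {
    pos <- x$eigenvalues[x$eigenvalues > 0]
    cat(sprintf("  variance represented by %d axes: %.1f%%\n", ncol(x$coords),
                100 * sum(pos[seq_len(min(ncol(x$coords), length(pos)))]) / sum(pos)))
  }
  invisible(x)
}

#' Principal Coordinates Analysis (classical MDS)
#'
#' Double-centers the squared distance matrix, B = -1/2 J D^2 J with
#' J = I - 11'/M, eigendecomposes B, and returns the first \code{dims}
#' eigenvectors scaled by the square root of their (positive) eigenvalues.
#' Because the convex-transformed distances are generally non-Euclidean,
#' negative eigenvalues are expected; they are reported in the full spectrum
#' but excluded from the coordinates (standard Gower treatment).
#'
#' Sign convention: each eigenvector is flipped so that its
#' largest-magnitude entry is positive, making the output deterministic
#' across linear-algebra backends.
#'
#' @param D distance matrix.
#' @param dims number of output dimensions (default 2).
#' @return a \code{psma_projection} with coords, full eigenvalue spectrum
#'   and the fraction of positive-eigenvalue variance represented.
#' @export
pcooa <- function(D, dims = 2L) {
  d <- unclass(D)
  m <- nrow(d)
  if (m < dims + 1L) stop("need at least dims+1 points, got ", m)
  B <- -0.5 * d^2
  B <- sweep(B, 1L, rowMeans(B))
  B <- sweep(B, 2L, colMeans(B))
  B <- (B + t(B)) / 2
  e <- eigen(B, symmetric = TRUE)
  lambda <- e$values
  tol <- max(abs(lambda)) * 1e-9
  # genuinely negative eigenvalues among the top `dims` are an error;
  # near-zero ones (degenerate configurations, e.g. collinear points) are
  # clamped to 0 and give a zero-width axis
  if (lambda[dims] < -tol)
    stop("only ", sum(lambda > tol), " positive eigenvalues for ", dims,
         " requested dims; spectrum: ",
         paste(signif(lambda[seq_len(min(6, m))], 4), collapse = ", "))
  V <- e$vectors[, seq_len(dims), drop = FALSE]
  for (j in seq_len(dims)) {
    i <- which.max(abs(V[, j]))
    if (V[i, j] < 0) V[, j] <- -V[, j]
  }
  coords <- V %*% diag(sqrt(pmax(lambda[seq_len(dims)], 0)), dims)
  ids <- rownames(d)
  if (is.null(ids)) ids <- paste0("mol", seq_len(m))
  new_projection(ids, coords, "pcooa", eigenvalues = lambda,
                 converged = TRUE,
                 extra = list(variance_represented =
                                sum(lambda[seq_len(dims)]) / sum(lambda[lambda > tol])))
}

#' Stress of a configuration
#'
#' Pure evaluation (no optimization) of the projection error of given
#' coordinates against the original distances d(i,j), with d-hat(i,j) the
#' configuration's pairwise Euclidean distances:
#' \describe{
#'   \item{kruskal}{sqrt( sum (d - dhat)^2 / sum d^2 )}
#'   \item{sammon}{(1 / sum d) * sum (d - dhat)^2 / d}
#' }
#' Sums run over unordered pairs i < j.
#'
#' @param D distance matrix.
#' @param coords configuration matrix, rows aligned with D.
#' @param kind "kruskal" or "sammon".
#' @return scalar stress >= 0.
#' @export
stress <- function(D, coords, kind = c("kruskal", "sammon")) {
  kind <- match.arg(kind)
  d <- unclass(D)
  if (nrow(coords) != nrow(d))
    stop("coords rows (", nrow(coords), ") != matrix size (", nrow(d), ")")
  ut <- upper.tri(d)
  orig <- d[ut]
  proj <- coord_dist(coords)[ut]
  if (kind == "kruskal") {
    sqrt(sum((orig - proj)^2) / sum(orig^2))
  } else {
    if (any(orig == 0)) stop("sammon stress undefined for zero original distances")
    sum((orig - proj)^2 / orig) / sum(orig)
  }
}

#' Shepard diagram data and projection R-squared
#'
#' Pairs every original distance with the corresponding projected distance
#' (upper triangle, each pair once) and reports the squared Pearson
#' correlation between the two vectors — the R^2 measuring how faithfully
#' the projection preserves distances (1 = distortion-free).
#'
#' @param D distance matrix.
#' @param coords configuration matrix, rows aligned with D.
#' @return list with original_d, projected_d and r2.
#' @export
shepard <- function(D, coords) {
  d <- unclass(D)
  if (nrow(coords) != nrow(d))
    stop("coords rows (", nrow(coords), ") != matrix size (", nrow(d), ")")
  ut <- upper.tri(d)
  orig <- d[ut]
  proj <- coord_dist(coords)[ut]
  list(original_d = orig, projected_d = proj,
       r2 = stats::cor(orig, proj)^2)
}
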