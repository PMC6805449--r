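# Moore-Penrose pseudo-inverse via SVD with a relative singular-value cutoff
pinv <- function(A, rel_tol = 1e-10) {
  s <- svd(A)
  keep <- s$d > rel_tol * max(s$d)
  if (!any(keep)) return(matrix(0, ncol(A), nrow(A)))
  s$v[, keep, drop = FALSE] %*%
    (t(s$u[, keep, drop = FALSE]) / s$d[keep])
}

#' Linear out-of-sample embedding transform
#'
#' Models the projection as a linear map of the metric-space representation:
#' D T = C, hence T = D^+ C, where D is the training distance matrix, C the
#' projected training coordinates and D^+ the Moore-Penrose pseudo-inverse
#' (tolerance-truncated SVD).  For full-rank D this equals the literal
#' inverse, so D T reproduces C exactly; the pseudo-inverse degrades
#' gracefully when near-duplicate molecules make D ill-conditioned.  The
#' linear T is an approximation for every projection method (exact training
#' reproduction, approximate for new molecules near the training set) — in
#' particular for t-SNE, whose map is non-linear.
#'
#' @param D training distance matrix.
#' @param C a \code{psma_projection} (or coordinate matrix) over the same
#'   molecules in the same order.
#' @param rel_tol relative singular-value cutoff (default 1e-10).
#' @return object of class \code{psma_embedding} with the M x P matrix T,
#'   the training ids, the recorded distance transform tag and the training
#'   reproduction residual \code{max|DT - C|}.
#' @export
compute_transform <- function(D, C, rel_tol = 1e-10) {
  d <- unclass(D)
  coords <- if (inherits(C, "psma_projection")) C$coords else as.matrix(C)
  ids <- rownames(d)
  if (is.null(ids)) ids <- paste0("mol", seq_len(nrow(d)))
  cids <- if (inherits(C, "psma_projection")) C$ids else rownames(coords)
  if (!is.null(cids) && !identical(as.character(cids), as.character(ids)))
    stop("distance matrix and coordinate ids disagree")
  if (nrow(coords) != nrow(d)) stop("row count mismatch")
  Tm <- pinv(d, rel_tol) %*% coords
  residual <- max(abs(d %*% Tm - coords))
  structure(list(T = Tm, training_ids = ids, pinv_tolerance = rel_tol,
                 residual = residual,
                 transform_tag = attr(D, "transform")),
            class = "psma_embedding")
}

#' @export
print.psma_embedding <- function(x, ...) {
  cat(sprintf("PSMA embedding transform: %d training molecules -> %d dims (training residual %.3g)\n",
              nrow(x$T), ncol(x$T), x$residual))
  invisible(x)
}

#' Embed new molecules into the trained reference space
#'
#' For each new molecule, its similarities to the training molecules are
#' converted to distances with the same transform used in training, and the
#' resulting row vector d is mapped to coordinates by d T.  A molecule
#' identical to training molecule i (distance row = row i of D) lands
#' exactly on C's row i; quality degrades gradually for molecules far from
#' the training support.
#'
#' @param transform a \code{psma_embedding} from [compute_transform()].
#' @param new_similarities Q x M matrix of similarities to the training
#'   molecules; columns must match the training ids (reordered by name when
#'   column names are present, otherwise taken as already ordered).
#' @param distances set TRUE if \code{new_similarities} already contains
#'   distances (skips the similarity transform).
#' @return Q x P coordinate matrix.
#' @export
embed_new <- function(transform, new_similarities, distances = FALSE) {
  s <- as.matrix(new_similarities)
  if (ncol(s) != length(transform$training_ids))
    stop("expected ", length(transform$training_ids),
         " columns (one per training molecule), got ", ncol(s))
  if (!is.null(colnames(s))) {
    miss <- setdiff(transform$training_ids, colnames(s))
    if (length(miss) > 0)
      stop("missing training ids in similarity columns: ",
           paste(utils::head(miss, 5), collapse = ", "))
    s <- s[, transform$training_ids, drop = FALSE]
  }
  d <- if (distances) s else {
    if (is.null(transform$transform_tag))
      stop("embedding transform carries no distance-transform tag; pass distances")
    apply_transform(s, transform$transform_tag)
  }
  out <- d %*% transform$T
  rownames(out) <- rownames(s)
  out
}
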