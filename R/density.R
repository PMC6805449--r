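#' Silverman normal-reference bandwidth
#'
#' \deqn{h = 1.06 \min(\hat\sigma, R/1.34)\, n^{-1/5}}
#' where \eqn{\hat\sigma} is the sample standard deviation and R the
#' interquartile range Q3 - Q1 (quartiles by the standard linear
#' interpolation convention, \code{stats::quantile} type 7).
#'
#' @param x numeric vector, length >= 2, with non-degenerate spread.
#' @return bandwidth (same units as x).
#' @export
silverman_bandwidth <- function(x) {
  n <- length(x)
  if (n < 2L) stop("need at least 2 values, got ", n)
  h <- 1.06 * min(stats::sd(x), stats::IQR(x) / 1.34) * n^(-1 / 5)
  if (!is.finite(h) || h <= 0)
    stop("degenerate sample (zero spread): bandwidth would be ", h)
  h
}

#' Fit a 2D Gaussian kernel density map
#'
#' Stores the support points and per-axis bandwidths of the product-kernel
#' estimator
#' \deqn{f(x,y) = \frac{1}{n h_x h_y} \sum_s
#'   \phi\!\left(\frac{x - x_s}{h_x}\right)
#'   \phi\!\left(\frac{y - y_s}{h_y}\right)}
#' with \eqn{\phi} the standard normal density.  Evaluation is always the
#' exact kernel sum — no grid precomputation or interpolation — so the
#' estimate integrates to 1 analytically.
#'
#' @param points N x 2 matrix of support coordinates.
#' @param hx,hy positive per-axis bandwidths.
#' @return object of class \code{psma_kdm}.
#' @export
kde2d_fit <- function(points, hx, hy) {
  points <- as.matrix(points)
  if (ncol(points) != 2L) stop("points must be N x 2")
  if (nrow(points) < 1L) stop("need at least one support point")
  if (!is.finite(hx) || hx <= 0 || !is.finite(hy) || hy <= 0)
    stop("bandwidths must be positive, got hx=", hx, " hy=", hy)
  structure(list(support = points, hx = hx, hy = hy, n = nrow(points)),
            class = "psma_kdm")
}

#' Evaluate a kernel density map
#'
#' Exact kernel-sum evaluation at arbitrary query points (no grid, no
#' interpolation), so grid resolution can only ever affect pictures, never
#' classification.
#'
#' @param kdm a \code{psma_kdm}.
#' @param queries Q x 2 matrix of query coordinates.
#' @return numeric vector of Q densities (>= 0).
#' @export
kde2d_eval <- function(kdm, queries) {
  queries <- matrix(as.numeric(queries), ncol = 2L)
  if (!all(is.finite(queries))) stop("queries must be finite")
  zx <- outer(queries[, 1], kdm$support[, 1], "-") / kdm$hx
  zy <- outer(queries[, 2], kdm$support[, 2], "-") / kdm$hy
  rowSums(stats::dnorm(zx) * stats::dnorm(zy)) / (kdm$n * kdm$hx * kdm$hy)
}

#' Evaluate a kernel density map on a lattice
#'
#' @param kdm a \code{psma_kdm}.
#' @param nx,ny lattice resolution (>= 2).
#' @param extent c(xmin, xmax, ymin, ymax); defaults to the support bounding
#'   box extended by 3 bandwidths.
#' @return list with axis vectors x (nx), y (ny) and z (nx x ny matrix,
#'   z\[i, j\] = f(x\[i\], y\[j\])).
#' @export
kde2d_grid <- function(kdm, nx = 100L, ny = 100L, extent = NULL) {
  if (nx < 2L || ny < 2L) stop("grid must be at least 2 x 2")
  if (is.null(extent)) {
    extent <- c(range(kdm$support[, 1]) + c(-3, 3) * kdm$hx,
                range(kdm$support[, 2]) + c(-3, 3) * kdm$hy)
  }
  if (length(extent) != 4L || !all(is.finite(extent)) ||
      extent[1] >= extent[2] || extent[3] >= extent[4])
    stop("degenerate extent: ", paste(extent, collapse = ", "))
  x <- seq(extent[1], extent[2], length.out = nx)
  y <- seq(extent[3], extent[4], length.out = ny)
  grid <- cbind(rep(x, times = ny), rep(y, each = nx))
  z <- matrix(kde2d_eval(kdm, grid), nrow = nx, ncol = ny)
  list(x = x, y = y, z = z)
}
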