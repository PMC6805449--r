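# Weighted pool-adjacent-violators for non-decreasing fits.  `y` are group
# means ordered by the predictor, `w` group weights; returns fitted group
# values.  Groups are pre-pooled over tied predictor values (Kruskal's
# "primary" tie treatment: a tied block shares one disparity).
pava <- function(y, w) {
  n <- length(y)
  ghat <- y
  gw <- w
  # index of the start of each active block
  lo <- seq_len(n)
  k <- 0L
  for (i in seq_len(n)) {
    k <- k + 1L
    ghat[k] <- y[i]; gw[k] <- w[i]; lo[k] <- i
    while (k > 1L && ghat[k - 1L] > ghat[k]) {
      ghat[k - 1L] <- (gw[k - 1L] * ghat[k - 1L] + gw[k] * ghat[k]) /
        (gw[k - 1L] + gw[k])
      gw[k - 1L] <- gw[k - 1L] + gw[k]
      k <- k - 1L
    }
  }
  out <- numeric(n)
  starts <- lo[seq_len(k)]
  ends <- c(starts[-1L] - 1L, n)
  for (b in seq_len(k)) out[starts[b]:ends[b]] <- ghat[b]
  out
}

# Disparities for Kruskal MDS: isotonic regression of projected distances on
# the rank order of the original distances, ties pooled.
disparities <- function(orig, proj) {
  o <- order(orig)
  grp <- cumsum(!duplicated(orig[o]))
  gw <- tabulate(grp)
  gmean <- rowsum(proj[o], grp, reorder = FALSE)[, 1] / gw
  fit <- pava(as.numeric(gmean), as.numeric(gw))
  dhat <- numeric(length(orig))
  dhat[o] <- fit[grp]
  dhat
}

# replace zero off-diagonal distances by `eps`, warning once
jitter_zeros <- function(d, eps = 1e-9) {
  z <- d == 0 & !diag(nrow(d))
  if (any(z)) {
    warning(sum(z) / 2, " zero off-diagonal distance(s) jittered to ", eps)
    d[z] <- eps
  }
  d
}

resolve_init <- function(init, D, dims) {
  if (is.character(init) && identical(init, "pcooa")) {
    pcooa(D, dims)$coords
  } else {
    init <- as.matrix(init)
    if (nrow(init) != nrow(D) || ncol(init) != dims)
      stop("init must be ", nrow(D), " x ", dims)
    init
  }
}

# stress-1 of a configuration given fixed disparities:
# sqrt( sum (dproj - dhat)^2 / sum dproj^2 )
stress1 <- function(proj, dhat) sqrt(sum((proj - dhat)^2) / sum(proj^2))

#' Kruskal non-metric multidimensional scaling
#'
#' Finds a low-dimensional configuration preserving only the rank order of
#' the input distances.  Each iteration fits disparities by monotone
#' (isotonic) regression of the configuration distances on the rank order of
#' D (tied originals share one disparity), then moves the configuration by a
#' Guttman-transform step; a step is only accepted if Kruskal's stress-1
#'
#' \deqn{S = \sqrt{\sum_{i<j} (\hat d_{ij} - d^*_{ij})^2 / \sum_{i<j} \hat d_{ij}^2}}
#'
#' (\eqn{\hat d} configuration distances, \eqn{d^*} disparities) decreases,
#' with step halving otherwise, so the recorded stress trace is
#' non-increasing.  Stress is returned as a fraction in \[0, 1\].
#'
#' @param D distance matrix; zero off-diagonal entries are jittered to 1e-9
#'   with a warning.
#' @param init starting configuration: "pcooa" (default, the principal
#'   coordinates solution) or an explicit matrix.
#' @param max_iter maximum accepted iterations (default 50).
#' @param tol convergence: stop when the stress improvement, on the percent
#'   scale, drops below tol (default 1e-3, i.e. 1e-5 as a fraction).
#' @param dims output dimensionality (default 2).
#' @return a \code{psma_projection} with final stress and the stress trace.
#' @export
kruskal_mds <- function(D, init = "pcooa", max_iter = 50L, tol = 1e-3,
                        dims = 2L) {
  d <- unclass(D)
  m <- nrow(d)
  if (m < 4L) stop("need at least 4 points, got ", m)
  d <- jitter_zeros(d)
  ut <- upper.tri(d)
  orig <- d[ut]
  X <- resolve_init(init, d, dims)

  conf_stress <- function(X) {
    proj <- coord_dist(X)[ut]
    dhat <- disparities(orig, proj)
    list(stress = stress1(proj, dhat), proj = proj, dhat = dhat)
  }
  cur <- conf_stress(X)
  trace <- cur$stress
  iter <- 0L
  converged <- FALSE
  while (iter < max_iter) {
    # Guttman transform with current disparities
    dp <- coord_dist(X)
    dh <- matrix(0, m, m)
    dh[ut] <- cur$dhat
    dh <- dh + t(dh)
    ratio <- ifelse(dp > 0, dh / dp, 0)
    diag(ratio) <- 0
    Xg <- (rowSums(ratio) * X - ratio %*% X) / m
    # accept only if stress decreases; halve step toward Xg otherwise
    alpha <- 1
    improved <- FALSE
    for (h in 1:10) {
      Xt <- (1 - alpha) * X + alpha * Xg
      cand <- conf_stress(Xt)
      if (cand$stress < cur$stress) {
        X <- Xt; prev <- cur$stress; cur <- cand; improved <- TRUE
        break
      }
      alpha <- alpha / 2
    }
    if (!improved) { converged <- TRUE; break }
    iter <- iter + 1L
    trace <- c(trace, cur$stress)
    if ((prev - cur$stress) * 100 < tol || cur$stress < 1e-12) {
      converged <- TRUE
      break
    }
  }
  ids <- rownames(d)
  if (is.null(ids)) ids <- paste0("mol", seq_len(m))
  new_projection(ids, X, "kmds", stress = cur$stress, iterations = iter,
                 converged = converged, trace = trace)
}

#' Sammon mapping
#'
#' Non-linear MDS minimizing Sammon's stress
#' \deqn{E = \frac{1}{\sum_{i<j} d_{ij}} \sum_{i<j} \frac{(d_{ij} - \hat d_{ij})^2}{d_{ij}}}
#' which weights each residual by the inverse original distance, emphasizing
#' the preservation of small distances.  Optimized by Sammon's
#' pseudo-Newton diagonal update scaled by the \code{magic} step factor,
#' with step halving whenever a step would increase the stress (so the
#' recorded trace is non-increasing).
#'
#' @param D distance matrix; zero off-diagonal entries are jittered (Eq.
#'   weights divide by d).
#' @param init "pcooa" (default) or an explicit starting matrix.
#' @param max_iter maximum iterations (default 100).
#' @param tol stop when the relative stress change drops below tol
#'   (default 1e-4).
#' @param magic step-size factor (default 0.3).
#' @param dims output dimensionality (default 2).
#' @return a \code{psma_projection} with final stress and trace.
#' @export
sammon <- function(D, init = "pcooa", max_iter = 100L, tol = 1e-4,
                   magic = 0.3, dims = 2L) {
  d <- unclass(D)
  m <- nrow(d)
  if (m < 3L) stop("need at least 3 points, got ", m)
  d <- jitter_zeros(d)
  ut <- upper.tri(d)
  orig <- d[ut]
  csum <- sum(orig)
  X <- resolve_init(init, d, dims)

  sstress <- function(X) {
    proj <- coord_dist(X)[ut]
    sum((orig - proj)^2 / orig) / csum
  }
  cur <- sstress(X)
  trace <- cur
  iter <- 0L
  converged <- FALSE
  offdiag <- !diag(m)
  while (iter < max_iter) {
    dp <- coord_dist(X)
    dp[dp == 0] <- 1e-12          # guards diagonal and coincident points
    delta <- d - dp
    A <- ifelse(offdiag, delta / (d * dp), 0)         # gradient weights
    B1 <- ifelse(offdiag, 1 / (d * dp), 0)
    grad <- matrix(0, m, dims)
    hess <- matrix(0, m, dims)
    for (q in seq_len(dims)) {
      DX <- outer(X[, q], X[, q], "-")
      grad[, q] <- (-2 / csum) * (rowSums(A) * X[, q] - A %*% X[, q])
      term <- B1 * (delta - (DX^2 / dp) * (1 + delta / dp))
      hess[, q] <- (-2 / csum) * rowSums(term)
    }
    step <- grad / pmax(abs(hess), 1e-12)
    alpha <- magic
    improved <- FALSE
    for (h in 1:10) {
      Xt <- X - alpha * step
      cand <- sstress(Xt)
      if (cand < cur) { X <- Xt; prev <- cur; cur <- cand; improved <- TRUE; break }
      alpha <- alpha / 2
    }
    if (!improved) { converged <- TRUE; break }
    iter <- iter + 1L
    trace <- c(trace, cur)
    if (prev - cur < tol * max(cur, 1e-12) || cur < 1e-14) {
      converged <- TRUE
      break
    }
  }
  ids <- rownames(d)
  if (is.null(ids)) ids <- paste0("mol", seq_len(m))
  new_projection(ids, X, "sammon", stress = cur, iterations = iter,
                 converged = converged, trace = trace)
}
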