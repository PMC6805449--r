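#' Generate a synthetic molecule set with known ground truth
#'
#' Emulates the external inputs of the pipeline — a similarity matrix plus
#' an activity table — from a stated latent world: cluster centroids placed
#' at mutual distance \code{separation} in a latent 2D plane, molecules
#' scattered around them with isotropic Gaussian noise, positives drawn
#' from the first cluster (with an exact fraction \code{label_noise} of all
#' labels flipped), and latent Euclidean distances mapped to similarities
#' by the algebraic inverse of the convex distance transform:
#' \deqn{s = \frac{(1+k)(1-d')}{k + 1 - d'}, \quad d' = d / (d_{max}(1 + 10^{-6}))}
#' so that transforming the similarities back with the same k reproduces
#' the rescaled latent distances exactly.  The max-rescaling keeps all
#' similarities strictly positive, which keeps the fixtures valid for every
#' distance transform (no infinite distances under neglog/inverse).
#'
#' Defaults state the package's reference world: a SIGMAR1-shaped set of
#' 56 positives and 170 negatives in two clusters separated by 10 noise
#' standard deviations with no label noise — the clean parameter-recovery
#' regime.
#'
#' @param n_pos,n_neg class sizes (>= 2 each).
#' @param n_clusters number of latent clusters (>= 1); positives live in
#'   cluster 1, negatives are spread round-robin over the others (or share
#'   cluster 1 when n_clusters = 1).
#' @param separation mutual centroid distance (latent units; >= 0).
#' @param noise_sd isotropic within-cluster standard deviation.
#' @param label_noise fraction of labels flipped, in \[0, 0.5).
#' @param k convexity parameter of the similarity mapping (> 0).
#' @param seed RNG seed; the whole set is deterministic given it.
#' @return object of class \code{psma_synthetic}: list with ids, latent
#'   (M x 2), labels (activity table), similarity and params.
#' @export
generate_clusters <- function(n_pos = 56L, n_neg = 170L, n_clusters = 2L,
                              separation = 10, noise_sd = 1,
                              label_noise = 0, k = 0.382, seed = 1L) {
  if (n_pos < 2L || n_neg < 2L) stop("need >=2 molecules per class")
  if (n_clusters < 1L) stop("need >=1 cluster")
  if (separation < 0) stop("separation must be >= 0")
  if (label_noise < 0 || label_noise >= 0.5)
    stop("label_noise must be in [0, 0.5), got ", label_noise)
  if (k <= 0) stop("k must be > 0")
  set.seed(seed)
  m <- n_pos + n_neg
  centroids <- if (n_clusters == 1L) {
    matrix(0, 1, 2)
  } else if (n_clusters == 2L) {
    rbind(c(0, 0), c(separation, 0))
  } else if (n_clusters == 3L) {
    separation * rbind(c(0, 0), c(1, 0), c(0.5, sqrt(3) / 2))
  } else {
    # circle with adjacent chord = separation (mutual distance approximate
    # beyond 3 clusters, exact between neighbours)
    r <- separation / (2 * sin(pi / n_clusters))
    ang <- 2 * pi * (seq_len(n_clusters) - 1) / n_clusters
    cbind(r * cos(ang), r * sin(ang))
  }
  cl <- integer(m)
  cl[seq_len(n_pos)] <- 1L
  cl[n_pos + seq_len(n_neg)] <- if (n_clusters == 1L) 1L else
    2L + (seq_len(n_neg) - 1L) %% (n_clusters - 1L)
  latent <- centroids[cl, , drop = FALSE] +
    matrix(stats::rnorm(2 * m, sd = noise_sd), m, 2)
  labels <- as.integer(cl == 1L)
  if (n_clusters == 1L) labels <- rep(c(1L, 0L), c(n_pos, n_neg))
  n_flip <- round(label_noise * m)
  if (n_flip > 0) {
    flip <- sample.int(m, n_flip)
    labels[flip] <- 1L - labels[flip]
  }
  ids <- sprintf("mol%03d", seq_len(m))
  d <- as.matrix(stats::dist(latent))
  dprime <- d / (max(d) * (1 + 1e-6))
  s <- (1 + k) * (1 - dprime) / (k + 1 - dprime)
  diag(s) <- 1
  dimnames(s) <- list(ids, ids)
  rownames(latent) <- ids
  structure(list(
    ids = ids, latent = latent,
    labels = data.frame(id = ids, ki = NA_real_, label = labels,
                        stringsAsFactors = FALSE),
    similarity = similarity_matrix(s),
    params = list(n_pos = n_pos, n_neg = n_neg, n_clusters = n_clusters,
                  separation = separation, noise_sd = noise_sd,
                  label_noise = label_noise, k = k, seed = seed)
  ), class = "psma_synthetic")
}

#' Named synthetic fixtures
#'
#' \describe{
#'   \item{tiny}{20 molecules (10 pos / 10 neg), for doctest-speed runs.}
#'   \item{unbalanced}{56 pos / 170 neg — the SIGMAR1-shaped class ratio,
#'     exercising the unbalanced-data regime (decent AUC, depressed MCC).}
#'   \item{overlap}{40 pos / 120 neg with clusters only 2 noise standard
#'     deviations apart — the hard, overlapping case.}
#' }
#' All fixtures are synthetic stand-ins for real similarity matrices.
#'
#' @param name fixture name.
#' @param seed RNG seed.
#' @return a \code{psma_synthetic} set.
#' @export
make_fixture <- function(name = c("tiny", "unbalanced", "overlap"),
                         seed = 1L) {
  name <- match.arg(name)
  switch(name,
    tiny       = generate_clusters(n_pos = 10L, n_neg = 10L, seed = seed),
    unbalanced = generate_clusters(n_pos = 56L, n_neg = 170L, seed = seed),
    overlap    = generate_clusters(n_pos = 40L, n_neg = 120L,
                                   separation = 2, seed = seed)
  )
}

#' Write a synthetic set as standard pipeline input files
#'
#' @param synth a \code{psma_synthetic} set.
#' @param outdir output directory.
#' @return invisible vector of the two file paths (similarity.tsv,
#'   activity.tsv).
#' @export
write_synthetic <- function(synth, outdir) {
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
  fs <- file.path(outdir, "similarity.tsv")
  m <- unclass(synth$similarity)
  tab <- rbind(c("id", colnames(m)),
               cbind(rownames(m), matrix(fmt_num(m), nrow(m))))
  utils::write.table(tab, fs, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  fa <- file.path(outdir, "activity.tsv")
  utils::write.table(data.frame(id = synth$ids, label = synth$labels$label),
                     fa, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(c(fs, fa))
}
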