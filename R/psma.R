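#' Fit a probabilistic surface of molecular activity
#'
#' Splits the projected training molecules into actives and inactives, fits
#' one 2D Gaussian kernel density map per class — with a common pair of
#' Silverman bandwidths computed once from all training points pooled — and
#' stores class priors, so that the posterior
#' \deqn{P(m_+ \mid (x,y)) = \frac{P((x,y) \mid m_+)\, P(m_+)}{P((x,y))}}
#' can be evaluated anywhere in the projected plane.  The two class maps are
#' proper densities (each integrates to 1); the priors default to the
#' empirical class frequencies of the training data, matching the
#' deliberately unbalanced composition of real screening sets, and can be
#' overridden for screening scenarios.
#'
#' @param coords a \code{psma_projection} or an M x 2 matrix with molecule
#'   ids as rownames.
#' @param labels activity table (data.frame with id, label) covering every
#'   coordinate row; see [activity_table()].
#' @param transform optional [compute_transform()] result, stored for
#'   out-of-sample embedding.
#' @param priors optional c(prior_pos, prior_neg), each in (0,1), summing
#'   to 1.
#' @param bandwidth_scale multiplier applied to both Silverman bandwidths
#'   (default 1).
#' @return object of class \code{psma_model}.
#' @export
fit_psma <- function(coords, labels, transform = NULL, priors = NULL,
                     bandwidth_scale = 1) {
  if (inherits(coords, "psma_projection")) {
    meta <- list(method = coords$method, seed = coords$seed,
                 stress = coords$stress)
    ids <- coords$ids
    coords <- coords$coords
  } else {
    meta <- list(method = "unknown")
    coords <- as.matrix(coords)
    ids <- rownames(coords)
  }
  if (is.null(ids)) stop("coordinates must carry molecule ids")
  lab <- labels$label[match(ids, labels$id)]
  if (anyNA(lab))
    stop("no label for id(s): ",
         paste(utils::head(ids[is.na(lab)], 5), collapse = ", "))
  n_pos <- sum(lab == 1L)
  n_neg <- sum(lab == 0L)
  if (n_pos < 2L || n_neg < 2L)
    stop("need >=2 molecules per class, got ", n_pos, " positive / ",
         n_neg, " negative")
  if (bandwidth_scale <= 0) stop("bandwidth_scale must be positive")
  # common bandwidths from all the data, shared by both class maps
  hx <- silverman_bandwidth(coords[, 1]) * bandwidth_scale
  hy <- silverman_bandwidth(coords[, 2]) * bandwidth_scale
  kdm_pos <- kde2d_fit(coords[lab == 1L, , drop = FALSE], hx, hy)
  kdm_neg <- kde2d_fit(coords[lab == 0L, , drop = FALSE], hx, hy)
  if (is.null(priors)) {
    prior_pos <- n_pos / (n_pos + n_neg)
  } else {
    if (length(priors) != 2L || abs(sum(priors) - 1) > 1e-8 ||
        any(priors <= 0) || any(priors >= 1))
      stop("priors must be two values in (0,1) summing to 1, got ",
           paste(priors, collapse = ", "))
    prior_pos <- priors[1]
  }
  model <- structure(list(
    kdm_pos = kdm_pos, kdm_neg = kdm_neg,
    prior_pos = prior_pos, prior_neg = 1 - prior_pos,
    transform = transform, projection_meta = meta,
    training_ids = ids
  ), class = "psma_model")
  mix <- model$prior_pos * kde2d_eval(kdm_pos, coords) +
    model$prior_neg * kde2d_eval(kdm_neg, coords)
  model$peak_density <- max(mix)
  model
}

#' @export
print.psma_model <- function(x, ...) {
  cat(sprintf(paste0("PSMA model: %d pos / %d neg training molecules ",
                     "(prior_pos %.4f)\n  bandwidths hx=%.4g hy=%.4g, ",
                     "projection %s\n"),
              x$kdm_pos$n, x$kdm_neg$n, x$prior_pos,
              x$kdm_pos$hx, x$kdm_pos$hy, x$projection_meta$method))
  invisible(x)
}

#' Posterior probability of activity at 2D coordinates
#'
#' Bayes quotient of the two class-conditional kernel density maps:
#' p_pos = L+ pi+ / (L+ pi+ + L- pi-), evaluated exactly (no grid
#' interpolation).  Where the total mixture density falls below 1e-12 times
#' its peak over the training support, the query is outside the model's
#' applicability domain: \code{in_domain} is FALSE and the posterior falls
#' back to the priors.
#'
#' @param model a fitted \code{psma_model}.
#' @param queries Q x 2 coordinate matrix.
#' @return data.frame with p_pos, p_neg, density_total, in_domain.
#' @export
posterior <- function(model, queries) {
  queries <- matrix(as.numeric(queries), ncol = 2L)
  lpos <- kde2d_eval(model$kdm_pos, queries)
  lneg <- kde2d_eval(model$kdm_neg, queries)
  num_pos <- lpos * model$prior_pos
  num_neg <- lneg * model$prior_neg
  den <- num_pos + num_neg
  eps <- 1e-12 * model$peak_density
  in_domain <- den > eps
  p_pos <- ifelse(den > 0, num_pos / den, model$prior_pos)
  p_neg <- ifelse(den > 0, num_neg / den, model$prior_neg)
  p_pos[!in_domain] <- model$prior_pos
  p_neg[!in_domain] <- model$prior_neg
  data.frame(p_pos = p_pos, p_neg = p_neg,
             density_total = den, in_domain = in_domain)
}

#' Classify 2D coordinates with a PSMA model
#'
#' A query is labelled positive iff its posterior p_pos exceeds
#' \code{threshold}; at the default 0.5 this is exactly
#' P(m+ | (x,y)) > P(m- | (x,y)).  Out-of-domain queries are labelled by
#' the priors with the flag propagated, and their score is the positive
#' prior so they sort neutrally in ROC sweeps.
#'
#' @param model a fitted \code{psma_model}.
#' @param queries Q x 2 coordinate matrix.
#' @param threshold posterior cutoff in (0, 1), default 0.5.
#' @return data.frame with label (integer 1/0), score (= p_pos) and
#'   in_domain.
#' @export
classify <- function(model, queries, threshold = 0.5) {
  if (threshold <= 0 || threshold >= 1)
    stop("threshold must be in (0,1), got ", threshold)
  post <- posterior(model, queries)
  data.frame(label = as.integer(post$p_pos > threshold),
             score = post$p_pos, in_domain = post$in_domain)
}

#' Posterior activity surface on a lattice
#'
#' Evaluates the posterior and both class likelihoods on an nx x ny lattice
#' for contour or 3D rendering.  Values at lattice nodes are exact (same
#' kernel sums as [posterior()]), so the resolution is purely cosmetic.
#'
#' @param model a fitted \code{psma_model}.
#' @param nx,ny lattice resolution (default 100).
#' @param extent c(xmin, xmax, ymin, ymax); defaults to the pooled support
#'   bounding box extended by 3 bandwidths.
#' @return list with x, y axes and nx x ny matrices p_pos, l_pos, l_neg.
#' @export
posterior_surface <- function(model, nx = 100L, ny = 100L, extent = NULL) {
  support <- rbind(model$kdm_pos$support, model$kdm_neg$support)
  if (is.null(extent)) {
    extent <- c(range(support[, 1]) + c(-3, 3) * model$kdm_pos$hx,
                range(support[, 2]) + c(-3, 3) * model$kdm_pos$hy)
  }
  gp <- kde2d_grid(model$kdm_pos, nx, ny, extent)
  gn <- kde2d_grid(model$kdm_neg, nx, ny, extent)
  grid <- cbind(rep(gp$x, times = ny), rep(gp$y, each = nx))
  post <- posterior(model, grid)
  list(x = gp$x, y = gp$y,
       p_pos = matrix(post$p_pos, nx, ny),
       l_pos = gp$z, l_neg = gn$z)
}

#' Serialize a PSMA model to a JSON bundle
#'
#' Stores support points, bandwidths, priors, the embedding transform and
#' projection provenance under a version tag so classify-only runs need no
#' refit.
#'
#' @param model a \code{psma_model}.
#' @param path output file path.
#' @return invisible path.
#' @export
write_psma <- function(model, path) {
  bundle <- list(
    format = "psma-model", version = 1L,
    prior_pos = model$prior_pos,
    hx = model$kdm_pos$hx, hy = model$kdm_pos$hy,
    support_pos = unname(model$kdm_pos$support),
    support_neg = unname(model$kdm_neg$support),
    training_ids = model$training_ids,
    peak_density = model$peak_density,
    projection_meta = model$projection_meta,
    transform = if (is.null(model$transform)) NULL else list(
      T = unname(model$transform$T),
      training_ids = model$transform$training_ids,
      pinv_tolerance = model$transform$pinv_tolerance,
      transform_tag = model$transform$transform_tag
    )
  )
  jsonlite::write_json(bundle, path, auto_unbox = TRUE, digits = NA,
                       null = "null")
  invisible(path)
}

#' Load a PSMA model bundle written by [write_psma()]
#' @param path bundle path.
#' @return a \code{psma_model}.
#' @export
read_psma <- function(path) {
  b <- jsonlite::read_json(path, simplifyVector = TRUE)
  if (!identical(b$format, "psma-model"))
    stop("not a psma model bundle: ", path)
  tr <- NULL
  if (!is.null(b$transform) && length(b$transform) > 0) {
    tr <- structure(list(T = as.matrix(b$transform$T),
                         training_ids = b$transform$training_ids,
                         pinv_tolerance = b$transform$pinv_tolerance,
                         residual = NA_real_,
                         transform_tag = b$transform$transform_tag),
                    class = "psma_embedding")
  }
  structure(list(
    kdm_pos = kde2d_fit(as.matrix(b$support_pos), b$hx, b$hy),
    kdm_neg = kde2d_fit(as.matrix(b$support_neg), b$hx, b$hy),
    prior_pos = b$prior_pos, prior_neg = 1 - b$prior_pos,
    transform = tr, projection_meta = b$projection_meta,
    training_ids = b$training_ids, peak_density = b$peak_density
  ), class = "psma_model")
}
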