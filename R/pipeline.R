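#' End-to-end PSMA pipeline
#'
#' Reproduces the full protocol: stratified train/test split, similarity to
#' distance transform (training block only), 2D projection of the training
#' distances, linear embedding transform T = D^+ C, per-class kernel
#' density maps with pooled Silverman bandwidths and empirical priors,
#' embedding of the held-out molecules from their similarity rows to the
#' training set, posterior classification, and ROC/AUC + MCC scoring.  The
#' run is deterministic given the seeds in the call.
#'
#' @param similarity similarity matrix covering all molecules.
#' @param activity activity table with a label for every molecule id.
#' @param method projection method: "pcooa", "kmds", "sammon" or "tsne".
#' @param transform similarity-to-distance transform (default "convex").
#' @param k convexity parameter (default 0.382).
#' @param clamp_sim similarity floor for inverse/neglog transforms.
#' @param dims projection dimensionality (default 2).
#' @param test_fraction held-out fraction (default 0.2).
#' @param split_seed seed of the train/test split.
#' @param tsne_seed seed of the t-SNE initialization.
#' @param perplexity t-SNE perplexity (default 30).
#' @param threshold classification cutoff (default 0.5).
#' @param priors optional priors override c(pos, neg).
#' @param stratified stratified split (default TRUE).
#' @param bandwidth_scale multiplier on both Silverman bandwidths.
#' @param outdir if non-NULL, artifacts are written there via
#'   [write_artifacts()].
#' @param grid surface lattice resolution when writing artifacts.
#' @return list with model (\code{psma_model}), report (AUC, MCC,
#'   confusion, ROC, Shepard r2, stress, sizes, seeds, config) and
#'   coords (per-molecule id, x, y, label, split, score).
#' @export
run_pipeline <- function(similarity, activity,
                         method = c("pcooa", "kmds", "sammon", "tsne"),
                         transform = "convex", k = 0.382, clamp_sim = 1e-6,
                         dims = 2L, test_fraction = 0.2, split_seed = 1L,
                         tsne_seed = 1L, perplexity = 30, threshold = 0.5,
                         priors = NULL, stratified = TRUE,
                         bandwidth_scale = 1, outdir = NULL, grid = 100L) {
  method <- match.arg(method)
  s <- unclass(similarity)
  ids <- rownames(s)
  missing_act <- setdiff(ids, activity$id)
  missing_sim <- setdiff(activity$id, ids)
  if (length(missing_act) > 0 || length(missing_sim) > 0)
    stop("id mismatch between similarity matrix and activity table; ",
         "missing from activity: ",
         paste(utils::head(missing_act, 5), collapse = ", "),
         "; missing from similarity: ",
         paste(utils::head(missing_sim, 5), collapse = ", "))
  activity <- activity[match(ids, activity$id), ]

  split <- split_train_test(activity, test_fraction = test_fraction,
                            seed = split_seed, stratified = stratified)
  tr <- split$train
  te <- split$test

  S_train <- similarity_matrix(s[tr, tr, drop = FALSE])
  D_train <- similarity_to_distance(S_train, method = transform, k = k,
                                    clamp_sim = clamp_sim)
  proj <- project(D_train, method = method, dims = dims, seed = tsne_seed,
                  perplexity = perplexity)
  emb <- compute_transform(D_train, proj)
  model <- fit_psma(proj, activity, transform = emb, priors = priors,
                    bandwidth_scale = bandwidth_scale)

  test_coords <- embed_new(emb, s[te, tr, drop = FALSE])
  truth <- activity$label[match(te, activity$id)]
  pred <- classify(model, test_coords, threshold = threshold)
  report <- evaluation_report(pred$score, truth, threshold = threshold)
  shep <- shepard(D_train, proj$coords)
  report <- c(report, list(
    shepard_r2 = shep$r2,
    stress = proj$stress,
    n_train = length(tr), n_test = length(te),
    method = method,
    config = list(transform = transform, k = k, dims = dims,
                  test_fraction = test_fraction, split_seed = split_seed,
                  tsne_seed = tsne_seed, perplexity = perplexity,
                  threshold = threshold, stratified = stratified,
                  bandwidth_scale = bandwidth_scale,
                  prior_pos = model$prior_pos)
  ))

  coords <- rbind(
    data.frame(id = tr, x = proj$coords[, 1], y = proj$coords[, 2],
               label = activity$label[match(tr, activity$id)],
               split = "train", score = NA_real_,
               stringsAsFactors = FALSE),
    data.frame(id = te, x = test_coords[, 1], y = test_coords[, 2],
               label = truth, split = "test", score = pred$score,
               stringsAsFactors = FALSE)
  )
  rownames(coords) <- NULL

  if (!is.null(outdir)) {
    surf <- posterior_surface(model, nx = grid, ny = grid)
    write_artifacts(coords, surf, report, outdir,
                    meta = list(method = method, k = k,
                                transform = transform,
                                hx = model$kdm_pos$hx, hy = model$kdm_pos$hy,
                                prior_pos = model$prior_pos,
                                split_seed = split_seed,
                                tsne_seed = tsne_seed))
    write_psma(model, file.path(outdir, "model.json"))
  }
  list(model = model, report = report, coords = coords)
}

#' Compare the four projection methods on one shared split
#'
#' Runs the full pipeline once per projection method with the same split
#' seed (so all methods face the same held-out molecules) and tabulates
#' AUC, MCC, stress and Shepard r2 per method.
#'
#' @param similarity similarity matrix.
#' @param activity activity table.
#' @param methods projection methods to compare (default all four).
#' @param ... further arguments passed to [run_pipeline()].
#' @return list with \code{table} (data.frame, one row per method) and
#'   \code{runs} (the full per-method pipeline results).
#' @export
compare_methods <- function(similarity, activity,
                            methods = c("pcooa", "kmds", "sammon", "tsne"),
                            ...) {
  runs <- lapply(methods, function(m)
    run_pipeline(similarity, activity, method = m, ...))
  names(runs) <- methods
  tab <- do.call(rbind, lapply(runs, function(r)
    data.frame(method = r$report$method,
               auc = r$report$auc, mcc = r$report$mcc,
               stress = if (is.null(r$report$stress)) NA_real_ else r$report$stress,
               shepard_r2 = r$report$shepard_r2,
               n_train = r$report$n_train, n_test = r$report$n_test,
               stringsAsFactors = FALSE)))
  rownames(tab) <- NULL
  list(table = tab, runs = runs)
}
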