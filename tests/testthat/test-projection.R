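# sorted pairwise-distance comparison: projections are only defined up to
# rotation/reflection/translation, so raw coordinates are never compared
pd_sorted <- function(coords) sort(as.vector(dist(coords)))

test_that("pcooa is an exact isometry on Euclidean-consistent distances", {
  pts <- rbind(c(0, 0), c(3, 0), c(0, 4))    # 3-4-5 triangle
  rownames(pts) <- c("a", "b", "c")
  D <- as.matrix(dist(pts))
  p <- pcooa(D)
  expect_equal(pd_sorted(p$coords), sort(c(3, 4, 5)), tolerance = 1e-9)

  set.seed(11)
  pts2 <- matrix(rnorm(100), 50, 2)
  p2 <- pcooa(as.matrix(dist(pts2)))
  expect_equal(pd_sorted(p2$coords), pd_sorted(pts2), tolerance = 1e-9)
  # agrees with the reference implementation up to per-axis sign
  cm <- cmdscale(dist(pts2), k = 2)
  expect_equal(abs(cor(p2$coords[, 1], cm[, 1])), 1, tolerance = 1e-9)
})

test_that("pcooa handles collinear and equidistant configurations", {
  line <- cbind(seq(0, 9), 0)
  p <- pcooa(as.matrix(dist(line)))
  expect_lt(p$eigenvalues[2] / p$eigenvalues[1], 1e-9)
  expect_equal(unname(sort(abs(diff(sort(p$coords[, 1]))))), rep(1, 9),
               tolerance = 1e-9)

  # regular simplex: all positive eigenvalues equal (closed form lambda =
  # 1/2 for unit mutual distances), and the full-rank projection is exact
  m <- 5
  d <- matrix(1, m, m); diag(d) <- 0
  ps <- pcooa(d)
  lam <- ps$eigenvalues[ps$eigenvalues > 1e-9]
  expect_equal(lam, rep(0.5, m - 1))
  full <- pcooa(d, dims = m - 1)
  pdist <- as.vector(dist(full$coords))
  expect_equal(pdist, rep(1, length(pdist)), tolerance = 1e-9)

  # frozen non-Euclidean matrix with only two positive eigenvalues:
  # requesting more dims than the positive rank errors with the spectrum
  dbad <- matrix(c(
    0, 3.585, 3.522, 3.011, 2.804,
    3.585, 0, 3.251, 3.759, 4.235,
    3.522, 3.251, 0, 0.615, 0.995,
    3.011, 3.759, 0.615, 0, 0.050,
    2.804, 4.235, 0.995, 0.050, 0), 5, 5)
  expect_error(pcooa(dbad, dims = 4), "positive eigenvalues")
  expect_silent(pcooa(dbad, dims = 2))
  expect_error(pcooa(matrix(0, 2, 2)), "dims")
})

test_that("pcooa sign convention makes output deterministic", {
  set.seed(12)
  D <- as.matrix(dist(matrix(rnorm(30), 15, 2)))
  p1 <- pcooa(D); p2 <- pcooa(D)
  expect_identical(p1$coords, p2$coords)
  for (j in 1:2) expect_gt(max(p1$coords[, j]), 0)
})

test_that("stress evaluators match the brute-force double loop", {
  set.seed(13)
  pts <- matrix(rnorm(8), 4, 2)
  D <- as.matrix(dist(pts))
  # perfect configuration: both stresses zero
  expect_equal(stress(D, pts, "kruskal"), 0, tolerance = 1e-12)
  expect_equal(stress(D, pts, "sammon"), 0, tolerance = 1e-12)
  # doubled configuration: metric residual appears, matches oracle
  expect_gt(stress(D, 2 * pts, "kruskal"), 0)
  expect_equal(stress(D, 2 * pts, "kruskal"),
               bf_stress(D, 2 * pts, "kruskal"), tolerance = 1e-12)
  expect_equal(stress(D, 2 * pts, "sammon"),
               bf_stress(D, 2 * pts, "sammon"), tolerance = 1e-12)
  # swapped pair in a 4-point line, against the independent oracle
  line <- cbind(0:3, 0)
  Dl <- as.matrix(dist(line))
  swapped <- line[c(1, 3, 2, 4), ]
  expect_equal(stress(Dl, swapped, "kruskal"),
               bf_stress(Dl, swapped, "kruskal"), tolerance = 1e-12)
  # six-term hand computation: residuals (1,1,0,0,1,1), denominator
  # 1+4+9+1+4+1 = 20
  expect_equal(stress(Dl, swapped, "kruskal"), sqrt(4 / 20))

  expect_error(stress(D, pts[1:3, ], "kruskal"), "rows")
})

test_that("shepard returns paired distances and r2 = squared Pearson", {
  set.seed(14)
  pts <- matrix(rnorm(24), 12, 2)
  D <- as.matrix(dist(pts))
  sh <- shepard(D, pts)
  expect_equal(sh$r2, 1, tolerance = 1e-12)
  expect_length(sh$original_d, 12 * 11 / 2)

  noisy <- pts + matrix(rnorm(24, sd = 0.3), 12, 2)
  sh2 <- shepard(D, noisy)
  expect_equal(sh2$r2, cor(sh2$original_d, sh2$projected_d)^2)

  shuffled <- pts[sample(12), ]
  expect_lt(shepard(D, shuffled)$r2, 0.5)
})

test_that("kruskal_mds descends and recovers rank structure", {
  set.seed(15)
  pts <- matrix(rnorm(40), 20, 2)
  D <- as.matrix(dist(pts))
  # exact configuration as init: stress already 0, nothing to improve
  r0 <- kruskal_mds(D, init = pts)
  expect_equal(r0$stress, 0, tolerance = 1e-8)

  # any monotone transform of a planar Euclidean D carries the same ranks
  Dm <- D^1.7
  r <- kruskal_mds(Dm)
  expect_lt(r$stress, 0.05)
  expect_true(all(diff(r$trace) <= 1e-12))       # monotone descent

  # optimization improves on a random start
  set.seed(16)
  rand <- matrix(rnorm(40), 20, 2)
  s_before <- psma:::stress1(as.matrix(dist(rand))[upper.tri(D)],
                             psma:::disparities(D[upper.tri(D)],
                                                as.matrix(dist(rand))[upper.tri(D)]))
  r2 <- kruskal_mds(D, init = rand)
  expect_lt(r2$stress, s_before)

  expect_error(kruskal_mds(D[1:3, 1:3]), "at least 4")
})

test_that("sammon descends, matches its own stress evaluator, and is
           scale-normalized", {
  set.seed(17)
  pts2d <- matrix(rnorm(40), 20, 2)
  r0 <- sammon(as.matrix(dist(pts2d)), init = pts2d)
  expect_equal(r0$stress, 0, tolerance = 1e-10)

  # 4D input: not embeddable in the plane, so stress stays positive
  pts <- matrix(rnorm(80), 20, 4)
  D <- as.matrix(dist(pts))
  r <- sammon(D, init = "pcooa")
  expect_gt(r$stress, 1e-6)
  expect_true(all(diff(r$trace) <= 1e-12))
  expect_equal(r$stress, stress(D, r$coords, "sammon"), tolerance = 1e-12)

  # scaling all original distances by c rescales the optimum but leaves the
  # normalized stress of the correspondingly scaled configuration unchanged
  cfac <- 3.7
  expect_equal(stress(cfac * D, cfac * r$coords, "sammon") /
                 stress(D, r$coords, "sammon"), 1, tolerance = 1e-9)
})

test_that("zero off-diagonal distances are jittered with a warning", {
  pts <- matrix(rnorm(20), 10, 2)
  pts[2, ] <- pts[1, ]                  # duplicate molecule
  D <- as.matrix(dist(pts))
  expect_warning(sammon(D), "jittered")
  expect_warning(kruskal_mds(D), "jittered")
})

test_that("tsne separates well-separated clusters and is seed-deterministic", {
  sy <- generate_clusters(n_pos = 30, n_neg = 60, separation = 10,
                          noise_sd = 1, seed = 18)
  D <- similarity_to_distance(sy$similarity)
  r <- tsne(D, perplexity = 10, seed = 1, max_iter = 500)
  expect_gt(silhouette_width(r$coords, sy$labels$label), 0.5)

  r2 <- tsne(D, perplexity = 10, seed = 1, max_iter = 500)
  expect_identical(r$coords, r2$coords)
  r3 <- tsne(D, perplexity = 10, seed = 2, max_iter = 500)
  expect_false(isTRUE(all.equal(r$coords, r3$coords)))

  expect_error(tsne(D[1:5, 1:5], perplexity = 30), "M >= 91")
})

test_that("locality is preserved better than a random projection baseline", {
  sy <- generate_clusters(n_pos = 20, n_neg = 40, n_clusters = 3,
                          separation = 8, noise_sd = 1, seed = 19)
  D <- similarity_to_distance(sy$similarity)
  set.seed(20)
  rand_base <- knn_overlap(sy$latent, matrix(rnorm(120), 60, 2))
  for (m in c("pcooa", "kmds", "sammon")) {
    proj <- project(D, m)
    expect_gt(knn_overlap(sy$latent, proj$coords), rand_base)
  }
})
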