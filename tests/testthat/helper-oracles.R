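# Independent oracles: deliberately naive implementations used only to
# check the package's vectorized code paths.

# brute-force 2D Gaussian product-kernel sum, explicit double loop
bf_kde <- function(support, hx, hy, queries) {
  n <- nrow(support)
  out <- numeric(nrow(queries))
  for (q in seq_len(nrow(queries))) {
    acc <- 0
    for (s in seq_len(n)) {
      acc <- acc + dnorm((queries[q, 1] - support[s, 1]) / hx) *
        dnorm((queries[q, 2] - support[s, 2]) / hy)
    }
    out[q] <- acc / (n * hx * hy)
  }
  out
}

# brute-force stress evaluation, explicit double loop over pairs
bf_stress <- function(D, coords, kind) {
  d <- unclass(D)
  m <- nrow(d)
  num <- 0; den <- 0
  for (i in seq_len(m - 1)) {
    for (j in (i + 1):m) {
      dij <- d[i, j]
      pij <- sqrt(sum((coords[i, ] - coords[j, ])^2))
      if (kind == "kruskal") {
        num <- num + (dij - pij)^2
        den <- den + dij^2
      } else {
        num <- num + (dij - pij)^2 / dij
        den <- den + dij
      }
    }
  }
  if (kind == "kruskal") sqrt(num / den) else num / den
}

# AUC as the fraction of (positive, negative) pairs with score_pos >
# score_neg, ties counted half (Mann-Whitney U normalization)
bf_auc <- function(scores, truth) {
  pos <- scores[truth == 1]
  neg <- scores[truth == 0]
  cmp <- outer(pos, neg, function(a, b) (a > b) + 0.5 * (a == b))
  mean(cmp)
}

# fraction of each point's 5 nearest neighbours (by row index sets)
# preserved between two configurations
knn_overlap <- function(A, B, k = 5) {
  da <- as.matrix(dist(A)); diag(da) <- Inf
  db <- as.matrix(dist(B)); diag(db) <- Inf
  mean(vapply(seq_len(nrow(da)), function(i) {
    length(intersect(order(da[i, ])[1:k], order(db[i, ])[1:k])) / k
  }, numeric(1)))
}

# mean silhouette width of a 2-class labelling in a coordinate space
silhouette_width <- function(coords, labels) {
  d <- as.matrix(dist(coords))
  mean(vapply(seq_len(nrow(d)), function(i) {
    own <- labels == labels[i]
    a <- mean(d[i, own & seq_along(labels) != i])
    b <- mean(d[i, !own])
    (b - a) / max(a, b)
  }, numeric(1)))
}

# write a labelled square matrix as delimited text
write_matrix_file <- function(m, path, sep = "\t") {
  tab <- rbind(c("id", colnames(m)), cbind(rownames(m), format(m, digits = 17)))
  write.table(tab, path, sep = sep, quote = FALSE,
              row.names = FALSE, col.names = FALSE)
}

# small valid similarity matrix used across io tests
toy_similarity <- function() {
  s <- matrix(c(1, 0.4, 0.2,
                0.4, 1, 0.6,
                0.2, 0.6, 1), 3, 3,
              dimnames = list(c("a", "b", "c"), c("a", "b", "c")))
  s
}
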