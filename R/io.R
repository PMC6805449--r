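# Delimiter auto-detection among tab/comma/semicolon; ties broken toward tab.
detect_delim <- function(path) {
  first <- readLines(path, n = 1L)
  counts <- c(
    "\t" = lengths(regmatches(first, gregexpr("\t", first, fixed = TRUE))),
    ","  = lengths(regmatches(first, gregexpr(",",  first, fixed = TRUE))),
    ";"  = lengths(regmatches(first, gregexpr(";",  first, fixed = TRUE)))
  )
  names(counts)[which.max(counts)]
}

#' Validate a similarity matrix
#'
#' Checks the invariants of a molecular similarity matrix: square, labelled,
#' entries in \[0, 1\], unit diagonal and symmetry within \code{tolerance}.
#' Asymmetries within tolerance are repaired by averaging \code{(S + t(S))/2};
#' anything larger is an error, since similarity calculators such as NAMS
#' produce symmetric output by construction and larger deviations signal
#' corrupt input.
#'
#' @param values numeric square matrix with identical row and column names.
#' @param ids optional character vector of molecule identifiers; defaults to
#'   the matrix dimnames.
#' @param tolerance maximum tolerated absolute asymmetry (default 1e-8).
#' @return the validated (and symmetrized) similarity matrix with a
#'   \code{"psma_similarity"} class attribute.
#' @export
similarity_matrix <- function(values, ids = NULL, tolerance = 1e-8) {
  values <- as.matrix(values)
  if (nrow(values) != ncol(values))
    stop("similarity matrix must be square, got ", nrow(values), "x", ncol(values))
  if (is.null(ids)) ids <- rownames(values)
  if (is.null(ids)) ids <- paste0("mol", seq_len(nrow(values)))
  ids <- as.character(ids)
  if (anyDuplicated(ids)) stop("duplicate molecule ids: ",
                               paste(unique(ids[duplicated(ids)]), collapse = ", "))
  if (!is.null(colnames(values)) && !is.null(rownames(values)) &&
      !identical(rownames(values), colnames(values)))
    stop("row and column ids differ")
  storage.mode(values) <- "double"
  bad <- which(values < 0 | values > 1, arr.ind = TRUE)
  if (nrow(bad) > 0L)
    stop(sprintf("similarity out of [0,1] at (%s, %s): %g",
                 ids[bad[1, 1]], ids[bad[1, 2]], values[bad[1, 1], bad[1, 2]]))
  asym <- abs(values - t(values))
  if (max(asym) > tolerance) {
    w <- which(asym == max(asym), arr.ind = TRUE)[1, ]
    stop(sprintf("asymmetry %.3g at (%s, %s) exceeds tolerance %g",
                 max(asym), ids[w[1]], ids[w[2]], tolerance))
  }
  values <- (values + t(values)) / 2
  dbad <- which(abs(diag(values) - 1) > tolerance)
  if (length(dbad) > 0L)
    stop(sprintf("diagonal not 1 at (%s, %s): %g",
                 ids[dbad[1]], ids[dbad[1]], diag(values)[dbad[1]]))
  diag(values) <- 1
  dimnames(values) <- list(ids, ids)
  class(values) <- c("psma_similarity", class(values))
  values
}

#' Read a molecular similarity matrix from delimited text
#'
#' Reads a labelled square matrix (header row and index column of molecule
#' ids) of pairwise similarities in \[0, 1\], e.g. a NAMS or Tanimoto matrix.
#' The delimiter is auto-detected among tab, comma and semicolon.
#'
#' @param path file path.
#' @param tolerance maximum tolerated asymmetry; see [similarity_matrix()].
#' @return a validated similarity matrix, ids preserved in file order.
#' @export
read_similarity_matrix <- function(path, tolerance = 1e-8) {
  sep <- detect_delim(path)
  df <- utils::read.table(path, header = TRUE, sep = sep, row.names = 1L,
                          check.names = FALSE, stringsAsFactors = FALSE)
  m <- as.matrix(df)
  if (!is.numeric(m)) stop("non-numeric entries in similarity matrix ", path)
  similarity_matrix(m, tolerance = tolerance)
}

#' Read an activity table
#'
#' Reads a two-column delimited file, either \code{id, ki_nM} (equilibrium
#' inhibition constants in nM) or \code{id, label} with labels in
#' \{1, 0\} or \{active, inactive\}.  When Ki values are given, the binary
#' label is derived as active iff Ki <= \code{cutoff_nm}; the 10 nM default
#' deliberately yields unbalanced class ratios typical of real screening data.
#'
#' @param path file path.
#' @param cutoff_nm activity threshold in nM (default 10).
#' @return data.frame with columns \code{id} (character), \code{ki} (numeric
#'   or NA) and \code{label} (integer, 1 = active).
#' @export
read_activity_table <- function(path, cutoff_nm = 10) {
  stopifnot(cutoff_nm > 0)
  sep <- detect_delim(path)
  df <- utils::read.table(path, header = TRUE, sep = sep,
                          check.names = FALSE, stringsAsFactors = FALSE)
  if (nrow(df) == 0L) stop("empty activity table: ", path)
  if (ncol(df) < 2L) stop("activity table needs id plus ki or label column")
  activity_table(df[[1]], values = df[[2]],
                 value_kind = .activity_kind(names(df)[2], df[[2]]),
                 cutoff_nm = cutoff_nm)
}

.activity_kind <- function(colname, values) {
  nm <- tolower(colname)
  if (grepl("ki", nm)) return("ki")
  if (grepl("label|class|activ", nm)) return("label")
  if (is.numeric(values) && all(values %in% c(0, 1))) "label" else "ki"
}

#' Construct an activity table from ids and Ki values or labels
#'
#' @param ids molecule identifiers (must be unique).
#' @param values Ki values in nM, or labels.
#' @param value_kind "ki" or "label".
#' @param cutoff_nm positives are Ki <= cutoff (default 10 nM).
#' @return data.frame with columns id, ki, label.
#' @export
activity_table <- function(ids, values, value_kind = c("ki", "label"),
                           cutoff_nm = 10) {
  value_kind <- match.arg(value_kind)
  ids <- as.character(ids)
  if (length(ids) == 0L) stop("empty activity table")
  if (anyDuplicated(ids))
    stop("duplicate ids in activity table: ",
         paste(unique(ids[duplicated(ids)]), collapse = ", "))
  if (value_kind == "ki") {
    ki <- suppressWarnings(as.numeric(values))
    if (anyNA(ki)) stop("non-numeric Ki for id ", ids[which(is.na(ki))[1]])
    if (any(ki <= 0)) stop("Ki must be positive, got ", min(ki),
                           " for id ", ids[which(ki <= 0)[1]])
    label <- as.integer(ki <= cutoff_nm)
  } else {
    v <- values
    if (is.character(v) || is.factor(v)) {
      v <- tolower(as.character(v))
      if (!all(v %in% c("active", "inactive", "0", "1")))
        stop("unrecognised labels: ", paste(setdiff(v, c("active", "inactive", "0", "1")), collapse = ", "))
      label <- as.integer(v %in% c("active", "1"))
    } else {
      if (!all(v %in% c(0, 1))) stop("numeric labels must be 0/1")
      label <- as.integer(v)
    }
    ki <- rep(NA_real_, length(ids))
  }
  data.frame(id = ids, ki = ki, label = label, stringsAsFactors = FALSE)
}

#' Read a fingerprint set
#'
#' Two-column delimited text \code{id, bitstring} where bitstring is a
#' constant-length string over \{0,1\} (structural keys or hashed bits).
#'
#' @param path file path.
#' @return list with \code{ids} and an M x B binary \code{bits} matrix.
#' @export
read_fingerprints <- function(path) {
  sep <- detect_delim(path)
  df <- utils::read.table(path, header = TRUE, sep = sep,
                          colClasses = "character", check.names = FALSE)
  ids <- df[[1]]
  bs <- df[[2]]
  lens <- nchar(bs)
  if (length(unique(lens)) != 1L)
    stop("fingerprints have differing lengths: ", paste(unique(lens), collapse = ", "))
  if (any(grepl("[^01]", bs))) stop("fingerprint bitstrings must contain only 0/1")
  bits <- t(vapply(strsplit(bs, ""), function(ch) as.integer(ch), integer(lens[1])))
  rownames(bits) <- ids
  list(ids = ids, bits = bits)
}

#' Tanimoto similarity matrix from binary fingerprints
#'
#' For fingerprints a, b the Tanimoto coefficient is
#' \deqn{T_c = |a \wedge b| / (|a| + |b| - |a \wedge b|)}
#' i.e. shared on-bits over total distinct on-bits.  A stand-in for
#' graph-matching similarities such as NAMS: the downstream pipeline accepts
#' any normalized similarity.
#'
#' @param fps fingerprint set as returned by [read_fingerprints()], or any
#'   list with \code{ids} and a binary \code{bits} matrix.
#' @return similarity matrix (see [similarity_matrix()]).
#' @export
tanimoto_similarity <- function(fps) {
  bits <- fps$bits
  if (nrow(bits) < 2L) stop("need at least 2 molecules")
  if (!all(bits %in% c(0L, 1L))) stop("fingerprint bits must be 0/1")
  on <- rowSums(bits)
  if (any(on == 0))
    stop("all-zero fingerprint for id ", fps$ids[which(on == 0)[1]],
         ": Tanimoto undefined")
  common <- bits %*% t(bits)
  denom <- outer(on, on, "+") - common
  s <- common / denom
  similarity_matrix(s, ids = fps$ids)
}

fmt_num <- function(x) sprintf("%.17g", x)

#' Write pipeline artifacts
#'
#' Writes the projected coordinates as TSV (id, x, y, label, split), the
#' posterior surface as a grid TSV plus a JSON metadata sidecar (axes,
#' bandwidths, priors, projection method, convexity k, seeds), a static
#' contour PNG, and the evaluation report as JSON.  Numeric values are
#' written at full double precision so a read round-trips bit-identically.
#'
#' @param coords data.frame with columns id, x, y and optionally label, split.
#' @param surface surface list from [posterior_surface()], or NULL.
#' @param report evaluation report list, or NULL.
#' @param outdir output directory (created if missing).
#' @param meta named list merged into the surface sidecar.
#' @return invisible character vector of files written.
#' @export
write_artifacts <- function(coords, surface = NULL, report = NULL, outdir,
                            meta = list()) {
  if (missing(outdir) || is.null(outdir) || !nzchar(outdir))
    stop("outdir must be a non-empty path")
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
  files <- character(0)

  if (!is.null(coords)) {
    df <- coords
    for (cl in c("x", "y")) df[[cl]] <- fmt_num(df[[cl]])
    f <- file.path(outdir, "coordinates.tsv")
    utils::write.table(df, f, sep = "\t", quote = FALSE, row.names = FALSE)
    files <- c(files, f)
  }
  if (!is.null(surface)) {
    f <- file.path(outdir, "surface.tsv")
    # rows index the x lattice, columns the y lattice; header row = y axis,
    # first column = x axis
    body <- matrix(fmt_num(surface$p_pos), nrow = length(surface$x))
    tab <- rbind(c("x_y", fmt_num(surface$y)),
                 cbind(fmt_num(surface$x), body))
    utils::write.table(tab, f, sep = "\t", quote = FALSE,
                       row.names = FALSE, col.names = FALSE)
    files <- c(files, f)
    side <- c(list(format = "psma-surface", version = 1L,
                   nx = length(surface$x), ny = length(surface$y),
                   xlim = range(surface$x), ylim = range(surface$y)),
              meta)
    fs <- file.path(outdir, "surface.json")
    jsonlite::write_json(side, fs, auto_unbox = TRUE, digits = NA, null = "null")
    files <- c(files, fs)
    fp <- file.path(outdir, "surface.png")
    grDevices::png(fp, width = 800, height = 700)
    graphics::filled.contour(surface$x, surface$y, surface$p_pos,
                             color.palette = grDevices::hcl.colors,
                             main = "P(active | x, y)", xlab = "dim 1", ylab = "dim 2")
    grDevices::dev.off()
    files <- c(files, fp)
  }
  if (!is.null(report)) {
    f <- file.path(outdir, "report.json")
    jsonlite::write_json(report, f, auto_unbox = TRUE, digits = NA, null = "null")
    files <- c(files, f)
  }
  invisible(files)
}

#' Read back a coordinates artifact
#' @param path path to coordinates.tsv as written by [write_artifacts()].
#' @return data.frame with numeric x, y.
#' @export
read_coordinates <- function(path) {
  df <- utils::read.table(path, header = TRUE, sep = "\t",
                          stringsAsFactors = FALSE, check.names = FALSE)
  df$x <- as.numeric(df$x)
  df$y <- as.numeric(df$y)
  df
}

#' Read back a surface artifact
#' @param path path to surface.tsv as written by [write_artifacts()].
#' @return list with x, y axis vectors and the posterior matrix p_pos.
#' @export
read_surface <- function(path) {
  tab <- as.matrix(utils::read.table(path, header = FALSE, sep = "\t",
                                     stringsAsFactors = FALSE,
                                     colClasses = "character"))
  y <- as.numeric(tab[1, -1])
  x <- as.numeric(tab[-1, 1])
  z <- matrix(as.numeric(tab[-1, -1]), nrow = length(x), ncol = length(y))
  list(x = x, y = y, p_pos = z)
}
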