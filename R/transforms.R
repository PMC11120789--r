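# Compositional transform, dissimilarity computation and principal coordinate
# embedding. The Aitchison distance is the Euclidean distance after the
# centered log-ratio (CLR) transform; PCoA embeds an arbitrary dissimilarity
# into Euclidean coordinates via Gower double-centering.

#' Centered log-ratio transform
#'
#' Replaces each sample row x by log(x + pseudocount) minus its mean, so every
#' output row sums to zero. The default pseudocount is half the smallest
#' positive value in the table when zeros are present, and 0 otherwise.
#'
#' @param table non-negative feature table (samples in rows).
#' @param pseudocount non-negative offset added before taking logs; must be
#'   positive if the table contains zeros. `NULL` (default) selects half the
#'   smallest positive entry when zeros are present.
#' @return real-valued matrix of the same shape; rows sum to zero.
#' @export
clr_transform <- function(table, pseudocount = NULL) {
  validate_feature_table(table)
  zero_rows <- rowSums(table) == 0
  if (any(zero_rows))
    stop("all-zero row(s): ", paste(rownames(table)[zero_rows], collapse = ", "))
  has_zero <- any(table == 0)
  if (is.null(pseudocount))
    pseudocount <- if (has_zero) min(table[table > 0]) / 2 else 0
  if (pseudocount < 0) stop("pseudocount must be non-negative")
  if (has_zero && pseudocount == 0)
    stop("table contains zeros; a positive pseudocount is required")
  lx <- log(table + pseudocount)
  lx - rowMeans(lx)
}

#' Pairwise dissimilarities between samples
#'
#' @param table feature table (samples in rows). Euclidean accepts any
#'   real-valued table; Aitchison and Bray-Curtis require non-negative input.
#' @param metric `"euclidean"`, `"aitchison"` (Euclidean on the CLR transform)
#'   or `"bray_curtis"`.
#' @param pseudocount passed to [clr_transform()] for the Aitchison metric.
#' @return square distance matrix with sample IDs.
#' @export
compute_distances <- function(table,
                              metric = c("euclidean", "aitchison", "bray_curtis"),
                              pseudocount = NULL) {
  metric <- match.arg(metric)
  validate_feature_table(table, allow_negative = metric == "euclidean")
  if (nrow(table) < 2L) stop("need at least 2 samples to compute distances")
  d <- switch(metric,
    euclidean = as.matrix(stats::dist(table)),
    aitchison = as.matrix(stats::dist(clr_transform(table, pseudocount))),
    bray_curtis = {
      zero_rows <- rowSums(table) == 0
      if (any(zero_rows))
        stop("Bray-Curtis undefined for all-zero row(s): ",
             paste(rownames(table)[zero_rows], collapse = ", "))
      as.matrix(vegan::vegdist(table, method = "bray"))
    })
  diag(d) <- 0
  validate_distance_matrix(d)
  d
}

#' Principal coordinate analysis (classical scaling)
#'
#' Embeds a dissimilarity matrix into Euclidean coordinates: the matrix
#' -0.5 * D^2 is double-centered (Gower) and eigendecomposed; coordinates are
#' eigenvectors scaled by the square root of their eigenvalues. Axes whose
#' eigenvalue does not exceed `max(n,1) * eps * largest eigenvalue` are
#' dropped; dropped negative-eigenvalue axes (which arise for non-Euclidean
#' dissimilarities such as Bray-Curtis) are counted and trigger a warning.
#' For reproducible output, each axis is oriented so its largest-magnitude
#' coordinate is positive.
#'
#' @param dist validated square distance matrix.
#' @param max_axes optional cap on the number of returned axes.
#' @return object of class `md3f_pcoa`: list with `ids`, `coordinates`
#'   (samples x axes, column means zero), `eigenvalues` (retained, positive,
#'   non-increasing) and `n_dropped_negative`.
#' @export
pcoa_embed <- function(dist, max_axes = NULL) {
  validate_distance_matrix(dist)
  n <- nrow(dist)
  if (n < 2L) stop("need at least 2 samples")
  a <- -0.5 * dist^2
  centred <- a - rowMeans(a)
  b <- centred - rep(colMeans(centred), each = n)
  b <- (b + t(b)) / 2  # enforce exact symmetry for eigen
  e <- eigen(b, symmetric = TRUE)
  tol <- max(n, 1) * .Machine$double.eps * max(abs(e$values), 0)
  keep <- e$values > tol
  n_neg <- sum(e$values < -tol)
  if (n_neg > 0L)
    warning(n_neg, " negative-eigenvalue axis/axes dropped (non-Euclidean input)")
  vals <- e$values[keep]
  coords <- e$vectors[, keep, drop = FALSE] %*%
    diag(sqrt(vals), nrow = length(vals))
  if (!is.null(max_axes)) {
    k <- min(max_axes, ncol(coords))
    coords <- coords[, seq_len(k), drop = FALSE]
    vals <- vals[seq_len(k)]
  }
  for (j in seq_len(ncol(coords))) {
    i <- which.max(abs(coords[, j]))
    if (coords[i, j] < 0) coords[, j] <- -coords[, j]
  }
  dimnames(coords) <- list(rownames(dist),
                           if (ncol(coords)) paste0("PCo", seq_len(ncol(coords))))
  structure(list(ids = rownames(dist), coordinates = coords,
                 eigenvalues = vals, n_dropped_negative = n_neg),
            class = "md3f_pcoa")
}

#' @export
print.md3f_pcoa <- function(x, ...) {
  cat("Principal coordinate embedding:", length(x$ids), "samples,",
      ncol(x$coordinates), "retained axes\n")
  if (x$n_dropped_negative > 0L)
    cat("  (", x$n_dropped_negative, "negative-eigenvalue axes dropped )\n")
  invisible(x)
}
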