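# Comparison methods: per-axis regressions on principal coordinates (PCo1,
# PCo2, PCoA) and per-feature univariate screens with multiplicity adjustment
# (uFDR, uHolm). Each returns an overall significance decision for time
# dependence. These procedures are deliberately implemented exactly as
# commonly practised -- e.g. the PCo2/PCoA overall p is a raw minimum over
# axes -- because their anticonservative behaviour under diffusion is part of
# what the simulation study measures; "fixing" them would change the question.

# Vectorised simple OLS of each column of y on x: slope, se, t and two-sided
# coefficient-test p per column. Constant columns yield NaN p (callers decide).
.col_slope_tests <- function(x, y) {
  y <- as.matrix(y)
  n <- length(x)
  if (n < 3L) stop("need at least 3 observations")
  if (nrow(y) != n) stop("response and regressor lengths differ")
  xc <- x - mean(x)
  sxx <- sum(xc^2)
  if (sxx == 0) stop("zero variance in regressor")
  slope <- as.vector(crossprod(xc, y)) / sxx
  syy <- pmax(colSums(y^2) - n * colMeans(y)^2, 0)
  # columns with (numerically) zero variance carry no information: their
  # round-off slope must not masquerade as a perfect fit
  const <- syy <= 1e-10 * pmax(colMeans(y^2), .Machine$double.xmin)
  slope[const] <- 0
  rss <- pmax(syy - slope^2 * sxx, 0)
  se <- sqrt(rss / (n - 2) / sxx)
  tstat <- slope / se
  p <- 2 * stats::pt(-abs(tstat), df = n - 2)
  p[const] <- NaN
  data.frame(slope = slope, se = se, t = tstat, p = p)
}

.new_baseline_result <- function(method, per_test_p, overall_p, n_tests,
                                 raw_p = NULL) {
  structure(list(method = method, per_test_p = per_test_p,
                 overall_p = overall_p, n_tests = n_tests, raw_p = raw_p),
            class = "md3f_baseline")
}

#' @export
print.md3f_baseline <- function(x, ...) {
  cat(sprintf("%s baseline: %d test(s), overall p = %.4g\n",
              x$method, x$n_tests, x$overall_p))
  invisible(x)
}

#' Principal-coordinate regression test for time dependence
#'
#' Regresses each of the first `k` retained principal coordinates on time and
#' takes the smallest two-sided coefficient-test p-value as the overall
#' significance, with no multiplicity adjustment (the minimum over axes is the
#' decision rule being evaluated, not a calibrated test).
#'
#' @param embedding `md3f_pcoa` object from [pcoa_embed()].
#' @param times per-sample observation times, aligned with `embedding$ids`.
#' @param k number of leading axes: `1`, `2` or `"all"`. If `k` exceeds the
#'   number of retained axes, all retained axes are used with a warning.
#' @return `md3f_baseline` object with method `"PCo1"`, `"PCo2"` or `"PCoA"`.
#' @export
pco_regression_test <- function(embedding, times, k = c("1", "2", "all")) {
  k <- match.arg(as.character(k), c("1", "2", "all"))
  coords <- embedding$coordinates
  if (length(times) != nrow(coords))
    stop("times must align with the embedding's samples")
  n_axes <- ncol(coords)
  if (n_axes == 0L) stop("embedding has no retained axes")
  want <- if (k == "all") n_axes else as.integer(k)
  if (want > n_axes) {
    warning("requested ", want, " axes but only ", n_axes,
            " retained; using all retained axes")
    want <- n_axes
  }
  res <- .col_slope_tests(times, coords[, seq_len(want), drop = FALSE])
  p <- res$p
  if (any(!is.finite(p))) {
    warning("constant coordinate axis; its p-value set to 1")
    p[!is.finite(p)] <- 1
  }
  method <- switch(k, "1" = "PCo1", "2" = "PCo2", all = "PCoA")
  .new_baseline_result(method, per_test_p = p, overall_p = min(p),
                       n_tests = want)
}

#' Univariate feature screen for time dependence
#'
#' Regresses every feature on time, adjusts the two-sided coefficient-test
#' p-values for multiplicity (Benjamini-Hochberg for `"fdr"`, Holm for
#' `"holm"`), and reports the minimum adjusted p-value as the overall
#' significance. Constant features get p = 1 with a warning.
#'
#' @param table feature table (samples in rows); real-valued input such as a
#'   CLR-transformed table is accepted.
#' @param times per-sample observation times.
#' @param adjust `"fdr"` (method uFDR) or `"holm"` (method uHolm).
#' @return `md3f_baseline` object; `per_test_p` holds the adjusted p-values
#'   and `raw_p` the unadjusted ones.
#' @export
univariate_screen_test <- function(table, times, adjust = c("fdr", "holm")) {
  adjust <- match.arg(adjust)
  validate_feature_table(table, allow_negative = TRUE)
  if (length(times) != nrow(table))
    stop("times must align with the table's samples")
  res <- .col_slope_tests(times, table)
  raw <- res$p
  if (any(!is.finite(raw))) {
    warning("constant feature(s); their p-values set to 1")
    raw[!is.finite(raw)] <- 1
  }
  adj <- stats::p.adjust(raw, method = if (adjust == "fdr") "BH" else "holm")
  .new_baseline_result(if (adjust == "fdr") "uFDR" else "uHolm",
                       per_test_p = adj, overall_p = min(adj),
                       n_tests = length(adj), raw_p = raw)
}

#' Run a baseline method by name
#'
#' Convenience dispatcher used by the simulation-study runner: `"PCo1"`,
#' `"PCo2"` and `"PCoA"` embed the rows of `table` with Euclidean PCoA and run
#' [pco_regression_test()]; `"uFDR"` and `"uHolm"` run
#' [univariate_screen_test()].
#'
#' @param method one of `"PCo1"`, `"PCo2"`, `"PCoA"`, `"uFDR"`, `"uHolm"`.
#' @param table samples-by-features matrix of observations.
#' @param times per-sample observation times.
#' @return `md3f_baseline` object.
#' @export
baseline_test <- function(method, table, times) {
  method <- match.arg(method, c("PCo1", "PCo2", "PCoA", "uFDR", "uHolm"))
  if (method %in% c("uFDR", "uHolm"))
    return(univariate_screen_test(table, times,
                                  adjust = if (method == "uFDR") "fdr" else "holm"))
  emb <- pcoa_embed(compute_distances(table, metric = "euclidean"))
  k <- switch(method, PCo1 = "1", PCo2 = "2", PCoA = "all")
  suppressWarnings(pco_regression_test(emb, times, k = k))
}
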