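# Simulation-study runner: rejection-rate (type I error / power) and bias
# grids over methods x n x d x alpha, plus a trajectory-recovery experiment.
#
# Seeding: each (cell, replicate) gets its own seed derived from the root seed
# by a fixed affine map modulo 2^31 - 1, so grids are deterministic under a
# fixed root seed, independent of evaluation order, and every derived seed
# stays below 2^31.

.replicate_seed <- function(seed, cell, replicate) {
  as.integer((as.numeric(seed) %% 2147483647 * 7919 +
                cell * 104729 + replicate * 1299709) %% 2147483647)
}

.md3f_methods <- c("MD3Flinear2", "MD3Flinear")
.baseline_methods <- c("PCo1", "PCo2", "PCoA", "uFDR", "uHolm")

#' Parameter-grid presets
#'
#' Two presets of the study grid are shipped, differing in their dimension
#' lists: `"paper-methods"` uses d in (1, 10, 100, 1000) and
#' `"paper-figure2"` uses d in (1, 10, 100, 400). Both cross sample sizes
#' n in (10, 20, 50, 100) with drift magnitudes alpha in (0, 0.5, 1, 2, 3).
#'
#' @param preset `"paper-methods"` or `"paper-figure2"`.
#' @param n,d,alpha optional overrides for the marginal value lists.
#' @return data.frame with one row per (n, d, alpha) cell.
#' @export
grid_preset <- function(preset = c("paper-methods", "paper-figure2"),
                        n = c(10, 20, 50, 100), d = NULL,
                        alpha = c(0, 0.5, 1, 2, 3)) {
  preset <- match.arg(preset)
  if (is.null(d))
    d <- if (preset == "paper-methods") c(1, 10, 100, 1000) else c(1, 10, 100, 400)
  expand.grid(n = n, d = d, alpha = alpha, KEEP.OUT.ATTRS = FALSE)
}

# Compute one replicate's overall p-value per requested method, sharing the
# simulated data (and the PCoA embedding) across methods.
.replicate_pvalues <- function(methods, sim, scaling) {
  p <- setNames(numeric(length(methods)), methods)
  if (any(methods %in% .md3f_methods)) {
    pairs <- prepost_pairs(sim)
    if ("MD3Flinear2" %in% methods)
      p[["MD3Flinear2"]] <- fit_md3f(pairs, "linear2", scaling)$slope_p
    if ("MD3Flinear" %in% methods)
      p[["MD3Flinear"]] <- fit_md3f(pairs, "linear", scaling)$slope_p
  }
  pco <- intersect(methods, c("PCo1", "PCo2", "PCoA"))
  if (length(pco)) {
    emb <- pcoa_embed(compute_distances(sim$X, "euclidean"))
    for (m in pco)
      p[[m]] <- suppressWarnings(
        pco_regression_test(emb, sim$s,
                            k = switch(m, PCo1 = "1", PCo2 = "2", PCoA = "all"))$overall_p)
  }
  for (m in intersect(methods, c("uFDR", "uHolm")))
    p[[m]] <- univariate_screen_test(sim$X, sim$s,
                                     adjust = if (m == "uFDR") "fdr" else "holm")$overall_p
  p
}

#' Rejection-rate grid (type I error and power)
#'
#' For each grid cell, simulates `replicates` pre/post datasets and records,
#' per method, the fraction of replicates whose overall p-value falls below
#' `level`. With alpha = 0 this estimates the type I error; otherwise, power.
#'
#' @param grid data.frame with columns `n`, `d`, `alpha` (see [grid_preset()]).
#' @param methods character vector from `"MD3Flinear2"`, `"MD3Flinear"`,
#'   `"PCo1"`, `"PCo2"`, `"PCoA"`, `"uFDR"`, `"uHolm"`.
#' @param replicates simulated datasets per cell (default 2000).
#' @param level nominal significance threshold (default 0.05).
#' @param seed root seed for the deterministic per-replicate seed stream.
#' @param time_rate exponential rate of the interpoint times.
#' @param scaling scaling passed to the drift-model fits.
#' @param progress emit per-cell progress messages (default `FALSE`).
#' @return data.frame with one row per method and cell: `method`, `n`, `d`,
#'   `alpha`, `replicates`, `rejection_fraction`, `seed`.
#' @export
run_rejection_grid <- function(grid, methods = "MD3Flinear2",
                               replicates = 2000, level = 0.05, seed = 1,
                               time_rate = 1,
                               scaling = c("time_scaled", "literal"),
                               progress = FALSE) {
  scaling <- match.arg(scaling)
  if (!all(c("n", "d", "alpha") %in% names(grid)))
    stop("grid must have columns n, d, alpha")
  unknown <- setdiff(methods, c(.md3f_methods, .baseline_methods))
  if (length(unknown))
    stop("unknown method(s): ", paste(unknown, collapse = ", "))
  if (level <= 0 || level >= 1) stop("level must be in (0, 1)")
  if (replicates < 1) stop("replicates must be positive")
  rows <- vector("list", nrow(grid))
  for (i in seq_len(nrow(grid))) {
    rej <- setNames(numeric(length(methods)), methods)
    for (r in seq_len(replicates)) {
      sc <- md3f_scenario(grid$n[i], grid$d[i], grid$alpha[i],
                          time_rate = time_rate,
                          seed = .replicate_seed(seed, i, r))
      pv <- .replicate_pvalues(methods, simulate_prepost(sc), scaling)
      rej <- rej + (pv < level)
    }
    rows[[i]] <- data.frame(method = methods, n = grid$n[i], d = grid$d[i],
                            alpha = grid$alpha[i], replicates = replicates,
                            rejection_fraction = unname(rej) / replicates,
                            seed = seed, stringsAsFactors = FALSE)
    if (progress)
      message(sprintf("cell %d/%d (n=%d d=%d alpha=%g) done",
                      i, nrow(grid), grid$n[i], grid$d[i], grid$alpha[i]))
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Bias grid for the drift estimators
#'
#' For each grid cell, simulates `replicates` pre/post datasets, fits the
#' chosen model, and summarises the estimator bias: the mean and SD over
#' replicates of (slope - alpha) for `linear` and (slope - alpha^2) for
#' `linear2`.
#'
#' @inheritParams run_rejection_grid
#' @param model `"linear2"` (default) or `"linear"`.
#' @return data.frame with one row per cell: `method`, `n`, `d`, `alpha`,
#'   `replicates`, `mean_bias`, `bias_sd`, `seed`.
#' @export
run_bias_grid <- function(grid, model = c("linear2", "linear"),
                          scaling = c("time_scaled", "literal"),
                          replicates = 500, seed = 1, time_rate = 1,
                          progress = FALSE) {
  model <- match.arg(model)
  scaling <- match.arg(scaling)
  if (!all(c("n", "d", "alpha") %in% names(grid)))
    stop("grid must have columns n, d, alpha")
  if (replicates < 1) stop("replicates must be positive")
  rows <- vector("list", nrow(grid))
  for (i in seq_len(nrow(grid))) {
    target <- if (model == "linear2") grid$alpha[i]^2 else grid$alpha[i]
    slopes <- numeric(replicates)
    for (r in seq_len(replicates)) {
      sc <- md3f_scenario(grid$n[i], grid$d[i], grid$alpha[i],
                          time_rate = time_rate,
                          seed = .replicate_seed(seed, i, r))
      slopes[r] <- fit_md3f(prepost_pairs(simulate_prepost(sc)),
                            model, scaling)$slope
    }
    rows[[i]] <- data.frame(
      method = if (model == "linear2") "MD3Flinear2" else "MD3Flinear",
      n = grid$n[i], d = grid$d[i], alpha = grid$alpha[i],
      replicates = replicates,
      mean_bias = mean(slopes - target), bias_sd = stats::sd(slopes),
      seed = seed, stringsAsFactors = FALSE)
    if (progress)
      message(sprintf("cell %d/%d (n=%d d=%d alpha=%g) done",
                      i, nrow(grid), grid$n[i], grid$d[i], grid$alpha[i]))
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Drift recovery from replicated trajectories
#'
#' Simulates independent multi-step trajectories, builds pairs against the
#' walk's starting point, fits the drift regression to each, and summarises
#' the slope estimates across replicates. Under `linear2`, the replicate mean
#' slope estimates the squared drift magnitude.
#'
#' @param scenario `md3f_scenario` giving `d`, `alpha` and `direction`.
#' @param n_steps,dt trajectory grid (see [simulate_trajectory()]).
#' @param replicates number of independent trajectories.
#' @param seed root seed for the per-replicate seed stream.
#' @param model,scaling passed to [fit_md3f()].
#' @param mode pairing mode (default `"baseline"`).
#' @return list with `mean_slope`, `sd_slope`, `se_mean` (Monte-Carlo standard
#'   error of the mean), `replicates` and the per-replicate `slopes`.
#' @export
run_trajectory_recovery <- function(scenario, n_steps = 10, dt = 1,
                                    replicates = 1000, seed = 1,
                                    model = c("linear2", "linear"),
                                    scaling = c("time_scaled", "literal"),
                                    mode = "baseline") {
  model <- match.arg(model)
  scaling <- match.arg(scaling)
  slopes <- numeric(replicates)
  for (r in seq_len(replicates)) {
    sc <- scenario
    sc$seed <- .replicate_seed(seed, 1L, r)
    traj <- simulate_trajectory(sc, n_steps = n_steps, dt = dt)
    tt <- trajectory_tables(traj)
    pairs <- build_pairs(tt$dist, tt$design, mode = mode)
    slopes[r] <- fit_md3f(pairs, model, scaling)$slope
  }
  list(mean_slope = mean(slopes), sd_slope = stats::sd(slopes),
       se_mean = stats::sd(slopes) / sqrt(replicates),
       replicates = replicates, slopes = slopes)
}

#' Pivot a grid-result table
#'
#' Reshapes a long result table (one row per method and cell) into a
#' method-by-cell table with stable ordering, suitable for [write_table()].
#' The pivoted value is `rejection_fraction` when present, else `mean_bias`.
#'
#' @param results data.frame from [run_rejection_grid()] or [run_bias_grid()].
#' @return data.frame with one row per method and one column per
#'   `n<d>.d<d>.a<alpha>` cell.
#' @export
summarize_grid <- function(results) {
  if (is.null(results) || nrow(results) == 0L) stop("empty result table")
  value_col <- if ("rejection_fraction" %in% names(results))
    "rejection_fraction" else "mean_bias"
  key <- paste0("n", results$n, ".d", results$d, ".a", results$alpha)
  if (anyDuplicated(paste(results$method, key)))
    stop("duplicate (method, cell) entries in results")
  cells <- unique(key[order(results$n, results$d, results$alpha)])
  methods <- unique(results$method)
  out <- data.frame(method = methods, stringsAsFactors = FALSE)
  for (cell in cells) {
    v <- rep(NA_real_, length(methods))
    sel <- key == cell
    v[match(results$method[sel], methods)] <- results[[value_col]][sel]
    out[[cell]] <- v
  }
  out
}
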