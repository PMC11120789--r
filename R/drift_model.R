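# The drift-magnitude regression. Repeated measures of a subject following a
# drift-diffusion process satisfy E[d^2(M_s, M_{s+t})] = alpha^2 t^2 + c * t,
# so the time-scaled squared interpoint distance d^2/t is linear in t with
# slope alpha^2. Ordinary least squares on (time interval, distance) pairs
# gives the drift estimator and a coefficient t-test for directed change.

#' Build (time interval, distance) pairs from a distance matrix and design
#'
#' For each subject, samples are ordered by time and pairs are formed:
#' \describe{
#'   \item{baseline}{each later sample against the subject's first sample
#'     (intervals measured from the start of the walk; the default pairing).}
#'   \item{consecutive}{each sample against its predecessor.}
#'   \item{all_pairs}{every ordered-by-time pair.}
#' }
#' Subjects with fewer than two timepoints are skipped with a warning.
#'
#' @param dist validated distance matrix containing every design sample.
#' @param design data.frame with columns `sample`, `subject`, `time`.
#' @param mode pairing mode; see above.
#' @param dedupe policy for duplicate (subject, time) records pointing at
#'   distinct samples: `"error"` (default) or `"first"` (keep first occurrence).
#' @return data.frame of class `md3f_pairs` with columns `subject`, `delta_t`,
#'   `distance`; the mode is attached as attribute `"mode"`.
#' @export
build_pairs <- function(dist, design,
                        mode = c("baseline", "consecutive", "all_pairs"),
                        dedupe = c("error", "first")) {
  mode <- match.arg(mode)
  dedupe <- match.arg(dedupe)
  validate_distance_matrix(dist)
  missing_samples <- setdiff(design$sample, rownames(dist))
  if (length(missing_samples))
    stop("design samples absent from distance matrix: ",
         paste(missing_samples, collapse = ", "))
  out <- vector("list", length(unique(design$subject)))
  names(out) <- unique(design$subject)
  for (sub in names(out)) {
    rec <- design[design$subject == sub, , drop = FALSE]
    if (anyDuplicated(rec$time)) {
      if (dedupe == "error")
        stop("subject '", sub, "' has duplicate times with distinct samples; ",
             "set dedupe = \"first\" to keep the first occurrence")
      rec <- rec[!duplicated(rec$time), , drop = FALSE]
    }
    if (nrow(rec) < 2L) {
      warning("subject '", sub, "' has fewer than 2 timepoints; skipped")
      next
    }
    rec <- rec[order(rec$time), , drop = FALSE]
    m <- nrow(rec)
    idx <- switch(mode,
      baseline = cbind(1L, 2:m),
      consecutive = cbind(seq_len(m - 1L), 2:m),
      all_pairs = t(utils::combn(m, 2L)))
    out[[sub]] <- data.frame(
      subject = sub,
      delta_t = rec$time[idx[, 2L]] - rec$time[idx[, 1L]],
      distance = dist[cbind(rec$sample[idx[, 1L]], rec$sample[idx[, 2L]])],
      stringsAsFactors = FALSE)
  }
  pairs <- do.call(rbind, out)
  if (is.null(pairs) || nrow(pairs) == 0L)
    stop("no usable pairs: every subject has fewer than 2 timepoints")
  rownames(pairs) <- NULL
  structure(pairs, mode = mode, class = c("md3f_pairs", "data.frame"))
}

# Internal: map pairs to the model-specific OLS response/regressor.
.pair_regression_data <- function(delta_t, distance, model, scaling) {
  switch(paste(model, scaling, sep = "."),
    linear2.time_scaled = list(y = distance^2 / delta_t, x = delta_t),
    linear2.literal     = list(y = distance^2, x = delta_t^2),
    linear.time_scaled  = list(y = distance / sqrt(delta_t), x = sqrt(delta_t)),
    linear.literal      = list(y = distance, x = delta_t))
}

#' Fit the drift-magnitude regression
#'
#' Ordinary least squares with intercept on the model-specific response and
#' regressor:
#' \describe{
#'   \item{linear2, time_scaled (default)}{d^2 / t on t; the slope estimates
#'     the squared drift magnitude and the intercept absorbs the per-unit-time
#'     diffusion contribution.}
#'   \item{linear2, literal}{d^2 on t^2.}
#'   \item{linear, time_scaled}{d / sqrt(t) on sqrt(t); the slope estimates the
#'     drift magnitude directly.}
#'   \item{linear, literal}{d on t.}
#' }
#' The slope p-value is the two-sided coefficient t-test. The drift magnitude
#' estimate is `sqrt(max(slope, 0))` for `linear2` and `max(slope, 0)` for
#' `linear` (a magnitude cannot be negative; the raw slope is kept).
#'
#' For noiseless data fitting the model exactly the slope standard error is 0;
#' the p-value is then reported as 0 for a nonzero slope and 1 otherwise.
#'
#' @param pairs `md3f_pairs` object or data.frame with columns `delta_t`
#'   (positive) and `distance` (non-negative); at least 3 pairs.
#' @param model `"linear2"` (squared quantities, default) or `"linear"`.
#' @param scaling `"time_scaled"` (default) or `"literal"`.
#' @return object of class `md3f_fit`: list with `model`, `scaling`, `slope`,
#'   `intercept`, `residual_variance`, `slope_se`, `slope_p`, `alpha_hat`,
#'   `n_pairs`.
#' @export
fit_md3f <- function(pairs, model = c("linear2", "linear"),
                     scaling = c("time_scaled", "literal")) {
  model <- match.arg(model)
  scaling <- match.arg(scaling)
  if (!all(c("delta_t", "distance") %in% names(pairs)))
    stop("pairs must have columns 'delta_t' and 'distance'")
  delta_t <- pairs$delta_t
  distance <- pairs$distance
  n <- length(delta_t)
  if (n < 3L) stop("need at least 3 pairs (slope, intercept and >= 1 residual df)")
  if (any(delta_t <= 0)) stop("all time intervals must be positive")
  if (any(distance < 0)) stop("distances must be non-negative")
  xy <- .pair_regression_data(delta_t, distance, model, scaling)
  if (stats::var(xy$x) == 0) stop("zero variance in regressor (all intervals equal)")
  if (max(abs(xy$y - mean(xy$y))) <= 1e-12 * (mean(abs(xy$y)) + 1)) {
    # constant response: the slope is exactly zero and carries no evidence
    return(structure(list(
      model = model, scaling = scaling, slope = 0, intercept = mean(xy$y),
      residual_variance = 0, slope_se = 0, slope_p = 1, alpha_hat = 0,
      n_pairs = n), class = "md3f_fit"))
  }
  fit <- stats::lm(y ~ x, data = xy)
  # summary.lm warns on noiseless (perfect-fit) input; the degenerate p-value
  # is handled explicitly below, so the warning is muffled
  sm <- suppressWarnings(summary(fit))
  cf <- sm$coefficients
  slope <- cf["x", "Estimate"]
  se <- cf["x", "Std. Error"]
  p <- cf["x", "Pr(>|t|)"]
  if (!is.finite(p)) p <- if (slope == 0) 1 else 0
  structure(list(
    model = model, scaling = scaling,
    slope = slope, intercept = cf["(Intercept)", "Estimate"],
    residual_variance = sm$sigma^2,
    slope_se = se, slope_p = p,
    alpha_hat = if (model == "linear2") sqrt(max(slope, 0)) else max(slope, 0),
    n_pairs = n), class = "md3f_fit")
}

#' @export
print.md3f_fit <- function(x, ...) {
  cat(sprintf("Drift regression (%s, %s), %d pairs\n", x$model, x$scaling, x$n_pairs))
  cat(sprintf("  slope     %.6g (se %.3g, p = %.4g)\n", x$slope, x$slope_se, x$slope_p))
  cat(sprintf("  intercept %.6g   residual variance %.6g\n",
              x$intercept, x$residual_variance))
  cat(sprintf("  drift magnitude estimate %.6g\n", x$alpha_hat))
  invisible(x)
}

#' Fit the drift regression separately for each subject
#'
#' Subjects contributing fewer than 3 usable pairs are reported as skipped
#' (attribute `"skipped"`), not treated as errors.
#'
#' @inheritParams build_pairs
#' @inheritParams fit_md3f
#' @return data.frame with one row per fitted subject (`subject`, `n_pairs`,
#'   `slope`, `intercept`, `slope_se`, `slope_p`, `alpha_hat`,
#'   `residual_variance`) and attribute `"skipped"`, a data.frame of
#'   (`subject`, `reason`).
#' @export
fit_per_subject <- function(dist, design,
                            mode = c("baseline", "consecutive", "all_pairs"),
                            model = c("linear2", "linear"),
                            scaling = c("time_scaled", "literal"),
                            dedupe = c("error", "first")) {
  mode <- match.arg(mode)
  model <- match.arg(model)
  scaling <- match.arg(scaling)
  dedupe <- match.arg(dedupe)
  subjects <- unique(design$subject)
  fits <- list()
  skipped <- list()
  for (sub in subjects) {
    sub_design <- design[design$subject == sub, , drop = FALSE]
    pairs <- withCallingHandlers(
      tryCatch(build_pairs(dist, sub_design, mode = mode, dedupe = dedupe),
               error = function(e) NULL),
      warning = function(w) invokeRestart("muffleWarning"))
    if (is.null(pairs) || nrow(pairs) < 3L) {
      skipped[[sub]] <- data.frame(subject = sub, reason = "insufficient pairs",
                                   stringsAsFactors = FALSE)
      next
    }
    f <- fit_md3f(pairs, model = model, scaling = scaling)
    fits[[sub]] <- data.frame(subject = sub, n_pairs = f$n_pairs,
                              slope = f$slope, intercept = f$intercept,
                              slope_se = f$slope_se, slope_p = f$slope_p,
                              alpha_hat = f$alpha_hat,
                              residual_variance = f$residual_variance,
                              stringsAsFactors = FALSE)
  }
  if (!length(fits)) stop("no subject has enough pairs to fit")
  out <- do.call(rbind, fits)
  rownames(out) <- NULL
  skipped <- if (length(skipped)) do.call(rbind, skipped) else
    data.frame(subject = character(), reason = character())
  rownames(skipped) <- NULL
  if (nrow(skipped))
    message(nrow(skipped), " subject(s) skipped: insufficient pairs")
  attr(out, "skipped") <- skipped
  out
}

#' Compare per-subject drift estimates between two groups
#'
#' Two-sample Student t-test (pooled variance) on per-subject drift magnitude
#' estimates. Groups are read from the design's `group` column via the
#' subject-to-group mapping; exactly two groups with at least two fitted
#' subjects each are required.
#'
#' @param fits per-subject fit table from [fit_per_subject()].
#' @param design design data.frame with `subject` and `group` columns.
#' @return object of class `md3f_group_comparison`: list with `group_labels`,
#'   `group_means`, `t_statistic`, `p_value`, `n_per_group`.
#' @export
compare_group_drifts <- function(fits, design) {
  if (!"group" %in% names(design)) stop("design has no 'group' column")
  map <- unique(design[, c("subject", "group"), drop = FALSE])
  if (anyDuplicated(map$subject))
    stop("subject(s) assigned to more than one group")
  grp <- map$group[match(fits$subject, map$subject)]
  if (anyNA(grp)) stop("fitted subject(s) missing from design")
  labels <- sort(unique(grp))
  if (length(labels) != 2L)
    stop("need exactly 2 groups, found ", length(labels))
  a <- fits$alpha_hat[grp == labels[1L]]
  b <- fits$alpha_hat[grp == labels[2L]]
  if (length(a) < 2L || length(b) < 2L)
    stop("each group needs at least 2 fitted subjects")
  pooled_ss <- sum((a - mean(a))^2) + sum((b - mean(b))^2)
  if (pooled_ss == 0) {  # degenerate: no within-group variability
    tstat <- if (mean(a) == mean(b)) 0 else sign(mean(a) - mean(b)) * Inf
    pval <- if (mean(a) == mean(b)) 1 else 0
  } else {
    tt <- stats::t.test(a, b, var.equal = TRUE)
    tstat <- unname(tt$statistic)
    pval <- tt$p.value
  }
  structure(list(group_labels = labels,
                 group_means = c(mean(a), mean(b)),
                 t_statistic = tstat, p_value = pval,
                 n_per_group = c(length(a), length(b))),
            class = "md3f_group_comparison")
}

#' @export
print.md3f_group_comparison <- function(x, ...) {
  cat(sprintf("Drift comparison: %s (n=%d, mean %.4g) vs %s (n=%d, mean %.4g)\n",
              x$group_labels[1L], x$n_per_group[1L], x$group_means[1L],
              x$group_labels[2L], x$n_per_group[2L], x$group_means[2L]))
  cat(sprintf("  Student t = %.4g, p = %.4g\n", x$t_statistic, x$p_value))
  invisible(x)
}
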