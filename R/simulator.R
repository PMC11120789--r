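# Drift-diffusion data generators. Two designs are supported: the pre/post
# design (two observations per subject, the second at a subject-specific
# exponential time) used throughout the simulation study, and full multi-step
# trajectories on a regular time grid.
#
# In d dimensions with drift magnitude alpha along unit direction W, the
# displacement over an interval s is N(alpha * s * W, s * I). With the default
# W = 1_d / sqrt(d) every coordinate has mean alpha * s / sqrt(d), so the
# squared mean displacement norm is (alpha * s)^2.

#' Define a simulation scenario
#'
#' @param n number of subjects (>= 2).
#' @param d number of dimensions (>= 1).
#' @param alpha drift magnitude (>= 0); 0 is pure diffusion.
#' @param time_rate rate of the exponential distribution of interpoint times
#'   (> 0, default 1).
#' @param seed optional integer seed; fixing it makes the generators
#'   bit-reproducible.
#' @param direction unit drift direction of length `d`; default
#'   `rep(1, d) / sqrt(d)`. Non-unit vectors are normalised with a warning.
#' @return object of class `md3f_scenario`.
#' @export
md3f_scenario <- function(n, d, alpha, time_rate = 1, seed = NULL,
                          direction = NULL) {
  if (n < 2L) stop("n must be at least 2")
  if (d < 1L) stop("d must be at least 1")
  if (alpha < 0) stop("alpha must be non-negative")
  if (time_rate <= 0) stop("time_rate must be positive")
  if (is.null(direction)) {
    direction <- rep(1, d) / sqrt(d)
  } else {
    if (length(direction) != d) stop("direction must have length d")
    nrm <- sqrt(sum(direction^2))
    if (nrm == 0) stop("direction must be a nonzero vector")
    if (abs(nrm - 1) > 1e-9) {
      warning("direction is not unit length; normalising")
      direction <- direction / nrm
    }
  }
  structure(list(n = as.integer(n), d = as.integer(d), alpha = alpha,
                 time_rate = time_rate, seed = seed, direction = direction),
            class = "md3f_scenario")
}

#' Simulate the pre/post design
#'
#' For each subject i, an interpoint time s_i ~ Exponential(`time_rate`) is
#' drawn, the pre observation sits at the multivariate origin at time 0, and
#' the post observation is the displacement X_i ~ N(alpha * s_i * direction,
#' s_i * I). Conditional on s, E[||X||^2 | s] = alpha^2 s^2 + d * s.
#'
#' @param scenario `md3f_scenario` object; its `seed`, when set, makes the
#'   draw deterministic.
#' @return object of class `md3f_prepost`: list with `s` (interpoint times),
#'   `X` (n x d displacement matrix with subject row names) and `scenario`.
#'   Use [prepost_pairs()] for the regression input and [prepost_tables()] for
#'   a feature-table/design view.
#' @export
simulate_prepost <- function(scenario) {
  stopifnot(inherits(scenario, "md3f_scenario"))
  if (!is.null(scenario$seed)) set.seed(scenario$seed)
  n <- scenario$n; d <- scenario$d
  s <- stats::rexp(n, rate = scenario$time_rate)
  mean_mat <- (scenario$alpha * s) %o% scenario$direction
  noise <- matrix(stats::rnorm(n * d, mean = 0, sd = rep(sqrt(s), d)), n, d)
  x <- mean_mat + noise
  rownames(x) <- paste0("S", seq_len(n))
  colnames(x) <- paste0("V", seq_len(d))
  structure(list(s = s, X = x, scenario = scenario), class = "md3f_prepost")
}

#' Regression pairs from a pre/post simulation
#'
#' With the pre observation at the origin, each subject contributes a single
#' (interval, distance) pair: (s_i, ||X_i||). All pairing modes coincide for
#' two timepoints.
#'
#' @param sim `md3f_prepost` object.
#' @return `md3f_pairs` data.frame.
#' @export
prepost_pairs <- function(sim) {
  stopifnot(inherits(sim, "md3f_prepost"))
  structure(data.frame(subject = rownames(sim$X), delta_t = sim$s,
                       distance = sqrt(rowSums(sim$X^2)),
                       stringsAsFactors = FALSE),
            mode = "baseline", class = c("md3f_pairs", "data.frame"))
}

#' Feature-table and design view of a pre/post simulation
#'
#' Stacks the pre (origin) and post (displacement) coordinates into a single
#' real-valued samples-by-dimensions matrix with a matching design table.
#'
#' @param sim `md3f_prepost` object.
#' @return list with `table` (2n x d matrix) and `design` (data.frame with
#'   `sample`, `subject`, `time`).
#' @export
prepost_tables <- function(sim) {
  stopifnot(inherits(sim, "md3f_prepost"))
  n <- nrow(sim$X)
  subjects <- rownames(sim$X)
  tab <- rbind(matrix(0, n, ncol(sim$X)), sim$X)
  rownames(tab) <- c(paste0(subjects, "_pre"), paste0(subjects, "_post"))
  colnames(tab) <- colnames(sim$X)
  design <- data.frame(sample = rownames(tab),
                       subject = rep(subjects, 2L),
                       time = c(rep(0, n), sim$s),
                       stringsAsFactors = FALSE)
  list(table = tab, design = design)
}

#' Simulate a multi-step drift-diffusion trajectory
#'
#' Positions start at the origin; each increment over `dt` is multivariate
#' normal with mean `alpha * dt * direction` and covariance `dt * I`.
#'
#' @param scenario `md3f_scenario`; `n` is ignored (one trajectory is drawn),
#'   `d`, `alpha`, `direction` and `seed` apply.
#' @param n_steps number of steps (>= 1).
#' @param dt step length (> 0, default 1).
#' @return object of class `md3f_trajectory`: list with `times`
#'   (0, dt, ..., n_steps * dt), `positions` ((n_steps + 1) x d matrix) and
#'   `scenario`.
#' @export
simulate_trajectory <- function(scenario, n_steps, dt = 1) {
  stopifnot(inherits(scenario, "md3f_scenario"))
  if (n_steps < 1L) stop("n_steps must be at least 1")
  if (dt <= 0) stop("dt must be positive")
  if (!is.null(scenario$seed)) set.seed(scenario$seed)
  d <- scenario$d
  inc <- matrix(stats::rnorm(n_steps * d, sd = sqrt(dt)), n_steps, d)
  inc <- inc + rep(scenario$alpha * dt * scenario$direction, each = n_steps)
  pos <- rbind(0, apply(inc, 2L, cumsum))
  if (n_steps == 1L) pos <- rbind(0, matrix(inc, 1L, d))
  times <- seq(0L, n_steps) * dt
  rownames(pos) <- paste0("T", seq_along(times) - 1L)
  colnames(pos) <- paste0("V", seq_len(d))
  structure(list(times = times, positions = pos, scenario = scenario),
            class = "md3f_trajectory")
}

#' Distance matrix and design view of a trajectory
#'
#' Euclidean distances between the trajectory's positions, with a one-subject
#' design table, ready for [build_pairs()] / [fit_md3f()].
#'
#' @param traj `md3f_trajectory` object.
#' @param subject subject label used in the design (default "S1").
#' @return list with `dist` (square matrix) and `design` (data.frame).
#' @export
trajectory_tables <- function(traj, subject = "S1") {
  stopifnot(inherits(traj, "md3f_trajectory"))
  d <- compute_distances(traj$positions, metric = "euclidean")
  design <- data.frame(sample = rownames(traj$positions), subject = subject,
                       time = traj$times, stringsAsFactors = FALSE)
  list(dist = d, design = design)
}
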