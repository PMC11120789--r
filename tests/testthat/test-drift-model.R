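# A small trajectory fixture: one subject observed at given times with known
# positions, so pair distances are exact.
make_dist <- function(pos) compute_distances(pos, "euclidean")

test_that("pair construction honours the pairing mode", {
  pos <- matrix(c(0, 1, 3), 3, 1, dimnames = list(c("a", "b", "c"), "x"))
  d <- make_dist(pos)
  design <- data.frame(sample = c("a", "b", "c"), subject = "S1",
                       time = c(0, 1, 2))

  base <- build_pairs(d, design, "baseline")
  expect_equal(base$delta_t, c(1, 2))
  expect_equal(base$distance, c(1, 3))

  cons <- build_pairs(d, design, "consecutive")
  expect_equal(cons$delta_t, c(1, 1))
  expect_equal(cons$distance, c(1, 2))

  ap <- build_pairs(d, design, "all_pairs")
  expect_equal(nrow(ap), 3)  # C(3,2)

  # two subjects with 2 timepoints each: all modes coincide
  pos2 <- matrix(c(0, 2, 0, 5), 4, 1,
                 dimnames = list(c("p1", "p2", "q1", "q2"), "x"))
  d2 <- make_dist(pos2)
  des2 <- data.frame(sample = rownames(pos2),
                     subject = c("P", "P", "Q", "Q"), time = c(0, 1, 0, 2))
  for (mode in c("baseline", "consecutive", "all_pairs")) {
    pr <- build_pairs(d2, des2, mode)
    expect_equal(nrow(pr), 2)
    expect_setequal(pr$distance, c(2, 5))
  }
})

test_that("duplicate times error unless deduplication is requested", {
  pos <- matrix(c(0, 1, 2), 3, 1, dimnames = list(c("a", "b", "c"), "x"))
  d <- make_dist(pos)
  design <- data.frame(sample = c("a", "b", "c"), subject = "S1",
                       time = c(0, 1, 1))
  expect_error(build_pairs(d, design), "duplicate times")
  pr <- build_pairs(d, design, dedupe = "first")
  expect_equal(nrow(pr), 1)
  expect_equal(pr$distance, 1)

  one <- design[1, ]
  expect_warning(expect_error(build_pairs(d, one), "no usable pairs"),
                 "fewer than 2 timepoints")
})

test_that("noiseless model data are recovered exactly in every mode", {
  # d^2 = t * (3 + 4 t): time-scaled squared response is 3 + 4 t exactly
  tt <- 1:4
  pairs <- data.frame(delta_t = tt, distance = sqrt(tt * (3 + 4 * tt)))
  f <- fit_md3f(pairs, "linear2", "time_scaled")
  expect_equal(f$slope, 4, tolerance = 1e-9)
  expect_equal(f$intercept, 3, tolerance = 1e-9)
  expect_equal(f$alpha_hat, 2, tolerance = 1e-9)
  expect_equal(f$residual_variance, 0, tolerance = 1e-9)
  expect_equal(f$slope_p, 0)

  # constant distance, unsquared literal model: zero slope, zero drift
  const <- data.frame(delta_t = 1:3, distance = 5)
  f2 <- fit_md3f(const, "linear", "literal")
  expect_equal(f2$slope, 0, tolerance = 1e-12)
  expect_equal(f2$alpha_hat, 0)
  expect_equal(f2$slope_p, 1)

  # exact d = 0.5 + 2 t under linear/literal
  lin <- data.frame(delta_t = tt, distance = 0.5 + 2 * tt)
  f3 <- fit_md3f(lin, "linear", "literal")
  expect_equal(f3$slope, 2, tolerance = 1e-9)
  expect_equal(f3$intercept, 0.5, tolerance = 1e-9)
})

test_that("each model/scaling equals direct OLS on the transformed variables", {
  set.seed(8)
  pairs <- data.frame(delta_t = stats::rexp(20) + 0.1,
                      distance = abs(stats::rnorm(20, 3)))
  forms <- list(
    list("linear2", "time_scaled", function(d, t) list(y = d^2 / t, x = t)),
    list("linear2", "literal",     function(d, t) list(y = d^2, x = t^2)),
    list("linear",  "time_scaled", function(d, t) list(y = d / sqrt(t), x = sqrt(t))),
    list("linear",  "literal",     function(d, t) list(y = d, x = t)))
  for (fm in forms) {
    f <- fit_md3f(pairs, fm[[1]], fm[[2]])
    xy <- fm[[3]](pairs$distance, pairs$delta_t)
    ref <- summary(stats::lm(y ~ x, data = xy))$coefficients
    expect_equal(f$slope, ref["x", "Estimate"], tolerance = 1e-12)
    expect_equal(f$slope_se, ref["x", "Std. Error"], tolerance = 1e-12)
    expect_equal(f$slope_p, ref["x", "Pr(>|t|)"], tolerance = 1e-12)
  }
})

test_that("degenerate pair sets are rejected", {
  expect_error(fit_md3f(data.frame(delta_t = 1:2, distance = 1:2)), "at least 3")
  expect_error(fit_md3f(data.frame(delta_t = rep(2, 5), distance = 1:5)),
               "zero variance")
  expect_error(fit_md3f(data.frame(delta_t = c(-1, 1, 2), distance = 1:3)),
               "positive")
})

test_that("rescaling all distances scales slope by c^2 and drift by c", {
  set.seed(9)
  pairs <- data.frame(delta_t = stats::rexp(30) + 0.05,
                      distance = abs(stats::rnorm(30, 2)))
  f1 <- fit_md3f(pairs)
  for (cc in c(0.5, 2.5)) {
    scaled <- transform(pairs, distance = distance * cc)
    f2 <- fit_md3f(scaled)
    expect_equal(f2$slope, cc^2 * f1$slope, tolerance = 1e-9)
    expect_equal(f2$alpha_hat, cc * f1$alpha_hat, tolerance = 1e-9)
    expect_equal(f2$slope_p, f1$slope_p, tolerance = 1e-9)
  }
})

test_that("null slope test is calibrated and its p-values are uniform", {
  reps <- 1000
  pvals <- numeric(reps)
  for (r in seq_len(reps)) {
    sim <- simulate_prepost(md3f_scenario(50, 10, 0, seed = 20000 + r))
    pvals[r] <- fit_md3f(prepost_pairs(sim))$slope_p
  }
  band <- binom_band(0.05, reps)
  expect_gte(mean(pvals < 0.05), band[1])
  expect_lte(mean(pvals < 0.05), band[2])
  expect_gt(stats::ks.test(pvals, "punif")$p.value, 0.001)
})

test_that("per-subject fitting skips short series and recovers known drift", {
  set.seed(10)
  # 5 subjects x 5 timepoints: all fit (baseline gives 4 pairs each)
  pos <- NULL; design <- NULL
  for (s in 1:5) {
    traj <- simulate_trajectory(md3f_scenario(2, 3, 1, seed = 100 + s),
                                n_steps = 4)
    p <- traj$positions
    rownames(p) <- paste0("S", s, "_", seq_len(nrow(p)))
    pos <- rbind(pos, p)
    design <- rbind(design, data.frame(sample = rownames(p),
                                       subject = paste0("S", s),
                                       time = traj$times))
  }
  d <- make_dist(pos)
  fits <- fit_per_subject(d, design)
  expect_equal(nrow(fits), 5)
  expect_equal(nrow(attr(fits, "skipped")), 0)

  # a 3-timepoint subject yields 2 baseline pairs and is skipped
  short <- design[design$subject == "S1", ][1:3, ]
  short$subject <- "short"
  both <- rbind(design[design$subject == "S2", ], short)
  expect_message(fits2 <- fit_per_subject(d, both), "skipped")
  sk <- attr(fits2, "skipped")
  expect_equal(sk$subject, "short")
  expect_equal(sk$reason, "insufficient pairs")
})

test_that("mean per-subject drift estimate recovers the simulated magnitude", {
  n_subj <- 200
  alphas <- numeric(n_subj)
  for (s in seq_len(n_subj)) {
    traj <- simulate_trajectory(md3f_scenario(2, 10, 1, seed = 3000 + s),
                                n_steps = 19)
    tt <- trajectory_tables(traj)
    alphas[s] <- fit_md3f(build_pairs(tt$dist, tt$design))$alpha_hat
  }
  se <- stats::sd(alphas) / sqrt(n_subj)
  expect_lt(abs(mean(alphas) - 1), 3 * se)
})

test_that("group comparison handles degenerate and separated groups", {
  fits <- data.frame(subject = paste0("S", 1:6),
                     alpha_hat = rep(1.5, 6))
  design <- data.frame(sample = paste0("S", 1:6), subject = paste0("S", 1:6),
                       time = 0, group = rep(c("a", "b"), each = 3))
  cmp <- compare_group_drifts(fits, design)
  expect_equal(cmp$t_statistic, 0)
  expect_equal(cmp$p_value, 1)

  fits$alpha_hat <- c(0, 0, 0, 10, 10, 10.1)
  cmp2 <- compare_group_drifts(fits, design)
  expect_lt(cmp2$p_value, 0.01)

  # agrees with the pooled-variance Student t-test
  set.seed(11)
  fits$alpha_hat <- stats::rnorm(6, 1)
  cmp3 <- compare_group_drifts(fits, design)
  ref <- stats::t.test(fits$alpha_hat[1:3], fits$alpha_hat[4:6],
                       var.equal = TRUE)
  expect_equal(cmp3$p_value, ref$p.value, tolerance = 1e-12)
  expect_equal(cmp3$t_statistic, unname(ref$statistic), tolerance = 1e-12)

  design$group <- "a"
  expect_error(compare_group_drifts(fits, design), "exactly 2 groups")
})

test_that("group test is calibrated when both groups share the same drift", {
  reps <- 400
  rej <- 0
  for (r in seq_len(reps)) {
    alphas <- matrix(NA_real_, 8, 1)
    for (s in 1:8) {
      traj <- simulate_trajectory(md3f_scenario(2, 5, 1, seed = r * 100 + s),
                                  n_steps = 9)
      tt <- trajectory_tables(traj)
      alphas[s] <- fit_md3f(build_pairs(tt$dist, tt$design))$alpha_hat
    }
    fits <- data.frame(subject = paste0("S", 1:8), alpha_hat = alphas[, 1])
    design <- data.frame(sample = paste0("S", 1:8), subject = paste0("S", 1:8),
                         time = 0, group = rep(c("a", "b"), each = 4))
    rej <- rej + (compare_group_drifts(fits, design)$p_value < 0.05)
  }
  band <- binom_band(0.05, reps)
  expect_gte(rej / reps, band[1])
  expect_lte(rej / reps, band[2])
})
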