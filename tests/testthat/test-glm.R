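test_that("the canonical HRF peaks near 5 s, vanishes at 0, and is grid-stable", {
  # independent oracle: the gamma-density difference on a fine grid
  tt <- seq(0, 32, by = 0.001)
  oracle <- dgamma(tt, 6, 1) - dgamma(tt, 16, 1) / 6
  oracle_peak <- tt[which.max(oracle)]

  h <- canonical_hrf(0.125)
  expect_equal(h$values[1], 0)
  expect_equal(max(h$values), 1)
  expect_lt(abs(h$times[which.max(h$values)] - oracle_peak), 0.125 + 1e-9)
  expect_lt(abs(oracle_peak - 5), 0.2)
  # single positive peak then undershoot, decaying tail
  expect_lt(min(h$values), 0)
  expect_lt(abs(h$values[length(h$values)]), 0.01)

  h2 <- canonical_hrf(0.25)
  expect_lt(abs(h2$times[which.max(h2$values)] -
                  h$times[which.max(h$values)]), 0.25 + 1e-9)
  expect_error(canonical_hrf(0), class = "roimvpa_invalid_parameter")
})

test_that("design matrices have the block structure the bookkeeping implies", {
  runs <- tidyr::expand_grid(run = 1:4,
                             condition = condition_table()$condition)
  runs$onset <- rep(seq(4, by = 20, length.out = 9), 4)
  runs$duration <- 10
  n_scans <- rep(110L, 4)
  motion <- lapply(1:4, function(i) matrix(rnorm(110 * 6, 0, 0.01), 110, 6))
  X <- build_design_matrix(runs, tr = 2, n_scans = n_scans, motion = motion)
  # 9 conditions x 4 runs + 6 motion x 4 runs + 4 constants
  expect_equal(ncol(X$matrix), 9 * 4 + 6 * 4 + 4)
  # condition columns are zero outside their run's rows
  off <- c(0, cumsum(n_scans))
  for (i in seq_len(nrow(X$labels))) {
    lab <- X$labels[i, ]
    outside <- setdiff(seq_len(sum(n_scans)),
                       off[lab$run] + seq_len(n_scans[lab$run]))
    expect_true(all(X$matrix[outside, i] == 0))
  }

  # a condition absent from a run contributes no column for that run
  runs2 <- runs[!(runs$run == 2 & runs$condition == "error"), ]
  X2 <- build_design_matrix(runs2, tr = 2, n_scans = n_scans)
  expect_equal(ncol(X2$matrix), 9 * 4 - 1 + 4)
  expect_equal(sum(X2$labels$condition == "error"), 3)

  # epoch beyond the run end is rejected, naming the run
  runs3 <- runs
  runs3$duration[runs3$run == 3 & runs3$condition == "conf_verbal"] <- 500
  expect_error(build_design_matrix(runs3, tr = 2, n_scans = n_scans),
               regexp = "run 3", class = "roimvpa_invalid_parameter")
})

test_that("condition columns equal a direct convolution oracle", {
  ep <- tibble::tibble(run = 1, condition = "disc_verbal_separate",
                       onset = 9.5, duration = 17)
  X <- build_design_matrix(ep, tr = 2, n_scans = 40L)
  col <- X$matrix[, 1]

  # oracle: explicit boxcar on the microtime grid, full FFT convolution
  dt <- 2 / 16; nf <- 40 * 16
  u <- numeric(nf)
  a <- floor(9.5 / dt) + 1; b <- floor((9.5 + 17) / dt)
  u[a:b] <- 1
  h <- canonical_hrf(dt)
  k <- h$values / sum(h$values)
  conv <- stats::convolve(c(u, numeric(length(k))), rev(k),
                          type = "open")[seq_len(nf)]
  oracle <- conv[seq(1, nf, by = 16)]
  expect_equal(col, oracle, tolerance = 1e-12)

  # support begins at the onset frame and decays after offset + tail
  expect_true(all(col[1:5] == 0))          # frames before 9.5 s
  expect_gt(max(col), 0.5)
  expect_lt(max(abs(col[30:40])), 0.05)    # past 26.5 s + tail
})

test_that("OLS betas match the normal-equations oracle and recover noise-free amplitudes", {
  fx <- tiny_fit()
  amps <- scene_amplitudes(fx$scene, 1)
  # noise-free round trip
  ds0 <- simulate_bold(fx$design, fx$scene,
                       noise = noise_params(sigma = 1e-14), seed = 21)
  fit0 <- fit_subject_glm(ds0, 1, 1)
  lab <- fit0$labels
  for (i in which(lab$type == "condition")) {
    expect_lt(max(abs(fit0$coefficients[i, ] - amps[, lab$condition[i]])),
              1e-6)
  }

  # random small instances against solve(X'X) X'y
  set.seed(31)
  for (rep in 1:20) {
    X <- matrix(rnorm(20 * 5), 20, 5)
    Y <- matrix(rnorm(20 * 10), 20, 10)
    dm <- structure(list(matrix = X,
                         labels = tibble::tibble(column = 1:5,
                                                 type = "condition",
                                                 condition = paste0("c", 1:5),
                                                 run = 1L)),
                    class = "design_matrix")
    fit <- fit_glm(Y, dm)
    oracle <- solve(t(X) %*% X, t(X) %*% Y)
    expect_lt(max(abs(fit$coefficients - oracle)), 1e-8)
    rss <- colSums((Y - X %*% oracle)^2)
    expect_equal(fit$sigma2, rss / (20 - 5), tolerance = 1e-10)
  }
})

test_that("a duplicated column triggers the pseudoinverse path with a warning", {
  X <- matrix(rnorm(30 * 3), 30, 3)
  X <- cbind(X, X[, 3])
  dm <- structure(list(matrix = X,
                       labels = tibble::tibble(column = 1:4, type = "condition",
                                               condition = paste0("c", 1:4),
                                               run = 1L)),
                  class = "design_matrix")
  expect_warning(fit <- fit_glm(matrix(rnorm(30 * 2), 30, 2), dm),
                 class = "roimvpa_rank_deficient")
  expect_equal(fit$rank, 3)
  expect_equal(fit$df_residual, 27)
})

test_that("contrast t equals the scalar formula oracle and scales correctly", {
  set.seed(41)
  X <- cbind(matrix(rnorm(25 * 3), 25, 3), 1)
  y <- matrix(rnorm(25), 25, 1)
  dm <- structure(list(matrix = X,
                       labels = tibble::tibble(
                         column = 1:4,
                         type = c(rep("condition", 3), "constant"),
                         condition = c("a", "b", "ctrl", "constant"),
                         run = 1L)),
                  class = "design_matrix")
  fit <- fit_glm(y, dm)
  sm <- contrast_t(fit, c(a = 1, b = 1, ctrl = -2))

  beta <- solve(t(X) %*% X, t(X) %*% y)
  cvec <- c(1, 1, -2, 0)
  s2 <- sum((y - X %*% beta)^2) / (25 - 4)
  t_oracle <- (t(cvec) %*% beta) /
    sqrt(s2 * t(cvec) %*% solve(t(X) %*% X) %*% cvec)
  expect_equal(as.numeric(sm$t), as.numeric(t_oracle), tolerance = 1e-10)

  # rescaling the contrast rescales the effect but not the t
  sm2 <- contrast_t(fit, c(a = 2, b = 2, ctrl = -4))
  expect_equal(as.numeric(sm2$t), as.numeric(sm$t), tolerance = 1e-10)
  expect_equal(as.numeric(sm2$effect), 2 * as.numeric(sm$effect),
               tolerance = 1e-10)

  expect_error(contrast_t(fit, c(bogus = 1)),
               class = "roimvpa_invalid_parameter")
  sm0 <- contrast_t(fit, c(a = 0, b = 0))
  expect_true(all(sm0$t == 0))
})

test_that("contrast weights are split over each condition's run columns", {
  fx <- tiny_fit()
  cvec <- roimvpa:::expand_contrast(fx$fit$labels, localizer_contrast())
  lab <- fx$fit$labels
  for (cond in names(localizer_contrast())) {
    idx <- lab$type == "condition" & lab$condition == cond
    expect_equal(sum(cvec[idx]), unname(localizer_contrast()[cond]))
    expect_equal(length(unique(cvec[idx])), 1)
  }
  expect_equal(sum(cvec[lab$condition == "error"]), 0)
})

test_that("group maps equal the one-sample t oracle, with df = n - 1", {
  set.seed(51)
  effects <- lapply(1:5, function(i) array(rnorm(24), c(4, 3, 2)))
  gm <- group_map(effects)
  expect_equal(gm$df, 4)
  Y <- sapply(effects, as.vector)
  oracle <- apply(Y, 1, function(v) unname(t.test(v)$statistic))
  expect_equal(as.vector(gm$t), oracle, tolerance = 1e-8)

  # 13 subjects -> df 12
  gm13 <- group_map(lapply(1:13, function(i) array(rnorm(8), c(2, 2, 2))))
  expect_equal(gm13$df, 12)

  # identical nonzero maps -> infinite, not NaN
  same <- lapply(1:4, function(i) array(1, c(2, 2, 1)))
  gmi <- group_map(same)
  expect_true(all(is.infinite(gmi$t)))
  expect_error(group_map(list(array(0, c(2, 2, 2)), array(0, c(2, 2, 3)))),
               class = "roimvpa_invalid_parameter")
})

test_that("motion regressors absorb motion-mixed signal without biasing condition betas", {
  p <- design_params(n_subjects = 1, n_sessions = 1, n_runs = 2,
                     mean_epoch_duration = 8)
  d <- generate_design(p, seed = 61)
  sc <- generate_scene(grid = c(4, 4, 2),
                       roi_specs = list(roi_spec("t", c(2, 2, 1),
                                                 n_voxels = 8)),
                       n_sessions = 1, seed = 62)
  amps <- scene_amplitudes(sc, 1)
  set.seed(63)
  bias <- replicate(25, {
    seed <- sample.int(1e6, 1)
    ds <- simulate_bold(d, sc, noise = noise_params(sigma = 0.3,
                                                    motion_mix = 1),
                        seed = seed)
    fit <- fit_subject_glm(ds, 1, 1, use_motion = TRUE)
    lab <- fit$labels
    idx <- which(lab$type == "condition" & lab$condition != "error")
    mean(vapply(idx, function(i) {
      mean(fit$coefficients[i, ] - amps[, lab$condition[i]])
    }, numeric(1)))
  })
  expect_lt(abs(mean(bias)), 3 * sd(bias) / sqrt(length(bias)))
})
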