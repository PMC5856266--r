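test_that("pattern extraction keeps the condition-by-run bookkeeping", {
  fx <- tiny_fit()
  lab <- fx$fit$labels
  # eight task conditions x four runs of condition-by-run betas
  task_betas <- sum(lab$type == "condition" & lab$condition != "error")
  expect_equal(task_betas, 32)

  ps <- extract_patterns(fx$fit, scene_mask(fx$scene, "t"))
  expect_equal(nrow(ps$x), 16)
  expect_equal(nrow(ps$info), 16)
  expect_equal(as.integer(table(ps$info$run)), rep(4L, 4))

  sep <- subset_patterns(ps, "separate")
  par <- subset_patterns(ps, "parallel")
  expect_equal(nrow(sep$x), 8)
  expect_equal(nrow(par$x), 8)
  for (s in list(sep, par)) {
    tab <- table(s$info$run, s$info$domain)
    expect_true(all(tab == 1))
  }

  # row order: run-major, canonical condition order inside each run
  expect_equal(ps$info$run, rep(1:4, each = 4))
  expect_equal(ps$info$condition[1:4], conditions_of_interest())
})

test_that("single-voxel masks give the raw beta values; bad inputs error", {
  fx <- tiny_fit()
  vox <- fx$scene$rois$t$voxels[1]
  ps <- extract_patterns(fx$fit, vox)
  expect_equal(ncol(ps$x), 1)
  lab <- fx$fit$labels
  i <- which(lab$type == "condition" & lab$condition == "disc_verbal_separate" &
               lab$run == 2)
  expect_equal(ps$x[ps$info$run == 2 &
                      ps$info$condition == "disc_verbal_separate", 1],
               fx$fit$coefficients[i, vox])

  expect_error(extract_patterns(fx$fit, array(FALSE, fx$scene$grid)),
               class = "roimvpa_invalid_parameter")
  # a missing (condition, run) beta is reported with the gap named
  broken <- fx$fit
  keep <- !(broken$labels$condition == "disc_spatial_parallel" &
              broken$labels$run == 3)
  broken$labels <- broken$labels[keep, ]
  broken$coefficients <- broken$coefficients[keep, , drop = FALSE]
  expect_error(extract_patterns(broken, vox),
               regexp = "disc_spatial_parallel/run3")
})

test_that("normalization removes a uniform magnitude offset", {
  ps <- make_patterns(n_vox = 30, delta = 0.5, noise_sd = 0, seed = 1)
  norm <- normalize_patterns(ps)
  expect_lt(max(abs(norm$x)), 1e-12)
})

test_that("leave-one-run-out decoding separates planted patterns and runs 4 folds", {
  delta <- rnorm(40, 0, 1)
  ps <- make_patterns(n_vox = 40, delta = delta, noise_sd = 0.05, seed = 2)
  fit <- loro_decode(ps)
  expect_length(fit$fold_accuracies, 4)
  expect_equal(fit$accuracy, 1.0)
  expect_equal(fit$accuracy, mean(fit$fold_accuracies))

  # missing class in training folds
  bad <- ps
  bad$info$domain <- rep("verbal", 8)
  expect_error(loro_decode(bad), class = "roimvpa_invalid_parameter")
})

test_that("identical class patterns decode at chance over many subjects", {
  accs <- vapply(1:200, function(i) {
    loro_decode(make_patterns(n_vox = 15, delta = 0, noise_sd = 1,
                              seed = 1000 + i))$accuracy
  }, numeric(1))
  se <- sd(accs) / sqrt(length(accs))
  expect_lt(abs(mean(accs) - 0.5), 3 * se)
})

test_that("accuracy bounds and fold bookkeeping hold on random inputs", {
  set.seed(7)
  for (i in 1:25) {
    ps <- make_patterns(n_vox = sample(2:20, 1),
                        delta = rnorm(1, 0, 0.5),
                        noise_sd = runif(1, 0.2, 2), seed = 2000 + i)
    fit <- loro_decode(ps)
    expect_true(all(fit$fold_accuracies >= 0 & fit$fold_accuracies <= 1))
    expect_true(all(fit$fold_accuracies * 2 == round(fit$fold_accuracies * 2)))
    expect_equal(fit$accuracy, mean(fit$fold_accuracies))
  }
})

test_that("group summaries follow the mean/SEM arithmetic", {
  r <- group_decode(c(0.5, 0.5, 0.5))
  expect_equal(r$mean, 0.5)
  expect_equal(r$sem, 0)

  vals <- c(0.625, 0.75, 0.5)
  r2 <- group_decode(vals)
  expect_equal(r2$mean, mean(vals))
  expect_equal(r2$sem, sd(vals) / sqrt(3))

  r13 <- group_decode(rep(c(0.5, 0.625), length.out = 13))
  expect_equal(r13$n, 13)
  expect_equal(r13$sem, sd(rep(c(0.5, 0.625), length.out = 13)) / sqrt(13))
})

test_that("permutation nulls store n_perm estimates and match direct relabeling", {
  sets <- lapply(1:3, function(s) make_patterns(n_vox = 12, delta = 0.8,
                                                noise_sd = 1, seed = 300 + s))
  null <- permutation_null(sets, n_perm = 150, seed = 4)
  expect_length(null$estimates, 150)
  expect_gte(null$critical, median(null$estimates))
  expect_true(all(null$estimates >= 0 & null$estimates <= 1))

  # the memoized fold/flip lookup reproduces a literal relabel-and-rerun
  ft <- roimvpa:::fold_flip_table(sets[[1]], cost = 1)
  flips_all <- as.matrix(expand.grid(0:1, 0:1, 0:1, 0:1))
  for (i in seq_len(nrow(flips_all))) {
    f <- as.integer(flips_all[i, ])
    expect_equal(roimvpa:::flip_accuracy(ft, f),
                 roimvpa:::loro_decode_relabeled(sets[[1]], f))
  }

  expect_warning(permutation_null(sets, n_perm = 50, seed = 1),
                 class = "roimvpa_small_null")
  # determinism
  n2 <- permutation_null(sets, n_perm = 150, seed = 4)
  expect_identical(null$estimates, n2$estimates)
})

test_that("significance requires strictly exceeding the critical value", {
  null <- structure(list(estimates = rep(0.5, 100), critical = 0.6,
                         n_perm = 100, alpha = 0.05, seed = 1),
                    class = "null_distribution")
  expect_false(is_significant(0.6, null))
  expect_true(is_significant(0.601, null))
})

test_that("cross-session transfer is perfect for a copied code and errors on mismatch", {
  s1 <- lapply(1:4, function(s) make_patterns(n_vox = 25, delta = rnorm(25),
                                              noise_sd = 0.05, seed = 400 + s))
  r12 <- cross_session_decode(s1, s1, "s1_to_s2")
  expect_equal(r12$mean, 1.0)
  r21 <- cross_session_decode(s1, s1, "s2_to_s1")
  expect_equal(r21$direction, "s2_to_s1")

  s2 <- lapply(1:4, function(s) make_patterns(n_vox = 10, delta = 0,
                                              noise_sd = 1, seed = 500 + s))
  expect_error(cross_session_decode(s1, s2, "s1_to_s2"),
               class = "roimvpa_invalid_parameter")
  expect_error(cross_session_decode(s1, s2[1:2], "s1_to_s2"),
               class = "roimvpa_invalid_parameter")
})

test_that("feature curves use the requested grid and skip oversized subsets", {
  sets <- lapply(1:2, function(s) make_patterns(n_vox = 120,
                                                delta = rnorm(120, 0, 0.8),
                                                noise_sd = 1, seed = 600 + s))
  fc <- feature_curve(sets, sizes = c(10, 30), n_draws = 2, seed = 5)
  expect_equal(fc$summary$size, c(10, 30))
  expect_equal(nrow(fc$per_subject), 2 * 2)
  expect_equal(fc$n_draws, 2)

  small <- lapply(sets, function(s) { s$x <- s$x[, 1:20]; s })
  expect_warning(fc2 <- feature_curve(small, sizes = c(10, 50), n_draws = 2,
                                      seed = 5),
                 class = "roimvpa_sizes_skipped")
  expect_equal(fc2$sizes, 10)
  expect_error(feature_curve(small, sizes = c(50, 60), n_draws = 2, seed = 5),
               class = "roimvpa_invalid_parameter")
  # determinism
  fc3 <- feature_curve(sets, sizes = c(10, 30), n_draws = 2, seed = 5)
  expect_identical(fc$per_subject, fc3$per_subject)
})

test_that("with a pattern in every voxel, more features do not hurt on average", {
  accs <- sapply(1:20, function(i) {
    set.seed(700 + i)
    sets <- list(make_patterns(n_vox = 100, delta = rnorm(100, 0, 0.35),
                               noise_sd = 1, seed = 800 + i))
    fc <- feature_curve(sets, sizes = c(10, 100), n_draws = 5, seed = i)
    fc$summary$mean
  })
  expect_gte(mean(accs[2, ]), mean(accs[1, ]))
})
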