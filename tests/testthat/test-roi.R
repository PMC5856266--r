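test_that("peak thresholding follows the one-tailed t quantile", {
  set.seed(1)
  tvals <- array(rnorm(200, 0, 3), c(10, 10, 2))
  sm <- structure(list(t = tvals, df = 12), class = "stat_map")
  bm <- threshold_peaks(sm, 0.001)
  # independent route: per-voxel one-tailed p-values
  pvals <- 1 - pt(tvals, df = 12)
  expect_identical(bm, pvals < 0.001)
  # the implied cutoff sits at the 0.999 quantile of t12 (~3.93)
  cut <- min(tvals[bm])
  expect_gt(cut, qt(0.999, 12))
  expect_gt(3.95, qt(0.999, 12))

  expect_identical(threshold_peaks(structure(list(t = array(0, c(2, 2, 2)),
                                                  df = 12),
                                             class = "stat_map"), 0.001),
                   array(FALSE, c(2, 2, 2)))
  # boundary: p = 1 keeps every finite voxel
  expect_true(all(threshold_peaks(sm, 1)))
  expect_error(threshold_peaks(structure(list(t = tvals, df = NULL),
                                         class = "stat_map"), 0.001),
               class = "roimvpa_invalid_parameter")
})

test_that("connectivity neighbourhoods behave as defined", {
  m <- array(FALSE, c(3, 3, 3))
  m[1, 1, 1] <- TRUE; m[2, 2, 2] <- TRUE        # share only a corner
  expect_equal(nrow(label_clusters(m, 6)$clusters), 2)
  expect_equal(nrow(label_clusters(m, 18)$clusters), 2)
  expect_equal(nrow(label_clusters(m, 26)$clusters), 1)

  m2 <- array(FALSE, c(3, 3, 3))
  m2[1, 1, 1] <- TRUE; m2[2, 2, 1] <- TRUE      # share an edge
  expect_equal(nrow(label_clusters(m2, 6)$clusters), 2)
  expect_equal(nrow(label_clusters(m2, 18)$clusters), 1)

  solid <- array(TRUE, c(3, 3, 3))
  cs <- label_clusters(solid, 18)
  expect_equal(cs$clusters$size, 27)

  expect_error(label_clusters(array(2, c(2, 2, 2)), 18),
               class = "roimvpa_invalid_parameter")
  expect_error(label_clusters(matrix(TRUE, 2, 2), 18),
               class = "roimvpa_invalid_parameter")
})

test_that("labels are deterministic: ordered by size, ties by peak coordinate", {
  m <- array(FALSE, c(6, 6, 2))
  m[1:2, 1, 1] <- TRUE          # size 2
  m[4:6, 4, 1] <- TRUE          # size 3
  m[1:2, 6, 2] <- TRUE          # size 2
  cs <- label_clusters(m, 6)
  expect_equal(cs$clusters$size, c(3, 2, 2))
  expect_equal(cs$clusters$peak_x, c(4, 1, 1))
  expect_true(cs$clusters$peak_y[2] < cs$clusters$peak_y[3])
})

test_that("random volumes match the independent flood-fill oracle", {
  set.seed(5)
  for (i in 1:12) {
    conn <- sample(c(6, 18, 26), 1)
    m <- array(runif(8 * 8 * 8) < 0.25, c(8, 8, 8))
    cs <- label_clusters(m, conn)
    expect_true(same_partition(partition_from_labels(cs$labels),
                               flood_fill_oracle(m, conn)))
    expect_equal(sum(cs$clusters$size), sum(m))
  }
})

test_that("the extent threshold is deterministic and calibrated on null maps", {
  set.seed(6)
  effects <- lapply(1:8, function(i) array(rnorm(10 * 10 * 6), c(10, 10, 6)))
  e1 <- cluster_extent_threshold(effects, n_perm = 100, seed = 3)
  e2 <- cluster_extent_threshold(effects, n_perm = 100, seed = 3)
  expect_identical(e1$threshold, e2$threshold)
  expect_length(e1$null, 100)
  expect_warning(cluster_extent_threshold(effects[1:3], n_perm = 100, seed = 1),
                 class = "roimvpa_coarse_null")
  expect_error(cluster_extent_threshold(effects, n_perm = 50, seed = 1),
               class = "roimvpa_invalid_parameter")

  # family-wise calibration: on pure-noise subject maps, a surviving cluster
  # appears in at most alpha (+ Monte-Carlo margin) of datasets
  survived <- replicate(60, {
    eff <- lapply(1:8, function(i) array(rnorm(10 * 10 * 6), c(10, 10, 6)))
    ext <- cluster_extent_threshold(eff, n_perm = 100,
                                    seed = sample.int(1e6, 1))
    gm <- group_map(eff)
    bm <- threshold_peaks(gm, 0.001)
    if (!any(bm)) return(FALSE)
    cl <- label_clusters(bm, 18)
    any(cl$clusters$size >= ext$threshold)
  })
  rate <- mean(survived)
  expect_lte(rate, 0.05 + 2 * sqrt(0.05 * 0.95 / 60))
})

test_that("the minimum-extent filter discards clusters below 25 voxels", {
  # constructed map with clusters of sizes 24, 25 and 40
  m <- array(FALSE, c(30, 10, 5))
  m[1:8, 1:3, 1] <- TRUE                 # 24 voxels
  m[15:19, 5:9, 1] <- TRUE               # 25 voxels
  m[21:30, 1:4, 3] <- TRUE               # 40 voxels
  cs <- label_clusters(m, 18)
  expect_setequal(cs$clusters$size, c(24, 25, 40))
  rs <- select_rois(cs, extent_threshold = 10, min_voxels = 25)
  expect_setequal(rs$rois$size, c(25, 40))
  expect_equal(min(rs$rois$size), 25)
  # masks are disjoint and inside the grid
  overlap <- Reduce(`+`, lapply(rs$masks, function(x) x * 1))
  expect_lte(max(overlap), 1)

  empty <- select_rois(label_clusters(array(FALSE, c(4, 4, 4)), 18))
  expect_equal(nrow(empty$rois), 0)
  expect_length(empty$masks, 0)
})

test_that("a planted multi-region scene is fully recovered by the localizer", {
  grid <- c(20, 20, 14)
  specs <- list(
    roi_spec("L_IFG", c(5, 5, 4), n_voxels = 90, role = "pattern-carrier"),
    roi_spec("R_IFG", c(15, 5, 4), n_voxels = 60, role = "localizer-only"),
    roi_spec("R_SFG", c(15, 15, 4), n_voxels = 40, role = "localizer-only"),
    roi_spec("L_OG", c(5, 15, 4), n_voxels = 32, role = "magnitude-confound"),
    roi_spec("R_OG", c(15, 10, 11), n_voxels = 27, role = "localizer-only"),
    roi_spec("L_Cer", c(5, 10, 11), n_voxels = 60, role = "localizer-only"))
  d <- generate_design(design_params(n_subjects = 13, n_sessions = 1,
                                     mean_epoch_duration = 10), seed = 71)
  sc <- generate_scene(grid, specs, n_sessions = 1, seed = 72)
  effects <- lapply(1:13, function(s) {
    ds <- simulate_bold(d, sc, seed = 73, subjects = s)
    contrast_t(fit_subject_glm(ds, s, 1), localizer_contrast())$effect
  })
  gm <- group_map(effects)
  ext <- cluster_extent_threshold(effects, n_perm = 100, seed = 74)
  cl <- label_clusters(threshold_peaks(gm, 0.001), 18, stat = gm$t)
  rs <- select_rois(cl, ext$threshold, min_voxels = 25)
  mt <- match_rois(rs, sc)
  expect_equal(nrow(rs$rois), 6)
  expect_setequal(mt$scene_roi, names(sc$rois))
  expect_true(all(mt$jaccard >= 0.5))
})
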