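#' Peak-level thresholding of a statistic map
#'
#' Retains a voxel iff its one-tailed p-value, from the t distribution with
#' the map's degrees of freedom, is below `p_peak` (the localizer contrast
#' is directional, so thresholding is one-tailed positive).
#'
#' @param stat_map A [group_map()] / [contrast_t()] object.
#' @param p_peak Peak-level p threshold (default 0.001).
#' @return Logical array of suprathreshold voxels.
#' @export
threshold_peaks <- function(stat_map, p_peak = 0.001) {
  if (p_peak <= 0 || p_peak >= 1) {
    # p_peak = 1 handled below as the boundary "keep all finite" case
    if (p_peak != 1) stop_invalid("`p_peak` must lie in (0, 1].")
  }
  if (is.null(stat_map$df) || is.na(stat_map$df)) {
    stop_invalid("statistic map carries no degrees of freedom.")
  }
  tcrit <- stats::qt(1 - p_peak, df = stat_map$df)
  out <- stat_map$t > tcrit & is.finite(stat_map$t)
  if (p_peak == 1) out <- is.finite(stat_map$t)
  out[is.na(out)] <- FALSE
  out
}

neighbor_offsets <- function(connectivity) {
  d <- as.matrix(expand.grid(dx = -1:1, dy = -1:1, dz = -1:1))
  d <- d[rowSums(abs(d)) > 0, , drop = FALSE]
  keep <- switch(as.character(connectivity),
                 "6" = rowSums(abs(d)) == 1,
                 "18" = rowSums(abs(d)) <= 2,
                 "26" = rep(TRUE, nrow(d)),
                 stop_invalid("`connectivity` must be 6, 18 or 26."))
  d[keep, , drop = FALSE]
}

#' Label connected clusters in a binary 3D map
#'
#' Breadth-first connected-component labeling under 6-, 18- or
#' 26-neighbourhoods. Labels are assigned deterministically: clusters are
#' numbered by decreasing size, ties broken by the lexicographically
#' smallest peak coordinate.
#'
#' @param binary_map Logical (or 0/1) 3D array.
#' @param connectivity 6, 18 or 26 (default 18).
#' @param stat Optional statistic array of the same shape; cluster peaks
#'   are then the maximum-statistic voxels (lexicographic tie-break),
#'   otherwise the lexicographically first voxel.
#' @return A `cluster_set`: `labels` (integer array), `clusters` tibble
#'   (`cluster`, `size`, `peak_x`, `peak_y`, `peak_z`, `peak_stat`),
#'   `connectivity`.
#' @export
label_clusters <- function(binary_map, connectivity = 18, stat = NULL) {
  if (is.null(dim(binary_map)) || length(dim(binary_map)) != 3) {
    stop_invalid("`binary_map` must be a 3D array.")
  }
  vals <- as.vector(binary_map)
  if (!all(vals %in% c(0, 1, TRUE, FALSE))) {
    stop_invalid("`binary_map` must be binary.")
  }
  grid <- dim(binary_map)
  offs <- neighbor_offsets(connectivity)
  mask <- which(vals > 0)
  labels <- integer(length(vals))
  comp <- 0L
  members <- list()
  for (v in mask) {
    if (labels[v] != 0L) next
    comp <- comp + 1L
    queue <- v
    labels[v] <- comp
    got <- v
    while (length(queue) > 0) {
      cur <- queue
      queue <- integer(0)
      co <- lin_to_coord(cur, grid)
      for (o in seq_len(nrow(offs))) {
        nb <- cbind(co[, 1] + offs[o, 1], co[, 2] + offs[o, 2],
                    co[, 3] + offs[o, 3])
        ok <- nb[, 1] >= 1 & nb[, 1] <= grid[1] &
          nb[, 2] >= 1 & nb[, 2] <= grid[2] &
          nb[, 3] >= 1 & nb[, 3] <= grid[3]
        if (!any(ok)) next
        lin <- coord_to_lin(nb[ok, , drop = FALSE], grid)
        lin <- lin[vals[lin] > 0 & labels[lin] == 0L]
        if (length(lin) > 0) {
          lin <- unique(lin)
          labels[lin] <- comp
          queue <- c(queue, lin)
          got <- c(got, lin)
        }
      }
    }
    members[[comp]] <- got
  }

  info <- purrr::map_dfr(seq_len(comp), function(k) {
    vox <- sort(members[[k]])
    co <- lin_to_coord(vox, grid)
    if (!is.null(stat)) {
      sv <- as.vector(stat)[vox]
      best <- which(sv == max(sv))
    } else {
      sv <- rep(NA_real_, length(vox))
      best <- seq_along(vox)
    }
    # lexicographic tie-break on (x, y, z)
    bco <- co[best, , drop = FALSE]
    ord <- order(bco[, 1], bco[, 2], bco[, 3])[1]
    pk <- bco[ord, ]
    tibble(old = k, size = length(vox),
           peak_x = pk[[1]], peak_y = pk[[2]], peak_z = pk[[3]],
           peak_stat = if (!is.null(stat)) max(sv) else NA_real_)
  })
  if (comp > 0) {
    ord <- order(-info$size, info$peak_x, info$peak_y, info$peak_z)
    info <- info[ord, ]
    relab <- integer(comp)
    relab[info$old] <- seq_len(comp)
    labels[labels > 0L] <- relab[labels[labels > 0L]]
    info$cluster <- seq_len(comp)
    info <- info[, c("cluster", "size", "peak_x", "peak_y", "peak_z",
                     "peak_stat")]
  } else {
    info <- tibble(cluster = integer(), size = integer(), peak_x = integer(),
                   peak_y = integer(), peak_z = integer(),
                   peak_stat = numeric())
  }
  structure(list(labels = array(labels, grid), clusters = info,
                 connectivity = connectivity),
            class = "cluster_set")
}

#' Permutation cluster-extent threshold
#'
#' Family-wise-error control at the cluster level by sign-flipping
#' permutation: each permutation flips the sign of whole subject contrast
#' images, recomputes the group one-sample t map, thresholds at `p_peak`,
#' and records the maximum cluster extent. The significant-extent threshold
#' is the smallest extent whose exceedance probability under that
#' max-extent null is at most `alpha` (the integer ceiling of the
#' `1 - alpha` quantile, raised by one where the discrete null makes the
#' quantile itself anti-conservative).
#'
#' @param effects List of per-subject contrast-effect 3D arrays.
#' @param p_peak Peak-level threshold (default 0.001).
#' @param alpha Cluster-level FWE target (default 0.05).
#' @param n_perm Number of sign-flip permutations (>= 100; default 1000).
#' @param seed Integer seed.
#' @param connectivity Cluster connectivity (default 18).
#' @return An `extent_threshold` list: `threshold` (voxels), `null`
#'   (max-extent per permutation), `p_peak`, `alpha`, `n_perm`, `seed`.
#' @export
cluster_extent_threshold <- function(effects, p_peak = 0.001, alpha = 0.05,
                                     n_perm = 1000, seed = 1,
                                     connectivity = 18) {
  if (n_perm < 100) stop_invalid("`n_perm` must be at least 100.")
  n <- length(effects)
  if (n < 5) {
    warn("fewer than 5 subjects: the sign-flip null is coarse.",
         class = "roimvpa_coarse_null")
  }
  null <- with_seed(derive_seed(seed, 505L), {
    vapply(seq_len(n_perm), function(i) {
      signs <- sample(c(-1, 1), n, replace = TRUE)
      flipped <- purrr::map2(effects, signs, function(e, s) e * s)
      gm <- group_map(flipped)
      bm <- threshold_peaks(gm, p_peak)
      if (!any(bm)) return(0)
      max(label_clusters(bm, connectivity)$clusters$size)
    }, numeric(1))
  })
  # smallest integer extent whose null exceedance probability is <= alpha;
  # on sparse discrete nulls this is the quantile + 1, keeping the
  # family-wise rate at or below alpha (the quantile itself can be exceeded
  # far more often than alpha when the null mass sits on a few small values)
  cand <- sort(unique(c(ceiling(null), max(ceiling(null)) + 1)))
  thr <- cand[which(vapply(cand, function(cc) mean(null >= cc),
                           numeric(1)) <= alpha)[1]]
  structure(list(threshold = thr,
                 null = null, p_peak = p_peak, alpha = alpha,
                 n_perm = n_perm, seed = seed),
            class = "extent_threshold")
}

#' Select regions of interest from labeled clusters
#'
#' Keeps clusters whose extent reaches both the permutation extent
#' threshold and the minimum-size filter (clusters with fewer than
#' `min_voxels` voxels are discarded because MVPA needs enough features).
#'
#' @param clusters A [label_clusters()] object.
#' @param extent_threshold Significant extent in voxels (default 0), e.g.
#'   from [cluster_extent_threshold()].
#' @param min_voxels Minimum cluster size (default 25).
#' @param names Optional character vector naming surviving clusters (in
#'   cluster order); default names are built from peak coordinates.
#' @return An `roi_set`: `masks` (named list of logical arrays), `rois`
#'   tibble (`name`, `size`, `peak_x`, `peak_y`, `peak_z`, `peak_stat`).
#' @export
select_rois <- function(clusters, extent_threshold = 0, min_voxels = 25,
                        names = NULL) {
  need <- max(extent_threshold, min_voxels)
  keep <- clusters$clusters[clusters$clusters$size >= need, ]
  nm <- if (!is.null(names)) {
    if (length(names) != nrow(keep)) {
      stop_invalid("`names` must match the number of surviving clusters.")
    }
    names
  } else if (nrow(keep) > 0) {
    sprintf("roi_%d_%d_%d", keep$peak_x, keep$peak_y, keep$peak_z)
  } else character(0)
  masks <- stats::setNames(purrr::map(keep$cluster, function(k) {
    clusters$labels == k
  }), nm)
  keep$name <- nm
  structure(list(masks = masks,
                 rois = keep[, c("name", "size", "peak_x", "peak_y",
                                 "peak_z", "peak_stat")]),
            class = "roi_set")
}

#' Match localized ROIs to planted scene regions
#'
#' @param roiset A [select_rois()] object.
#' @param scene The generating [generate_scene()] object.
#' @return Tibble `roi`, `scene_roi`, `jaccard`: each localized ROI paired
#'   with the planted region it overlaps most.
#' @export
match_rois <- function(roiset, scene) {
  purrr::map_dfr(names(roiset$masks), function(nm) {
    vox <- which(roiset$masks[[nm]])
    jac <- vapply(scene$rois, function(r) {
      length(intersect(vox, r$voxels)) / length(union(vox, r$voxels))
    }, numeric(1))
    best <- which.max(jac)
    tibble(roi = nm, scene_roi = names(scene$rois)[best],
           jaccard = jac[[best]])
  })
}
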