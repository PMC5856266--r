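#' Extract beta patterns for one ROI
#'
#' Pulls, from a fitted subject/session GLM, the per-(condition, run) beta
#' values inside an ROI mask for the four rule-discovery conditions of
#' interest: with four runs this yields sixteen multivoxel beta patterns
#' (out of the thirty-two condition-by-run betas the GLM estimates for the
#' eight task conditions). Rows are ordered run-major, then by canonical
#' condition order; voxels follow mask scan order. Betas are not normalized
#' (the magnitude confound is reported, not removed; see
#' [normalize_patterns()] for the sensitivity flag).
#'
#' @param fit A [fit_glm()] object.
#' @param roi_mask Logical array (or integer vector of linear voxel
#'   indices) selecting the ROI.
#' @param conditions Conditions to extract (default the four of interest).
#' @param roi_name Optional ROI name carried in the result.
#' @return A `beta_pattern_set`: `x` (samples x voxels), `info` tibble
#'   (`row`, `run`, `condition`, `domain`, `search`), `voxels`, `roi_name`.
#' @export
extract_patterns <- function(fit, roi_mask,
                             conditions = conditions_of_interest(),
                             roi_name = NULL) {
  vox <- if (is.logical(roi_mask) || !is.null(dim(roi_mask))) {
    which(as.vector(roi_mask) > 0)
  } else {
    as.integer(roi_mask)
  }
  if (length(vox) == 0) stop_invalid("ROI mask is empty.")
  lab <- fit$labels
  runs <- sort(unique(lab$run[lab$type == "condition"]))
  want <- tidyr::expand_grid(run = runs, condition = conditions)
  have <- lab[lab$type == "condition", c("condition", "run")]
  missing <- dplyr::anti_join(want, have, by = c("condition", "run"))
  if (nrow(missing) > 0) {
    stop_invalid(paste0("missing (condition, run) betas: ",
                        paste(sprintf("%s/run%d", missing$condition,
                                      missing$run), collapse = ", "), "."))
  }
  cond_order <- condition_table()$condition
  want$condition <- factor(want$condition,
                           levels = cond_order[cond_order %in% conditions])
  want <- want[order(want$run, want$condition), ]
  want$condition <- as.character(want$condition)
  rows <- purrr::map2_int(want$condition, want$run, function(cond, r) {
    which(lab$type == "condition" & lab$condition == cond & lab$run == r)
  })
  x <- t(fit$coefficients[rows, , drop = FALSE])[vox, , drop = FALSE]
  x <- t(x)
  info <- dplyr::left_join(want,
                           condition_table()[, c("condition", "domain", "search")],
                           by = "condition")
  info$row <- seq_len(nrow(info))
  info <- info[, c("row", "run", "condition", "domain", "search")]
  structure(list(x = x, info = info, voxels = vox, roi_name = roi_name),
            class = "beta_pattern_set")
}

#' Split a pattern set by search type
#'
#' @param patterns A [extract_patterns()] set.
#' @param search `"separate"` or `"parallel"`.
#' @return A `beta_pattern_set` with the 8 samples of that search type
#'   (one verbal and one spatial per run).
#' @export
subset_patterns <- function(patterns, search = c("separate", "parallel")) {
  search <- match.arg(search)
  keep <- which(patterns$info$search == search)
  info <- patterns$info[keep, ]
  info$row <- seq_len(nrow(info))
  structure(list(x = patterns$x[keep, , drop = FALSE], info = info,
                 voxels = patterns$voxels, roi_name = patterns$roi_name,
                 search = search),
            class = "beta_pattern_set")
}

#' Mean-center each pattern across voxels (sensitivity flag)
#'
#' Removes each sample's mean beta, the normalization that would remove a
#' uniform magnitude confound. Off by default throughout the package.
#'
#' @param patterns A `beta_pattern_set`.
#' @return The set with row-centered `x`.
#' @export
normalize_patterns <- function(patterns) {
  patterns$x <- patterns$x - rowMeans(patterns$x)
  patterns
}

check_loro_input <- function(patterns) {
  info <- patterns$info
  tab <- table(info$run, info$domain)
  if (!all(tab == 1) || ncol(tab) != 2) {
    stop_invalid("leave-one-run-out decoding needs exactly one verbal and one spatial sample per run.")
  }
  invisible(sort(unique(info$run)))
}

# Linear SVM train/predict for one fold. Ties (decision value exactly 0)
# go to the lexicographically first class label; a message records it.
svm_fold <- function(xtr, ytr, xte) {
  lev <- sort(unique(as.character(ytr)))
  fit <- e1071::svm(xtr, factor(ytr, levels = lev), kernel = "linear",
                    cost = getOption("roimvpa.svm_cost", 1),
                    scale = FALSE, type = "C-classification")
  pr <- stats::predict(fit, xte, decision.values = TRUE)
  dv <- attr(pr, "decision.values")
  pred <- as.character(pr)
  tie <- abs(dv[, 1]) < 1e-12
  if (any(tie)) {
    inform(sprintf("%d tied decision value(s) broken toward '%s'.",
                   sum(tie), lev[1]), class = "roimvpa_tie")
    pred[tie] <- lev[1]
  }
  pred
}

#' Leave-one-run-out decoding for one subject
#'
#' Trains a linear maximum-margin (soft-margin SVM) classifier on the
#' domain labels of three runs' beta patterns (6 samples) and tests on the
#' held-out run's two patterns; rotates over the four runs and averages.
#'
#' @param patterns An 8-sample `beta_pattern_set` (one search type).
#' @param cost SVM regularization constant C (default 1).
#' @return A `loro_fit`: `fold_accuracies` (named by held-out run),
#'   `accuracy` (their mean), `n_voxels`.
#' @export
loro_decode <- function(patterns, cost = 1) {
  runs <- check_loro_input(patterns)
  info <- patterns$info
  old <- options(roimvpa.svm_cost = cost); on.exit(options(old))
  accs <- vapply(runs, function(r) {
    tr <- info$run != r
    if (length(unique(info$domain[tr])) < 2) {
      stop_invalid("a class is missing from the training folds.")
    }
    pred <- svm_fold(patterns$x[tr, , drop = FALSE], info$domain[tr],
                     patterns$x[!tr, , drop = FALSE])
    mean(pred == info$domain[!tr])
  }, numeric(1))
  structure(list(fold_accuracies = stats::setNames(accs, paste0("run", runs)),
                 accuracy = mean(accs), n_voxels = ncol(patterns$x)),
            class = "loro_fit")
}

#' Group decoding summary
#'
#' @param accuracies Numeric vector of per-subject accuracies, or a list of
#'   [loro_decode()] fits.
#' @return A `decoding_result`: `subjects` tibble (`subject`, `accuracy`),
#'   `mean`, `sem` (sd/sqrt(n)), `n`.
#' @export
group_decode <- function(accuracies) {
  if (is.list(accuracies) && !is.data.frame(accuracies)) {
    accuracies <- vapply(accuracies, function(a) {
      if (inherits(a, "loro_fit")) a$accuracy else as.numeric(a)
    }, numeric(1))
  }
  n <- length(accuracies)
  structure(list(subjects = tibble(subject = seq_len(n), accuracy = accuracies),
                 mean = mean(accuracies),
                 sem = if (n > 1) stats::sd(accuracies) / sqrt(n) else 0,
                 n = n),
            class = "decoding_result")
}

# Per-subject fold/flip table for the within-run permutation scheme.
# For a fold leaving out run r, the trained classifier depends only on
# which of the three training runs have their verbal/spatial pair swapped
# (8 configurations); swapping the test pair maps fold accuracy a -> 1 - a.
# Training each of the 4 x 8 configurations once therefore reproduces the
# LORO accuracy of all 16 within-run relabelings exactly.
fold_flip_table <- function(patterns, cost = 1) {
  runs <- check_loro_input(patterns)
  info <- patterns$info
  old <- options(roimvpa.svm_cost = cost); on.exit(options(old))
  tab <- matrix(NA_real_, nrow = length(runs), ncol = 8,
                dimnames = list(paste0("run", runs), NULL))
  for (ri in seq_along(runs)) {
    r <- runs[ri]
    tr_idx <- which(info$run != r)
    te_idx <- which(info$run == r)
    tr_runs <- sort(unique(info$run[tr_idx]))
    for (cfg in 0:7) {
      bits <- as.integer(intToBits(cfg))[1:3]
      y <- info$domain[tr_idx]
      for (b in which(bits == 1L)) {
        swap <- info$run[tr_idx] == tr_runs[b]
        y[swap] <- ifelse(y[swap] == "verbal", "spatial", "verbal")
      }
      pred <- svm_fold(patterns$x[tr_idx, , drop = FALSE], y,
                       patterns$x[te_idx, , drop = FALSE])
      tab[ri, cfg + 1] <- mean(pred == info$domain[te_idx])
    }
  }
  list(tab = tab, runs = runs)
}

# LORO accuracy for one subject under a given within-run flip vector,
# looked up from the fold/flip table.
flip_accuracy <- function(ft, flips) {
  runs <- ft$runs
  vapply(seq_along(runs), function(ri) {
    tr_flips <- flips[-ri]
    cfg <- sum(tr_flips * 2^(seq_along(tr_flips) - 1)) + 1
    a <- ft$tab[ri, cfg]
    if (flips[ri] == 1L) 1 - a else a
  }, numeric(1)) |> mean()
}

# Reference path: relabel the patterns and rerun loro_decode (used to
# validate the table lookup; identical by construction).
loro_decode_relabeled <- function(patterns, flips, cost = 1) {
  info <- patterns$info
  runs <- sort(unique(info$run))
  dom <- info$domain
  for (i in seq_along(runs)) {
    if (flips[i] == 1L) {
      swap <- info$run == runs[i]
      dom[swap] <- ifelse(dom[swap] == "verbal", "spatial", "verbal")
    }
  }
  relab <- patterns
  relab$info$domain <- dom
  # accuracy is still scored against the permuted labels
  loro_decode(relab, cost = cost)$accuracy
}

#' Permutation null distribution of group decoding accuracy
#'
#' For each of `n_perm` iterations, every subject's domain labels are
#' independently permuted within run (each run's verbal/spatial pair is
#' swapped or not, uniformly at random), the leave-one-run-out analysis is
#' rerun, and the group-mean accuracy is recorded. The critical value is
#' the empirical 95th percentile of the null, computed with "higher"
#' interpolation so the significance criterion is never anti-conservative.
#'
#' @param pattern_sets List (per subject) of 8-sample `beta_pattern_set`s.
#' @param n_perm Number of permutations (default 1000; a warning is issued
#'   below 100, where the percentile is unstable).
#' @param seed Integer seed.
#' @param cost SVM regularization constant.
#' @param alpha Significance level defining the critical percentile
#'   (default 0.05).
#' @return A `null_distribution`: `estimates` (length `n_perm` group
#'   means), `critical`, `n_perm`, `alpha`, `seed`.
#' @export
permutation_null <- function(pattern_sets, n_perm = 1000, seed = 1,
                             cost = 1, alpha = 0.05) {
  if (n_perm < 100) {
    warn("`n_perm` < 100: the 95th-percentile critical value is unstable.",
         class = "roimvpa_small_null")
  }
  tables <- purrr::map(pattern_sets, fold_flip_table, cost = cost)
  n_sub <- length(tables)
  estimates <- with_seed(derive_seed(seed, 606L), {
    vapply(seq_len(n_perm), function(i) {
      mean(vapply(tables, function(ft) {
        flips <- sample(0:1, length(ft$runs), replace = TRUE)
        flip_accuracy(ft, flips)
      }, numeric(1)))
    }, numeric(1))
  })
  structure(list(estimates = estimates,
                 critical = quantile_higher(estimates, 1 - alpha),
                 n_perm = n_perm, alpha = alpha, seed = seed, n = n_sub),
            class = "null_distribution")
}

#' Compare an observed group accuracy to a permutation null
#'
#' Significance requires the observed accuracy to be strictly greater than
#' the null's critical percentile.
#'
#' @param result A [group_decode()] result (or a single accuracy).
#' @param null A [permutation_null()] distribution.
#' @return Logical.
#' @export
is_significant <- function(result, null) {
  acc <- if (inherits(result, "decoding_result")) result$mean else result
  acc > null$critical
}

#' Cross-session decoding
#'
#' Trains on all eight samples of one session's search subset and tests on
#' all eight of the other session's; there are no folds. Both directions
#' are reported separately by calling this twice.
#'
#' @param patterns_s1,patterns_s2 Lists (per subject) of 8-sample
#'   `beta_pattern_set`s from sessions 1 and 2, same ROI and voxel order.
#' @param direction `"s1_to_s2"` (train on session 1) or `"s2_to_s1"`.
#' @param cost SVM regularization constant.
#' @return A `decoding_result` of per-subject transfer accuracies.
#' @export
cross_session_decode <- function(patterns_s1, patterns_s2,
                                 direction = c("s1_to_s2", "s2_to_s1"),
                                 cost = 1) {
  direction <- match.arg(direction)
  if (length(patterns_s1) != length(patterns_s2)) {
    stop_invalid("need the same subjects in both sessions.")
  }
  old <- options(roimvpa.svm_cost = cost); on.exit(options(old))
  accs <- purrr::map2_dbl(patterns_s1, patterns_s2, function(p1, p2) {
    if (ncol(p1$x) != ncol(p2$x)) {
      stop_invalid("voxel counts differ between sessions.")
    }
    tr <- if (direction == "s1_to_s2") p1 else p2
    te <- if (direction == "s1_to_s2") p2 else p1
    pred <- svm_fold(tr$x, tr$info$domain, te$x)
    mean(pred == te$info$domain)
  })
  out <- group_decode(accs)
  out$direction <- direction
  out
}

#' Decoding accuracy as a function of feature count
#'
#' For each subset size (default 10 to 100 voxels in steps of 10) draws
#' `n_draws` random voxel subsets without replacement, reruns the
#' leave-one-run-out analysis on each, averages draws within subject, then
#' averages across subjects. Sizes exceeding the ROI's voxel count are
#' skipped with a warning.
#'
#' @param pattern_sets List (per subject) of 8-sample `beta_pattern_set`s.
#' @param sizes Integer vector of subset sizes (default `seq(10, 100, 10)`).
#' @param n_draws Random draws per size (default 10).
#' @param seed Integer seed.
#' @param cost SVM regularization constant.
#' @return A `feature_curve`: `per_subject` tibble (`size`, `subject`,
#'   `accuracy`), `summary` tibble (`size`, `mean`, `sem`), `n_draws`,
#'   `sizes`.
#' @export
feature_curve <- function(pattern_sets, sizes = seq(10, 100, by = 10),
                          n_draws = 10, seed = 1, cost = 1) {
  n_vox <- ncol(pattern_sets[[1]]$x)
  usable <- sizes[sizes <= n_vox]
  if (length(usable) == 0) {
    stop_invalid(sprintf("all subset sizes exceed the ROI's %d voxels.", n_vox))
  }
  if (length(usable) < length(sizes)) {
    warn(sprintf("skipping subset size(s) %s: ROI has only %d voxels.",
                 paste(setdiff(sizes, usable), collapse = ", "), n_vox),
         class = "roimvpa_sizes_skipped")
  }
  per <- purrr::imap_dfr(pattern_sets, function(ps, subj) {
    purrr::map_dfr(usable, function(sz) {
      accs <- vapply(seq_len(n_draws), function(d) {
        vox <- with_seed(derive_seed(seed, as.integer(subj), sz, d),
                         sample.int(n_vox, sz))
        sub <- ps
        sub$x <- ps$x[, vox, drop = FALSE]
        loro_decode(sub, cost = cost)$accuracy
      }, numeric(1))
      tibble(size = sz, subject = as.integer(subj), accuracy = mean(accs))
    })
  })
  summ <- per |>
    dplyr::group_by(.data$size) |>
    dplyr::summarise(mean = mean(.data$accuracy),
                     sem = stats::sd(.data$accuracy) / sqrt(dplyr::n()),
                     .groups = "drop")
  structure(list(per_subject = per, summary = summ, n_draws = n_draws,
                 sizes = usable),
            class = "feature_curve")
}
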