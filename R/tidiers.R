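#' @importFrom generics tidy glance
#' @export
generics::tidy

#' @export
generics::glance

#' @method tidy decoding_result
#' @export
tidy.decoding_result <- function(x, ...) x$subjects

#' @method glance decoding_result
#' @export
glance.decoding_result <- function(x, ...) {
  tibble(mean = x$mean, sem = x$sem, n = x$n,
         search = x$search %||% NA_character_,
         direction = x$direction %||% NA_character_)
}

#' @method tidy loro_fit
#' @export
tidy.loro_fit <- function(x, ...) {
  tibble(fold = names(x$fold_accuracies),
         accuracy = unname(x$fold_accuracies))
}

#' @method glance loro_fit
#' @export
glance.loro_fit <- function(x, ...) {
  tibble(accuracy = x$accuracy, n_folds = length(x$fold_accuracies),
         n_voxels = x$n_voxels)
}

#' @method tidy null_distribution
#' @export
tidy.null_distribution <- function(x, ...) {
  tibble(permutation = seq_along(x$estimates), accuracy = x$estimates)
}

#' @method glance null_distribution
#' @export
glance.null_distribution <- function(x, ...) {
  tibble(n_perm = x$n_perm, critical = x$critical, alpha = x$alpha,
         mean = mean(x$estimates))
}

#' @method tidy feature_curve
#' @export
tidy.feature_curve <- function(x, ...) x$per_subject

#' @method glance feature_curve
#' @export
glance.feature_curve <- function(x, ...) {
  dplyr::mutate(x$summary, n_draws = x$n_draws)
}

#' @method tidy cluster_set
#' @export
tidy.cluster_set <- function(x, ...) x$clusters

#' @method tidy roi_set
#' @export
tidy.roi_set <- function(x, ...) x$rois

#' @method tidy confound_table
#' @export
tidy.confound_table <- function(x, ...) x$cells

#' @method glance confound_table
#' @export
glance.confound_table <- function(x, ...) x$differences

#' @method tidy rm_anova
#' @export
tidy.rm_anova <- function(x, ...) {
  as_tibble(x)[, c("effect", "df1", "df2", "statistic", "p.value")]
}

#' @method tidy stat_map
#' @export
tidy.stat_map <- function(x, ...) {
  v <- as.vector(x$t)
  if (!is.null(dim(x$t))) {
    co <- lin_to_coord(seq_along(v), dim(x$t))
    tibble(x = co[, 1], y = co[, 2], z = co[, 3], t = v,
           effect = as.vector(x$effect))
  } else {
    tibble(voxel = seq_along(v), t = v, effect = as.vector(x$effect))
  }
}

#' @method print decoding_result
#' @export
print.decoding_result <- function(x, ...) {
  cat(sprintf("<decoding_result> group accuracy %.1f%% ± %.1f%% SEM (n = %d)\n",
              100 * x$mean, 100 * x$sem, x$n))
  invisible(x)
}

#' @method print null_distribution
#' @export
print.null_distribution <- function(x, ...) {
  cat(sprintf("<null_distribution> %d permutations, mean %.1f%%, critical (%.0fth pct) %.1f%%\n",
              x$n_perm, 100 * mean(x$estimates), 100 * (1 - x$alpha),
              100 * x$critical))
  invisible(x)
}
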