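#' @importFrom ggplot2 autoplot ggplot aes geom_col geom_errorbar geom_hline
#'   geom_histogram geom_vline geom_line geom_point geom_ribbon labs
#'   facet_grid position_dodge theme_minimal scale_y_continuous
NULL

#' @export
ggplot2::autoplot

#' Plot a group decoding result
#'
#' Bar of the group-mean accuracy with an SEM error bar, the 50% chance
#' line, and (if supplied) the permutation critical value as a dashed line.
#'
#' @param object A [group_decode()] result.
#' @param null Optional [permutation_null()] distribution.
#' @param ... Unused.
#' @return A ggplot.
#' @method autoplot decoding_result
#' @export
autoplot.decoding_result <- function(object, null = NULL, ...) {
  d <- glance(object)
  d$label <- paste0(ifelse(is.na(d$search), "", d$search),
                    ifelse(is.na(d$direction), "", d$direction))
  p <- ggplot(d, aes(x = .data$label, y = .data$mean)) +
    geom_col(fill = "grey70", width = 0.6) +
    geom_errorbar(aes(ymin = .data$mean - .data$sem,
                      ymax = .data$mean + .data$sem), width = 0.15) +
    geom_hline(yintercept = 0.5) +
    scale_y_continuous(labels = function(x) sprintf("%.0f%%", 100 * x)) +
    labs(x = NULL, y = "classification accuracy") +
    theme_minimal()
  if (!is.null(null)) {
    p <- p + geom_hline(yintercept = null$critical, linetype = "dashed",
                        colour = "red")
  }
  p
}

#' Plot a permutation null distribution
#'
#' @param object A [permutation_null()] distribution.
#' @param observed Optional observed group accuracy to mark.
#' @param ... Unused.
#' @return A ggplot.
#' @method autoplot null_distribution
#' @export
autoplot.null_distribution <- function(object, observed = NULL, ...) {
  p <- ggplot(tidy(object), aes(x = .data$accuracy)) +
    geom_histogram(bins = 30, fill = "grey70", colour = "grey40") +
    geom_vline(xintercept = object$critical, linetype = "dashed",
               colour = "red") +
    labs(x = "permuted group accuracy", y = "count") +
    theme_minimal()
  if (!is.null(observed)) {
    p <- p + geom_vline(xintercept = observed, colour = "blue")
  }
  p
}

#' Plot a feature-count curve
#'
#' Group-mean decoding accuracy (±SEM ribbon) against the number of
#' randomly drawn voxels.
#'
#' @param object A [feature_curve()] result.
#' @param ... Unused.
#' @return A ggplot.
#' @method autoplot feature_curve
#' @export
autoplot.feature_curve <- function(object, ...) {
  s <- object$summary
  ggplot(s, aes(x = .data$size, y = .data$mean)) +
    geom_ribbon(aes(ymin = .data$mean - .data$sem,
                    ymax = .data$mean + .data$sem), fill = "grey85") +
    geom_line() + geom_point() +
    geom_hline(yintercept = 0.5) +
    scale_y_continuous(labels = function(x) sprintf("%.0f%%", 100 * x)) +
    labs(x = "voxels included", y = "classification accuracy") +
    theme_minimal()
}

#' Plot the beta-magnitude confound table
#'
#' Mean beta per condition of interest, one panel per ROI — the diagnostic
#' view in which a uniform verbal-spatial offset stands out.
#'
#' @param object A [mean_beta_table()] result.
#' @param ... Unused.
#' @return A ggplot.
#' @method autoplot confound_table
#' @export
autoplot.confound_table <- function(object, ...) {
  d <- object$cells
  ggplot(d, aes(x = .data$search, y = .data$mean, fill = .data$domain)) +
    geom_col(position = position_dodge(width = 0.8), width = 0.7) +
    geom_errorbar(aes(ymin = .data$mean - .data$sd,
                      ymax = .data$mean + .data$sd),
                  position = position_dodge(width = 0.8), width = 0.2) +
    facet_grid(cols = ggplot2::vars(.data$roi)) +
    labs(x = NULL, y = "mean beta") +
    theme_minimal()
}
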