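#' Verbal-minus-spatial differences from a cell-mean table
#'
#' Given per-(roi, domain, search) mean beta values, returns the absolute
#' verbal-minus-spatial difference per ROI and search type — the magnitude
#' diagnostic that flags regions whose decodability could come from a
#' uniform amplitude offset rather than pattern structure.
#'
#' @param cells Tibble with columns `roi`, `domain`, `search`, `mean`.
#' @return Tibble `roi`, `search`, `difference` (>= 0), with `is_max`
#'   marking the table-wide largest difference.
#' @export
#' @examples
#' cells <- tibble::tribble(
#'   ~roi, ~domain, ~search, ~mean,
#'   "L_IFG", "verbal", "separate", 0.25,
#'   "L_IFG", "spatial", "separate", 0.14)
#' beta_differences(cells)  # difference 0.11
beta_differences <- function(cells) {
  out <- cells |>
    dplyr::select(dplyr::all_of(c("roi", "domain", "search", "mean"))) |>
    tidyr::pivot_wider(names_from = "domain", values_from = "mean") |>
    dplyr::mutate(difference = abs(.data$verbal - .data$spatial)) |>
    dplyr::select(dplyr::all_of(c("roi", "search", "difference")))
  out$is_max <- out$difference == max(out$difference)
  out
}

#' Beta-magnitude confound table
#'
#' Mean beta value per ROI and condition of interest (averaged over voxels,
#' runs and subjects; SD across subjects), plus the absolute
#' verbal-minus-spatial mean-beta difference per search type.
#'
#' @param pattern_sets Named list (per ROI) of lists (per subject) of
#'   16-sample [extract_patterns()] sets.
#' @return A `confound_table`: `cells` tibble (`roi`, `condition`, `domain`,
#'   `search`, `mean`, `sd`) and `differences` from [beta_differences()].
#' @export
mean_beta_table <- function(pattern_sets) {
  if (is.null(names(pattern_sets))) {
    names(pattern_sets) <- paste0("roi", seq_along(pattern_sets))
  }
  cells <- purrr::imap_dfr(pattern_sets, function(subjects, roi) {
    per_subj <- purrr::imap_dfr(subjects, function(ps, subj) {
      if (nrow(ps$info) != 16) {
        stop_invalid(sprintf("ROI '%s': subject %s has an incomplete pattern set (%d of 16 samples).",
                             roi, subj, nrow(ps$info)))
      }
      ps$info |>
        dplyr::mutate(beta = rowMeans(ps$x), subject = as.character(subj)) |>
        dplyr::group_by(.data$condition, .data$domain, .data$search,
                        .data$subject) |>
        dplyr::summarise(beta = mean(.data$beta), .groups = "drop")
    })
    per_subj |>
      dplyr::group_by(.data$condition, .data$domain, .data$search) |>
      dplyr::summarise(mean = mean(.data$beta), sd = stats::sd(.data$beta),
                       .groups = "drop") |>
      dplyr::mutate(roi = roi)
  })
  cells <- cells[, c("roi", "condition", "domain", "search", "mean", "sd")]
  structure(list(cells = cells, differences = beta_differences(cells)),
            class = "confound_table")
}

#' Two-by-two repeated-measures ANOVA
#'
#' Within-subject ANOVA for a balanced 2 x 2 design (e.g. hemisphere by
#' session on decoding accuracies): each effect is tested against its own
#' subject-by-effect error stratum. With two-level factors no sphericity
#' correction is needed. Fitted with [stats::aov()] error strata.
#'
#' @param data Tibble in long form.
#' @param subject,factor_a,factor_b,value Column names (strings).
#' @return An `rm_anova`: tibble with `effect`, `df1`, `df2`, `sumsq`,
#'   `error_sumsq`, `statistic`, `p.value`; attribute `total_ss`.
#' @export
rm_anova_2x2 <- function(data, subject = "subject", factor_a = "hemisphere",
                         factor_b = "session", value = "accuracy") {
  d <- tibble(
    subject = factor(data[[subject]]),
    A = factor(data[[factor_a]]),
    B = factor(data[[factor_b]]),
    y = data[[value]]
  )
  if (nlevels(d$A) != 2 || nlevels(d$B) != 2) {
    stop_invalid("both factors must have exactly 2 levels.")
  }
  if (any(table(d$subject, d$A, d$B) != 1)) {
    stop_invalid("design must be complete and balanced: one observation per subject x cell.")
  }
  fit <- stats::aov(y ~ A * B + Error(subject / (A * B)), data = d)
  sm <- summary(fit)
  pull_stratum <- function(name, term) {
    tab <- sm[[paste0("Error: ", name)]][[1]]
    rn <- trimws(rownames(tab))
    i <- which(rn == term)
    j <- which(rn == "Residuals")
    list(df1 = tab[i, "Df"], df2 = tab[j, "Df"],
         sumsq = tab[i, "Sum Sq"], error_sumsq = tab[j, "Sum Sq"],
         statistic = tab[i, "F value"], p.value = tab[i, "Pr(>F)"])
  }
  rows <- list(
    c(list(effect = factor_a), pull_stratum("subject:A", "A")),
    c(list(effect = factor_b), pull_stratum("subject:B", "B")),
    c(list(effect = paste0(factor_a, ":", factor_b)),
      pull_stratum("subject:A:B", "A:B"))
  )
  out <- dplyr::bind_rows(lapply(rows, as_tibble))
  # degenerate 0/0 strata (no effect and no error variability, e.g. all
  # cells equal within every subject) are reported as F = 0, not noise
  tol <- 1e-12 * max(1, sum(d$y^2))
  zero <- out$sumsq < tol & out$error_sumsq < tol
  out$statistic[zero] <- 0
  out$p.value[zero] <- 1
  subj_tab <- sm[["Error: subject"]][[1]]
  total_ss <- sum(out$sumsq, out$error_sumsq, subj_tab[, "Sum Sq"])
  structure(out, class = c("rm_anova", class(tibble())),
            total_ss = total_ss, n_subjects = nlevels(d$subject))
}

#' Paired t-test
#'
#' Standard two-tailed paired t-test with df = n - 1. Zero-variance
#' differences are flagged degenerate rather than raising an error: equal
#' vectors give t = 0, p = 1; a constant nonzero difference gives a signed
#' infinite t with p = 0.
#'
#' @param x,y Paired numeric vectors (length >= 2).
#' @return A `ttest_result` tibble row: `estimate` (mean difference),
#'   `statistic`, `df`, `p.value`, `degenerate`.
#' @export
paired_t <- function(x, y) {
  if (length(x) != length(y) || length(x) < 2) {
    stop_invalid("`x` and `y` must be paired vectors of equal length >= 2.")
  }
  d <- x - y
  n <- length(d)
  if (stats::sd(d) == 0) {
    md <- mean(d)
    out <- tibble(estimate = md,
                  statistic = if (md == 0) 0 else sign(md) * Inf,
                  df = n - 1,
                  p.value = if (md == 0) 1 else 0,
                  degenerate = TRUE)
  } else {
    tt <- stats::t.test(x, y, paired = TRUE)
    out <- tibble(estimate = unname(tt$estimate),
                  statistic = unname(tt$statistic),
                  df = unname(tt$parameter),
                  p.value = tt$p.value,
                  degenerate = FALSE)
  }
  structure(out, class = c("ttest_result", class(tibble())))
}

#' Session-wise behavioral summary and paired test
#'
#' Collapses a [generate_behavior()] table to per-subject session means and
#' tests the session-1 vs session-2 difference with [paired_t()].
#'
#' @param behavior A `behavior_table`.
#' @return List: `session_means` tibble (`session`, `mean`), `test` a
#'   `ttest_result`.
#' @export
behavior_session_test <- function(behavior) {
  per <- behavior |>
    dplyr::group_by(.data$subject, .data$session) |>
    dplyr::summarise(exemplars = mean(.data$exemplars), .groups = "drop")
  wide <- tidyr::pivot_wider(per, names_from = "session",
                             values_from = "exemplars", names_prefix = "s")
  list(
    session_means = per |>
      dplyr::group_by(.data$session) |>
      dplyr::summarise(mean = mean(.data$exemplars), .groups = "drop"),
    test = paired_t(wide$s1, wide$s2)
  )
}
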