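#' Build a run-concatenated GLM design matrix
#'
#' One boxcar-convolved column per (condition, run) pair for the conditions
#' present in that run, zero outside the run's rows; optional six motion
#' regressors per run; one constant column per run. Runs are concatenated
#' in order.
#'
#' @param run_design Tibble of epochs for one subject/session: columns
#'   `run`, `condition`, `onset`, `duration` (onsets relative to run start).
#' @param tr Repetition time, seconds.
#' @param n_scans Integer vector of scans per run (in run order).
#' @param motion Optional list (per run) of scans x 6 motion-trace matrices.
#' @param hrf An [canonical_hrf()] kernel, or `NULL` to build one at the
#'   microtime resolution `tr / oversample`.
#' @param oversample Microtime oversampling factor (default 16).
#' @return A `design_matrix`: list with `matrix` (time x regressors),
#'   `labels` (tibble: `column`, `type`, `condition`, `run`), `frame_times`,
#'   `tr`, `n_scans`.
#' @export
build_design_matrix <- function(run_design, tr, n_scans, motion = NULL,
                                hrf = NULL, oversample = 16) {
  runs <- sort(unique(run_design$run))
  if (length(n_scans) != length(runs)) {
    stop_invalid("`n_scans` needs one value per run.")
  }
  if (is.null(hrf)) hrf <- canonical_hrf(tr / oversample)

  for (i in seq_along(runs)) {
    ep <- run_design[run_design$run == runs[i], ]
    over <- ep$onset + ep$duration > n_scans[i] * tr
    if (any(over)) {
      stop_invalid(sprintf(
        "epoch(s) %s of condition(s) %s extend beyond the end of run %d (%g s).",
        paste(which(over), collapse = ","),
        paste(unique(ep$condition[over]), collapse = ","),
        runs[i], n_scans[i] * tr))
    }
  }

  cond_order <- condition_table()$condition
  total <- sum(n_scans)
  offsets <- cumsum(c(0, n_scans[-length(n_scans)]))
  cols <- list(); labels <- list()

  for (i in seq_along(runs)) {
    ep <- run_design[run_design$run == runs[i], ]
    present <- cond_order[cond_order %in% unique(ep$condition)]
    for (cond in present) {
      e <- ep[ep$condition == cond, ]
      x <- numeric(total)
      x[offsets[i] + seq_len(n_scans[i])] <-
        convolved_regressor(e$onset, e$duration, tr, n_scans[i], hrf, oversample)
      cols <- c(cols, list(x))
      labels <- c(labels, list(tibble(type = "condition", condition = cond,
                                      run = runs[i])))
    }
  }
  if (!is.null(motion)) {
    for (i in seq_along(runs)) {
      m <- motion[[i]]
      if (nrow(m) != n_scans[i]) {
        stop_invalid(sprintf("motion trace for run %d has %d rows, expected %d.",
                             runs[i], nrow(m), n_scans[i]))
      }
      for (j in seq_len(ncol(m))) {
        x <- numeric(total)
        x[offsets[i] + seq_len(n_scans[i])] <- m[, j]
        cols <- c(cols, list(x))
        labels <- c(labels, list(tibble(type = "motion",
                                        condition = paste0("motion", j),
                                        run = runs[i])))
      }
    }
  }
  for (i in seq_along(runs)) {
    x <- numeric(total)
    x[offsets[i] + seq_len(n_scans[i])] <- 1
    cols <- c(cols, list(x))
    labels <- c(labels, list(tibble(type = "constant", condition = "constant",
                                    run = runs[i])))
  }

  X <- do.call(cbind, cols)
  lab <- dplyr::bind_rows(labels)
  lab$column <- seq_len(nrow(lab))
  lab <- lab[, c("column", "type", "condition", "run")]
  colnames(X) <- paste0(lab$condition, "_run", lab$run)
  structure(list(matrix = X, labels = lab,
                 frame_times = (seq_len(total) - 1) * tr,
                 tr = tr, n_scans = n_scans),
            class = "design_matrix")
}

#' Fit a per-voxel ordinary-least-squares GLM
#'
#' @param bold Time x voxels data matrix (runs concatenated in the same
#'   order as the design), or a list of voxels x time run matrices.
#' @param design A [build_design_matrix()] object.
#' @param grid Optional 3D grid dims carried through to maps.
#' @return A `glm_fit`: `coefficients` (regressors x voxels), `labels`,
#'   `sigma2` (residual variance per voxel, RSS / (n - rank)),
#'   `df_residual`, `rank`, `xtx_inv` (the (X'X)^- used for contrasts),
#'   `grid`.
#' @export
fit_glm <- function(bold, design, grid = NULL) {
  if (is.list(bold) && !is.matrix(bold)) {
    bold <- do.call(rbind, lapply(bold, t))
  }
  X <- design$matrix
  if (nrow(bold) != nrow(X)) {
    stop_invalid(sprintf("data has %d time points but the design has %d rows.",
                         nrow(bold), nrow(X)))
  }
  qrX <- qr(X)
  rank <- qrX$rank
  if (rank < ncol(X)) {
    warn(sprintf("design matrix is rank deficient (rank %d < %d columns); using the pseudoinverse.",
                 rank, ncol(X)),
         class = "roimvpa_rank_deficient")
    sv <- svd(X)
    pos <- sv$d > max(sv$d) * 1e-10
    pinv <- sv$v[, pos, drop = FALSE] %*%
      (t(sv$u[, pos, drop = FALSE]) / sv$d[pos])
    beta <- pinv %*% bold
    xtx_inv <- pinv %*% t(pinv)
  } else {
    beta <- qr.coef(qrX, bold)
    R <- qr.R(qrX)
    xtx_inv <- chol2inv(R[seq_len(rank), seq_len(rank), drop = FALSE])
  }
  fitted <- X %*% beta
  rss <- colSums((bold - fitted)^2)
  dfres <- nrow(X) - rank
  structure(list(coefficients = beta, labels = design$labels,
                 sigma2 = rss / dfres, df_residual = dfres, rank = rank,
                 xtx_inv = xtx_inv, grid = grid),
            class = "glm_fit")
}

# expand per-condition contrast weights over run-specific columns,
# dividing each condition's weight equally over the runs in which it occurs
expand_contrast <- function(labels, weights) {
  unknown <- setdiff(names(weights), labels$condition[labels$type == "condition"])
  if (length(unknown) > 0) {
    stop_invalid(sprintf("contrast names unknown to the design: %s.",
                         paste(unknown, collapse = ", ")))
  }
  cvec <- numeric(nrow(labels))
  for (cond in names(weights)) {
    idx <- which(labels$type == "condition" & labels$condition == cond)
    cvec[idx] <- weights[[cond]] / length(idx)
  }
  cvec
}

#' Localizer contrast weights
#'
#' The rule-discovery-versus-control localizer: each of the four discovery
#' conditions weighted +1, each of the two control conditions weighted -2.
#'
#' @return Named numeric contrast vector over condition labels.
#' @export
localizer_contrast <- function() {
  c(disc_verbal_separate = 1, disc_spatial_separate = 1,
    disc_verbal_parallel = 1, disc_spatial_parallel = 1,
    ctrl_verbal = -2, ctrl_spatial = -2)
}

#' Subject-level t-contrast map
#'
#' Computes `t = c'b / sqrt(s2 * c'(X'X)^- c)` per voxel, with per-condition
#' weights expanded uniformly over that condition's run-specific columns.
#'
#' @param fit A [fit_glm()] object.
#' @param weights Named numeric vector of per-condition contrast weights.
#' @return A `stat_map`: `t` and `effect` (`c'b`) vectors (3D arrays when
#'   the fit carries a grid), `df`, `contrast` (the expanded vector).
#' @export
contrast_t <- function(fit, weights) {
  cvec <- expand_contrast(fit$labels, weights)
  eff <- drop(crossprod(cvec, fit$coefficients))
  se2 <- drop(t(cvec) %*% fit$xtx_inv %*% cvec) * fit$sigma2
  tval <- ifelse(se2 > 0, eff / sqrt(se2), 0)
  shape <- function(v) if (!is.null(fit$grid)) array(v, fit$grid) else v
  structure(list(t = shape(tval), effect = shape(eff), df = fit$df_residual,
                 contrast = cvec),
            class = "stat_map")
}

#' Group-level one-sample t map
#'
#' Voxel-wise one-sample t across subjects on contrast-effect images
#' (random-effects inference on the localizer contrast), df = n - 1.
#' Voxels with zero between-subject variance but a nonzero mean are flagged
#' infinite (signed), not NaN.
#'
#' @param effects List of per-subject contrast-effect volumes (equal dims).
#' @return A `stat_map` with `t`, `effect` (group mean), `df`, `n`.
#' @export
group_map <- function(effects) {
  if (length(effects) < 2) stop_invalid("need at least 2 subjects.")
  dims <- lapply(effects, function(e) dim(e) %||% length(e))
  if (length(unique(vapply(dims, paste, "", collapse = "x"))) != 1) {
    stop_invalid("subject maps are on misaligned grids.")
  }
  Y <- vapply(effects, as.vector, numeric(length(as.vector(effects[[1]]))))
  n <- ncol(Y)
  m <- rowMeans(Y)
  s <- sqrt(rowSums((Y - m)^2) / (n - 1))
  tval <- ifelse(s > 0, m / (s / sqrt(n)),
                 ifelse(m == 0, 0, sign(m) * Inf))
  shape <- function(v) if (!is.null(dim(effects[[1]]))) array(v, dim(effects[[1]])) else v
  structure(list(t = shape(tval), effect = shape(m), df = n - 1, n = n),
            class = "stat_map")
}

`%||%` <- function(a, b) if (is.null(a)) b else a
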