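#' Noise model parameters
#'
#' @param sigma Gaussian noise SD in signal units (default 1).
#' @param ar1_rho Lag-1 temporal autocorrelation of the noise (default 0,
#'   i.i.d.).
#' @param drift_order Polynomial drift order per run (default 0, none).
#' @param drift_sd SD of random drift coefficients when `drift_order > 0`.
#' @param motion_walk_sd Per-step SD of the six simulated motion random
#'   walks (default 0.02).
#' @param motion_mix Coefficient mixing motion traces into the signal
#'   (default 0: traces are generated but do not contaminate the data;
#'   raise it to test motion-regressor efficacy).
#' @return A `noise_params` list.
#' @export
noise_params <- function(sigma = 1.0, ar1_rho = 0.0, drift_order = 0,
                         drift_sd = 0.5, motion_walk_sd = 0.02,
                         motion_mix = 0) {
  check_positive(sigma, "sigma")
  if (abs(ar1_rho) >= 1) stop_invalid("`ar1_rho` must satisfy |rho| < 1.")
  check_count(drift_order, "drift_order", min = 0)
  structure(list(sigma = sigma, ar1_rho = ar1_rho, drift_order = drift_order,
                 drift_sd = drift_sd, motion_walk_sd = motion_walk_sd,
                 motion_mix = motion_mix),
            class = "noise_params")
}

ar1_noise <- function(n_voxels, n_scans, sigma, rho) {
  e <- matrix(stats::rnorm(n_voxels * n_scans, 0, sigma), n_voxels, n_scans)
  if (rho != 0) {
    # innovations scaled so the marginal SD stays sigma
    e <- e * sqrt(1 - rho^2)
    e <- t(apply(e, 1, function(z) stats::filter(z, rho, method = "recursive")))
    e[, 1] <- e[, 1] / sqrt(1 - rho^2)
  }
  e
}

#' Simulate a BOLD dataset
#'
#' Forward model mirroring the GLM: each voxel's time course is the sum over
#' conditions of its ground-truth amplitude times the boxcar-convolved HRF,
#' plus optional polynomial drift, optional motion leakage, and Gaussian
#' (optionally AR(1)) noise. Deterministic given the seed; every
#' subject/session/run draws its own derived seed so any single run can be
#' regenerated in isolation.
#'
#' @param design An [generate_design()] tibble.
#' @param scene A [generate_scene()] object.
#' @param noise A [noise_params()] object.
#' @param hrf HRF kernel, or `NULL` for the canonical default.
#' @param seed Integer seed.
#' @param subjects Optional subset of subjects to simulate (default all);
#'   simulating one subject at a time keeps memory bounded at full grids.
#' @param n_scans Optional override of scans per run (a tibble like
#'   [design_n_scans()]); a run too short for its design is an error. By
#'   default run lengths cover the last epoch plus the haemodynamic tail.
#' @param oversample Microtime oversampling factor (default 16).
#' @return A `bold_dataset`: `data[[subj]][[sess]][[run]]` voxels x time
#'   matrices, `motion[[subj]][[sess]][[run]]` scans x 6 matrices,
#'   `n_scans` tibble, plus the generating `design`, `scene`, `noise`,
#'   `tr`, `seed`.
#' @export
simulate_bold <- function(design, scene, noise = noise_params(), hrf = NULL,
                          seed = 1, subjects = NULL, n_scans = NULL,
                          oversample = 16) {
  params <- attr(design, "params")
  tr <- params$tr
  if (is.null(hrf)) hrf <- canonical_hrf(tr / oversample)
  subjects <- subjects %||% sort(unique(design$subject))
  scans <- n_scans %||% design_n_scans(design, tr)
  nvox <- prod(scene$grid)

  data <- list(); motion <- list()
  for (subj in subjects) {
    skey <- as.character(subj)
    data[[skey]] <- list(); motion[[skey]] <- list()
    for (sess in sort(unique(design$session))) {
      amp <- scene_amplitudes(scene, sess)
      d_ss <- design[design$subject == subj & design$session == sess, ]
      runs <- sort(unique(d_ss$run))
      data[[skey]][[sess]] <- list(); motion[[skey]][[sess]] <- list()
      for (run in runs) {
        ep <- d_ss[d_ss$run == run, ]
        n_scan <- scans$n_scans[scans$subject == subj & scans$session == sess &
                                  scans$run == run]
        if (max(ep$onset + ep$duration) > n_scan * tr) {
          stop_invalid(sprintf("run %d is shorter than its design.", run))
        }
        present <- intersect(condition_table()$condition, unique(ep$condition))
        R <- vapply(present, function(cond) {
          e <- ep[ep$condition == cond, ]
          convolved_regressor(e$onset, e$duration, tr, n_scan, hrf, oversample)
        }, numeric(n_scan))
        signal <- amp[, present, drop = FALSE] %*% t(R)

        run_seed <- derive_seed(seed, subj, sess, run)
        y <- with_seed(run_seed, {
          mo <- apply(matrix(stats::rnorm(n_scan * 6, 0, noise$motion_walk_sd),
                             n_scan, 6), 2, cumsum)
          out <- signal + ar1_noise(nvox, n_scan, noise$sigma, noise$ar1_rho)
          if (noise$drift_order > 0) {
            tt <- seq(-1, 1, length.out = n_scan)
            P <- stats::poly(tt, noise$drift_order, raw = FALSE)
            cf <- matrix(stats::rnorm(nvox * noise$drift_order, 0, noise$drift_sd),
                         nvox, noise$drift_order)
            out <- out + cf %*% t(P) * sqrt(n_scan)
          }
          if (noise$motion_mix != 0) {
            W <- matrix(stats::rnorm(nvox * 6), nvox, 6)
            out <- out + noise$motion_mix * W %*% t(mo)
          }
          list(y = out, mo = mo)
        })
        data[[skey]][[sess]][[run]] <- y$y
        motion[[skey]][[sess]][[run]] <- y$mo
      }
    }
  }
  structure(list(data = data, motion = motion, n_scans = scans,
                 design = design, scene = scene, noise = noise, tr = tr,
                 seed = seed, subjects = subjects),
            class = "bold_dataset")
}

#' Fit the matched GLM for one subject and session
#'
#' Convenience wrapper: builds the design matrix for this subject/session
#' from the dataset's own design (condition regressors, six motion
#' regressors per run, run constants) and fits the per-voxel GLM on the
#' concatenated runs.
#'
#' @param dataset A [simulate_bold()] dataset.
#' @param subject,session Indices.
#' @param use_motion Include the motion regressors (default TRUE).
#' @param oversample Microtime oversampling factor (default 16).
#' @return A [fit_glm()] object carrying the scene grid.
#' @export
fit_subject_glm <- function(dataset, subject, session, use_motion = TRUE,
                            oversample = 16) {
  d_ss <- dataset$design[dataset$design$subject == subject &
                           dataset$design$session == session, ]
  runs <- sort(unique(d_ss$run))
  sc <- dataset$n_scans
  n_scans <- vapply(runs, function(r) {
    sc$n_scans[sc$subject == subject & sc$session == session & sc$run == r]
  }, integer(1))
  mo <- if (use_motion) dataset$motion[[as.character(subject)]][[session]] else NULL
  X <- build_design_matrix(d_ss, dataset$tr, n_scans, motion = mo,
                           oversample = oversample)
  fit_glm(dataset$data[[as.character(subject)]][[session]], X,
          grid = dataset$scene$grid)
}
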