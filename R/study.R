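#' Simulate an ROI-scale study and return beta patterns
#'
#' Convenience wrapper running the full forward-and-inverse path at the
#' scale of a single region: generates a design, plants a single region of
#' the requested role and size, simulates BOLD runs for every subject, fits
#' each subject's GLM (with motion regressors), and extracts the
#' 16-sample beta pattern sets. Used for calibration studies (chance level,
#' type-I error, power), where localization is not under test and the
#' planted mask is used directly.
#'
#' @param n_subjects Number of subjects (default 13).
#' @param n_sessions Sessions to simulate (default 1).
#' @param n_voxels ROI size in voxels (default 50).
#' @param sigma_pat Domain-pattern SD (default 0: no domain signal).
#' @param confound_delta Uniform verbal-spatial offset (default 0).
#' @param role Region role; derived from the effect sizes by default
#'   (pattern-carrier if `sigma_pat > 0`, magnitude-confound if
#'   `confound_delta != 0`, else localizer-only).
#' @param session_remap Redraw patterns per session (default TRUE).
#' @param mean_epoch_duration Epoch means per session (default 17 s, and
#'   10 s when two sessions are simulated).
#' @param noise A [noise_params()] object.
#' @param seed Integer seed.
#' @return List: `patterns[[subject]][[session]]` 16-sample
#'   `beta_pattern_set`s, plus `scene`, `design`, `seed`.
#' @export
simulate_roi_patterns <- function(n_subjects = 13, n_sessions = 1,
                                  n_voxels = 50, sigma_pat = 0,
                                  confound_delta = 0, role = NULL,
                                  session_remap = TRUE,
                                  mean_epoch_duration = NULL,
                                  noise = noise_params(), seed = 1) {
  if (is.null(role)) {
    role <- if (sigma_pat > 0) "pattern-carrier"
    else if (confound_delta != 0) "magnitude-confound"
    else "localizer-only"
  }
  if (is.null(mean_epoch_duration)) {
    mean_epoch_duration <- c(17, 10)[seq_len(n_sessions)]
  }
  params <- design_params(n_subjects = n_subjects, n_sessions = n_sessions,
                          mean_epoch_duration = mean_epoch_duration)
  design <- generate_design(params, seed = derive_seed(seed, 1L))
  # smallest grid holding the blob with a one-voxel margin
  side <- ceiling((n_voxels * 2)^(1 / 3)) + 2
  grid <- c(side, side, side)
  scene <- generate_scene(
    grid = grid,
    roi_specs = list(roi_spec("target", center = ceiling(grid / 2),
                              n_voxels = n_voxels, role = role)),
    effects = effect_params(sigma_pat = sigma_pat,
                            confound_delta = confound_delta,
                            session_remap = session_remap),
    n_sessions = n_sessions,
    seed = derive_seed(seed, 2L)
  )
  mask <- scene_mask(scene, "target")
  patterns <- purrr::map(seq_len(n_subjects), function(subj) {
    ds <- simulate_bold(design, scene, noise = noise,
                        seed = derive_seed(seed, 3L), subjects = subj)
    lapply(seq_len(n_sessions), function(sess) {
      fit <- fit_subject_glm(ds, subj, sess)
      extract_patterns(fit, mask, roi_name = "target")
    })
  })
  list(patterns = patterns, scene = scene, design = design, seed = seed)
}

#' Group LORO decoding for a simulated study
#'
#' @param study A [simulate_roi_patterns()] result.
#' @param search Search type to decode (default `"separate"`).
#' @param session Session (default 1).
#' @param cost SVM regularization constant.
#' @return A [group_decode()] result.
#' @export
decode_study <- function(study, search = "separate", session = 1, cost = 1) {
  subsets <- purrr::map(study$patterns, function(p) {
    subset_patterns(p[[session]], search)
  })
  res <- group_decode(purrr::map(subsets, loro_decode, cost = cost))
  res$search <- search
  res$session <- session
  res
}

#' Search-type pattern subsets for a simulated study
#'
#' @param study A [simulate_roi_patterns()] result.
#' @param search Search type.
#' @param session Session.
#' @return List (per subject) of 8-sample `beta_pattern_set`s.
#' @export
study_subsets <- function(study, search = "separate", session = 1) {
  purrr::map(study$patterns, function(p) subset_patterns(p[[session]], search))
}
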