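#' Specify a ground-truth region of interest
#'
#' Regions are compact voxel blobs placed in the simulation grid. A region
#' is either an ellipsoid (give `radii`) or a blob of an exact voxel count
#' (give `n_voxels`: the `n_voxels` grid voxels nearest the center, ties
#' broken lexicographically, giving deterministic shapes).
#'
#' @param name Region name.
#' @param center Integer voxel coordinate (length 3, 1-based).
#' @param radii Ellipsoid radii in voxels (length 3), or `NULL`.
#' @param n_voxels Exact region size in voxels, or `NULL`.
#' @param role One of `"localizer-only"` (responds to the task but carries
#'   no domain information), `"pattern-carrier"` (adds a multivoxel domain
#'   code), `"magnitude-confound"` (adds a uniform verbal-spatial amplitude
#'   offset with no pattern structure).
#' @return An `roi_spec` list.
#' @export
roi_spec <- function(name, center, radii = NULL, n_voxels = NULL,
                     role = c("localizer-only", "pattern-carrier",
                              "magnitude-confound")) {
  role <- match.arg(role)
  if (is.null(radii) == is.null(n_voxels)) {
    stop_invalid("give exactly one of `radii` or `n_voxels`.")
  }
  if (!is.null(radii)) check_positive(radii, "radii")
  if (!is.null(n_voxels)) check_count(n_voxels, "n_voxels")
  structure(list(name = name, center = as.integer(center), radii = radii,
                 n_voxels = n_voxels, role = role),
            class = "roi_spec")
}

#' Default ground-truth regions
#'
#' Six regions whose voxel counts mirror the cluster sizes a
#' rule-discovery-versus-control localizer typically yields
#' (463, 167, 102, 32, 27, 300 voxels): a left inferior-frontal analogue
#' carrying the domain pattern, a left orbital analogue carrying the
#' uniform magnitude confound, and four task-responsive regions with no
#' domain information.
#'
#' @param grid 3D grid dimensions.
#' @return List of [roi_spec()] objects.
#' @export
default_roi_specs <- function(grid = c(36, 36, 30)) {
  list(
    roi_spec("L_IFG", center = c(10, 24, 16), n_voxels = 463,
             role = "pattern-carrier"),
    roi_spec("R_IFG", center = c(27, 24, 16), n_voxels = 167,
             role = "localizer-only"),
    roi_spec("R_SFG", center = c(22, 28, 24), n_voxels = 102,
             role = "localizer-only"),
    roi_spec("L_OG", center = c(12, 12, 8), n_voxels = 32,
             role = "magnitude-confound"),
    roi_spec("R_OG", center = c(25, 12, 8), n_voxels = 27,
             role = "localizer-only"),
    roi_spec("L_Cer", center = c(13, 30, 6), n_voxels = 300,
             role = "localizer-only")
  )
}

#' Effect-size parameters for the ground truth
#'
#' @param amp_discovery,amp_confirmation,amp_control,amp_error Mean response
#'   amplitudes (signal units) of the four phases inside every region.
#'   Discovery exceeds control so the localizer contrast can find the
#'   regions.
#' @param gain_range Per-voxel multiplicative gain, drawn uniformly in this
#'   range, shared across conditions: response heterogeneity across voxels.
#' @param sigma_pat SD of the zero-mean voxel-wise domain-pattern offsets in
#'   pattern-carrier regions (default 0.5 signal units).
#' @param confound_delta Uniform verbal-minus-spatial amplitude offset added
#'   to discovery conditions in magnitude-confound regions (default 0.48).
#' @param session_remap If `TRUE` (default) domain patterns are drawn
#'   independently per session (the domain code remaps between sessions);
#'   if `FALSE` session 1's patterns are reused.
#' @return An `effect_params` list.
#' @export
effect_params <- function(amp_discovery = 1.0, amp_confirmation = 0.6,
                          amp_control = 0.2, amp_error = 0.3,
                          gain_range = c(0.5, 1.5),
                          sigma_pat = 0.5, confound_delta = 0.48,
                          session_remap = TRUE) {
  if (amp_discovery <= amp_control) {
    stop_invalid("`amp_discovery` must exceed `amp_control` so the localizer contrast is positive.")
  }
  if (sigma_pat < 0) stop_invalid("`sigma_pat` must be non-negative.")
  structure(list(amp_discovery = amp_discovery,
                 amp_confirmation = amp_confirmation,
                 amp_control = amp_control, amp_error = amp_error,
                 gain_range = gain_range, sigma_pat = sigma_pat,
                 confound_delta = confound_delta,
                 session_remap = session_remap),
            class = "effect_params")
}

roi_voxels <- function(spec, grid) {
  if (!is.null(spec$n_voxels)) {
    # n nearest voxels to the center, lexicographic tie-break
    idx <- seq_len(prod(grid))
    co <- lin_to_coord(idx, grid)
    d2 <- (co[, 1] - spec$center[1])^2 + (co[, 2] - spec$center[2])^2 +
      (co[, 3] - spec$center[3])^2
    ord <- order(d2, co[, 1], co[, 2], co[, 3])
    sort(idx[ord[seq_len(spec$n_voxels)]])
  } else {
    r <- spec$radii
    lo <- pmax(1, floor(spec$center - r))
    hi <- pmin(grid, ceiling(spec$center + r))
    if (any(spec$center - r < 0.5) || any(spec$center + r > grid + 0.5)) {
      stop_invalid(sprintf("region '%s' does not fit inside the grid.", spec$name))
    }
    co <- as.matrix(expand.grid(x = lo[1]:hi[1], y = lo[2]:hi[2], z = lo[3]:hi[3]))
    d <- ((co[, 1] - spec$center[1]) / r[1])^2 +
      ((co[, 2] - spec$center[2]) / r[2])^2 +
      ((co[, 3] - spec$center[3]) / r[3])^2
    sort(coord_to_lin(co[d <= 1, , drop = FALSE], grid))
  }
}

#' Generate a ground-truth scene
#'
#' Builds the voxel-level ground truth the simulator plants and the
#' analysis is later judged against: region masks, per-condition response
#' amplitudes with per-voxel gain, session-specific zero-mean domain
#' patterns in pattern-carrier regions, and a uniform verbal-spatial
#' magnitude offset in confound regions. Outside all regions every
#' condition's amplitude is zero.
#'
#' @param grid 3D grid dimensions (default `c(36, 36, 30)`).
#' @param roi_specs List of [roi_spec()]s (default [default_roi_specs()]).
#' @param effects An [effect_params()] object.
#' @param n_sessions Sessions to draw patterns for (default 2).
#' @param seed Integer seed.
#' @return A `ground_truth_scene` object: `grid`, `rois` (per region:
#'   `voxels` linear indices, `role`, `center`, `size`, `gain`), `effects`,
#'   `patterns[[roi]][[session]][[domain]]` and `seed`.
#' @export
generate_scene <- function(grid = c(36, 36, 30),
                           roi_specs = default_roi_specs(grid),
                           effects = effect_params(),
                           n_sessions = 2, seed = 1) {
  grid <- as.integer(grid)
  if (length(grid) != 3 || any(grid < 1)) stop_invalid("`grid` must be 3 positive dims.")
  vox <- lapply(roi_specs, roi_voxels, grid = grid)
  names(vox) <- vapply(roi_specs, `[[`, "", "name")
  all_vox <- unlist(vox)
  if (anyDuplicated(all_vox)) {
    stop_invalid("ROI specifications overlap; overlapping regions would confound the localizer.")
  }

  rois <- with_seed(derive_seed(seed, 303L), {
    purrr::imap(vox, function(v, nm) {
      spec <- roi_specs[[which(names(vox) == nm)]]
      list(name = nm, voxels = v, role = spec$role, center = spec$center,
           size = length(v),
           gain = stats::runif(length(v), effects$gain_range[1],
                               effects$gain_range[2]))
    })
  })

  patterns <- with_seed(derive_seed(seed, 404L), {
    purrr::map(rois, function(r) {
      if (r$role != "pattern-carrier") return(NULL)
      lapply(seq_len(n_sessions), function(sess) {
        if (sess > 1 && !effects$session_remap) {
          return(NULL)  # resolved to session 1 at lookup time
        }
        lapply(stats::setNames(nm = c("verbal", "spatial")), function(dom) {
          p <- stats::rnorm(r$size, 0, effects$sigma_pat)
          if (effects$sigma_pat > 0) p - mean(p) else p
        })
      })
    })
  })

  structure(list(grid = grid, rois = rois, effects = effects,
                 patterns = patterns, n_sessions = n_sessions, seed = seed),
            class = "ground_truth_scene")
}

phase_amplitude <- function(effects) {
  c(discovery = effects$amp_discovery, confirmation = effects$amp_confirmation,
    control = effects$amp_control, error = effects$amp_error)
}

roi_pattern <- function(scene, roi_name, session, domain) {
  p <- scene$patterns[[roi_name]]
  if (is.null(p)) return(NULL)
  sess <- if (session <= length(p) && !is.null(p[[session]])) session else 1L
  p[[sess]][[domain]]
}

#' Per-voxel condition amplitudes for one session
#'
#' @param scene A `ground_truth_scene`.
#' @param session Session number.
#' @return Matrix (voxels in full grid) x (9 conditions): the mean response
#'   amplitude each condition evokes at each voxel.
#' @export
scene_amplitudes <- function(scene, session) {
  conds <- condition_table()
  amp <- matrix(0, nrow = prod(scene$grid), ncol = nrow(conds),
                dimnames = list(NULL, conds$condition))
  base <- phase_amplitude(scene$effects)
  for (r in scene$rois) {
    a <- outer(r$gain, base[conds$phase])     # voxels x conditions
    if (r$role == "magnitude-confound") {
      verbal_disc <- conds$phase == "discovery" & conds$domain %in% "verbal"
      a[, verbal_disc] <- a[, verbal_disc] + scene$effects$confound_delta
    }
    if (r$role == "pattern-carrier") {
      for (ci in which(conds$of_interest)) {
        p <- roi_pattern(scene, r$name, session, conds$domain[ci])
        if (!is.null(p)) a[, ci] <- a[, ci] + p
      }
    }
    amp[r$voxels, ] <- a
  }
  amp
}

#' Binary mask for a scene region
#'
#' @param scene A `ground_truth_scene`.
#' @param name Region name.
#' @return Logical 3D array over the scene grid.
#' @export
scene_mask <- function(scene, name) {
  r <- scene$rois[[name]]
  if (is.null(r)) stop_invalid(sprintf("no region named '%s' in scene.", name))
  m <- array(FALSE, scene$grid)
  m[r$voxels] <- TRUE
  m
}

#' @export
print.ground_truth_scene <- function(x, ...) {
  cat(sprintf("<ground_truth_scene> grid %s, %d regions\n",
              paste(x$grid, collapse = "x"), length(x$rois)))
  for (r in x$rois) {
    cat(sprintf("  %-8s %-18s %4d voxels, center (%s)\n", r$name, r$role,
                r$size, paste(r$center, collapse = ",")))
  }
  invisible(x)
}
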