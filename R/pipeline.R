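#' Pipeline run configuration
#'
#' Collects every stage's parameters under one master seed. Stage toggles
#' switch off downstream analyses; the simulation and GLM always run.
#'
#' @param seed Master seed; every stochastic draw derives its own seed from
#'   it, so any stage is reproducible in isolation.
#' @param design A [design_params()] object.
#' @param scene_grid,roi_specs,effects Scene settings (see
#'   [generate_scene()]); `roi_specs = NULL` uses [default_roi_specs()].
#' @param noise A [noise_params()] object.
#' @param p_peak,cluster_alpha,n_perm_cluster,min_voxels,connectivity ROI
#'   localization settings.
#' @param cost,n_perm,alpha Decoding and permutation-test settings.
#' @param feature_sizes,feature_draws Feature-curve settings.
#' @param feature_rois ROI names for the feature curves (`NULL` = all).
#' @param anova_rois Two ROI names treated as the left/right pair for the
#'   hemisphere-by-session repeated-measures ANOVA (`NULL` = skip unless
#'   exactly two pattern-analogue ROIs are localized).
#' @param behavior A [behavior_params()] object, or `NULL` to reuse the
#'   design's subject count.
#' @param stages Named logical toggles: `localize`, `decode`, `permtest`,
#'   `cross_session`, `feature_curve`, `confound`, `anova`, `behavior`.
#' @param output_dir Directory for [render_report()] artifacts (`NULL` =
#'   in-memory only).
#' @return A `run_config` list (validated).
#' @export
run_config <- function(seed = 1,
                       design = design_params(),
                       scene_grid = c(36, 36, 30),
                       roi_specs = NULL,
                       effects = effect_params(),
                       noise = noise_params(),
                       p_peak = 0.001, cluster_alpha = 0.05,
                       n_perm_cluster = 200, min_voxels = 25,
                       connectivity = 18,
                       cost = 1, n_perm = 1000, alpha = 0.05,
                       feature_sizes = seq(10, 100, by = 10),
                       feature_draws = 10,
                       feature_rois = NULL,
                       anova_rois = NULL,
                       behavior = NULL,
                       stages = list(),
                       output_dir = NULL) {
  default_stages <- list(localize = TRUE, decode = TRUE, permtest = TRUE,
                         cross_session = TRUE, feature_curve = TRUE,
                         confound = TRUE, anova = TRUE, behavior = TRUE)
  stages <- utils::modifyList(default_stages, stages)
  cfg <- structure(
    list(seed = seed, design = design, scene_grid = scene_grid,
         roi_specs = roi_specs, effects = effects, noise = noise,
         p_peak = p_peak, cluster_alpha = cluster_alpha,
         n_perm_cluster = n_perm_cluster, min_voxels = min_voxels,
         connectivity = connectivity, cost = cost, n_perm = n_perm,
         alpha = alpha, feature_sizes = feature_sizes,
         feature_draws = feature_draws, feature_rois = feature_rois,
         anova_rois = anova_rois,
         behavior = behavior %||% behavior_params(design$n_subjects),
         stages = stages, output_dir = output_dir),
    class = "run_config")
  validate_run_config(cfg)
  cfg
}

validate_run_config <- function(cfg) {
  stopifnot(inherits(cfg$design, "design_params"),
            inherits(cfg$effects, "effect_params"),
            inherits(cfg$noise, "noise_params"))
  if (cfg$p_peak <= 0 || cfg$p_peak >= 1) stop_invalid("`p_peak` must be in (0,1).")
  if (cfg$alpha <= 0 || cfg$alpha >= 1) stop_invalid("`alpha` must be in (0,1).")
  check_count(cfg$n_perm, "n_perm")
  invisible(cfg)
}

#' Read / write a run configuration as YAML
#'
#' @param path YAML file path.
#' @return For `read_run_config()`, a validated `run_config`.
#' @export
read_run_config <- function(path) {
  y <- yaml::read_yaml(path)
  args <- list(
    seed = y$seed %||% 1,
    design = do.call(design_params, y$design %||% list()),
    effects = do.call(effect_params, y$effects %||% list()),
    noise = do.call(noise_params, y$noise %||% list()),
    behavior = if (!is.null(y$behavior)) do.call(behavior_params, y$behavior),
    stages = y$stages %||% list()
  )
  if (!is.null(y$scene_grid)) args$scene_grid <- unlist(y$scene_grid)
  if (!is.null(y$roi_specs)) {
    args$roi_specs <- purrr::map(y$roi_specs, function(s) {
      do.call(roi_spec, lapply(s, function(v) if (is.list(v)) unlist(v) else v))
    })
  }
  for (nm in c("p_peak", "cluster_alpha", "n_perm_cluster", "min_voxels",
               "connectivity", "cost", "n_perm", "alpha", "feature_draws",
               "output_dir")) {
    if (!is.null(y[[nm]])) args[[nm]] <- y[[nm]]
  }
  for (nm in c("feature_sizes", "feature_rois", "anova_rois")) {
    if (!is.null(y[[nm]])) args[[nm]] <- unlist(y[[nm]])
  }
  do.call(run_config, args)
}

#' @rdname read_run_config
#' @param cfg A `run_config`.
#' @export
write_run_config <- function(cfg, path) {
  y <- list(
    seed = cfg$seed,
    design = unclass(cfg$design),
    scene_grid = cfg$scene_grid,
    roi_specs = if (!is.null(cfg$roi_specs)) {
      purrr::map(cfg$roi_specs, function(s) {
        s <- unclass(s)
        s[!vapply(s, is.null, logical(1))]
      })
    },
    effects = unclass(cfg$effects),
    noise = unclass(cfg$noise),
    p_peak = cfg$p_peak, cluster_alpha = cfg$cluster_alpha,
    n_perm_cluster = cfg$n_perm_cluster, min_voxels = cfg$min_voxels,
    connectivity = cfg$connectivity, cost = cfg$cost, n_perm = cfg$n_perm,
    alpha = cfg$alpha, feature_sizes = cfg$feature_sizes,
    feature_draws = cfg$feature_draws, feature_rois = cfg$feature_rois,
    anova_rois = cfg$anova_rois,
    behavior = list(n_subjects = cfg$behavior$n_subjects,
                    subject_cv = cfg$behavior$subject_cv,
                    noise_cv = cfg$behavior$noise_cv),
    stages = cfg$stages,
    output_dir = cfg$output_dir
  )
  y <- y[!vapply(y, is.null, logical(1))]
  yaml::write_yaml(y, path)
  invisible(path)
}

run_stage <- function(name, code) {
  tryCatch(force(code), error = function(e) {
    abort(sprintf("pipeline stage '%s' failed: %s", name,
                  conditionMessage(e)),
          class = "roimvpa_stage_error", parent = e)
  })
}

#' Run the full simulate-model-localize-decode pipeline
#'
#' Executes the stages in dependency order: simulate BOLD data per subject,
#' fit subject GLMs for both sessions, localize ROIs from the session-1
#' group localizer contrast (peak p < `p_peak`, permutation cluster-extent
#' correction at `cluster_alpha`, minimum-extent filter), then — inside the
#' localized ROIs, reused for both sessions — leave-one-run-out decoding
#' with permutation nulls, cross-session transfer in both directions,
#' feature-count curves, the beta-magnitude confound table, the
#' hemisphere-by-session repeated-measures ANOVA, and the behavioral
#' summary. Re-running with the same config reproduces all numbers.
#'
#' @param config A [run_config()].
#' @return A `run_report` (see [render_report()]): tibbles `decoding`,
#'   `cross_session`, `rois`, `confound`, `anova`, `behavior`, lists
#'   `nulls`, `feature_curves`, and `provenance`.
#' @export
run_pipeline <- function(config = run_config()) {
  validate_run_config(config)
  seed <- config$seed
  n_sessions <- config$design$n_sessions

  design <- run_stage("design", generate_design(config$design,
                                                seed = derive_seed(seed, 11L)))
  scene <- run_stage("scene", generate_scene(
    grid = config$scene_grid,
    roi_specs = config$roi_specs %||% default_roi_specs(config$scene_grid),
    effects = config$effects, n_sessions = n_sessions,
    seed = derive_seed(seed, 12L)))

  # simulate + fit one subject at a time; keep only fits and localizer maps
  fits <- list(); localizer_effects <- list()
  run_stage("simulate/glm", {
    for (subj in seq_len(config$design$n_subjects)) {
      ds <- simulate_bold(design, scene, noise = config$noise,
                          seed = derive_seed(seed, 13L), subjects = subj)
      fits[[subj]] <- lapply(seq_len(n_sessions), function(sess) {
        fit_subject_glm(ds, subj, sess)
      })
      cmap <- contrast_t(fits[[subj]][[1]], localizer_contrast())
      localizer_effects[[subj]] <- cmap$effect
    }
  })

  report <- list(provenance = list(seed = seed,
                                   package_version = as.character(utils::packageVersion("roimvpa")),
                                   config = config))
  report$scene <- scene$rois |> purrr::map_dfr(function(r) {
    tibble(name = r$name, role = r$role, size = r$size)
  })

  roiset <- NULL
  if (config$stages$localize) {
    roiset <- run_stage("localize", {
      gm <- group_map(localizer_effects)
      ext <- cluster_extent_threshold(localizer_effects,
                                      p_peak = config$p_peak,
                                      alpha = config$cluster_alpha,
                                      n_perm = config$n_perm_cluster,
                                      seed = derive_seed(seed, 14L),
                                      connectivity = config$connectivity)
      bm <- threshold_peaks(gm, config$p_peak)
      cl <- label_clusters(bm, config$connectivity, stat = gm$t)
      select_rois(cl, ext$threshold, config$min_voxels)
    })
    report$rois <- roiset$rois
    report$roi_match <- match_rois(roiset, scene)
    # carry planted names where the overlap is decisive
    good <- report$roi_match$jaccard >= 0.25
    nm <- ifelse(good, report$roi_match$scene_roi, report$roi_match$roi)
    nm[duplicated(nm)] <- report$roi_match$roi[duplicated(nm)]
    names(roiset$masks) <- nm
    report$rois$name <- nm
  } else {
    report$rois <- tibble(name = character(), size = integer())
  }

  searches <- c("separate", "parallel")
  if (config$stages$decode && !is.null(roiset) && length(roiset$masks) > 0) {
    pat <- run_stage("patterns", {
      purrr::map(roiset$masks, function(mask) {
        purrr::map(fits, function(fsub) {
          lapply(fsub, extract_patterns, roi_mask = mask)
        })
      })
    })
    decode_tbl <- list(); nulls <- list(); accs_store <- list()
    run_stage("decode", {
      for (roi in names(pat)) {
        for (sess in seq_len(n_sessions)) {
          for (srch in searches) {
            subsets <- purrr::map(pat[[roi]], function(p) {
              subset_patterns(p[[sess]], srch)
            })
            res <- group_decode(purrr::map(subsets, loro_decode,
                                           cost = config$cost))
            key <- paste(roi, sess, srch, sep = "|")
            accs_store[[key]] <- res$subjects$accuracy
            row <- tibble(roi = roi, session = sess, search = srch,
                          accuracy = res$mean, sem = res$sem, n = res$n)
            if (config$stages$permtest) {
              nl <- permutation_null(subsets, n_perm = config$n_perm,
                                     seed = derive_seed(seed, 15L, sess,
                                                        match(srch, searches),
                                                        match(roi, names(pat))),
                                     cost = config$cost, alpha = config$alpha)
              nulls[[key]] <- nl
              row$critical <- nl$critical
              row$significant <- is_significant(res, nl)
            }
            decode_tbl[[key]] <- row
          }
        }
      }
    })
    report$decoding <- dplyr::bind_rows(decode_tbl)
    report$nulls <- nulls

    if (config$stages$cross_session && n_sessions >= 2) {
      report$cross_session <- run_stage("cross_session", {
        purrr::map_dfr(names(pat), function(roi) {
          purrr::map_dfr(searches, function(srch) {
            p1 <- purrr::map(pat[[roi]], function(p) subset_patterns(p[[1]], srch))
            p2 <- purrr::map(pat[[roi]], function(p) subset_patterns(p[[2]], srch))
            purrr::map_dfr(c("s1_to_s2", "s2_to_s1"), function(dirn) {
              r <- cross_session_decode(p1, p2, dirn, cost = config$cost)
              tibble(roi = roi, search = srch, direction = dirn,
                     accuracy = r$mean, sem = r$sem, n = r$n)
            })
          })
        })
      })
    }

    if (config$stages$feature_curve) {
      report$feature_curves <- run_stage("feature_curve", {
        rois_fc <- config$feature_rois %||% names(pat)
        rois_fc <- intersect(rois_fc, names(pat))
        out <- list()
        for (roi in rois_fc) {
          for (srch in searches) {
            subsets <- purrr::map(pat[[roi]], function(p) {
              subset_patterns(p[[1]], srch)
            })
            if (ncol(subsets[[1]]$x) < min(config$feature_sizes)) next
            out[[paste(roi, srch, sep = "|")]] <-
              feature_curve(subsets, sizes = config$feature_sizes,
                            n_draws = config$feature_draws,
                            seed = derive_seed(seed, 16L,
                                               match(roi, names(pat)),
                                               match(srch, searches)),
                            cost = config$cost)
          }
        }
        out
      })
    }

    if (config$stages$confound) {
      report$confound <- run_stage("confound", {
        mean_beta_table(purrr::map(pat, function(roi_pat) {
          purrr::map(roi_pat, function(p) p[[1]])
        }))
      })
    }

    if (config$stages$anova) {
      report$anova <- run_stage("anova", {
        pair <- config$anova_rois %||% intersect(c("L_IFG", "R_IFG"),
                                                 names(pat))
        if (length(pair) != 2 || n_sessions < 2) {
          NULL
        } else {
          purrr::map(stats::setNames(nm = searches), function(srch) {
            long <- purrr::map_dfr(pair, function(roi) {
              purrr::map_dfr(1:2, function(sess) {
                key <- paste(roi, sess, srch, sep = "|")
                tibble(subject = seq_along(accs_store[[key]]),
                       hemisphere = roi, session = paste0("s", sess),
                       accuracy = accs_store[[key]])
              })
            })
            rm_anova_2x2(long)
          })
        }
      })
    }
  }

  if (config$stages$behavior) {
    report$behavior <- run_stage("behavior", {
      b <- generate_behavior(config$behavior, seed = derive_seed(seed, 17L))
      behavior_session_test(b)
    })
  }

  structure(report, class = "run_report")
}

#' Render a run report to disk
#'
#' Writes TSV tables (a decoding table with one row per ROI and one
#' accuracy column per session-by-search cell, cross-session and
#' feature-curve tables, the confound table, the ROI report), the null
#' distributions as JSON, and a plain-text summary. Re-rendering the same
#' report writes byte-identical files.
#'
#' @param report A [run_pipeline()] result.
#' @param dir Output directory.
#' @return Invisibly, the files written.
#' @export
render_report <- function(report, dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  files <- character(0)
  put <- function(name, x) {
    p <- file.path(dir, name)
    readr::write_tsv(x, p)
    files <<- c(files, p)
  }
  summary_lines <- character(0)
  if (!is.null(report$decoding) && nrow(report$decoding) > 0) {
    wide <- report$decoding |>
      dplyr::mutate(cell = paste0("s", .data$session, "_", .data$search),
                    value = sprintf("%.2f±%.2f", 100 * .data$accuracy,
                                    100 * .data$sem)) |>
      dplyr::select(dplyr::all_of(c("roi", "cell", "value"))) |>
      tidyr::pivot_wider(names_from = "cell", values_from = "value")
    put("decoding_wide.tsv", wide)
    put("decoding.tsv", report$decoding)
    summary_lines <- c(summary_lines, "Decoding accuracy vs critical value:",
                       purrr::pmap_chr(report$decoding, function(...) {
                         r <- list(...)
                         sprintf("  %s s%d %s: %.1f%% (critical %s)%s",
                                 r$roi, r$session, r$search, 100 * r$accuracy,
                                 if (!is.null(r$critical)) sprintf("%.1f%%", 100 * r$critical) else "-",
                                 if (isTRUE(r$significant)) " *" else "")
                       }))
  } else {
    summary_lines <- c(summary_lines,
                       "No ROIs survived localization; decoding not run.")
  }
  if (!is.null(report$rois)) put("rois.tsv", report$rois)
  if (!is.null(report$cross_session)) put("cross_session.tsv", report$cross_session)
  if (!is.null(report$confound)) {
    put("confound_cells.tsv", report$confound$cells)
    put("confound_differences.tsv", report$confound$differences)
  }
  if (!is.null(report$feature_curves) && length(report$feature_curves) > 0) {
    fc <- purrr::imap_dfr(report$feature_curves, function(f, key) {
      dplyr::mutate(f$summary,
                    roi = sub("\\|.*$", "", key),
                    search = sub("^.*\\|", "", key), .before = 1)
    })
    put("feature_curves.tsv", fc)
  }
  if (!is.null(report$nulls) && length(report$nulls) > 0) {
    p <- file.path(dir, "null_distributions.json")
    jsonlite::write_json(
      purrr::map(report$nulls, function(n) {
        list(critical = n$critical, n_perm = n$n_perm, alpha = n$alpha,
             seed = n$seed, estimates = n$estimates)
      }),
      p, auto_unbox = TRUE, digits = NA)
    files <- c(files, p)
  }
  if (!is.null(report$anova)) {
    p <- file.path(dir, "anova.json")
    jsonlite::write_json(purrr::map(report$anova, function(a) {
      as.list(as_tibble(a))
    }), p, auto_unbox = TRUE, digits = NA)
    files <- c(files, p)
  }
  if (!is.null(report$behavior)) {
    put("behavior_session_means.tsv", report$behavior$session_means)
    put("behavior_test.tsv", as_tibble(report$behavior$test))
  }
  writeLines(summary_lines, file.path(dir, "summary.txt"))
  files <- c(files, file.path(dir, "summary.txt"))
  invisible(files)
}

#' @export
print.run_report <- function(x, ...) {
  cat("<run_report>\n")
  if (!is.null(x$rois)) {
    cat(sprintf("  %d ROI(s) localized\n", nrow(x$rois)))
  }
  if (!is.null(x$decoding)) {
    cat(sprintf("  decoding: %d ROI x session x search cells\n",
                nrow(x$decoding)))
  }
  invisible(x)
}
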