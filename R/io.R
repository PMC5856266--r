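#' Write a simulated dataset to a BIDS-style file tree
#'
#' One NIfTI-1 volume (double precision, so read-back is bit-exact) and one
#' events TSV (`onset`, `duration`, `trial_type`; seconds, onsets relative
#' to run start) per run, motion traces as TSV, and a JSON sidecar holding
#' the ground-truth scene and seeds.
#'
#' @param dataset A [simulate_bold()] dataset.
#' @param dir Output directory (created if needed).
#' @return Invisibly, a character vector of the files written.
#' @export
write_dataset <- function(dataset, dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  if (file.access(dir, 2) != 0) {
    abort(sprintf("directory '%s' is not writable.", dir),
          class = "roimvpa_io_error")
  }
  written <- character(0)
  wr <- function(path, fun) {
    tryCatch(fun(path), error = function(e) {
      abort(sprintf("failed writing '%s': %s", path, conditionMessage(e)),
            class = "roimvpa_io_error")
    })
    written <<- c(written, path)
  }
  for (subj in dataset$subjects) {
    skey <- as.character(subj)
    for (sess in seq_along(dataset$data[[skey]])) {
      base <- file.path(dir, sprintf("sub-%02d", subj), sprintf("ses-%d", sess))
      dir.create(base, recursive = TRUE, showWarnings = FALSE)
      for (run in seq_along(dataset$data[[skey]][[sess]])) {
        y <- dataset$data[[skey]][[sess]][[run]]
        vol <- array(y, c(dataset$scene$grid, ncol(y)))
        stem <- file.path(base, sprintf("run-%d", run))
        wr(paste0(stem, "_bold.nii.gz"), function(p) {
          RNifti::writeNifti(RNifti::asNifti(vol, datatype = "double"), p,
                             datatype = "double")
        })
        ep <- dataset$design[dataset$design$subject == subj &
                               dataset$design$session == sess &
                               dataset$design$run == run, ]
        wr(paste0(stem, "_events.tsv"), function(p) {
          readr::write_tsv(tibble(onset = ep$onset, duration = ep$duration,
                                  trial_type = ep$condition), p)
        })
        mo <- dataset$motion[[skey]][[sess]][[run]]
        colnames(mo) <- paste0("motion", 1:6)
        wr(paste0(stem, "_motion.tsv"), function(p) {
          readr::write_tsv(as_tibble(mo), p)
        })
      }
    }
  }
  scene <- dataset$scene
  sidecar <- list(
    seed = dataset$seed, tr = dataset$tr, grid = scene$grid,
    scene_seed = scene$seed,
    effects = unclass(scene$effects),
    rois = purrr::map(scene$rois, function(r) {
      r[c("name", "voxels", "role", "center", "size", "gain")]
    }),
    patterns = scene$patterns,
    noise = unclass(dataset$noise)
  )
  wr(file.path(dir, "ground_truth.json"), function(p) {
    jsonlite::write_json(sidecar, p, auto_unbox = TRUE, digits = NA,
                         null = "null", pretty = TRUE)
  })
  invisible(written)
}

#' Read back a written dataset
#'
#' @param dir Directory produced by [write_dataset()].
#' @return List: `data[[subject]][[session]][[run]]` voxels x time matrices,
#'   `events` tibble (`subject`, `session`, `run`, `onset`, `duration`,
#'   `trial_type`), `motion`, `ground_truth` (parsed sidecar).
#' @export
read_dataset <- function(dir) {
  gt_path <- file.path(dir, "ground_truth.json")
  if (!file.exists(gt_path)) {
    abort(sprintf("'%s' does not look like a dataset directory (no ground_truth.json).",
                  dir), class = "roimvpa_io_error")
  }
  gt <- jsonlite::read_json(gt_path, simplifyVector = TRUE)
  data <- list(); motion <- list(); events <- list()
  for (sdir in sort(list.dirs(dir, recursive = FALSE))) {
    subj <- sub("^sub-0*", "", basename(sdir))
    if (!grepl("^sub-", basename(sdir))) next
    data[[subj]] <- list(); motion[[subj]] <- list()
    for (ses_dir in sort(list.dirs(sdir, recursive = FALSE))) {
      sess <- as.integer(sub("^ses-", "", basename(ses_dir)))
      runs <- sort(list.files(ses_dir, pattern = "_bold\\.nii\\.gz$"))
      data[[subj]][[sess]] <- list(); motion[[subj]][[sess]] <- list()
      for (f in runs) {
        run <- as.integer(sub("^run-(\\d+)_.*$", "\\1", f))
        img <- RNifti::readNifti(file.path(ses_dir, f))
        vol <- array(as.numeric(img), dim(img))
        data[[subj]][[sess]][[run]] <- matrix(vol, ncol = dim(img)[4])
        ev <- readr::read_tsv(file.path(ses_dir, sprintf("run-%d_events.tsv", run)),
                              show_col_types = FALSE)
        events[[length(events) + 1]] <- dplyr::mutate(
          ev, subject = as.integer(subj), session = sess, run = run,
          .before = 1)
        motion[[subj]][[sess]][[run]] <- as.matrix(
          readr::read_tsv(file.path(ses_dir, sprintf("run-%d_motion.tsv", run)),
                          show_col_types = FALSE))
      }
    }
  }
  list(data = data, events = dplyr::bind_rows(events), motion = motion,
       ground_truth = gt)
}

#' Write a 3D map or mask as NIfTI-1
#'
#' @param x 3D numeric/logical array.
#' @param path Output path (`.nii` or `.nii.gz`).
#' @return `path`, invisibly.
#' @export
write_map <- function(x, path) {
  RNifti::writeNifti(RNifti::asNifti(array(as.numeric(x), dim(x)),
                                     datatype = "double"),
                     path, datatype = "double")
  invisible(path)
}
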