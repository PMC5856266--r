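# Shared fixtures, built in code at test time.

# A synthetic 8-sample beta_pattern_set (one search type), bypassing the
# simulation: class mean difference `delta` (vector or scalar) plus iid
# Gaussian noise.
make_patterns <- function(n_vox = 20, delta = 0, noise_sd = 1, seed = 1,
                          search = "separate", n_runs = 4) {
  set.seed(seed)
  domains <- rep(c("verbal", "spatial"), n_runs)
  runs <- rep(seq_len(n_runs), each = 2)
  mu <- matrix(0, length(domains), n_vox)
  if (length(delta) == 1) delta <- rep(delta, n_vox)
  mu[domains == "verbal", ] <- matrix(delta, sum(domains == "verbal"),
                                      n_vox, byrow = TRUE)
  x <- mu + matrix(rnorm(length(domains) * n_vox, 0, noise_sd),
                   length(domains), n_vox)
  info <- tibble::tibble(
    row = seq_along(domains), run = runs,
    condition = paste0("disc_", domains, "_", search),
    domain = domains, search = search)
  structure(list(x = x, info = info, voxels = seq_len(n_vox),
                 roi_name = "synthetic", search = search),
            class = "beta_pattern_set")
}

# Small single-subject dataset + fitted GLM, reused by several files.
tiny_fit <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      p <- design_params(n_subjects = 1, n_sessions = 1,
                         mean_epoch_duration = 8)
      d <- generate_design(p, seed = 11)
      sc <- generate_scene(
        grid = c(5, 5, 3),
        roi_specs = list(roi_spec("t", c(3, 3, 2), n_voxels = 10,
                                  role = "pattern-carrier")),
        effects = effect_params(sigma_pat = 0.5),
        n_sessions = 1, seed = 12)
      ds <- simulate_bold(d, sc, seed = 13)
      cache <<- list(design = d, scene = sc, dataset = ds,
                     fit = fit_subject_glm(ds, 1, 1))
    }
    cache
  }
})

# Independent connected-components oracle built on igraph: voxels are graph
# nodes, edges join suprathreshold voxels within the chosen neighbourhood.
flood_fill_oracle <- function(binary_map, connectivity) {
  grid <- dim(binary_map)
  vox <- which(as.vector(binary_map) > 0)
  if (length(vox) == 0) return(integer(0))
  co <- cbind((vox - 1) %% grid[1] + 1,
              ((vox - 1) %/% grid[1]) %% grid[2] + 1,
              (vox - 1) %/% (grid[1] * grid[2]) + 1)
  edges <- c()
  if (length(vox) > 1) {
    for (i in seq_along(vox)) {
      dx <- abs(co[, 1] - co[i, 1]); dy <- abs(co[, 2] - co[i, 2])
      dz <- abs(co[, 3] - co[i, 3])
      adj <- pmax(dx, dy, dz) == 1 &
        switch(as.character(connectivity),
               "6" = dx + dy + dz == 1,
               "18" = dx + dy + dz <= 2,
               "26" = TRUE)
      for (j in which(adj)) if (j > i) edges <- c(edges, i, j)
    }
  }
  g <- igraph::make_empty_graph(n = length(vox), directed = FALSE)
  if (length(edges) > 0) g <- igraph::add_edges(g, edges)
  membership <- igraph::components(g)$membership
  # return the partition as a canonical list of sorted voxel sets
  unname(lapply(split(vox, membership), sort))
}

# Canonical partition from a label volume, for comparison with the oracle.
partition_from_labels <- function(labels) {
  vox <- which(as.vector(labels) > 0)
  unname(lapply(split(vox, as.vector(labels)[vox]), sort))
}

same_partition <- function(a, b) {
  key <- function(p) sort(vapply(p, function(v) paste(v, collapse = ","), ""))
  identical(key(a), key(b))
}
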