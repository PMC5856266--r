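# Internal helpers shared across modules.

#' @importFrom rlang abort warn inform .data
#' @importFrom tibble tibble as_tibble
NULL

# Deterministic child-seed derivation: fold integer keys into the master seed
# with a large prime multiplier, staying below 2^31 so set.seed() accepts it.
# Documented contract: derive_seed(s, k1, k2, ...) is reproducible in
# isolation, so any single subject / permutation / draw can be regenerated
# without running the surrounding loop.
derive_seed <- function(seed, ...) {
  keys <- c(...)
  m <- 2147483629
  s <- as.double(seed %% m)
  for (k in keys) {
    s <- (s * 48271 + as.double(k) + 1) %% m
  }
  as.integer(s)
}

# Evaluate `code` under set.seed(seed) without disturbing the caller's RNG
# stream.
with_seed <- function(seed, code) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) {
      assign(".Random.seed", old, envir = globalenv())
    } else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  }, add = TRUE)
  set.seed(seed)
  force(code)
}

stop_invalid <- function(msg, ...) {
  abort(msg, class = "roimvpa_invalid_parameter", ...)
}

check_count <- function(x, name, min = 1) {
  if (length(x) != 1 || !is.numeric(x) || is.na(x) || x < min || x != round(x)) {
    stop_invalid(sprintf("`%s` must be a single integer >= %d (got %s).",
                         name, min, paste(format(x), collapse = ",")))
  }
  invisible(as.integer(x))
}

check_positive <- function(x, name) {
  if (any(!is.finite(x)) || any(x <= 0)) {
    stop_invalid(sprintf("`%s` must be strictly positive.", name))
  }
  invisible(x)
}

# 95th-percentile style empirical quantile with "higher" interpolation
# (ceil of the zero-based rank q*(n-1)), so critical values err on the
# conservative side.
quantile_higher <- function(x, prob) {
  xs <- sort(x)
  n <- length(xs)
  idx <- min(n, ceiling(prob * (n - 1)) + 1)
  xs[[idx]]
}

# linear index <-> (i,j,k) for a 3D grid
lin_to_coord <- function(idx, grid) {
  idx0 <- idx - 1L
  i <- idx0 %% grid[1]
  j <- (idx0 %/% grid[1]) %% grid[2]
  k <- idx0 %/% (grid[1] * grid[2])
  cbind(x = i + 1L, y = j + 1L, z = k + 1L)
}

coord_to_lin <- function(coord, grid) {
  (coord[, 3] - 1L) * grid[1] * grid[2] + (coord[, 2] - 1L) * grid[1] + coord[, 1]
}
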