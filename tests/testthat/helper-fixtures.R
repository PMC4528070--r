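# Shared fixtures, all built in code.

# A 1D row of `n` voxels, one x-oriented fixel per voxel.
line_grid <- function(n = 5) {
  fixel_grid(c(n, 1, 1), c(1, 1, 1),
             data.frame(i = seq_len(n), j = 1, k = 1, x = 1, y = 0, z = 0))
}

# Straight x-axis streamline through voxel centers from voxel a to voxel b
# (mm, extends half a voxel beyond each end so both are fully traversed).
line_streamline <- function(a, b) {
  rbind(c(a - 0.9, 0.5, 0.5), c(b - 0.1, 0.5, 0.5))
}

# Wrap a dense matrix as a fixel_connectivity for unit tests that need full
# control over c_fi.
make_conn <- function(mat, prune = 0) {
  f <- nrow(mat)
  structure(
    list(matrix = fixelcfe:::as_gc_sparse(Matrix::Matrix(mat, sparse = TRUE)),
         n_streamlines_per_fixel = rep(1L, f), prune = prune,
         n_streamlines = 1L, unvisited = integer(0)),
    class = "fixel_connectivity"
  )
}

# Random pruned connectivity with unit diagonal over f fixels.
random_conn <- function(f, density = 0.3, prune = 0.01) {
  m <- matrix(0, f, f)
  n_off <- round(density * f * (f - 1))
  idx <- sample(which(row(m) != col(m)), n_off)
  m[idx] <- runif(n_off, prune, 1)
  diag(m) <- 1
  make_conn(m, prune = prune)
}

# Independent voxel-visitation oracle: dense supersampling of a polyline.
supersample_voxels <- function(s, grid, step = 0.01) {
  pts <- list()
  for (seg in seq_len(nrow(s) - 1)) {
    a <- s[seg, ]; b <- s[seg + 1, ]
    n <- max(2, ceiling(sqrt(sum((b - a)^2)) / step))
    tt <- seq(0, 1, length.out = n)
    pts[[seg]] <- outer(tt, b - a) + rep(a, each = n)
  }
  pts <- do.call(rbind, pts)
  idx <- floor(sweep(sweep(pts, 2, grid$origin, `-`), 2, grid$voxel_size, `/`)) + 1
  ok <- idx[, 1] >= 1 & idx[, 1] <= grid$shape[1] &
    idx[, 2] >= 1 & idx[, 2] <= grid$shape[2] &
    idx[, 3] >= 1 & idx[, 3] <= grid$shape[3]
  unique(idx[ok, , drop = FALSE])
}

# Cached small arc phantom shared across test files (built once per run).
cached_arc_phantom <- local({
  ph <- NULL
  function(n_streamlines = 150) {
    if (is.null(ph)) {
      ph <<- generate_phantom(builtin_scenes("arc", seed = 42,
                                             n_streamlines = n_streamlines))
    }
    ph
  }
})
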