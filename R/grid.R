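#' Fixel grids
#'
#' A fixel grid is the spatial/angular skeleton of a fixel-based analysis: a
#' regular voxel lattice where each voxel holds zero or more *fixels* (specific
#' fibre populations within that voxel), each with a unit orientation vector.
#' Orientations are axial: `v` and `-v` describe the same fibre population.
#'
#' Geometry is axis-aligned. Voxel `(i, j, k)` (1-based) spans
#' `origin + ((i-1)..i) * voxel_size` along x (and analogously y, z); its
#' center is `origin + (c(i, j, k) - 0.5) * voxel_size`. Voxel extents are
#' half-open (`[lo, hi)`) so every point in space belongs to exactly one voxel.
#'
#' Fixel ids are the row numbers of the `fixels` tibble; the constructor sorts
#' fixels into raster order (i fastest, then j, then k) so ids are dense and
#' deterministic. Scalar fixel maps (AFD, t-statistics, enhanced statistics,
#' p-values) are plain numeric vectors of length `n_fixels(grid)` indexed by
#' fixel id.
#'
#' @param shape integer length-3, voxels per dimension.
#' @param voxel_size numeric length-3, voxel edge lengths in mm.
#' @param fixels data frame with columns `i`, `j`, `k` (1-based voxel index)
#'   and `x`, `y`, `z` (unit orientation). Extra columns are preserved.
#' @param origin numeric length-3, mm coordinate of the corner of voxel
#'   (1,1,1). Default `c(0, 0, 0)`.
#' @return An object of class `fixel_grid`.
#' @examples
#' g <- fixel_grid(c(3, 1, 1), c(1, 1, 1),
#'                 data.frame(i = 1:3, j = 1, k = 1, x = 1, y = 0, z = 0))
#' n_fixels(g)
#' @export
fixel_grid <- function(shape, voxel_size, fixels, origin = c(0, 0, 0)) {
  shape <- as.integer(shape)
  voxel_size <- as.numeric(voxel_size)
  if (length(shape) != 3L || any(shape < 1L)) {
    stop_structural("`shape` must be 3 positive integers")
  }
  if (length(voxel_size) != 3L || any(voxel_size <= 0)) {
    stop_structural("`voxel_size` must be 3 positive lengths (mm)")
  }
  fixels <- tibble::as_tibble(fixels)
  req <- c("i", "j", "k", "x", "y", "z")
  if (!all(req %in% names(fixels))) {
    stop_structural("`fixels` needs columns %s", paste(req, collapse = ", "))
  }
  fixels$i <- as.integer(fixels$i)
  fixels$j <- as.integer(fixels$j)
  fixels$k <- as.integer(fixels$k)
  if (nrow(fixels) > 0) {
    if (any(fixels$i < 1L | fixels$i > shape[1] |
            fixels$j < 1L | fixels$j > shape[2] |
            fixels$k < 1L | fixels$k > shape[3])) {
      stop_structural("fixel voxel indices outside grid shape")
    }
    nrm <- sqrt(fixels$x^2 + fixels$y^2 + fixels$z^2)
    if (any(abs(nrm - 1) > 1e-6)) {
      stop_structural("fixel orientations must be unit vectors (tol 1e-6)")
    }
    lin <- fixels$i + (fixels$j - 1L) * shape[1] +
      (fixels$k - 1L) * shape[1] * shape[2]
    ord <- order(lin)  # stable: within-voxel input order preserved
    fixels <- fixels[ord, , drop = FALSE]
    fixels$voxel <- lin[ord]
  } else {
    fixels$voxel <- integer(0)
  }
  structure(
    list(shape = shape, voxel_size = voxel_size, origin = as.numeric(origin),
         fixels = fixels),
    class = "fixel_grid"
  )
}

#' @export
print.fixel_grid <- function(x, ...) {
  cat(sprintf("<fixel_grid> %d x %d x %d voxels (%.2g x %.2g x %.2g mm), %d fixels\n",
              x$shape[1], x$shape[2], x$shape[3],
              x$voxel_size[1], x$voxel_size[2], x$voxel_size[3],
              n_fixels(x)))
  invisible(x)
}

#' Number of fixels in a grid
#' @param grid a [fixel_grid()].
#' @return integer count.
#' @export
n_fixels <- function(grid) {
  stopifnot(inherits(grid, "fixel_grid"))
  nrow(grid$fixels)
}

#' @rdname fixel_grid
#' @param grid a `fixel_grid`.
#' @param ids fixel ids (default all).
#' @return `voxel_centers()`: an n x 3 matrix of voxel-center mm coordinates
#'   for the voxels holding the given fixels.
#' @export
voxel_centers <- function(grid, ids = seq_len(n_fixels(grid))) {
  fx <- grid$fixels[ids, , drop = FALSE]
  ijk <- cbind(fx$i, fx$j, fx$k)
  sweep(sweep(ijk - 0.5, 2, grid$voxel_size, `*`), 2, grid$origin, `+`)
}

# Orientation matrix (F x 3) of the grid's fixels.
fixel_directions <- function(grid, ids = seq_len(n_fixels(grid))) {
  fx <- grid$fixels[ids, , drop = FALSE]
  m <- cbind(fx$x, fx$y, fx$z)
  dimnames(m) <- NULL
  m
}

# 1-based voxel index of mm points (n x 3 matrix); may fall outside the grid.
mm_to_voxel <- function(grid, pts) {
  pts <- matrix(pts, ncol = 3)
  idx <- sweep(pts, 2, grid$origin, `-`)
  idx <- sweep(idx, 2, grid$voxel_size, `/`)
  storage.mode(idx) <- "double"
  floor(idx) + 1
}

voxel_in_grid <- function(grid, ijk) {
  ijk[, 1] >= 1 & ijk[, 1] <= grid$shape[1] &
    ijk[, 2] >= 1 & ijk[, 2] <= grid$shape[2] &
    ijk[, 3] >= 1 & ijk[, 3] <= grid$shape[3]
}

voxel_linear <- function(grid, ijk) {
  ijk[, 1] + (ijk[, 2] - 1) * grid$shape[1] +
    (ijk[, 3] - 1) * grid$shape[1] * grid$shape[2]
}

# Per-voxel fixel lookup: a list mapping linear voxel index -> fixel ids.
# Exploits raster ordering: fixels of one voxel are contiguous rows.
voxel_fixel_index <- function(grid) {
  split(seq_len(n_fixels(grid)), grid$fixels$voxel)
}

#' Voxel-index to mm affine of a grid
#'
#' The 4x4 matrix mapping homogeneous 0-based voxel indices to the mm
#' coordinates of voxel centers (NIfTI-style convention); axis-aligned by
#' construction.
#' @param grid a [fixel_grid()].
#' @return a 4x4 numeric matrix.
#' @export
grid_affine <- function(grid) {
  a <- diag(4)
  diag(a)[1:3] <- grid$voxel_size
  a[1:3, 4] <- grid$origin + grid$voxel_size / 2
  a
}

check_map <- function(values, grid, what = "fixel map") {
  if (length(values) != n_fixels(grid)) {
    stop_structural("%s has length %d but grid has %d fixels",
                    what, length(values), n_fixels(grid))
  }
  invisible(values)
}
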