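#' Exact voxel traversal of a streamline
#'
#' Clips each polyline segment against the voxel lattice and returns one
#' record per *contiguous visit* of a voxel: the ordered voxels the
#' streamline passes through, with the mm points where the path enters and
#' leaves each voxel. Voxel extents are half-open; a voxel revisited after
#' the path has left it yields a new record. Parts of the path outside the
#' grid are dropped.
#'
#' The entry/exit pair is what defines the local streamline tangent used to
#' assign streamlines to fixels.
#'
#' @param s an n x 3 streamline matrix (mm).
#' @param grid a [fixel_grid()].
#' @return a tibble with columns `i`, `j`, `k`, `voxel` (linear index),
#'   `entry_x/y/z`, `exit_x/y/z`; zero rows if the streamline misses the grid.
#' @export
traverse_voxels <- function(s, grid) {
  s <- as.matrix(s)
  stopifnot(ncol(s) == 3, nrow(s) >= 2)
  vox_list <- list(); ent_list <- list(); ext_list <- list()
  for (seg in seq_len(nrow(s) - 1)) {
    a <- s[seg, ]; b <- s[seg + 1, ]; d <- b - a
    ts <- numeric(0)
    for (dim in 1:3) {
      if (d[dim] == 0) next
      # lattice planes at origin + m * voxel_size crossed strictly inside (0,1)
      lo <- (min(a[dim], b[dim]) - grid$origin[dim]) / grid$voxel_size[dim]
      hi <- (max(a[dim], b[dim]) - grid$origin[dim]) / grid$voxel_size[dim]
      planes <- seq(ceiling(lo - 1e-12), floor(hi + 1e-12))
      tt <- (grid$origin[dim] + planes * grid$voxel_size[dim] - a[dim]) / d[dim]
      ts <- c(ts, tt[tt > 1e-12 & tt < 1 - 1e-12])
    }
    ts <- sort(unique(round(ts, 12)))
    bounds <- c(0, ts, 1)
    mids <- (head(bounds, -1) + tail(bounds, -1)) / 2
    pts_mid <- outer(mids, d) + rep(a, each = length(mids))
    ijk <- mm_to_voxel(grid, pts_mid)
    ent <- outer(head(bounds, -1), d) + rep(a, each = length(mids))
    ext <- outer(tail(bounds, -1), d) + rep(a, each = length(mids))
    keep <- (tail(bounds, -1) - head(bounds, -1)) > 1e-12
    vox_list[[seg]] <- ijk[keep, , drop = FALSE]
    ent_list[[seg]] <- ent[keep, , drop = FALSE]
    ext_list[[seg]] <- ext[keep, , drop = FALSE]
  }
  ijk <- do.call(rbind, vox_list)
  ent <- do.call(rbind, ent_list)
  ext <- do.call(rbind, ext_list)
  if (is.null(ijk) || nrow(ijk) == 0) return(empty_traversal())
  # merge consecutive records in the same voxel (including across segments)
  nr <- nrow(ijk)
  new_visit <- c(TRUE, rowSums(abs(ijk[-1, , drop = FALSE] -
                                     ijk[-nr, , drop = FALSE])) > 0)
  visit <- cumsum(new_visit)
  first <- !duplicated(visit)
  last <- rev(!duplicated(rev(visit)))
  ijk <- ijk[first, , drop = FALSE]
  ent <- ent[first, , drop = FALSE]
  ext <- ext[last, , drop = FALSE]
  inside <- voxel_in_grid(grid, ijk)
  ijk <- ijk[inside, , drop = FALSE]
  if (nrow(ijk) == 0) return(empty_traversal())
  tibble::tibble(
    i = as.integer(ijk[, 1]), j = as.integer(ijk[, 2]), k = as.integer(ijk[, 3]),
    voxel = as.integer(voxel_linear(grid, ijk)),
    entry_x = ent[inside, 1], entry_y = ent[inside, 2], entry_z = ent[inside, 3],
    exit_x = ext[inside, 1], exit_y = ext[inside, 2], exit_z = ext[inside, 3]
  )
}

empty_traversal <- function() {
  tibble::tibble(i = integer(), j = integer(), k = integer(), voxel = integer(),
                 entry_x = numeric(), entry_y = numeric(), entry_z = numeric(),
                 exit_x = numeric(), exit_y = numeric(), exit_z = numeric())
}

#' Assign a streamline to fixels via local tangents
#'
#' For each voxel visit, the local tangent is the unit vector from the entry
#' to the exit point of the visit. The masked fixel in that voxel with the
#' smallest axial angle to the tangent is assigned, provided the angle is at
#' most `max_angle_deg` (ties broken by lowest fixel id). Visits with a
#' degenerate (zero-length) tangent, and voxels with no masked fixel within
#' the angular cutoff, assign nothing. A streamline contributes each fixel at
#' most once.
#'
#' @param s an n x 3 streamline matrix (mm).
#' @param grid a [fixel_grid()].
#' @param mask logical per fixel; `NULL` means all fixels.
#' @param max_angle_deg tangent-to-fixel angular cutoff, degrees. Default 45.
#' @param vox_index optional precomputed [voxel_fixel_index()] of `grid`.
#' @return sorted integer vector of fixel ids.
#' @export
assign_streamline_to_fixels <- function(s, grid, mask = NULL,
                                        max_angle_deg = 45, vox_index = NULL) {
  if (is.null(mask)) mask <- rep(TRUE, n_fixels(grid))
  check_map(mask, grid, "fixel mask")
  if (is.null(vox_index)) vox_index <- voxel_fixel_index(grid)
  visits <- traverse_voxels(s, grid)
  assign_visits_to_fixels(visits, grid, mask, max_angle_deg, vox_index,
                          fixel_directions(grid))
}

# Core of streamline-to-fixel assignment, on a precomputed traversal.
assign_visits_to_fixels <- function(visits, grid, mask, max_angle_deg,
                                    vox_index, dirs) {
  if (nrow(visits) == 0) return(integer(0))
  hit <- integer(0)
  for (r in seq_len(nrow(visits))) {
    tang <- c(visits$exit_x[r] - visits$entry_x[r],
              visits$exit_y[r] - visits$entry_y[r],
              visits$exit_z[r] - visits$entry_z[r])
    len <- sqrt(sum(tang^2))
    if (len < 1e-9) next
    cand <- vox_index[[as.character(visits$voxel[r])]]
    cand <- cand[mask[cand]]
    if (!length(cand)) next
    ang <- axial_angle_deg(dirs[cand, , drop = FALSE], tang / len)
    best <- which.min(ang)  # candidates ascend in id, so ties pick lowest id
    if (ang[best] <= max_angle_deg + 1e-9) hit <- c(hit, cand[best])
  }
  sort(unique(hit))
}

#' Build the sparse fixel-fixel connectivity matrix from a tractogram
#'
#' The connectivity from fixel f to fixel i is
#' \deqn{c_{fi} = |S_f \cap S_i| / |S_f|,}
#' the proportion of the streamlines traversing f that also traverse i. The
#' measure is asymmetric (`c_fi != c_if` in general) and `c_ff = 1` for every
#' visited fixel. Entries below `prune` are removed (no renormalisation),
#' which discards probabilistically unlikely connections and keeps the matrix
#' sparse. Fixels never visited by any streamline keep only an implicit
#' self-connection `c_ff = 1`, so smoothing and enhancement degrade to the
#' identity there; they are reported in the `unvisited` diagnostic.
#'
#' @param tract a [tractogram()] (non-empty).
#' @param grid a [fixel_grid()].
#' @param mask logical per fixel (`NULL` = all).
#' @param prune minimum stored connectivity value. Default 0.01.
#' @param max_angle_deg streamline-to-fixel assignment cutoff, degrees.
#' @return an object of class `fixel_connectivity`: fields `matrix` (sparse
#'   F x F, rows index f), `n_streamlines_per_fixel`, `prune`,
#'   `n_streamlines`, `unvisited` (fixel ids never traversed).
#' @export
build_connectivity <- function(tract, grid, mask = NULL, prune = 0.01,
                               max_angle_deg = 45) {
  stopifnot(inherits(tract, "tractogram"))
  if (length(tract) == 0) stop_structural("empty tractogram")
  f_total <- n_fixels(grid)
  vox_index <- voxel_fixel_index(grid)
  sets <- lapply(tract, assign_streamline_to_fixels, grid = grid, mask = mask,
                 max_angle_deg = max_angle_deg, vox_index = vox_index)
  connectivity_from_sets(sets, f_total, prune, length(tract))
}

# Assemble the pruned connectivity matrix from per-streamline fixel sets.
connectivity_from_sets <- function(sets, f_total, prune, n_streamlines) {
  sets <- sets[lengths(sets) > 0]
  if (!length(sets)) stop_structural("no streamline maps to any fixel")
  counts <- tabulate(unlist(sets), nbins = f_total)
  ii <- unlist(lapply(sets, function(s) rep(s, each = length(s))))
  jj <- unlist(lapply(sets, function(s) rep(s, times = length(s))))
  pair <- Matrix::sparseMatrix(i = ii, j = jj, x = 1,
                               dims = c(f_total, f_total))
  visited <- counts > 0
  inv <- ifelse(visited, 1 / counts, 0)
  cmat <- Matrix::Diagonal(x = inv) %*% pair
  # prune, keeping the (always-1) diagonal; unvisited fixels get c_ff = 1
  trip <- Matrix::summary(methods::as(cmat, "TsparseMatrix"))
  keep <- trip$x >= prune | trip$i == trip$j
  cmat <- Matrix::sparseMatrix(i = trip$i[keep], j = trip$j[keep],
                               x = trip$x[keep], dims = c(f_total, f_total))
  Matrix::diag(cmat)[!visited] <- 1
  structure(
    list(matrix = as_gc_sparse(cmat),
         n_streamlines_per_fixel = counts,
         prune = prune,
         n_streamlines = n_streamlines,
         unvisited = which(!visited)),
    class = "fixel_connectivity"
  )
}

#' @export
print.fixel_connectivity <- function(x, ...) {
  cat(sprintf("<fixel_connectivity> %d fixels, %d stored connections (prune %.3g), %d streamlines\n",
              nrow(x$matrix), Matrix::nnzero(x$matrix), x$prune, x$n_streamlines))
  if (length(x$unvisited)) {
    cat(sprintf("  %d fixels never visited by a streamline\n", length(x$unvisited)))
  }
  invisible(x)
}

#' Write / read a connectivity matrix as coordinate triplets
#'
#' Gzipped TSV of `row`, `col`, `value` triplets (1-based), preceded by one
#' `#`-prefixed JSON header line recording the fixel count, prune threshold
#' and streamline count.
#'
#' @param conn a `fixel_connectivity`.
#' @param path output path (written gzip-compressed).
#' @return `read_connectivity()`: a `fixel_connectivity`.
#' @export
write_connectivity <- function(conn, path) {
  stopifnot(inherits(conn, "fixel_connectivity"))
  trip <- Matrix::summary(methods::as(conn$matrix, "TsparseMatrix"))
  con <- gzfile(path, "w")
  on.exit(close(con))
  hdr <- jsonlite::toJSON(list(n_fixels = nrow(conn$matrix), prune = conn$prune,
                               n_streamlines = conn$n_streamlines,
                               n_streamlines_per_fixel = conn$n_streamlines_per_fixel),
                          auto_unbox = TRUE, digits = NA)
  writeLines(paste0("# ", hdr), con)
  writeLines("row\tcol\tvalue", con)
  writeLines(sprintf("%d\t%d\t%.17g", trip$i, trip$j, trip$x), con)
  invisible(path)
}

#' @rdname write_connectivity
#' @export
read_connectivity <- function(path) {
  con <- gzfile(path, "r")
  on.exit(close(con))
  hdr <- jsonlite::fromJSON(sub("^#\\s*", "", readLines(con, n = 1L)))
  tab <- utils::read.delim(con, sep = "\t", header = TRUE)
  f_total <- hdr$n_fixels
  cmat <- Matrix::sparseMatrix(i = tab$row, j = tab$col, x = tab$value,
                               dims = c(f_total, f_total))
  counts <- hdr$n_streamlines_per_fixel %||% rep(NA_integer_, f_total)
  structure(
    list(matrix = as_gc_sparse(cmat),
         n_streamlines_per_fixel = counts,
         prune = hdr$prune,
         n_streamlines = hdr$n_streamlines,
         unvisited = which(counts == 0)),
    class = "fixel_connectivity"
  )
}
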