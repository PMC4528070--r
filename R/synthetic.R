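#' Bundle and phantom scene specifications
#'
#' A bundle is an analytic tract: a polyline centerline, a radius bounding
#' its cross-section, and dispersed streamlines drawn around the centerline
#' with Gaussian perpendicular jitter (constant per streamline, carried along
#' a parallel-ish frame so the bundle stays coherent through curves).
#'
#' @param centerline n x 3 matrix of control points, mm.
#' @param radius bundle radius, mm (> 0); offsets are redrawn until they fall
#'   inside it.
#' @param n_streamlines streamlines to draw (>= 1).
#' @param dispersion_sd standard deviation of the perpendicular Gaussian
#'   jitter, mm.
#' @param label bundle name.
#' @return a `bundle_spec`.
#' @export
bundle_spec <- function(centerline, radius, n_streamlines, dispersion_sd, label) {
  centerline <- as.matrix(centerline)
  stopifnot(ncol(centerline) == 3, nrow(centerline) >= 2)
  if (radius <= 0) stop_structural("radius must be > 0")
  if (n_streamlines < 1) stop_structural("n_streamlines must be >= 1")
  structure(list(centerline = centerline, radius = radius,
                 n_streamlines = as.integer(n_streamlines),
                 dispersion_sd = dispersion_sd, label = label),
            class = "bundle_spec")
}

#' @rdname bundle_spec
#' @param shape,voxel_size,origin grid geometry (see [fixel_grid()]).
#' @param bundles list of `bundle_spec`s.
#' @param seed RNG seed for streamline dispersion.
#' @param truth_labels bundle labels whose fixels constitute the true-signal
#'   region.
#' @param truth_region optional predicate on voxel-center mm coordinates
#'   (n x 3 matrix -> logical) further restricting the truth mask, for focal
#'   lesions along a bundle.
#' @return `phantom_scene()`: a `phantom_scene`.
#' @export
phantom_scene <- function(shape, voxel_size, bundles, seed = 1,
                          truth_labels = NULL, truth_region = NULL,
                          origin = c(0, 0, 0)) {
  stopifnot(all(vapply(bundles, inherits, logical(1), "bundle_spec")))
  labels <- vapply(bundles, `[[`, character(1), "label")
  if (anyDuplicated(labels)) stop_structural("bundle labels must be unique")
  structure(list(shape = as.integer(shape), voxel_size = as.numeric(voxel_size),
                 origin = as.numeric(origin), bundles = bundles, seed = seed,
                 truth_labels = truth_labels %||% labels,
                 truth_region = truth_region),
            class = "phantom_scene")
}

# Resample a polyline at approximately equal arc-length steps.
resample_polyline <- function(pts, step) {
  seg <- sqrt(rowSums(diff(pts)^2))
  arc <- c(0, cumsum(seg))
  s_out <- seq(0, arc[length(arc)], by = step)
  if (s_out[length(s_out)] < arc[length(arc)]) s_out <- c(s_out, arc[length(arc)])
  apply(pts, 2, function(col) stats::approx(arc, col, xout = s_out)$y)
}

# Orthonormal frame (normal, binormal) along a polyline, from a fixed
# reference vector; smooth for moderately curved centerlines.
polyline_frame <- function(pts) {
  n <- nrow(pts)
  # central differences (one-sided at the ends)
  tang <- pts[pmin(seq_len(n) + 1, n), , drop = FALSE] -
    pts[pmax(seq_len(n) - 1, 1), , drop = FALSE]
  tang <- unit_rows(tang)
  ref <- c(0, 0, 1)
  if (max(abs(tang %*% ref)) > 0.9) ref <- c(0, 1, 0)
  nrm <- t(apply(tang, 1, function(tv) {
    v <- ref - sum(ref * tv) * tv
    v / sqrt(sum(v^2))
  }))
  bin <- t(vapply(seq_len(n), function(r) {
    c(tang[r, 2] * nrm[r, 3] - tang[r, 3] * nrm[r, 2],
      tang[r, 3] * nrm[r, 1] - tang[r, 1] * nrm[r, 3],
      tang[r, 1] * nrm[r, 2] - tang[r, 2] * nrm[r, 1])
  }, numeric(3)))
  list(normal = nrm, binormal = bin)
}

draw_bundle_streamlines <- function(bundle, step) {
  ctr <- resample_polyline(bundle$centerline, step)
  frame <- polyline_frame(ctr)
  lapply(seq_len(bundle$n_streamlines), function(s) {
    repeat {
      uv <- rnorm(2, sd = bundle$dispersion_sd)
      if (sum(uv^2) <= bundle$radius^2) break
    }
    ctr + uv[1] * frame$normal + uv[2] * frame$binormal
  })
}

# Greedy axial clustering of unit tangents within one voxel: tangents join
# the nearest cluster within `sep_deg`, otherwise found a new one; cluster
# directions are principal eigenvectors of the orientation scatter; clusters
# ending up closer than `sep_deg` are merged.
cluster_tangents <- function(tangents, sep_deg = 30) {
  scatter <- vector("list", 0)
  dirs <- matrix(numeric(0), 0, 3)
  sizes <- integer(0)
  for (r in seq_len(nrow(tangents))) {
    tv <- tangents[r, ]
    if (nrow(dirs)) {
      ang <- axial_angle_deg(dirs, tv)
      best <- which.min(ang)
    } else best <- integer(0)
    if (length(best) && ang[best] <= sep_deg) {
      scatter[[best]] <- scatter[[best]] + tcrossprod(tv)
      sizes[best] <- sizes[best] + 1L
      dirs[best, ] <- principal_axis(scatter[[best]])
    } else {
      scatter[[length(scatter) + 1L]] <- tcrossprod(tv)
      dirs <- rbind(dirs, tv)
      sizes <- c(sizes, 1L)
    }
  }
  # merge clusters that drifted within sep_deg of each other
  repeat {
    if (nrow(dirs) < 2) break
    merged <- FALSE
    for (a in seq_len(nrow(dirs) - 1)) {
      ang <- axial_angle_deg(dirs[-seq_len(a), , drop = FALSE], dirs[a, ])
      hit <- which(ang < sep_deg)
      if (length(hit)) {
        b <- a + hit[1]
        scatter[[a]] <- scatter[[a]] + scatter[[b]]
        sizes[a] <- sizes[a] + sizes[b]
        dirs[a, ] <- principal_axis(scatter[[a]])
        scatter[[b]] <- NULL
        dirs <- dirs[-b, , drop = FALSE]
        sizes <- sizes[-b]
        merged <- TRUE
        break
      }
    }
    if (!merged) break
  }
  list(directions = dirs, sizes = sizes)
}

principal_axis <- function(m) {
  v <- eigen(m, symmetric = TRUE)$vectors[, 1]
  v / sqrt(sum(v^2))
}

#' Generate a phantom: fixel grid, tractogram, connectivity and truth masks
#'
#' Samples dispersed streamlines along each bundle's centerline, derives
#' fixels per voxel by axial clustering of the local streamline tangents
#' (clusters at least 30 degrees apart; bundles crossing at shallower angles
#' merge into one fixel), builds the pruned fixel-fixel connectivity matrix,
#' and maps each bundle's streamlines back to fixels to form per-bundle
#' truth masks. Deterministic given the scene seed.
#'
#' The per-fixel streamline visitation density, scaled to max 1, is returned
#' as `afd` — a stand-in for apparent fibre density so that analysis-mask
#' construction can be exercised on synthetic data.
#'
#' @param scene a [phantom_scene()].
#' @param prune connectivity pruning threshold.
#' @return a list with `grid`, `tract` ([tractogram()]), `conn`
#'   ([build_connectivity()] result), `truth` (logical mask over fixels),
#'   `bundle_masks` (named list, one mask per bundle), `afd`,
#'   `streamline_bundle` (label per streamline).
#' @export
generate_phantom <- function(scene, prune = 0.01) {
  stopifnot(inherits(scene, "phantom_scene"))
  step <- 0.5 * min(scene$voxel_size)
  streamlines <- list()
  bundle_of <- character(0)
  with_seed(scene$seed, {
    for (b in scene$bundles) {
      sl <- draw_bundle_streamlines(b, step)
      streamlines <- c(streamlines, sl)
      bundle_of <- c(bundle_of, rep(b$label, length(sl)))
    }
  })
  tract <- tractogram(streamlines)
  proto <- fixel_grid(scene$shape, scene$voxel_size,
                      data.frame(i = integer(0), j = integer(0), k = integer(0),
                                 x = numeric(0), y = numeric(0), z = numeric(0)),
                      origin = scene$origin)
  visits <- lapply(tract, traverse_voxels, grid = proto)
  # per-voxel tangent pools
  all_visits <- dplyr::bind_rows(visits)
  tang <- cbind(all_visits$exit_x - all_visits$entry_x,
                all_visits$exit_y - all_visits$entry_y,
                all_visits$exit_z - all_visits$entry_z)
  len <- sqrt(rowSums(tang^2))
  ok <- len > 1e-9
  tang <- tang[ok, , drop = FALSE] / len[ok]
  vox_of <- all_visits$voxel[ok]
  fixel_rows <- list()
  for (vox in sort(unique(vox_of))) {
    cl <- cluster_tangents(tang[vox_of == vox, , drop = FALSE])
    ord <- order(-cl$sizes)
    ijk <- arrayInd(vox, scene$shape)
    fixel_rows[[length(fixel_rows) + 1L]] <- tibble::tibble(
      i = ijk[1], j = ijk[2], k = ijk[3],
      x = cl$directions[ord, 1], y = cl$directions[ord, 2],
      z = cl$directions[ord, 3], visits = cl$sizes[ord]
    )
  }
  grid <- fixel_grid(scene$shape, scene$voxel_size, dplyr::bind_rows(fixel_rows),
                     origin = scene$origin)
  vox_index <- voxel_fixel_index(grid)
  dirs <- fixel_directions(grid)
  all_mask <- rep(TRUE, n_fixels(grid))
  sets <- lapply(visits, assign_visits_to_fixels, grid = grid, mask = all_mask,
                 max_angle_deg = 45, vox_index = vox_index, dirs = dirs)
  conn <- connectivity_from_sets(sets, n_fixels(grid), prune, length(tract))
  bundle_masks <- lapply(stats::setNames(nm = unique(bundle_of)), function(lb) {
    ids <- sort(unique(unlist(sets[bundle_of == lb])))
    mask <- rep(FALSE, n_fixels(grid))
    mask[ids] <- TRUE
    mask
  })
  truth <- Reduce(`|`, bundle_masks[scene$truth_labels])
  if (!is.null(scene$truth_region)) {
    truth <- truth & scene$truth_region(voxel_centers(grid))
  }
  visits_per_fixel <- tabulate(unlist(sets), nbins = n_fixels(grid))
  afd <- visits_per_fixel / max(visits_per_fixel)
  list(grid = grid, tract = tract, conn = conn, truth = truth,
       bundle_masks = bundle_masks, afd = afd,
       streamline_bundle = bundle_of)
}

#' Generate simulation test-statistic images
#'
#' Each realisation draws i.i.d. standard-normal noise over the masked
#' fixels; the paired signal+noise image adds `snr` to the true-signal
#' fixels of *the same* noise draw (unit binary signal scaled by SNR, since
#' the noise has unit standard deviation). Fixels outside the mask stay 0.
#' Realisations use independently derived sub-seeds, so any subset can be
#' regenerated in any order.
#'
#' @param mask logical analysis mask.
#' @param truth logical truth mask (subset of `mask`).
#' @param snr signal-to-noise ratio (signal amplitude / noise sd). >= 0.
#' @param n_realisations number of paired realisations.
#' @param seed master seed.
#' @return list with `noise` and `signal`: lists of numeric fixel maps.
#' @export
generate_statistic_images <- function(mask, truth, snr, n_realisations, seed = 1) {
  if (any(truth & !mask)) stop_structural("truth mask must lie inside the analysis mask")
  if (snr < 0) stop_structural("snr must be >= 0")
  seeds <- derive_seeds(seed, n_realisations)
  sig <- snr * as.numeric(truth)
  noise <- vector("list", n_realisations)
  signal <- vector("list", n_realisations)
  for (k in seq_len(n_realisations)) {
    nm <- numeric(length(mask))
    nm[mask] <- with_seed(seeds[k], rnorm(sum(mask)))
    noise[[k]] <- nm
    signal[[k]] <- nm + sig
  }
  list(noise = noise, signal = signal)
}

#' Estimate the signal-to-noise ratio of a statistic image
#'
#' SNR is the signal amplitude expressed in units of the noise standard
#' deviation: the mean excess of the true-signal fixels over the background,
#' divided by the background standard deviation. A unit binary signal in
#' noise of sd 0.5 therefore has SNR 2, and [generate_statistic_images()]
#' with unit noise realises `snr` directly as the planted amplitude.
#'
#' @param map numeric fixel map (signal + noise).
#' @param truth logical mask of the true-signal fixels.
#' @return estimated SNR.
#' @export
estimate_snr <- function(map, truth) {
  if (!any(truth) || all(truth)) {
    stop_structural("need both signal and background fixels")
  }
  (mean(map[truth]) - mean(map[!truth])) / stats::sd(map[!truth])
}

#' Built-in phantom scenes
#'
#' Five toy-scale presets echoing archetypal white-matter evaluation
#' regions: `"arc"` (a curved bundle crossing a straight one; the curved
#' bundle is true), `"fanning"` (a trunk fanning into three branches, all
#' true), `"thin"` (one long thin bundle, all true), `"focal"` (the thin
#' bundle with only its middle third true), and `"multi"` (three disjoint
#' bundles, jointly true). All fit in grids of at most 32^3 voxels.
#'
#' @param name one of `"arc"`, `"fanning"`, `"thin"`, `"focal"`, `"multi"`;
#'   `NULL` returns the named list of all presets.
#' @param seed scene seed.
#' @param n_streamlines streamlines per bundle.
#' @return a [phantom_scene()] (or a named list of them).
#' @export
builtin_scenes <- function(name = NULL, seed = 1, n_streamlines = 300) {
  arc_ctr <- t(vapply(seq(0, pi / 2, length.out = 25), function(a) {
    c(10 - 7 * cos(a), 3 + 7 * sin(a), 5.5)
  }, numeric(3)))
  scenes <- list(
    arc = phantom_scene(
      shape = c(16, 16, 11), voxel_size = c(1, 1, 1), seed = seed,
      bundles = list(
        bundle_spec(arc_ctr, radius = 1.6, n_streamlines = n_streamlines,
                    dispersion_sd = 0.8, label = "arc"),
        bundle_spec(rbind(c(1, 6.5, 5.5), c(15, 6.5, 5.5)), radius = 1.6,
                    n_streamlines = n_streamlines, dispersion_sd = 0.8,
                    label = "crossing")
      ),
      truth_labels = "arc"
    ),
    fanning = phantom_scene(
      shape = c(20, 16, 11), voxel_size = c(1, 1, 1), seed = seed,
      bundles = list(
        bundle_spec(rbind(c(1, 8, 5.5), c(9, 8, 5.5), c(18, 3, 5.5)),
                    radius = 1.4, n_streamlines = n_streamlines,
                    dispersion_sd = 0.7, label = "fan_a"),
        bundle_spec(rbind(c(1, 8, 5.5), c(9, 8, 5.5), c(18, 8, 5.5)),
                    radius = 1.4, n_streamlines = n_streamlines,
                    dispersion_sd = 0.7, label = "fan_b"),
        bundle_spec(rbind(c(1, 8, 5.5), c(9, 8, 5.5), c(18, 13, 5.5)),
                    radius = 1.4, n_streamlines = n_streamlines,
                    dispersion_sd = 0.7, label = "fan_c")
      )
    ),
    thin = phantom_scene(
      shape = c(30, 10, 9), voxel_size = c(1, 1, 1), seed = seed,
      bundles = list(
        bundle_spec(rbind(c(1, 3, 4.5), c(15, 7, 4.5), c(29, 3, 4.5)),
                    radius = 1, n_streamlines = n_streamlines,
                    dispersion_sd = 0.5, label = "thin")
      )
    ),
    focal = phantom_scene(
      shape = c(30, 10, 9), voxel_size = c(1, 1, 1), seed = seed,
      bundles = list(
        bundle_spec(rbind(c(1, 3, 4.5), c(15, 7, 4.5), c(29, 3, 4.5)),
                    radius = 1, n_streamlines = n_streamlines,
                    dispersion_sd = 0.5, label = "thin")
      ),
      truth_region = function(ctr) ctr[, 1] >= 10 & ctr[, 1] <= 20
    ),
    multi = phantom_scene(
      shape = c(20, 20, 9), voxel_size = c(1, 1, 1), seed = seed,
      bundles = list(
        bundle_spec(rbind(c(1, 4, 4.5), c(19, 4, 4.5)), radius = 1.2,
                    n_streamlines = n_streamlines, dispersion_sd = 0.6,
                    label = "m1"),
        bundle_spec(rbind(c(1, 10, 4.5), c(19, 10, 4.5)), radius = 1.2,
                    n_streamlines = n_streamlines, dispersion_sd = 0.6,
                    label = "m2"),
        bundle_spec(rbind(c(1, 16, 4.5), c(19, 16, 4.5)), radius = 1.2,
                    n_streamlines = n_streamlines, dispersion_sd = 0.6,
                    label = "m3")
      )
    )
  )
  if (is.null(name)) return(scenes)
  if (!name %in% names(scenes)) {
    stop_structural("unknown scene '%s' (have: %s)", name,
                    paste(names(scenes), collapse = ", "))
  }
  scenes[[name]]
}
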