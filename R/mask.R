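#' Build the fixel analysis mask by two-step AFD thresholding
#'
#' Fixels with poor correspondence across subjects (typically near the
#' grey/white interface) have low apparent fibre density (AFD) in a
#' population template and should be excluded from analysis; but a single
#' strict AFD threshold would also discard genuine crossing-fibre fixels
#' whose AFD is low through partial volume. The two-step rule keeps both
#' concerns apart:
#'
#' 1. keep fixels with AFD strictly above `high_thresh`;
#' 2. form the 3D voxel mask of all voxels containing at least one surviving
#'    fixel;
#' 3. final mask = fixels with AFD strictly above `low_thresh` *and* lying in
#'    a step-2 voxel.
#'
#' @param grid a [fixel_grid()].
#' @param afd numeric AFD per fixel (non-negative), length `n_fixels(grid)`.
#' @param high_thresh,low_thresh the two AFD thresholds; defaults 0.33 and
#'   0.1. Both strict (`>`).
#' @return logical vector, `TRUE` for fixels in the analysis mask.
#' @examples
#' g <- fixel_grid(c(2, 1, 1), c(1, 1, 1),
#'                 data.frame(i = c(1, 1, 2), j = 1, k = 1,
#'                            x = c(1, 0, 1), y = c(0, 1, 0), z = 0))
#' build_analysis_mask(g, c(0.5, 0.2, 0.2))  # TRUE TRUE FALSE
#' @export
build_analysis_mask <- function(grid, afd, high_thresh = 0.33, low_thresh = 0.1) {
  check_map(afd, grid, "AFD map")
  if (any(afd < 0)) stop_structural("AFD values must be non-negative")
  if (!(0 <= low_thresh && low_thresh <= high_thresh)) {
    stop_structural("need 0 <= low_thresh <= high_thresh")
  }
  seed_fixels <- afd > high_thresh
  seed_voxels <- unique(grid$fixels$voxel[seed_fixels])
  (afd > low_thresh) & (grid$fixels$voxel %in% seed_voxels)
}

#' 3D voxel mask of voxels holding at least one masked fixel
#'
#' @param grid a [fixel_grid()].
#' @param fixel_mask logical per fixel.
#' @return a logical 3D array of dimension `grid$shape`.
#' @export
voxel_mask_from_fixels <- function(grid, fixel_mask) {
  check_map(fixel_mask, grid, "fixel mask")
  arr <- array(FALSE, dim = grid$shape)
  arr[unique(grid$fixels$voxel[fixel_mask])] <- TRUE
  arr
}

#' Match subject fixels to template fixels by angular correspondence
#'
#' For each template fixel, finds the subject fixel in the *same voxel* with
#' the smallest axial angle (arccos of the absolute dot product — fixel
#' orientations have no polarity) and matches it if that angle does not
#' exceed `angular_tol_deg`. Template fixels with no match within tolerance
#' are left unmatched (`NA`); extracting values for them yields 0. Subject
#' fixels that match no template fixel are ignored. Each subject fixel is
#' used at most once (greedy by smallest angle, ties broken by lowest subject
#' fixel id).
#'
#' @param template,subject two [fixel_grid()]s sharing shape, voxel size and
#'   origin (the subject already warped to template space).
#' @param angular_tol_deg maximum axial angle, degrees. Default 30.
#' @return integer vector of length `n_fixels(template)`: matched subject
#'   fixel id or `NA` for unmatched.
#' @export
match_subject_fixels <- function(template, subject, angular_tol_deg = 30) {
  stopifnot(inherits(template, "fixel_grid"), inherits(subject, "fixel_grid"))
  if (!identical(template$shape, subject$shape) ||
      !isTRUE(all.equal(template$voxel_size, subject$voxel_size)) ||
      !isTRUE(all.equal(template$origin, subject$origin))) {
    stop_structural("template and subject grids must share geometry")
  }
  sub_index <- voxel_fixel_index(subject)
  sub_dirs <- fixel_directions(subject)
  tmp_dirs <- fixel_directions(template)
  out <- rep(NA_integer_, n_fixels(template))
  tmp_by_voxel <- voxel_fixel_index(template)
  for (vox in names(tmp_by_voxel)) {
    tids <- tmp_by_voxel[[vox]]
    sids <- sub_index[[vox]]
    if (is.null(sids)) next
    ang <- matrix(0, length(tids), length(sids))
    for (a in seq_along(tids)) {
      ang[a, ] <- axial_angle_deg(sub_dirs[sids, , drop = FALSE], tmp_dirs[tids[a], ])
    }
    # greedy: repeatedly take the globally smallest angle within the voxel
    repeat {
      m <- which(ang == min(ang), arr.ind = TRUE)
      if (!nrow(m) || min(ang) > angular_tol_deg) break
      # ties: lowest subject fixel id, then lowest template id
      m <- m[order(m[, 2], m[, 1]), , drop = FALSE][1, ]
      out[tids[m[1]]] <- sids[m[2]]
      ang[m[1], ] <- Inf
      ang[, m[2]] <- Inf
      if (all(!is.finite(ang))) break
    }
  }
  out
}

#' Extract subject fixel values onto the template index
#'
#' Realises a correspondence from [match_subject_fixels()]: matched template
#' fixels take the subject's value, unmatched fixels are assigned 0.
#'
#' @param subject_values numeric per subject fixel.
#' @param corr integer correspondence (template-length, `NA` = unmatched).
#' @return numeric vector of template length.
#' @export
extract_subject_values <- function(subject_values, corr) {
  out <- numeric(length(corr))
  ok <- !is.na(corr)
  if (any(corr[ok] < 1 | corr[ok] > length(subject_values))) {
    stop_structural("correspondence refers to fixels outside the subject map")
  }
  out[ok] <- subject_values[corr[ok]]
  out
}
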