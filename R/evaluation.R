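#' AFROC curve over simulation realisations
#'
#' Alternative free-response ROC for family-wise evaluation of enhanced
#' statistic images: as a common threshold sweeps down from the maximum
#' enhanced signal+noise value towards zero,
#' * FPR(h) = fraction of noise-only realisations with *any* fixel above h
#'   anywhere in the image (a family-wise false positive), and
#' * TPR(h) = mean over signal realisations of the fraction of true-signal
#'   fixels above h.
#'
#' @param noise_maps list of enhanced noise-only fixel maps (one per
#'   realisation).
#' @param signal_maps list of enhanced signal+noise fixel maps, same length.
#' @param truth logical mask of true-signal fixels (non-empty).
#' @param n_thresholds number of evenly spaced thresholds in
#'   `(0, max(signal_maps)]`. Default 1000.
#' @return a tibble of class `afroc_curve` with columns `threshold`
#'   (descending), `fpr`, `tpr`.
#' @export
afroc_curve <- function(noise_maps, signal_maps, truth, n_thresholds = 1000) {
  if (!length(noise_maps) || !length(signal_maps)) {
    stop_structural("need at least one noise and one signal realisation")
  }
  if (length(noise_maps) != length(signal_maps)) {
    stop_structural("noise and signal realisation lists must have equal length")
  }
  if (!any(truth)) stop_structural("truth mask is empty")
  hmax <- max(vapply(signal_maps, max, numeric(1)))
  if (hmax <= 0) stop_structural("no positive enhanced signal value to sweep")
  thresholds <- seq(hmax, hmax / n_thresholds, length.out = n_thresholds)
  noise_max <- vapply(noise_maps, max, numeric(1))
  truth_mat <- do.call(cbind, lapply(signal_maps, function(m) m[truth]))
  fpr <- vapply(thresholds, function(h) mean(noise_max > h), numeric(1))
  tpr <- vapply(thresholds, function(h) mean(truth_mat > h), numeric(1))
  tibble::new_tibble(
    tibble::tibble(threshold = thresholds, fpr = fpr, tpr = tpr),
    class = "afroc_curve"
  )
}

#' Restricted normalised area under an AFROC curve
#'
#' Trapezoidal area of TPR over FPR restricted to `FPR <= fpr_max` (linear
#' interpolation at the cut), divided by `fpr_max` so the result spans
#' [0, 1]. The restriction reflects that family-wise false-positive rates
#' above 0.05 are of no practical interest.
#'
#' @param curve an [afroc_curve()].
#' @param fpr_max FPR restriction, default 0.05.
#' @return normalised AUC in [0, 1].
#' @export
afroc_auc <- function(curve, fpr_max = 0.05) {
  stopifnot(all(c("fpr", "tpr") %in% names(curve)))
  ord <- order(curve$fpr, curve$tpr)
  fpr <- curve$fpr[ord]
  tpr <- curve$tpr[ord]
  # anchor at FPR 0: TPR attained while no realisation has any false positive
  if (fpr[1] > 0) {
    fpr <- c(0, fpr)
    tpr <- c(0, tpr)
  }
  if (max(fpr) < fpr_max) {
    # degenerate perfect-specificity tail: extend the last TPR to the cut
    fpr <- c(fpr, fpr_max)
    tpr <- c(tpr, tpr[length(tpr)])
  } else if (!any(fpr == fpr_max)) {
    above <- which(fpr > fpr_max)[1]
    below <- above - 1L
    frac <- (fpr_max - fpr[below]) / (fpr[above] - fpr[below])
    cut_tpr <- tpr[below] + frac * (tpr[above] - tpr[below])
    keep <- fpr < fpr_max
    fpr <- c(fpr[keep], fpr_max)
    tpr <- c(tpr[keep], cut_tpr)
  } else {
    keep <- fpr <= fpr_max
    fpr <- fpr[keep]
    tpr <- tpr[keep]
  }
  area <- sum(diff(fpr) * (head(tpr, -1) + tail(tpr, -1)) / 2)
  area / fpr_max
}

#' Sweep smoothing and enhancement parameters over a phantom
#'
#' For each combination of SNR, smoothing FWHM and CFE exponents, generates
#' (or reuses) paired noise / signal+noise realisations on the phantom,
#' smooths, variance-renormalises, enhances, and scores the AFROC AUC at
#' `fpr_max = 0.05`. Noise realisations are shared across combinations
#' (paired design), so AUC differences between parameter sets are not
#' confounded by noise sampling.
#'
#' @param phantom a [generate_phantom()] result (or compatible list with
#'   `grid`, `conn` and masks).
#' @param truth logical truth mask.
#' @param mask logical analysis mask (default: all fixels).
#' @param snr_list,fwhm_list,E_list,H_list,C_list parameter values to cross.
#' @param n_realisations realisations per combination.
#' @param seed master seed; realisation noise is derived from it.
#' @param dh CFE integration step.
#' @param n_thresholds thresholds per AFROC curve.
#' @return a tibble with one row per combination: `snr`, `fwhm`, `E`, `H`,
#'   `C`, `auc`, `n_realisations`, `seed`.
#' @export
parameter_sweep <- function(phantom, truth, mask = NULL,
                            snr_list = c(1, 2, 3), fwhm_list = 10,
                            E_list = 2, H_list = 3, C_list = 0.5,
                            n_realisations = 100, seed = 1, dh = 0.1,
                            n_thresholds = 1000) {
  grid <- phantom$grid
  conn <- phantom$conn
  if (is.null(conn)) stop_structural("phantom must carry a connectivity matrix")
  if (is.null(mask)) mask <- rep(TRUE, n_fixels(grid))
  grid_combos <- tidyr::expand_grid(snr = snr_list, fwhm = fwhm_list,
                                    E = E_list, H = H_list, C = C_list)
  weights_cache <- lapply(stats::setNames(nm = unique(grid_combos$fwhm)), function(fw) {
    compute_smoothing_weights(conn, grid, fwhm_mm = fw)
  })
  raw <- generate_statistic_images(mask, truth, snr = 1, # signal added later
                                   n_realisations = n_realisations, seed = seed)
  sig_ind <- as.numeric(truth)
  rows <- purrr::pmap(grid_combos, function(snr, fwhm, E, H, C) {
    w <- weights_cache[[as.character(fwhm)]]
    params <- cfe_params(E = E, H = H, C = C, dh = dh)
    enh_noise <- lapply(raw$noise, function(nm) {
      cfe_enhance(variance_renormalise(smooth_fixels(nm, w), w), conn, params)
    })
    enh_signal <- lapply(raw$noise, function(nm) {
      sm <- variance_renormalise(smooth_fixels(nm + snr * sig_ind, w), w)
      cfe_enhance(sm, conn, params)
    })
    curve <- afroc_curve(enh_noise, enh_signal, truth, n_thresholds)
    tibble::tibble(snr = snr, fwhm = fwhm, E = E, H = H, C = C,
                   auc = afroc_auc(curve), n_realisations = n_realisations,
                   seed = seed)
  })
  dplyr::bind_rows(rows)
}
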