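#' Connectivity-based smoothing weights
#'
#' Fixel data are smoothed only with fixels that share streamlines: the raw
#' weight between fixels f and i is the product of a spatial Gaussian kernel
#' and the fixel-fixel connectivity,
#' \deqn{w_{fi} = \exp(-d_{fi}^2 / 2\sigma^2) \cdot c_{fi},}
#' where d is the Euclidean distance between voxel centers (mm) and
#' \eqn{\sigma = \mathrm{FWHM} / (2\sqrt{2\ln 2})}. This keeps smoothing
#' tract-specific — a zero-connectivity pair never exchanges signal, no
#' matter how close in space — while the Gaussian stops remote fixels of the
#' same bundle (whose values may differ systematically) from dominating.
#'
#' Weights beyond `truncate_sigma` standard deviations are dropped, and each
#' row is normalised to sum to 1 so that smoothing preserves constants. A
#' zero FWHM yields identity weights.
#'
#' @param conn a [build_connectivity()] result.
#' @param grid the matching [fixel_grid()].
#' @param fwhm_mm Gaussian kernel full width at half maximum, mm (>= 0).
#' @param truncate_sigma spatial truncation radius in units of sigma.
#' @return an object of class `smoothing_weights` with fields `matrix`
#'   (sparse row-stochastic F x F), `fwhm_mm`, `isolated` (fixels whose row
#'   degenerated to the identity).
#' @export
compute_smoothing_weights <- function(conn, grid, fwhm_mm, truncate_sigma = 3) {
  stopifnot(inherits(conn, "fixel_connectivity"))
  f_total <- n_fixels(grid)
  if (nrow(conn$matrix) != f_total) {
    stop_structural("connectivity (%d fixels) does not match grid (%d fixels)",
                    nrow(conn$matrix), f_total)
  }
  if (fwhm_mm < 0) stop_structural("fwhm_mm must be >= 0")
  if (fwhm_mm == 0) {
    w <- Matrix::Diagonal(f_total)
    return(structure(list(matrix = as_gc_sparse(w),
                          fwhm_mm = 0, isolated = integer(0)),
                     class = "smoothing_weights"))
  }
  sigma <- fwhm_to_sigma(fwhm_mm)
  trip <- Matrix::summary(methods::as(conn$matrix, "TsparseMatrix"))
  ctr <- voxel_centers(grid)
  d2 <- rowSums((ctr[trip$i, , drop = FALSE] - ctr[trip$j, , drop = FALSE])^2)
  keep <- d2 <= (truncate_sigma * sigma)^2
  w_raw <- exp(-d2[keep] / (2 * sigma^2)) * trip$x[keep]
  w <- Matrix::sparseMatrix(i = trip$i[keep], j = trip$j[keep], x = w_raw,
                            dims = c(f_total, f_total))
  rs <- Matrix::rowSums(w)
  isolated <- which(rs <= 0)
  if (length(isolated)) {
    w <- w + Matrix::sparseMatrix(i = isolated, j = isolated,
                                  x = rep(1, length(isolated)),
                                  dims = c(f_total, f_total))
    rs[isolated] <- 1
  }
  w <- Matrix::Diagonal(x = 1 / rs) %*% w
  structure(list(matrix = as_gc_sparse(w),
                 fwhm_mm = fwhm_mm, isolated = isolated),
            class = "smoothing_weights")
}

#' @export
print.smoothing_weights <- function(x, ...) {
  cat(sprintf("<smoothing_weights> %d fixels, FWHM %.3g mm, %d stored weights\n",
              nrow(x$matrix), x$fwhm_mm, Matrix::nnzero(x$matrix)))
  invisible(x)
}

#' FWHM to Gaussian sigma
#'
#' `FWHM = 2 sqrt(2 ln 2) sigma`.
#' @param fwhm_mm full width at half maximum, mm.
#' @return sigma in mm.
#' @export
fwhm_to_sigma <- function(fwhm_mm) fwhm_mm / (2 * sqrt(2 * log(2)))

#' Smooth a fixel map with precomputed weights
#'
#' `out_f = sum_i w_fi values_i` — a sparse matrix-vector product.
#'
#' @param values numeric fixel map.
#' @param weights a [compute_smoothing_weights()] result.
#' @return numeric fixel map of the same length.
#' @export
smooth_fixels <- function(values, weights) {
  stopifnot(inherits(weights, "smoothing_weights"))
  if (length(values) != nrow(weights$matrix)) {
    stop_structural("map length %d does not match weights (%d fixels)",
                    length(values), nrow(weights$matrix))
  }
  as.vector(weights$matrix %*% values)
}

#' Restore unit noise variance after smoothing
#'
#' Smoothing independent unit-variance noise leaves fixel f with variance
#' `sum_i w_fi^2`; dividing by its square root restores standard deviation 1
#' exactly, per fixel. Used in simulation studies so that smoothing a
#' simulated test-statistic image is equivalent to smoothing the underlying
#' data. Rows with zero weight mass pass through unchanged.
#'
#' @param values smoothed fixel map (from unit-variance independent noise).
#' @param weights the [compute_smoothing_weights()] used to smooth.
#' @return renormalised fixel map.
#' @export
variance_renormalise <- function(values, weights) {
  stopifnot(inherits(weights, "smoothing_weights"))
  if (length(values) != nrow(weights$matrix)) {
    stop_structural("map length %d does not match weights (%d fixels)",
                    length(values), nrow(weights$matrix))
  }
  fac <- sqrt(Matrix::rowSums(weights$matrix^2))
  fac[fac == 0] <- 1
  values / fac
}
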