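#' Study configuration for the end-to-end CFE pipeline
#'
#' Bundles all paths and parameters of a fixel-based analysis. Parameter
#' defaults are the recommended set: E = 2, H = 3, C = 0.5, 10 mm FWHM
#' smoothing, connectivity pruning at 0.01, alpha = 0.05.
#'
#' @param fixel_dir fixel dataset directory (see [write_fixel_dir()]); if an
#'   `afd.tsv` map is present the analysis mask is built from it, otherwise
#'   all fixels are analysed.
#' @param tracks tractogram path (`.tck`, or the plain-text format).
#' @param manifest text file listing one subject fixel-value TSV per line,
#'   ordered as the design rows.
#' @param design,contrast whitespace-delimited design matrix / contrast files.
#' @param out output directory.
#' @param prune,fwhm,E,H,C,dh,n_permutations,seed,alpha pipeline parameters.
#' @param mask_high,mask_low the two AFD thresholds of
#'   [build_analysis_mask()].
#' @return a `run_config` list.
#' @export
run_config <- function(fixel_dir, tracks, manifest, design, contrast, out,
                       prune = 0.01, fwhm = 10, E = 2, H = 3, C = 0.5,
                       dh = 0.1, n_permutations = 5000, seed = 1,
                       alpha = 0.05, mask_high = 0.33, mask_low = 0.1) {
  structure(list(fixel_dir = fixel_dir, tracks = tracks, manifest = manifest,
                 design = design, contrast = contrast, out = out,
                 prune = prune, fwhm = fwhm, E = E, H = H, C = C, dh = dh,
                 n_permutations = n_permutations, seed = seed, alpha = alpha,
                 mask_high = mask_high, mask_low = mask_low),
            class = "run_config")
}

#' Run the full CFE study pipeline
#'
#' Chains mask construction, connectivity, smoothing, CFE enhancement and
#' max-statistic permutation inference, writing fixel maps (t-statistic,
#' enhanced statistic, FWE p-value, significance mask), the null
#' distribution, and a machine-readable run manifest (parameters, input
#' digests, package version) to the output directory. Deterministic given
#' the seed; inputs are never mutated.
#'
#' @param config a [run_config()].
#' @return the [cfe_permutation_test()] fit, invisibly; side effect: files
#'   under `config$out`.
#' @export
run_study <- function(config) {
  stopifnot(inherits(config, "run_config"))
  inputs <- c(config$tracks, config$manifest, config$design, config$contrast)
  missing_in <- inputs[!file.exists(inputs)]
  if (length(missing_in)) {
    stop_structural("unreadable input: %s", missing_in[1])
  }
  ds <- read_fixel_dir(config$fixel_dir)
  grid <- ds$grid
  subject_files <- trimws(readLines(config$manifest))
  subject_files <- subject_files[nzchar(subject_files)]
  design <- read_design(config$design)
  contrast <- read_contrast(config$contrast)
  if (length(subject_files) != nrow(design)) {
    stop_structural("manifest lists %d subjects but design has %d rows",
                    length(subject_files), nrow(design))
  }
  data <- do.call(rbind, lapply(subject_files, function(p) {
    utils::read.delim(p)$value
  }))
  if (ncol(data) != n_fixels(grid)) {
    stop_structural("subject maps have %d fixels but grid has %d",
                    ncol(data), n_fixels(grid))
  }
  mask <- if (!is.null(ds$values$afd)) {
    build_analysis_mask(grid, ds$values$afd, config$mask_high, config$mask_low)
  } else rep(TRUE, n_fixels(grid))
  tract <- if (grepl("\\.tck$", config$tracks)) {
    read_tck(config$tracks)
  } else read_tract_text(config$tracks)
  conn <- build_connectivity(tract, grid, mask = mask, prune = config$prune)
  weights <- compute_smoothing_weights(conn, grid, fwhm_mm = config$fwhm)
  fit <- cfe_permutation_test(
    data, design, contrast, conn,
    params = cfe_params(config$E, config$H, config$C, config$dh),
    weights = weights, n_permutations = config$n_permutations,
    seed = config$seed
  )
  dir.create(config$out, showWarnings = FALSE, recursive = TRUE)
  write_fixel_dir(grid, config$out, values = list(
    tstat = fit$tstat, enhanced = fit$enhanced, pvalue = fit$pvalue,
    significant = as.numeric(significant_fixels(fit$pvalue, config$alpha)),
    mask = as.numeric(mask)
  ))
  utils::write.table(data.frame(max_enhanced = fit$null_max),
                     file.path(config$out, "null_distribution.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  manifest <- list(
    parameters = unclass(config),
    input_md5 = as.list(tools::md5sum(inputs)),
    n_fixels = n_fixels(grid),
    n_masked = sum(mask),
    package_version = as.character(utils::packageVersion("fixelcfe"))
  )
  jsonlite::write_json(manifest, file.path(config$out, "run_manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(fit)
}
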