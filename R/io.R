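#' Read and write a fixel dataset directory
#'
#' On-disk layout (all tables TSV with a one-line header):
#' * `geometry.json` — grid shape, voxel size (mm), origin, and the derived
#'   4x4 voxel-to-mm affine (axis-aligned).
#' * `index.tsv` — one row per voxel that contains fixels: `i j k count
#'   offset`, with `offset` the 0-based row of the voxel's first fixel in
#'   `directions.tsv` (fixels of one voxel are contiguous, raster order).
#' * `directions.tsv` — F rows `x y z` of unit orientations, fixel id =
#'   0-based row number.
#' * `<name>.tsv` — one column `value`, F rows, per named scalar map.
#'
#' @param path directory path.
#' @param grid a [fixel_grid()].
#' @param values named list of numeric fixel maps to store alongside.
#' @return `read_fixel_dir()`: a list with `grid` and `values` (named list);
#'   `write_fixel_dir()`: `path`, invisibly.
#' @export
write_fixel_dir <- function(grid, path, values = list()) {
  stopifnot(inherits(grid, "fixel_grid"))
  dir.create(path, showWarnings = FALSE, recursive = TRUE)
  geom <- list(shape = grid$shape, voxel_size = grid$voxel_size,
               origin = grid$origin, affine = grid_affine(grid),
               voxel_convention = "half-open [lo, hi) mm extents; affine maps 0-based voxel index to voxel-center mm")
  jsonlite::write_json(geom, file.path(path, "geometry.json"),
                       auto_unbox = TRUE, digits = NA, matrix = "rowmajor")
  fx <- grid$fixels
  rle_vox <- rle(fx$voxel)
  offs <- cumsum(c(0L, head(rle_vox$lengths, -1)))
  first <- offs + 1L
  idx <- data.frame(i = fx$i[first], j = fx$j[first], k = fx$k[first],
                    count = rle_vox$lengths, offset = offs)
  utils::write.table(idx, file.path(path, "index.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  utils::write.table(data.frame(x = fx$x, y = fx$y, z = fx$z),
                     file.path(path, "directions.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  for (nm in names(values)) {
    check_map(values[[nm]], grid, nm)
    utils::write.table(data.frame(value = values[[nm]]),
                       file.path(path, paste0(nm, ".tsv")), sep = "\t",
                       quote = FALSE, row.names = FALSE)
  }
  invisible(path)
}

#' @rdname write_fixel_dir
#' @export
read_fixel_dir <- function(path) {
  geom <- jsonlite::fromJSON(file.path(path, "geometry.json"))
  idx <- utils::read.delim(file.path(path, "index.tsv"))
  dirs <- utils::read.delim(file.path(path, "directions.tsv"))
  fixels <- data.frame(
    i = rep(idx$i, idx$count), j = rep(idx$j, idx$count),
    k = rep(idx$k, idx$count), x = dirs$x, y = dirs$y, z = dirs$z
  )
  grid <- fixel_grid(geom$shape, geom$voxel_size, fixels, origin = geom$origin)
  value_files <- setdiff(list.files(path, pattern = "\\.tsv$"),
                         c("index.tsv", "directions.tsv"))
  values <- lapply(stats::setNames(nm = sub("\\.tsv$", "", value_files)),
                   function(nm) {
                     utils::read.delim(file.path(path, paste0(nm, ".tsv")))$value
                   })
  list(grid = grid, values = values)
}

#' Read and write a 3D voxel mask as NIfTI
#'
#' @param mask logical 3D array (e.g. from [voxel_mask_from_fixels()]).
#' @param grid the [fixel_grid()] supplying the geometry.
#' @param path `.nii` / `.nii.gz` path.
#' @return `read_voxel_mask_nifti()`: a logical 3D array.
#' @export
write_voxel_mask_nifti <- function(mask, grid, path) {
  stopifnot(is.array(mask), identical(dim(mask), as.integer(grid$shape)))
  img <- RNifti::asNifti(array(as.integer(mask), dim = dim(mask)))
  RNifti::pixdim(img) <- grid$voxel_size
  RNifti::writeNifti(img, path)
  invisible(path)
}

#' @rdname write_voxel_mask_nifti
#' @export
read_voxel_mask_nifti <- function(path) {
  img <- RNifti::readNifti(path)
  array(as.vector(img) != 0, dim = dim(img))
}

#' Read a whitespace-delimited design matrix or contrast vector
#'
#' One subject per row, no header; a contrast file holds a single row (or
#' column) of numbers.
#'
#' @param path text file path.
#' @return `read_design()`: numeric matrix; `read_contrast()`: numeric vector.
#' @export
read_design <- function(path) {
  as.matrix(utils::read.table(path, header = FALSE))
}

#' @rdname read_design
#' @export
read_contrast <- function(path) {
  as.numeric(as.matrix(utils::read.table(path, header = FALSE)))
}
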