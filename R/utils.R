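#' @importFrom stats rnorm sd setNames
#' @importFrom utils head tail
NULL

# Evaluate `code` under a fixed RNG seed, restoring the caller's RNG state.
with_seed <- function(seed, code) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(seed)
  force(code)
}

# Derive independent per-unit sub-seeds from a master seed so realisations
# can be generated in any order with identical results.
derive_seeds <- function(seed, n) {
  with_seed(seed, sample.int(.Machine$integer.max - 1L, n))
}

`%||%` <- function(x, y) if (is.null(x)) y else x

stop_structural <- function(...) {
  stop(sprintf(...), call. = FALSE)
}

# Axial (orientation, not direction) angle in degrees between rows of unit
# vectors `a` (matrix) and a single unit vector `b`.
axial_angle_deg <- function(a, b) {
  d <- pmin(1, abs(as.vector(a %*% b)))
  acos(d) * 180 / pi
}

# Coerce any Matrix class (incl. symmetric/triangular storage) to a general
# column-compressed sparse matrix so @x walks every stored entry.
as_gc_sparse <- function(m) {
  methods::as(methods::as(methods::as(m, "CsparseMatrix"), "generalMatrix"),
              "CsparseMatrix")
}

unit_rows <- function(m) {
  n <- sqrt(rowSums(m^2))
  m / n
}
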