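#' Tractograms
#'
#' A tractogram is an ordered collection of streamlines; each streamline is an
#' n x 3 matrix of mm coordinates (n >= 2, consecutive points distinct).
#'
#' @param streamlines a list of numeric n x 3 matrices.
#' @return an object of class `tractogram` (a list of matrices with metadata).
#' @export
tractogram <- function(streamlines) {
  if (!is.list(streamlines)) stop_structural("`streamlines` must be a list")
  streamlines <- lapply(streamlines, function(s) {
    s <- as.matrix(s)
    if (ncol(s) != 3 || nrow(s) < 2) {
      stop_structural("each streamline must be an n x 3 matrix with n >= 2")
    }
    if (!all(is.finite(s))) stop_structural("streamline coordinates must be finite")
    storage.mode(s) <- "double"
    dimnames(s) <- NULL
    if (any(rowSums((s[-1, , drop = FALSE] - s[-nrow(s), , drop = FALSE])^2) == 0)) {
      stop_structural("consecutive streamline points must be distinct")
    }
    s
  })
  structure(streamlines, class = "tractogram")
}

#' @export
print.tractogram <- function(x, ...) {
  np <- vapply(x, nrow, integer(1))
  cat(sprintf("<tractogram> %d streamlines, %d points total\n",
              length(x), sum(np)))
  invisible(x)
}

#' @export
`[.tractogram` <- function(x, i) {
  tractogram(unclass(x)[i])
}

#' Read and write MRtrix track (.tck) files
#'
#' The TCK container: an ASCII header opened by the line `mrtrix tracks`,
#' followed by `key: value` lines (at least `datatype: Float32LE`,
#' `file: . <offset>` and `count:`), closed by `END`; then, at byte
#' `<offset>`, little-endian float32 xyz triplets with a NaN triplet
#' terminating each streamline and an Inf triplet terminating the file.
#' Coordinates are mm.
#'
#' @param path file path.
#' @return `read_tck()`: a [tractogram()]; `write_tck()`: `path`, invisibly.
#' @export
read_tck <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  magic <- readLines(con, n = 1L)
  if (!identical(trimws(magic), "mrtrix tracks")) {
    stop_structural("not a TCK file (missing 'mrtrix tracks' magic): %s", path)
  }
  offset <- NA_integer_
  datatype <- NULL
  repeat {
    ln <- readLines(con, n = 1L)
    if (!length(ln)) stop_structural("TCK header not terminated by END")
    if (trimws(ln) == "END") break
    kv <- regmatches(ln, regexec("^([^:]+):\\s*(.*)$", ln))[[1]]
    if (length(kv) == 3) {
      key <- trimws(kv[2]); val <- trimws(kv[3])
      if (key == "file") {
        offset <- as.integer(sub("^\\.\\s+", "", val))
      } else if (key == "datatype") {
        datatype <- val
      }
    }
  }
  if (is.na(offset)) stop_structural("TCK header lacks a 'file: . <offset>' entry")
  if (!is.null(datatype) && datatype != "Float32LE") {
    stop_structural("unsupported TCK datatype '%s' (only Float32LE)", datatype)
  }
  seek(con, where = offset, origin = "start")
  raw_vals <- readBin(con, "numeric", n = file.size(path), size = 4L,
                      endian = "little")
  m <- matrix(raw_vals, ncol = 3, byrow = TRUE)
  is_sep <- rowSums(is.na(m)) > 0
  is_eof <- rowSums(is.infinite(m)) > 0
  stop_at <- which(is_eof)[1]
  if (!is.na(stop_at)) m <- m[seq_len(stop_at - 1), , drop = FALSE]
  grp <- cumsum(c(TRUE, head(is_sep[seq_len(nrow(m))], -1)))
  keep <- !is_sep[seq_len(nrow(m))]
  sl <- split.data.frame(m[keep, , drop = FALSE], grp[keep])
  tractogram(unname(lapply(sl, as.matrix)))
}

#' @rdname read_tck
#' @param tract a [tractogram()].
#' @export
write_tck <- function(tract, path) {
  stopifnot(inherits(tract, "tractogram"))
  header <- c("mrtrix tracks",
              "datatype: Float32LE",
              sprintf("count: %d", length(tract)),
              "timestamp: 0")
  # 'file: . <offset>' must state its own end position; fixed-width offset
  # avoids a circular computation.
  probe <- paste0(paste(c(header, "file: . OFFSET", "END"), collapse = "\n"), "\n")
  offset <- nchar(probe, type = "bytes") - nchar("OFFSET") + nchar("      ")
  header <- c(header, sprintf("file: . %6d", offset), "END")
  con <- file(path, "wb")
  on.exit(close(con))
  writeLines(header, con, sep = "\n")
  for (s in tract) {
    writeBin(as.numeric(t(s)), con, size = 4L, endian = "little")
    writeBin(rep(NaN_real_(), 3), con, size = 4L, endian = "little")
  }
  writeBin(rep(Inf, 3), con, size = 4L, endian = "little")
  invisible(path)
}

NaN_real_ <- function() NaN

#' Read and write the plain-text streamline format
#'
#' A human-readable exchange format for fixtures: one point per line as
#' whitespace-separated `x y z` (mm), streamlines separated by blank lines;
#' `#` starts a comment.
#'
#' @param path file path.
#' @return `read_tract_text()`: a [tractogram()].
#' @export
read_tract_text <- function(path) {
  lines <- trimws(readLines(path))
  lines <- lines[!startsWith(lines, "#")]
  grp <- cumsum(lines == "")
  keep <- lines != ""
  blocks <- split(lines[keep], grp[keep])
  tractogram(unname(lapply(blocks, function(b) {
    do.call(rbind, lapply(strsplit(b, "\\s+"), as.numeric))
  })))
}

#' @rdname read_tract_text
#' @param tract a [tractogram()].
#' @export
write_tract_text <- function(tract, path) {
  stopifnot(inherits(tract, "tractogram"))
  con <- file(path, "w")
  on.exit(close(con))
  for (idx in seq_along(tract)) {
    s <- tract[[idx]]
    writeLines(apply(s, 1, function(p) paste(format(p, digits = 10), collapse = " ")), con)
    if (idx < length(tract)) writeLines("", con)
  }
  invisible(path)
}
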