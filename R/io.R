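#' Write / read a 4D volume as NIfTI
#'
#' @param v A [vol4d()] (or a 3D array for maps).
#' @param path Output path (`.nii` or `.nii.gz`).
#' @return `read_volume()` returns a `vol4d`; `write_volume()` the path,
#'   invisibly.
#' @export
write_volume <- function(v, path) {
  if (inherits(v, "vol4d")) {
    img <- RNifti::asNifti(v$data)
    RNifti::pixdim(img) <- c(v$voxel_size, v$tr)
  } else {
    img <- RNifti::asNifti(unclass(v))
  }
  RNifti::writeNifti(img, path)
  invisible(path)
}

#' @rdname write_volume
#' @param tr Repetition time override if the file stores none.
#' @export
read_volume <- function(path, tr = NULL) {
  if (!file.exists(path)) stopf("file not found: %s", path)
  img <- RNifti::readNifti(path)
  arr <- array(as.numeric(img), dim = dim(img))
  pd <- RNifti::pixdim(img)
  if (length(dim(arr)) == 3L) return(arr)
  vol4d(arr, voxel_size = pd[1:3],
        tr = if (!is.null(tr)) tr else if (length(pd) >= 4 && pd[4] > 0) pd[4] else 1)
}

#' Write / read a motion-parameter file
#'
#' Plain-text, whitespace-delimited, six columns per row (translations in mm,
#' rotations in radians), one row per volume.
#'
#' @param m T x 6 motion matrix.
#' @param path File path.
#' @export
write_motion <- function(m, path) {
  m <- as_motion(m)
  utils::write.table(format(m, digits = 10, scientific = FALSE, trim = TRUE),
                     path, row.names = FALSE, col.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_motion
#' @export
read_motion <- function(path) {
  if (!file.exists(path)) stopf("file not found: %s", path)
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines))]
  vals <- lapply(seq_along(lines), function(i) {
    parts <- strsplit(trimws(lines[i]), "\\s+")[[1]]
    num <- suppressWarnings(as.numeric(parts))
    if (length(num) != 6L || anyNA(num))
      stopf("motion file %s: row %d has %d column(s), expected 6 numeric values",
            path, i, length(parts))
    num
  })
  do.call(rbind, vals)
}

#' Write / read a behavioural table (TSV)
#'
#' @param behavior Data frame with subject scores.
#' @param path File path.
#' @export
write_behavior <- function(behavior, path) {
  readr::write_tsv(behavior, path)
  invisible(path)
}

#' @rdname write_behavior
#' @export
read_behavior <- function(path) {
  if (!file.exists(path)) stopf("file not found: %s", path)
  readr::read_tsv(path, show_col_types = FALSE, progress = FALSE)
}
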