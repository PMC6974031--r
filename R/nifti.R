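#' Minimal NIfTI-1 input/output
#'
#' Single-file (`.nii`, optionally gzipped) NIfTI-1 volumes. Supports the
#' datatypes this pipeline produces and consumes: uint8, int16, int32,
#' float32 and float64. The affine is taken from the sform when
#' `sform_code > 0`, otherwise built from `pixdim`. Written files always
#' carry an sform. Conventions: the affine maps *zero-based* lattice
#' coordinates (i, j, k, 1) to mm, as NIfTI defines; the R-facing API uses
#' 1-based indices and converts internally.
#'
#' @param path file path (`.nii` or `.nii.gz`).
#' @return `read_nifti()` returns a list with elements `data` (array),
#'   `affine` (4x4), `voxel_size_mm`, `tr_s` (for 4-D files) and `dims`.
#' @name nifti-io
NULL

.nifti_dtypes <- data.frame(
  code   = c(2L, 4L, 8L, 16L, 64L),
  what   = c("integer", "integer", "integer", "double", "double"),
  size   = c(1L, 2L, 4L, 4L, 8L),
  signed = c(FALSE, TRUE, TRUE, TRUE, TRUE),
  name   = c("uint8", "int16", "int32", "float32", "float64"),
  stringsAsFactors = FALSE
)

#' @rdname nifti-io
#' @export
read_nifti <- function(path) {
  if (!file.exists(path)) abort_validation("NIfTI file not found: %s", path)
  con <- gzfile(path, "rb")
  on.exit(close(con))
  sizeof_hdr <- readBin(con, "integer", 1, size = 4, endian = "little")
  endian <- "little"
  if (sizeof_hdr != 348L) {
    sw <- .swap_int32(sizeof_hdr)
    if (sw == 348L) endian <- "big" else
      abort_validation("not a NIfTI-1 file (sizeof_hdr = %d): %s", sizeof_hdr, path)
  }
  readBin(con, "raw", 36)                                  # unused header fields
  dim0 <- readBin(con, "integer", 8, size = 2, endian = endian)
  readBin(con, "raw", 14)
  datatype <- readBin(con, "integer", 1, size = 2, endian = endian)
  readBin(con, "integer", 1, size = 2, endian = endian)    # bitpix
  readBin(con, "integer", 1, size = 2, endian = endian)    # slice_start
  pixdim <- readBin(con, "numeric", 8, size = 4, endian = endian)
  vox_offset <- readBin(con, "numeric", 1, size = 4, endian = endian)
  scl_slope <- readBin(con, "numeric", 1, size = 4, endian = endian)
  scl_inter <- readBin(con, "numeric", 1, size = 4, endian = endian)
  readBin(con, "raw", 132)                                 # bytes 120..251
  readBin(con, "integer", 1, size = 2, endian = endian)    # qform_code
  sform_code <- readBin(con, "integer", 1, size = 2, endian = endian)
  readBin(con, "numeric", 6, size = 4, endian = endian)    # quaternion + qoffset
  srow <- matrix(readBin(con, "numeric", 12, size = 4, endian = endian),
                 nrow = 3, byrow = TRUE)
  readBin(con, "raw", 16)                                  # intent_name
  magic <- rawToChar(readBin(con, "raw", 4))
  if (!startsWith(magic, "n+1") && !startsWith(magic, "ni1"))
    abort_validation("bad NIfTI magic string in %s", path)
  ndim <- dim0[1]
  if (ndim < 1 || ndim > 7)
    abort_validation("unsupported NIfTI dimensionality %d", ndim)
  dims <- dim0[2:(1 + ndim)]
  spec <- .nifti_dtypes[.nifti_dtypes$code == datatype, ]
  if (nrow(spec) == 0)
    abort_validation("unsupported NIfTI datatype code %d", datatype)
  nvox <- prod(dims)
  skip <- round(vox_offset) - 348
  if (skip > 0) readBin(con, "raw", skip)
  vals <- readBin(con, spec$what, nvox, size = spec$size,
                  signed = spec$signed, endian = endian)
  if (length(vals) < nvox)
    abort_validation("truncated NIfTI data in %s", path)
  if (!is.na(scl_slope) && scl_slope != 0 && !(scl_slope == 1 && scl_inter == 0))
    vals <- vals * scl_slope + scl_inter
  data <- array(vals, dim = dims)
  voxel_size <- abs(pixdim[2:4])
  affine <- if (sform_code > 0) rbind(srow, c(0, 0, 0, 1)) else {
    a <- diag(4); a[1, 1] <- voxel_size[1]; a[2, 2] <- voxel_size[2]
    a[3, 3] <- voxel_size[3]; a
  }
  list(data = data, affine = affine, voxel_size_mm = voxel_size,
       tr_s = if (ndim >= 4) pixdim[5] else NA_real_, dims = dims,
       datatype = spec$name)
}

.swap_int32 <- function(x) {
  b <- writeBin(as.integer(x), raw(), size = 4, endian = "little")
  readBin(rev(b), "integer", 1, size = 4, endian = "little")
}

#' @rdname nifti-io
#' @param data 3-D or 4-D numeric array.
#' @param voxel_size_mm length-3 voxel size in mm.
#' @param tr_s repetition time in seconds (4-D data).
#' @param affine optional 4x4 voxel-to-mm matrix; defaults to a diagonal
#'   affine built from `voxel_size_mm`.
#' @param datatype one of `"float32"`, `"float64"`, `"int16"`, `"int32"`,
#'   `"uint8"`.
#' @export
write_nifti <- function(data, path, voxel_size_mm = c(2, 2, 2), tr_s = 0,
                        affine = NULL, datatype = "float32") {
  dims <- dim(data)
  if (is.null(dims) || !(length(dims) %in% c(3L, 4L)))
    abort_validation("write_nifti() needs a 3-D or 4-D array")
  spec <- .nifti_dtypes[.nifti_dtypes$name == datatype, ]
  if (nrow(spec) == 0) abort_validation("unsupported datatype '%s'", datatype)
  if (is.null(affine)) {
    affine <- diag(4)
    affine[1, 1] <- voxel_size_mm[1]
    affine[2, 2] <- voxel_size_mm[2]
    affine[3, 3] <- voxel_size_mm[3]
  }
  con <- if (grepl("\\.gz$", path)) gzfile(path, "wb") else file(path, "wb")
  on.exit(close(con))
  wi <- function(x, size) writeBin(as.integer(x), con, size = size, endian = "little")
  wf <- function(x) writeBin(as.numeric(x), con, size = 4, endian = "little")
  wi(348L, 4)                                   # sizeof_hdr
  writeBin(raw(36), con)
  dim0 <- rep(1L, 8); dim0[1] <- length(dims); dim0[2:(1 + length(dims))] <- dims
  wi(dim0, 2)
  writeBin(raw(14), con)
  wi(spec$code, 2); wi(spec$size * 8L, 2); wi(0L, 2)   # datatype, bitpix, slice_start
  pixdim <- c(1, voxel_size_mm, tr_s, 0, 0, 0)
  wf(pixdim)
  wf(352); wf(1); wf(0)                         # vox_offset, scl_slope, scl_inter
  writeBin(raw(132), con)                       # bytes 120..251
  wi(0L, 2); wi(1L, 2)                          # qform_code, sform_code = 1
  wf(rep(0, 6))                                 # quaternion b,c,d + qoffset x,y,z
  wf(t(affine[1:3, ]))
  writeBin(raw(16), con)
  writeBin(c(charToRaw("n+1"), as.raw(0)), con)
  writeBin(raw(4), con)                         # extension flag
  if (spec$what == "integer") {
    writeBin(as.integer(round(data)), con, size = spec$size, endian = "little")
  } else {
    writeBin(as.numeric(data), con, size = spec$size, endian = "little")
  }
  invisible(path)
}

#' Read a BOLD series or an ROI mask from NIfTI
#'
#' @param path NIfTI file.
#' @param expect_4d if `TRUE` the file must be 4-D (a BOLD series); if
#'   `FALSE` it must be 3-D and is binarized at `> 0` into an ROI mask.
#' @param name mask name (defaults to the file stem).
#' @return for 4-D input, the `read_nifti()` list; for 3-D input an object
#'   of class `roi_mask` with fields `name`, `dims`, `voxel_size_mm`,
#'   `affine` and `indices` (1-based linear voxel indices).
#' @export
read_volume <- function(path, expect_4d = FALSE, name = NULL) {
  vol <- read_nifti(path)
  ndim <- length(vol$dims)
  if (expect_4d) {
    if (ndim != 4) abort_validation("expected 4-D volume, got %d-D: %s", ndim, path)
    return(vol)
  }
  if (ndim != 3) abort_validation("expected 3-D mask, got %d-D: %s", ndim, path)
  idx <- which(vol$data > 0)
  if (length(idx) == 0) abort_validation("mask is empty: %s", path)
  roi_mask(name %||% sub("\\.nii(\\.gz)?$", "", basename(path)),
           dims = vol$dims, voxel_size_mm = vol$voxel_size_mm,
           affine = vol$affine, indices = idx)
}

#' Construct an ROI mask
#'
#' @param name region name.
#' @param dims lattice dimensions (length 3).
#' @param voxel_size_mm voxel size in mm.
#' @param affine 4x4 voxel-to-mm affine (zero-based voxel convention).
#' @param indices 1-based linear indices of included voxels.
#' @export
roi_mask <- function(name, dims, voxel_size_mm, affine = NULL, indices) {
  dims <- as.integer(dims)
  if (length(dims) != 3) abort_validation("mask dims must have length 3")
  indices <- as.integer(indices)
  if (length(indices) == 0) abort_validation("mask '%s' has no voxels", name)
  if (any(indices < 1L | indices > prod(dims)))
    abort_validation("mask '%s' has out-of-lattice indices", name)
  if (is.null(affine)) {
    affine <- diag(4)
    diag(affine)[1:3] <- voxel_size_mm
  }
  structure(list(name = name, dims = dims,
                 voxel_size_mm = as.numeric(voxel_size_mm),
                 affine = affine, indices = sort(unique(indices))),
            class = "roi_mask")
}

#' @export
print.roi_mask <- function(x, ...) {
  cat(sprintf("<roi_mask> %s: %d voxels on %s lattice (%s mm)\n", x$name,
              length(x$indices), paste(x$dims, collapse = "x"),
              paste(x$voxel_size_mm, collapse = "x")))
  invisible(x)
}

#' Convert voxel indices to ijk triplets and mm coordinates
#'
#' `voxel_to_mm()` applies the affine to zero-based ijk coordinates;
#' `mm_to_voxel()` is its inverse.
#' @param ijk matrix (n x 3) of 1-based voxel coordinates.
#' @param affine 4x4 affine.
#' @export
voxel_to_mm <- function(ijk, affine) {
  ijk <- matrix(ijk, ncol = 3)
  xyz1 <- cbind(ijk - 1, 1) %*% t(affine)
  xyz1[, 1:3, drop = FALSE]
}

#' @rdname voxel_to_mm
#' @param xyz matrix (n x 3) of mm coordinates.
#' @export
mm_to_voxel <- function(xyz, affine) {
  xyz <- matrix(xyz, ncol = 3)
  ijk0 <- cbind(xyz, 1) %*% t(solve(affine))
  ijk0[, 1:3, drop = FALSE] + 1
}

linear_to_ijk <- function(idx, dims) {
  idx0 <- idx - 1L
  i <- idx0 %% dims[1]
  j <- (idx0 %/% dims[1]) %% dims[2]
  k <- idx0 %/% (dims[1] * dims[2])
  cbind(i, j, k) + 1L
}

ijk_to_linear <- function(ijk, dims) {
  ijk <- matrix(ijk, ncol = 3)
  (ijk[, 1] - 1L) + (ijk[, 2] - 1L) * dims[1] +
    (ijk[, 3] - 1L) * dims[1] * dims[2] + 1L
}
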