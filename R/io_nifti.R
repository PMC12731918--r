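#' Minimal NIfTI-1 volume I/O
#'
#' Reads and writes single-file NIfTI-1 (`.nii`, `.nii.gz`) volumes for
#' axis-aligned grids. The on-disk x-fastest array is converted to the
#' package's internal `(slice, row, col)` axis order; spacing is taken from
#' `pixdim` and the origin from the sform (or qform offsets) translation.
#' Rotated/oblique orientations are not supported and raise an error. No
#' pre-installed R NIfTI package is available in this stack, hence this
#' deliberately small reader/writer; it supports the datatypes the package
#' writes (uint8, int16, int32, float32, float64) and both endiannesses.
#'
#' @param path path ending in `.nii` or `.nii.gz`.
#' @param modality `"MRI"` or `"PET"` tag for the returned volume.
#' @return [read_nifti()] returns a `volume_image`.
#' @export
read_nifti <- function(path, modality = c("MRI", "PET")) {
  modality <- match.arg(modality)
  if (!file.exists(path)) stop("read_nifti: file not found: ", path)
  con <- gzfile(path, "rb")
  on.exit(close(con))
  hdr_raw <- readBin(con, "raw", n = 348L)
  if (length(hdr_raw) < 348L) stop("read_nifti: truncated header in ", path)
  endian <- .Platform$endian
  sizeof_hdr <- readBin(hdr_raw[1:4], "integer", size = 4, endian = endian)
  if (sizeof_hdr != 348L) {
    endian <- if (endian == "little") "big" else "little"
    sizeof_hdr <- readBin(hdr_raw[1:4], "integer", size = 4, endian = endian)
    if (sizeof_hdr != 348L) stop("read_nifti: not a NIfTI-1 file: ", path)
  }
  rd_i16 <- function(off, n) readBin(hdr_raw[(off + 1):(off + 2 * n)],
                                     "integer", n = n, size = 2,
                                     endian = endian)
  rd_f32 <- function(off, n) readBin(hdr_raw[(off + 1):(off + 4 * n)],
                                     "double", n = n, size = 4,
                                     endian = endian)
  magic <- rawToChar(hdr_raw[345:347])
  if (!magic %in% c("n+1", "ni1")) {
    stop("read_nifti: bad magic string in ", path)
  }
  dim_ <- rd_i16(40, 8)
  ndim <- dim_[1]
  if (ndim < 3L) dim_[(ndim + 2):8] <- 1L
  if (any(dim_[5:8] > 1L)) {
    stop("read_nifti: only 3-D volumes are supported (", path, ")")
  }
  nx <- dim_[2]; ny <- dim_[3]; nz <- dim_[4]
  datatype <- rd_i16(70, 1)
  pixdim <- rd_f32(76, 8)
  vox_offset <- rd_f32(108, 1)
  scl_slope <- rd_f32(112, 1)
  scl_inter <- rd_f32(116, 1)
  qform_code <- rd_i16(252, 1)
  sform_code <- rd_i16(254, 1)
  quatern <- rd_f32(256, 3)
  qoffset <- rd_f32(268, 3)
  srow <- rbind(rd_f32(280, 4), rd_f32(296, 4), rd_f32(312, 4))
  origin <- c(0, 0, 0)  # (z, y, x)
  if (sform_code > 0L) {
    rot <- srow[, 1:3]
    if (max(abs(rot - diag(diag(rot)))) > 1e-4 * max(abs(rot))) {
      stop("read_nifti: rotated/oblique sform not supported (", path, ")")
    }
    origin <- c(srow[3, 4], srow[2, 4], srow[1, 4])
  } else if (qform_code > 0L) {
    if (max(abs(quatern)) > 1e-6) {
      stop("read_nifti: rotated qform not supported (", path, ")")
    }
    origin <- c(qoffset[3], qoffset[2], qoffset[1])
  }
  spec <- switch(as.character(datatype),
    "2"   = list(what = "integer", size = 1, signed = FALSE),
    "4"   = list(what = "integer", size = 2, signed = TRUE),
    "8"   = list(what = "integer", size = 4, signed = TRUE),
    "16"  = list(what = "double", size = 4, signed = TRUE),
    "64"  = list(what = "double", size = 8, signed = TRUE),
    "256" = list(what = "integer", size = 1, signed = TRUE),
    "512" = list(what = "integer", size = 2, signed = FALSE),
    stop("read_nifti: unsupported datatype code ", datatype, " in ", path)
  )
  skip <- as.integer(round(vox_offset)) - 348L
  if (skip > 0L) readBin(con, "raw", n = skip)
  nvox <- as.double(nx) * ny * nz
  vals <- readBin(con, spec$what, n = nvox, size = spec$size,
                  signed = spec$signed, endian = endian)
  if (length(vals) != nvox) stop("read_nifti: truncated data in ", path)
  if (is.finite(scl_slope) && scl_slope != 0 &&
      !(scl_slope == 1 && scl_inter == 0)) {
    vals <- vals * scl_slope + scl_inter
  }
  arr <- aperm(array(as.numeric(vals), dim = c(nx, ny, nz)), c(3, 2, 1))
  volume_image(arr, spacing = c(pixdim[4], pixdim[3], pixdim[2]),
               origin = origin, modality = modality)
}

#' @rdname read_nifti
#' @param vol a `volume_image` or `binary_mask` (masks are written as 0/1
#'   uint8 volumes).
#' @return [write_nifti()] returns `path` invisibly.
#' @export
write_nifti <- function(vol, path) {
  if (inherits(vol, "binary_mask")) {
    data <- array(as.integer(vol$data), dim = dim(vol$data))
    datatype <- 2L; bitpix <- 8L
    spacing <- vol$spacing; origin <- vol$origin
  } else if (inherits(vol, "volume_image")) {
    data <- vol$data
    datatype <- 16L; bitpix <- 32L
    spacing <- vol$spacing; origin <- vol$origin
  } else {
    stop("write_nifti: `vol` must be a volume_image or binary_mask")
  }
  d <- dim(data)  # (nz, ny, nx)
  con <- if (grepl("\\.gz$", path)) gzfile(path, "wb") else file(path, "wb")
  on.exit(close(con))
  w_i32 <- function(x) writeBin(as.integer(x), con, size = 4,
                                endian = "little")
  w_i16 <- function(x) writeBin(as.integer(x), con, size = 2,
                                endian = "little")
  w_f32 <- function(x) writeBin(as.double(x), con, size = 4,
                                endian = "little")
  w_chr <- function(s, n) {
    r <- raw(n)
    b <- charToRaw(s)
    if (length(b) > 0) r[seq_along(b)] <- b
    writeBin(r, con)
  }
  w_i32(348)                         # sizeof_hdr
  writeBin(raw(36), con)             # data_type..dim_info (unused)
  w_i16(c(3, d[3], d[2], d[1], 1, 1, 1, 1))        # dim (x, y, z fastest first)
  w_f32(c(0, 0, 0)); w_i16(0)        # intent_p*, intent_code
  w_i16(datatype); w_i16(bitpix); w_i16(0)         # datatype, bitpix, slice_start
  w_f32(c(1, spacing[3], spacing[2], spacing[1], 0, 0, 0, 0))  # pixdim
  w_f32(352)                         # vox_offset
  w_f32(1); w_f32(0)                 # scl_slope, scl_inter
  w_i16(0); writeBin(raw(2), con)    # slice_end, slice_code, xyzt_units
  w_f32(c(0, 0, 0, 0))               # cal_max, cal_min, slice_duration, toffset
  w_i32(c(0, 0))                     # glmax, glmin
  w_chr("adipoquant", 80)            # descrip
  w_chr("", 24)                      # aux_file
  w_i16(0); w_i16(1)                 # qform_code, sform_code
  w_f32(c(0, 0, 0))                  # quaternions
  w_f32(c(origin[3], origin[2], origin[1]))        # qoffsets (informational)
  w_f32(c(spacing[3], 0, 0, origin[3]))            # srow_x
  w_f32(c(0, spacing[2], 0, origin[2]))            # srow_y
  w_f32(c(0, 0, spacing[1], origin[1]))            # srow_z
  w_chr("", 16)                      # intent_name
  w_chr("n+1", 4)                    # magic
  writeBin(raw(4), con)              # extension flag
  flat <- as.vector(aperm(data, c(3, 2, 1)))       # x fastest on disk
  if (datatype == 2L) {
    writeBin(as.integer(flat), con, size = 1, endian = "little")
  } else {
    writeBin(as.double(flat), con, size = 4, endian = "little")
  }
  invisible(path)
}

#' Read a NIfTI file as a binary mask
#'
#' Convenience wrapper: any nonzero voxel becomes `TRUE`.
#'
#' @inheritParams read_nifti
#' @param label label for the mask.
#' @return A `binary_mask`.
#' @export
read_nifti_mask <- function(path, label = "") {
  v <- read_nifti(path, modality = "MRI")
  binary_mask(v$data != 0, v$spacing, label = label, origin = v$origin)
}
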