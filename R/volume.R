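#' 3-D scalar volume with voxel geometry
#'
#' The common carrier for MRI and PET images. Data are stored in a fixed
#' internal axis order `(slice, row, col)`; per-axis voxel spacing and the
#' world-space position of voxel `(0, 0, 0)`'s centre are carried alongside.
#' Converters to and from on-disk axis conventions live at the I/O boundary
#' ([read_nifti()], [write_nifti()]), never in analysis code.
#'
#' @param data numeric 3-D array, indexed `[slice, row, col]`; all values
#'   must be finite.
#' @param spacing numeric length-3, voxel spacing `(dz, dy, dx)` in mm,
#'   strictly positive.
#' @param origin numeric length-3, world coordinates (mm) of the centre of
#'   voxel `(0, 0, 0)`, in `(z, y, x)` order.
#' @param modality `"MRI"` or `"PET"`.
#'
#' @return An object of class `volume_image`.
#' @export
volume_image <- function(data, spacing, origin = c(0, 0, 0),
                         modality = c("MRI", "PET")) {
  modality <- match.arg(modality)
  data <- as.array(data)
  if (length(dim(data)) != 3L) {
    stop("volume_image: `data` must be a 3-D array (slice, row, col)")
  }
  if (any(dim(data) < 1L)) stop("volume_image: all dims must be >= 1")
  if (!all(is.finite(data))) stop("volume_image: data values must be finite")
  spacing <- as.numeric(spacing)
  origin <- as.numeric(origin)
  if (length(spacing) != 3L || any(!is.finite(spacing)) || any(spacing <= 0)) {
    stop("volume_image: spacing must be 3 strictly positive finite values")
  }
  if (length(origin) != 3L || any(!is.finite(origin))) {
    stop("volume_image: origin must be 3 finite values")
  }
  structure(
    list(data = data, spacing = spacing, origin = origin, modality = modality),
    class = "volume_image"
  )
}

#' Binary mask sharing a volume's geometry
#'
#' @param data logical 3-D array `[slice, row, col]`.
#' @param spacing voxel spacing `(dz, dy, dx)` in mm.
#' @param label free-text label (e.g. `"SAT"`, `"VAT"`, `"EXT"`).
#' @param origin world position of voxel `(0,0,0)` centre, `(z, y, x)` mm.
#'
#' @return An object of class `binary_mask`.
#' @export
binary_mask <- function(data, spacing, label = "", origin = c(0, 0, 0)) {
  data <- as.array(data)
  if (length(dim(data)) != 3L) {
    stop("binary_mask: `data` must be a 3-D array (slice, row, col)")
  }
  storage.mode(data) <- "logical"
  if (anyNA(data)) stop("binary_mask: data must not contain NA")
  spacing <- as.numeric(spacing)
  if (length(spacing) != 3L || any(!is.finite(spacing)) || any(spacing <= 0)) {
    stop("binary_mask: spacing must be 3 strictly positive finite values")
  }
  structure(
    list(data = data, spacing = spacing, origin = as.numeric(origin),
         label = as.character(label)[1]),
    class = "binary_mask"
  )
}

#' @export
print.volume_image <- function(x, ...) {
  d <- dim(x$data)
  cat(sprintf("<volume_image %s> %d x %d x %d (slice x row x col), spacing %s mm\n",
              x$modality, d[1], d[2], d[3],
              paste(signif(x$spacing, 4), collapse = " x ")))
  invisible(x)
}

#' @export
print.binary_mask <- function(x, ...) {
  d <- dim(x$data)
  cat(sprintf("<binary_mask '%s'> %d x %d x %d, %d voxels set\n",
              x$label, d[1], d[2], d[3], sum(x$data)))
  invisible(x)
}

# shared-geometry check used by every voxelwise operation
check_same_geometry <- function(a, b, what = "operands") {
  if (!identical(dim(a$data), dim(b$data))) {
    stop(sprintf("geometry error: %s differ in dims (%s vs %s)", what,
                 paste(dim(a$data), collapse = "x"),
                 paste(dim(b$data), collapse = "x")))
  }
  if (max(abs(a$spacing - b$spacing)) > 1e-9) {
    stop(sprintf("geometry error: %s differ in spacing", what))
  }
  invisible(TRUE)
}

#' Voxelwise set difference of two masks
#'
#' Computes `a AND NOT b`, the mask-arithmetic primitive behind SAT
#' (external minus internal body contour) and VAT (internal minus exclusion
#' organs) depot construction.
#'
#' @param a,b `binary_mask` objects with identical dims and spacing.
#' @param label label for the result (default `a$label`).
#' @return A `binary_mask`.
#' @export
mask_and_not <- function(a, b, label = a$label) {
  stopifnot(inherits(a, "binary_mask"), inherits(b, "binary_mask"))
  check_same_geometry(a, b, "masks")
  binary_mask(a$data & !b$data, a$spacing, label = label, origin = a$origin)
}
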