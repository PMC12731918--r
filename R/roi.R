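#' Per-slice polygon contour
#'
#' A closed polygon on one axial slice, in continuous 0-based voxel
#' coordinates with pixel centres at integer positions. The polygon is
#' implicitly closed (last vertex connects to the first).
#'
#' @param slice_index 0-based slice index (integer >= 0).
#' @param vertices numeric matrix with >= 3 rows and 2 columns `(row, col)`.
#' @param label one of `"EXT"` (external body outline), `"INT"` (internal
#'   abdominal wall) or `"EXC"` (exclusion organ: kidney, spinal marrow).
#' @return An object of class `roi_contour`.
#' @export
roi_contour <- function(slice_index, vertices, label = c("EXT", "INT", "EXC")) {
  label <- match.arg(label)
  vertices <- as.matrix(vertices)
  if (nrow(vertices) < 3L) {
    stop("invalid-annotation error: contour needs >= 3 vertices")
  }
  if (ncol(vertices) != 2L || !all(is.finite(vertices))) {
    stop("invalid-annotation error: vertices must be a finite n x 2 matrix")
  }
  slice_index <- as.integer(slice_index)
  if (is.na(slice_index) || slice_index < 0L) {
    stop("invalid-annotation error: slice_index must be a non-negative integer")
  }
  structure(list(slice_index = slice_index, vertices = vertices, label = label),
            class = "roi_contour")
}

#' Annotation set over a slice range
#'
#' Bundles all polygon contours for one scan together with the slice range
#' they cover (inclusive, 0-based; anatomically the pelvic floor at L4-L5 up
#' to the diaphragm) and the voxel grid the coordinates refer to. Per slice,
#' at most one EXT and one INT contour are allowed (one body outline each);
#' multiple EXC contours (several organs) are allowed and are unioned at
#' rasterization.
#'
#' @param contours list of [roi_contour()] objects.
#' @param slice_range integer length-2 `(first, last)`, inclusive.
#' @param dims grid dims `(nz, ny, nx)`.
#' @param spacing voxel spacing `(dz, dy, dx)` mm.
#' @return An object of class `roi_set`.
#' @export
roi_set <- function(contours, slice_range, dims, spacing) {
  dims <- as.integer(dims)
  slice_range <- as.integer(slice_range)
  if (length(dims) != 3L || any(dims < 1L)) {
    stop("roi_set: dims must be 3 positive integers")
  }
  if (length(slice_range) != 2L || slice_range[1] > slice_range[2]) {
    stop("roi_set: slice_range must be (first, last) with first <= last")
  }
  if (slice_range[1] < 0L || slice_range[2] >= dims[1]) {
    stop("roi_set: slice_range must lie within the grid")
  }
  if (!is.list(contours)) stop("roi_set: contours must be a list")
  per_slice <- list()
  for (ct in contours) {
    if (!inherits(ct, "roi_contour")) {
      stop("roi_set: every element of `contours` must be an roi_contour")
    }
    if (ct$slice_index < slice_range[1] || ct$slice_index > slice_range[2]) {
      stop(sprintf("roi_set: contour on slice %d outside slice_range [%d, %d]",
                   ct$slice_index, slice_range[1], slice_range[2]))
    }
    if (ct$label %in% c("EXT", "INT")) {
      key <- paste(ct$slice_index, ct$label)
      if (!is.null(per_slice[[key]])) {
        stop(sprintf(
          "invalid-annotation error: multiple %s contours on slice %d",
          ct$label, ct$slice_index))
      }
      per_slice[[key]] <- TRUE
    }
  }
  structure(
    list(contours = contours, slice_range = slice_range,
         dims = dims, spacing = as.numeric(spacing)),
    class = "roi_set"
  )
}

#' @export
print.roi_set <- function(x, ...) {
  labs <- vapply(x$contours, `[[`, "", "label")
  cat(sprintf("<roi_set> %d contours (EXT %d, INT %d, EXC %d), slices %d..%d on %s grid\n",
              length(labs), sum(labs == "EXT"), sum(labs == "INT"),
              sum(labs == "EXC"), x$slice_range[1], x$slice_range[2],
              paste(x$dims, collapse = "x")))
  invisible(x)
}

# Even-odd (crossing-number) inside test for all pixel centres of one slice,
# vectorized over pixels. `verts` is n x 2 (row, col); returns an ny x nx
# logical matrix. A centre exactly on an edge counts as inside
# (boundary-inclusive), handled by an explicit on-segment test.
polygon_fill_slice <- function(verts, ny, nx) {
  eps <- 1e-9
  n <- nrow(verts)
  py <- rep(0:(ny - 1L), times = nx)   # row coordinate of each centre
  px <- rep(0:(nx - 1L), each = ny)    # col coordinate
  inside <- logical(ny * nx)
  on_edge <- logical(ny * nx)
  for (i in seq_len(n)) {
    j <- if (i == 1L) n else i - 1L
    y1 <- verts[i, 1]; x1 <- verts[i, 2]
    y2 <- verts[j, 1]; x2 <- verts[j, 2]
    # crossing test on the edge's half-open row interval
    crosses <- (y1 > py) != (y2 > py)
    if (any(crosses)) {
      xin <- (x2 - x1) * (py[crosses] - y1) / (y2 - y1) + x1
      hit <- px[crosses] < xin
      idx <- which(crosses)[hit]
      inside[idx] <- !inside[idx]
    }
    # boundary-inclusive: centre collinear with the edge and within its bbox
    cross <- (x2 - x1) * (py - y1) - (y2 - y1) * (px - x1)
    seg_len <- max(abs(x2 - x1), abs(y2 - y1), 1)
    col <- abs(cross) <= eps * seg_len
    if (any(col)) {
      within <- col &
        px >= pmin(x1, x2) - eps & px <= pmax(x1, x2) + eps &
        py >= pmin(y1, y2) - eps & py <= pmax(y1, y2) + eps
      on_edge <- on_edge | within
    }
  }
  matrix(inside | on_edge, nrow = ny, ncol = nx)
}

#' Rasterize one annotation label to a binary mask
#'
#' For each slice, a pixel is set iff its centre lies inside (or on the
#' boundary of) any polygon carrying `label` on that slice, using the
#' even-odd fill rule. Slices with no contour of that label are all-false;
#' multiple same-label polygons on a slice are OR-ed (EXC organs).
#'
#' @param roiset an [roi_set()].
#' @param label `"EXT"`, `"INT"` or `"EXC"`.
#' @param dims optional grid dims `(nz, ny, nx)`; defaults to the roi_set's.
#' @param spacing optional spacing; defaults to the roi_set's.
#' @return A `binary_mask` labelled with `label`.
#' @export
rasterize <- function(roiset, label = c("EXT", "INT", "EXC"),
                      dims = roiset$dims, spacing = roiset$spacing) {
  stopifnot(inherits(roiset, "roi_set"))
  label <- match.arg(label)
  dims <- as.integer(dims)
  if (!identical(dims, roiset$dims)) {
    stop("geometry error: requested grid dims do not match roi_set grid_ref")
  }
  nz <- dims[1]; ny <- dims[2]; nx <- dims[3]
  out <- array(FALSE, dim = dims)
  for (ct in roiset$contours) {
    if (ct$label != label) next
    v <- ct$vertices
    if (any(v[, 1] < 0 | v[, 1] > ny - 1 | v[, 2] < 0 | v[, 2] > nx - 1)) {
      stop(sprintf(
        "out-of-bounds error: contour vertex outside grid on slice %d",
        ct$slice_index))
    }
    s <- ct$slice_index + 1L
    out[s, , ] <- out[s, , ] | polygon_fill_slice(v, ny, nx)
  }
  binary_mask(out, spacing, label = label)
}
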