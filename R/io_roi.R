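#' Read a contour annotation file (ROI JSON)
#'
#' The on-disk schema is:
#' \preformatted{
#' {"grid": {"dims": [nz, ny, nx], "spacing_mm": [dz, dy, dx]},
#'  "slice_range": [first, last],
#'  "contours": [{"slice": 12, "label": "EXT",
#'                "vertices": [[row, col], ...]}, ...]}
#' }
#' Coordinates are 0-based voxel coordinates with pixel centres at integers.
#'
#' @param path path to a UTF-8 JSON file.
#' @return An [roi_set()].
#' @export
read_roi_json <- function(path) {
  if (!file.exists(path)) stop("read_roi_json: file not found: ", path)
  js <- tryCatch(jsonlite::fromJSON(path, simplifyMatrix = TRUE,
                                    simplifyDataFrame = FALSE),
                 error = function(e) {
                   stop("read_roi_json: malformed JSON in ", path, ": ",
                        conditionMessage(e))
                 })
  for (field in c("grid", "slice_range", "contours")) {
    if (is.null(js[[field]])) {
      stop("read_roi_json: schema error, missing field `", field, "`")
    }
  }
  for (field in c("dims", "spacing_mm")) {
    if (is.null(js$grid[[field]])) {
      stop("read_roi_json: schema error, missing field `grid.", field, "`")
    }
  }
  contours <- lapply(js$contours, function(ct) {
    for (field in c("slice", "label", "vertices")) {
      if (is.null(ct[[field]])) {
        stop("read_roi_json: schema error, missing field `contours[].",
             field, "`")
      }
    }
    v <- ct$vertices
    if (is.list(v)) v <- do.call(rbind, v)
    if (!ct$label %in% c("EXT", "INT", "EXC")) {
      stop("read_roi_json: schema error, field `contours[].label` must be ",
           "EXT, INT or EXC (got \"", ct$label, "\")")
    }
    roi_contour(ct$slice, v, ct$label)
  })
  roi_set(contours, js$slice_range, js$grid$dims, js$grid$spacing_mm)
}

#' Write an roi_set to the ROI JSON schema
#'
#' @param roiset an [roi_set()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_roi_json <- function(roiset, path) {
  stopifnot(inherits(roiset, "roi_set"))
  obj <- list(
    grid = list(dims = roiset$dims, spacing_mm = roiset$spacing),
    slice_range = roiset$slice_range,
    contours = lapply(roiset$contours, function(ct) {
      list(slice = ct$slice_index, label = ct$label,
           vertices = unname(ct$vertices))
    })
  )
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}
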