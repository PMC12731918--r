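#' Slice-level adaptive threshold policy
#'
#' On fat-phase MRI, adipose tissue is bright and lean tissue dark, so a
#' per-slice intensity threshold separates fat from non-fat within an
#' annotated region. The threshold on slice `s` is `T_s = mu_s + k * sigma_s`
#' where `mu_s` and `sigma_s` are the mean and population (1/N) standard
#' deviation of the slice's statistics region; voxels with intensity `>= T_s`
#' are kept.
#'
#' @param k SD multiplier (default 0: threshold at the slice mean, which
#'   cleanly splits a bright-fat/dark-lean bimodal mixture).
#' @param stat_region `"INT_REGION"` (statistics over pixels inside the
#'   internal abdominal contour on that slice; default, insensitive to
#'   background air) or `"WHOLE_SLICE"`.
#' @param apply_to_sat logical; also apply the threshold to the SAT ring
#'   (default `TRUE`).
#' @return An object of class `threshold_policy`.
#' @export
threshold_policy <- function(k = 0,
                             stat_region = c("INT_REGION", "WHOLE_SLICE"),
                             apply_to_sat = TRUE) {
  stat_region <- match.arg(stat_region)
  k <- as.numeric(k)
  if (length(k) != 1L || !is.finite(k)) stop("threshold_policy: k must be finite")
  structure(list(k = k, stat_region = stat_region,
                 apply_to_sat = isTRUE(apply_to_sat)),
            class = "threshold_policy")
}

#' Compute one slice's intensity threshold
#'
#' @param intensities numeric vector of MRI intensities from the slice's
#'   statistics region.
#' @param policy a [threshold_policy()].
#' @return The scalar threshold `T = mu + k * sigma` (population SD).
#' @export
slice_threshold <- function(intensities, policy = threshold_policy()) {
  intensities <- as.numeric(intensities)
  if (length(intensities) == 0L) {
    stop("empty-region error: no intensities supplied to slice_threshold")
  }
  mu <- mean(intensities)
  sigma <- sqrt(mean((intensities - mu)^2))  # population SD, pinned
  mu + policy$k * sigma
}

# per-slice keep-mask {intensity >= T_s}; stat region per policy.
# Returns NULL (caller warns / yields empty) if the stat region is empty.
slice_keep_mask <- function(mri_slice, stat_mask_slice, policy) {
  stats_px <- if (policy$stat_region == "WHOLE_SLICE") {
    as.numeric(mri_slice)
  } else {
    mri_slice[stat_mask_slice]
  }
  if (length(stats_px) == 0L) return(NULL)
  mri_slice >= slice_threshold(stats_px, policy)
}

#' Build the subcutaneous fat (SAT) depot mask
#'
#' The SAT compartment is the ring between the external body outline and the
#' internal abdominal wall: `ext AND NOT int`. When `policy$apply_to_sat` is
#' `TRUE` the slice-level intensity threshold is additionally applied so only
#' bright (fat) voxels are retained.
#'
#' @param ext,int_ rasterized EXT / INT `binary_mask`s.
#' @param mri the fat-phase MRI `volume_image` (same grid).
#' @param policy a [threshold_policy()].
#' @param slice_range optional 0-based inclusive `(first, last)`; slices
#'   outside it are forced all-false.
#' @return A `binary_mask` labelled `"SAT"`.
#' @export
build_sat_mask <- function(ext, int_, mri, policy = threshold_policy(),
                           slice_range = NULL) {
  check_same_geometry(ext, int_, "EXT/INT masks")
  if (!identical(dim(ext$data), dim(mri$data))) {
    stop("geometry error: mask dims do not match MRI dims")
  }
  base <- ext$data & !int_$data
  if (policy$apply_to_sat) {
    nz <- dim(base)[1]
    for (s in seq_len(nz)) {
      if (!any(base[s, , ])) next
      keep <- slice_keep_mask(mri$data[s, , ], int_$data[s, , ], policy)
      if (is.null(keep)) {
        # INT empty on this slice: fall back to statistics over the SAT ring
        # itself so an annotated ring is not silently dropped
        keep <- slice_keep_mask(mri$data[s, , ], base[s, , ], policy)
      }
      base[s, , ] <- base[s, , ] & keep
    }
  }
  base <- apply_slice_range(base, slice_range)
  binary_mask(base, ext$spacing, label = "SAT", origin = ext$origin)
}

#' Build the visceral fat (VAT) depot mask
#'
#' The VAT candidate region on each slice is the interior of the abdominal
#' wall minus the exclusion organs (`int AND NOT exc`; kidneys and spinal
#' marrow would otherwise contribute false FDG signal). The slice-level
#' threshold then discards low-intensity (lean) voxels, keeping only
#' high-intensity adipose tissue.
#'
#' @param int_,exc rasterized INT / EXC `binary_mask`s.
#' @inheritParams build_sat_mask
#' @return A `binary_mask` labelled `"VAT"`.
#' @export
build_vat_mask <- function(int_, exc, mri, policy = threshold_policy(),
                           slice_range = NULL) {
  check_same_geometry(int_, exc, "INT/EXC masks")
  if (!identical(dim(int_$data), dim(mri$data))) {
    stop("geometry error: mask dims do not match MRI dims")
  }
  cand <- int_$data & !exc$data
  nz <- dim(cand)[1]
  for (s in seq_len(nz)) {
    if (!any(cand[s, , ])) next
    keep <- slice_keep_mask(mri$data[s, , ], int_$data[s, , ], policy)
    if (is.null(keep)) {
      warning(sprintf(
        "build_vat_mask: empty statistics region on slice %d; VAT empty there",
        s - 1L))
      cand[s, , ] <- FALSE
    } else {
      cand[s, , ] <- cand[s, , ] & keep
    }
  }
  cand <- apply_slice_range(cand, slice_range)
  binary_mask(cand, int_$spacing, label = "VAT", origin = int_$origin)
}

apply_slice_range <- function(arr, slice_range) {
  if (is.null(slice_range)) return(arr)
  nz <- dim(arr)[1]
  keep <- seq_len(nz) - 1L >= slice_range[1] &
    seq_len(nz) - 1L <= slice_range[2]
  arr[!keep, , ] <- FALSE
  arr
}

#' Depot volume in cm^3
#'
#' Number of set voxels times the voxel volume `dz * dy * dx` (mm^3),
#' converted to cm^3.
#'
#' @param mask a `binary_mask`.
#' @return Volume in cm^3.
#' @export
depot_volume <- function(mask) {
  stopifnot(inherits(mask, "binary_mask"))
  sum(mask$data) * prod(mask$spacing) / 1000
}

#' Full volumetric + metabolic measurement of one scan
#'
#' Composes the pipeline: rasterize the EXT/INT/EXC annotations, build the
#' SAT and VAT depot masks with slice-level thresholding, compute depot
#' volumes, resample each depot mask onto the PET grid (nearest neighbour)
#' and extract global SUVmean (unweighted slice average). Slices outside the
#' annotated range contribute nothing.
#'
#' @param mri fat-phase MRI `volume_image`.
#' @param pet co-registered PET `volume_image` (shared world frame), or
#'   `NULL` to skip SUV extraction (SUV fields become `NA`).
#' @param roiset an [roi_set()] on the MRI grid.
#' @param policy a [threshold_policy()].
#' @return A one-row data.frame of class `depot_measurements` with columns
#'   `sat_volume_cm3`, `vat_volume_cm3`, `vat_sat_ratio`, `sat_suv_mean`,
#'   `vat_suv_mean`. The ratio is `NA` (undefined sentinel) when SAT volume
#'   is zero; SUV means are `NA` when the resampled depot is empty on the
#'   PET grid.
#' @export
measure_scan <- function(mri, pet, roiset, policy = threshold_policy()) {
  stopifnot(inherits(mri, "volume_image"), inherits(roiset, "roi_set"))
  if (!identical(dim(mri$data), as.integer(roiset$dims))) {
    stop("geometry error: roi_set grid_ref does not match MRI dims")
  }
  ext <- rasterize(roiset, "EXT")
  int_ <- rasterize(roiset, "INT")
  exc <- rasterize(roiset, "EXC")
  ext$origin <- int_$origin <- exc$origin <- mri$origin
  sat <- build_sat_mask(ext, int_, mri, policy, roiset$slice_range)
  vat <- build_vat_mask(int_, exc, mri, policy, roiset$slice_range)
  sat_v <- depot_volume(sat)
  vat_v <- depot_volume(vat)
  ratio <- if (sat_v > 0) vat_v / sat_v else NA_real_
  sat_suv <- vat_suv <- NA_real_
  if (!is.null(pet)) {
    stopifnot(inherits(pet, "volume_image"))
    sat_pet <- resample_mask_to_pet(sat, mri, pet)
    vat_pet <- resample_mask_to_pet(vat, mri, pet)
    sat_suv <- suv_mean(pet, sat_pet)$global_mean
    vat_suv <- suv_mean(pet, vat_pet)$global_mean
  }
  out <- data.frame(sat_volume_cm3 = sat_v, vat_volume_cm3 = vat_v,
                    vat_sat_ratio = ratio, sat_suv_mean = sat_suv,
                    vat_suv_mean = vat_suv)
  class(out) <- c("depot_measurements", class(out))
  out
}
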