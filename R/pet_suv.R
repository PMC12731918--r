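# Nearest MRI index along one axis for each PET voxel centre, in world mm.
# PET centre w maps to u = (w - mri_origin)/mri_spacing; the nearest integer
# index with ties broken toward the LOWER index is ceiling(u - 0.5).
# Indices outside [0, n-1] are flagged NA (centre outside the MRI FOV).
nn_axis_index <- function(n_to, o_to, s_to, n_from, o_from, s_from) {
  w <- o_to + (0:(n_to - 1L)) * s_to
  u <- (w - o_from) / s_from
  idx <- ceiling(u - 0.5)
  idx[idx < 0 | idx > n_from - 1L] <- NA_integer_
  as.integer(idx)
}

#' Resample a mask from the MRI grid onto the PET grid
#'
#' Each PET voxel takes the value of the MRI-grid voxel whose centre is
#' nearest in world millimetres (nearest-neighbour interpolation; ties broken
#' toward the lower index, deterministically). PET voxels whose centres fall
#' outside the MRI field of view are `FALSE`. The mask is moved to PET
#' resolution — PET activity values are never interpolated.
#'
#' @param mask `binary_mask` on the MRI grid.
#' @param mri_geom `volume_image` (or any object with `$data` dims,
#'   `$spacing`, `$origin`) defining the MRI grid.
#' @param pet_geom `volume_image` defining the target PET grid.
#' @return A `binary_mask` on the PET grid.
#' @export
resample_mask_to_pet <- function(mask, mri_geom, pet_geom) {
  stopifnot(inherits(mask, "binary_mask"))
  if (!identical(dim(mask$data), dim(mri_geom$data))) {
    stop("geometry error: mask dims do not match source grid dims")
  }
  dfrom <- dim(mri_geom$data); dto <- dim(pet_geom$data)
  iz <- nn_axis_index(dto[1], pet_geom$origin[1], pet_geom$spacing[1],
                      dfrom[1], mri_geom$origin[1], mri_geom$spacing[1])
  iy <- nn_axis_index(dto[2], pet_geom$origin[2], pet_geom$spacing[2],
                      dfrom[2], mri_geom$origin[2], mri_geom$spacing[2])
  ix <- nn_axis_index(dto[3], pet_geom$origin[3], pet_geom$spacing[3],
                      dfrom[3], mri_geom$origin[3], mri_geom$spacing[3])
  if (all(is.na(iz)) || all(is.na(iy)) || all(is.na(ix))) {
    warning("resample_mask_to_pet: PET and MRI fields of view do not overlap")
  }
  out <- array(FALSE, dim = dto)
  okz <- which(!is.na(iz)); oky <- which(!is.na(iy)); okx <- which(!is.na(ix))
  if (length(okz) && length(oky) && length(okx)) {
    sub <- mask$data[iz[okz] + 1L, iy[oky] + 1L, ix[okx] + 1L, drop = FALSE]
    out[okz, oky, okx] <- sub
  }
  binary_mask(out, pet_geom$spacing, label = mask$label,
              origin = pet_geom$origin)
}

#' Slice-wise and global SUVmean over a depot mask
#'
#' Per PET slice, the mean uptake over the mask's voxels; slices with no
#' masked voxel are excluded. The headline `global_mean` is the unweighted
#' mean of the per-slice means (slice-wise averaging); the voxel-weighted
#' pooled mean is also returned for comparison.
#'
#' @param pet PET `volume_image`.
#' @param pet_mask `binary_mask` on the same grid.
#' @return A list of class `suv_result`: `per_slice` (data.frame with
#'   `pet_slice_index` 0-based, `suv_mean`, `voxel_count`), `global_mean`
#'   (`NA` sentinel if the mask is empty), and `voxel_weighted_mean`.
#' @export
suv_mean <- function(pet, pet_mask) {
  stopifnot(inherits(pet, "volume_image"), inherits(pet_mask, "binary_mask"))
  check_same_geometry(pet, pet_mask, "PET and mask")
  nz <- dim(pet$data)[1]
  counts <- integer(nz); means <- rep(NA_real_, nz)
  for (s in seq_len(nz)) {
    m <- pet_mask$data[s, , ]
    counts[s] <- sum(m)
    if (counts[s] > 0L) means[s] <- mean(pet$data[s, , ][m])
  }
  keep <- counts > 0L
  per_slice <- data.frame(pet_slice_index = which(keep) - 1L,
                          suv_mean = means[keep],
                          voxel_count = counts[keep])
  global_mean <- if (any(keep)) mean(means[keep]) else NA_real_
  vw <- if (any(keep)) {
    sum(means[keep] * counts[keep]) / sum(counts[keep])
  } else {
    NA_real_
  }
  structure(list(per_slice = per_slice, global_mean = global_mean,
                 voxel_weighted_mean = vw),
            class = "suv_result")
}
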