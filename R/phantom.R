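#' Specification for a synthetic abdominal PET/MR phantom
#'
#' The phantom emulates the features of an annotated abdominal fat-phase
#' PET/MR scan: a bright subcutaneous fat ring between two nested elliptical
#' body contours (EXT outside, INT inside), scattered bright visceral fat
#' inside the abdominal cavity, two kidney-like ellipsoids plus one
#' spine-like posterior cylinder as exclusion organs, dark lean tissue
#' elsewhere inside INT, and a co-registered coarser PET grid whose uptake
#' is constant per tissue with visceral fat markedly hotter than
#' subcutaneous fat.
#'
#' Defaults mirror the acquisition the package targets: MRI voxel spacing
#' `(2.09, 1.39, 1.39)` mm with PET 2x coarser in-plane; test-sized grid
#' `(40, 96, 120)` (scan-scale `(100, 291, 360)` is supported but slow).
#' Intensity means `mu_fat = 900`, `mu_lean = 100` with `noise_sd = 50` are
#' artifact-level choices: the bright/dark separation is ~8 SD, matching the
#' strong fat/lean contrast of fat-phase MRI and making the mean-based
#' slice threshold analytically clean. Uptake constants `sat_uptake = 0.24`
#' and `vat_uptake = 0.75` echo typical SAT/VAT SUVmean magnitudes.
#'
#' @param dims grid dims `(nz, ny, nx)`.
#' @param mri_spacing MRI voxel spacing `(dz, dy, dx)` mm.
#' @param pet_spacing PET voxel spacing; default same `dz`, 2x in-plane.
#' @param body_semi_axes outer body ellipse semi-axes `(ry, rx)` in voxels;
#'   default scales with the grid.
#' @param taper fractional shrinkage of the body ellipse at the end slices
#'   (quadratic along z).
#' @param sat_thickness subcutaneous ring thickness in voxels.
#' @param n_vat_blobs number of random visceral fat blobs (a central
#'   visceral fat column is always present so every annotated slice carries
#'   fat).
#' @param blob_radius_range in-plane radius range (voxels) of random blobs.
#' @param mu_fat,mu_lean,mu_organ,noise_sd MRI intensity model (means and
#'   shared Gaussian SD; `noise_sd = 0` gives exact constant tissues).
#' @param sat_uptake,vat_uptake,lean_uptake PET uptake constants per tissue.
#' @param pet_noise_sd additive Gaussian noise SD on PET (default 0).
#' @param n_contour_vertices vertices per traced ellipse polygon (>= 36).
#' @param seed RNG seed making the phantom fully reproducible.
#' @return An object of class `phantom_spec`.
#' @export
phantom_spec <- function(dims = c(40, 96, 120),
                         mri_spacing = c(2.09, 1.39, 1.39),
                         pet_spacing = c(mri_spacing[1], 2 * mri_spacing[2],
                                         2 * mri_spacing[3]),
                         body_semi_axes = c(0.38 * dims[2], 0.42 * dims[3]),
                         taper = 0.15,
                         sat_thickness = max(4, round(dims[2] / 16)),
                         n_vat_blobs = 8,
                         blob_radius_range = c(2, 6),
                         mu_fat = 900, mu_lean = 100, mu_organ = 150,
                         noise_sd = 50,
                         sat_uptake = 0.24, vat_uptake = 0.75,
                         lean_uptake = 0.05,
                         pet_noise_sd = 0,
                         n_contour_vertices = 48,
                         seed = 1L) {
  spec <- list(dims = as.integer(dims), mri_spacing = as.numeric(mri_spacing),
               pet_spacing = as.numeric(pet_spacing),
               body_semi_axes = as.numeric(body_semi_axes), taper = taper,
               sat_thickness = sat_thickness, n_vat_blobs = n_vat_blobs,
               blob_radius_range = blob_radius_range,
               mu_fat = mu_fat, mu_lean = mu_lean, mu_organ = mu_organ,
               noise_sd = noise_sd, sat_uptake = sat_uptake,
               vat_uptake = vat_uptake, lean_uptake = lean_uptake,
               pet_noise_sd = pet_noise_sd,
               n_contour_vertices = as.integer(n_contour_vertices),
               seed = as.integer(seed))
  if (any(spec$dims < c(3L, 16L, 16L))) {
    stop("phantom spec error: dims too small for a body with a fat ring")
  }
  if (spec$mu_fat <= spec$mu_lean) {
    stop("phantom spec error: mu_fat must exceed mu_lean")
  }
  if (any(spec$mri_spacing <= 0) || any(spec$pet_spacing <= 0)) {
    stop("phantom spec error: spacings must be positive")
  }
  inner <- spec$body_semi_axes - spec$sat_thickness
  if (any(inner < 4)) {
    stop("phantom spec error: sat_thickness leaves no abdominal cavity")
  }
  if (spec$n_contour_vertices < 36L) {
    stop("phantom spec error: need >= 36 vertices per traced contour")
  }
  structure(spec, class = "phantom_spec")
}

# closed polygon tracing an axis-aligned ellipse, vertices (row, col)
ellipse_polygon <- function(cy, cx, ry, rx, n) {
  th <- 2 * pi * (0:(n - 1L)) / n
  cbind(cy + ry * sin(th), cx + rx * cos(th))
}

#' Generate a synthetic abdominal PET/MR phantom
#'
#' Deterministic given `spec$seed`. The ground-truth label map is derived by
#' rasterizing the emitted contours, so annotation and voxel truth are
#' consistent by construction: subcutaneous fat is exactly `EXT minus INT`,
#' exclusion organs lie strictly inside INT, and visceral fat is a subset of
#' `INT minus EXC` present on every annotated slice.
#'
#' @param spec a [phantom_spec()].
#' @return A list of class `phantom_case`: `mri` and `pet`
#'   (`volume_image`s), `truth_rois` ([roi_set()]), `truth_labels` (integer
#'   array; 0 background, 1 SAT, 2 VAT, 3 lean, 4 organ), and bookkeeping
#'   `sat_voxels`, `vat_voxels` plus the `spec`.
#' @export
generate_phantom <- function(spec = phantom_spec()) {
  stopifnot(inherits(spec, "phantom_spec"))
  set.seed(spec$seed)
  nz <- spec$dims[1]; ny <- spec$dims[2]; nx <- spec$dims[3]
  cy <- (ny - 1) / 2; cx <- (nx - 1) / 2
  slice_range <- c(1L, nz - 2L)
  slices <- slice_range[1]:slice_range[2]
  mid <- mean(slices)
  half <- max(slices) - mid
  ry_o <- spec$body_semi_axes[1]; rx_o <- spec$body_semi_axes[2]
  contours <- list()
  inner_axes <- matrix(0, nz, 2)  # per-slice inner ellipse semi-axes
  for (s in slices) {
    f <- 1 - spec$taper * ((s - mid) / half)^2
    ry <- f * ry_o; rx <- f * rx_o
    ry_i <- ry - spec$sat_thickness; rx_i <- rx - spec$sat_thickness
    inner_axes[s + 1L, ] <- c(ry_i, rx_i)
    contours <- c(contours, list(
      roi_contour(s, ellipse_polygon(cy, cx, ry, rx,
                                     spec$n_contour_vertices), "EXT"),
      roi_contour(s, ellipse_polygon(cy, cx, ry_i, rx_i,
                                     spec$n_contour_vertices), "INT")))
  }
  # exclusion organs: two kidney ellipsoids + one spine column, all inside
  # the smallest inner ellipse so EXC is strictly within INT on every slice
  min_ri <- apply(inner_axes[slices + 1L, , drop = FALSE], 2, min)
  kz <- mid; kaz <- max(2, 0.35 * (half + 1))
  organs <- list(
    list(type = "kidney", z0 = kz, az = kaz,
         y0 = cy + 0.30 * min_ri[1], x0 = cx - 0.45 * min_ri[2],
         ay = 0.18 * min_ri[1], ax = 0.14 * min_ri[2]),
    list(type = "kidney", z0 = kz, az = kaz,
         y0 = cy + 0.30 * min_ri[1], x0 = cx + 0.45 * min_ri[2],
         ay = 0.18 * min_ri[1], ax = 0.14 * min_ri[2]),
    list(type = "spine", y0 = cy + 0.65 * min_ri[1], x0 = cx,
         ay = 0.14 * min_ri[1], ax = 0.10 * min_ri[2])
  )
  for (s in slices) {
    for (og in organs) {
      if (og$type == "kidney") {
        u <- (s - og$z0) / og$az
        if (abs(u) >= 0.999) next
        g <- sqrt(1 - u^2)
        poly <- ellipse_polygon(og$y0, og$x0, g * og$ay, g * og$ax, 36L)
      } else {
        poly <- ellipse_polygon(og$y0, og$x0, og$ay, og$ax, 36L)
      }
      contours <- c(contours, list(roi_contour(s, poly, "EXC")))
    }
  }
  rois <- roi_set(contours, slice_range, spec$dims, spec$mri_spacing)
  ext <- rasterize(rois, "EXT")$data
  int_ <- rasterize(rois, "INT")$data
  exc <- rasterize(rois, "EXC")$data
  sat <- ext & !int_
  cavity <- int_ & !exc

  # visceral fat: a guaranteed central fat column plus random blobs;
  # n_vat_blobs = 0 means no visceral fat at all (core included)
  fat_vis <- array(FALSE, dim = spec$dims)
  gy <- matrix(rep(0:(ny - 1L), nx), ny, nx)
  gx <- matrix(rep(0:(nx - 1L), each = ny), ny, nx)
  n_blobs <- spec$n_vat_blobs
  if (n_blobs < 0) stop("phantom spec error: n_vat_blobs must be >= 0")
  if (n_blobs > 0) {
    for (s in slices) {
      ri <- inner_axes[s + 1L, ]
      core <- ((gy - (cy - 0.2 * ri[1])) / (0.50 * ri[1]))^2 +
        ((gx - cx) / (0.45 * ri[2]))^2 <= 1
      fat_vis[s + 1L, , ] <- core
    }
  }
  cav_idx <- which(cavity, arr.ind = TRUE)
  if (n_blobs > 0 && nrow(cav_idx) > 0) {
    centers <- cav_idx[sample.int(nrow(cav_idx), n_blobs, replace = TRUE), ,
                       drop = FALSE]
    radii <- stats::runif(n_blobs, spec$blob_radius_range[1],
                          spec$blob_radius_range[2])
    rz_scale <- spec$mri_spacing[3] / spec$mri_spacing[1]
    for (b in seq_len(n_blobs)) {
      r <- radii[b]; rz <- max(1, r * rz_scale)
      zr <- max(1L, centers[b, 1] - ceiling(rz)):
        min(nz, centers[b, 1] + ceiling(rz))
      for (s in zr) {
        u <- (s - centers[b, 1]) / rz
        if (abs(u) >= 1) next
        g <- r * sqrt(1 - u^2)
        disk <- (gy - (centers[b, 2] - 1L))^2 + (gx - (centers[b, 3] - 1L))^2 <=
          g^2
        fat_vis[s, , ] <- fat_vis[s, , ] | disk
      }
    }
  }
  vat <- fat_vis & cavity
  lean <- cavity & !vat
  labels <- array(0L, dim = spec$dims)
  labels[sat] <- 1L
  labels[vat] <- 2L
  labels[lean] <- 3L
  labels[exc & int_] <- 4L

  mri <- array(0, dim = spec$dims)
  mri[labels == 1L | labels == 2L] <- spec$mu_fat
  mri[labels == 3L] <- spec$mu_lean
  mri[labels == 4L] <- spec$mu_organ
  if (spec$noise_sd > 0) {
    mri <- mri + array(stats::rnorm(length(mri), 0, spec$noise_sd),
                       dim = spec$dims)
    mri[mri < 0] <- 0
  }
  mri_img <- volume_image(mri, spec$mri_spacing, origin = c(0, 0, 0),
                          modality = "MRI")

  # PET on its own coarser grid, centre-aligned with the MRI world frame
  pet_dims <- c(nz, ceiling(ny * spec$mri_spacing[2] / spec$pet_spacing[2]),
                ceiling(nx * spec$mri_spacing[3] / spec$pet_spacing[3]))
  mri_center <- (spec$dims - 1) / 2 * spec$mri_spacing
  # centre-aligned, then nudged half an MRI voxel in-plane so PET centres
  # coincide with MRI centres (never the midpoint knife-edge, which would
  # make nearest-neighbour ties flip under float32 header round-trips)
  pet_origin <- mri_center - (pet_dims - 1) / 2 * spec$pet_spacing +
    c(0, spec$mri_spacing[2] / 2, spec$mri_spacing[3] / 2)
  uptake_lut <- c(0, spec$sat_uptake, spec$vat_uptake, spec$lean_uptake,
                  spec$lean_uptake)  # background, SAT, VAT, lean, organ
  iz <- nn_axis_index(pet_dims[1], pet_origin[1], spec$pet_spacing[1],
                      nz, 0, spec$mri_spacing[1])
  iy <- nn_axis_index(pet_dims[2], pet_origin[2], spec$pet_spacing[2],
                      ny, 0, spec$mri_spacing[2])
  ix <- nn_axis_index(pet_dims[3], pet_origin[3], spec$pet_spacing[3],
                      nx, 0, spec$mri_spacing[3])
  pet <- array(0, dim = pet_dims)
  okz <- which(!is.na(iz)); oky <- which(!is.na(iy)); okx <- which(!is.na(ix))
  lab_sub <- labels[iz[okz] + 1L, iy[oky] + 1L, ix[okx] + 1L, drop = FALSE]
  pet[okz, oky, okx] <- uptake_lut[lab_sub + 1L]
  if (spec$pet_noise_sd > 0) {
    pet <- pet + array(stats::rnorm(length(pet), 0, spec$pet_noise_sd),
                       dim = pet_dims)
  }
  pet_img <- volume_image(pet, spec$pet_spacing, origin = pet_origin,
                          modality = "PET")

  structure(list(mri = mri_img, pet = pet_img, truth_rois = rois,
                 truth_labels = labels,
                 sat_voxels = sum(labels == 1L), vat_voxels = sum(labels == 2L),
                 spec = spec),
            class = "phantom_case")
}

#' @export
print.phantom_case <- function(x, ...) {
  cat(sprintf("<phantom_case> dims %s, SAT %d vox, VAT %d vox, seed %d\n",
              paste(x$spec$dims, collapse = "x"), x$sat_voxels, x$vat_voxels,
              x$spec$seed))
  invisible(x)
}

#' Smoothly perturb an annotation set
#'
#' Simulates an imperfect annotator or model prediction: each contour's
#' vertices are displaced radially from the polygon centroid by a smooth
#' low-frequency sinusoid along the vertex sequence with peak amplitude
#' `magnitude` voxels. Star-shaped contours (all the phantom's) remain
#' simple polygons for amplitudes small relative to their radius; vertices
#' are clamped to the grid so rasterization never goes out of bounds.
#'
#' @param rois an [roi_set()].
#' @param magnitude peak vertex displacement in voxels (0 returns the input
#'   unchanged).
#' @param seed RNG seed.
#' @return A perturbed [roi_set()].
#' @export
perturb_roi <- function(rois, magnitude, seed = 1L) {
  stopifnot(inherits(rois, "roi_set"), magnitude >= 0)
  if (magnitude == 0) return(rois)
  set.seed(seed)
  ny <- rois$dims[2]; nx <- rois$dims[3]
  contours <- lapply(rois$contours, function(ct) {
    v <- ct$vertices
    n <- nrow(v)
    ctr <- colMeans(v)
    dir <- sweep(v, 2, ctr)
    len <- sqrt(rowSums(dir^2))
    len[len == 0] <- 1
    dir <- dir / len
    f <- sample(1:3, 1)
    phi <- stats::runif(1, 0, 2 * pi)
    disp <- magnitude * sin(2 * pi * f * (seq_len(n) - 1) / n + phi)
    v2 <- v + dir * disp
    v2[, 1] <- pmin(pmax(v2[, 1], 0), ny - 1)
    v2[, 2] <- pmin(pmax(v2[, 2], 0), nx - 1)
    roi_contour(ct$slice_index, v2, ct$label)
  })
  roi_set(contours, rois$slice_range, rois$dims, rois$spacing)
}

#' Seeded validation cohort of phantoms with paired imperfect annotations
#'
#' Generates `n` phantoms with per-case anatomical variation (body size
#' jitter) and, for each, a perturbed copy of the ground-truth annotations
#' standing in for a second method (model prediction or second reader), so
#' the full evaluate-and-agree pipeline can run end to end.
#'
#' @param n number of cases (>= 2).
#' @param template a [phantom_spec()] used as the base for every case.
#' @param seed master seed; case seeds are derived from it.
#' @param perturb_magnitude vertex perturbation amplitude for the
#'   "predicted" annotations (voxels).
#' @param size_jitter multiplicative body-size jitter range.
#' @return A list of `n` entries, each `list(case = phantom_case,
#'   predicted_rois = roi_set)`.
#' @export
make_validation_cohort <- function(n, template = phantom_spec(), seed = 1L,
                                   perturb_magnitude = 1,
                                   size_jitter = c(0.85, 1.1)) {
  if (n < 2) stop("make_validation_cohort: need n >= 2")
  set.seed(seed)
  scales <- stats::runif(n, size_jitter[1], size_jitter[2])
  case_seeds <- sample.int(.Machine$integer.max %/% 2, n)
  lapply(seq_len(n), function(i) {
    sp <- template
    sp$body_semi_axes <- template$body_semi_axes * scales[i]
    sp$seed <- case_seeds[i]
    case <- generate_phantom(sp)
    pred <- perturb_roi(case$truth_rois, perturb_magnitude,
                        seed = case_seeds[i] + 7L)
    list(case = case, predicted_rois = pred)
  })
}
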