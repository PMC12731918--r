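# Small in-code fixtures shared across test files.

square_contour <- function(slice, lo, hi, label = "EXT") {
  roi_contour(slice, rbind(c(lo, lo), c(lo, hi), c(hi, hi), c(hi, lo)), label)
}

# one-slice roi_set on an nz x n x n grid
single_square_rois <- function(lo = 2, hi = 12, n = 20, nz = 1,
                               label = "EXT", slice = 0) {
  roi_set(list(square_contour(slice, lo, hi, label)),
          slice_range = c(0, nz - 1), dims = c(nz, n, n),
          spacing = c(1, 1, 1))
}

disk_mask <- function(n, r, cy = (n - 1) / 2, cx = (n - 1) / 2, nz = 1,
                      spacing = c(1, 1, 1), label = "") {
  g <- expand.grid(y = 0:(n - 1), x = 0:(n - 1))
  sl <- matrix((g$y - cy)^2 + (g$x - cx)^2 <= r^2, n, n)
  arr <- array(FALSE, dim = c(nz, n, n))
  for (s in seq_len(nz)) arr[s, , ] <- sl
  binary_mask(arr, spacing, label = label)
}

# random star-shaped polygon around (cy, cx): strictly positive smooth
# radius as a low-order Fourier series in angle
random_star_polygon <- function(cy, cx, r_base, n_vertices = 24) {
  th <- sort(stats::runif(n_vertices, 0, 2 * pi))
  r <- r_base * (1 + 0.35 * sin(2 * th + stats::runif(1, 0, 2 * pi)) +
                   0.2 * sin(3 * th + stats::runif(1, 0, 2 * pi)))
  cbind(cy + r * sin(th), cx + r * cos(th))
}

small_phantom <- function(seed = 1, noise_sd = 0, dims = c(10, 56, 72), ...) {
  generate_phantom(phantom_spec(dims = dims, noise_sd = noise_sd,
                                seed = seed, ...))
}

tiny_seg_cfg <- function(epochs = 25, ...) {
  seg_config(input_size = c(48, 64), channels = 6, epochs = epochs,
             learning_rate = 0.02, slices_per_case = 2L, ...)
}

# restrict 3-channel mask lists to given 0-based slices (for fair Dice)
keep_slices <- function(masks, slices) {
  lapply(masks, function(m) {
    keep <- array(FALSE, dim = dim(m$data))
    keep[slices + 1L, , ] <- TRUE
    m$data <- m$data & keep
    m
  })
}

truth_masks_of <- function(rois) {
  lapply(c("EXT", "INT", "EXC"), function(lb) rasterize(rois, lb))
}

heldout_masks_dice <- function(ckpt, case, cfg) {
  s <- adipoquant:::select_slices(case$rois, cfg)
  pred <- keep_slices(predict_seg_model(ckpt, case$mri, slices = s), s)
  truth <- keep_slices(truth_masks_of(case$rois), s)
  adipoquant:::masks_dice(pred, truth)
}
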