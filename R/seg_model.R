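#' Training configuration for the slice segmentation network
#'
#' The network is a small fully-convolutional encoder-decoder trained on
#' 2-D axial slices (the annotation unit): 3x3 convolution, 2x2 average
#' pool, 3x3 convolution, nearest-neighbour upsample with a skip
#' concatenation, 3x3 convolution, and a 1x1 sigmoid head with three
#' independent output channels (EXT, INT, EXC — independent sigmoids, not
#' softmax, because the labels nest spatially: EXC lies inside INT inside
#' EXT). Inputs are resized to `input_size` and z-scored per slice; the loss
#' is per-channel binary cross-entropy. Optimizer (Adam), learning rate,
#' epochs and batch size are artifact-level defaults, tunable here.
#'
#' @param input_size `(H, W)` network input, both even (default
#'   `c(224, 224)`).
#' @param channels base channel width of the encoder.
#' @param epochs,learning_rate,batch_size positive optimization
#'   hyperparameters.
#' @param seed RNG seed controlling initialization and shuffling.
#' @param slices_per_case if set, at most this many (evenly spaced)
#'   annotated slices are taken per training case; `NULL` uses all.
#' @param init `NULL` (random initialization) or a `seg_checkpoint` (or
#'   path to one) to continue from.
#' @return An object of class `seg_config`.
#' @export
seg_config <- function(input_size = c(224, 224), channels = 8,
                       epochs = 30, learning_rate = 0.01, batch_size = 8,
                       seed = 1L, slices_per_case = NULL, init = NULL) {
  input_size <- as.integer(input_size)
  if (length(input_size) != 2L || any(input_size < 8L) ||
      any(input_size %% 2L != 0L)) {
    stop("seg_config: input_size must be two even integers >= 8")
  }
  if (epochs < 1 || learning_rate <= 0 || batch_size < 1 || channels < 1) {
    stop("seg_config: hyperparameters must be positive")
  }
  structure(list(input_size = input_size, channels = as.integer(channels),
                 epochs = as.integer(epochs),
                 learning_rate = learning_rate,
                 batch_size = as.integer(batch_size), seed = as.integer(seed),
                 slices_per_case = slices_per_case, init = init,
                 n_labels = 3L, labels = c("EXT", "INT", "EXC")),
            class = "seg_config")
}

# ---- image resizing --------------------------------------------------------

#' Resize a 2-D grid
#'
#' Bilinear (images) or nearest-neighbour (label masks) resampling with
#' centre-aligned pixel coordinates.
#'
#' @param m numeric or logical matrix.
#' @param out_dim target `(rows, cols)`.
#' @param method `"bilinear"` or `"nearest"`.
#' @return A matrix of dims `out_dim`.
#' @export
resize2d <- function(m, out_dim, method = c("bilinear", "nearest")) {
  method <- match.arg(method)
  h <- nrow(m); w <- ncol(m)
  h2 <- out_dim[1]; w2 <- out_dim[2]
  sr <- (seq_len(h2) - 0.5) * h / h2 - 0.5   # source row coords, 0-based
  sc <- (seq_len(w2) - 0.5) * w / w2 - 0.5
  if (method == "nearest") {
    ri <- pmin(pmax(round(sr) + 1, 1), h)
    ci <- pmin(pmax(round(sc) + 1, 1), w)
    out <- m[ri, ci, drop = FALSE]
  } else {
    r0 <- pmin(pmax(floor(sr), 0), h - 1); r1 <- pmin(r0 + 1, h - 1)
    c0 <- pmin(pmax(floor(sc), 0), w - 1); c1 <- pmin(c0 + 1, w - 1)
    fr <- pmin(pmax(sr - r0, 0), 1); fc <- pmin(pmax(sc - c0, 0), 1)
    m00 <- m[r0 + 1, c0 + 1, drop = FALSE]; m01 <- m[r0 + 1, c1 + 1, drop = FALSE]
    m10 <- m[r1 + 1, c0 + 1, drop = FALSE]; m11 <- m[r1 + 1, c1 + 1, drop = FALSE]
    wr <- matrix(fr, h2, w2); wc <- matrix(fc, h2, w2, byrow = TRUE)
    out <- m00 * (1 - wr) * (1 - wc) + m01 * (1 - wr) * wc +
      m10 * wr * (1 - wc) + m11 * wr * wc
  }
  out
}

#' Preprocess one slice for the network
#'
#' Bilinear resize to the configured input size followed by per-slice
#' z-scoring `(x - mean) / sd` with an SD floor of `1e-8` (a constant slice
#' becomes all zeros).
#'
#' @param slice 2-D numeric matrix.
#' @param cfg a [seg_config()].
#' @return Matrix of dims `cfg$input_size`, mean ~0, SD ~1.
#' @export
preprocess_slice <- function(slice, cfg = seg_config()) {
  x <- resize2d(slice, cfg$input_size, "bilinear")
  mu <- mean(x)
  sigma <- sqrt(mean((x - mu)^2))
  (x - mu) / max(sigma, 1e-8)
}

# ---- network plumbing (im2col convolutions on BLAS) ------------------------

# 3x3 neighbourhood gather indices for an H x W grid stored column-major as
# a length-HW vector; out-of-grid neighbours point at a padding row HW+1.
neighbor_index <- function(h, w) {
  hw <- h * w
  r <- rep(seq_len(h), w); c <- rep(seq_len(w), each = h)
  idx <- matrix(hw + 1L, hw, 9L)
  j <- 0L
  for (dc in -1:1) {
    for (dr in -1:1) {
      j <- j + 1L
      nr <- r + dr; nc <- c + dc
      ok <- nr >= 1L & nr <= h & nc >= 1L & nc <= w
      idx[ok, j] <- nr[ok] + (nc[ok] - 1L) * h
    }
  }
  idx
}

pool_index <- function(h, w) {
  h2 <- h %/% 2L; w2 <- w %/% 2L
  ro <- rep(seq_len(h2), w2); co <- rep(seq_len(w2), each = h2)
  list(i00 = (2L * ro - 1L) + (2L * co - 2L) * h,
       i10 = (2L * ro) + (2L * co - 2L) * h,
       i01 = (2L * ro - 1L) + (2L * co - 1L) * h,
       i11 = (2L * ro) + (2L * co - 1L) * h)
}

upsample_index <- function(h, w) {
  h2 <- h %/% 2L
  r <- rep(seq_len(h), w); c <- rep(seq_len(w), each = h)
  ((r + 1L) %/% 2L) + (((c + 1L) %/% 2L) - 1L) * h2
}

net_geometry <- function(input_size) {
  h <- input_size[1]; w <- input_size[2]
  list(h = h, w = w, hw = h * w,
       nidx_full = neighbor_index(h, w),
       nidx_half = neighbor_index(h %/% 2L, w %/% 2L),
       pool = pool_index(h, w),
       up = upsample_index(h, w))
}

im2col <- function(f, nidx) {
  cin <- ncol(f)
  fp <- rbind(f, 0)
  big <- fp[as.vector(nidx), , drop = FALSE]     # (9*HW) x Cin, offset blocks
  dim(big) <- NULL
  matrix(big, nrow = nrow(f))                    # HW x (9*Cin)
}

col2im <- function(dp, nidx, cin) {
  hw <- nrow(dp)
  big <- matrix(dp, nrow = hw * 9L)              # (9*HW) x Cin
  out <- matrix(0, hw + 1L, cin)
  for (j in 1:9) {
    rows <- ((j - 1L) * hw + 1L):(j * hw)
    tgt <- nidx[, j]
    out[tgt, ] <- out[tgt, , drop = FALSE] + big[rows, , drop = FALSE]
  }
  out[seq_len(hw), , drop = FALSE]
}

init_weights <- function(cfg) {
  c0 <- cfg$channels
  he <- function(nin, nrow_, ncol_) {
    matrix(stats::rnorm(nrow_ * ncol_, 0, sqrt(2 / nin)), nrow_, ncol_)
  }
  list(w1 = he(9, 9L, c0),              b1 = numeric(c0),
       w2 = he(9 * c0, 9L * c0, 2L * c0), b2 = numeric(2L * c0),
       w3 = he(9 * 3 * c0, 9L * 3L * c0, c0), b3 = numeric(c0),
       w4 = he(c0, c0, 3L),             b4 = numeric(3L))
}

net_forward <- function(x, wts, geo) {
  # x: HW x 1 z-scored image
  p1 <- im2col(x, geo$nidx_full)
  h1 <- p1 %*% wts$w1
  h1 <- sweep(h1, 2, wts$b1, "+"); h1a <- pmax(h1, 0)
  pl <- geo$pool
  hp <- (h1a[pl$i00, , drop = FALSE] + h1a[pl$i10, , drop = FALSE] +
           h1a[pl$i01, , drop = FALSE] + h1a[pl$i11, , drop = FALSE]) / 4
  p2 <- im2col(hp, geo$nidx_half)
  h2 <- sweep(p2 %*% wts$w2, 2, wts$b2, "+"); h2a <- pmax(h2, 0)
  up <- h2a[geo$up, , drop = FALSE]
  cat_ <- cbind(up, h1a)
  p3 <- im2col(cat_, geo$nidx_full)
  h3 <- sweep(p3 %*% wts$w3, 2, wts$b3, "+"); h3a <- pmax(h3, 0)
  logits <- sweep(h3a %*% wts$w4, 2, wts$b4, "+")
  probs <- 1 / (1 + exp(-logits))
  list(probs = probs, cache = list(p1 = p1, h1a = h1a, hp = hp, p2 = p2,
                                   h2a = h2a, cat_ = cat_, p3 = p3,
                                   h3a = h3a))
}

net_backward <- function(probs, y, wts, geo, cache) {
  hw <- nrow(probs)
  dlogits <- (probs - y) / (hw * ncol(y))        # d(mean BCE)/dlogits
  g <- list()
  g$w4 <- t(cache$h3a) %*% dlogits
  g$b4 <- colSums(dlogits)
  dh3a <- dlogits %*% t(wts$w4)
  dh3 <- dh3a * (cache$h3a > 0)
  g$w3 <- t(cache$p3) %*% dh3
  g$b3 <- colSums(dh3)
  dcat <- col2im(dh3 %*% t(wts$w3), geo$nidx_full, ncol(cache$cat_))
  c2 <- ncol(cache$h2a)
  dup <- dcat[, seq_len(c2), drop = FALSE]
  dh1a_skip <- dcat[, (c2 + 1L):ncol(dcat), drop = FALSE]
  # nearest-upsample backward: sum over the 4 children of each coarse pixel
  pl <- geo$pool
  dh2a <- dup[pl$i00, , drop = FALSE] + dup[pl$i10, , drop = FALSE] +
    dup[pl$i01, , drop = FALSE] + dup[pl$i11, , drop = FALSE]
  dh2 <- dh2a * (cache$h2a > 0)
  g$w2 <- t(cache$p2) %*% dh2
  g$b2 <- colSums(dh2)
  dhp <- col2im(dh2 %*% t(wts$w2), geo$nidx_half, ncol(cache$hp))
  # average-pool backward
  dh1a <- matrix(0, hw, ncol(cache$h1a))
  dh1a[pl$i00, ] <- dhp / 4; dh1a[pl$i10, ] <- dhp / 4
  dh1a[pl$i01, ] <- dhp / 4; dh1a[pl$i11, ] <- dhp / 4
  dh1a <- dh1a + dh1a_skip
  dh1 <- dh1a * (cache$h1a > 0)
  g$w1 <- t(cache$p1) %*% dh1
  g$b1 <- colSums(dh1)
  g
}

bce_loss <- function(probs, y) {
  eps <- 1e-7
  p <- pmin(pmax(probs, eps), 1 - eps)
  -mean(y * log(p) + (1 - y) * log(1 - p))
}

adam_init <- function(wts) {
  list(m = lapply(wts, function(w) w * 0), v = lapply(wts, function(w) w * 0),
       t = 0)
}

adam_step <- function(wts, grads, st, lr, beta1 = 0.9, beta2 = 0.999,
                      eps = 1e-8) {
  st$t <- st$t + 1
  for (nm in names(wts)) {
    st$m[[nm]] <- beta1 * st$m[[nm]] + (1 - beta1) * grads[[nm]]
    st$v[[nm]] <- beta2 * st$v[[nm]] + (1 - beta2) * grads[[nm]]^2
    mhat <- st$m[[nm]] / (1 - beta1^st$t)
    vhat <- st$v[[nm]] / (1 - beta2^st$t)
    wts[[nm]] <- wts[[nm]] - lr * mhat / (sqrt(vhat) + eps)
  }
  list(wts = wts, st = st)
}

# ---- dataset construction --------------------------------------------------

# one training sample per annotated slice: z-scored resized image x (HW x 1)
# and resized 3-channel label matrix y (HW x 3)
case_to_samples <- function(mri, labels_by_channel, slice_indices, cfg) {
  geo_hw <- prod(cfg$input_size)
  lapply(slice_indices, function(s) {
    x <- preprocess_slice(mri$data[s + 1L, , ], cfg)
    y <- matrix(0, geo_hw, 3L)
    for (ch in 1:3) {
      lab <- resize2d(labels_by_channel[[ch]][s + 1L, , ] * 1,
                      cfg$input_size, "nearest")
      y[, ch] <- as.numeric(lab)
    }
    list(x = matrix(as.numeric(x), ncol = 1L), y = y)
  })
}

select_slices <- function(rois, cfg) {
  s <- rois$slice_range[1]:rois$slice_range[2]
  if (!is.null(cfg$slices_per_case) && length(s) > cfg$slices_per_case) {
    s <- s[unique(round(seq(1, length(s), length.out = cfg$slices_per_case)))]
  }
  s
}

cases_to_dataset <- function(cases, cfg) {
  out <- list()
  for (case in cases) {
    labs <- lapply(c("EXT", "INT", "EXC"),
                   function(lb) rasterize(case$rois, lb)$data)
    out <- c(out, case_to_samples(case$mri, labs, select_slices(case$rois, cfg),
                                  cfg))
  }
  out
}

# ---- training / prediction -------------------------------------------------

train_on_dataset <- function(dataset, cfg, wts = NULL, version = "V1",
                             fingerprint = NA_character_) {
  if (length(dataset) == 0L) {
    stop("configuration error: empty training set")
  }
  set.seed(cfg$seed)
  geo <- net_geometry(cfg$input_size)
  if (is.null(wts)) wts <- init_weights(cfg)
  st <- adam_init(wts)
  n <- length(dataset)
  log <- data.frame(epoch = integer(0), loss = numeric(0))
  for (ep in seq_len(cfg$epochs)) {
    ord <- sample.int(n)
    ep_loss <- 0
    b <- 0L
    while (b < n) {
      take <- ord[(b + 1L):min(b + cfg$batch_size, n)]
      b <- b + length(take)
      acc <- NULL
      for (i in take) {
        smp <- dataset[[i]]
        fw <- net_forward(smp$x, wts, geo)
        ep_loss <- ep_loss + bce_loss(fw$probs, smp$y)
        g <- net_backward(fw$probs, smp$y, wts, geo, fw$cache)
        acc <- if (is.null(acc)) g else Map(`+`, acc, g)
      }
      acc <- lapply(acc, function(x) x / length(take))
      upd <- adam_step(wts, acc, st, cfg$learning_rate)
      wts <- upd$wts; st <- upd$st
    }
    log <- rbind(log, data.frame(epoch = ep, loss = ep_loss / n))
  }
  structure(list(weights = wts, config = cfg, version = version,
                 training_fingerprint = fingerprint, n_samples = n,
                 log = log),
            class = "seg_checkpoint")
}

#' Train the slice segmentation network
#'
#' @param cases list of training cases, each `list(mri = volume_image,
#'   rois = roi_set)`; label masks are rasterized from the annotations.
#' @param cfg a [seg_config()]. With `cfg$init` set to a checkpoint (or its
#'   path), training continues from those weights — the staged V1 -> V2 ->
#'   V3 initialization scheme.
#' @param version version tag recorded in the checkpoint.
#' @return A `seg_checkpoint`: network weights, the config snapshot, a
#'   fingerprint of the training set, the version tag and a per-epoch mean
#'   loss log (`$log`).
#' @export
train_seg_model <- function(cases, cfg = seg_config(), version = "V1") {
  if (length(cases) == 0L) stop("configuration error: no training cases")
  dataset <- cases_to_dataset(cases, cfg)
  wts <- NULL
  if (!is.null(cfg$init)) {
    ckpt <- if (is.character(cfg$init)) load_checkpoint(cfg$init) else cfg$init
    stopifnot(inherits(ckpt, "seg_checkpoint"))
    if (!identical(ckpt$config$input_size, cfg$input_size) ||
        !identical(ckpt$config$channels, cfg$channels)) {
      stop("configuration error: init checkpoint geometry mismatch")
    }
    wts <- ckpt$weights
  }
  fp <- sprintf("n_cases=%d;n_slices=%d", length(cases), length(dataset))
  train_on_dataset(dataset, cfg, wts, version, fp)
}

#' Predict annotation masks for a volume
#'
#' Runs the network slice by slice: preprocess, forward pass, sigmoid,
#' threshold at 0.5, nearest-neighbour resize back to the native in-plane
#' size.
#'
#' @param checkpoint a `seg_checkpoint`.
#' @param mri a `volume_image`.
#' @param slices 0-based slice indices to predict (default all).
#' @return Named list of three `binary_mask`s (`EXT`, `INT`, `EXC`) on the
#'   MRI grid.
#' @export
predict_seg_model <- function(checkpoint, mri, slices = NULL) {
  stopifnot(inherits(checkpoint, "seg_checkpoint"),
            inherits(mri, "volume_image"))
  cfg <- checkpoint$config
  geo <- net_geometry(cfg$input_size)
  d <- dim(mri$data)
  if (is.null(slices)) slices <- 0:(d[1] - 1L)
  masks <- lapply(1:3, function(i) array(FALSE, dim = d))
  for (s in slices) {
    x <- preprocess_slice(mri$data[s + 1L, , ], cfg)
    fw <- net_forward(matrix(as.numeric(x), ncol = 1L), checkpoint$weights,
                      geo)
    for (ch in 1:3) {
      pm <- matrix(fw$probs[, ch] >= 0.5, cfg$input_size[1],
                   cfg$input_size[2])
      masks[[ch]][s + 1L, , ] <- resize2d(pm, d[2:3], "nearest") > 0.5
    }
  }
  out <- lapply(1:3, function(ch) {
    binary_mask(masks[[ch]], mri$spacing, label = cfg$labels[ch],
                origin = mri$origin)
  })
  names(out) <- cfg$labels
  out
}

#' Save / load a model checkpoint
#'
#' Round-trips bit-identically: a loaded checkpoint reproduces identical
#' predictions on any fixed input.
#'
#' @param checkpoint a `seg_checkpoint`.
#' @param path file path (`.rds`).
#' @return `save_checkpoint` returns `path` invisibly; `load_checkpoint`
#'   returns the checkpoint.
#' @export
save_checkpoint <- function(checkpoint, path) {
  stopifnot(inherits(checkpoint, "seg_checkpoint"))
  saveRDS(checkpoint, path)
  invisible(path)
}

#' @rdname save_checkpoint
#' @export
load_checkpoint <- function(path) {
  ckpt <- readRDS(path)
  if (!inherits(ckpt, "seg_checkpoint")) {
    stop("load_checkpoint: not a seg_checkpoint file")
  }
  ckpt
}

# pooled Dice of a predicted 3-channel mask set against truth masks
masks_dice <- function(pred, truth) {
  num <- 0; den <- 0
  for (ch in seq_along(pred)) {
    num <- num + 2 * sum(pred[[ch]]$data & truth[[ch]]$data)
    den <- den + sum(pred[[ch]]$data) + sum(truth[[ch]]$data)
  }
  if (den == 0) 1 else num / den
}

#' Closed-loop annotate-correct-retrain harness
#'
#' Desk-scale analog of iterative model refinement: round 1 trains on the
#' first batch's manual (ground-truth) annotations; each later round first
#' predicts the new batch with the previous checkpoint, an oracle
#' "expert corrector" replaces any predicted label whose Dice against
#' ground truth falls below `dice_threshold` with the ground truth, and the
#' model is retrained — initialized from the previous round's weights — on
#' the union of all corrected batches so far.
#'
#' @param rounds list (length >= 2) of case batches; each batch is a list of
#'   `list(mri = volume_image, rois = roi_set)` with `rois` the ground
#'   truth.
#' @param cfg a [seg_config()].
#' @param dice_threshold per-label correction threshold in `[0, 1]`
#'   (1 means every label is replaced by ground truth).
#' @return List of one `seg_checkpoint` per round, tagged `V1`, `V2`, ...
#' @export
closed_loop_train <- function(rounds, cfg = seg_config(),
                              dice_threshold = 0.9) {
  if (length(rounds) < 2L) stop("closed_loop_train: need >= 2 rounds")
  checkpoints <- list()
  dataset <- list()
  ckpt <- NULL
  for (r in seq_along(rounds)) {
    batch <- rounds[[r]]
    for (case in batch) {
      truth_masks <- lapply(c("EXT", "INT", "EXC"),
                            function(lb) rasterize(case$rois, lb))
      if (r == 1L || is.null(ckpt)) {
        labs <- lapply(truth_masks, `[[`, "data")
      } else {
        pred <- predict_seg_model(ckpt, case$mri,
                                  slices = select_slices(case$rois, cfg))
        labs <- lapply(1:3, function(ch) {
          if (dice(pred[[ch]], truth_masks[[ch]]) < dice_threshold) {
            truth_masks[[ch]]$data
          } else {
            pred[[ch]]$data
          }
        })
      }
      dataset <- c(dataset,
                   case_to_samples(case$mri, labs,
                                   select_slices(case$rois, cfg), cfg))
    }
    cfg_r <- cfg
    cfg_r$seed <- cfg$seed + r
    ckpt <- train_on_dataset(dataset, cfg_r,
                             wts = if (is.null(ckpt)) NULL else ckpt$weights,
                             version = paste0("V", r),
                             fingerprint = sprintf("round=%d;n_slices=%d", r,
                                                   length(dataset)))
    checkpoints[[r]] <- ckpt
  }
  checkpoints
}
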