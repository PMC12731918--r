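# Independent brute-force oracles. These deliberately use different
# algorithms from the package code paths they check.

# winding-number point-in-polygon (angle summation), boundary-inclusive.
# verts: n x 2 (row, col); point (py, px). Independent of the package's
# even-odd crossing implementation; agrees with it on simple polygons.
oracle_point_in_polygon <- function(verts, py, px) {
  n <- nrow(verts)
  eps <- 1e-9
  total <- 0
  for (i in seq_len(n)) {
    j <- if (i == n) 1L else i + 1L
    ay <- verts[i, 1] - py; ax <- verts[i, 2] - px
    by <- verts[j, 1] - py; bx <- verts[j, 2] - px
    # on-segment check
    cross <- ax * by - ay * bx
    dot <- ax * bx + ay * by
    la <- sqrt(ax^2 + ay^2); lb <- sqrt(bx^2 + by^2)
    if (la < eps || lb < eps) return(TRUE)                 # on a vertex
    if (abs(cross) < eps * max(la, lb) && dot <= eps) return(TRUE)  # on edge
    total <- total + atan2(cross, dot)
  }
  abs(total) > pi  # winding number != 0
}

oracle_rasterize_slice <- function(verts, ny, nx) {
  out <- matrix(FALSE, ny, nx)
  for (r in 0:(ny - 1)) {
    for (c in 0:(nx - 1)) {
      out[r + 1, c + 1] <- oracle_point_in_polygon(verts, r, c)
    }
  }
  out
}

# brute-force 3x3 morphology on a logical matrix, FALSE padding
oracle_morph3x3 <- function(m, op) {
  ny <- nrow(m); nx <- ncol(m)
  out <- matrix(FALSE, ny, nx)
  for (r in 1:ny) {
    for (c in 1:nx) {
      vals <- logical(0)
      for (dr in -1:1) {
        for (dc in -1:1) {
          rr <- r + dr; cc <- c + dc
          vals <- c(vals, if (rr >= 1 && rr <= ny && cc >= 1 && cc <= nx) {
            m[rr, cc]
          } else {
            FALSE
          })
        }
      }
      out[r, c] <- if (op == "dilate") any(vals) else all(vals)
    }
  }
  out
}

oracle_contour_slice <- function(m) {
  oracle_morph3x3(m, "dilate") & !oracle_morph3x3(m, "erode")
}

# exhaustive nearest-centre search in world mm over all source voxels
oracle_resample <- function(mask_arr, from_spacing, from_origin,
                            to_dims, to_spacing, to_origin) {
  dfrom <- dim(mask_arr)
  centers <- expand.grid(z = 0:(dfrom[1] - 1), y = 0:(dfrom[2] - 1),
                         x = 0:(dfrom[3] - 1))
  cw <- cbind(from_origin[1] + centers$z * from_spacing[1],
              from_origin[2] + centers$y * from_spacing[2],
              from_origin[3] + centers$x * from_spacing[3])
  out <- array(FALSE, dim = to_dims)
  for (z in 0:(to_dims[1] - 1)) {
    for (y in 0:(to_dims[2] - 1)) {
      for (x in 0:(to_dims[3] - 1)) {
        w <- c(to_origin[1] + z * to_spacing[1],
               to_origin[2] + y * to_spacing[2],
               to_origin[3] + x * to_spacing[3])
        d2 <- (cw[, 1] - w[1])^2 + (cw[, 2] - w[2])^2 + (cw[, 3] - w[3])^2
        # outside FOV if the centre is beyond half a voxel of the nearest
        # centre along any axis
        uz <- (w[1] - from_origin[1]) / from_spacing[1]
        uy <- (w[2] - from_origin[2]) / from_spacing[2]
        ux <- (w[3] - from_origin[3]) / from_spacing[3]
        if (uz <= -0.5 || uz > dfrom[1] - 0.5 || uy <= -0.5 ||
            uy > dfrom[2] - 0.5 || ux <= -0.5 || ux > dfrom[3] - 0.5) next
        best <- which(d2 == min(d2))
        # ties toward the lower index: candidates are ordered z-fastest;
        # pick the one with smallest (z, y, x) index tuple
        k <- best[1]
        out[z + 1, y + 1, x + 1] <- mask_arr[centers$z[k] + 1,
                                             centers$y[k] + 1,
                                             centers$x[k] + 1]
      }
    }
  }
  out
}

# ICC(2,1) via R's ANOVA machinery (different code path from the package's
# direct sums-of-squares computation)
oracle_icc_21 <- function(a, b) {
  n <- length(a)
  df <- data.frame(y = c(a, b),
                   subj = factor(rep(seq_len(n), 2)),
                   rater = factor(rep(1:2, each = n)))
  ms <- anova(lm(y ~ subj + rater, data = df))$`Mean Sq`
  msr <- ms[1]; msc <- ms[2]; mse <- ms[3]
  k <- 2
  (msr - mse) / (msr + (k - 1) * mse + (k / n) * (msc - mse))
}

# full 2^n sign-enumeration Wilcoxon oracle (midranks, negative-rank sum,
# doubled smaller tail)
oracle_wilcoxon <- function(d) {
  d <- d[d != 0]
  n <- length(d)
  r <- rank(abs(d))
  w_neg <- sum(r[d < 0])
  signs <- as.matrix(expand.grid(rep(list(c(0, 1)), n)))
  null_w <- as.vector(signs %*% r)
  obs_min <- min(w_neg, sum(r) - w_neg)
  min(1, 2 * mean(null_w <= obs_min))
}

# direct-formula Dice on arrays
oracle_dice <- function(a, b) {
  if (sum(a) + sum(b) == 0) return(1)
  2 * sum(a & b) / (sum(a) + sum(b))
}
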