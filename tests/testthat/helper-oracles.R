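# Independent brute-force oracles, deliberately written with plain scalar
# loops so they share no code path with the package implementation.

# 8-connected labelling by explicit stack-based flood fill.
flood_fill_label <- function(mask) {
  h <- nrow(mask); w <- ncol(mask)
  lab <- matrix(0L, h, w)
  nxt <- 0L
  for (r in seq_len(h)) for (c in seq_len(w)) {
    if (mask[r, c] && lab[r, c] == 0L) {
      nxt <- nxt + 1L
      stack <- list(c(r, c))
      lab[r, c] <- nxt
      while (length(stack)) {
        p <- stack[[length(stack)]]
        stack[[length(stack)]] <- NULL
        for (dr in -1:1) for (dc in -1:1) {
          rr <- p[1] + dr; cc <- p[2] + dc
          if (rr >= 1 && rr <= h && cc >= 1 && cc <= w &&
              mask[rr, cc] && lab[rr, cc] == 0L) {
            lab[rr, cc] <- nxt
            stack[[length(stack) + 1L]] <- c(rr, cc)
          }
        }
      }
    }
  }
  lab
}

# Exhaustive Otsu: try every cut point, compute the between-class variance
# from first principles, return the smallest maximiser.
otsu_exhaustive <- function(counts) {
  best_t <- NA_integer_; best_v <- -Inf
  for (t in 1:255) {
    n_lo <- 0; s_lo <- 0; n_hi <- 0; s_hi <- 0
    for (v in 0:255) {
      if (v < t) { n_lo <- n_lo + counts[v + 1]; s_lo <- s_lo + v * counts[v + 1] }
      else { n_hi <- n_hi + counts[v + 1]; s_hi <- s_hi + v * counts[v + 1] }
    }
    if (n_lo == 0 || n_hi == 0) next
    bcv <- n_lo * n_hi * (s_lo / n_lo - s_hi / n_hi)^2
    if (bcv > best_v + 1e-9) { best_v <- bcv; best_t <- t }
  }
  best_t
}

# Scalar even-odd point-in-polygon with inclusive boundary.
point_in_polygon_scalar <- function(px, py, v) {
  n <- nrow(v)
  inside <- FALSE
  eps <- 1e-9
  j <- n
  for (i in seq_len(n)) {
    xi <- v[i, 1]; yi <- v[i, 2]; xj <- v[j, 1]; yj <- v[j, 2]
    # on-boundary check
    cross <- (px - xi) * (yj - yi) - (py - yi) * (xj - xi)
    if (abs(cross) <= eps * max(1, sqrt((xj - xi)^2 + (yj - yi)^2)) &&
        px >= min(xi, xj) - eps && px <= max(xi, xj) + eps &&
        py >= min(yi, yj) - eps && py <= max(yi, yj) + eps) {
      return(TRUE)
    }
    if ((yi > py) != (yj > py) &&
        px < (xj - xi) * (py - yi) / (yj - yi) + xi) {
      inside <- !inside
    }
    j <- i
  }
  inside
}

# ---- fixture builders ------------------------------------------------------

make_disk_mask <- function(h, w, cx, cy, r) {
  m <- matrix(FALSE, h, w)
  for (row in seq_len(h)) for (col in seq_len(w)) {
    if ((col - 1 - cx)^2 + (row - 1 - cy)^2 <= r^2) m[row, col] <- TRUE
  }
  m
}

random_mask <- function(h = 64, w = 64, p = 0.25) {
  matrix(stats::runif(h * w) < p, h, w)
}

random_blob_mask <- function(h = 64, w = 64, n_blobs = 8) {
  m <- matrix(FALSE, h, w)
  for (i in seq_len(n_blobs)) {
    cx <- stats::runif(1, 3, w - 4); cy <- stats::runif(1, 3, h - 4)
    r <- stats::runif(1, 1.5, 4)
    m <- m | make_disk_mask(h, w, cx, cy, r)
  }
  m
}

# synthetic constant RGB stack for io tests
constant_stack <- function(h = 4, w = 4, rgb = c(10, 20, 30), n_slices = 1) {
  planes <- lapply(seq_len(n_slices), function(s) {
    a <- array(0L, c(h, w, 3))
    for (k in 1:3) a[, , k] <- as.integer(rgb[k])
    a
  })
  fluorquant:::new_rgb_stack(planes)
}
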