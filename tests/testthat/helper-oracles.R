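# Independent oracles, deliberately written on different code paths than the
# package implementation (scalar loops, naive enumeration).

# Textbook sRGB -> CIELab for a single pixel, published D65 constants.
oracle_lab <- function(r, g, b) {
  expand <- function(u) {
    u <- u / 255
    if (u <= 0.04045) u / 12.92 else ((u + 0.055) / 1.055)^2.4
  }
  rl <- expand(r); gl <- expand(g); bl <- expand(b)
  x <- 0.4124564 * rl + 0.3575761 * gl + 0.1804375 * bl
  y <- 0.2126729 * rl + 0.7151522 * gl + 0.0721750 * bl
  z <- 0.0193339 * rl + 0.1191920 * gl + 0.9503041 * bl
  f <- function(t) if (t > 216 / 24389) t^(1 / 3) else (24389 / 27 * t + 16) / 116
  fx <- f(x / 0.95047); fy <- f(y / 1); fz <- f(z / 1.08883)
  c(L = 116 * fy - 16, a = 500 * (fx - fy), b = 200 * (fy - fz))
}

# Naive per-pixel even-odd test: count ray crossings one edge at a time.
oracle_point_in_polygon <- function(x, y, vx, vy) {
  n <- length(vx)
  crossings <- 0L
  for (i in seq_len(n)) {
    j <- if (i == 1L) n else i - 1L
    y1 <- vy[j]; y2 <- vy[i]
    if ((y1 > y) != (y2 > y)) {
      xint <- vx[j] + (y - y1) * (vx[i] - vx[j]) / (y2 - y1)
      if (x < xint) crossings <- crossings + 1L
    }
  }
  crossings %% 2L == 1L
}

oracle_rasterize <- function(vx, vy, shape) {
  mask <- matrix(FALSE, shape[1], shape[2])
  for (row in seq_len(shape[1])) {
    for (col in seq_len(shape[2])) {
      mask[row, col] <- oracle_point_in_polygon(col - 1, row - 1, vx, vy)
    }
  }
  mask
}

# Exhaustive Otsu: try every interior bin edge, recompute class statistics
# from scratch by splitting the raw vector.
oracle_otsu <- function(values, n_bins) {
  edges <- seq(min(values), max(values), length.out = n_bins + 1)
  cand <- edges[-c(1, n_bins + 1)]
  best_t <- NA_real_; best_v <- -Inf
  for (t in cand) {
    lower <- values[values <= t]; upper <- values[values > t]
    if (length(lower) == 0L || length(upper) == 0L) next
    w0 <- length(lower) / length(values)
    v <- w0 * (1 - w0) * (mean(lower) - mean(upper))^2
    if (v > best_v + 1e-12) { best_v <- v; best_t <- t }
  }
  list(threshold = best_t, inter_class_variance = best_v)
}

# AUC by exhaustive enumeration of all malignant x benign pairs.
oracle_auc <- function(scores, labels) {
  sm <- scores[labels == "malignant"]
  sb <- scores[labels == "benign"]
  total <- 0
  for (m in sm) for (b in sb) {
    total <- total + if (m > b) 1 else if (m == b) 0.5 else 0
  }
  total / (length(sm) * length(sb))
}

# ICC(2,1) through base aov(), an independent route to the mean squares.
oracle_icc21 <- function(mat) {
  n <- nrow(mat); k <- ncol(mat)
  d <- data.frame(
    y = as.vector(mat),
    lesion = factor(rep(seq_len(n), times = k)),
    rater = factor(rep(seq_len(k), each = n))
  )
  ms <- summary(stats::aov(y ~ lesion + rater, data = d))[[1]][, "Mean Sq"]
  msr <- ms[1]; msc <- ms[2]; mse <- ms[3]
  (msr - mse) / (msr + (k - 1) * mse + k * (msc - mse) / n)
}

# small helpers used across test files
solid_mask <- function(shape, rows, cols) {
  m <- matrix(FALSE, shape[1], shape[2])
  m[rows, cols] <- TRUE
  m
}

flat_image <- function(rgb, h = 8, w = 8) {
  arr <- array(0, dim = c(h, w, 3))
  for (ch in 1:3) arr[, , ch] <- rgb[ch]
  rgb_image(arr)
}
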