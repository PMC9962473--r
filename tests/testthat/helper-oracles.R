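# Independent oracle implementations used to cross-check the package's
# image operations. Each is written as a direct, brute-force second path
# and stays independent of the code it checks.

# exhaustive Otsu: try every threshold T, compute between-class variance
# from the two class means directly
otsu_bruteforce <- function(gray) {
  g <- as.integer(round(gray))
  best_t <- NA_integer_; best_v <- -Inf
  for (t in 0:254) {
    lo <- g[g <= t]; hi <- g[g > t]
    if (!length(lo) || !length(hi)) next
    w0 <- length(lo) / length(g); w1 <- 1 - w0
    v <- w0 * w1 * (mean(lo) - mean(hi))^2
    if (v > best_v + 1e-12) { best_v <- v; best_t <- t }
  }
  best_t
}

# queue-based flood fill labeling
floodfill_components <- function(mask, connectivity = 8) {
  h <- nrow(mask); w <- ncol(mask)
  lab <- matrix(0L, h, w)
  nb <- if (connectivity == 8)
    expand.grid(dr = -1:1, dc = -1:1)[-5, ] else
    data.frame(dr = c(-1, 1, 0, 0), dc = c(0, 0, -1, 1))
  cur <- 0L
  for (c0 in seq_len(w)) for (r0 in seq_len(h)) {
    if (mask[r0, c0] == 1 && lab[r0, c0] == 0L) {
      cur <- cur + 1L
      queue <- list(c(r0, c0)); lab[r0, c0] <- cur
      while (length(queue)) {
        p <- queue[[1]]; queue <- queue[-1]
        for (k in seq_len(nrow(nb))) {
          r <- p[1] + nb$dr[k]; c <- p[2] + nb$dc[k]
          if (r >= 1 && r <= h && c >= 1 && c <= w &&
              mask[r, c] == 1 && lab[r, c] == 0L) {
            lab[r, c] <- cur
            queue[[length(queue) + 1L]] <- c(r, c)
          }
        }
      }
    }
  }
  lab
}

# dilation as an explicit Minkowski sum: union of all square-offset shifts
minkowski_dilate <- function(mask, radius) {
  h <- nrow(mask); w <- ncol(mask)
  out <- matrix(0, h, w)
  for (dr in -radius:radius) for (dc in -radius:radius) {
    rs <- max(1, 1 + dr):min(h, h + dr)
    cs <- max(1, 1 + dc):min(w, w + dc)
    sub <- matrix(0, h, w)
    sub[rs, cs] <- mask[rs - dr, cs - dc]
    out[sub == 1] <- 1
  }
  out
}

# number of 8-neighbors of every pixel
neighbor_counts <- function(mask) {
  h <- nrow(mask); w <- ncol(mask)
  acc <- matrix(0, h, w)
  for (dr in -1:1) for (dc in -1:1) {
    if (dr == 0 && dc == 0) next
    rs <- max(1, 1 + dr):min(h, h + dr)
    cs <- max(1, 1 + dc):min(w, w + dc)
    sub <- matrix(0, h, w)
    sub[rs, cs] <- mask[rs - dr, cs - dc]
    acc <- acc + sub
  }
  acc
}

# skeleton endpoints: foreground pixels with exactly one 8-neighbor
count_endpoints <- function(mask) sum(mask == 1 & neighbor_counts(mask) == 1)

random_mask <- function(h, w, p = 0.4, seed = 1) {
  set.seed(seed)
  matrix(as.numeric(stats::runif(h * w) < p), h, w)
}

random_gray <- function(h, w, seed = 1) {
  set.seed(seed)
  matrix(sample(0:255, h * w, replace = TRUE), h, w)
}

random_rgb <- function(h, w, seed = 1) {
  set.seed(seed)
  array(sample(0:255, h * w * 3, replace = TRUE), c(h, w, 3))
}
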