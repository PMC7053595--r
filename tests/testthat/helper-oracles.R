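# Independent brute-force reference implementations used to check the
# package's fast paths. These deliberately share no code with R/.

# half-sample reflection of index i (1-based) into [1, n]
reflect1 <- function(i, n) {
  if (n == 1) return(1L)
  while (i < 1 || i > n) {
    if (i < 1) i <- 1 - i
    if (i > n) i <- 2 * n + 1 - i
  }
  i
}

# per-pixel disk median with reflective border, via sort()
oracle_disk_median <- function(m, radius) {
  nr <- nrow(m); nc <- ncol(m)
  offs <- expand.grid(dr = -radius:radius, dc = -radius:radius)
  offs <- offs[offs$dr^2 + offs$dc^2 <= radius^2, ]
  out <- matrix(0, nr, nc)
  for (r in seq_len(nr)) for (c in seq_len(nc)) {
    vals <- mapply(function(dr, dc) {
      m[reflect1(r + dr, nr), reflect1(c + dc, nc)]
    }, offs$dr, offs$dc)
    s <- sort(vals)
    out[r, c] <- s[(length(s) + 1) / 2]  # disk size is odd
  }
  out
}

# per-pixel maximum over a slice window, via explicit loops
oracle_mip <- function(arr, start, n) {
  d <- dim(arr)
  out <- matrix(-Inf, d[1], d[2])
  for (r in seq_len(d[1])) for (c in seq_len(d[2])) {
    for (z in start:(start + n - 1)) out[r, c] <- max(out[r, c], arr[r, c, z])
  }
  out
}

# exhaustive window-sum maximization
oracle_window <- function(arr, n) {
  nz <- dim(arr)[3]
  sums <- sapply(seq_len(nz - n + 1), function(s) sum(arr[, , s:(s + n - 1)]))
  which(sums == max(sums))[1]
}

# exhaustive Otsu: for every candidate bin boundary, compute the
# between-class variance directly from class weights and means
oracle_otsu <- function(v, n_bins = 256L) {
  v <- as.numeric(v)
  lo <- min(v); hi <- max(v)
  if (hi <= lo) return(NA_real_)
  w <- (hi - lo) / n_bins
  lev <- pmin(floor((v - lo) / w), n_bins - 1)  # 0-based bin index
  mids <- lo + (lev + 0.5) * w
  best <- -Inf; best_k <- NA
  for (k in 1:(n_bins - 1)) {           # threshold = lo + k * w
    below <- lev < k
    n0 <- sum(below); n1 <- sum(!below)
    if (n0 == 0 || n1 == 0) next
    w0 <- n0 / length(v); w1 <- n1 / length(v)
    sb <- w0 * w1 * (mean(mids[below]) - mean(mids[!below]))^2
    if (sb > best) { best <- sb; best_k <- k }
  }
  lo + best_k * w
}

# iterative flood fill labelling, raster order, stack-based
oracle_label <- function(mask, connectivity = 8) {
  nr <- nrow(mask); nc <- ncol(mask)
  lab <- matrix(0L, nr, nc)
  if (connectivity == 8) {
    nb <- cbind(dr = c(-1, -1, -1, 0, 0, 1, 1, 1), dc = c(-1, 0, 1, -1, 1, -1, 0, 1))
  } else {
    nb <- cbind(dr = c(-1, 0, 0, 1), dc = c(0, -1, 1, 0))
  }
  nxt <- 0L
  for (r in seq_len(nr)) for (c in seq_len(nc)) {
    if (!mask[r, c] || lab[r, c] != 0L) next
    nxt <- nxt + 1L
    stack <- list(c(r, c)); lab[r, c] <- nxt
    while (length(stack) > 0) {
      p <- stack[[length(stack)]]; stack[[length(stack)]] <- NULL
      for (i in seq_len(nrow(nb))) {
        rr <- p[1] + nb[i, 1]; cc <- p[2] + nb[i, 2]
        if (rr >= 1 && rr <= nr && cc >= 1 && cc <= nc &&
            mask[rr, cc] && lab[rr, cc] == 0L) {
          lab[rr, cc] <- nxt
          stack[[length(stack) + 1]] <- c(rr, cc)
        }
      }
    }
  }
  lab
}

# exact Mann-Whitney by enumeration of all C(m+n, m) group assignments
oracle_mw_exact <- function(a, b, alternative = "two.sided") {
  pool <- c(a, b)
  m <- length(a)
  u_of <- function(x, y) sum(outer(x, y, ">")) + 0.5 * sum(outer(x, y, "=="))
  u_obs <- u_of(a, b)
  splits <- utils::combn(length(pool), m)
  u_all <- apply(splits, 2, function(idx) u_of(pool[idx], pool[-idx]))
  p_less <- mean(u_all <= u_obs + 1e-9)
  p_greater <- mean(u_all >= u_obs - 1e-9)
  p <- switch(alternative,
              less = p_less,
              greater = p_greater,
              two.sided = min(1, 2 * min(p_less, p_greater)))
  list(U = u_obs, p_value = p)
}

# type-7 quantile computed from first principles on the sorted sample
oracle_quartiles <- function(v) {
  s <- sort(v); n <- length(s)
  q7 <- function(p) {
    h <- (n - 1) * p + 1
    lo <- floor(h)
    s[lo] + (h - lo) * (s[min(lo + 1, n)] - s[lo])
  }
  c(q1 = q7(0.25), median = q7(0.5), q3 = q7(0.75))
}

# small random calibrated image
random_image <- function(nr = 12, nc = 10, max_int = 255, pixel_size = 100) {
  calibrated_image(matrix(sample(0:max_int, nr * nc, replace = TRUE) + 0,
                          nr, nc), pixel_size)
}

# build a binary mask directly from a logical matrix
mask_of <- function(m, pixel_size = 100) binary_mask(m, pixel_size)

# render a clean 2-D Gaussian blob field (no noise) for detection tests
blob_field <- function(nr, nc, centers, amp = 150, sigma = 2, bg = 0,
                       pixel_size = 120) {
  m <- matrix(bg, nr, nc)
  for (i in seq_len(nrow(centers))) {
    r0 <- centers[i, 1]; c0 <- centers[i, 2]
    rr <- max(1, r0 - 8):min(nr, r0 + 8)
    cc <- max(1, c0 - 8):min(nc, c0 + 8)
    g <- exp(-((rr - r0)^2) / (2 * sigma^2)) %o% exp(-((cc - c0)^2) / (2 * sigma^2))
    m[rr, cc] <- m[rr, cc] + amp * g
  }
  calibrated_image(round(m), pixel_size)
}
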