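# Brute-force reference implementations, deliberately naive: each recomputes
# a quantity by direct enumeration so the vectorized pipeline can be checked
# against first principles.

mk_img <- function(m, px = 1) image2d(m, px)
mk_mask <- function(m, px = 1) binary_mask(m > 0, px)

# queue-based flood fill, labels assigned in raster-scan (row, column) order
oracle_flood_fill <- function(mask, connectivity = 8L) {
  h <- nrow(mask); w <- ncol(mask)
  lab <- matrix(0L, h, w)
  nb <- if (connectivity == 8L)
    cbind(c(-1, -1, -1, 0, 0, 1, 1, 1), c(-1, 0, 1, -1, 1, -1, 0, 1))
  else cbind(c(-1, 1, 0, 0), c(0, 0, -1, 1))
  nxt <- 0L
  for (y in seq_len(h)) for (x in seq_len(w)) {
    if (!mask[y, x] || lab[y, x] != 0L) next
    nxt <- nxt + 1L
    queue <- list(c(y, x))
    lab[y, x] <- nxt
    while (length(queue)) {
      p <- queue[[1L]]; queue <- queue[-1L]
      for (k in seq_len(nrow(nb))) {
        ny <- p[1L] + nb[k, 1L]; nx <- p[2L] + nb[k, 2L]
        if (ny >= 1 && ny <= h && nx >= 1 && nx <= w &&
            mask[ny, nx] && lab[ny, nx] == 0L) {
          lab[ny, nx] <- nxt
          queue[[length(queue) + 1L]] <- c(ny, nx)
        }
      }
    }
  }
  lab
}

# erosion/dilation/top-hat by exhaustive neighborhood scan with a
# dx^2 + dy^2 <= r^2 disk; out-of-image neighbors are ignored
oracle_morph <- function(px, radius, fun) {
  h <- nrow(px); w <- ncol(px)
  out <- matrix(0, h, w)
  r <- ceiling(radius)
  for (y in seq_len(h)) for (x in seq_len(w)) {
    vals <- c()
    for (dy in -r:r) for (dx in -r:r) {
      if (dy^2 + dx^2 > radius^2) next
      ny <- y + dy; nx <- x + dx
      if (ny >= 1 && ny <= h && nx >= 1 && nx <= w) vals <- c(vals, px[ny, nx])
    }
    out[y, x] <- fun(vals)
  }
  out
}

oracle_tophat <- function(px, radius) {
  opened <- oracle_morph(oracle_morph(px, radius, min), radius, max)
  pmax(px - opened, 0)
}

# exhaustive Otsu: test every candidate threshold (all unique values),
# maximizing between-class variance of {v <= t} vs {v > t}
oracle_otsu <- function(v) {
  v <- as.vector(v)
  u <- sort(unique(v))
  best <- -Inf; best_t <- u[1L]
  for (t in u[-length(u)]) {
    a <- v[v <= t]; b <- v[v > t]
    bcv <- (length(a) / length(v)) * (length(b) / length(v)) *
      (mean(a) - mean(b))^2
    if (bcv > best) { best <- bcv; best_t <- t }
  }
  best_t
}

# per-pixel accumulation of object measurements
oracle_measure <- function(lab, imgs = list(), cell_lab = NULL, px_um = 1) {
  ids <- sort(setdiff(unique(as.vector(lab)), 0L))
  h <- nrow(lab); w <- ncol(lab)
  rows <- lapply(ids, function(id) {
    n <- 0L; sy <- 0; sx <- 0; edge <- FALSE
    sums <- stats::setNames(numeric(length(imgs)), names(imgs))
    for (y in seq_len(h)) for (x in seq_len(w)) {
      if (lab[y, x] != id) next
      n <- n + 1L; sy <- sy + (y - 1); sx <- sx + (x - 1)
      if (y == 1 || y == h || x == 1 || x == w) edge <- TRUE
      for (nm in names(imgs)) sums[nm] <- sums[nm] + imgs[[nm]][y, x]
    }
    cy <- sy / n; cx <- sx / n
    cid <- if (is.null(cell_lab)) 0L else
      cell_lab[round(cy) + 1L, round(cx) + 1L]
    out <- data.frame(object_id = id, cell_id = cid, area_um2 = n * px_um^2,
                      centroid_y = cy, centroid_x = cx, touches_edge = edge)
    for (nm in names(imgs)) {
      out[[paste0("mean_", nm)]] <- sums[nm] / n
      out[[paste0("sum_", nm)]] <- sums[nm]
    }
    out
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

# exhaustive peak detector: tests every interior sample against the
# prominence definition, then greedy min-separation by descending height
oracle_peaks <- function(x, frac, min_sep_px) {
  n <- length(x)
  rng <- max(x) - min(x)
  if (rng == 0) return(integer())
  cand <- c()
  for (i in 2:(n - 1)) {
    # first sample of a plateau that is a strict local maximum
    j <- i
    while (j < n && x[j + 1] == x[i]) j <- j + 1
    if (x[i - 1] >= x[i] || (j < n && x[j + 1] >= x[i]) || j == n) next
    if (i > 1 && x[i - 1] == x[i]) next  # not the first sample of its plateau
    # prominence: walk out to higher ground on both sides
    lm <- x[i]; k <- i - 1
    while (k >= 1 && x[k] <= x[i]) { lm <- min(lm, x[k]); k <- k - 1 }
    rm_ <- x[i]; k <- j + 1
    while (k <= n && x[k] <= x[i]) { rm_ <- min(rm_, x[k]); k <- k + 1 }
    if (x[i] - max(lm, rm_) >= frac * rng) cand <- c(cand, i)
  }
  if (!length(cand)) return(integer())
  keep <- c()
  for (i in cand[order(-x[cand], cand)]) {
    if (!length(keep) || all(abs(keep - i) >= min_sep_px)) keep <- c(keep, i)
  }
  sort(keep)
}

# sort-based quantile gate: survivors have mean inside the closed interval
# [Q(low), Q(high)] of the empirical distribution (type-7 interpolation
# computed from first principles)
oracle_gate_survivors <- function(means, low_q, high_q) {
  qs <- function(p) {
    s <- sort(means)
    h <- 1 + p * (length(s) - 1)
    lo <- floor(h); hi <- ceiling(h)
    s[lo] + (h - lo) * (s[hi] - s[lo])
  }
  which(means >= qs(low_q) & means <= qs(high_q))
}

# draw a filled disk into a matrix (test fixture construction)
put_disk <- function(m, cy, cx, r, val) {
  for (y in seq_len(nrow(m))) for (x in seq_len(ncol(m)))
    if ((y - cy)^2 + (x - cx)^2 <= r^2) m[y, x] <- val
  m
}

# minimal 4-D stack from a list of 2-D signal matrices (one per channel),
# replicated over n_z slices
toy_stack <- function(channels, px = 1, n_z = 1L) {
  h <- nrow(channels[[1L]]); w <- ncol(channels[[1L]])
  a <- array(0, dim = c(n_z, length(channels), h, w))
  for (z in seq_len(n_z)) for (ch in seq_along(channels))
    a[z, ch, , ] <- channels[[ch]]
  roles <- seq_along(channels)
  names(roles) <- names(channels)
  image_stack(a, px, roles)
}
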