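#' Maximum Z-projection of one channel
#'
#' Per-pixel maximum over slices; the standard projection for morphology and
#' puncta-counting channels.
#'
#' @param stack an [image_stack()].
#' @param role channel role tag.
#' @return An [image2d()] on the same pixel grid.
#' @export
max_project <- function(stack, role) {
  ch <- .role_index(stack, role)
  nz <- dim(stack$pixels)[1L]
  slices <- lapply(seq_len(nz), function(z) stack$pixels[z, ch, , ])
  image2d(Reduce(pmax, slices), stack$pixel_size_um)
}

#' Sum Z-projection of one channel
#'
#' Per-pixel sum over slices; used for integrated-intensity readouts (TMRE,
#' DQ-BSA) where total signal, not peak signal, is the quantity of interest.
#'
#' @inheritParams max_project
#' @return An [image2d()].
#' @export
sum_project <- function(stack, role) {
  ch <- .role_index(stack, role)
  nz <- dim(stack$pixels)[1L]
  slices <- lapply(seq_len(nz), function(z) stack$pixels[z, ch, , ])
  image2d(Reduce(`+`, slices), stack$pixel_size_um)
}

# Disk structuring element: offsets with dx^2 + dy^2 <= r^2.
disc_kernel <- function(radius_px) {
  r <- as.integer(radius_px)
  d <- outer((-r:r)^2, (-r:r)^2, `+`)
  d <= radius_px^2
}

# Grayscale erosion/dilation by an arbitrary flat structuring element,
# computed as min/max over shifted copies; pixels outside the image are
# ignored (treated as +Inf for erosion, -Inf for dilation).
.morph <- function(px, kern, fun = pmin, fill = Inf) {
  kr <- (nrow(kern) - 1L) %/% 2L
  kc <- (ncol(kern) - 1L) %/% 2L
  h <- nrow(px); w <- ncol(px)
  out <- matrix(fill, h, w)
  for (dy in -kr:kr) for (dx in -kc:kc) {
    if (!kern[dy + kr + 1L, dx + kc + 1L]) next
    ys <- max(1L, 1L - dy):min(h, h - dy)   # destination rows
    xs <- max(1L, 1L - dx):min(w, w - dx)
    out[ys, xs] <- fun(out[ys, xs], px[ys + dy, xs + dx])
  }
  out
}

# column/row shift with constant fill
.shift_cols <- function(m, dx, fill) {
  w <- ncol(m)
  out <- matrix(fill, nrow(m), w)
  xs <- max(1L, 1L - dx):min(w, w - dx)
  out[, xs] <- m[, xs + dx]
  out
}
.shift_rows <- function(m, dy, fill) {
  h <- nrow(m)
  out <- matrix(fill, h, ncol(m))
  ys <- max(1L, 1L - dy):min(h, h - dy)
  out[ys, ] <- m[ys + dy, ]
  out
}

# disc-decomposed grayscale morphology: a disc of radius r is the union of
# horizontal segments of half-width floor(sqrt(r^2 - dy^2)); horizontal
# running minima are built incrementally, then combined over row shifts.
# Identical to min/max over all in-bounds disc offsets (outside ignored).
.morph_disc <- function(px, radius, fun = pmin, fill = Inf) {
  r <- as.integer(radius)
  hw <- floor(sqrt(pmax(radius^2 - (0:r)^2, 0)))   # half-width per |dy|
  seg <- vector("list", max(hw) + 1L)
  seg[[1L]] <- px
  cur <- px
  for (w in seq_len(max(hw))) {
    cur <- fun(cur, fun(.shift_cols(px, -w, fill), .shift_cols(px, w, fill)))
    seg[[w + 1L]] <- cur
  }
  out <- matrix(fill, nrow(px), ncol(px))
  for (dy in -r:r)
    out <- fun(out, .shift_rows(seg[[hw[abs(dy) + 1L] + 1L]], dy, fill))
  out
}

erode_gray  <- function(px, kern) .morph(px, kern, pmin,  Inf)
dilate_gray <- function(px, kern) .morph(px, kern, pmax, -Inf)

#' White top-hat filter
#'
#' Image minus its morphological opening with a disk structuring element
#' (pixels at squared distance at most `radius_px^2` from the centre).
#' Suppresses background larger than the disk while preserving tubules and
#' puncta thinner than it; the output is non-negative everywhere.
#'
#' @param image an [image2d()].
#' @param radius_px disk radius in pixels (integer >= 1).
#' @return An [image2d()].
#' @export
tophat <- function(image, radius_px) {
  if (radius_px < 1) stop("radius_px must be >= 1")
  opened <- .morph_disc(.morph_disc(image$pixels, radius_px, pmin, Inf),
                        radius_px, pmax, -Inf)
  image2d(pmax(image$pixels - opened, 0), image$pixel_size_um)
}

#' Gaussian blur
#'
#' Separable Gaussian convolution with symmetric (reflect) boundary
#' handling; the kernel is truncated at 4 sigma and normalised so total
#' intensity is conserved.
#'
#' @param image an [image2d()].
#' @param sigma_px standard deviation in pixels (> 0).
#' @return An [image2d()].
#' @export
gaussian_blur <- function(image, sigma_px) {
  if (!is.numeric(sigma_px) || sigma_px <= 0) stop("sigma_px must be > 0")
  r <- max(1L, ceiling(4 * sigma_px))
  k <- stats::dnorm(-r:r, sd = sigma_px)
  k <- k / sum(k)
  px <- image$pixels
  h <- nrow(px); w <- ncol(px)
  refl <- function(n) {   # symmetric reflection, valid for any r
    i <- (1L - r):(n + r)
    j <- ((i - 1L) %% (2L * n) + 2L * n) %% (2L * n)
    ifelse(j < n, j + 1L, 2L * n - j)
  }
  pad <- px[refl(h), refl(w), drop = FALSE]
  band <- function(n) {   # n x (n + 2r) banded convolution matrix
    B <- matrix(0, n, n + 2L * r)
    B[cbind(rep(seq_len(n), each = 2L * r + 1L),
            rep(seq_len(n), each = 2L * r + 1L) + rep(0:(2L * r), n))] <- rep(k, n)
    B
  }
  out <- band(h) %*% pad %*% t(band(w))
  image2d(out, image$pixel_size_um)
}

# Otsu threshold: the intensity value t maximizing between-class variance
# of {v <= t} vs {v > t}.  Exact over the unique values for discrete images;
# continuous-valued images (e.g. blurred) are binned to 4096 levels first.
otsu_threshold <- function(v) {
  v <- as.vector(v)
  u <- sort(unique(v))
  if (length(u) < 2L) stop("otsu requires at least 2 distinct intensities")
  if (length(u) > 4096L) {
    br <- seq(u[1L], u[length(u)], length.out = 4097L)
    idx <- pmin(findInterval(v, br, rightmost.closed = TRUE), 4096L)
    cnt0 <- tabulate(idx, 4096L)
    keep <- cnt0 > 0L
    u <- br[-1L][keep]                  # candidate thresholds: bin upper edges
    cnt <- cnt0[keep]
    # class means use bin-mean intensities
    u_mean <- rowsum(v, idx)[, 1L] / cnt0[keep]
    n <- length(v)
    cw <- cumsum(cnt); cs <- cumsum(cnt * u_mean)
    tot <- cs[length(cs)]
    i <- seq_len(length(u) - 1L)
    bcv <- (cw[i] / n) * (1 - cw[i] / n) *
      (cs[i] / cw[i] - (tot - cs[i]) / (n - cw[i]))^2
    return(u[i[which.max(bcv)]])
  }
  cnt <- tabulate(match(v, u), nbins = length(u))
  n <- length(v)
  cw <- cumsum(cnt)                # pixels <= u[i]
  cs <- cumsum(cnt * u)            # intensity sum <= u[i]
  tot <- cs[length(cs)]
  i <- seq_len(length(u) - 1L)     # t = u[i]; both classes non-empty
  w0 <- cw[i] / n
  w1 <- 1 - w0
  m0 <- cs[i] / cw[i]
  m1 <- (tot - cs[i]) / (n - cw[i])
  bcv <- w0 * w1 * (m0 - m1)^2
  u[i[which.max(bcv)]]
}

#' Threshold an image into a binary mask
#'
#' A pixel is foreground iff its intensity is strictly greater than the
#' threshold.  `"fixed"` uses the supplied value; `"otsu"` maximizes
#' between-class variance over the exact intensity histogram.  The applied
#' threshold is recorded in the provenance log and attached as attribute
#' `"threshold"`.
#'
#' @param image an [image2d()].
#' @param method `"fixed"` or `"otsu"`.
#' @param value threshold for `"fixed"`.
#' @return A [binary_mask()] with attribute `"threshold"`.
#' @export
threshold_binarize <- function(image, method = c("otsu", "fixed"), value = NULL) {
  method <- match.arg(method)
  thr <- if (method == "fixed") {
    if (is.null(value)) stop("method 'fixed' requires a value")
    value
  } else {
    otsu_threshold(image$pixels)
  }
  m <- binary_mask(image$pixels > thr, image$pixel_size_um)
  attr(m, "threshold") <- thr
  prov_record("threshold_binarize", list(method = method),
              list(threshold = thr, n_foreground = sum(m$pixels)))
  m
}

# Relabel so labels run 1..n in raster-scan order (rows, then columns) of
# each object's first pixel.
raster_relabel <- function(lab) {
  nz <- which(lab > 0L)
  if (!length(nz)) return(lab)
  h <- nrow(lab); w <- ncol(lab)
  r <- (nz - 1L) %% h; cc <- (nz - 1L) %/% h
  key <- r * w + cc                      # row-major position
  o <- order(key)
  first <- !duplicated(lab[nz][o])
  map <- integer(max(lab))
  map[lab[nz][o][first]] <- seq_len(sum(first))
  lab[nz] <- map[lab[nz]]
  lab
}

#' Connected-component labeling
#'
#' Maximal connected foreground regions under 4- or 8-connectivity, labeled
#' `1..n` in raster-scan order of each object's first pixel.
#'
#' @param mask a [binary_mask()].
#' @param connectivity 4 or 8.
#' @return A [labeled_mask()].
#' @export
connected_components <- function(mask, connectivity = 8L) {
  if (!connectivity %in% c(4L, 8L)) stop("connectivity must be 4 or 8")
  px <- mask$pixels
  lab <- matrix(as.integer(EBImage::bwlabel(px * 1)), nrow(px), ncol(px))
  if (connectivity == 8L && max(lab) > 1L) {
    h <- nrow(lab); w <- ncol(lab)
    a1 <- lab[-h, -w]; b1 <- lab[-1, -1]   # down-right diagonal pairs
    a2 <- lab[-1, -w]; b2 <- lab[-h, -1]   # up-right diagonal pairs
    pa <- c(a1[a1 > 0 & b1 > 0 & a1 != b1], a2[a2 > 0 & b2 > 0 & a2 != b2])
    pb <- c(b1[a1 > 0 & b1 > 0 & a1 != b1], b2[a2 > 0 & b2 > 0 & a2 != b2])
    if (length(pa)) {
      parent <- seq_len(max(lab))
      find <- function(i) { while (parent[i] != i) { parent[i] <<- parent[parent[i]]; i <- parent[i] }; i }
      for (j in seq_along(pa)) {
        ra <- find(pa[j]); rb <- find(pb[j])
        if (ra != rb) parent[max(ra, rb)] <- min(ra, rb)
      }
      roots <- vapply(seq_len(max(lab)), find, integer(1L))
      lab[lab > 0L] <- roots[lab[lab > 0L]]
    }
  }
  labeled_mask(raster_relabel(lab), mask$pixel_size_um)
}

# Reduce each connected cluster of candidate seed pixels to one point and
# greedily enforce a minimum pairwise separation, highest distance value
# first (ties broken by raster order).  Returns a seed label image.
.select_seeds <- function(dist, mask, min_sep) {
  mx <- .morph_disc(dist, max(1L, ceiling(min_sep)), pmax, -Inf)
  cand <- mask & dist >= mx - 1e-9 & dist > 0
  if (!any(cand)) return(NULL)
  clust <- connected_components(binary_mask(cand, 1), 8L)$labels
  n <- max(clust)
  h <- nrow(dist); w <- ncol(dist)
  pts <- matrix(0, n, 4L)  # y, x, dist, component-of-mask
  comp <- connected_components(binary_mask(mask, 1), 8L)$labels
  members <- split(which(clust > 0L), clust[clust > 0L])
  for (i in seq_len(n)) {
    idx <- members[[as.character(i)]]
    yy <- (idx - 1L) %% h + 1L; xx <- (idx - 1L) %/% h + 1L
    j <- which.max(dist[idx])   # representative: highest point of plateau
    pts[i, ] <- c(yy[j], xx[j], dist[idx[j]], comp[yy[j], xx[j]])
  }
  keep <- logical(n)
  o <- order(-pts[, 3L], (pts[, 1L] - 1) * w + pts[, 2L])
  for (i in o) {
    same <- which(keep & pts[, 4L] == pts[i, 4L])
    if (!length(same) ||
        all((pts[same, 1L] - pts[i, 1L])^2 + (pts[same, 2L] - pts[i, 2L])^2 >= min_sep^2))
      keep[i] <- TRUE
  }
  # guarantee every mask component keeps at least one seed
  for (cmp in setdiff(unique(pts[, 4L]), pts[keep, 4L])) {
    cand_i <- which(pts[, 4L] == cmp)
    keep[cand_i[which.max(pts[cand_i, 3L])]] <- TRUE
  }
  seeds <- matrix(0L, h, w)
  ki <- which(keep)
  seeds[cbind(pts[ki, 1L], pts[ki, 2L])] <- seq_along(ki)
  seeds
}

#' Split touching objects by distance-transform watershed
#'
#' Seeds are local maxima of the Euclidean distance transform separated by at
#' least `min_seed_distance_px`; every foreground pixel is then assigned to
#' the nearest seed by geodesic region growing, so the union of the output
#' labels equals the input mask exactly.  A mask with well-separated blobs
#' reduces to plain connected-component labeling.
#'
#' @param mask a [binary_mask()].
#' @param min_seed_distance_px minimum seed separation in pixels.
#' @return A [labeled_mask()].
#' @export
watershed_split <- function(mask, min_seed_distance_px = 3) {
  px <- mask$pixels
  if (!any(px)) return(labeled_mask(matrix(0L, nrow(px), ncol(px)), mask$pixel_size_um))
  d <- matrix(as.numeric(EBImage::distmap(px * 1)), nrow(px), ncol(px))
  # light smoothing of the EDT for seed detection only: suppresses the
  # spurious ridge maxima a noise-jagged object boundary induces, without
  # moving the well-separated maxima of genuinely merged objects
  ds <- gaussian_blur(image2d(d, 1), 0.8)$pixels
  seeds <- .select_seeds(ds, px, min_seed_distance_px)
  lab <- EBImage::propagate(matrix(0, nrow(px), ncol(px)), seeds, mask = px)
  lab <- matrix(as.integer(lab), nrow(px), ncol(px))
  # propagate is geodesic: any stranded foreground pixel would be a bug, but
  # guard by merging strays into connected components of the residue
  if (any(px & lab == 0L)) {
    res <- connected_components(binary_mask(px & lab == 0L, mask$pixel_size_um), 8L)$labels
    lab[res > 0L] <- max(lab) + res[res > 0L]
  }
  labeled_mask(raster_relabel(lab), mask$pixel_size_um)
}

#' Per-object measurements
#'
#' One row per label: physical area, intensity-independent centroid (0-based
#' `(y, x)` pixel coordinates), mean and summed intensity per requested
#' channel, the enclosing cell label sampled at the object's centroid, and an
#' image-border flag.
#'
#' @param labels a [labeled_mask()] of objects.
#' @param intensity_images named list of [image2d()], role -> image.
#' @param cell_labels optional [labeled_mask()] of cells on the same grid.
#' @return A data.frame with columns `object_id`, `cell_id`, `area_um2`,
#'   `centroid_y`, `centroid_x`, `touches_edge`, then `mean_<role>` and
#'   `sum_<role>` per intensity image.
#' @export
measure_objects <- function(labels, intensity_images = list(), cell_labels = NULL) {
  lab <- labels$labels
  h <- nrow(lab); w <- ncol(lab)
  for (im in intensity_images)
    if (nrow(im$pixels) != h || ncol(im$pixels) != w ||
        !isTRUE(all.equal(im$pixel_size_um, labels$pixel_size_um)))
      stop("grid mismatch between labels and intensity image")
  if (!is.null(cell_labels) &&
      (nrow(cell_labels$labels) != h || ncol(cell_labels$labels) != w))
    stop("grid mismatch between labels and cell labels")
  ids <- sort(setdiff(unique(as.vector(lab)), 0L))
  if (!length(ids)) {
    out <- data.frame(object_id = integer(), cell_id = integer(),
                      area_um2 = numeric(), centroid_y = numeric(),
                      centroid_x = numeric(), touches_edge = logical())
    for (role in names(intensity_images)) {
      out[[paste0("mean_", role)]] <- numeric()
      out[[paste0("sum_", role)]] <- numeric()
    }
    return(out)
  }
  nz <- which(lab > 0L)
  lv <- lab[nz]
  g <- match(lv, ids)
  yy <- (nz - 1L) %% h   # 0-based
  xx <- (nz - 1L) %/% h
  npx <- tabulate(g, length(ids))
  cy <- rowsum(as.numeric(yy), g)[, 1L] / npx
  cx <- rowsum(as.numeric(xx), g)[, 1L] / npx
  edge <- as.logical(tabulate(g[yy == 0L | yy == h - 1L | xx == 0L | xx == w - 1L],
                              length(ids)))
  cell_id <- integer(length(ids))
  if (!is.null(cell_labels)) {
    ry <- pmin(pmax(round(cy), 0), h - 1) + 1L
    rx <- pmin(pmax(round(cx), 0), w - 1) + 1L
    cell_id <- cell_labels$labels[cbind(ry, rx)]
  }
  out <- data.frame(object_id = ids, cell_id = cell_id,
                    area_um2 = npx * labels$pixel_size_um^2,
                    centroid_y = cy, centroid_x = cx, touches_edge = edge)
  for (role in names(intensity_images)) {
    iv <- intensity_images[[role]]$pixels[nz]
    s <- rowsum(iv, g)[, 1L]
    out[[paste0("mean_", role)]] <- s / npx
    out[[paste0("sum_", role)]] <- s
  }
  rownames(out) <- NULL
  out
}
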