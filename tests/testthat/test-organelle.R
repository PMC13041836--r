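# whole-field single cell: label 1 everywhere, nucleus in a corner block
.one_cell <- function(h, w, px = 1) {
  nm <- matrix(0L, h, w); nm[2:3, 2:3] <- 1L
  cell_segmentation(labeled_mask(nm, px), labeled_mask(matrix(1L, h, w), px))
}

# brute-force touching predicate: any object pixel within Chebyshev
# distance 1 of a mask pixel
.oracle_touching <- function(lab, mask) {
  ids <- sort(setdiff(unique(as.vector(lab)), 0L))
  touch <- c()
  for (id in ids) {
    idx <- which(lab == id, arr.ind = TRUE)
    hit <- FALSE
    for (k in seq_len(nrow(idx))) {
      ys <- max(1, idx[k, 1] - 1):min(nrow(lab), idx[k, 1] + 1)
      xs <- max(1, idx[k, 2] - 1):min(ncol(lab), idx[k, 2] + 1)
      if (any(mask[ys, xs])) { hit <- TRUE; break }
    }
    if (hit) touch <- c(touch, id)
  }
  touch
}

test_that("mitolysosome counting excludes network-touching puncta", {
  seg <- .one_cell(12, 12)
  gfp <- matrix(FALSE, 12, 12); gfp[5:8, 5:6] <- TRUE
  mch <- matrix(0L, 12, 12)
  mch[6, 6] <- 1L                 # overlaps the GFP mask
  mch[4, 7] <- 2L                 # 8-adjacent (diagonal) to it
  mch[10, 10:11] <- 3L            # isolated
  lab <- labeled_mask(mch, 1)
  res <- count_mitolysosomes(seg, binary_mask(gfp, 1), lab)
  expect_equal(res$per_cell$n_mitolysosomes, 1L)
  expect_equal(res$per_cell$n_touching, 2L)
  expect_equal(res$field_mean, 1)
  expect_equal(sort(.oracle_touching(mch, gfp)), c(1L, 2L))

  empty <- labeled_mask(matrix(0L, 12, 12), 1)
  expect_equal(count_mitolysosomes(seg, binary_mask(gfp, 1), empty)$field_mean, 0)
})

test_that("counted plus touching puncta partition the total per cell", {
  set.seed(41)
  for (i in 1:8) {
    seg <- .one_cell(20, 20)
    gfp <- matrix(runif(400) < 0.1, 20, 20)
    mch <- connected_components(mk_mask(matrix(rbinom(400, 1, 0.15), 20, 20)), 8L)
    res <- count_mitolysosomes(seg, binary_mask(gfp, 1), mch)
    expect_equal(res$per_cell$n_total,
                 res$per_cell$n_touching + res$per_cell$n_mitolysosomes)
    expect_equal(res$per_cell$n_total, mch$n_objects)
    oracle_touch <- .oracle_touching(mch$labels, gfp)
    expect_equal(res$per_cell$n_touching, length(oracle_touch))
  }
})

test_that("flux ratio follows the arm means and is scale-equivariant", {
  expect_equal(compute_flux(c(6, 6, 6), c(6, 6))$flux_ratio, 1)
  f <- compute_flux(c(2, 4, 6), c(8, 8, 8))
  expect_equal(f$flux_ratio, 2)
  expect_true(f$defined)
  f0 <- compute_flux(c(0, 0), c(3, 5))
  expect_false(f0$defined)
  expect_true(is.na(f0$flux_ratio))
  expect_error(compute_flux(numeric(), c(1)), "empty arm")
  set.seed(43)
  for (i in 1:10) {
    a <- rpois(30, 6); b <- rpois(30, 12)
    if (mean(a) == 0) next
    k <- runif(1, 0.5, 4)
    expect_equal(compute_flux(k * a, k * b)$flux_ratio,
                 compute_flux(a, b)$flux_ratio)
  }
})

test_that("mitochondrial mass accumulates masked area per cell", {
  seg <- .one_cell(10, 10, px = 0.3)
  expect_equal(mito_mass(seg, binary_mask(matrix(FALSE, 10, 10), 0.3))$mito_area_um2, 0)
  m <- matrix(FALSE, 10, 10); m[1:10, 1:10] <- TRUE
  expect_equal(mito_mass(seg, binary_mask(m, 0.3))$mito_area_um2, 100 * 0.09)
  set.seed(47)
  cm <- matrix(sample(0:3, 144, replace = TRUE), 12, 12)
  nm <- matrix(0L, 12, 12); nm[1, 1:3] <- 1:3
  seg2 <- cell_segmentation(labeled_mask(nm, 0.5), labeled_mask(cm, 0.5))
  mask <- matrix(runif(144) < 0.4, 12, 12)
  got <- mito_mass(seg2, binary_mask(mask, 0.5))
  for (id in got$cell_id)
    expect_equal(got$mito_area_um2[got$cell_id == id],
                 sum(mask & cm == id) * 0.25)
})

# two-level background with nonzero spread so the mean + k*sd cutoff is real
.tmre_fixture <- function(px = 0.5) {
  seg <- .one_cell(20, 20, px)
  mtg <- matrix(0L, 20, 20)
  mtg[5, 5:7] <- 1L          # 3 px = 0.75 um^2: small
  mtg[12:15, 5:9] <- 2L      # 20 px = 5 um^2: network fragment
  mtg[5, 15:16] <- 3L        # 2 px = 0.5 um^2: small
  tmre <- matrix(rep(c(9, 11), 200), 20, 20)   # background mean 10, sd ~1
  tmre[5, 5:7] <- 100        # polarized small
  tmre[12:15, 5:9] <- 120
  tmre[5, 15:16] <- 10       # depolarized small: at background level
  list(seg = seg, mtg = labeled_mask(mtg, px), tmre = image2d(tmre, px))
}

test_that("depolarized classification separates small TMRE-dark objects", {
  fx <- .tmre_fixture()
  r <- classify_depolarized(fx$seg, fx$mtg, fx$tmre)
  expect_equal(r$per_cell$n_individualized_small, 2L)
  expect_equal(r$per_cell$n_depolarized, 1L)
  bg <- fx$tmre$pixels[fx$mtg$labels == 0L]
  expect_equal(r$tmre_background_cutoff, mean(bg) + 3 * sd(bg))

  # counts bounded by each other; all-large masks give zeros
  big <- labeled_mask(matrix(rep(c(0L, 1L), each = 200), 20, 20), 0.5)
  r2 <- classify_depolarized(fx$seg, big, fx$tmre)
  expect_equal(r2$per_cell$n_individualized_small, 0L)
  expect_equal(r2$per_cell$n_depolarized, 0L)
})

test_that("depolarization counts are invariant to uniform TMRE offsets and relabeling", {
  fx <- .tmre_fixture()
  r <- classify_depolarized(fx$seg, fx$mtg, fx$tmre)
  for (c in c(-5, 13.7, 250)) {
    shifted <- image2d(fx$tmre$pixels + c, 0.5)
    rs <- classify_depolarized(fx$seg, fx$mtg, shifted)
    expect_identical(rs$per_cell, r$per_cell)
  }
  perm <- c(3L, 1L, 2L)
  relab <- fx$mtg$labels
  relab[relab > 0L] <- perm[relab[relab > 0L]]
  rr <- classify_depolarized(fx$seg, labeled_mask(relab, 0.5), fx$tmre)
  expect_identical(rr$per_cell, r$per_cell)
})

test_that("touching-puncta counts match brute-force adjacency", {
  seg <- .one_cell(14, 14)
  target <- matrix(FALSE, 14, 14); target[6:9, 6:9] <- TRUE
  ves <- matrix(0L, 14, 14)
  ves[2, 2] <- 1L                  # gap > 2 px: not touching
  ves[5, 5] <- 2L                  # diagonal contact
  ves[7, 7] <- 3L                  # fully inside: containment is touching
  ves[12, 12:13] <- 4L             # far
  ves[6, 11] <- 5L                 # 2 px gap: not touching
  r <- count_touching_puncta(seg, labeled_mask(ves, 1), binary_mask(target, 1))
  expect_equal(r$per_cell$n_touching, 2L)
  expect_equal(sort(.oracle_touching(ves, target)), c(2L, 3L))

  far <- matrix(0L, 14, 14); far[1:2, 1] <- 1L
  expect_equal(count_touching_puncta(seg, labeled_mask(far, 1),
                                     binary_mask(target, 1))$per_cell$n_touching, 0L)
})

# one cell filling the field with a single-pixel nucleus at (cy, cx) and
# single-pixel vesicles at stated distances along a row
.distance_fixture <- function(dists_px, cy = 10, cx = 3, h = 20, w = 40) {
  nm <- matrix(0L, h, w); nm[cy, cx] <- 1L
  seg <- cell_segmentation(labeled_mask(nm, 1), labeled_mask(matrix(1L, h, w), 1))
  lv <- matrix(0L, h, w)
  for (i in seq_along(dists_px)) lv[cy, cx + dists_px[i]] <- i
  list(seg = seg, lyso = labeled_mask(lv, 1), nuclei = seg$nuclei,
       areas = data.frame(cell_id = 1L, mito_area_um2 = 10))
}

test_that("peripheral-lysosome statistic uses the exclusive 75th percentile", {
  fx <- .distance_fixture(c(1L, 2L, 3L, 4L))
  r <- lysosome_distribution(fx$seg, fx$lyso, fx$nuclei, fx$areas)
  expect_equal(sort(r$distances$distance_um), c(1, 2, 3, 4))
  # exclusive linear interpolation from first principles: h = 0.75 * (n + 1)
  s <- sort(r$distances$distance_um); hpos <- 0.75 * 5
  want <- s[floor(hpos)] + (hpos - floor(hpos)) * (s[ceiling(hpos)] - s[floor(hpos)])
  expect_equal(r$percentile_threshold_um, want)   # 3.75
  expect_equal(sum(r$distances$peripheral), 1L)
  expect_equal(r$per_cell$peripheral_per_mito_area, 1 / 10)

  # ties: all at one distance, threshold equals it, strict > marks none
  nm <- matrix(0L, 20, 40); nm[10, 10] <- 1L
  seg <- cell_segmentation(labeled_mask(nm, 1), labeled_mask(matrix(1L, 20, 40), 1))
  lv <- matrix(0L, 20, 40)
  lv[10, 15] <- 1L; lv[10, 5] <- 2L; lv[15, 10] <- 3L; lv[5, 10] <- 4L
  r2 <- lysosome_distribution(seg, labeled_mask(lv, 1), seg$nuclei,
                              data.frame(cell_id = 1L, mito_area_um2 = 4))
  expect_equal(unique(r2$distances$distance_um), 5)
  expect_equal(sum(r2$distances$peripheral), 0L)

  # an external reference shifts the threshold
  r3 <- lysosome_distribution(fx$seg, fx$lyso, fx$nuclei, fx$areas,
                              reference_distances = c(0.5, 1, 1.5, 2))
  expect_gt(sum(r3$distances$peripheral), sum(r$distances$peripheral))
})

test_that("a self-referenced threshold never marks more than a quarter peripheral", {
  set.seed(53)
  for (n in c(5L, 8L, 82L, 100L, 41L)) {
    d <- round(runif(n, 1, 30))
    lv <- matrix(0L, 40, 80); nm <- matrix(0L, 40, 80); nm[20, 10] <- 1L
    seg <- cell_segmentation(labeled_mask(nm, 1),
                             labeled_mask(matrix(1L, 40, 80), 1))
    ang <- runif(n, 0, 2 * pi)
    yy <- pmin(pmax(round(20 + d * sin(ang)), 1), 40)
    xx <- pmin(pmax(round(10 + d * cos(ang)), 2), 80)
    pts <- unique(cbind(yy, xx))
    for (i in seq_len(nrow(pts))) lv[pts[i, 1], pts[i, 2]] <- i
    r <- lysosome_distribution(seg, labeled_mask(lv, 1), seg$nuclei,
                               data.frame(cell_id = 1L, mito_area_um2 = 1))
    expect_lte(mean(r$distances$peripheral), 0.25)
  }
})

test_that("masked means match exhaustive loops and flag empty masks", {
  img <- mk_img(matrix(7, 6, 6))
  mask <- binary_mask(matrix(TRUE, 6, 6), 1)
  expect_equal(as.numeric(mean_intensity_in_mask(img, mask)), 7)
  m2 <- matrix(FALSE, 6, 6); m2[1, 1:2] <- TRUE
  i2 <- matrix(0, 6, 6); i2[1, 1:2] <- c(2, 4)
  expect_equal(as.numeric(mean_intensity_in_mask(mk_img(i2), binary_mask(m2, 1))), 3)
  v <- mean_intensity_in_mask(img, binary_mask(matrix(FALSE, 6, 6), 1))
  expect_true(is.na(v))
  expect_false(attr(v, "defined"))

  set.seed(59)
  for (i in 1:6) {
    im <- matrix(runif(100), 10, 10)
    mk <- matrix(runif(100) < 0.5, 10, 10)
    if (!any(mk)) next
    acc <- 0; n <- 0
    for (y in 1:10) for (x in 1:10) if (mk[y, x]) { acc <- acc + im[y, x]; n <- n + 1 }
    expect_equal(as.numeric(mean_intensity_in_mask(mk_img(im), binary_mask(mk, 1))),
                 acc / n)
  }
})

test_that("nuclear means read the nucleus mask; uniform markers give fold one", {
  seg <- .one_cell(10, 10)
  z <- nuclear_mean_intensity(seg, mk_img(matrix(0, 10, 10)))
  expect_equal(z$field_mean, 0)
  u <- mk_img(matrix(13, 10, 10))
  expect_equal(nuclear_mean_intensity(seg, u)$field_mean,
               cytosol_mean_intensity(seg, u)$field_mean)
})

test_that("per-cell statistics are invariant under permutation of cell ids", {
  set.seed(61)
  cm <- matrix(0L, 16, 16)
  cm[2:7, 2:7] <- 1L; cm[2:7, 10:15] <- 2L; cm[10:15, 2:7] <- 3L
  nm <- matrix(0L, 16, 16); nm[4, 4] <- 1L; nm[4, 12] <- 2L; nm[12, 4] <- 3L
  mask <- matrix(runif(256) < 0.3, 16, 16)
  seg <- cell_segmentation(labeled_mask(nm, 1), labeled_mask(cm, 1))
  perm <- c(2L, 3L, 1L)
  cm2 <- cm; cm2[cm > 0] <- perm[cm[cm > 0]]
  nm2 <- nm; nm2[nm > 0] <- perm[nm[nm > 0]]
  seg2 <- cell_segmentation(labeled_mask(nm2, 1), labeled_mask(cm2, 1))
  a <- mito_mass(seg, binary_mask(mask, 1))
  b <- mito_mass(seg2, binary_mask(mask, 1))
  expect_equal(b$mito_area_um2[match(perm[a$cell_id], b$cell_id)], a$mito_area_um2)
})
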