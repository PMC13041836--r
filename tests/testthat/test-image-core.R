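test_that("stack write/read round-trips bit-identically and validates channels", {
  set.seed(1)
  px <- array(sample(0:4095, 3 * 2 * 16 * 14, replace = TRUE),
              dim = c(3, 2, 16, 14))
  st <- image_stack(px, 0.3, c(dapi = 1L, gfp = 2L))
  f <- tempfile(fileext = ".tif")
  write_stack(st, f)
  st2 <- load_stack(f, c(dapi = 1L, gfp = 2L), 0.3)
  expect_identical(dim(st2$pixels), dim(st$pixels))
  expect_identical(st2$pixels, st$pixels)
  expect_error(load_stack(f, c(a = 1L, b = 2L, c = 3L), 0.3),
               "channel-count mismatch")
  expect_error(load_stack(tempfile(), c(a = 1L), 0.3), "not found")
})

test_that("projections match per-pixel loops and respect trivial cases", {
  one <- toy_stack(list(gfp = matrix(1:12, 3, 4)))
  expect_equal(max_project(one, "gfp")$pixels, matrix(1:12, 3, 4))
  expect_equal(sum_project(one, "gfp")$pixels, matrix(1:12, 3, 4))
  expect_error(max_project(one, "tmre"), "unknown channel role")

  s1 <- matrix(c(0, 2, 1, 3), 2, 2, byrow = TRUE)
  s2 <- matrix(c(5, 1, 0, 1), 2, 2, byrow = TRUE)
  a <- array(0, dim = c(2, 1, 2, 2)); a[1, 1, , ] <- s1; a[2, 1, , ] <- s2
  st <- image_stack(a, 1, c(gfp = 1L))
  expect_equal(max_project(st, "gfp")$pixels,
               matrix(c(5, 2, 1, 3), 2, 2, byrow = TRUE))
  expect_equal(sum_project(st, "gfp")$pixels, s1 + s2)

  set.seed(42)
  a <- array(runif(4 * 1 * 7 * 6), dim = c(4, 1, 7, 6))
  st <- image_stack(a, 1, c(x = 1L))
  mx <- matrix(0, 7, 6); sm <- matrix(0, 7, 6)
  for (y in 1:7) for (x in 1:6) {
    mx[y, x] <- max(a[, 1, y, x]); sm[y, x] <- sum(a[, 1, y, x])
  }
  expect_equal(max_project(st, "x")$pixels, mx)
  expect_equal(sum_project(st, "x")$pixels, sm)
})

test_that("top-hat matches the brute-force morphology oracle", {
  expect_equal(tophat(mk_img(matrix(7, 9, 9)), 2)$pixels, matrix(0, 9, 9))
  m <- matrix(0, 9, 9); m[5, 5] <- 11
  th <- tophat(mk_img(m), 2)$pixels
  expect_equal(th[5, 5], 11)
  expect_equal(sum(th), 11)
  expect_error(tophat(mk_img(m), 0), "radius")

  set.seed(7)
  for (i in 1:6) {
    img <- matrix(runif(16 * 16) * 100, 16, 16)
    r <- sample(2:4, 1)
    expect_equal(tophat(mk_img(img), r)$pixels, oracle_tophat(img, r))
  }
})

test_that("top-hat output is bounded by the input and non-negative", {
  set.seed(11)
  for (i in 1:10) {
    img <- matrix(rexp(14 * 17) * 50, 14, 17)
    th <- tophat(mk_img(img), sample(1:5, 1))$pixels
    expect_true(all(th >= 0))
    expect_true(all(th <= img + 1e-9))
  }
})

test_that("gaussian blur preserves constants, symmetry and the analytic kernel", {
  expect_lt(max(abs(gaussian_blur(mk_img(matrix(3.7, 12, 12)), 2)$pixels - 3.7)), 1e-9)
  m <- matrix(0, 31, 31); m[16, 16] <- 1
  bl <- gaussian_blur(mk_img(m), 1.5)$pixels
  expect_equal(which(bl == max(bl)), which(m == 1))
  expect_equal(bl, t(bl))                       # radial symmetry
  expect_equal(bl, bl[31:1, ])
  expect_equal(sum(bl), 1, tolerance = 1e-3)    # intensity conservation
  # analytic 2-D Gaussian within 1% at r <= 3 sigma
  k1 <- dnorm(-6:6, sd = 1.5); k1 <- k1 / sum(k1)
  for (dy in -4:4) for (dx in -4:4) {
    if (dy^2 + dx^2 > (3 * 1.5)^2) next
    expect_equal(bl[16 + dy, 16 + dx], k1[7 + dy] * k1[7 + dx],
                 tolerance = 0.01)
  }
  expect_error(gaussian_blur(mk_img(m), 0), "sigma")
})

test_that("thresholding follows the strict-inequality contract and Otsu oracle", {
  img <- mk_img(matrix(c(0, 10, 10, 0), 2, 2, byrow = TRUE))
  expect_identical(threshold_binarize(img, "fixed", 5)$pixels,
                   matrix(c(FALSE, TRUE, TRUE, FALSE), 2, 2, byrow = TRUE))
  z <- mk_img(matrix(0, 3, 3))
  expect_false(any(threshold_binarize(z, "fixed", 0)$pixels))
  expect_error(threshold_binarize(z, "otsu"), "distinct")
  expect_error(threshold_binarize(img, "fixed"), "value")

  set.seed(5)
  v <- c(round(rnorm(600, 20, 2)), round(rnorm(400, 200, 6)))
  img <- mk_img(matrix(v, 40, 25))
  mask <- threshold_binarize(img, "otsu")
  thr <- attr(mask, "threshold")
  expect_equal(thr, oracle_otsu(v))
  expect_gte(thr, 20); expect_lte(thr, 200)
  expect_gte(sum(mask$pixels & matrix(v, 40, 25) > 100) / 400, 0.99)
})

test_that("connected components agree with flood fill under both connectivities", {
  empty <- connected_components(mk_mask(matrix(0, 5, 5)), 8L)
  expect_equal(empty$n_objects, 0L)
  diagm <- matrix(0, 4, 4); diagm[2, 2] <- 1; diagm[3, 3] <- 1
  expect_equal(connected_components(mk_mask(diagm), 8L)$n_objects, 1L)
  expect_equal(connected_components(mk_mask(diagm), 4L)$n_objects, 2L)

  set.seed(13)
  for (i in 1:30) {
    m <- matrix(rbinom(20 * 20, 1, 0.4), 20, 20)
    for (conn in c(4L, 8L)) {
      got <- connected_components(mk_mask(m), conn)$labels
      expect_identical(got, oracle_flood_fill(m > 0, conn))
    }
  }
})

test_that("component count is invariant to transposition and rotation", {
  set.seed(17)
  for (i in 1:8) {
    m <- matrix(rbinom(15 * 18, 1, 0.35), 15, 18)
    n0 <- connected_components(mk_mask(m), 8L)$n_objects
    expect_equal(connected_components(mk_mask(t(m)), 8L)$n_objects, n0)
    rot90 <- t(m)[, nrow(m):1, drop = FALSE]
    expect_equal(connected_components(mk_mask(rot90), 8L)$n_objects, n0)
  }
})

test_that("watershed splits merged disks, preserves the mask, and reduces to labeling", {
  m <- put_disk(matrix(0, 15, 15), 8, 8, 4, 1)
  ws <- watershed_split(mk_mask(m), 3)
  expect_equal(ws$n_objects, 1L)
  expect_identical(ws$labels > 0L, m > 0)

  # two radius-4 disks overlapping by 2 px (centres 6 apart)
  m2 <- put_disk(put_disk(matrix(0, 17, 23), 9, 8, 4, 1), 9, 14, 4, 1)
  ws2 <- watershed_split(mk_mask(m2), 3)
  expect_equal(ws2$n_objects, 2L)
  expect_identical(ws2$labels > 0L, m2 > 0)
  areas <- tabulate(ws2$labels[ws2$labels > 0L])
  disk_area <- sum(put_disk(matrix(0, 15, 15), 8, 8, 4, 1))
  expect_true(all(abs(areas - disk_area) / disk_area <= 0.15))

  # well-separated blobs: identical to connected components
  set.seed(19)
  m3 <- matrix(0, 40, 40)
  for (c in list(c(8, 8), c(8, 30), c(30, 8), c(30, 30), c(20, 20)))
    m3 <- put_disk(m3, c[1], c[2], 3, 1)
  ws3 <- watershed_split(mk_mask(m3), 3)
  cc3 <- connected_components(mk_mask(m3), 8L)
  expect_equal(ws3$n_objects, 5L)
  expect_identical(ws3$labels, cc3$labels)
})

test_that("watershed label union equals the mask on random inputs", {
  set.seed(23)
  for (i in 1:10) {
    m <- matrix(rbinom(25 * 25, 1, 0.45), 25, 25)
    ws <- watershed_split(mk_mask(m), 2.5)
    expect_identical(ws$labels > 0L, m > 0)
  }
})

test_that("measure_objects equals per-pixel accumulation", {
  lab <- matrix(0L, 4, 4); lab[2:3, 2:3] <- 1L
  t1 <- measure_objects(labeled_mask(lab, 0.5))
  expect_equal(t1$area_um2, 1.0)   # 4 px x 0.25 um^2

  ints <- matrix(0, 4, 4); ints[2:3, 2:3] <- c(10, 20, 30, 40)
  t2 <- measure_objects(labeled_mask(lab, 0.5), list(x = image2d(ints, 0.5)))
  expect_equal(t2$mean_x, 25); expect_equal(t2$sum_x, 100)

  set.seed(29)
  for (i in 1:8) {
    m <- matrix(rbinom(15 * 15, 1, 0.4), 15, 15)
    lab <- connected_components(mk_mask(m), 8L)
    img1 <- matrix(runif(225) * 50, 15, 15)
    img2 <- matrix(rpois(225, 9), 15, 15)
    cells <- labeled_mask(matrix(rep(1:3, each = 75), 15, 15), 1)
    got <- measure_objects(lab, list(a = mk_img(img1), b = mk_img(img2)), cells)
    want <- oracle_measure(lab$labels, list(a = img1, b = img2), cells$labels)
    expect_equal(got, want)
  }
})

test_that("total measured area equals pixel area times foreground count", {
  set.seed(31)
  for (i in 1:6) {
    m <- matrix(rbinom(20 * 20, 1, 0.3), 20, 20)
    px_um <- runif(1, 0.1, 1)
    lab <- connected_components(binary_mask(m > 0, px_um), 8L)
    tab <- measure_objects(lab)
    expect_equal(sum(tab$area_um2), sum(m) * px_um^2)
  }
})

test_that("image operations are deterministic", {
  set.seed(37)
  img <- matrix(runif(30 * 30) * 100, 30, 30)
  expect_identical(tophat(mk_img(img), 3)$pixels, tophat(mk_img(img), 3)$pixels)
  m <- img > 50
  expect_identical(watershed_split(binary_mask(m, 1), 3)$labels,
                   watershed_split(binary_mask(m, 1), 3)$labels)
})
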