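# crisp two-level images: Otsu reduces to separating the two values
.nuclei_field <- function(centres, r = 4, dim = c(64L, 64L), amp = 150) {
  m <- matrix(0, dim[1L], dim[2L])
  for (c in centres) m <- put_disk(m, c[1L], c[2L], r, amp)
  m
}

test_that("nucleus segmentation finds planted nuclei and filters debris", {
  cent <- list(c(12, 12), c(12, 40), c(32, 26), c(50, 12), c(50, 45))
  lab <- segment_nuclei(mk_img(.nuclei_field(cent)), min_area_um2 = 10)
  expect_equal(lab$n_objects, 5L)

  # hot pixels only: everything below the minimum area
  salt <- matrix(0, 64, 64); salt[cbind(c(5, 30, 55), c(7, 44, 20))] <- 120
  expect_equal(segment_nuclei(mk_img(salt), min_area_um2 = 5)$n_objects, 0L)

  expect_error(segment_nuclei(mk_img(matrix(3, 32, 32)), 5), "distinct")

  # one sub-threshold nucleus among four
  m <- .nuclei_field(list(c(12, 12), c(12, 40), c(40, 40)))
  m <- put_disk(m, 40, 12, 1, 150)   # 5 px, area 5 um^2 at 1 um pixels
  expect_equal(segment_nuclei(mk_img(m), min_area_um2 = 20)$n_objects, 3L)
})

test_that("cell segmentation grows nucleus-labeled cells inside the cytoplasm mask", {
  dapi <- .nuclei_field(list(c(32, 32)), r = 3)
  cyto <- put_disk(matrix(0, 64, 64), 32, 32, 14, 60)
  nuclei <- segment_nuclei(mk_img(dapi), 5)
  cells <- segment_cells(mk_img(cyto), nuclei, sigma_px = 2)
  expect_equal(cells$n_objects, 1L)
  expect_true(all(cells$labels[nuclei$labels == 1L] == 1L))  # nucleus inside cell

  # two touching cells: partition splits at the midline
  dapi2 <- .nuclei_field(list(c(32, 20), c(32, 44)), r = 3)
  cyto2 <- put_disk(put_disk(matrix(0, 64, 64), 32, 20, 13, 60), 32, 44, 13, 60)
  nuclei2 <- segment_nuclei(mk_img(dapi2), 5)
  cells2 <- segment_cells(mk_img(cyto2), nuclei2, sigma_px = 2)
  expect_equal(cells2$n_objects, 2L)
  expect_equal(cells2$labels[32, 24], cells2$labels[32, 20])
  expect_equal(cells2$labels[32, 40], cells2$labels[32, 44])
  expect_true(cells2$labels[32, 20] != cells2$labels[32, 44])
  # cells are disjoint by construction of a label image; nuclei stay inside
  for (id in 1:2)
    expect_true(all(cells2$labels[nuclei2$labels == id] == id))

  # nucleus without surrounding cytoplasm: cell collapses to the nucleus
  salt <- matrix(0, 64, 64); salt[cbind(c(3, 60), c(3, 60))] <- 40
  cells3 <- segment_cells(mk_img(salt), nuclei, sigma_px = 2)
  expect_identical(cells3$labels == 1L, nuclei$labels == 1L)

  empty <- labeled_mask(matrix(0L, 64, 64), 1)
  expect_warning(c4 <- segment_cells(mk_img(cyto), empty, 2), "no nuclei")
  expect_equal(c4$n_objects, 0L)
})

.toy_seg <- function(cells_m, nuclei_m, px = 1) {
  cell_segmentation(labeled_mask(nuclei_m, px), labeled_mask(cells_m, px))
}

test_that("edge exclusion removes exactly the border-touching cells, idempotently", {
  cm <- matrix(0L, 20, 20)
  cm[3:6, 3:6] <- 1L; cm[3:6, 12:15] <- 2L; cm[14:17, 3:6] <- 3L
  cm[14:17, 12:15] <- 4L; cm[9:12, 8:11] <- 5L
  cm[1:4, 17:20] <- 6L                       # straddles the border
  nm <- matrix(0L, 20, 20)
  for (id in 1:6) nm[which(cm == id)[1:2]] <- id
  seg <- exclude_edge_cells(.toy_seg(cm, nm))
  expect_equal(seg$excluded_edge_ids, 6L)
  expect_equal(retained_cells(seg), 1:5)
  expect_false(any(seg$nuclei$labels == 6L))
  expect_identical(exclude_edge_cells(seg), seg)   # idempotent

  all_interior <- .toy_seg(cm * (cm != 6L), nm * (nm != 6L))
  expect_length(exclude_edge_cells(all_interior)$excluded_edge_ids, 0L)

  border_only <- matrix(1L, 8, 8)
  seg_b <- exclude_edge_cells(.toy_seg(border_only, matrix(0L, 8, 8)))
  expect_length(retained_cells(seg_b), 0L)
})

test_that("intensity gating matches the sort-based quantile oracle", {
  # ten 2x2 cells with mean intensities 1..10
  cm <- matrix(0L, 8, 40); ch <- matrix(0, 8, 40)
  for (i in 1:10) {
    ys <- 3:4; xs <- (4 * i - 2):(4 * i - 1)
    cm[ys, xs] <- i; ch[ys, xs] <- i
  }
  nm <- matrix(0L, 8, 40); for (i in 1:10) nm[3, 4 * i - 2] <- i
  seg <- .toy_seg(cm, nm)

  s0 <- gate_cells_by_intensity(seg, mk_img(ch), 0, 1)
  expect_equal(retained_cells(s0), 1:10)        # trivial gate keeps all

  s1 <- gate_cells_by_intensity(seg, mk_img(ch), 0.25, 0.75)
  expect_equal(retained_cells(s1), oracle_gate_survivors(1:10, 0.25, 0.75))
  expect_equal(s1$excluded_gate_ids, c(1:3, 8:10))
  expect_equal(unname(s1$gate_bounds), c(3.25, 7.75))

  flat <- mk_img((ch > 0) * 5)                  # all means equal: ties retained
  s2 <- gate_cells_by_intensity(seg, flat, 0.25, 0.75)
  expect_equal(retained_cells(s2), 1:10)

  set.seed(3)
  for (i in 1:10) {                             # random means vs oracle
    means <- round(runif(10) * 100, 2)
    chr <- cm * 0
    for (j in 1:10) chr[cm == j] <- means[j]
    sr <- gate_cells_by_intensity(seg, mk_img(chr), 0.2, 0.8)
    expect_equal(retained_cells(sr), sort(oracle_gate_survivors(means, 0.2, 0.8)))
  }
})

test_that("gating commutes with relabeling of cell ids", {
  cm <- matrix(0L, 8, 40); ch <- matrix(0, 8, 40)
  set.seed(9)
  means <- runif(10) * 50
  for (i in 1:10) {
    cm[3:4, (4 * i - 2):(4 * i - 1)] <- i
    ch[3:4, (4 * i - 2):(4 * i - 1)] <- means[i]
  }
  nm <- matrix(0L, 8, 40); for (i in 1:10) nm[3, 4 * i - 2] <- i
  perm <- sample(10)
  cm2 <- cm; cm2[cm > 0] <- perm[cm[cm > 0]]
  nm2 <- nm; nm2[nm > 0] <- perm[nm[nm > 0]]
  r1 <- retained_cells(gate_cells_by_intensity(.toy_seg(cm, nm), mk_img(ch), 0.2, 0.8))
  r2 <- retained_cells(gate_cells_by_intensity(.toy_seg(cm2, nm2), mk_img(ch), 0.2, 0.8))
  expect_equal(sort(perm[r1]), r2)
})
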