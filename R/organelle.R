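# Shared "touching" predicate: an object touches a mask iff at least one of
# its pixels overlaps the mask or is 8-adjacent to it.  Implemented by
# dilating the mask with a 3x3 box and testing overlap.
touching_label_ids <- function(labels, mask) {
  dil <- dilate_gray(mask$pixels * 1, matrix(TRUE, 3L, 3L)) > 0
  sort(setdiff(unique(labels$labels[dil]), 0L))
}

# per-cell tallies of object cell ids over a fixed id set (zeros kept)
.per_cell_counts <- function(cell_ids, obj_cells) {
  vapply(cell_ids, function(cid) sum(obj_cells == cid), integer(1L))
}

#' Count mitolysosomes (mCherry-only puncta) per cell
#'
#' A watershed-split mCherry punctum counts as a mitolysosome for its cell
#' iff none of its pixels coincides with, or is 8-adjacent to, the GFP
#' network mask: red-only puncta mark mitochondria inside acidified
#' lysosomes, where GFP is quenched.
#'
#' @param seg a [cell_segmentation()] (after edge exclusion / gating).
#' @param gfp_mask a [binary_mask()] of the GFP mitochondrial network
#'   (top-hat, threshold).
#' @param mcherry_labels a [labeled_mask()] of mCherry objects (top-hat,
#'   threshold, watershed).
#' @return A list with `per_cell` (data.frame `cell_id`, `n_total`,
#'   `n_touching`, `n_mitolysosomes`) and `field_mean` (mean mitolysosomes
#'   per retained cell).
#' @export
count_mitolysosomes <- function(seg, gfp_mask, mcherry_labels) {
  ids <- retained_cells(seg)
  if (!length(ids)) stop("no retained cells")
  obj <- measure_objects(mcherry_labels, cell_labels = seg$cells)
  touch <- touching_label_ids(mcherry_labels, gfp_mask)
  obj$touching <- obj$object_id %in% touch
  obj <- obj[obj$cell_id %in% ids, , drop = FALSE]
  per_cell <- data.frame(
    cell_id = ids,
    n_total = .per_cell_counts(ids, obj$cell_id),
    n_touching = .per_cell_counts(ids, obj$cell_id[obj$touching]),
    n_mitolysosomes = .per_cell_counts(ids, obj$cell_id[!obj$touching]))
  list(per_cell = per_cell, field_mean = mean(per_cell$n_mitolysosomes))
}

#' Mitophagy flux from paired mitolysosome counts
#'
#' The flux is the ratio of the mean mitolysosome count per cell with
#' lysosomal protease inhibitors (degradation blocked, mitolysosomes
#' accumulate) to the mean without.  Cells are not paired across wells, so
#' the ratio is taken between arm means.
#'
#' @param counts_minus,counts_plus numeric vectors of per-cell counts for
#'   the two arms (both non-empty).
#' @return An object of class `"FluxResult"`.
#' @export
compute_flux <- function(counts_minus, counts_plus) {
  if (!length(counts_minus) || !length(counts_plus)) stop("empty arm")
  m0 <- mean(counts_minus); m1 <- mean(counts_plus)
  defined <- m0 > 0
  structure(list(counts_minus = counts_minus, counts_plus = counts_plus,
                 mean_minus = m0, mean_plus = m1,
                 flux_ratio = if (defined) m1 / m0 else NA_real_,
                 n_minus = length(counts_minus), n_plus = length(counts_plus),
                 defined = defined),
            class = "FluxResult")
}

#' @export
print.FluxResult <- function(x, ...) {
  cat(sprintf("Mitophagy flux: mean %0.3g (-inh, n=%d) vs %0.3g (+inh, n=%d)\n",
              x$mean_minus, x$n_minus, x$mean_plus, x$n_plus))
  if (x$defined) cat(sprintf("  flux ratio = %0.4g\n", x$flux_ratio))
  else cat("  flux ratio undefined (zero mean without inhibitor)\n")
  invisible(x)
}

#' Mitochondrial mass per cell
#'
#' Summed segmented mitochondrial area (um^2) inside each retained cell.
#'
#' @param seg a [cell_segmentation()].
#' @param mito_mask a [binary_mask()] of mitochondria.
#' @return data.frame `cell_id`, `mito_area_um2`.
#' @export
mito_mass <- function(seg, mito_mask) {
  if (any(dim(mito_mask$pixels) != dim(seg$cells$labels)))
    stop("grid mismatch")
  ids <- retained_cells(seg)
  lab <- seg$cells$labels
  px2 <- seg$cells$pixel_size_um^2
  cnt <- vapply(ids, function(cid) sum(mito_mask$pixels[lab == cid]), integer(1L))
  data.frame(cell_id = ids, mito_area_um2 = cnt * px2)
}

#' Classify individualized and depolarized mitochondria
#'
#' MTG objects smaller than `area_cutoff_um2` inside retained cells are
#' "individualized small" mitochondria; of those, objects whose mean TMRE
#' (sum projection) falls below the background-derived cutoff — mean +
#' `bg_k` * sd of TMRE over non-mitochondrial pixels within retained cells —
#' are "depolarized".  The cutoff construction makes the counts exactly
#' invariant to a uniform additive TMRE offset.
#'
#' @param seg a [cell_segmentation()].
#' @param mtg_labels a [labeled_mask()] of MTG objects.
#' @param tmre_sum an [image2d()], the TMRE sum projection.
#' @param area_cutoff_um2 small-mitochondrion area cutoff (default 1 um^2).
#' @param bg_k multiplier on the background sd.
#' @return An object of class `"DepolarizationResult"` with `per_cell`
#'   (`cell_id`, `n_individualized_small`, `n_depolarized`),
#'   `tmre_background_cutoff` and `area_cutoff_um2`.
#' @export
classify_depolarized <- function(seg, mtg_labels, tmre_sum,
                                 area_cutoff_um2 = 1.0, bg_k = 3) {
  ids <- retained_cells(seg)
  inside <- seg$cells$labels > 0L
  bg_px <- inside & mtg_labels$labels == 0L
  if (!any(bg_px)) stop("no background pixels: MTG mask covers all retained cells")
  bg <- tmre_sum$pixels[bg_px]
  cutoff <- mean(bg) + bg_k * stats::sd(bg)
  obj <- measure_objects(mtg_labels, list(tmre = tmre_sum), cell_labels = seg$cells)
  obj <- obj[obj$cell_id %in% ids, , drop = FALSE]
  small <- obj[obj$area_um2 < area_cutoff_um2, , drop = FALSE]
  depol <- small[small$mean_tmre < cutoff, , drop = FALSE]
  per_cell <- data.frame(
    cell_id = ids,
    n_individualized_small = .per_cell_counts(ids, small$cell_id),
    n_depolarized = .per_cell_counts(ids, depol$cell_id))
  prov_record("classify_depolarized",
              list(area_cutoff_um2 = area_cutoff_um2, bg_k = bg_k),
              list(tmre_background_cutoff = cutoff))
  structure(list(per_cell = per_cell, tmre_background_cutoff = cutoff,
                 area_cutoff_um2 = area_cutoff_um2),
            class = "DepolarizationResult")
}

#' @export
print.DepolarizationResult <- function(x, ...) {
  cat(sprintf(
    "Depolarization: mean %.3g small / %.3g depolarized per cell (n=%d, TMRE cutoff %.4g)\n",
    mean(x$per_cell$n_individualized_small), mean(x$per_cell$n_depolarized),
    nrow(x$per_cell), x$tmre_background_cutoff))
  invisible(x)
}

#' Count vesicles touching a target mask per cell
#'
#' Same 8-adjacency "touching" predicate as [count_mitolysosomes()], with
#' opposite polarity: a vesicle (e.g. LC3 autophagosome, LAMP1 lysosome)
#' counts iff it overlaps or touches the mitochondrial mask — the
#' mitophagosome / mito-lysosome contact readout.
#'
#' @param seg a [cell_segmentation()].
#' @param vesicle_labels a [labeled_mask()] of vesicles.
#' @param target_mask a [binary_mask()] (e.g. mitochondria).
#' @return A list with `per_cell` (`cell_id`, `n_total`, `n_touching`) and
#'   `field_mean` of touching counts.
#' @export
count_touching_puncta <- function(seg, vesicle_labels, target_mask) {
  ids <- retained_cells(seg)
  obj <- measure_objects(vesicle_labels, cell_labels = seg$cells)
  touch <- touching_label_ids(vesicle_labels, target_mask)
  obj$touching <- obj$object_id %in% touch
  obj <- obj[obj$cell_id %in% ids, , drop = FALSE]
  per_cell <- data.frame(
    cell_id = ids,
    n_total = .per_cell_counts(ids, obj$cell_id),
    n_touching = .per_cell_counts(ids, obj$cell_id[obj$touching]))
  list(per_cell = per_cell,
       field_mean = if (length(ids)) mean(per_cell$n_touching) else NA_real_)
}

#' Peripheral-lysosome distribution statistic
#'
#' Each vesicle's distance (um) is measured from its centroid to the nearest
#' pixel of its cell's nucleus.  Vesicles strictly beyond the 75th
#' percentile of `reference_distances` (or, if absent, of the analyzed
#' field's pooled distances) are "peripheral"; the per-cell statistic is the
#' peripheral count normalised by the cell's mitochondrial area.
#' Percentiles use exclusive linear interpolation (R quantile type 6), which
#' guarantees at most a quarter of the reference population lies strictly
#' above the threshold.
#'
#' @param seg a [cell_segmentation()].
#' @param lyso_labels a [labeled_mask()] of lysosome vesicles.
#' @param nuclei a [labeled_mask()] of nuclei (cell-matched labels).
#' @param mito_area_per_cell data.frame `cell_id`, `mito_area_um2` (from
#'   [mito_mass()]).
#' @param reference_distances optional numeric vector of distances (um) from
#'   the declared reference condition; the threshold is taken there so the
#'   statistic is comparable across arms.
#' @return An object of class `"SpatialDistribution"`: `distances`
#'   (per-vesicle data.frame), `percentile_threshold_um`, `per_cell`
#'   (`cell_id`, `peripheral_count`, `mito_area_um2`,
#'   `peripheral_per_mito_area`), `reference_condition`.
#' @export
lysosome_distribution <- function(seg, lyso_labels, nuclei, mito_area_per_cell,
                                  reference_distances = NULL) {
  ids <- retained_cells(seg)
  obj <- measure_objects(lyso_labels, cell_labels = seg$cells)
  obj <- obj[obj$cell_id %in% ids, , drop = FALSE]
  px <- lyso_labels$pixel_size_um
  h <- nrow(nuclei$labels)
  nl <- nuclei$labels
  nuc_idx <- split(which(nl > 0L), nl[nl > 0L])   # nucleus pixels per cell id
  dist_um <- numeric(nrow(obj))
  for (i in seq_len(nrow(obj))) {
    idx <- nuc_idx[[as.character(obj$cell_id[i])]]
    if (is.null(idx))
      stop(sprintf("cell %d has no nucleus", obj$cell_id[i]))
    ny <- (idx - 1L) %% h; nx <- (idx - 1L) %/% h
    dist_um[i] <- sqrt(min((ny - obj$centroid_y[i])^2 + (nx - obj$centroid_x[i])^2)) * px
  }
  pooled <- if (is.null(reference_distances)) dist_um else reference_distances
  if (!length(pooled)) stop("no distances to take the percentile threshold from")
  # exclusive linear-interpolation percentile: with the strict ">" rule this
  # marks at most 25% of the pooled population peripheral for every n
  thr <- stats::quantile(pooled, 0.75, names = FALSE, type = 6)
  obj$distance_um <- dist_um
  obj$peripheral <- dist_um > thr
  per_cell <- data.frame(
    cell_id = ids,
    peripheral_count = .per_cell_counts(ids, obj$cell_id[obj$peripheral]))
  per_cell <- merge(per_cell, mito_area_per_cell, by = "cell_id", all.x = TRUE)
  per_cell$peripheral_per_mito_area <-
    ifelse(per_cell$mito_area_um2 > 0,
           per_cell$peripheral_count / per_cell$mito_area_um2, NA_real_)
  prov_record("lysosome_distribution",
              list(reference = if (is.null(reference_distances)) "self" else "external"),
              list(percentile_threshold_um = thr))
  structure(list(
    distances = obj[, c("object_id", "cell_id", "distance_um", "peripheral")],
    percentile_threshold_um = thr, per_cell = per_cell,
    reference_condition = if (is.null(reference_distances)) "self" else "reference"),
    class = "SpatialDistribution")
}

#' @export
print.SpatialDistribution <- function(x, ...) {
  cat(sprintf(
    "Lysosome distribution: %d vesicles, 75th-percentile threshold %.3g um (%s)\n",
    nrow(x$distances), x$percentile_threshold_um, x$reference_condition))
  cat(sprintf("  mean peripheral per mito area: %.4g /um^2\n",
              mean(x$per_cell$peripheral_per_mito_area, na.rm = TRUE)))
  invisible(x)
}

#' Mean intensity over a mask
#'
#' Arithmetic mean of `intensity` over the foreground of `mask`, either
#' field-wide or restricted per retained cell.  An empty mask yields `NA`
#' flagged as undefined.
#'
#' @param intensity an [image2d()].
#' @param mask a [binary_mask()].
#' @param per_cell if `TRUE`, one value per retained cell of `cells`.
#' @param cells a [cell_segmentation()] (required when `per_cell`).
#' @return A single number with attribute `defined`, or a data.frame
#'   `cell_id`, `mean_intensity`, `defined`.
#' @export
mean_intensity_in_mask <- function(intensity, mask, per_cell = FALSE, cells = NULL) {
  if (any(dim(intensity$pixels) != dim(mask$pixels))) stop("grid mismatch")
  if (!per_cell) {
    n <- sum(mask$pixels)
    val <- if (n) mean(intensity$pixels[mask$pixels]) else NA_real_
    attr(val, "defined") <- n > 0
    return(val)
  }
  if (is.null(cells)) stop("per_cell requires a CellSegmentation")
  ids <- retained_cells(cells)
  lab <- cells$cells$labels
  res <- lapply(ids, function(cid) {
    sel <- lab == cid & mask$pixels
    n <- sum(sel)
    data.frame(cell_id = cid,
               mean_intensity = if (n) mean(intensity$pixels[sel]) else NA_real_,
               defined = n > 0)
  })
  do.call(rbind, res)
}

#' Mean nuclear marker intensity per cell
#'
#' Mean of the marker over each retained cell's nucleus mask — the nuclear
#' translocation readout; the condition-level statistic is the mean over
#' cells.
#'
#' @param seg a [cell_segmentation()].
#' @param marker an [image2d()].
#' @return list with `per_cell` (`cell_id`, `nuclear_mean`) and `field_mean`.
#' @export
nuclear_mean_intensity <- function(seg, marker) {
  ids <- retained_cells(seg)
  nl <- seg$nuclei$labels
  nm <- vapply(ids, function(cid) {
    sel <- nl == cid
    if (any(sel)) mean(marker$pixels[sel]) else NA_real_
  }, numeric(1L))
  list(per_cell = data.frame(cell_id = ids, nuclear_mean = nm),
       field_mean = mean(nm, na.rm = TRUE))
}

#' Mean cytosolic marker intensity per cell
#'
#' Mean of the marker over each retained cell's cytosol (cell mask minus
#' nucleus mask); the denominator of the nuclear-translocation ratio.
#'
#' @inheritParams nuclear_mean_intensity
#' @return list with `per_cell` (`cell_id`, `cyto_mean`) and `field_mean`.
#' @export
cytosol_mean_intensity <- function(seg, marker) {
  ids <- retained_cells(seg)
  cl <- seg$cells$labels
  nl <- seg$nuclei$labels
  cm <- vapply(ids, function(cid) {
    sel <- cl == cid & nl != cid
    if (any(sel)) mean(marker$pixels[sel]) else NA_real_
  }, numeric(1L))
  list(per_cell = data.frame(cell_id = ids, cyto_mean = cm),
       field_mean = mean(cm, na.rm = TRUE))
}
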