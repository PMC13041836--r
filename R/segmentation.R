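#' Cell-by-cell segmentation result
#'
#' Nuclei and cells share label ids (a cell carries the label of its seed
#' nucleus).  Exclusion never renumbers: excluded cells are erased from the
#' masks and their ids recorded, so per-cell statistics are stable under the
#' field's original labeling.
#'
#' @param nuclei a [labeled_mask()] of nuclei.
#' @param cells a [labeled_mask()] of cells seeded from `nuclei`.
#' @return An object of class `"CellSegmentation"`.
#' @export
cell_segmentation <- function(nuclei, cells) {
  structure(list(nuclei = nuclei, cells = cells,
                 excluded_edge_ids = integer(), excluded_gate_ids = integer(),
                 gate_bounds = NULL, gate_warning = FALSE),
            class = "CellSegmentation")
}

#' @export
print.CellSegmentation <- function(x, ...) {
  cat(sprintf("CellSegmentation: %d retained cells (%d edge-excluded, %d gate-excluded)\n",
              length(retained_cells(x)), length(x$excluded_edge_ids),
              length(x$excluded_gate_ids)))
  if (!is.null(x$gate_bounds))
    cat(sprintf("  gate bounds: [%.4g, %.4g]\n", x$gate_bounds[1L], x$gate_bounds[2L]))
  invisible(x)
}

#' Ids of cells retained for analysis
#' @param seg a [cell_segmentation()].
#' @return sorted integer vector of retained cell labels.
#' @export
retained_cells <- function(seg) {
  sort(setdiff(unique(as.vector(seg$cells$labels)), 0L))
}

#' Segment nuclei from a DAPI image
#'
#' Otsu threshold, hole filling, 8-connected labeling, then removal of
#' objects below `min_area_um2` (debris and noise specks).
#'
#' @param dapi an [image2d()].
#' @param min_area_um2 minimum nucleus area.
#' @return A [labeled_mask()].
#' @export
segment_nuclei <- function(dapi, min_area_um2 = 5) {
  mask <- threshold_binarize(dapi, "otsu")
  filled <- matrix(as.integer(EBImage::fillHull(mask$pixels * 1)) > 0,
                   nrow(mask$pixels), ncol(mask$pixels))
  lab <- connected_components(binary_mask(filled, dapi$pixel_size_um), 8L)
  tab <- tabulate(lab$labels[lab$labels > 0L])
  small <- which(tab * dapi$pixel_size_um^2 < min_area_um2)
  if (length(small)) {
    m <- lab$labels
    m[m %in% small] <- 0L
    lab <- labeled_mask(raster_relabel(m), dapi$pixel_size_um)
  }
  prov_record("segment_nuclei", list(min_area_um2 = min_area_um2),
              list(threshold = attr(mask, "threshold"), n_nuclei = lab$n_objects))
  lab
}

#' Segment cells from a cytoplasm-wide channel seeded by nuclei
#'
#' The channel is Gaussian-blurred and Otsu-thresholded into a cytoplasm
#' mask; cells are grown geodesically from the nucleus seeds inside that
#' mask, so each cell inherits its nucleus label.  Cytoplasm unreachable
#' from any nucleus stays background.
#'
#' @param cyto an [image2d()] of a cell-filling channel (e.g. blurrable GFP).
#' @param nuclei a [labeled_mask()] from [segment_nuclei()].
#' @param sigma_px Gaussian blur sigma.
#' @return A [labeled_mask()] of cells with nucleus-matched labels.
#' @export
segment_cells <- function(cyto, nuclei, sigma_px = 8) {
  if (nrow(cyto$pixels) != nrow(nuclei$labels) ||
      ncol(cyto$pixels) != ncol(nuclei$labels))
    stop("grid mismatch between cytoplasm image and nuclei")
  if (nuclei$n_objects == 0L) {
    warning("no nuclei: returning empty cell labeling")
    return(labeled_mask(matrix(0L, nrow(cyto$pixels), ncol(cyto$pixels)),
                        cyto$pixel_size_um))
  }
  bl <- gaussian_blur(cyto, sigma_px)
  mask <- threshold_binarize(bl, "otsu")
  m <- mask$pixels | nuclei$labels > 0L   # nuclei always belong to their cell
  lab <- EBImage::propagate(matrix(0, nrow(m), ncol(m)), nuclei$labels, mask = m)
  lab <- matrix(as.integer(lab), nrow(m), ncol(m))
  prov_record("segment_cells", list(sigma_px = sigma_px),
              list(threshold = attr(mask, "threshold")))
  labeled_mask(lab, cyto$pixel_size_um)
}

#' Exclude cells touching the field border
#'
#' Cells not fully depicted in the field of view are removed from both the
#' cell and nucleus masks; their ids are appended to `excluded_edge_ids`.
#' Idempotent.
#'
#' @param seg a [cell_segmentation()].
#' @return The updated segmentation.
#' @export
exclude_edge_cells <- function(seg) {
  m <- seg$cells$labels
  h <- nrow(m); w <- ncol(m)
  border <- unique(c(m[1L, ], m[h, ], m[, 1L], m[, w]))
  border <- sort(setdiff(border, 0L))
  if (length(border)) {
    m[m %in% border] <- 0L
    nm <- seg$nuclei$labels
    nm[nm %in% border] <- 0L
    seg$cells <- labeled_mask(m, seg$cells$pixel_size_um)
    seg$nuclei <- labeled_mask(nm, seg$nuclei$pixel_size_um)
    seg$excluded_edge_ids <- sort(union(seg$excluded_edge_ids, border))
  }
  seg
}

#' Gate cells on mean reporter intensity
#'
#' Per-cell mean intensity of `channel` is computed over the cell mask;
#' cells strictly below the `low_q` quantile or strictly above the `high_q`
#' quantile of the field's distribution are excluded, keeping the
#' medium-intensity population.  Quantiles use R's default linear
#' interpolation, so ties sit inside the closed interval and are retained.
#'
#' @param seg a [cell_segmentation()].
#' @param channel an [image2d()] (e.g. the GFP reporter).
#' @param low_q,high_q gate quantiles, `0 <= low_q < high_q <= 1`.
#' @return The updated segmentation with `gate_bounds` set; a warning flag
#'   is raised when fewer than 3 cells survive.
#' @export
gate_cells_by_intensity <- function(seg, channel, low_q = 0.10, high_q = 0.90) {
  stopifnot(low_q >= 0, high_q <= 1, low_q < high_q)
  ids <- retained_cells(seg)
  if (!length(ids)) return(seg)
  lab <- seg$cells$labels
  nz <- which(lab > 0L)
  g <- match(lab[nz], ids)
  means <- rowsum(channel$pixels[nz], g)[, 1L] / tabulate(g, length(ids))
  bounds <- stats::quantile(means, c(low_q, high_q), names = FALSE, type = 7)
  out <- ids[means < bounds[1L] | means > bounds[2L]]
  if (length(out)) {
    m <- lab; m[m %in% out] <- 0L
    nm <- seg$nuclei$labels; nm[nm %in% out] <- 0L
    seg$cells <- labeled_mask(m, seg$cells$pixel_size_um)
    seg$nuclei <- labeled_mask(nm, seg$nuclei$pixel_size_um)
    seg$excluded_gate_ids <- sort(union(seg$excluded_gate_ids, out))
  }
  seg$gate_bounds <- bounds
  if (length(retained_cells(seg)) < 3L) {
    warning("fewer than 3 cells retained after intensity gating")
    seg$gate_warning <- TRUE
  }
  prov_record("gate_cells_by_intensity", list(low_q = low_q, high_q = high_q),
              list(bounds = bounds, n_excluded = length(out)))
  seg
}
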