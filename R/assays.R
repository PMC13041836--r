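#' Default analysis options
#'
#' Shared tunables of the classical segmentation pipeline.  Defaults:
#' top-hat disk radius 5 px, watershed seed separation 3 px, cytoplasm blur
#' sigma 8 px, GFP gate quantiles (0.10, 0.90), minimum nucleus area 5 um^2,
#' TMRE small-mitochondrion area cutoff 1 um^2 with background cutoff at
#' mean + 3 sd, and a debris floor of 0.2 um^2 on segmented organelle
#' objects (isolated shot-noise pixels that survive thresholding).
#'
#' @param ... overrides of the defaults.
#' @return A named list of options.
#' @export
assay_options <- function(...) {
  opts <- list(tophat_radius_px = 5L, min_seed_distance_px = 3,
               cyto_sigma_px = 8, gate_low_q = 0.10, gate_high_q = 0.90,
               min_nucleus_area_um2 = 5, min_object_area_um2 = 0.2,
               area_cutoff_um2 = 1.0, bg_k = 3,
               min_prominence_frac = 0.2, min_separation_um = 0.06,
               po_ratio = 2.75, o2_per_o = 2, gate = TRUE)
  ov <- list(...)
  unknown <- setdiff(names(ov), names(opts))
  if (length(unknown))
    stop(sprintf("unknown option(s): %s", paste(unknown, collapse = ", ")))
  utils::modifyList(opts, ov)
}

# nuclei + cells + edge exclusion (+ optional intensity gate) from a stack
.segment_field <- function(stack, cyto_role, gate_role = NULL, opts = assay_options()) {
  dapi <- max_project(stack, "dapi")
  nuclei <- segment_nuclei(dapi, opts$min_nucleus_area_um2)
  cyto <- max_project(stack, cyto_role)
  cells <- segment_cells(cyto, nuclei, opts$cyto_sigma_px)
  seg <- exclude_edge_cells(cell_segmentation(nuclei, cells))
  if (!is.null(gate_role) && isTRUE(opts$gate))
    seg <- gate_cells_by_intensity(seg, max_project(stack, gate_role),
                                   opts$gate_low_q, opts$gate_high_q)
  seg
}

# top-hat -> Otsu mask of a max projection
.puncta_mask <- function(stack, role, opts) {
  threshold_binarize(tophat(max_project(stack, role), opts$tophat_radius_px), "otsu")
}

# remove labeled objects below a physical-area debris floor
.drop_debris <- function(labels, min_area_um2) {
  if (min_area_um2 <= 0 || labels$n_objects == 0L) return(labels)
  tab <- tabulate(labels$labels[labels$labels > 0L])
  drop <- which(tab * labels$pixel_size_um^2 < min_area_um2)
  if (!length(drop)) return(labels)
  m <- labels$labels
  m[m %in% drop] <- 0L
  labeled_mask(raster_relabel(m), labels$pixel_size_um)
}

#' Analyze one mito-QC field
#'
#' Full per-field pipeline: nuclei (DAPI) + cells (blurred GFP) with edge
#' exclusion and GFP intensity gating; GFP network mask and watershed-split
#' mCherry objects via top-hat/Otsu; mCherry puncta not touching the GFP
#' mask counted as mitolysosomes per cell.
#'
#' @param stack an [image_stack()] with roles `dapi`, `gfp`, `mcherry`.
#' @param opts an [assay_options()] list.
#' @return list: `seg`, `per_cell`, `field_mean`, `mcherry_labels`,
#'   `counted_ids` (mCherry labels counted as mitolysosomes).
#' @export
analyze_mitoqc_field <- function(stack, opts = assay_options()) {
  seg <- .segment_field(stack, "gfp", gate_role = "gfp", opts = opts)
  gfp_mask <- .puncta_mask(stack, "gfp", opts)
  mch_mask <- .puncta_mask(stack, "mcherry", opts)
  mch_labels <- watershed_split(mch_mask, opts$min_seed_distance_px)
  res <- count_mitolysosomes(seg, gfp_mask, mch_labels)
  obj <- measure_objects(mch_labels, cell_labels = seg$cells)
  touch <- touching_label_ids(mch_labels, gfp_mask)
  counted <- obj$object_id[!(obj$object_id %in% touch) &
                             obj$cell_id %in% retained_cells(seg)]
  c(res, list(seg = seg, mcherry_labels = mch_labels, counted_ids = counted))
}

#' Analyze one TMRE/MTG membrane-potential field
#'
#' Cells from blurred MTG; MTG objects from top-hat/Otsu on the max
#' projection; TMRE read from the sum projection; depolarized classification
#' per [classify_depolarized()].
#'
#' @param stack roles `dapi`, `mtg`, `tmre`.
#' @param opts an [assay_options()] list.
#' @return list: `seg`, `result` (DepolarizationResult).
#' @export
analyze_tmre_field <- function(stack, opts = assay_options()) {
  seg <- .segment_field(stack, "mtg", opts = opts)
  mtg_labels <- .drop_debris(connected_components(.puncta_mask(stack, "mtg", opts), 8L),
                             opts$min_object_area_um2)
  tmre_sum <- sum_project(stack, "tmre")
  list(seg = seg,
       result = classify_depolarized(seg, mtg_labels, tmre_sum,
                                     opts$area_cutoff_um2, opts$bg_k))
}

#' Analyze one mitochondrial-mass field
#'
#' @param stack roles `dapi` and `mito_marker`.
#' @param opts an [assay_options()] list.
#' @return list: `seg`, `per_cell` (mito area per cell, um^2).
#' @export
analyze_mito_mass_field <- function(stack, opts = assay_options()) {
  seg <- .segment_field(stack, "mito_marker", opts = opts)
  mask <- .puncta_mask(stack, "mito_marker", opts)
  list(seg = seg, per_cell = mito_mass(seg, mask))
}

#' Analyze one touching-puncta (colocalization) field
#'
#' Vesicles (watershed-split) touching the target mask are counted per cell
#' — the LC3-mitophagosome or LAMP1-mitochondrion contact readout.
#'
#' @param stack roles `dapi`, `vesicle_role`, `target_role`.
#' @param vesicle_role,target_role channel role tags.
#' @param opts an [assay_options()] list.
#' @return list: `seg`, `per_cell`, `field_mean`.
#' @export
analyze_touching_field <- function(stack, vesicle_role = "lc3",
                                   target_role = "mito_marker",
                                   opts = assay_options()) {
  seg <- .segment_field(stack, target_role, opts = opts)
  ves <- watershed_split(.puncta_mask(stack, vesicle_role, opts),
                         opts$min_seed_distance_px)
  target <- .puncta_mask(stack, target_role, opts)
  c(list(seg = seg), count_touching_puncta(seg, ves, target))
}

#' Analyze one lysosome-distribution field
#'
#' @param stack roles `dapi`, `lamp1`, `mito_marker`.
#' @param reference_distances optional distances (um) from the reference
#'   condition fixing the 75th-percentile threshold.
#' @param opts an [assay_options()] list.
#' @return list: `seg`, `result` (SpatialDistribution).
#' @export
analyze_lysosome_field <- function(stack, reference_distances = NULL,
                                   opts = assay_options()) {
  seg <- .segment_field(stack, "mito_marker", opts = opts)
  lyso <- watershed_split(.puncta_mask(stack, "lamp1", opts),
                          opts$min_seed_distance_px)
  mito_mask <- .puncta_mask(stack, "mito_marker", opts)
  areas <- mito_mass(seg, mito_mask)
  list(seg = seg,
       result = lysosome_distribution(seg, lyso, seg$nuclei, areas,
                                      reference_distances))
}

#' Analyze one nuclear-translocation field
#'
#' Nuclear and cytosolic marker means per retained cell, plus their
#' field-level ratio.
#'
#' @param stack roles `dapi`, `marker`.
#' @param opts an [assay_options()] list.
#' @return list: `seg`, `per_cell`, `nuclear_mean`, `cyto_mean`, `ratio`.
#' @export
analyze_nuclear_field <- function(stack, opts = assay_options()) {
  seg <- .segment_field(stack, "marker", opts = opts)
  marker <- max_project(stack, "marker")
  nuc <- nuclear_mean_intensity(seg, marker)
  cyt <- cytosol_mean_intensity(seg, marker)
  per_cell <- merge(nuc$per_cell, cyt$per_cell, by = "cell_id")
  list(seg = seg, per_cell = per_cell,
       nuclear_mean = nuc$field_mean, cyto_mean = cyt$field_mean,
       ratio = nuc$field_mean / cyt$field_mean)
}

#' Analyze one DQ-BSA lysosomal-activity field
#'
#' Mean DQ-BSA sum-projection intensity inside the LAMP1 mask, per retained
#' cell.
#'
#' @param stack roles `dapi`, `lamp1`, `dqbsa`, plus a cytoplasm-filling
#'   channel named by `cyto_role`.
#' @param cyto_role channel used for cell detection (default `lamp1`).
#' @param opts an [assay_options()] list.
#' @return list: `seg`, `per_cell`, `field_mean`.
#' @export
analyze_dqbsa_field <- function(stack, cyto_role = "lamp1",
                                opts = assay_options()) {
  seg <- .segment_field(stack, cyto_role, opts = opts)
  lamp_mask <- .puncta_mask(stack, "lamp1", opts)
  dq <- sum_project(stack, "dqbsa")
  pc <- mean_intensity_in_mask(dq, lamp_mask, per_cell = TRUE, cells = seg)
  list(seg = seg, per_cell = pc,
       field_mean = mean(pc$mean_intensity[pc$defined]))
}
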