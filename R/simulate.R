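#' Synthetic-field parameters
#'
#' Geometry, intensity and noise settings for the synthetic fluorescence
#' fields.  The generator emulates the statistical structure the assays
#' quantify — per-cell object counts, intensity contrasts, radial vesicle
#' positions — not micrograph texture.  Cells are placed on a jittered grid
#' with guaranteed separation from each other and from the field border;
#' mitochondrial networks are random-walk tubules of fixed width; puncta and
#' vesicles are Gaussian spots.  Noise is Poisson shot noise on the signal
#' plus additive Gaussian read noise (the standard camera model).  Default
#' intensity amplitudes give a high signal-to-noise regime in which Otsu
#' thresholding recovers essentially all planted foreground.
#'
#' @param field_size_px `(H, W)` in pixels.
#' @param pixel_size_um micrometres per pixel edge.
#' @param n_cells number of cells to place.
#' @param cell_radius_um `(mean, sd)` of cell radius.
#' @param nucleus_radius_um `(mean, sd)` of nucleus radius.
#' @param mito_segments_per_cell tubule walks drawn per cell.
#' @param mito_width_um tubule width.
#' @param puncta_per_cell Poisson mean of planted puncta/vesicles per cell.
#' @param puncta_radius_um Gaussian radius (sigma) of planted spots.
#' @param background_level camera background offset (detector numbers).
#' @param noise list with `gaussian_sd` (read noise sd) and `poisson` flag.
#' @param n_z number of z slices per stack.
#' @return A list of class `"FieldParams"`.
#' @export
field_params <- function(field_size_px = c(416L, 416L),
                         pixel_size_um = 0.3,
                         n_cells = 16L,
                         cell_radius_um = c(10, 0.45),
                         nucleus_radius_um = c(2.1, 0.15),
                         mito_segments_per_cell = 2L,
                         mito_width_um = 0.5,
                         puncta_per_cell = 6,
                         puncta_radius_um = 0.45,
                         background_level = 8,
                         noise = list(gaussian_sd = 2, poisson = TRUE),
                         n_z = 2L) {
  stopifnot(all(field_size_px > 0), pixel_size_um > 0, n_cells >= 0,
            all(cell_radius_um > 0), all(nucleus_radius_um > 0),
            mito_width_um > 0, puncta_per_cell >= 0, puncta_radius_um > 0,
            background_level >= 0, n_z >= 1)
  structure(as.list(environment()), class = "FieldParams")
}

# --- internal drawing helpers (1-based matrix coordinates) -----------------

# jittered-grid cell layout; guarantees cells neither touch each other nor
# the field border under the default geometry
.layout_cells <- function(p) {
  n <- p$n_cells
  if (n == 0L)
    return(data.frame(cell_id = integer(), cy = numeric(), cx = numeric(),
                      r_cell = numeric(), r_nuc = numeric()))
  h <- p$field_size_px[1L]; w <- p$field_size_px[2L]
  k <- ceiling(sqrt(n))
  r_cell <- pmax(4, stats::rnorm(n, p$cell_radius_um[1L], p$cell_radius_um[2L])) / p$pixel_size_um
  r_nuc <- pmax(2, stats::rnorm(n, p$nucleus_radius_um[1L], p$nucleus_radius_um[2L])) / p$pixel_size_um
  margin <- max(r_cell) + 6
  sy <- (h - 2 * margin) / k; sx <- (w - 2 * margin) / k
  gi <- (seq_len(n) - 1L) %/% k; gj <- (seq_len(n) - 1L) %% k
  jit <- min(3, max(0, (min(sy, sx) - 2 * max(r_cell) - 4) / 2))
  cy <- margin + (gi + 0.5) * sy + stats::runif(n, -jit, jit)
  cx <- margin + (gj + 0.5) * sx + stats::runif(n, -jit, jit)
  data.frame(cell_id = seq_len(n), cy = cy, cx = cx,
             r_cell = r_cell, r_nuc = r_nuc)
}

# set pixels of a filled disk to at least `value`
.add_disk <- function(m, cy, cx, r, value) {
  ys <- max(1L, floor(cy - r)):min(nrow(m), ceiling(cy + r))
  xs <- max(1L, floor(cx - r)):min(ncol(m), ceiling(cx + r))
  sub <- outer((ys - cy)^2, (xs - cx)^2, `+`) <= r^2
  m[ys, xs][sub] <- pmax(m[ys, xs][sub], value)
  m
}

# add a Gaussian spot (amplitude at centre), truncated at 4 sigma
.add_spot <- function(m, cy, cx, sigma, amp) {
  r <- ceiling(4 * sigma)
  ys <- max(1L, floor(cy - r)):min(nrow(m), ceiling(cy + r))
  xs <- max(1L, floor(cx - r)):min(ncol(m), ceiling(cx + r))
  g <- amp * exp(-outer((ys - cy)^2, (xs - cx)^2, `+`) / (2 * sigma^2))
  m[ys, xs] <- m[ys, xs] + g
  m
}

# random-walk tubule pixels for one cell, confined to the cytoplasmic
# annulus; returns an n x 2 matrix of (y, x) integer pixels
.walk_tubule <- function(cell, n_steps = 35L) {
  r0 <- stats::runif(1, cell$r_nuc + 3, cell$r_cell - 6)
  a0 <- stats::runif(1, 0, 2 * pi)
  y <- cell$cy + r0 * sin(a0); x <- cell$cx + r0 * cos(a0)
  dir <- stats::runif(1, 0, 2 * pi)
  pts <- matrix(0, n_steps, 2L)
  k <- 0L
  for (i in seq_len(n_steps)) {
    dir <- dir + stats::rnorm(1, 0, 0.35)
    for (try in 1:8) {
      ny <- y + sin(dir); nx <- x + cos(dir)
      rr <- sqrt((ny - cell$cy)^2 + (nx - cell$cx)^2)
      if (rr > cell$r_nuc + 2 && rr < cell$r_cell - 5) break
      dir <- dir + stats::runif(1, 0, 2 * pi)  # bounce
    }
    rr <- sqrt((ny - cell$cy)^2 + (nx - cell$cx)^2)
    if (rr <= cell$r_nuc + 2 || rr >= cell$r_cell - 5) break
    y <- ny; x <- nx
    k <- k + 1L
    pts[k, ] <- c(round(y), round(x))
  }
  pts[seq_len(k), , drop = FALSE]
}

# mitochondrial-network mask for all cells (logical matrix)
.draw_networks <- function(p, cells) {
  m <- matrix(FALSE, p$field_size_px[1L], p$field_size_px[2L])
  for (i in seq_len(nrow(cells))) {
    for (s in seq_len(p$mito_segments_per_cell)) {
      pts <- .walk_tubule(cells[i, ])
      if (nrow(pts)) m[pts] <- TRUE
    }
  }
  r <- max(1L, round(p$mito_width_um / 2 / p$pixel_size_um))
  .morph(m * 1, disc_kernel(r), pmax, -Inf) > 0
}

# distance of every pixel to the nearest TRUE pixel of `mask`
.dist_to <- function(mask) {
  if (!any(mask)) return(matrix(Inf, nrow(mask), ncol(mask)))
  d <- EBImage::distmap((!mask) * 1)
  matrix(as.numeric(d), nrow(mask), ncol(mask))
}

# sequentially sample `n` points from candidate pixels with a minimum
# pairwise separation; returns (y, x) matrix with <= n rows
.place_points <- function(cand_idx, h, n, min_sep) {
  out <- matrix(0, n, 2L)
  k <- 0L
  avail <- cand_idx
  while (k < n && length(avail)) {
    pick <- avail[sample.int(length(avail), 1L)]
    py <- (pick - 1L) %% h + 1L; px <- (pick - 1L) %/% h + 1L
    k <- k + 1L
    out[k, ] <- c(py, px)
    ay <- (avail - 1L) %% h + 1L; ax <- (avail - 1L) %/% h + 1L
    avail <- avail[(ay - py)^2 + (ax - px)^2 >= min_sep^2]
  }
  out[seq_len(k), , drop = FALSE]
}

# candidate pixel indices in the cytoplasmic annulus of one cell
.cyto_candidates <- function(p, cell, dist_net, min_net_dist, inset = 5) {
  h <- p$field_size_px[1L]; w <- p$field_size_px[2L]
  ys <- max(1L, floor(cell$cy - cell$r_cell)):min(h, ceiling(cell$cy + cell$r_cell))
  xs <- max(1L, floor(cell$cx - cell$r_cell)):min(w, ceiling(cell$cx + cell$r_cell))
  yy <- rep(ys, times = length(xs)); xx <- rep(xs, each = length(ys))
  rr2 <- (yy - cell$cy)^2 + (xx - cell$cx)^2
  ok <- rr2 <= (cell$r_cell - inset)^2 & rr2 >= (cell$r_nuc + 3)^2
  idx <- (xx - 1L) * h + yy
  idx[ok & dist_net[idx] >= min_net_dist]
}

# Poisson + Gaussian camera noise on one plane of deterministic signal
.noisy_plane <- function(signal, p) {
  v <- as.vector(signal)
  out <- if (isTRUE(p$noise$poisson)) stats::rpois(length(v), v) else v
  if (p$noise$gaussian_sd > 0)
    out <- out + stats::rnorm(length(v), 0, p$noise$gaussian_sd)
  matrix(pmin(pmax(round(out), 0), 65535), nrow(signal), ncol(signal))
}

# assemble an ImageStack from per-channel deterministic signal matrices;
# slice 2..n_z carry attenuated copies of the signal, noise is per-plane
.assemble_stack <- function(p, channels) {
  h <- p$field_size_px[1L]; w <- p$field_size_px[2L]
  nc <- length(channels)
  atten <- c(1, rep(0.6, p$n_z - 1L))
  px <- array(0, dim = c(p$n_z, nc, h, w))
  for (z in seq_len(p$n_z)) for (ch in seq_len(nc))
    px[z, ch, , ] <- .noisy_plane(channels[[ch]] * atten[z] + p$background_level, p)
  roles <- seq_len(nc)
  names(roles) <- names(channels)
  image_stack(px, p$pixel_size_um, roles, z_step_um = 0.5)
}

.AMP <- list(dapi = 160, network = 120, cyto = 60, punctum = 200,
             small_mito = 160, tmre_network = 120, tmre_polarized = 160,
             vesicle = 170, marker_cyto = 70)

# --- generators ------------------------------------------------------------

#' Generate a paired mito-QC field (without / with lysosomal inhibitors)
#'
#' Both stacks share the cell layout and mitochondrial network (drawn in GFP
#' and mCherry); each arm plants Poisson-distributed mCherry-only puncta per
#' cell off the network, with the "plus inhibitor" arm at `lambda *
#' flux_ratio`.  Optionally a fraction of puncta is planted on the network
#' (touching the GFP mask) to exercise the exclusion rule.
#'
#' @param params a [field_params()]; `puncta_per_cell` is the minus-arm
#'   Poisson mean.
#' @param flux_ratio true ratio of plus/minus puncta rates (>= 1).
#' @param seed integer seed; the generator is a pure function of
#'   `(params, flux_ratio, touching_fraction, seed)`.
#' @param touching_fraction fraction of each cell's puncta planted on the
#'   network.
#' @return `list(stack_minus, stack_plus, truth)`; `truth$cells` records the
#'   per-cell planted counts per arm (off-network = true mitolysosomes, plus
#'   touching counts), `truth$flux_ratio_true` the generating ratio.
#' @export
generate_mitoqc_pair <- function(params, flux_ratio, seed, touching_fraction = 0) {
  stopifnot(flux_ratio >= 1, touching_fraction >= 0, touching_fraction < 1)
  set.seed(seed)
  p <- params
  h <- p$field_size_px[1L]
  cells <- .layout_cells(p)
  net <- .draw_networks(p, cells)
  dist_net <- .dist_to(net)
  net_idx <- which(net)
  sig_sp <- p$puncta_radius_um / p$pixel_size_um
  lam <- c(minus = p$puncta_per_cell, plus = p$puncta_per_cell * flux_ratio)

  dapi <- matrix(0, h, p$field_size_px[2L])
  gfp <- matrix(0, h, p$field_size_px[2L])
  mch0 <- matrix(0, h, p$field_size_px[2L])
  for (i in seq_len(nrow(cells))) {
    cl <- cells[i, ]
    dapi <- .add_disk(dapi, cl$cy, cl$cx, cl$r_nuc, .AMP$dapi)
    gfp <- .add_disk(gfp, cl$cy, cl$cx, cl$r_cell, .AMP$cyto)
  }
  gfp[net] <- gfp[net] + .AMP$network
  mch0[net] <- mch0[net] + .AMP$network

  truth_cells <- cells[, c("cell_id", "cy", "cx", "r_cell", "r_nuc")]
  names(truth_cells)[2:3] <- c("nucleus_y", "nucleus_x")
  truth_cells$nucleus_y <- truth_cells$nucleus_y - 1  # 0-based convention
  truth_cells$nucleus_x <- truth_cells$nucleus_x - 1
  positions <- list()
  stacks <- list()
  for (arm in c("minus", "plus")) {
    mch <- mch0
    n_off <- integer(nrow(cells)); n_touch <- integer(nrow(cells))
    pos_arm <- list()
    for (i in seq_len(nrow(cells))) {
      cl <- cells[i, ]
      n_tot <- stats::rpois(1L, lam[[arm]])
      nt <- stats::rbinom(1L, n_tot, touching_fraction)
      cand <- .cyto_candidates(p, cl, dist_net, min_net_dist = 4.5)
      pts <- .place_points(cand, h, n_tot - nt, min_sep = 5)
      tpts <- matrix(0, 0L, 2L)
      if (nt > 0L && length(net_idx)) {
        cyv <- (net_idx - 1L) %% h + 1L; cxv <- (net_idx - 1L) %/% h + 1L
        on_cell <- net_idx[(cyv - cl$cy)^2 + (cxv - cl$cx)^2 <= (cl$r_cell - 4)^2]
        tpts <- .place_points(on_cell, h, nt, min_sep = 5)
      }
      for (j in seq_len(nrow(pts)))
        mch <- .add_spot(mch, pts[j, 1L], pts[j, 2L], sig_sp, .AMP$punctum)
      for (j in seq_len(nrow(tpts)))
        mch <- .add_spot(mch, tpts[j, 1L], tpts[j, 2L], sig_sp, .AMP$punctum)
      n_off[i] <- nrow(pts); n_touch[i] <- nrow(tpts)
      if (nrow(pts) || nrow(tpts))
        pos_arm[[length(pos_arm) + 1L]] <- data.frame(
          cell_id = cl$cell_id,
          y = c(pts[, 1L], tpts[, 1L]) - 1, x = c(pts[, 2L], tpts[, 2L]) - 1,
          touching = rep(c(FALSE, TRUE), c(nrow(pts), nrow(tpts))))
    }
    truth_cells[[paste0("n_mitolysosomes_true_", arm)]] <- n_off
    truth_cells[[paste0("n_touching_true_", arm)]] <- n_touch
    positions[[arm]] <- if (length(pos_arm)) do.call(rbind, pos_arm) else
      data.frame(cell_id = integer(), y = numeric(), x = numeric(), touching = logical())
    stacks[[arm]] <- .assemble_stack(p, list(dapi = dapi, gfp = gfp, mcherry = mch))
  }
  list(stack_minus = stacks$minus, stack_plus = stacks$plus,
       truth = list(cells = truth_cells, puncta = positions,
                    flux_ratio_true = flux_ratio,
                    touching_fraction = touching_fraction, seed = seed))
}

#' Generate a TMRE / MitoTracker Green membrane-potential field
#'
#' The MTG channel carries the mitochondrial network plus `n_small`
#' individualized objects per cell, each smaller than 1 um^2, of which
#' `n_depolarized` carry no TMRE signal (background only) and the remainder
#' are brightly polarized.  The TMRE channel also stains the network.
#'
#' @param params a [field_params()].
#' @param n_small individualized small mitochondria per cell.
#' @param n_depolarized of those, how many are depolarized (TMRE-dark).
#' @param seed integer seed.
#' @return `list(stack, truth)` with channels `dapi`, `mtg`, `tmre`.
#' @export
generate_tmre_field <- function(params, n_small, n_depolarized, seed) {
  stopifnot(n_small >= 0, n_depolarized >= 0, n_depolarized <= n_small)
  set.seed(seed)
  p <- params
  h <- p$field_size_px[1L]
  cells <- .layout_cells(p)
  net <- .draw_networks(p, cells)
  dist_net <- .dist_to(net)
  dapi <- matrix(0, h, p$field_size_px[2L])
  mtg <- matrix(0, h, p$field_size_px[2L])
  tmre <- matrix(0, h, p$field_size_px[2L])
  for (i in seq_len(nrow(cells))) {
    cl <- cells[i, ]
    dapi <- .add_disk(dapi, cl$cy, cl$cx, cl$r_nuc, .AMP$dapi)
    mtg <- .add_disk(mtg, cl$cy, cl$cx, cl$r_cell, .AMP$cyto)
  }
  mtg[net] <- mtg[net] + .AMP$network
  tmre[net] <- tmre[net] + .AMP$tmre_network
  sig <- 0.8  # spot sigma in px: thresholded footprint stays below 1 um^2
  n_pol <- n_small - n_depolarized
  tc <- cells[, c("cell_id", "cy", "cx", "r_cell", "r_nuc")]
  tc$n_small_mito_true <- rep(0L, nrow(tc))
  tc$n_depolarized_true <- rep(0L, nrow(tc))
  for (i in seq_len(nrow(cells))) {
    cl <- cells[i, ]
    cand <- .cyto_candidates(p, cl, dist_net, min_net_dist = 5)
    pts <- .place_points(cand, h, n_small, min_sep = 8)
    if (nrow(pts) < n_small)
      stop("could not place all small mitochondria without overlap")
    for (j in seq_len(nrow(pts))) {
      mtg <- .add_spot(mtg, pts[j, 1L], pts[j, 2L], sig, .AMP$small_mito)
      if (j <= n_pol)
        tmre <- .add_spot(tmre, pts[j, 1L], pts[j, 2L], sig, .AMP$tmre_polarized)
    }
    tc$n_small_mito_true[i] <- nrow(pts)
    tc$n_depolarized_true[i] <- nrow(pts) - n_pol
  }
  stack <- .assemble_stack(p, list(dapi = dapi, mtg = mtg, tmre = tmre))
  list(stack = stack,
       truth = list(cells = tc, n_small = n_small,
                    n_depolarized = n_depolarized, seed = seed))
}

#' Generate a lysosome-distribution field
#'
#' Vesicles (LAMP1 channel) are planted at nucleus-edge distances drawn from
#' a two-component radial mixture: a perinuclear component and, with
#' probability `peripheral_fraction`, a peripheral component near the cell
#' margin.  The mito-marker channel carries the network used for the
#' per-mitochondrial-area normalisation and for cytoplasm detection.
#'
#' @param params a [field_params()]; `puncta_per_cell` is the Poisson mean of
#'   vesicles per cell.
#' @param peripheral_fraction mixture weight of the peripheral component.
#' @param seed integer seed.
#' @return `list(stack, truth)` with channels `dapi`, `lamp1`, `mito_marker`;
#'   `truth$vesicles` records each vesicle's planted nucleus-edge distance
#'   (um) and component.
#' @export
generate_lamp1_field <- function(params, peripheral_fraction, seed) {
  stopifnot(peripheral_fraction >= 0, peripheral_fraction <= 1)
  set.seed(seed)
  p <- params
  h <- p$field_size_px[1L]
  cells <- .layout_cells(p)
  net <- .draw_networks(p, cells)
  dapi <- matrix(0, h, p$field_size_px[2L])
  lamp1 <- matrix(0, h, p$field_size_px[2L])
  mito <- matrix(0, h, p$field_size_px[2L])
  for (i in seq_len(nrow(cells))) {
    cl <- cells[i, ]
    dapi <- .add_disk(dapi, cl$cy, cl$cx, cl$r_nuc, .AMP$dapi)
    mito <- .add_disk(mito, cl$cy, cl$cx, cl$r_cell, .AMP$cyto)
  }
  mito[net] <- mito[net] + .AMP$network
  ves <- list()
  for (i in seq_len(nrow(cells))) {
    cl <- cells[i, ]
    n <- stats::rpois(1L, p$puncta_per_cell)
    if (n == 0L) next
    dmax <- (cl$r_cell - cl$r_nuc - 5) * p$pixel_size_um
    comp <- stats::rbinom(n, 1L, peripheral_fraction)
    d <- ifelse(comp == 1L,
                stats::runif(n, 0.65 * dmax, 0.95 * dmax),
                stats::runif(n, 0.1 * dmax, 0.40 * dmax))
    ang <- stats::runif(n, 0, 2 * pi)
    rad <- cl$r_nuc + d / p$pixel_size_um
    vy <- cl$cy + rad * sin(ang); vx <- cl$cx + rad * cos(ang)
    for (j in seq_len(n))
      lamp1 <- .add_spot(lamp1, vy[j], vx[j], 1.5, .AMP$vesicle)
    ves[[length(ves) + 1L]] <- data.frame(
      cell_id = cl$cell_id, y = vy - 1, x = vx - 1,
      distance_um = d, peripheral_component = comp == 1L)
  }
  ves <- if (length(ves)) do.call(rbind, ves) else
    data.frame(cell_id = integer(), y = numeric(), x = numeric(),
               distance_um = numeric(), peripheral_component = logical())
  stack <- .assemble_stack(p, list(dapi = dapi, lamp1 = lamp1, mito_marker = mito))
  list(stack = stack,
       truth = list(cells = cells, vesicles = ves,
                    peripheral_fraction_true = peripheral_fraction, seed = seed))
}

#' Generate a nuclear-translocation marker field
#'
#' The marker channel has cytoplasmic mean `c` and nuclear mean
#' `c * nuclear_fold` (plus camera noise), emulating the nuclear enrichment
#' of a transcription factor or coactivator.
#'
#' @param params a [field_params()].
#' @param nuclear_fold true nuclear/cytoplasmic mean ratio (> 0).
#' @param seed integer seed.
#' @return `list(stack, truth)` with channels `dapi`, `marker`.
#' @export
generate_nuclear_marker_field <- function(params, nuclear_fold, seed) {
  stopifnot(nuclear_fold > 0)
  set.seed(seed)
  p <- params
  h <- p$field_size_px[1L]
  cells <- .layout_cells(p)
  dapi <- matrix(0, h, p$field_size_px[2L])
  marker <- matrix(0, h, p$field_size_px[2L])
  # total in-cell means (signal + camera background) must sit in the stated
  # ratio, so the drawn amplitudes compensate for the background offset
  cbase <- .AMP$marker_cyto
  cyto_amp <- cbase - p$background_level
  nuc_amp <- cbase * nuclear_fold - p$background_level
  if (cyto_amp < 0 || nuc_amp < 0)
    stop("background_level too high for the requested marker means")
  for (i in seq_len(nrow(cells))) {
    cl <- cells[i, ]
    dapi <- .add_disk(dapi, cl$cy, cl$cx, cl$r_nuc, .AMP$dapi)
    marker <- .add_disk(marker, cl$cy, cl$cx, cl$r_cell, cyto_amp)
    marker <- .add_disk(marker, cl$cy, cl$cx, cl$r_nuc, nuc_amp)
  }
  tc <- cells[, c("cell_id", "cy", "cx", "r_cell", "r_nuc")]
  tc$nuclear_marker_mean_true <- rep(cbase * nuclear_fold, nrow(tc))
  tc$cyto_marker_mean_true <- rep(cbase, nrow(tc))
  stack <- .assemble_stack(p, list(dapi = dapi, marker = marker))
  list(stack = stack,
       truth = list(cells = tc, nuclear_fold_true = nuclear_fold, seed = seed))
}

#' Generate a STED-like cristae line profile
#'
#' A raised-cosine comb with exactly `round(cristae_per_um * length_um)`
#' equally spaced peaks, plus Gaussian noise.  The sampling step must
#' satisfy Nyquist for the requested cristae frequency.
#'
#' @param cristae_per_um true peak density (1/um).
#' @param length_um profile length.
#' @param pixel_size_um sampling step (um/sample).
#' @param noise_sd Gaussian noise sd (intensity units; peak amplitude 100).
#' @param seed integer seed.
#' @return `list(profile, truth)`; `truth$peak_positions_um` holds the exact
#'   planted maxima.
#' @export
generate_line_profile <- function(cristae_per_um, length_um, pixel_size_um,
                                  noise_sd = 0, seed = 1L) {
  stopifnot(cristae_per_um >= 0, length_um > 0, pixel_size_um > 0, noise_sd >= 0)
  if (cristae_per_um > 0 && pixel_size_um >= 1 / (2 * cristae_per_um))
    stop("Nyquist violation: pixel_size_um must be < 1/(2 * cristae_per_um)")
  set.seed(seed)
  n <- round(length_um / pixel_size_um) + 1L
  x <- (seq_len(n) - 1L) * pixel_size_um
  k <- round(cristae_per_um * length_um)
  amp <- 100; bg <- 20
  signal <- if (k == 0L) rep(bg, n) else bg + amp * 0.5 * (1 - cos(2 * pi * k * x / length_um))
  ints <- signal + stats::rnorm(n, 0, noise_sd)
  prof <- line_profile(ints, pixel_size_um)
  pk <- if (k == 0L) numeric() else (seq_len(k) - 0.5) * length_um / k
  list(profile = prof,
       truth = list(n_peaks = k, peak_positions_um = pk,
                    cristae_per_um_true = if (length_um > 0) k / ((n - 1L) * pixel_size_um) else 0,
                    seed = seed))
}

#' Generate a mito-stress-test OCR trace
#'
#' Piecewise-constant oxygen-consumption trace over the four protocol phases
#' (basal, oligomycin, FCCP, rotenone/antimycin A) with Gaussian noise.
#'
#' @param levels list/vector with `basal_raw`, `post_oligo_raw`, `fccp_raw`,
#'   `rot_aa_raw` (pmol O2/min, all >= 0).
#' @param n_per_phase measurements per phase (>= 1).
#' @param noise_sd Gaussian noise sd.
#' @param seed integer seed.
#' @return `list(trace, truth)`; `trace` is an `OCRTrace` data.frame.
#' @export
generate_ocr_trace <- function(levels, n_per_phase = 3L, noise_sd = 0, seed = 1L) {
  lv <- unlist(levels)[c("basal_raw", "post_oligo_raw", "fccp_raw", "rot_aa_raw")]
  stopifnot(!anyNA(lv), all(lv >= 0), n_per_phase >= 1)
  set.seed(seed)
  phases <- rep(c("basal", "oligomycin", "fccp", "rot_aa"), each = n_per_phase)
  n <- length(phases)
  ocr <- rep(as.numeric(lv), each = n_per_phase) + stats::rnorm(n, 0, noise_sd)
  tr <- data.frame(time_min = seq_len(n) * 6.5, ocr = ocr,
                   ecar = rep(as.numeric(lv) / 5, each = n_per_phase),
                   phase = phases, well_id = "sim", group = "sim",
                   stringsAsFactors = FALSE)
  class(tr) <- c("OCRTrace", "data.frame")
  list(trace = tr, truth = list(levels = as.list(lv), seed = seed))
}
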