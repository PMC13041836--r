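.ASSAYS <- c("mitoqc_flux", "membrane_potential", "mito_mass",
             "touching_puncta", "lysosome_distribution",
             "nuclear_translocation", "dqbsa", "cristae", "respirometry",
             "simulate")

.COMMON_KEYS <- c("assay", "out_dir", "seed", "pixel_size_um",
                  "channel_roles", "options")
.ASSAY_KEYS <- list(
  mitoqc_flux = c("input_dir_minus", "input_dir_plus"),
  membrane_potential = "input_dir",
  mito_mass = "input_dir",
  touching_puncta = c("input_dir", "vesicle_role", "target_role"),
  lysosome_distribution = c("input_dir", "reference_dir"),
  nuclear_translocation = "input_dir",
  dqbsa = c("input_dir", "cyto_role"),
  cristae = "input_dir",
  respirometry = c("input_csv", "injections"),
  simulate = "scenario")

.validate_config <- function(config) {
  if (is.null(config$assay) || !config$assay %in% .ASSAYS)
    stop(sprintf("config must set assay to one of: %s",
                 paste(.ASSAYS, collapse = ", ")))
  allowed <- c(.COMMON_KEYS, .ASSAY_KEYS[[config$assay]])
  unknown <- setdiff(names(config), allowed)
  if (length(unknown))
    stop(sprintf("unknown config key(s): %s", paste(unknown, collapse = ", ")))
  if (is.null(config$out_dir)) stop("config must set out_dir")
  config
}

.roles_from_config <- function(config, default) {
  if (is.null(config$channel_roles)) return(default)
  unlist(config$channel_roles)
}

# load every TIFF in a directory; corrupt files are skipped with a warning
.load_fields <- function(dir, roles, pixel_size_um) {
  files <- sort(list.files(dir, pattern = "\\.tiff?$", full.names = TRUE))
  if (!length(files)) stop(sprintf("no TIFF files in %s", dir))
  stacks <- list(); skipped <- character()
  for (f in files) {
    st <- tryCatch(load_stack(f, roles, pixel_size_um),
                   error = function(e) {
                     warning(sprintf("skipping %s: %s", basename(f),
                                     conditionMessage(e)))
                     NULL
                   })
    if (is.null(st)) skipped <- c(skipped, f) else stacks[[basename(f)]] <- st
  }
  list(stacks = stacks, skipped = skipped)
}

.summarise <- function(values) {
  v <- values[is.finite(values)]
  data.frame(mean = mean(v), sem = stats::sd(v) / sqrt(length(v)), n = length(v))
}

.write_outputs <- function(out_dir, per_cell, summary, prefix) {
  pc <- file.path(out_dir, paste0(prefix, "_per_cell.csv"))
  sm <- file.path(out_dir, paste0(prefix, "_summary.csv"))
  utils::write.csv(per_cell, pc, row.names = FALSE)
  utils::write.csv(summary, sm, row.names = FALSE)
  c(pc, sm)
}

#' Run an assay end-to-end from a configuration
#'
#' Configuration-driven orchestration: `config` is a YAML file path or a
#' list with an `assay` switch (one of `mitoqc_flux`, `membrane_potential`,
#' `mito_mass`, `touching_puncta`, `lysosome_distribution`,
#' `nuclear_translocation`, `dqbsa`, `cristae`, `respirometry`,
#' `simulate`), input locations, `channel_roles`, `pixel_size_um`, a `seed`
#' and per-module `options` (see [assay_options()]).  Unknown keys are
#' rejected by name.  Per-cell and summary CSVs plus a JSON-lines
#' provenance log are written under `out_dir`; corrupt input fields are
#' skipped and counted.  Outputs are deterministic for a fixed config and
#' seed.
#'
#' @param config list or YAML path.
#' @return Invisibly, a list: `status` (`"ok"` or `"partial"`), `outputs`
#'   (paths written), `n_fields`, `n_skipped`, and the assay's headline
#'   result object.
#' @export
run_assay <- function(config) {
  if (is.character(config)) config <- yaml::read_yaml(config)
  config <- .validate_config(config)
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  old_prov <- set_provenance_log(file.path(config$out_dir, "provenance.jsonl"))
  on.exit(options(mitoquant.provenance = old_prov), add = TRUE)
  prov_record("run_assay", config[setdiff(names(config), "options")])
  if (!is.null(config$seed)) set.seed(config$seed)
  opts <- do.call(assay_options, if (is.null(config$options)) list() else config$options)
  px <- if (is.null(config$pixel_size_um)) 0.3 else config$pixel_size_um
  out <- switch(config$assay,
    simulate = .run_simulate(config, px),
    mitoqc_flux = .run_mitoqc_flux(config, px, opts),
    membrane_potential = .run_per_field(config, px, opts,
      roles = c(dapi = 1L, mtg = 2L, tmre = 3L),
      fn = function(st) {
        r <- analyze_tmre_field(st, opts)
        r$result$per_cell
      },
      stat_col = "n_depolarized", prefix = "membrane_potential"),
    mito_mass = .run_per_field(config, px, opts,
      roles = c(dapi = 1L, mito_marker = 2L),
      fn = function(st) analyze_mito_mass_field(st, opts)$per_cell,
      stat_col = "mito_area_um2", prefix = "mito_mass"),
    touching_puncta = .run_per_field(config, px, opts,
      roles = c(dapi = 1L, lc3 = 2L, mito_marker = 3L),
      fn = function(st) analyze_touching_field(
        st, if (is.null(config$vesicle_role)) "lc3" else config$vesicle_role,
        if (is.null(config$target_role)) "mito_marker" else config$target_role,
        opts)$per_cell,
      stat_col = "n_touching", prefix = "touching_puncta"),
    lysosome_distribution = .run_lysosome(config, px, opts),
    nuclear_translocation = .run_per_field(config, px, opts,
      roles = c(dapi = 1L, marker = 2L),
      fn = function(st) analyze_nuclear_field(st, opts)$per_cell,
      stat_col = "nuclear_mean", prefix = "nuclear_translocation"),
    dqbsa = .run_per_field(config, px, opts,
      roles = c(dapi = 1L, lamp1 = 2L, dqbsa = 3L),
      fn = function(st) analyze_dqbsa_field(
        st, if (is.null(config$cyto_role)) "lamp1" else config$cyto_role,
        opts)$per_cell,
      stat_col = "mean_intensity", prefix = "dqbsa"),
    cristae = .run_cristae(config, opts),
    respirometry = .run_respirometry(config, opts))
  invisible(out)
}

.run_per_field <- function(config, px, opts, roles, fn, stat_col, prefix) {
  roles <- .roles_from_config(config, roles)
  lf <- .load_fields(config$input_dir, roles, px)
  rows <- list()
  for (nm in names(lf$stacks)) {
    r <- tryCatch(fn(lf$stacks[[nm]]), error = function(e) {
      warning(sprintf("field %s failed: %s", nm, conditionMessage(e)))
      NULL
    })
    if (is.null(r)) { lf$skipped <- c(lf$skipped, nm); next }
    r$field <- nm
    rows[[nm]] <- r
  }
  if (!length(rows)) stop("all fields failed")
  per_cell <- do.call(rbind, rows)
  rownames(per_cell) <- NULL
  summary <- .summarise(per_cell[[stat_col]])
  outputs <- .write_outputs(config$out_dir, per_cell, summary, prefix)
  list(status = if (length(lf$skipped)) "partial" else "ok",
       outputs = outputs, n_fields = length(rows),
       n_skipped = length(lf$skipped), per_cell = per_cell, summary = summary)
}

.run_mitoqc_flux <- function(config, px, opts) {
  roles <- .roles_from_config(config, c(dapi = 1L, gfp = 2L, mcherry = 3L))
  arms <- list(minus = config$input_dir_minus, plus = config$input_dir_plus)
  counts <- list(); rows <- list(); skipped <- 0L
  for (arm in names(arms)) {
    lf <- .load_fields(arms[[arm]], roles, px)
    skipped <- skipped + length(lf$skipped)
    for (nm in names(lf$stacks)) {
      r <- tryCatch(analyze_mitoqc_field(lf$stacks[[nm]], opts),
                    error = function(e) {
                      warning(sprintf("field %s failed: %s", nm, conditionMessage(e)))
                      NULL
                    })
      if (is.null(r)) { skipped <- skipped + 1L; next }
      pc <- r$per_cell
      pc$arm <- arm; pc$field <- nm
      rows[[paste(arm, nm)]] <- pc
      counts[[arm]] <- c(counts[[arm]], pc$n_mitolysosomes)
    }
  }
  if (is.null(counts$minus) || is.null(counts$plus))
    stop("both arms must contribute at least one analyzable field")
  flux <- compute_flux(counts$minus, counts$plus)
  per_cell <- do.call(rbind, rows); rownames(per_cell) <- NULL
  summary <- data.frame(mean_minus = flux$mean_minus, mean_plus = flux$mean_plus,
                        flux_ratio = flux$flux_ratio, defined = flux$defined,
                        n_minus = flux$n_minus, n_plus = flux$n_plus)
  outputs <- .write_outputs(config$out_dir, per_cell, summary, "mitoqc_flux")
  prov_record("compute_flux", derived = list(flux_ratio = flux$flux_ratio))
  list(status = if (skipped) "partial" else "ok", outputs = outputs,
       n_fields = length(rows), n_skipped = skipped, flux = flux,
       per_cell = per_cell, summary = summary)
}

.run_lysosome <- function(config, px, opts) {
  roles <- .roles_from_config(config, c(dapi = 1L, lamp1 = 2L, mito_marker = 3L))
  ref <- NULL
  if (!is.null(config$reference_dir)) {
    rf <- .load_fields(config$reference_dir, roles, px)
    ref <- unlist(lapply(rf$stacks, function(st)
      analyze_lysosome_field(st, NULL, opts)$result$distances$distance_um))
  }
  lf <- .load_fields(config$input_dir, roles, px)
  rows <- list(); skipped <- length(lf$skipped)
  for (nm in names(lf$stacks)) {
    r <- tryCatch(analyze_lysosome_field(lf$stacks[[nm]], ref, opts),
                  error = function(e) {
                    warning(sprintf("field %s failed: %s", nm, conditionMessage(e)))
                    NULL
                  })
    if (is.null(r)) { skipped <- skipped + 1L; next }
    pc <- r$result$per_cell
    pc$field <- nm
    rows[[nm]] <- pc
  }
  if (!length(rows)) stop("all fields failed")
  per_cell <- do.call(rbind, rows); rownames(per_cell) <- NULL
  summary <- .summarise(per_cell$peripheral_per_mito_area)
  outputs <- .write_outputs(config$out_dir, per_cell, summary, "lysosome_distribution")
  list(status = if (skipped) "partial" else "ok", outputs = outputs,
       n_fields = length(rows), n_skipped = skipped,
       per_cell = per_cell, summary = summary)
}

.run_cristae <- function(config, opts) {
  files <- sort(list.files(config$input_dir, pattern = "\\.csv$", full.names = TRUE))
  if (!length(files)) stop(sprintf("no CSV files in %s", config$input_dir))
  rows <- list(); skipped <- 0L
  for (f in files) {
    r <- tryCatch({
      prof <- read_line_profile(f)
      pk <- detect_peaks(prof, opts$min_prominence_frac, opts$min_separation_um)
      data.frame(profile = basename(f), n_peaks = length(pk),
                 length_um = prof$length_um,
                 cristae_per_um = cristae_density(pk, prof))
    }, error = function(e) {
      warning(sprintf("profile %s failed: %s", basename(f), conditionMessage(e)))
      NULL
    })
    if (is.null(r)) skipped <- skipped + 1L else rows[[f]] <- r
  }
  if (!length(rows)) stop("all profiles failed")
  per_profile <- do.call(rbind, rows); rownames(per_profile) <- NULL
  summary <- .summarise(per_profile$cristae_per_um)
  outputs <- .write_outputs(config$out_dir, per_profile, summary, "cristae")
  list(status = if (skipped) "partial" else "ok", outputs = outputs,
       n_fields = nrow(per_profile), n_skipped = skipped,
       per_cell = per_profile, summary = summary)
}

.run_respirometry <- function(config, opts) {
  df <- utils::read.csv(config$input_csv)
  if (!"well_id" %in% names(df)) df$well_id <- "well"
  rows <- list()
  for (w in unique(df$well_id)) {
    tr <- parse_trace(df[df$well_id == w, , drop = FALSE],
                      injections = unlist(config$injections))
    rp <- respiratory_parameters(tr)
    rows[[w]] <- data.frame(
      well_id = w, group = tr$group[1L], nonmito = rp$nonmito,
      basal = rp$basal, atp_linked = rp$atp_linked,
      proton_leak = rp$proton_leak, maximal = rp$maximal,
      reserve_capacity = rp$reserve_capacity,
      mito_atp_rate = rp$atp_linked * opts$o2_per_o * opts$po_ratio,
      quality_flag = rp$quality_flag)
  }
  per_well <- do.call(rbind, rows); rownames(per_well) <- NULL
  summary <- .summarise(per_well$basal)
  outputs <- .write_outputs(config$out_dir, per_well, summary, "respirometry")
  list(status = "ok", outputs = outputs, n_fields = nrow(per_well),
       n_skipped = 0L, per_cell = per_well, summary = summary)
}

#' Simulate fields to disk
#'
#' `scenario` (in the config) selects a generator (`mitoqc_pair`, `tmre`,
#' `lamp1`, `nuclear_marker`) with its effect parameters and `n_fields`;
#' stacks are written as 16-bit TIFFs with a ground-truth JSON per field.
#' Field seeds are `seed + field index`, so a scenario is exactly
#' reproducible.
#'
#' @param config validated config list (assay `"simulate"`).
#' @param px pixel size fallback.
#' @return list with `status`, written `outputs`.
#' @keywords internal
.run_simulate <- function(config, px) {
  sc <- config$scenario
  if (is.null(sc$generator)) stop("scenario must name a generator")
  n_fields <- if (is.null(sc$n_fields)) 1L else sc$n_fields
  seed0 <- if (is.null(config$seed)) 1L else config$seed
  fp <- do.call(field_params, if (is.null(sc$params)) list() else sc$params)
  outs <- character()
  for (i in seq_len(n_fields)) {
    sd <- seed0 + i
    tag <- sprintf("field_%02d", i)
    if (sc$generator == "mitoqc_pair") {
      g <- generate_mitoqc_pair(fp, sc$flux_ratio %||% 2, sd,
                                sc$touching_fraction %||% 0)
      for (arm in c("minus", "plus")) {
        d <- file.path(config$out_dir, arm)
        dir.create(d, showWarnings = FALSE, recursive = TRUE)
        f <- file.path(d, paste0(tag, ".tif"))
        write_stack(g[[paste0("stack_", arm)]], f)
        outs <- c(outs, f)
      }
    } else {
      g <- switch(sc$generator,
        tmre = generate_tmre_field(fp, sc$n_small %||% 8, sc$n_depolarized %||% 3, sd),
        lamp1 = generate_lamp1_field(fp, sc$peripheral_fraction %||% 0.2, sd),
        nuclear_marker = generate_nuclear_marker_field(fp, sc$nuclear_fold %||% 2, sd),
        stop(sprintf("unknown generator '%s'", sc$generator)))
      f <- file.path(config$out_dir, paste0(tag, ".tif"))
      write_stack(g$stack, f)
      outs <- c(outs, f)
    }
    tf <- file.path(config$out_dir, paste0(tag, "_truth.json"))
    jsonlite::write_json(g$truth, tf, auto_unbox = TRUE, digits = NA,
                         dataframe = "columns")
    outs <- c(outs, tf)
  }
  list(status = "ok", outputs = outs, n_fields = n_fields, n_skipped = 0L)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
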