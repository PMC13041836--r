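#' Parse an extracellular-flux (mito stress test) trace
#'
#' Rows must carry `time_min` (strictly increasing) and `ocr`; phases come
#' either from an explicit `phase` column (`basal`, `oligomycin`, `fccp`,
#' `rot_aa`) or from three injection timestamps (oligomycin, FCCP,
#' rotenone/antimycin A) assigning rows to half-open intervals
#' `[t_inj, t_next)`.  All four phases must be present, in protocol order.
#'
#' @param table data.frame of measurements (optionally `ecar`, `well_id`,
#'   `group`).
#' @param injections numeric vector of the three injection times (minutes),
#'   required when `table` has no `phase` column.
#' @return An `OCRTrace` (data.frame subclass).
#' @export
parse_trace <- function(table, injections = NULL) {
  if (!all(c("time_min", "ocr") %in% names(table)))
    stop("required columns: time_min, ocr")
  if (is.unsorted(table$time_min, strictly = TRUE))
    stop("time_min must be strictly increasing")
  phases <- c("basal", "oligomycin", "fccp", "rot_aa")
  if (!"phase" %in% names(table)) {
    if (is.null(injections) || length(injections) != 3L)
      stop("need a phase column or exactly 3 injection times")
    if (is.unsorted(injections, strictly = TRUE)) stop("injections must be increasing")
    table$phase <- phases[findInterval(table$time_min, injections) + 1L]
  }
  if (!all(table$phase %in% phases)) stop("unknown phase label")
  missing <- setdiff(phases, unique(table$phase))
  if (length(missing))
    stop(sprintf("missing phase: %s", paste(missing, collapse = ", ")))
  idx <- match(table$phase, phases)
  if (is.unsorted(idx)) stop("phases out of protocol order")
  if (!"well_id" %in% names(table)) table$well_id <- "well"
  if (!"group" %in% names(table)) table$group <- ""
  class(table) <- c("OCRTrace", "data.frame")
  table
}

#' Mito-stress-test respiratory parameters
#'
#' Phase summaries follow the standard protocol: basal = last basal
#' measurement, oligomycin = phase minimum, FCCP = phase maximum (covering
#' sequential FCCP additions), non-mitochondrial = mean of the
#' rotenone/antimycin A phase.  All parameters except `nonmito` are
#' corrected by subtracting the rotenone/AA-insensitive OCR, which makes
#' them invariant to a uniform additive offset of the trace.  By
#' construction `basal = atp_linked + proton_leak` and
#' `reserve_capacity = maximal - basal` hold exactly.  Negative corrected
#' values are reported as computed with a quality flag.
#'
#' @param trace an `OCRTrace` from [parse_trace()].
#' @param summaries optional overrides of the per-phase summary statistics:
#'   named list with functions for `basal`, `oligomycin`, `fccp`, `rot_aa`.
#' @return An object of class `"RespiratoryParameters"`.
#' @export
respiratory_parameters <- function(trace, summaries = list()) {
  stopifnot(inherits(trace, "OCRTrace") || all(c("phase", "ocr") %in% names(trace)))
  sfun <- utils::modifyList(list(
    basal = function(v) v[length(v)],
    oligomycin = min,
    fccp = max,
    rot_aa = mean), summaries)
  ph <- split(trace$ocr, trace$phase)
  for (p in c("basal", "oligomycin", "fccp", "rot_aa"))
    if (!length(ph[[p]])) stop(sprintf("empty phase: %s", p))
  basal_raw <- sfun$basal(ph$basal)
  oligo_raw <- sfun$oligomycin(ph$oligomycin)
  fccp_raw <- sfun$fccp(ph$fccp)
  nonmito <- sfun$rot_aa(ph$rot_aa)
  # the decomposition is built bottom-up so the accounting identities
  # basal = atp_linked + proton_leak and reserve = maximal - basal hold
  # bit-exactly, not merely to rounding
  atp_linked <- basal_raw - oligo_raw      # oligomycin-sensitive respiration
  proton_leak <- oligo_raw - nonmito       # oligomycin-insensitive, rot/AA-sensitive
  basal <- atp_linked + proton_leak
  maximal <- fccp_raw - nonmito
  reserve <- maximal - basal
  structure(list(nonmito = nonmito, basal = basal, atp_linked = atp_linked,
                 proton_leak = proton_leak, maximal = maximal,
                 reserve_capacity = reserve,
                 raw = c(basal = basal_raw, oligomycin = oligo_raw,
                         fccp = fccp_raw, rot_aa = nonmito),
                 quality_flag = any(c(basal, proton_leak, atp_linked,
                                      maximal, reserve) < 0)),
            class = "RespiratoryParameters")
}

#' @export
print.RespiratoryParameters <- function(x, ...) {
  cat("Respiratory parameters (pmol O2/min, non-mito corrected):\n")
  for (f in c("nonmito", "basal", "atp_linked", "proton_leak", "maximal",
              "reserve_capacity"))
    cat(sprintf("  %-17s %8.4g\n", f, x[[f]]))
  if (x$quality_flag) cat("  [quality flag: negative corrected value]\n")
  invisible(x)
}

#' Mitochondrial ATP production rate from oligomycin-sensitive OCR
#'
#' `atp_linked * o2_per_o * po_ratio`: each O2 provides two O atom
#' reductions, each coupled to `po_ratio` ATP under oxidative
#' phosphorylation.  Constants follow the standard extracellular-flux
#' ATP-rate convention and are exposed as parameters.
#'
#' @param trace an `OCRTrace`.
#' @param po_ratio ATP per O (default 2.75).
#' @param o2_per_o O atoms per O2 (default 2).
#' @return ATP production rate, pmol ATP/min.
#' @export
atp_production_rate <- function(trace, po_ratio = 2.75, o2_per_o = 2) {
  rp <- respiratory_parameters(trace)
  rp$atp_linked * o2_per_o * po_ratio
}

#' Per-phase ECAR summary
#'
#' Mean extracellular acidification rate per protocol phase (descriptive
#' only; no glycolytic ATP decomposition is attempted).
#'
#' @param trace an `OCRTrace` with an `ecar` column.
#' @return Named numeric vector of phase means.
#' @export
ecar_phase_means <- function(trace) {
  if (!"ecar" %in% names(trace)) stop("trace has no ecar column")
  vapply(split(trace$ecar, trace$phase)[c("basal", "oligomycin", "fccp", "rot_aa")],
         mean, numeric(1L))
}
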