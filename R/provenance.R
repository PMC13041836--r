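#' Provenance logging
#'
#' Interactive image-analysis tools hide the thresholds an operator picked;
#' here every derived value (Otsu threshold, TMRE background cutoff,
#' percentile threshold, gate bounds) is appended to a JSON-lines log so a
#' run can be audited and replayed.  Logging is off until a sink is set.
#'
#' @param path file to append JSON-lines records to, or `NULL` to disable.
#' @return The previous sink path, invisibly.
#' @export
set_provenance_log <- function(path) {
  old <- getOption("mitoquant.provenance")
  options(mitoquant.provenance = path)
  invisible(old)
}

# Append one {op, params, derived} record if a sink is configured.
prov_record <- function(op, params = list(), derived = list()) {
  path <- getOption("mitoquant.provenance")
  if (is.null(path)) return(invisible(NULL))
  rec <- jsonlite::toJSON(list(op = op, params = params, derived = derived),
                          auto_unbox = TRUE, digits = NA, null = "null")
  cat(rec, "\n", sep = "", file = path, append = TRUE)
  invisible(NULL)
}
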