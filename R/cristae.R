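#' STED line-profile container
#'
#' Intensity samples along a transect drawn across a mitochondrion in a
#' STED image (typical acquisition: 30 nm pixels).  Profile length is
#' `(n - 1) * pixel_size_um`.
#'
#' @param intensities numeric vector, length >= 2.
#' @param pixel_size_um micrometres per sample.
#' @return An object of class `"LineProfile"`.
#' @export
line_profile <- function(intensities, pixel_size_um) {
  if (length(intensities) < 2L || !all(is.finite(intensities)))
    stop("intensities must be >= 2 finite values")
  if (pixel_size_um <= 0) stop("pixel_size_um must be positive")
  structure(list(intensities = as.numeric(intensities),
                 pixel_size_um = pixel_size_um,
                 length_um = (length(intensities) - 1L) * pixel_size_um),
            class = "LineProfile")
}

#' Read a line profile from CSV
#'
#' Expects columns `position_um` (uniformly spaced) and `intensity`.
#'
#' @param path CSV file with a header row.
#' @return A [line_profile()].
#' @export
read_line_profile <- function(path) {
  df <- utils::read.csv(path)
  if (!all(c("position_um", "intensity") %in% names(df)))
    stop("CSV must have columns position_um, intensity")
  steps <- diff(df$position_um)
  if (any(steps <= 0) || diff(range(steps)) > 1e-6 * mean(steps))
    stop("position_um must be uniformly increasing")
  line_profile(df$intensity, mean(steps))
}

# Prominence of the local maximum at index i: height above the higher of
# the two minima separating it from higher ground (or the signal end).
.peak_prominence <- function(x, i) {
  n <- length(x)
  left_min <- x[i]
  j <- i - 1L
  while (j >= 1L && x[j] <= x[i]) { left_min <- min(left_min, x[j]); j <- j - 1L }
  right_min <- x[i]
  j <- i + 1L
  while (j <= n && x[j] <= x[i]) { right_min <- min(right_min, x[j]); j <- j + 1L }
  x[i] - max(left_min, right_min)
}

#' Detect fluorescence peaks along a line profile
#'
#' Local maxima (first sample of a plateau; profile endpoints excluded) with
#' prominence at least `min_prominence_frac` of the profile's full intensity
#' range and pairwise separation at least `min_separation_um`.  When two
#' candidates conflict, the taller (ties: lower index) wins.  A flat profile
#' has zero peaks.
#'
#' @param profile a [line_profile()].
#' @param min_prominence_frac fraction of (max - min), in (0, 1).
#' @param min_separation_um minimum peak spacing (default 0.06 um = two
#'   acquisition pixels at 30 nm).
#' @return Sorted integer vector of peak indices (1-based) with attribute
#'   `"positions_um"`.
#' @export
detect_peaks <- function(profile, min_prominence_frac = 0.2,
                         min_separation_um = 0.06) {
  stopifnot(min_prominence_frac > 0, min_prominence_frac < 1)
  x <- profile$intensities
  n <- length(x)
  rng <- max(x) - min(x)
  empty <- integer()
  attr(empty, "positions_um") <- numeric()
  if (rng == 0) return(empty)
  # local maxima via run-length encoding: a plateau is a peak iff the value
  # before it is lower and the value after it is lower; report its first index
  r <- rle(x)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  k <- length(r$values)
  is_pk <- vapply(seq_len(k), function(i) {
    i > 1L && i < k && r$values[i] > r$values[i - 1L] && r$values[i] > r$values[i + 1L]
  }, logical(1L))
  cand <- starts[is_pk]
  if (!length(cand)) return(empty)
  prom <- vapply(cand, function(i) .peak_prominence(x, i), numeric(1L))
  cand <- cand[prom >= min_prominence_frac * rng]
  if (!length(cand)) return(empty)
  o <- order(-x[cand], cand)
  keep <- integer()
  min_sep_px <- min_separation_um / profile$pixel_size_um
  for (i in cand[o]) {
    if (!length(keep) || all(abs(keep - i) >= min_sep_px)) keep <- c(keep, i)
  }
  keep <- sort(keep)
  attr(keep, "positions_um") <- (keep - 1L) * profile$pixel_size_um
  keep
}

#' Cristae density along a profile
#'
#' Number of detected peaks divided by the profile length — cristae per
#' micrometre of mitochondrion imaged.
#'
#' @param peaks integer peak indices from [detect_peaks()].
#' @param profile the [line_profile()] the peaks were detected on.
#' @return Density in 1/um.
#' @export
cristae_density <- function(peaks, profile) {
  if (profile$length_um <= 0) stop("zero-length profile")
  length(peaks) / profile$length_um
}
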