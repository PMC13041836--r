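#' Multi-channel image stack
#'
#' In-memory model of a multi-channel fluorescence Z-stack.  Pixels are kept
#' on a 4-D array indexed `(z, channel, y, x)`; intensities are raw detector
#' numbers (non-negative, finite), never rescaled.  Physical calibration is
#' carried alongside: `pixel_size_um` (isotropic in x/y) and `z_step_um`.
#' `channel_roles` maps an assay role tag (e.g. `"dapi"`, `"gfp"`,
#' `"mcherry"`, `"tmre"`, `"mtg"`, `"lamp1"`, `"lc3"`, `"mito_marker"`,
#' `"dqbsa"`) to a channel index; each role names exactly one channel.
#'
#' @param pixels 4-D numeric array `(z, channel, y, x)`, non-negative finite.
#' @param pixel_size_um micrometres per pixel edge (x/y), positive.
#' @param channel_roles named integer vector, role tag -> channel index.
#' @param z_step_um micrometres between consecutive z slices.
#' @return An object of class `"ImageStack"`.
#' @export
image_stack <- function(pixels, pixel_size_um, channel_roles, z_step_um = 0.5) {
  if (length(dim(pixels)) != 4L)
    stop("pixels must be a 4-D (z, channel, y, x) array")
  if (!all(is.finite(pixels)) || any(pixels < 0))
    stop("intensities must be finite and non-negative")
  storage.mode(pixels) <- "double"
  if (!is.numeric(pixel_size_um) || length(pixel_size_um) != 1L || pixel_size_um <= 0)
    stop("pixel_size_um must be a single positive number")
  roles <- as.integer(channel_roles)
  names(roles) <- names(channel_roles)
  if (is.null(names(roles)) || any(!nzchar(names(roles))) || anyDuplicated(names(roles)))
    stop("channel_roles must be uniquely named")
  if (any(roles < 1L) || any(roles > dim(pixels)[2L]))
    stop("channel_roles indices out of range")
  if (anyDuplicated(roles))
    stop("each role must map to a distinct channel")
  structure(list(pixels = pixels, pixel_size_um = pixel_size_um,
                 z_step_um = z_step_um, channel_roles = roles),
            class = "ImageStack")
}

#' @export
print.ImageStack <- function(x, ...) {
  d <- dim(x$pixels)
  cat(sprintf("ImageStack: %d z x %d ch x %d x %d px (%.3g um/px)\n",
              d[1], d[2], d[3], d[4], x$pixel_size_um))
  cat("  roles:", paste(sprintf("%s=%d", names(x$channel_roles),
                                x$channel_roles), collapse = ", "), "\n")
  invisible(x)
}

#' Single-plane intensity image
#'
#' @param pixels numeric matrix `(y, x)` of finite intensities.
#' @param pixel_size_um micrometres per pixel edge.
#' @return An object of class `"Image2D"`.
#' @export
image2d <- function(pixels, pixel_size_um) {
  if (!is.matrix(pixels) || !all(is.finite(pixels)))
    stop("pixels must be a finite numeric matrix")
  structure(list(pixels = pixels, pixel_size_um = pixel_size_um),
            class = "Image2D")
}

#' @export
print.Image2D <- function(x, ...) {
  cat(sprintf("Image2D: %d x %d px (%.3g um/px), range [%.4g, %.4g]\n",
              nrow(x$pixels), ncol(x$pixels), x$pixel_size_um,
              min(x$pixels), max(x$pixels)))
  invisible(x)
}

#' Binary (foreground/background) mask
#'
#' @param pixels logical matrix `(y, x)`.
#' @param pixel_size_um micrometres per pixel edge.
#' @return An object of class `"BinaryMask"`.
#' @export
binary_mask <- function(pixels, pixel_size_um) {
  if (!is.matrix(pixels)) stop("pixels must be a matrix")
  storage.mode(pixels) <- "logical"
  if (anyNA(pixels)) stop("mask must not contain NA")
  structure(list(pixels = pixels, pixel_size_um = pixel_size_um),
            class = "BinaryMask")
}

#' @export
print.BinaryMask <- function(x, ...) {
  cat(sprintf("BinaryMask: %d x %d px, %d foreground\n",
              nrow(x$pixels), ncol(x$pixels), sum(x$pixels)))
  invisible(x)
}

#' Labeled object mask
#'
#' Integer image where 0 is background and positive values identify objects.
#' Freshly created label masks use contiguous labels `1..n_objects`;
#' filtering operations (edge or gate exclusion) may leave gaps while keeping
#' labels stable.
#'
#' @param labels integer matrix `(y, x)`, non-negative.
#' @param pixel_size_um micrometres per pixel edge.
#' @return An object of class `"LabeledMask"` with an `n_objects` field
#'   (number of distinct non-zero labels).
#' @export
labeled_mask <- function(labels, pixel_size_um) {
  if (!is.matrix(labels)) stop("labels must be a matrix")
  storage.mode(labels) <- "integer"
  if (anyNA(labels) || any(labels < 0L)) stop("labels must be non-negative integers")
  structure(list(labels = labels, pixel_size_um = pixel_size_um,
                 n_objects = length(setdiff(unique(as.vector(labels)), 0L))),
            class = "LabeledMask")
}

#' @export
print.LabeledMask <- function(x, ...) {
  cat(sprintf("LabeledMask: %d x %d px, %d objects\n",
              nrow(x$labels), ncol(x$labels), x$n_objects))
  invisible(x)
}

# role -> channel index lookup with a clear error
.role_index <- function(stack, role) {
  if (!role %in% names(stack$channel_roles))
    stop(sprintf("unknown channel role '%s' (have: %s)", role,
                 paste(names(stack$channel_roles), collapse = ", ")))
  stack$channel_roles[[role]]
}
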