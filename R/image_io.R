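#' Read a multi-page TIFF as an ImageStack
#'
#' Planes are interpreted in `"zc"` order (for each z slice, all channels in
#' sequence) or `"cz"` order (for each channel, all slices).  Stacks written
#' by [write_stack()] carry a JSON sidecar (`<path>.meta.json`) recording
#' the plane layout; when present it is checked against the declared roles, so
#' declaring three roles on a two-channel file fails loudly instead of
#' silently mis-slicing.  Intensities are read as stored integer detector
#' numbers; no rescaling is applied.
#'
#' @param path multi-page TIFF file.
#' @param channel_roles named integer vector, role tag -> channel index.
#' @param pixel_size_um micrometres per pixel edge.
#' @param z_step_um micrometres between slices.
#' @param plane_order `"zc"` (default) or `"cz"`.
#' @return An [image_stack()].
#' @export
load_stack <- function(path, channel_roles, pixel_size_um,
                       z_step_um = 0.5, plane_order = c("zc", "cz")) {
  plane_order <- match.arg(plane_order)
  if (!file.exists(path)) stop(sprintf("file not found: %s", path))
  pages <- tiff::readTIFF(path, all = TRUE, as.is = TRUE)
  if (!length(pages)) stop("empty TIFF")
  n_ch <- length(channel_roles)
  sidecar <- paste0(path, ".meta.json")
  if (file.exists(sidecar)) {
    meta <- tryCatch(jsonlite::fromJSON(sidecar), error = function(e) NULL)
    if (!is.null(meta$n_channels) && meta$n_channels != n_ch)
      stop(sprintf("channel-count mismatch: file has %d channels, %d roles declared",
                   meta$n_channels, n_ch))
    if (!is.null(meta$plane_order)) plane_order <- meta$plane_order
  }
  if (length(pages) %% n_ch != 0L)
    stop(sprintf("channel-count mismatch: %d pages not divisible by %d declared channels",
                 length(pages), n_ch))
  n_z <- length(pages) %/% n_ch
  if (!all(vapply(pages, is.numeric, logical(1L))))
    stop("non-numeric pixel data")
  h <- nrow(pages[[1L]]); w <- ncol(pages[[1L]])
  px <- array(0, dim = c(n_z, n_ch, h, w))
  for (i in seq_along(pages)) {
    if (plane_order == "zc") {
      z <- (i - 1L) %/% n_ch + 1L; ch <- (i - 1L) %% n_ch + 1L
    } else {
      ch <- (i - 1L) %/% n_z + 1L; z <- (i - 1L) %% n_z + 1L
    }
    pg <- pages[[i]]
    if (length(dim(pg)) == 3L) pg <- pg[, , 1L]  # tolerate grayscale-as-RGB
    px[z, ch, , ] <- pg
  }
  image_stack(px, pixel_size_um, channel_roles, z_step_um)
}

#' Write an ImageStack to a multi-page TIFF
#'
#' Planes are written as 16-bit unsigned integers in `"zc"` order with a
#' JSON sidecar `<path>.meta.json` (`n_z`, `n_channels`, roles, plane order,
#' pixel size) so [load_stack()] can validate the declared channel layout.
#' Intensities must already be integers in `[0, 65535]`; writing rounds
#' nothing silently.
#'
#' @param stack an [image_stack()].
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_stack <- function(stack, path) {
  px <- stack$pixels
  if (any(px != round(px)) || any(px > 65535))
    stop("write_stack stores 16-bit integers: intensities must be whole numbers in [0, 65535]")
  d <- dim(px)
  planes <- vector("list", d[1L] * d[2L])
  i <- 1L
  for (z in seq_len(d[1L])) for (ch in seq_len(d[2L])) {
    planes[[i]] <- px[z, ch, , ] / 65535
    i <- i + 1L
  }
  tiff::writeTIFF(planes, path, bits.per.sample = 16L)
  jsonlite::write_json(list(
    writer = "mitoquant", n_z = d[1L], n_channels = d[2L],
    roles = as.list(stack$channel_roles), plane_order = "zc",
    pixel_size_um = stack$pixel_size_um, z_step_um = stack$z_step_um),
    paste0(path, ".meta.json"), auto_unbox = TRUE, digits = NA)
  invisible(path)
}
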