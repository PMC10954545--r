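#' Multi-channel image stack with physical voxel size
#'
#' Thin container for 2D or 3D confocal data. Channels are numeric arrays
#' indexed `[x, y]` or `[x, y, z]`; the physical position of a voxel centre
#' is its 0-based index times the voxel size, in micrometres.
#'
#' @param channels Named list of numeric arrays, all of the same dimensions.
#' @param voxel_size Numeric vector `(x, y, z)` in um; strictly positive.
#'   For 2D data the z entry is ignored but must still be positive.
#' @return Object of class `image_stack`.
#' @export
image_stack <- function(channels, voxel_size) {
  if (!is.list(channels) || length(channels) == 0L ||
      is.null(names(channels)) || any(names(channels) == "")) {
    stop("`channels` must be a non-empty named list of arrays", call. = FALSE)
  }
  dims <- lapply(channels, function(ch) dim(ch) %||% length(ch))
  if (length(unique(lapply(dims, as.integer))) != 1L) {
    stop("all channels must share the same dimensions", call. = FALSE)
  }
  if (any(voxel_size <= 0) || length(voxel_size) < 2L) {
    stop("`voxel_size` must be positive (x, y[, z]) in um", call. = FALSE)
  }
  if (length(voxel_size) == 2L) voxel_size <- c(voxel_size, 1)
  for (ch in channels) {
    if (any(ch < 0, na.rm = TRUE)) {
      stop("intensities must be nonnegative", call. = FALSE)
    }
  }
  structure(list(channels = channels, voxel_size = as.numeric(voxel_size)),
            class = "image_stack")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' @export
print.image_stack <- function(x, ...) {
  d <- dim(x$channels[[1L]]) %||% length(x$channels[[1L]])
  cat(sprintf("image_stack: %s px, voxel %s um, channels: %s\n",
              paste(d, collapse = " x "),
              paste(signif(x$voxel_size[seq_along(d)], 4), collapse = " x "),
              paste(names(x$channels), collapse = ", ")))
  invisible(x)
}

#' Lateral extent of a stack in micrometres
#' @param stack An `image_stack`.
#' @return Numeric `(x_um, y_um)`.
#' @keywords internal
lateral_extent_um <- function(stack) {
  d <- dim(stack$channels[[1L]])
  c(d[1L] * stack$voxel_size[1L], d[2L] * stack$voxel_size[2L])
}

#' Read a multi-page TIFF into an image stack
#'
#' Pages are assigned to channels in order of `channel_names`; with one name
#' and several pages the pages are stacked as z-planes of one 3D channel,
#' otherwise pages cycle through channels fastest (channel-interleaved).
#'
#' @param path TIFF file.
#' @param channel_names Character vector of channel names.
#' @param voxel_size `(x, y, z)` in um (TIFF rarely stores a trustworthy
#'   voxel size, so it is explicit here).
#' @return An [image_stack()].
#' @export
read_image_stack <- function(path, channel_names, voxel_size) {
  if (!requireNamespace("tiff", quietly = TRUE)) {
    stop("reading TIFF requires the 'tiff' package", call. = FALSE)
  }
  pages <- tiff::readTIFF(path, all = TRUE, as.is = TRUE)
  if (!is.list(pages)) pages <- list(pages)
  # readTIFF returns [row, col] = [y, x]; transpose to [x, y]
  pages <- lapply(pages, t)
  nc <- length(channel_names)
  if (length(pages) %% nc != 0L) {
    stop("page count is not a multiple of the channel count", call. = FALSE)
  }
  nz <- length(pages) %/% nc
  chans <- lapply(seq_len(nc), function(ci) {
    planes <- pages[seq(ci, length(pages), by = nc)]
    if (nz == 1L) planes[[1L]]
    else array(unlist(planes), dim = c(dim(planes[[1L]]), nz))
  })
  names(chans) <- channel_names
  image_stack(chans, voxel_size)
}

#' Write an image stack to a multi-page TIFF
#'
#' z-planes are written channel-interleaved, matching [read_image_stack()].
#' Intensities are rescaled to [0, 1] by the global maximum.
#'
#' @param stack An `image_stack`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_image_stack <- function(stack, path) {
  if (!requireNamespace("tiff", quietly = TRUE)) {
    stop("writing TIFF requires the 'tiff' package", call. = FALSE)
  }
  mx <- max(1e-12, max(vapply(stack$channels, max, 0)))
  d <- dim(stack$channels[[1L]])
  nz <- if (length(d) == 3L) d[3L] else 1L
  pages <- list()
  for (z in seq_len(nz)) {
    for (ch in stack$channels) {
      plane <- if (length(d) == 3L) ch[, , z] else ch
      pages[[length(pages) + 1L]] <- t(plane) / mx
    }
  }
  tiff::writeTIFF(pages, path, bits.per.sample = 16L)
  invisible(path)
}
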