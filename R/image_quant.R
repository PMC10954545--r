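#' Hysteresis thresholds from sampled compartment intensities
#'
#' Thresholds for background removal are derived from the intensities of
#' (typically ten) randomly chosen labelled compartments in the channel:
#' the high threshold is their mean, the low threshold their minimum minus
#' two sample standard deviations, floored at zero. The exact formulas are
#' configurable through `high_fun` / `low_fun` should a different convention
#' be needed.
#'
#' @param intensities Numeric vector of sampled compartment intensities
#'   (length >= 2, nonnegative).
#' @param high_fun,low_fun Functions mapping the sample to the two
#'   thresholds; defaults implement mean and min - 2 sd.
#' @return Object of class `hysteresis_thresholds`: list with `high`, `low`.
#' @export
derive_thresholds <- function(intensities,
                              high_fun = mean,
                              low_fun = function(x) {
                                max(0, min(x) - 2 * stats::sd(x))
                              }) {
  if (length(intensities) < 2L) {
    stop("need at least 2 compartment intensities (s.d. undefined)",
         call. = FALSE)
  }
  if (any(intensities < 0)) {
    stop("intensities must be nonnegative", call. = FALSE)
  }
  high <- high_fun(intensities)
  low <- low_fun(intensities)
  hysteresis_thresholds(high = high, low = low)
}

#' @rdname derive_thresholds
#' @param high,low Threshold values, `0 <= low <= high`.
#' @export
hysteresis_thresholds <- function(high, low) {
  stopifnot_scalar_num(high, "high", min = 0)
  stopifnot_scalar_num(low, "low", min = 0)
  if (low > high) stop("`low` must not exceed `high`", call. = FALSE)
  structure(list(high = high, low = low), class = "hysteresis_thresholds")
}

# all full-connectivity neighbour offsets (8 in 2D, 26 in 3D)
neighbour_offsets <- function(nd) {
  grid <- do.call(expand.grid, rep(list(c(-1L, 0L, 1L)), nd))
  grid <- as.matrix(grid)
  grid[rowSums(abs(grid)) > 0L, , drop = FALSE]
}

shift_logical <- function(m, off) {
  d <- dim(m)
  out <- array(FALSE, d)
  src <- dst <- vector("list", length(d))
  for (k in seq_along(d)) {
    o <- off[k]
    if (abs(o) >= d[k]) return(out)
    if (o >= 0) {
      src[[k]] <- seq_len(d[k] - o)
      dst[[k]] <- seq.int(1L + o, d[k])
    } else {
      src[[k]] <- seq.int(1L - o, d[k])
      dst[[k]] <- seq_len(d[k] + o)
    }
  }
  piece <- do.call(`[`, c(list(m), src, list(drop = FALSE)))
  do.call(`[<-`, c(list(out), dst, list(piece)))
}

#' Hysteresis background filter
#'
#' Two-threshold segmentation: a voxel is foreground when it is at or above
#' the low threshold and connected (full neighbour connectivity:
#' 8-connected in 2D, 26-connected in 3D) to at least one voxel at or above
#' the high threshold through voxels at or above the low threshold.
#' Implemented as iterated geodesic dilation of the high seeds inside the
#' low mask.
#'
#' @param channel 2D matrix or 3D array of intensities.
#' @param thresholds A [hysteresis_thresholds()] object.
#' @return Logical array of the same shape: `TRUE` for retained voxels.
#' @export
hysteresis_filter <- function(channel, thresholds) {
  stopifnot(inherits(thresholds, "hysteresis_thresholds"))
  if (is.null(dim(channel))) stop("`channel` must be 2D or 3D", call. = FALSE)
  grow <- channel >= thresholds$low
  mask <- channel >= thresholds$high
  if (!any(mask)) return(mask)
  offs <- neighbour_offsets(length(dim(channel)))
  repeat {
    dil <- mask
    for (r in seq_len(nrow(offs))) {
      dil <- dil | shift_logical(mask, offs[r, ])
    }
    new <- dil & grow
    if (sum(new) == sum(mask)) break
    mask <- new
  }
  mask
}

#' Subdivide a stack into square lateral regions
#'
#' Tiles the imaging plane into non-overlapping `size_um` x `size_um`
#' regions spanning the full depth; incomplete border tiles are discarded.
#' Used to assess colocalization at tissue scale region by region.
#'
#' @param stack An [image_stack()].
#' @param size_um Region edge length in um (default 25).
#' @return List of `image_stack` tiles (possibly empty, with a warning when
#'   the stack is smaller than a single region); each tile carries an
#'   `offset_px` attribute with its 0-based lateral origin.
#' @export
subdivide_regions <- function(stack, size_um = 25) {
  stopifnot(inherits(stack, "image_stack"))
  stopifnot_scalar_num(size_um, "size_um", min = 0, strict_min = TRUE)
  d <- dim(stack$channels[[1L]])
  vx <- stack$voxel_size[1L]
  vy <- stack$voxel_size[2L]
  npx <- floor(size_um / vx + 1e-9)
  npy <- floor(size_um / vy + 1e-9)
  ntx <- d[1L] %/% npx
  nty <- d[2L] %/% npy
  if (npx < 1L || npy < 1L || ntx < 1L || nty < 1L) {
    warning("stack smaller than one region; returning empty list",
            call. = FALSE)
    return(list())
  }
  out <- vector("list", ntx * nty)
  k <- 0L
  for (ty in seq_len(nty)) {
    for (tx in seq_len(ntx)) {
      xi <- seq.int((tx - 1L) * npx + 1L, tx * npx)
      yi <- seq.int((ty - 1L) * npy + 1L, ty * npy)
      chans <- lapply(stack$channels, function(ch) {
        if (length(d) == 3L) ch[xi, yi, , drop = FALSE]
        else ch[xi, yi, drop = FALSE]
      })
      tile <- image_stack(chans, stack$voxel_size)
      attr(tile, "offset_px") <- c(xi[1L] - 1L, yi[1L] - 1L)
      k <- k + 1L
      out[[k]] <- tile
    }
  }
  out
}

#' Manders colocalization coefficients
#'
#' `M1` is the fraction of channel A's integrated intensity (within A's
#' foreground mask) that falls inside channel B's mask; `M2` is the
#' symmetric quantity for B. Masks typically come from [hysteresis_filter()]
#' applied to each channel.
#'
#' @param ch_a,ch_b Intensity arrays of identical shape.
#' @param mask_a,mask_b Logical foreground masks of the same shape.
#' @return Named numeric vector `c(M1 = ..., M2 = ...)`, both in [0, 1].
#' @export
manders <- function(ch_a, ch_b, mask_a, mask_b) {
  if (!identical(dim(ch_a), dim(ch_b)) ||
      !identical(dim(ch_a), dim(mask_a)) ||
      !identical(dim(ch_a), dim(mask_b))) {
    stop("channels and masks must share one shape", call. = FALSE)
  }
  tot_a <- sum(ch_a[mask_a])
  tot_b <- sum(ch_b[mask_b])
  if (tot_a <= 0 || tot_b <= 0) {
    stop("zero masked intensity: Manders coefficients undefined",
         call. = FALSE)
  }
  both <- mask_a & mask_b
  c(M1 = sum(ch_a[both]) / tot_a, M2 = sum(ch_b[both]) / tot_b)
}

#' Colocalization of two channels across 25-um regions
#'
#' Convenience wrapper reproducing the per-region colocalization workflow:
#' derive hysteresis thresholds per channel from sampled compartment
#' intensities, remove background, tile the stack into square regions and
#' compute Manders coefficients in each region.
#'
#' @param stack An [image_stack()].
#' @param ch_a,ch_b Channel names.
#' @param compartments_a,compartments_b Numeric vectors of sampled
#'   compartment intensities per channel (see [derive_thresholds()]).
#' @param size_um Region edge length in um (default 25).
#' @return Data.frame with one row per region: `region`, `M1`, `M2`.
#'   Regions where a channel has no foreground are dropped with a warning.
#' @export
colocalize_regions <- function(stack, ch_a, ch_b, compartments_a,
                               compartments_b, size_um = 25) {
  thr_a <- derive_thresholds(compartments_a)
  thr_b <- derive_thresholds(compartments_b)
  tiles <- subdivide_regions(stack, size_um = size_um)
  res <- lapply(seq_along(tiles), function(i) {
    a <- drop(tiles[[i]]$channels[[ch_a]])
    b <- drop(tiles[[i]]$channels[[ch_b]])
    ma <- hysteresis_filter(a, thr_a)
    mb <- hysteresis_filter(b, thr_b)
    if (sum(a[ma]) <= 0 || sum(b[mb]) <= 0) return(NULL)
    m <- manders(a, b, ma, mb)
    data.frame(region = i, M1 = m[["M1"]], M2 = m[["M2"]])
  })
  dropped <- sum(vapply(res, is.null, TRUE))
  if (dropped > 0L) {
    warning(dropped, " region(s) without foreground dropped", call. = FALSE)
  }
  do.call(rbind, res[!vapply(res, is.null, TRUE)])
}
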