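#' Specification for a polyhedral-cell confocal phantom
#'
#' Describes a synthetic fluorescence image of a lattice of rectangular
#' "cells" whose walls carry three signal classes: a uniform face signal on
#' the wall planes, an edge signal concentrated where walls meet and
#' decaying as `exp(-d / edge_decay_um)` with distance `d` from the edge,
#' and intracellular punctae rendered as Gaussian spots. The ideal image is
#' convolved with a Gaussian point-spread function and corrupted with
#' Poisson shot noise followed by additive Gaussian read noise — the
#' standard confocal noise approximation. Each cell edge receives its own
#' log-normal brightness multiplier (`edge_sdlog`), emulating the strong
#' edge-to-edge variability seen in real meristems; this inter-edge
#' variability, not shot noise, dominates the variance of edge-distance
#' intensity profiles.
#'
#' @param n_cells Integer vector, cells per axis: length 2 for a mid-plane
#'   section, length 3 for a volume (default `c(3, 3)`).
#' @param cell_size_um Cell edge length per axis in um (default 8).
#' @param margin_um Empty margin around the lattice in um (default 1).
#' @param voxel_size_um Voxel size `(x, y[, z])` in um
#'   (default `c(0.1, 0.1, 0.3)`).
#' @param wall_thickness_um Rendered thickness of the wall signal band in
#'   um (default 0.7: two adjacent plasma membranes plus the wall, on the
#'   order of the profile width once blurred by the PSF).
#' @param face_intensity,edge_intensity Peak intensities of the two wall
#'   signal classes (defaults 40 and 150).
#' @param edge_decay_um Perpendicular decay length of the edge signal in um
#'   (default 1).
#' @param edge_sdlog Log-normal s.d. of the per-edge brightness multiplier
#'   (default 0.7, a coefficient of variation of about 80%, matching the
#'   wide +/- 1 s.d. ribbons of measured single-edge profiles).
#' @param punctae_density Punctae per um^2 (2D) or um^3 (3D), default 0.05.
#' @param punctae_intensity,punctae_sigma_um Amplitude and Gaussian radius
#'   of each punctum (defaults 300, 0.15).
#' @param background_intensity Uniform background (cytoplasmic) intensity
#'   added everywhere (default 5).
#' @param psf_sigma_um Gaussian PSF s.d. in um (default 0.15; 0 disables).
#' @param gain Photons per intensity unit for Poisson shot noise
#'   (default 1; 0 disables shot noise).
#' @param read_noise_sd Gaussian read noise s.d. (default 3; 0 disables).
#' @param seed Integer seed.
#' @return Object of class `phantom_spec`.
#' @export
phantom_spec <- function(n_cells = c(3L, 3L), cell_size_um = 8,
                         margin_um = 1, voxel_size_um = c(0.1, 0.1, 0.3),
                         wall_thickness_um = 0.7, face_intensity = 40,
                         edge_intensity = 150, edge_decay_um = 1,
                         edge_sdlog = 0.7, punctae_density = 0.05,
                         punctae_intensity = 300, punctae_sigma_um = 0.15,
                         background_intensity = 5,
                         psf_sigma_um = 0.15, gain = 1, read_noise_sd = 3,
                         seed = 1L) {
  nd <- length(n_cells)
  if (!nd %in% c(2L, 3L)) stop("`n_cells` must have length 2 or 3",
                               call. = FALSE)
  cell_size_um <- rep_len(cell_size_um, nd)
  stopifnot_scalar_num(edge_decay_um, "edge_decay_um", 0, strict_min = TRUE)
  stopifnot_scalar_num(psf_sigma_um, "psf_sigma_um", 0)
  if (face_intensity < 0 || edge_intensity < 0 || punctae_intensity < 0) {
    stop("intensities must be nonnegative", call. = FALSE)
  }
  n_px <- vapply(seq_len(nd), function(k) {
    as.integer(round((n_cells[k] * cell_size_um[k] + 2 * margin_um) /
                       voxel_size_um[k]))
  }, 1L)
  if (prod(as.numeric(n_px)) > 6.7e7) {
    stop("phantom would exceed the resource guard (", prod(n_px),
         " voxels)", call. = FALSE)
  }
  structure(list(n_cells = as.integer(n_cells),
                 cell_size_um = cell_size_um, margin_um = margin_um,
                 voxel_size_um = voxel_size_um[seq_len(nd)],
                 wall_thickness_um = wall_thickness_um,
                 face_intensity = face_intensity,
                 edge_intensity = edge_intensity,
                 edge_decay_um = edge_decay_um, edge_sdlog = edge_sdlog,
                 punctae_density = punctae_density,
                 punctae_intensity = punctae_intensity,
                 punctae_sigma_um = punctae_sigma_um,
                 background_intensity = background_intensity,
                 psf_sigma_um = psf_sigma_um, gain = gain,
                 read_noise_sd = read_noise_sd, seed = as.integer(seed),
                 n_px = n_px),
            class = "phantom_spec")
}

# circular (wrap-around) Gaussian blur via FFT; conserves total intensity
# to machine precision. sigma_px per dimension; 0 skips a dimension.
gaussian_blur_fft <- function(img, sigma_px) {
  d <- dim(img)
  if (all(sigma_px <= 0)) return(img)
  kern1 <- lapply(seq_along(d), function(k) {
    n <- d[k]
    if (sigma_px[k] <= 0) {
      g <- numeric(n); g[1L] <- 1; g
    } else {
      pos <- pmin(0:(n - 1L), n - (0:(n - 1L)))
      g <- exp(-pos^2 / (2 * sigma_px[k]^2))
      g / sum(g)
    }
  })
  kern <- kern1[[1L]]
  for (k in seq_along(d)[-1L]) kern <- outer(kern, kern1[[k]])
  kern <- array(kern, d)
  Re(stats::fft(stats::fft(img) * stats::fft(kern), inverse = TRUE)) /
    length(img)
}

# per-axis distance to the nearest wall plane and that plane's index
axis_wall_distance <- function(spec, k) {
  coord <- (seq_len(spec$n_px[k]) - 1L) * spec$voxel_size_um[k]
  planes <- spec$margin_um + (0:spec$n_cells[k]) * spec$cell_size_um[k]
  idx <- vapply(coord, function(x) which.min(abs(planes - x)), 1L)
  list(dist = abs(coord - planes[idx]), idx = idx, coord = coord,
       planes = planes)
}

# noiseless signal components of a phantom; RNG state must be set by caller
render_components <- function(spec) {
  nd <- length(spec$n_px)
  ax <- lapply(seq_len(nd), function(k) axis_wall_distance(spec, k))
  d <- spec$n_px
  expand_axis <- function(v, k) {
    aperm(array(v, dim = c(d[k], d[-k])),
          order(c(k, seq_len(nd)[-k])))
  }
  D <- lapply(seq_len(nd), function(k) expand_axis(ax[[k]]$dist, k))
  I <- lapply(seq_len(nd), function(k) expand_axis(ax[[k]]$idx, k))
  half_t <- spec$wall_thickness_um / 2
  near <- lapply(D, function(x) x <= half_t)
  wall_mask <- Reduce(`|`, near)

  if (nd == 2L) {
    d_edge <- sqrt(D[[1L]]^2 + D[[2L]]^2)
    edge_id <- (I[[1L]] - 1L) * (spec$n_cells[2L] + 1L) + I[[2L]]
  } else {
    sumsq <- D[[1L]]^2 + D[[2L]]^2 + D[[3L]]^2
    dmax <- pmax(D[[1L]], D[[2L]], D[[3L]])
    d_edge <- sqrt(pmax(sumsq - dmax^2, 0))
    # edge line = the two axes with the smallest distances; id combines the
    # line's axis and the two plane indices
    ax_far <- (D[[1L]] == dmax) * 1L +
      (D[[2L]] == dmax & D[[1L]] != dmax) * 2L +
      (D[[3L]] == dmax & D[[1L]] != dmax & D[[2L]] != dmax) * 3L
    np1 <- max(spec$n_cells) + 2L
    ia <- ifelse(ax_far == 1L, I[[2L]], I[[1L]])
    ib <- ifelse(ax_far == 3L, I[[2L]], I[[3L]])
    edge_id <- (ax_far - 1L) * np1 * np1 + (ia - 1L) * np1 + ib
  }
  uid <- sort(unique(as.vector(edge_id)))
  mult <- stats::rlnorm(length(uid), meanlog = -spec$edge_sdlog^2 / 2,
                        sdlog = spec$edge_sdlog)
  m_arr <- array(mult[match(edge_id, uid)], dim = d)

  face <- spec$face_intensity * wall_mask
  edge <- spec$edge_intensity * m_arr * exp(-d_edge / spec$edge_decay_um) *
    wall_mask

  # punctae: Poisson number of Gaussian spots, uniform over the field
  extent <- spec$n_px * spec$voxel_size_um
  n_punc <- stats::rpois(1L, spec$punctae_density * prod(extent))
  punc <- array(0, dim = d)
  if (n_punc > 0L && spec$punctae_intensity > 0) {
    centers <- vapply(seq_len(nd),
                      function(k) stats::runif(n_punc, 0, extent[k]),
                      numeric(n_punc))
    centers <- matrix(centers, ncol = nd)
    sig_px <- spec$punctae_sigma_um / spec$voxel_size_um
    for (p in seq_len(n_punc)) {
      ctr_px <- centers[p, ] / spec$voxel_size_um + 1
      lo <- pmax(1L, floor(ctr_px - 4 * sig_px))
      hi <- pmin(d, ceiling(ctr_px + 4 * sig_px))
      if (any(lo > hi)) next
      idx <- lapply(seq_len(nd), function(k) seq.int(lo[k], hi[k]))
      g1 <- lapply(seq_len(nd), function(k) {
        exp(-((idx[[k]] - ctr_px[k]))^2 / (2 * sig_px[k]^2))
      })
      spot <- g1[[1L]]
      for (k in seq_len(nd)[-1L]) spot <- outer(spot, g1[[k]])
      old <- do.call(`[`, c(list(punc), idx, list(drop = FALSE)))
      punc <- do.call(`[<-`, c(list(punc), idx,
                               list(old + spec$punctae_intensity * spot)))
    }
  }
  list(face = face, edge = edge, punctae = punc, wall_mask = wall_mask,
       d_edge = d_edge, axes = ax)
}

apply_noise <- function(img, spec) {
  out <- img
  if (spec$gain > 0) {
    # blur can leave values a hair below zero; Poisson needs lambda >= 0
    out <- stats::rpois(length(img),
                        pmax(as.vector(img), 0) * spec$gain) / spec$gain
  }
  if (spec$read_noise_sd > 0) {
    out <- out + stats::rnorm(length(img), 0, spec$read_noise_sd)
  }
  array(pmax(out, 0), dim = dim(img))
}

#' Render a confocal phantom with known ground truth
#'
#' @param spec A [phantom_spec()].
#' @return List: `stack` (an [image_stack()] with one channel `"signal"`),
#'   `noiseless` (PSF-blurred ideal image), `components` (noiseless face /
#'   edge / punctae images before blurring), `wall_mask`, `edge_distance`
#'   (per-voxel distance to the nearest cell edge, um), `spec`.
#' @examples
#' ph <- make_phantom(phantom_spec(n_cells = c(2, 2), seed = 3))
#' ph$stack
#' @export
make_phantom <- function(spec) {
  stopifnot(inherits(spec, "phantom_spec"))
  with_seed(spec$seed, {
    comp <- render_components(spec)
    ideal <- comp$face + comp$edge + comp$punctae + spec$background_intensity
    blurred <- gaussian_blur_fft(ideal,
                                 spec$psf_sigma_um / spec$voxel_size_um)
    noisy <- apply_noise(blurred, spec)
    list(stack = image_stack(list(signal = noisy), spec$voxel_size_um),
         noiseless = blurred,
         components = comp[c("face", "edge", "punctae")],
         wall_mask = comp$wall_mask, edge_distance = comp$d_edge,
         spec = spec)
  })
}

#' Wall traces along a phantom's cell walls, anchored at cell edges
#'
#' Generates straight traces that start at an interior wall junction (a
#' cell edge in the mid-plane) and run along a wall towards the middle of
#' the wall, the geometry used for edge-distance intensity profiles.
#' Traces on walls parallel to the y axis are labelled
#' longitudinal-anticlinal and those parallel to x transverse-anticlinal.
#'
#' @param spec A 2D [phantom_spec()].
#' @param length_um Trace length in um (default: half the cell size).
#' @param max_traces Cap on the number of traces (default all).
#' @return List of [wall_trace()] objects.
#' @export
phantom_wall_traces <- function(spec, length_um = NULL, max_traces = Inf) {
  stopifnot(inherits(spec, "phantom_spec"))
  if (length(spec$n_px) != 2L) {
    stop("wall traces are generated for 2D phantoms", call. = FALSE)
  }
  if (is.null(length_um)) length_um <- min(spec$cell_size_um) / 2
  px <- spec$margin_um + (0:spec$n_cells[1L]) * spec$cell_size_um[1L]
  py <- spec$margin_um + (0:spec$n_cells[2L]) * spec$cell_size_um[2L]
  traces <- list()
  dirs <- list(c(0, 1), c(0, -1), c(1, 0), c(-1, 0))
  classes <- c("longitudinal-anticlinal", "longitudinal-anticlinal",
               "transverse-anticlinal", "transverse-anticlinal")
  k <- 0L
  for (i in seq.int(2L, length(px) - 1L)) {
    for (j in seq.int(2L, length(py) - 1L)) {
      for (dd in seq_along(dirs)) {
        if (length(traces) >= max_traces) return(traces)
        k <- k + 1L
        anchor <- c(px[i], py[j])
        end <- anchor + dirs[[dd]] * length_um
        traces[[length(traces) + 1L]] <-
          wall_trace(rbind(anchor, end), wall_class = classes[dd],
                     id = sprintf("corner%d.%d_dir%d", i, j, dd))
      }
    }
  }
  traces
}

#' Simulate an ablation experiment as a pre/post phantom pair
#'
#' Renders one phantom geometry twice: the pre-ablation image unchanged,
#' and the post-ablation image with the edge-class signal scaled by
#' `1 - depletion(d)` where `d` is the distance to the wound centre in um,
#' and a circular wound region zeroed out. Face and punctae signal are
#' unchanged (tissue deformation is not simulated); the two images share
#' geometry, punctae and edge brightness but have independent noise.
#'
#' @param spec A [phantom_spec()].
#' @param depletion Function of distance-to-wound (um) returning the
#'   fractional edge-signal loss in [0, 1].
#' @param wound_center_um Wound centre (defaults to the image centre).
#' @param wound_radius_um Radius of the zeroed wound region (default 2).
#' @return List: `pre`, `post` (image_stacks), `pre_noiseless`,
#'   `post_noiseless`, `wound_mask`, `wound_center_um`, `spec`.
#' @export
make_ablation_pair <- function(spec, depletion,
                               wound_center_um = NULL,
                               wound_radius_um = 2) {
  stopifnot(inherits(spec, "phantom_spec"), is.function(depletion))
  test_d <- seq(0, 100, by = 0.5)
  dep <- depletion(test_d)
  if (any(dep < 0 | dep > 1 | !is.finite(dep))) {
    stop("`depletion` must map distances to [0, 1]", call. = FALSE)
  }
  nd <- length(spec$n_px)
  extent <- spec$n_px * spec$voxel_size_um
  if (is.null(wound_center_um)) wound_center_um <- extent / 2
  comp <- with_seed(spec$seed, render_components(spec))
  coords <- lapply(seq_len(nd), function(k) {
    (seq_len(spec$n_px[k]) - 1L) * spec$voxel_size_um[k]
  })
  sq <- lapply(seq_len(nd), function(k) {
    v <- (coords[[k]] - wound_center_um[k])^2
    aperm(array(v, dim = c(spec$n_px[k], spec$n_px[-k])),
          order(c(k, seq_len(nd)[-k])))
  })
  d_wound <- sqrt(Reduce(`+`, sq))
  wound_mask <- d_wound < wound_radius_um

  dep_arr <- array(depletion(as.vector(d_wound)), dim = dim(d_wound))
  pre_ideal <- comp$face + comp$edge + comp$punctae +
    spec$background_intensity
  post_ideal <- comp$face + comp$edge * (1 - dep_arr) + comp$punctae +
    spec$background_intensity
  post_ideal[wound_mask] <- 0
  sig_px <- spec$psf_sigma_um / spec$voxel_size_um
  pre_blur <- gaussian_blur_fft(pre_ideal, sig_px)
  post_blur <- gaussian_blur_fft(post_ideal, sig_px)
  pre_noisy <- with_seed(derive_seed(spec$seed, "pre"),
                         apply_noise(pre_blur, spec))
  post_noisy <- with_seed(derive_seed(spec$seed, "post"),
                          apply_noise(post_blur, spec))
  list(pre = image_stack(list(signal = pre_noisy), spec$voxel_size_um),
       post = image_stack(list(signal = post_noisy), spec$voxel_size_um),
       pre_noiseless = pre_blur, post_noiseless = post_blur,
       wound_mask = wound_mask, wound_center_um = wound_center_um,
       spec = spec)
}
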