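WALL_CLASSES <- c("longitudinal-anticlinal", "transverse-anticlinal",
                  "longitudinal-periclinal", "transverse-periclinal")

#' Manually traced cell-wall path anchored at a cell edge
#'
#' An ordered polyline in physical coordinates running along one cell wall,
#' starting at the cell edge (the junction where walls meet). The wall class
#' records the wall's orientation relative to the organ axis and surface,
#' one of the four canonical classes.
#'
#' @param points Two-column numeric matrix (or data.frame) of `(x, y)`
#'   positions in um; the first point is the edge anchor.
#' @param wall_class One of `"longitudinal-anticlinal"`,
#'   `"transverse-anticlinal"`, `"longitudinal-periclinal"`,
#'   `"transverse-periclinal"`.
#' @param id Optional trace identifier (used in error messages and for
#'   matching pre/post ablation traces).
#' @return Object of class `wall_trace`.
#' @export
wall_trace <- function(points, wall_class, id = NULL) {
  points <- as.matrix(points)
  if (ncol(points) != 2L || nrow(points) < 2L || !is.numeric(points) ||
      any(!is.finite(points))) {
    stop("`points` must be a finite n x 2 matrix with n >= 2", call. = FALSE)
  }
  steps <- diff(points)
  if (any(rowSums(steps^2) == 0)) {
    stop("consecutive trace points must be distinct", call. = FALSE)
  }
  wall_class <- match.arg(wall_class, WALL_CLASSES)
  structure(list(points = unname(points), wall_class = wall_class,
                 id = id %||% "trace"),
            class = "wall_trace")
}

# resample a polyline at arc-length positions s (linear interpolation);
# returns positions and unit tangents
resample_polyline <- function(points, s) {
  seg <- diff(points)
  seg_len <- sqrt(rowSums(seg^2))
  cum <- c(0, cumsum(seg_len))
  si <- pmin(pmax(s, 0), cum[length(cum)])
  k <- findInterval(si, cum, rightmost.closed = TRUE)
  k <- pmin(k, nrow(points) - 1L)
  frac <- (si - cum[k]) / seg_len[k]
  pos <- points[k, , drop = FALSE] + seg[k, , drop = FALSE] * frac
  tang <- seg[k, , drop = FALSE] / seg_len[k]
  list(pos = pos, tangent = tang)
}

#' Intensity profile along a wall trace, by distance from the cell edge
#'
#' Samples the channel along the trace at pixel pitch. At each arc-length
#' position the intensity is averaged over `width_px` pixels placed
#' perpendicular to the local trace direction at unit pixel spacing
#' (nearest-pixel lookup, no sub-pixel interpolation), reproducing a
#' fixed-width plot profile. Distances are arc length from the edge anchor,
#' in um, and each sample is assigned to a half-open bin
#' `[k*bin_width, (k+1)*bin_width)`.
#'
#' @param channel 2D intensity matrix indexed `[x, y]` (a mid-plane
#'   section).
#' @param trace A [wall_trace()] in um coordinates.
#' @param voxel_size `(x, y[, z])` voxel size in um.
#' @param bin_width_um Bin width in um (default 0.5).
#' @param width_px Profile width in pixels (default 7).
#' @return Data.frame of class `profile_samples`: `distance_um`,
#'   `intensity`, `bin`; attributes `trace_id`, `wall_class`,
#'   `bin_width_um`.
#' @export
edge_profile <- function(channel, trace, voxel_size, bin_width_um = 0.5,
                         width_px = 7L) {
  stopifnot(inherits(trace, "wall_trace"))
  if (length(dim(channel)) != 2L) {
    stop("`channel` must be a 2D matrix (mid-plane section)", call. = FALSE)
  }
  stopifnot_scalar_num(bin_width_um, "bin_width_um", 0, strict_min = TRUE)
  width_px <- as.integer(width_px)
  if (width_px < 1L) stop("`width_px` must be >= 1", call. = FALSE)
  vx <- voxel_size[1L]
  vy <- voxel_size[2L]
  pitch <- min(vx, vy)
  pts <- trace$points
  total <- sum(sqrt(rowSums(diff(pts)^2)))
  s <- seq(0, total, by = pitch)
  rs <- resample_polyline(pts, s)
  normal <- cbind(-rs$tangent[, 2L], rs$tangent[, 1L])
  offs <- (seq_len(width_px) - (width_px + 1) / 2) * pitch
  d <- dim(channel)
  acc <- numeric(length(s))
  for (o in offs) {
    px <- rs$pos[, 1L] + normal[, 1L] * o
    py <- rs$pos[, 2L] + normal[, 2L] * o
    ix <- round(px / vx) + 1L
    iy <- round(py / vy) + 1L
    if (any(ix < 1L | ix > d[1L] | iy < 1L | iy > d[2L])) {
      stop(sprintf("trace '%s' leaves the image bounds", trace$id),
           call. = FALSE)
    }
    acc <- acc + channel[cbind(ix, iy)]
  }
  out <- data.frame(
    distance_um = s,
    intensity = acc / width_px,
    bin = as.integer(floor(s / bin_width_um + 1e-9))
  )
  attr(out, "trace_id") <- trace$id
  attr(out, "wall_class") <- trace$wall_class
  attr(out, "bin_width_um") <- bin_width_um
  class(out) <- c("profile_samples", "data.frame")
  out
}

# per-trace, per-bin mean intensities; one row per (trace, bin)
trace_bin_means <- function(profiles) {
  do.call(rbind, lapply(seq_along(profiles), function(i) {
    p <- profiles[[i]]
    agg <- stats::aggregate(p$intensity, by = list(bin = p$bin), FUN = mean)
    data.frame(trace = attr(p, "trace_id") %||% paste0("trace", i),
               wall_class = attr(p, "wall_class") %||% NA_character_,
               bin = agg$bin, intensity = agg$x,
               stringsAsFactors = FALSE)
  }))
}

#' Aggregate edge profiles and find the significance distance
#'
#' Pools per-trace profiles of one wall class into per-bin mean and
#' standard deviation, and determines the significance distance: the
#' distance from the cell edge at which the signal first becomes
#' significantly lower than at the edge, assessed by one-way ANOVA across
#' bins (observations are per-trace bin means) followed by a post-hoc Tukey
#' test of every bin against bin 0 at level `alpha`. Reported bins are
#' contiguous from the edge; trailing bins covered by fewer than two traces
#' are dropped.
#'
#' @param profiles List of [edge_profile()] results (same bin width). When
#'   several wall classes are present, each is aggregated separately.
#' @param alpha Significance level for the Tukey comparison (default 0.05).
#' @return An object of class `edge_profile_summary` (one wall class) or a
#'   named list of them: `bins` data.frame (`bin`, `distance_um` = left
#'   edge, `mean`, `sd`, `n`), `significance_distance_um` (numeric, `NA` if
#'   no bin is significantly below the edge), `anova` (F and p across
#'   bins), `wall_class`.
#' @export
aggregate_profiles <- function(profiles, alpha = 0.05) {
  stopifnot(is.list(profiles), length(profiles) >= 1L)
  tb <- trace_bin_means(profiles)
  bw <- attr(profiles[[1L]], "bin_width_um") %||% 0.5
  classes <- unique(tb$wall_class)
  res <- lapply(classes, function(cl) {
    aggregate_one_class(tb[tb$wall_class %in% cl, ], alpha, cl, bw)
  })
  names(res) <- classes
  if (length(res) == 1L) res[[1L]] else res
}

aggregate_one_class <- function(tb, alpha, wall_class, bw = 0.5) {
  if (length(unique(tb$trace)) < 2L) {
    stop("need at least 2 traces per wall class", call. = FALSE)
  }
  counts <- table(tb$bin)
  bins_ok <- sort(as.integer(names(counts))[counts >= 2L])
  run <- -1L
  while ((run + 1L) %in% bins_ok) run <- run + 1L
  if (run < 0L) {
    stop("the edge bin is not covered by at least 2 traces", call. = FALSE)
  }
  tb <- tb[tb$bin %in% 0L:run, ]
  agg_mean <- tapply(tb$intensity, tb$bin, mean)
  agg_sd <- tapply(tb$intensity, tb$bin, stats::sd)
  agg_n <- tapply(tb$intensity, tb$bin, length)
  bins <- data.frame(bin = as.integer(names(agg_mean)),
                     distance_um = as.integer(names(agg_mean)) * bw,
                     mean = as.numeric(agg_mean), sd = as.numeric(agg_sd),
                     n = as.integer(agg_n))
  bins <- bins[order(bins$bin), ]
  rownames(bins) <- NULL

  sig_dist <- NA_real_
  an <- list(f = NA_real_, p_value = NA_real_)
  if (nrow(bins) >= 2L) {
    fac <- factor(tb$bin, levels = sort(unique(tb$bin)))
    a <- anova_oneway(tb$intensity, fac)
    an <- list(f = a$f, p_value = a$p_value)
    tk <- stats::TukeyHSD(a$fit)$group
    pairs <- rownames(tk)
    vs0 <- grepl("-0$", pairs)
    if (any(vs0)) {
      cand_bins <- as.integer(sub("-0$", "", pairs[vs0]))
      ok <- tk[vs0, "p adj"] < alpha & tk[vs0, "diff"] < 0
      if (any(ok)) sig_dist <- min(cand_bins[ok]) * bw
    }
  }
  structure(list(bins = bins, significance_distance_um = sig_dist,
                 anova = an, wall_class = wall_class,
                 bin_width_um = bw),
            class = "edge_profile_summary")
}

#' @export
print.edge_profile_summary <- function(x, ...) {
  cat(sprintf("edge profile (%s): %d bins, n = %d traces\n",
              x$wall_class %||% "unclassified", nrow(x$bins),
              max(x$bins$n)))
  cat(sprintf("significance distance: %s\n",
              if (is.na(x$significance_distance_um)) "none"
              else sprintf("%.1f um", x$significance_distance_um)))
  invisible(x)
}

#' @export
plot.edge_profile_summary <- function(x, ...) {
  b <- x$bins
  ylim <- range(b$mean - b$sd, b$mean + b$sd, na.rm = TRUE)
  plot(b$distance_um, b$mean, type = "l", ylim = ylim,
       xlab = "distance from edge (um)", ylab = "mean intensity", ...)
  graphics::polygon(c(b$distance_um, rev(b$distance_um)),
                    c(b$mean - b$sd, rev(b$mean + b$sd)),
                    border = NA, col = grDevices::adjustcolor("grey", 0.5))
  graphics::lines(b$distance_um, b$mean)
  if (!is.na(x$significance_distance_um)) {
    graphics::abline(v = x$significance_distance_um, lty = 2)
  }
  invisible(x)
}

#' Post/pre ablation intensity ratios per wall and distance bin
#'
#' For each wall (matched by trace id between the pre- and post-ablation
#' profile lists) the per-bin mean intensities are computed and the ratio
#' post/pre is formed per bin; bins whose pre-ablation mean is zero are
#' excluded with a warning. Ratios are then aggregated across walls.
#'
#' @param pre_profiles,post_profiles Lists of [edge_profile()] results with
#'   matching trace ids.
#' @return List of class `ablation_ratios`: `per_wall` data.frame (`trace`,
#'   `bin`, `distance_um`, `ratio`) and `summary` data.frame (`bin`,
#'   `distance_um`, `mean_ratio`, `sd_ratio`, `n`).
#' @export
ablation_ratio <- function(pre_profiles, post_profiles) {
  pre <- trace_bin_means(pre_profiles)
  post <- trace_bin_means(post_profiles)
  if (!setequal(unique(pre$trace), unique(post$trace))) {
    stop("pre and post profiles must cover the same walls", call. = FALSE)
  }
  m <- merge(pre, post, by = c("trace", "bin"),
             suffixes = c("_pre", "_post"))
  zero <- m$intensity_pre == 0
  if (any(zero)) {
    warning(sum(zero), " bin(s) with zero pre-ablation intensity excluded",
            call. = FALSE)
    m <- m[!zero, ]
  }
  bw <- attr(pre_profiles[[1L]], "bin_width_um") %||% 0.5
  per_wall <- data.frame(trace = m$trace, bin = m$bin,
                         distance_um = m$bin * bw,
                         ratio = m$intensity_post / m$intensity_pre,
                         stringsAsFactors = FALSE)
  per_wall <- per_wall[order(per_wall$trace, per_wall$bin), ]
  mean_r <- tapply(per_wall$ratio, per_wall$bin, mean)
  sd_r <- tapply(per_wall$ratio, per_wall$bin, stats::sd)
  n_r <- tapply(per_wall$ratio, per_wall$bin, length)
  summary <- data.frame(bin = as.integer(names(mean_r)),
                        distance_um = as.integer(names(mean_r)) * bw,
                        mean_ratio = as.numeric(mean_r),
                        sd_ratio = as.numeric(sd_r),
                        n = as.integer(n_r))
  summary <- summary[order(summary$bin), ]
  rownames(per_wall) <- rownames(summary) <- NULL
  structure(list(per_wall = per_wall, summary = summary),
            class = "ablation_ratios")
}

#' @export
print.ablation_ratios <- function(x, ...) {
  cat(sprintf("ablation ratios: %d walls, %d bins\n",
              length(unique(x$per_wall$trace)), nrow(x$summary)))
  print(utils::head(x$summary, 10))
  invisible(x)
}

#' Compare the ablation response of two channels per distance bin
#'
#' Per bin, a one-way ANOVA (with post-hoc Tukey test, which for two groups
#' coincides with the ANOVA F-test) compares the per-wall ratios of the two
#' channels.
#'
#' @param ratios_a,ratios_b [ablation_ratio()] results for the two channels.
#' @param alpha Significance level (default 0.05).
#' @return Data.frame: `bin`, `distance_um`, `diff` (mean A - mean B),
#'   `p_adj`, `significant`.
#' @export
compare_ablation_channels <- function(ratios_a, ratios_b, alpha = 0.05) {
  stopifnot(inherits(ratios_a, "ablation_ratios"),
            inherits(ratios_b, "ablation_ratios"))
  bins <- intersect(ratios_a$summary$bin, ratios_b$summary$bin)
  nz <- ratios_a$summary$bin > 0L
  bw <- if (any(nz)) {
    ratios_a$summary$distance_um[nz][1L] / ratios_a$summary$bin[nz][1L]
  } else 0.5
  out <- lapply(bins, function(b) {
    ra <- ratios_a$per_wall$ratio[ratios_a$per_wall$bin == b]
    rb <- ratios_b$per_wall$ratio[ratios_b$per_wall$bin == b]
    if (length(ra) < 2L || length(rb) < 2L) return(NULL)
    tk <- tukey_oneway(c(ra, rb),
                       rep(c("A", "B"), c(length(ra), length(rb))))
    data.frame(bin = b, distance_um = b * bw,
               diff = mean(ra) - mean(rb), p_adj = tk$p_adj[1L],
               significant = tk$p_adj[1L] < alpha)
  })
  do.call(rbind, out[!vapply(out, is.null, TRUE)])
}
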