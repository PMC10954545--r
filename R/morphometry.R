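#' Two-sided root outline
#'
#' The two manually traced sides of a lateral root, ordered along the
#' longitudinal axis, plus the tip position, all in um.
#'
#' @param side1,side2 Two-column numeric matrices (or data.frames) of
#'   `(x, y)` points, each with at least 2 rows.
#' @param tip `(x, y)` of the root tip.
#' @return Object of class `root_outline`.
#' @export
root_outline <- function(side1, side2, tip) {
  side1 <- as.matrix(side1); side2 <- as.matrix(side2)
  tip <- as.numeric(tip)
  if (ncol(side1) != 2L || ncol(side2) != 2L ||
      nrow(side1) < 2L || nrow(side2) < 2L) {
    stop("each side needs >= 2 (x, y) points", call. = FALSE)
  }
  if (length(tip) != 2L || any(!is.finite(c(side1, side2, tip)))) {
    stop("coordinates must be finite; `tip` is one (x, y) point",
         call. = FALSE)
  }
  structure(list(side1 = unname(side1), side2 = unname(side2), tip = tip),
            class = "root_outline")
}

# minimum distance from each row of a to any row of b (vectorized all-pairs)
nn_distances <- function(a, b) {
  d2 <- outer(rowSums(a^2), rowSums(b^2), `+`) - 2 * tcrossprod(a, b)
  sqrt(pmax(apply(d2, 1L, min), 0))
}

#' Maximum root diameter from nearest-neighbour outline distances
#'
#' For every point on side 1 the Euclidean distance to its nearest
#' neighbour on side 2 is computed. Points within `tip_exclude_um` of the
#' tip — measured as arc length along side 1 from the point closest to the
#' tip landmark — are excluded so the tapering tip does not dilute the
#' measurement, and the maximum diameter is the mean of the `top_k` largest
#' retained distances (all of them, with a warning, if fewer remain).
#'
#' @param outline A [root_outline()].
#' @param tip_exclude_um Tip exclusion zone in um (default 100).
#' @param top_k Number of largest distances averaged (default 10).
#' @param symmetric Also measure side2 -> side1 and pool the distances
#'   (default `FALSE`, the one-directional convention).
#' @return List of class `diameter_result`: `distances` (retained
#'   nearest-neighbour distances, um), `max_diameter` (um),
#'   `n_excluded_tip`.
#' @export
max_diameter <- function(outline, tip_exclude_um = 100, top_k = 10L,
                         symmetric = FALSE) {
  stopifnot(inherits(outline, "root_outline"))
  stopifnot_scalar_num(tip_exclude_um, "tip_exclude_um", min = 0)
  top_k <- as.integer(top_k)
  if (top_k < 1L) stop("`top_k` must be >= 1", call. = FALSE)

  measure_side <- function(from, to) {
    d <- nn_distances(from, to)
    seg <- sqrt(rowSums(diff(from)^2))
    arc <- c(0, cumsum(seg))
    tip_idx <- which.min(colSums((t(from) - outline$tip)^2))
    arc_from_tip <- abs(arc - arc[tip_idx])
    keep <- arc_from_tip >= tip_exclude_um
    list(d = d[keep], n_excl = sum(!keep))
  }
  m1 <- measure_side(outline$side1, outline$side2)
  dists <- m1$d
  n_excl <- m1$n_excl
  if (symmetric) {
    m2 <- measure_side(outline$side2, outline$side1)
    dists <- c(dists, m2$d)
    n_excl <- n_excl + m2$n_excl
  }
  if (length(dists) == 0L) {
    stop("root shorter than exclusion zone", call. = FALSE)
  }
  if (length(dists) < top_k) {
    warning("fewer than `top_k` retained distances; using all ",
            length(dists), call. = FALSE)
  }
  top <- sort(dists, decreasing = TRUE)[seq_len(min(top_k, length(dists)))]
  structure(list(distances = dists, max_diameter = mean(top),
                 n_excluded_tip = n_excl),
            class = "diameter_result")
}

#' @export
print.diameter_result <- function(x, ...) {
  cat(sprintf("max diameter: %.2f um (%d distances, %d tip points excluded)\n",
              x$max_diameter, length(x$distances), x$n_excluded_tip))
  invisible(x)
}

#' Relative diameter increase between treatments
#'
#' Percent change of the mean maximum diameter of a treated group relative
#' to its control, `100 * (mean(treated) - mean(control)) / mean(control)`.
#'
#' @param control,treated Numeric vectors of per-root maximum diameters.
#' @return Percent increase (a single number; negative for shrinkage).
#' @export
relative_increase <- function(control, treated) {
  if (length(control) == 0L || length(treated) == 0L) {
    stop("both groups must be non-empty", call. = FALSE)
  }
  mc <- mean(control)
  if (mc == 0) stop("control mean is zero", call. = FALSE)
  100 * (mean(treated) - mc) / mc
}

#' Compare diameter response across genotypes and treatments
#'
#' Two-way ANOVA (genotype x treatment, Type II sums of squares) with
#' post-hoc Tukey test on the cell means, plus the percent diameter
#' increase per genotype. An optional pre-flight check warns when the root
#' lengths of compared groups differ significantly (Welch two-sample test),
#' since diameter comparisons presume length-matched samples.
#'
#' @param diameter Numeric vector of per-root maximum diameters.
#' @param genotype,treatment Factors (or coercible), one label per root;
#'   `treatment` must have a control level first (by factor order) for the
#'   percent increase.
#' @param length_um Optional per-root lengths for the pre-flight
#'   length-matching check.
#' @return List of class `growth_comparison`: `increase_pct` (named by
#'   genotype), `anova` (two-way table), `tukey` (interaction-cell
#'   contrasts), `length_check_p` (or `NA`).
#' @export
growth_compare <- function(diameter, genotype, treatment, length_um = NULL) {
  genotype <- factor(genotype); treatment <- factor(treatment)
  res <- anova_twoway_tukey(diameter, genotype, treatment)
  ctrl <- levels(treatment)[1L]
  inc <- vapply(levels(genotype), function(g) {
    relative_increase(diameter[genotype == g & treatment == ctrl],
                      diameter[genotype == g & treatment != ctrl])
  }, 0)
  len_p <- NA_real_
  if (!is.null(length_um)) {
    len_p <- stats::t.test(length_um ~ genotype == levels(genotype)[1L]
                           )$p.value
    if (len_p < 0.05) {
      warning("mean root length differs between genotypes (p = ",
              signif(len_p, 3), "); diameter comparison may be confounded",
              call. = FALSE)
    }
  }
  structure(list(increase_pct = inc, anova = res$table, tukey = res$tukey,
                 length_check_p = len_p),
            class = "growth_comparison")
}

#' @export
print.growth_comparison <- function(x, ...) {
  cat("relative diameter increase (%):\n")
  print(round(x$increase_pct, 1))
  cat("\ntwo-way ANOVA (Type II):\n")
  print(x$anova, row.names = FALSE)
  invisible(x)
}

#' Read root outlines and tip positions from CSV
#'
#' Outline CSV columns: `root_id`, `side` (1 or 2), `point_index`, `x_um`,
#' `y_um`; tips CSV columns: `root_id`, `x_um`, `y_um`.
#'
#' @param outlines_path,tips_path CSV paths.
#' @return Named list of [root_outline()] objects, one per root id.
#' @export
read_root_outlines <- function(outlines_path, tips_path) {
  ol <- utils::read.csv(outlines_path, stringsAsFactors = FALSE)
  tp <- utils::read.csv(tips_path, stringsAsFactors = FALSE)
  need <- c("root_id", "side", "point_index", "x_um", "y_um")
  if (!all(need %in% names(ol))) {
    stop("outline CSV needs columns: ", paste(need, collapse = ", "),
         call. = FALSE)
  }
  ids <- unique(ol$root_id)
  out <- lapply(ids, function(id) {
    sub <- ol[ol$root_id == id, ]
    s1 <- sub[sub$side == 1, ]; s1 <- s1[order(s1$point_index), ]
    s2 <- sub[sub$side == 2, ]; s2 <- s2[order(s2$point_index), ]
    tip <- tp[tp$root_id == id, c("x_um", "y_um")]
    if (nrow(tip) != 1L) {
      stop("tips CSV must have exactly one row for root ", id, call. = FALSE)
    }
    root_outline(as.matrix(s1[, c("x_um", "y_um")]),
                 as.matrix(s2[, c("x_um", "y_um")]),
                 as.numeric(tip))
  })
  names(out) <- ids
  out
}

#' Read wall traces from CSV
#'
#' Columns: `trace_id`, `wall_class`, `point_index`, `x_um`, `y_um`.
#'
#' @param path CSV path.
#' @return Named list of [wall_trace()] objects.
#' @export
read_wall_traces <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("trace_id", "wall_class", "point_index", "x_um", "y_um")
  if (!all(need %in% names(df))) {
    stop("trace CSV needs columns: ", paste(need, collapse = ", "),
         call. = FALSE)
  }
  ids <- unique(df$trace_id)
  out <- lapply(ids, function(id) {
    sub <- df[df$trace_id == id, ]
    sub <- sub[order(sub$point_index), ]
    wall_trace(as.matrix(sub[, c("x_um", "y_um")]),
               wall_class = sub$wall_class[1L], id = as.character(id))
  })
  names(out) <- ids
  out
}
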