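# Independent oracles used across the suite. These deliberately use naive
# loop-based algorithms so they share no code path with the package.

# flood fill from every pixel >= high through pixels >= low, full
# connectivity, explicit stack
flood_fill_oracle <- function(img, low, high) {
  d <- dim(img)
  nd <- length(d)
  offs <- as.matrix(do.call(expand.grid, rep(list(-1:1), nd)))
  offs <- offs[rowSums(abs(offs)) > 0, , drop = FALSE]
  grow <- img >= low
  visited <- array(FALSE, d)
  seeds <- which(img >= high)
  stack <- lapply(seeds, function(i) arrayInd(i, d)[1, ])
  visited[seeds] <- TRUE
  while (length(stack)) {
    cur <- stack[[length(stack)]]
    stack[[length(stack)]] <- NULL
    for (r in seq_len(nrow(offs))) {
      nb <- cur + offs[r, ]
      if (any(nb < 1L) || any(nb > d)) next
      nbm <- matrix(nb, 1L)
      if (!visited[nbm] && grow[nbm]) {
        visited[nbm] <- TRUE
        stack[[length(stack) + 1L]] <- nb
      }
    }
  }
  visited
}

# naive double-loop nearest-neighbour diameter measurement
max_diameter_oracle <- function(outline, tip_exclude_um = 100, top_k = 10L) {
  s1 <- outline$side1
  s2 <- outline$side2
  n <- nrow(s1)
  dmin <- numeric(n)
  for (i in seq_len(n)) {
    dmin[i] <- min(sqrt((s2[, 1] - s1[i, 1])^2 + (s2[, 2] - s1[i, 2])^2))
  }
  arc <- c(0, cumsum(sqrt(rowSums(diff(s1)^2))))
  tip_idx <- which.min((s1[, 1] - outline$tip[1])^2 +
                         (s1[, 2] - outline$tip[2])^2)
  keep <- abs(arc - arc[tip_idx]) >= tip_exclude_um
  retained <- sort(dmin[keep], decreasing = TRUE)
  mean(retained[seq_len(min(top_k, length(retained)))])
}

# independent super-rank ordering: recompute criteria from raw group means
# and sort a data.frame by rank sum with the documented tie-breaks
super_rank_oracle <- function(qm, candidates) {
  v <- qm$values[match(candidates, qm$protein_ids), , drop = FALSE]
  gm <- function(g) rowMeans(v[, qm$groups == g, drop = FALSE])
  bait <- gm("bait"); neg <- gm("negative")
  ea <- bait / gm("comparatorA"); eb <- bait / gm("comparatorB")
  r1 <- rank(-bait); r2 <- rank(-ea); r3 <- rank(-eb); r4 <- rank(neg)
  rs <- r1 + r2 + r3 + r4
  candidates[order(rs, r1, candidates)]
}

# random blob image: sum of Gaussian bumps on a noisy background
random_blob_image <- function(n = 16L, n_blobs = 3L, amp = 100) {
  img <- matrix(stats::runif(n * n, 0, 5), n, n)
  for (b in seq_len(n_blobs)) {
    cx <- stats::runif(1, 2, n - 1)
    cy <- stats::runif(1, 2, n - 1)
    a <- amp * stats::runif(1, 0.2, 1)
    s <- stats::runif(1, 0.8, 2.5)
    g <- outer(seq_len(n), seq_len(n), function(i, j) {
      a * exp(-((i - cx)^2 + (j - cy)^2) / (2 * s^2))
    })
    img <- img + g
  }
  img
}

# jagged random two-sided outline for oracle comparisons
random_outline <- function(n_points = 200L, length_um = 400) {
  x <- seq(0, length_um, length.out = n_points)
  w <- 40 + 20 * sin(x / stats::runif(1, 30, 90)) +
    stats::rnorm(n_points, 0, 3)
  w <- pmax(w, 5)
  mid <- stats::rnorm(1, 0, 5) + cumsum(stats::rnorm(n_points, 0, 0.5))
  root_outline(cbind(x, mid + w / 2), cbind(x, mid - w / 2),
               tip = c(0, mid[1]))
}

# synthetic per-trace profile samples (bypasses images) for aggregation
# tests: intensity_fun maps distance (um) to mean intensity
synthetic_profile <- function(intensity_fun, trace_id, noise_sd = 1,
                              max_um = 5, pitch = 0.1,
                              wall_class = "longitudinal-anticlinal") {
  s <- seq(0, max_um, by = pitch)
  out <- data.frame(
    distance_um = s,
    intensity = intensity_fun(s) + stats::rnorm(length(s), 0, noise_sd),
    bin = as.integer(floor(s / 0.5 + 1e-9))
  )
  attr(out, "trace_id") <- trace_id
  attr(out, "wall_class") <- wall_class
  attr(out, "bin_width_um") <- 0.5
  class(out) <- c("profile_samples", "data.frame")
  out
}

# small labelled quantification matrix built from explicit per-group rows
toy_matrix <- function(bait, compA, compB, neg, ids = NULL) {
  vals <- cbind(bait, compA, compB, neg)
  groups <- rep(c("bait", "comparatorA", "comparatorB", "negative"),
                times = c(ncol(bait), ncol(compA), ncol(compB), ncol(neg)))
  quant_matrix(vals, groups = groups,
               protein_ids = ids %||% paste0("P", seq_len(nrow(vals))))
}

`%||%` <- function(a, b) if (is.null(a)) b else a
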