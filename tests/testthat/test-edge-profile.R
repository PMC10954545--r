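vz <- c(0.1, 0.1, 1)

test_that("edge profile is flat on a uniform image and exact at width 1", {
  img <- matrix(42, 80, 80)
  tr <- wall_trace(rbind(c(2, 4), c(6, 4)), "transverse-anticlinal")
  pr <- edge_profile(img, tr, vz)
  expect_true(all(pr$intensity == 42))
  expect_equal(pr$distance_um, seq(0, 4, by = 0.1))
  expect_equal(pr$bin, as.integer(floor(pr$distance_um / 0.5 + 1e-9)))

  # width 1 on a single-pixel line recovers the raw pixel values
  img2 <- matrix(0, 80, 80)
  line_vals <- seq(10, 100, length.out = 41)
  img2[21:61, 41] <- line_vals            # x from 2.0 to 6.0 um at y = 4.0
  tr2 <- wall_trace(rbind(c(2, 4), c(6, 4)), "transverse-anticlinal")
  pr2 <- edge_profile(img2, tr2, vz, width_px = 1)
  expect_equal(pr2$intensity, line_vals)
})

test_that("binned means of an exponential decay match the analytic average", {
  # paint intensity by distance from the anchor along x
  n <- 120
  img <- matrix(0, n, n)
  anchor_px <- 21
  for (i in seq_len(n)) {
    d <- max(0, (i - anchor_px)) * 0.1
    img[i, ] <- 100 * exp(-d / 2)
  }
  tr <- wall_trace(rbind(c(2, 5), c(9.5, 5)), "longitudinal-anticlinal")
  pr <- edge_profile(img, tr, vz)
  got <- tapply(pr$intensity, pr$bin, mean)
  for (b in 0:14) {
    a <- b * 0.5; bb <- a + 0.5
    analytic <- 100 * 2 * (exp(-a / 2) - exp(-bb / 2)) / 0.5
    expect_equal(unname(got[as.character(b)]), analytic,
                 tolerance = 0.03)
  }
})

test_that("edge profile is equivariant under translation and 90-degree rotation", {
  set.seed(24)
  img <- matrix(runif(100 * 100, 0, 50), 100, 100)
  tr <- wall_trace(rbind(c(2.03, 3.11), c(5.47, 6.81), c(7.13, 6.2)),
                   "longitudinal-periclinal")
  pr <- edge_profile(img, tr, vz)

  # translate by a whole number of pixels
  shift_px <- c(7, 11)
  img_t <- matrix(0, 100, 100)
  img_t[(1 + shift_px[1]):100, (1 + shift_px[2]):100] <-
    img[1:(100 - shift_px[1]), 1:(100 - shift_px[2])]
  tr_t <- wall_trace(tr$points + rep(shift_px * 0.1, each = 3),
                     tr$wall_class)
  pr_t <- edge_profile(img_t, tr_t, vz)
  expect_equal(pr_t$intensity, pr$intensity)

  # rotate image and trace by 90 degrees: (x, y) -> (y, X - x)
  nx <- nrow(img)
  X <- (nx - 1) * 0.1
  img_r <- t(img)[, rev(seq_len(nx))]
  tr_r <- wall_trace(cbind(tr$points[, 2], X - tr$points[, 1]),
                     tr$wall_class)
  pr_r <- edge_profile(img_r, tr_r, vz)
  expect_equal(pr_r$intensity, pr$intensity)

  # a trace leaving the image is an error naming the trace
  tr_out <- wall_trace(rbind(c(9, 9), c(12, 9)), "transverse-anticlinal",
                       id = "runaway")
  expect_error(edge_profile(img, tr_out, vz), "runaway")
})

test_that("profiles along symmetric trajectories of a symmetric phantom agree", {
  sp <- phantom_spec(n_cells = c(2, 2), edge_sdlog = 0, punctae_density = 0,
                     gain = 0, read_noise_sd = 0, seed = 1)
  ph <- make_phantom(sp)
  img <- drop(ph$stack$channels$signal)
  ctr <- sp$margin_um + sp$cell_size_um[1]   # the single interior corner
  dirs <- list(c(0, 1), c(0, -1), c(1, 0), c(-1, 0))
  profs <- lapply(dirs, function(d) {
    tr <- wall_trace(rbind(c(ctr, ctr), c(ctr, ctr) + 3 * d),
                     "longitudinal-anticlinal")
    edge_profile(img, tr, sp$voxel_size_um)$intensity
  })
  for (k in 2:4) {
    expect_equal(profs[[k]], profs[[1]], tolerance = 1e-6)
  }
})

test_that("significance distance finds a planted step and ignores flat noise", {
  set.seed(25)
  step_profiles <- lapply(1:50, function(i) {
    synthetic_profile(function(d) ifelse(d < 2, 100, 50), paste0("t", i),
                      noise_sd = 5)
  })
  agg <- aggregate_profiles(step_profiles)
  expect_s3_class(agg, "edge_profile_summary")
  expect_equal(agg$significance_distance_um, 2.0)
  expect_equal(agg$bins$distance_um, seq(0, 5, by = 0.5))
  expect_true(all(agg$bins$n == 50))

  # flat traces with i.i.d. noise: no significance in >= 95% of runs
  set.seed(26)
  hits <- replicate(40, {
    profs <- lapply(1:8, function(i) {
      synthetic_profile(function(d) rep(80, length(d)), paste0("t", i),
                        noise_sd = 8)
    })
    !is.na(aggregate_profiles(profs)$significance_distance_um)
  })
  expect_lte(mean(hits), 0.05 + 2 * sqrt(0.05 * 0.95 / 40))

  # a single trace is not enough
  expect_error(aggregate_profiles(step_profiles[1]), "at least 2 traces")

  # single bin: nothing to compare
  set.seed(27)
  short <- lapply(1:3, function(i) {
    synthetic_profile(function(d) rep(10, length(d)), paste0("s", i),
                      max_um = 0.4)
  })
  agg1 <- aggregate_profiles(short)
  expect_true(is.na(agg1$significance_distance_um))
})

test_that("wall classes are aggregated separately", {
  set.seed(28)
  profs <- c(
    lapply(1:3, function(i) synthetic_profile(function(d) 100 - 10 * d,
                                              paste0("a", i))),
    lapply(1:3, function(i) synthetic_profile(function(d) rep(50, length(d)),
                                              paste0("p", i),
                                              wall_class =
                                                "transverse-periclinal")))
  agg <- aggregate_profiles(profs)
  expect_named(agg, c("longitudinal-anticlinal", "transverse-periclinal"))
  expect_equal(nrow(agg[[1]]$bins), nrow(agg[[2]]$bins))
})

test_that("ablation ratios recover identity, scaling and planted depletion", {
  set.seed(29)
  mk <- function(fun, ids) {
    lapply(ids, function(i) synthetic_profile(fun, i, noise_sd = 0))
  }
  pre <- mk(function(d) 100 * exp(-d / 2) + 20, c("w1", "w2", "w3"))
  expect_equal(ablation_ratio(pre, pre)$summary$mean_ratio,
               rep(1, 11))
  post <- lapply(pre, function(p) { p$intensity <- p$intensity / 2; p })
  expect_equal(ablation_ratio(pre, post)$summary$mean_ratio,
               rep(0.5, 11))

  # zero pre-ablation bins are excluded with a warning
  pre0 <- mk(function(d) ifelse(d < 1, 0, 50), c("w1", "w2"))
  post0 <- mk(function(d) rep(25, length(d)), c("w1", "w2"))
  expect_warning(r0 <- ablation_ratio(pre0, post0), "zero pre-ablation")
  expect_false(any(r0$summary$bin %in% 0:1))

  # mismatched wall sets are an error
  expect_error(ablation_ratio(pre, post[1:2]), "same walls")
})

test_that("generative ablation recovery: edge depletion appears in the ratio", {
  sp <- phantom_spec(n_cells = c(3, 3), face_intensity = 0,
                     punctae_density = 0, background_intensity = 0,
                     edge_decay_um = 2, seed = 55)
  dep <- function(d) 0.4 * (d < 6)
  ctr <- sp$margin_um + 1.5 * sp$cell_size_um[1]
  pair <- make_ablation_pair(sp, dep, wound_center_um = c(ctr, ctr),
                             wound_radius_um = 1)
  # keep the traces that lie entirely inside the depleted zone
  trs <- Filter(function(tr) {
    all(sqrt(rowSums(sweep(tr$points, 2, c(ctr, ctr))^2)) < 6)
  }, phantom_wall_traces(sp, length_um = 3))
  expect_gte(length(trs), 2)
  prof <- function(st) lapply(trs, function(tr) {
    edge_profile(drop(st$channels$signal), tr, sp$voxel_size_um)
  })
  rr <- ablation_ratio(prof(pair$pre), prof(pair$post))
  expect_true(all(abs(rr$summary$mean_ratio - 0.6) < 0.1))
})

test_that("channel comparison flags a differential ablation response", {
  set.seed(30)
  mk <- function(level, ids, sd = 0.05) {
    lapply(ids, function(i) synthetic_profile(function(d) rep(100, length(d)),
                                              i))
  }
  ratio_from <- function(post_scale, ids) {
    pre <- lapply(ids, function(i)
      synthetic_profile(function(d) rep(100, length(d)), i, noise_sd = 2))
    post <- lapply(seq_along(ids), function(k) {
      p <- pre[[k]]
      p$intensity <- p$intensity * post_scale +
        rnorm(nrow(p), 0, 2)
      p
    })
    ablation_ratio(pre, post)
  }
  ra <- ratio_from(0.5, paste0("a", 1:6))
  rb <- ratio_from(1.0, paste0("b", 1:6))
  cmp <- compare_ablation_channels(ra, rb)
  expect_true(all(cmp$significant))
  expect_true(all(cmp$diff < 0))
})
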