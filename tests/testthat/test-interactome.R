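test_that("bait-completeness filter keeps exactly the fully detected proteins", {
  qm <- toy_matrix(bait = rbind(c(10, 0, 12), c(10, 11, 12)),
                   compA = rbind(c(0, 0), c(0, 0)),
                   compB = rbind(c(0, 0), c(0, 0)),
                   neg = rbind(c(0, 0), c(0, 0)))
  out <- filter_complete_in_bait(qm)
  expect_identical(out$protein_ids, "P2")

  # brute-force row scan on a random matrix with planted missingness
  set.seed(41)
  vals <- matrix(rlnorm(200 * 12, 10, 1), 200, 12)
  vals[runif(length(vals)) < 0.3] <- 0
  qm <- quant_matrix(vals, groups = rep(c("bait", "comparatorA",
                                          "comparatorB", "negative"),
                                        each = 3))
  out <- filter_complete_in_bait(qm)
  expected <- qm$protein_ids[apply(vals[, 1:3] > 0, 1, all)]
  expect_identical(out$protein_ids, expected)

  # idempotent, subset of input rows
  expect_identical(filter_complete_in_bait(out)$protein_ids,
                   out$protein_ids)
  expect_true(all(out$protein_ids %in% qm$protein_ids))

  qm_nobait <- quant_matrix(vals, groups = rep("comparatorA", 12))
  expect_error(filter_complete_in_bait(qm_nobait), "no samples")
})

test_that("half-minimum imputation replaces zeros with half the global nonzero minimum", {
  qm <- toy_matrix(bait = rbind(c(10, 4, 12), c(9, 11, 12)),
                   compA = rbind(c(0, 8), c(6, 0)),
                   compB = rbind(c(7, 7), c(7, 7)),
                   neg = rbind(c(0, 0), c(5, 5)))
  out <- impute_half_minimum(qm)
  expect_equal(min(out$values), 2)           # min nonzero is 4
  expect_equal(out$values[qm$values > 0], qm$values[qm$values > 0])
  expect_true(all(out$values > 0))

  # identity on a zero-free matrix; idempotent in general
  expect_equal(impute_half_minimum(out)$values, out$values)

  # random matrix: output minimum is half the input nonzero minimum
  set.seed(7)
  vals <- matrix(rlnorm(50 * 12, 3, 1), 50, 12)
  vals[runif(length(vals)) < 0.2] <- 0
  qm <- quant_matrix(vals, groups = rep(c("bait", "comparatorA",
                                          "comparatorB", "negative"),
                                        each = 3))
  out <- impute_half_minimum(qm)
  expect_equal(min(out$values), min(vals[vals > 0]) / 2)
  # nonzero multiset preserved
  expect_equal(sort(out$values[vals > 0]), sort(vals[vals > 0]))

  allzero <- quant_matrix(matrix(0, 2, 4), groups = rep(c("bait", "negative"),
                                                        each = 2))
  expect_error(impute_half_minimum(allzero), "no detected values")
})

test_that("volcano statistic matches its closed form and is antisymmetric", {
  # zero pooled SE: d = (8 - 2) / (0 + 2) = 3 on the raw scale
  qm <- toy_matrix(bait = rbind(c(8, 8, 8)), compA = rbind(c(2, 2, 2)),
                   compB = rbind(c(1, 1, 1)), neg = rbind(c(1, 1, 1)))
  rec <- volcano_enrich(qm, "comparatorA", log2_transform = FALSE)
  expect_equal(rec$d_stat, 3)
  expect_true(rec$significant)

  # identical groups: all d = 0, nothing significant
  set.seed(5)
  x <- matrix(rlnorm(20 * 3, 12, 1), 20, 3)
  qm0 <- toy_matrix(bait = x, compA = x, compB = x, neg = x)
  rec0 <- volcano_enrich(qm0, "comparatorA", seed = 2)
  expect_equal(rec0$d_stat, rep(0, 20))
  expect_false(any(rec0$significant))

  # antisymmetry under swapping the two groups
  set.seed(6)
  a <- matrix(rlnorm(30 * 3, 12, 1), 30, 3)
  b <- matrix(rlnorm(30 * 3, 12, 1), 30, 3)
  qm_ab <- toy_matrix(bait = a, compA = b, compB = b, neg = b)
  qm_ba <- toy_matrix(bait = b, compA = a, compB = a, neg = a)
  expect_equal(volcano_enrich(qm_ab, "comparatorA", seed = 1)$d_stat,
               -volcano_enrich(qm_ba, "comparatorA", seed = 1)$d_stat)

  # reproducible under a fixed seed even when relabellings are subsampled
  set.seed(8)
  big <- matrix(rlnorm(40 * 6, 12, 1), 40, 6)
  qm_big <- quant_matrix(cbind(big, big + 1),
                         groups = rep(c("bait", "comparatorA"), each = 6))
  r1 <- volcano_enrich(qm_big, "comparatorA", n_perm = 50, seed = 9)
  r2 <- volcano_enrich(qm_big, "comparatorA", n_perm = 50, seed = 9)
  expect_identical(r1$q_value, r2$q_value)
  expect_false(attr(r1, "params")$exhaustive)

  expect_error(volcano_enrich(qm, "comparatorA", s0 = -1), "s0")
  one_rep <- quant_matrix(matrix(c(1, 2), 1), groups = c("bait",
                                                         "comparatorA"))
  expect_error(volcano_enrich(one_rep, "comparatorA"), "2 replicates")
})

test_that("volcano permutation FDR detects planted enrichment and controls errors", {
  sim <- make_quant_matrix(matrix_spec(n_proteins = 500, n_interactors = 50,
                                       fold = 8, seed = 21))
  qm <- impute_half_minimum(filter_complete_in_bait(sim$matrix))
  rec <- volcano_enrich(qm, "comparatorA", seed = 21)
  called <- rec$protein_id[rec$significant]
  truth <- intersect(sim$interactors, qm$protein_ids)
  power <- mean(truth %in% called)
  fdp <- if (length(called)) mean(!(called %in% sim$interactors)) else 0
  expect_gt(power, 0.5)
  expect_lte(fdp, 0.3)   # fdr = 0.2 plus binomial slack
})

test_that("significant-in-both intersection equals the brute-force AND", {
  rec <- function(ids, sig) {
    data.frame(protein_id = ids, significant = ids %in% sig,
               stringsAsFactors = FALSE)
  }
  ids <- c("p1", "p2", "p3")
  expect_identical(intersect_significant(rec(ids, c("p1", "p2")),
                                         rec(ids, c("p2", "p3"))), "p2")
  expect_identical(intersect_significant(rec(ids, "p1"), rec(ids, "p3")),
                   character(0))
  expect_error(intersect_significant(rec(ids, "p1"),
                                     rec(c("p1", "p2"), "p1")),
               "universes")
  set.seed(3)
  for (i in 1:10) {
    ids <- sprintf("q%03d", 1:50)
    sa <- ids[runif(50) < 0.4]
    sb <- ids[runif(50) < 0.4]
    expect_identical(intersect_significant(rec(ids, sa), rec(ids, sb)),
                     sort(ids[ids %in% sa & ids %in% sb]))
  }
})

test_that("super rank reproduces the hand-worked example and its tie rules", {
  # group means per criterion: bait abundance (100, 50, 200),
  # enrichment A (10, 20, 2), enrichment B (8, 20, 2), negative (0, 0, 5)
  qm <- toy_matrix(bait = cbind(c(100, 50, 200)),
                   compA = cbind(c(10, 2.5, 100)),
                   compB = cbind(c(12.5, 2.5, 100)),
                   neg = cbind(c(0, 0, 5)),
                   ids = c("P1", "P2", "P3"))
  rt <- super_rank(qm, c("P1", "P2", "P3"))
  expect_equal(rt$rank_sum[match(c("P1", "P2", "P3"), rt$protein_id)],
               c(7.5, 6.5, 10))
  expect_equal(rt$super_rank[match(c("P2", "P1", "P3"), rt$protein_id)],
               1:3)

  # full tie: order decided by bait-abundance rank then protein id
  qm_tie <- toy_matrix(bait = cbind(c(5, 5, 5)), compA = cbind(c(1, 1, 1)),
                       compB = cbind(c(1, 1, 1)), neg = cbind(c(2, 2, 2)),
                       ids = c("B", "A", "C"))
  rt_tie <- super_rank(qm_tie, c("B", "A", "C"))
  expect_identical(rt_tie$protein_id, c("A", "B", "C"))

  expect_error(super_rank(qm, character(0)), "empty")
  expect_error(super_rank(qm, "nope"), "not in matrix")
})

test_that("super rank properties: column sums, oracle order, monotone invariance", {
  set.seed(11)
  for (i in 1:5) {
    n <- sample(20:60, 1)
    vals <- matrix(rlnorm(n * 8, 8, 1.5), n, 8)
    qm <- quant_matrix(vals, groups = rep(c("bait", "comparatorA",
                                            "comparatorB", "negative"),
                                          each = 2))
    rt <- super_rank(qm, qm$protein_ids)
    for (col in c("rank_bait_abundance", "rank_enrich_a", "rank_enrich_b",
                  "rank_negative_abundance")) {
      expect_equal(sum(rt[[col]]), n * (n + 1) / 2)
    }
    expect_identical(rt$protein_id, super_rank_oracle(qm, qm$protein_ids))
  }

  # a strictly monotone transform of one criterion's values leaves the
  # ordering unchanged; use a single-replicate negative control so the
  # group mean is transformed directly (criterion 4 only)
  set.seed(12)
  vals <- matrix(rlnorm(30 * 7, 8, 1.5), 30, 7)
  groups <- c(rep(c("bait", "comparatorA", "comparatorB"), each = 2),
              "negative")
  qm1 <- quant_matrix(vals, groups = groups)
  vals2 <- vals
  vals2[, 7] <- log1p(vals2[, 7]) * 3 + 1
  qm2 <- quant_matrix(vals2, groups = groups)
  expect_identical(super_rank(qm1, qm1$protein_ids)$protein_id,
                   super_rank(qm2, qm2$protein_ids)$protein_id)
})

test_that("end-to-end ranking recovers planted interactors", {
  sim <- make_quant_matrix(matrix_spec(seed = 33))
  res <- rank_interactome(sim$matrix, seed = 33)
  top50 <- res$ranking$protein_id[res$ranking$super_rank <= 50]
  expect_gte(mean(sim$interactors %in% top50), 0.9)
  fdp <- mean(!(res$candidates %in% sim$interactors))
  expect_lte(fdp, 0.25)
})
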