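#' Keep proteins detected in every bait replicate
#'
#' Comparative co-immunoprecipitation lists are dominated by proteins seen
#' sporadically; the first filter retains only proteins with a strictly
#' positive intensity in every replicate of the bait pull-down. Detection in
#' the comparator or negative-control samples is not required.
#'
#' @param qm A [quant_matrix()].
#' @param bait Group label of the bait pull-down (default "bait").
#' @return A `quant_matrix` restricted to bait-complete proteins, row order
#'   preserved.
#' @export
filter_complete_in_bait <- function(qm, bait = "bait") {
  stopifnot(inherits(qm, "quant_matrix"))
  cols <- group_columns(qm, bait)
  keep <- rowSums(qm$values[, cols, drop = FALSE] > 0) == length(cols)
  qm[keep]
}

#' Half-minimum imputation of non-detected intensities
#'
#' Replaces every remaining zero by half the smallest nonzero intensity of
#' the whole matrix (a single global value, the conventional "half-minimum"
#' floor for left-censored label-free data). Detected values are untouched.
#'
#' @param qm A [quant_matrix()], typically already bait-filtered.
#' @return A strictly positive `quant_matrix`.
#' @export
impute_half_minimum <- function(qm) {
  stopifnot(inherits(qm, "quant_matrix"))
  v <- qm$values
  nz <- v[v > 0]
  if (length(nz) == 0L) {
    stop("matrix has no detected values; half-minimum undefined",
         call. = FALSE)
  }
  v[v == 0] <- min(nz) / 2
  quant_matrix(v, groups = qm$groups, replicates = qm$replicates,
               protein_ids = qm$protein_ids)
}

# SAM-style moderated statistic per protein: difference of group means over
# (pooled standard error + s0). x, y: matrices proteins x replicates.
sam_d_stat <- function(x, y, s0) {
  n1 <- ncol(x); n2 <- ncol(y)
  m1 <- rowMeans(x); m2 <- rowMeans(y)
  ss <- rowSums((x - m1)^2) + rowSums((y - m2)^2)
  sp2 <- ss / (n1 + n2 - 2)
  se <- sqrt(sp2 * (1 / n1 + 1 / n2))
  (m1 - m2) / (se + s0)
}

all_relabellings <- function(n1, n2) {
  utils::combn(n1 + n2, n1, simplify = FALSE)
}

#' SAM-style volcano enrichment of bait versus one comparator
#'
#' For each protein computes the moderated two-sample statistic
#' d = (mean_bait - mean_comparator) / (pooled SE + s0) on log2 intensities
#' (the scale on which the conventional fudge constant s0 = 2 is meaningful),
#' and a permutation q-value: group labels are permuted (exhaustively when
#' the number of distinct relabellings is at most `n_perm`, otherwise
#' `n_perm` random relabellings under `seed`), the null statistics are pooled
#' across proteins, per-protein permutation p-values are converted to
#' q-values by Benjamini-Hochberg. A protein is called significantly
#' enriched when its q-value is at most `fdr` and its effect is positive
#' (higher in the bait).
#'
#' @param qm Imputed, strictly positive [quant_matrix()].
#' @param comparator Group label to test the bait against.
#' @param bait Bait group label (default "bait").
#' @param s0 Fudge constant added to the denominator (default 2).
#' @param fdr Significance threshold on the q-value (default 0.2).
#' @param n_perm Maximum number of relabellings (default 1000).
#' @param seed Seed for random relabellings; required when the relabelling
#'   space is subsampled, and used in all cases for reproducibility.
#' @param log2_transform Analyse log2(intensity) (default TRUE). Disable
#'   only for data already on a log-like scale.
#' @return A data.frame of class `enrichment_records` with columns
#'   `protein_id`, `effect` (difference of group means on the analysis
#'   scale), `d_stat`, `p_value`, `q_value`, `significant`; attributes
#'   record the parameters.
#' @export
volcano_enrich <- function(qm, comparator, bait = "bait", s0 = 2,
                           fdr = 0.2, n_perm = 1000, seed = 1L,
                           log2_transform = TRUE) {
  stopifnot(inherits(qm, "quant_matrix"))
  stopifnot_scalar_num(s0, "s0", min = 0)
  stopifnot_scalar_num(fdr, "fdr", min = 0, strict_min = TRUE)
  if (fdr >= 1) stop("`fdr` must be in (0, 1)", call. = FALSE)
  ib <- group_columns(qm, bait)
  ic <- group_columns(qm, comparator)
  if (length(ib) < 2L || length(ic) < 2L) {
    stop("both groups need at least 2 replicates", call. = FALSE)
  }
  v <- qm$values
  if (any(v <= 0) && log2_transform) {
    stop("matrix contains non-positive values; impute before enrichment",
         call. = FALSE)
  }
  if (log2_transform) v <- log2(v)
  xb <- v[, ib, drop = FALSE]
  xc <- v[, ic, drop = FALSE]
  d_obs <- sam_d_stat(xb, xc, s0)
  if (s0 == 0 && any(!is.finite(d_obs))) {
    warning("s0 = 0 with zero-variance proteins: infinite statistics for ",
            sum(!is.finite(d_obs)), " protein(s)", call. = FALSE)
  }

  n1 <- length(ib); n2 <- length(ic)
  pool <- cbind(xb, xc)
  n_distinct <- choose(n1 + n2, n1)
  labellings <- if (n_distinct <= n_perm) {
    all_relabellings(n1, n2)
  } else {
    with_seed(seed, replicate(n_perm, sample.int(n1 + n2, n1),
                              simplify = FALSE))
  }
  null_d <- unlist(lapply(labellings, function(idx) {
    sam_d_stat(pool[, idx, drop = FALSE],
               pool[, -idx, drop = FALSE], s0)
  }), use.names = FALSE)

  # pooled-null permutation p-value, then BH across proteins
  null_abs <- sort(abs(null_d))
  n_null <- length(null_abs)
  ge <- n_null - findInterval(abs(d_obs) - 1e-12, null_abs)
  p <- (ge + 1) / (n_null + 1)
  q <- stats::p.adjust(p, method = "BH")
  effect <- rowMeans(xb) - rowMeans(xc)
  out <- data.frame(
    protein_id = qm$protein_ids,
    effect = effect,
    d_stat = d_obs,
    p_value = p,
    q_value = q,
    significant = q <= fdr & effect > 0,
    stringsAsFactors = FALSE
  )
  attr(out, "params") <- list(comparator = comparator, bait = bait, s0 = s0,
                              fdr = fdr, n_perm = length(labellings),
                              exhaustive = n_distinct <= n_perm, seed = seed,
                              log2_transform = log2_transform)
  class(out) <- c("enrichment_records", "data.frame")
  out
}

#' Proteins significant against both comparators
#'
#' @param records_a,records_b Results of [volcano_enrich()] against the two
#'   comparator interactomes, over the same protein universe.
#' @return Character vector of protein ids significant in both comparisons,
#'   sorted by id.
#' @export
intersect_significant <- function(records_a, records_b) {
  ua <- sort(records_a$protein_id)
  ub <- sort(records_b$protein_id)
  if (!identical(ua, ub)) {
    stop("the two enrichment results cover different protein universes",
         call. = FALSE)
  }
  sig <- intersect(records_a$protein_id[records_a$significant],
                   records_b$protein_id[records_b$significant])
  sort(sig)
}

# average ranks, largest value = rank 1 when descending
rank_desc <- function(x) rank(-x, ties.method = "average")
rank_asc <- function(x) rank(x, ties.method = "average")

#' Super-rank candidate interactors on four criteria
#'
#' Candidates are ranked by (1) abundance in the bait interactome
#' (descending), (2) enrichment over comparator A (descending),
#' (3) enrichment over comparator B (descending) and (4) abundance in the
#' negative control (ascending). Abundance is the mean intensity across a
#' group's replicates; enrichment is the ratio of bait to comparator mean
#' intensity. Ties within a criterion get average ranks. The super rank is
#' the ascending rank of the sum of the four ranks; ties in the sum are
#' broken by bait-abundance rank, then protein id.
#'
#' @param qm Imputed [quant_matrix()].
#' @param candidates Character vector of candidate protein ids
#'   (typically from [intersect_significant()]).
#' @param bait,comparator_a,comparator_b,negative Group labels.
#' @return A data.frame of class `rank_table`, sorted by `super_rank`, with
#'   the per-criterion values, the four rank columns, `rank_sum` and
#'   `super_rank`.
#' @export
super_rank <- function(qm, candidates, bait = "bait",
                       comparator_a = "comparatorA",
                       comparator_b = "comparatorB",
                       negative = "negative") {
  stopifnot(inherits(qm, "quant_matrix"))
  if (length(candidates) == 0L) {
    stop("empty candidate list", call. = FALSE)
  }
  missing_ids <- setdiff(candidates, qm$protein_ids)
  if (length(missing_ids)) {
    stop("candidates not in matrix: ", paste(missing_ids, collapse = ", "),
         call. = FALSE)
  }
  sub <- qm[match(candidates, qm$protein_ids)]
  gmean <- function(g) rowMeans(sub$values[, group_columns(sub, g),
                                           drop = FALSE])
  ab_bait <- gmean(bait)
  ab_neg <- gmean(negative)
  enr_a <- ab_bait / gmean(comparator_a)
  enr_b <- ab_bait / gmean(comparator_b)

  r1 <- rank_desc(ab_bait)
  r2 <- rank_desc(enr_a)
  r3 <- rank_desc(enr_b)
  r4 <- rank_asc(ab_neg)
  rank_sum <- r1 + r2 + r3 + r4
  ord <- order(rank_sum, r1, candidates)
  super <- integer(length(ord))
  super[ord] <- seq_along(ord)

  out <- data.frame(
    protein_id = candidates,
    bait_abundance = ab_bait,
    enrichment_a = enr_a,
    enrichment_b = enr_b,
    negative_abundance = ab_neg,
    rank_bait_abundance = r1,
    rank_enrich_a = r2,
    rank_enrich_b = r3,
    rank_negative_abundance = r4,
    rank_sum = rank_sum,
    super_rank = super,
    stringsAsFactors = FALSE
  )
  out <- out[order(out$super_rank), ]
  rownames(out) <- NULL
  class(out) <- c("rank_table", "data.frame")
  out
}

#' Run the full interactome ranking pipeline
#'
#' Filter to bait-complete proteins, impute non-detections with the global
#' half-minimum, test enrichment of the bait against each comparator
#' (SAM-style statistic, permutation FDR), intersect the two significant
#' sets and super-rank the surviving candidates.
#'
#' @inheritParams volcano_enrich
#' @inheritParams super_rank
#' @return A list of class `interactome_ranking` with elements `filtered`
#'   (bait-complete matrix), `imputed`, `records_a`, `records_b`,
#'   `candidates` and `ranking` (the [super_rank()] table; `NULL` when no
#'   protein passes both tests).
#' @examples
#' sim <- make_quant_matrix(matrix_spec(n_proteins = 80, n_interactors = 8,
#'                                      seed = 7))
#' res <- rank_interactome(sim$matrix, seed = 7)
#' head(res$ranking)
#' @export
rank_interactome <- function(qm, bait = "bait", comparator_a = "comparatorA",
                             comparator_b = "comparatorB",
                             negative = "negative", s0 = 2, fdr = 0.2,
                             n_perm = 1000, seed = 1L,
                             log2_transform = TRUE) {
  filtered <- filter_complete_in_bait(qm, bait = bait)
  if (nrow(filtered$values) == 0L) {
    stop("no protein is detected in all bait replicates", call. = FALSE)
  }
  imputed <- impute_half_minimum(filtered)
  rec_a <- volcano_enrich(imputed, comparator_a, bait = bait, s0 = s0,
                          fdr = fdr, n_perm = n_perm, seed = seed,
                          log2_transform = log2_transform)
  rec_b <- volcano_enrich(imputed, comparator_b, bait = bait, s0 = s0,
                          fdr = fdr, n_perm = n_perm,
                          seed = derive_seed(seed, "comparatorB"),
                          log2_transform = log2_transform)
  cand <- intersect_significant(rec_a, rec_b)
  ranking <- if (length(cand)) {
    super_rank(imputed, cand, bait = bait, comparator_a = comparator_a,
               comparator_b = comparator_b, negative = negative)
  } else {
    NULL
  }
  structure(
    list(filtered = filtered, imputed = imputed, records_a = rec_a,
         records_b = rec_b, candidates = cand, ranking = ranking),
    class = "interactome_ranking"
  )
}

#' @export
print.interactome_ranking <- function(x, ...) {
  cat(sprintf("interactome ranking: %d bait-complete proteins, %d candidates\n",
              nrow(x$filtered$values), length(x$candidates)))
  if (!is.null(x$ranking)) {
    cat("top candidates:\n")
    print(utils::head(x$ranking[, c("protein_id", "rank_sum", "super_rank")]))
  }
  invisible(x)
}
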