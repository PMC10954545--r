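#' Specification for a synthetic LFQ co-immunoprecipitation matrix
#'
#' Describes a simulated label-free quantification experiment with four
#' sample groups — bait pull-down, two comparator pull-downs and an
#' untagged negative control — and a planted set of true bait interactors.
#' Baseline protein abundances are log-normal; replicate noise is
#' log-normal; planted interactors are multiplied by `fold` in the bait
#' samples only; low-intensity values drop out (to zero) with a logistic
#' intensity-dependent probability, mimicking left-censored detection.
#'
#' Defaults emulate a three-replicate co-immunoprecipitation design:
#' 500 proteins, 25 planted interactors, 8-fold bait enrichment, log2
#' abundances centred at 20 with s.d. 2, replicate s.d. 0.5 (about 40%
#' coefficient of variation, typical of affinity-purification LFQ), and a
#' dropout curve whose half-maximal point sits 2.5 abundance s.d. below the
#' median, so non-detection is essentially a low-abundance phenomenon.
#'
#' @param n_proteins Number of proteins (default 500).
#' @param n_interactors Number of planted true interactors (default 25).
#' @param n_replicates Replicates per group (default 3).
#' @param fold Bait enrichment factor of planted interactors (default 8;
#'   1 plants no signal).
#' @param log2_mean,log2_sd Location and scale of baseline log2 abundance
#'   (defaults 20, 2).
#' @param replicate_sd Replicate-to-replicate s.d. on the log2 scale
#'   (default 0.5).
#' @param dropout_max Maximal dropout probability for vanishing intensity
#'   (default 0.5; must be < 1).
#' @param dropout_mid log2 intensity at which dropout is half-maximal
#'   (default `log2_mean - 5`, so detection loss is concentrated in the
#'   low-abundance tail).
#' @param dropout_scale Logistic width of the dropout curve in log2 units
#'   (default 1.2).
#' @param groups Group labels (bait, comparator A, comparator B, negative).
#' @param seed Integer seed; generation is a pure function of the spec.
#' @return Object of class `matrix_spec`.
#' @export
matrix_spec <- function(n_proteins = 500L, n_interactors = 25L,
                        n_replicates = 3L, fold = 8,
                        log2_mean = 20, log2_sd = 2, replicate_sd = 0.5,
                        dropout_max = 0.5, dropout_mid = log2_mean - 5,
                        dropout_scale = 1.2,
                        groups = c("bait", "comparatorA", "comparatorB",
                                   "negative"),
                        seed = 1L) {
  n_proteins <- as.integer(n_proteins)
  n_interactors <- as.integer(n_interactors)
  if (n_interactors < 0L || n_interactors > n_proteins) {
    stop("`n_interactors` must be in [0, n_proteins]", call. = FALSE)
  }
  stopifnot_scalar_num(fold, "fold", min = 0, strict_min = TRUE)
  if (dropout_max < 0 || dropout_max >= 1) {
    stop("`dropout_max` must be in [0, 1)", call. = FALSE)
  }
  structure(list(n_proteins = n_proteins, n_interactors = n_interactors,
                 n_replicates = as.integer(n_replicates), fold = fold,
                 log2_mean = log2_mean, log2_sd = log2_sd,
                 replicate_sd = replicate_sd, dropout_max = dropout_max,
                 dropout_mid = dropout_mid, dropout_scale = dropout_scale,
                 groups = groups, seed = as.integer(seed)),
            class = "matrix_spec")
}

#' Simulate a quantification matrix with planted interactors
#'
#' @param spec A [matrix_spec()].
#' @return List with `matrix` (a [quant_matrix()]), `interactors`
#'   (character vector of planted protein ids) and `is_interactor`
#'   (logical per protein).
#' @examples
#' sim <- make_quant_matrix(matrix_spec(n_proteins = 100, seed = 42))
#' sim$matrix
#' @export
make_quant_matrix <- function(spec) {
  stopifnot(inherits(spec, "matrix_spec"))
  with_seed(spec$seed, {
    np <- spec$n_proteins
    groups <- rep(spec$groups, each = spec$n_replicates)
    ns <- length(groups)
    baseline <- stats::rnorm(np, spec$log2_mean, spec$log2_sd)
    interactor <- rep(FALSE, np)
    interactor[sample.int(np, spec$n_interactors)] <- TRUE
    log2v <- matrix(stats::rnorm(np * ns, 0, spec$replicate_sd), np, ns) +
      baseline
    bait_cols <- groups == spec$groups[1L]
    log2v[interactor, bait_cols] <- log2v[interactor, bait_cols] +
      log2(spec$fold)
    p_drop <- spec$dropout_max /
      (1 + exp((log2v - spec$dropout_mid) / spec$dropout_scale))
    vals <- 2^log2v
    vals[stats::runif(np * ns) < p_drop] <- 0
    ids <- sprintf("P%04d", seq_len(np))
    qm <- quant_matrix(vals, groups = groups, protein_ids = ids)
    list(matrix = qm, interactors = ids[interactor],
         is_interactor = interactor)
  })
}
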