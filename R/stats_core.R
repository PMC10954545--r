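#' One-way analysis of variance
#'
#' Classical fixed-effects one-way ANOVA via [stats::aov()], returning the F
#' statistic and p-value for the group factor. Degenerate
#' within-group-variance cases yield a p-value at machine precision rather
#' than `NaN`.
#'
#' @param values Numeric observations.
#' @param group Factor (or coercible) of group labels, one per observation.
#' @return List with `f`, `p_value`, `df_between`, `df_within`, and the
#'   fitted `aov` object.
#' @export
anova_oneway <- function(values, group) {
  group <- factor(group)
  if (length(values) != length(group)) {
    stop("`values` and `group` lengths differ", call. = FALSE)
  }
  if (nlevels(group) < 2L) {
    stop("need at least 2 groups", call. = FALSE)
  }
  if (any(table(group) < 1L)) {
    stop("every group needs at least one observation", call. = FALSE)
  }
  fit <- stats::aov(values ~ group)
  tab <- summary(fit)[[1L]]
  f <- tab[["F value"]][1L]
  p <- tab[["Pr(>F)"]][1L]
  if (is.na(f) || stats::var(values) == 0) {
    # zero between- and within-group variance: no evidence either way
    f <- 0
    p <- 1
  }
  if (is.infinite(f) || (is.na(p) && f > 0)) {
    p <- .Machine$double.xmin
  }
  list(f = f, p_value = p,
       df_between = tab[["Df"]][1L], df_within = tab[["Df"]][2L],
       fit = fit)
}

#' Tukey honest significant differences for a one-way design
#'
#' @inheritParams anova_oneway
#' @return Data.frame with columns `pair`, `diff`, `lwr`, `upr`, `p_adj`.
#' @export
tukey_oneway <- function(values, group) {
  a <- anova_oneway(values, group)
  tk <- stats::TukeyHSD(a$fit)$group
  data.frame(pair = rownames(tk), diff = tk[, "diff"], lwr = tk[, "lwr"],
             upr = tk[, "upr"], p_adj = tk[, "p adj"],
             row.names = NULL, stringsAsFactors = FALSE)
}

#' Two-way ANOVA with post-hoc Tukey test
#'
#' Fits `values ~ f1 * f2` with [stats::aov()]; the ANOVA table uses Type II
#' sums of squares by default (robust to mild imbalance, such as unequal
#' group sizes between treatments), via [car::Anova()]. Tukey HSD is
#' computed on the interaction cell means with
#' [stats::TukeyHSD()]. Incomplete designs (an empty cell, or a single
#' observation per cell, which leaves the interaction inestimable) are
#' errors.
#'
#' @param values Numeric observations.
#' @param f1,f2 The two crossed factors.
#' @param ss_type `"II"` (default), `"I"` or `"III"` sums of squares.
#' @return List with `table` (data.frame: term, sum_sq, df, f, p_value),
#'   `tukey` (data.frame of interaction-cell contrasts: pair, diff, lwr,
#'   upr, p_adj) and the fitted `aov` object.
#' @export
anova_twoway_tukey <- function(values, f1, f2, ss_type = c("II", "I", "III")) {
  ss_type <- match.arg(ss_type)
  f1 <- factor(f1); f2 <- factor(f2)
  if (length(values) != length(f1) || length(values) != length(f2)) {
    stop("`values`, `f1`, `f2` lengths differ", call. = FALSE)
  }
  if (nlevels(f1) < 2L || nlevels(f2) < 2L) {
    stop("each factor needs at least 2 levels", call. = FALSE)
  }
  cells <- table(f1, f2)
  if (any(cells == 0L)) {
    stop("empty design cell: the design must be fully crossed", call. = FALSE)
  }
  if (all(cells == 1L)) {
    stop("single observation per cell: interaction not estimable",
         call. = FALSE)
  }
  dat <- data.frame(values = values, f1 = f1, f2 = f2)
  fit <- stats::aov(values ~ f1 * f2, data = dat)
  tab <- if (ss_type == "I") {
    s <- summary(fit)[[1L]]
    data.frame(term = trimws(rownames(s)), sum_sq = s[["Sum Sq"]],
               df = s[["Df"]], f = s[["F value"]], p_value = s[["Pr(>F)"]],
               stringsAsFactors = FALSE)
  } else {
    a <- car::Anova(fit, type = if (ss_type == "II") 2 else 3)
    data.frame(term = trimws(rownames(a)), sum_sq = a[["Sum Sq"]],
               df = a[["Df"]], f = a[["F value"]], p_value = a[["Pr(>F)"]],
               stringsAsFactors = FALSE)
  }
  tk <- stats::TukeyHSD(fit, "f1:f2")[["f1:f2"]]
  tukey <- data.frame(pair = rownames(tk), diff = tk[, "diff"],
                      lwr = tk[, "lwr"], upr = tk[, "upr"],
                      p_adj = tk[, "p adj"], row.names = NULL,
                      stringsAsFactors = FALSE)
  list(table = tab, tukey = tukey, fit = fit)
}
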