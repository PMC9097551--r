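#' Cohen effect size f-squared from partial eta squared
#'
#' `f2 = R2 / (1 - R2)`; the conventional effect size for F-ratios.
#'
#' @param R_squared partial eta squared in `[0, 1)`.
#' @return f-squared (>= 0).
#' @export
effect_size_f2 <- function(R_squared) {
  if (any(R_squared < 0 | R_squared >= 1))
    stop("R_squared must lie in [0, 1)")
  R_squared / (1 - R_squared)
}

#' Invert f-squared back to partial eta squared
#'
#' @param f_squared effect size (>= 0).
#' @return Partial eta squared `f2 / (1 + f2)`.
#' @export
f2_to_r2 <- function(f_squared) {
  if (any(f_squared < 0)) stop("f_squared must be >= 0")
  f_squared / (1 + f_squared)
}

#' Equivalent Cohen d for an f-squared effect size
#'
#' Two-group equivalence `d = 2 * sqrt(f2)` (for two groups `f = d / 2`).
#'
#' @param f_squared effect size (>= 0).
#' @return Cohen d.
#' @export
cohens_d_from_f2 <- function(f_squared) 2 * sqrt(f_squared)

#' Classical one-way fixed-effects ANOVA
#'
#' @param groups list of numeric vectors (>= 2 groups, each >= 2 values).
#' @return List with `F`, `df1` (k - 1), `df2` (N - k), `p`, `method`.
#' @export
anova_oneway <- function(groups) {
  if (length(groups) < 2) stop("need at least 2 groups")
  if (any(vapply(groups, length, integer(1)) < 2))
    stop("every group needs at least 2 values (empty or singleton group)")
  v <- unlist(groups, use.names = FALSE)
  g <- factor(rep(seq_along(groups), vapply(groups, length, integer(1))))
  fit <- stats::oneway.test(v ~ g, var.equal = TRUE)
  list(F = unname(fit$statistic), df1 = unname(fit$parameter[1]),
       df2 = unname(fit$parameter[2]), p = fit$p.value,
       method = "one-way fixed-effects ANOVA")
}

#' Tukey-Kramer pairwise comparisons
#'
#' Studentized-range post-hoc comparisons after one-way ANOVA, with the
#' Kramer correction for unequal group sizes.
#'
#' @param groups list of numeric vectors (named, optionally).
#' @return data.frame with `pair`, `diff`, `p_adj`.
#' @export
tukey_kramer <- function(groups) {
  if (length(groups) < 2) stop("need at least 2 groups")
  if (any(vapply(groups, length, integer(1)) < 2))
    stop("every group needs at least 2 values")
  if (is.null(names(groups)))
    names(groups) <- paste0("g", seq_along(groups))
  v <- unlist(groups, use.names = FALSE)
  g <- factor(rep(names(groups), vapply(groups, length, integer(1))),
              levels = names(groups))
  hsd <- stats::TukeyHSD(stats::aov(v ~ g))$g
  data.frame(pair = rownames(hsd), diff = hsd[, "diff"],
             p_adj = hsd[, "p adj"], row.names = NULL)
}

#' Paired Wilcoxon signed-rank test
#'
#' Two-sided test of paired differences: exact distribution for up to 25
#' nonzero differences without ties, normal approximation with tie
#' correction otherwise. Zero differences are removed first; if none
#' remain the test degenerates to p = 1.
#'
#' @param paired_a,paired_b equal-length numeric vectors.
#' @param exact_max largest n for which the exact distribution is used.
#' @return List with `p`, `V` (signed-rank statistic), `n` (nonzero
#'   differences) and `method`.
#' @export
wilcoxon_signed_rank <- function(paired_a, paired_b, exact_max = 25) {
  if (length(paired_a) != length(paired_b))
    stop("paired vectors must have equal length")
  d <- paired_a - paired_b
  d <- d[d != 0]
  n <- length(d)
  if (n == 0)
    return(list(p = 1, V = NA_real_, n = 0L,
                method = "degenerate (all differences zero)"))
  ties <- any(duplicated(abs(d)))
  exact <- n <= exact_max && !ties
  ht <- suppressWarnings(
    stats::wilcox.test(d, alternative = "two.sided", mu = 0,
                       exact = exact, correct = !exact))
  list(p = ht$p.value, V = unname(ht$statistic), n = n,
       method = if (exact) "exact signed-rank distribution"
                else "normal approximation with tie correction")
}

#' Participants needed for a two-tailed test at a given effect size
#'
#' Closed-form normal-approximation power equation:
#' `n = ceiling(((z_{1-alpha/2} + z_{power}) / d)^2 + z_{1-alpha/2}^2 / 2)`,
#' floored at 2.
#'
#' @param d Cohen effect size (> 0).
#' @param alpha two-tailed significance level.
#' @param power target power in (0, 1).
#' @return Smallest integer sample size.
#' @export
sample_size <- function(d, alpha = 0.05, power = 0.80) {
  if (d <= 0) stop("effect size d must be positive")
  if (!(alpha > 0 && alpha < 1)) stop("alpha must lie in (0, 1)")
  if (!(power > 0 && power < 1))
    stop("power must lie in (0, 1); the requested power is unreachable")
  za <- stats::qnorm(1 - alpha / 2)
  zb <- stats::qnorm(power)
  max(2L, as.integer(ceiling(((za + zb) / d)^2 + za^2 / 2)))
}

#' Mean and population standard deviation of per-subject accuracies
#'
#' The dispersion convention is the population standard deviation
#' (divisor n), matching how the per-subject result tables are summarized.
#'
#' @param per_subject_values numeric vector.
#' @return List with `mean` and `std`.
#' @export
summarize_accuracies <- function(per_subject_values) {
  if (!length(per_subject_values)) stop("no values supplied")
  m <- mean(per_subject_values)
  list(mean = m, std = sqrt(mean((per_subject_values - m)^2)))
}
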