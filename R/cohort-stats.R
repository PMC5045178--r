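#' Significance stars for a p-value
#'
#' Thresholds follow the convention used throughout the figures:
#' n.s. = p > 0.05, * = p <= 0.05, ** = p <= 0.01, *** = p <= 0.001.
#'
#' @param p p-value in `[0, 1]`.
#' @return One of "n.s.", "*", "**", "***".
#' @export
significance_stars <- function(p) {
  stopifnot(is.numeric(p), p >= 0, p <= 1)
  if (p <= 0.001) "***" else if (p <= 0.01) "**" else if (p <= 0.05) "*" else "n.s."
}

#' Classic (equal-variance) Student's two-sample t-test
#'
#' Two-sided, pooled-variance t-test with df = n_a + n_b - 2. The classic
#' form (not Welch) is used deliberately: it is the test named in the
#' original comparisons of genotype cohorts.
#'
#' @param a,b numeric vectors, each of length >= 2.
#' @return list(t_statistic, p_value, df, means, sds, ns).
#' @export
students_t_test <- function(a, b) {
  if (length(a) < 2L || length(b) < 2L)
    stop("each group needs at least 2 observations")
  if (stats::var(a) + stats::var(b) == 0)
    stop("degenerate variance: both groups are constant")
  ht <- stats::t.test(a, b, var.equal = TRUE)
  list(t_statistic = unname(ht$statistic),
       p_value = unname(ht$p.value),
       df = unname(ht$parameter),
       means = c(a = mean(a), b = mean(b)),
       sds = c(a = sd(a), b = sd(b)),
       ns = c(a = length(a), b = length(b)))
}

#' Compare genotype groups against a reference
#'
#' Tests every non-reference group against the reference with the classic
#' Student's t-test and assigns significance stars. No multiple-testing
#' correction is applied (matching the original analyses, which report raw
#' per-comparison p-values).
#'
#' @param groups either a named list of numeric vectors, or a data.frame
#'   with columns `label` and `value`.
#' @param reference label of the reference group.
#' @return data.frame with one row per non-reference group: group and
#'   reference labels, ns, means, sds, `t_statistic`, `p_value`, `stars`.
#' @export
compare_genotypes <- function(groups, reference) {
  if (is.data.frame(groups)) {
    stopifnot(all(c("label", "value") %in% names(groups)))
    groups <- split(groups$value, groups$label)
  }
  if (!reference %in% names(groups))
    stop(sprintf("reference group '%s' not present", reference))
  ref <- groups[[reference]]
  others <- setdiff(names(groups), reference)
  rows <- lapply(others, function(g) {
    tt <- students_t_test(groups[[g]], ref)
    data.frame(group = g, reference = reference,
               n = length(groups[[g]]), n_ref = length(ref),
               mean = unname(tt$means["a"]), mean_ref = unname(tt$means["b"]),
               sd = unname(tt$sds["a"]), sd_ref = unname(tt$sds["b"]),
               t_statistic = tt$t_statistic, p_value = tt$p_value,
               stars = significance_stars(tt$p_value),
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

#' Male-rescue percent
#'
#' In the male rescue assay the expected number of males is 38% of the eggs
#' laid (the him-8 background consistently yields 38% male progeny), so
#' rescue is `100 * males / (0.38 * eggs)`.
#'
#' @param males_observed observed male count (>= 0).
#' @param eggs_laid number of eggs laid (> 0, >= males).
#' @param expected_male_fraction expected male fraction of progeny
#'   (default 0.38).
#' @return rescue percent (>= 0).
#' @export
rescue_percent <- function(males_observed, eggs_laid,
                           expected_male_fraction = 0.38) {
  if (eggs_laid <= 0) stop("eggs_laid must be > 0")
  if (males_observed < 0 || males_observed > eggs_laid)
    stop("males_observed must lie in [0, eggs_laid]")
  100 * males_observed / (expected_male_fraction * eggs_laid)
}

#' Chi-square test of male rescue against an expected rescue rate
#'
#' Goodness-of-fit chi-square (1 df) on the two-cell male / non-male table,
#' with the expected male count given by the rescue model:
#' `expected_rescue_rate * expected_male_fraction * total`. This compares an
#' observed rescue to the rescue expected under a control (e.g. vector
#' RNAi) rate.
#'
#' @param observed integer vector `c(males, non_males)`.
#' @param expected_rescue_rate expected rescue rate as a fraction in (0, 1)
#'   of the maximal (100%) rescue.
#' @param expected_male_fraction default 0.38.
#' @return list(chi2, p_value, expected, small_expected) where
#'   `small_expected` flags an expected cell below 1.
#' @export
chi_square_rescue <- function(observed, expected_rescue_rate,
                              expected_male_fraction = 0.38) {
  stopifnot(length(observed) == 2L, all(observed >= 0), sum(observed) > 0)
  if (expected_rescue_rate <= 0 || expected_rescue_rate >= 1 / expected_male_fraction)
    stop("expected_rescue_rate out of range")
  total <- sum(observed)
  e_males <- expected_rescue_rate * expected_male_fraction * total
  expected <- c(males = e_males, non_males = total - e_males)
  ht <- suppressWarnings(
    stats::chisq.test(observed, p = expected / total)
  )
  list(chi2 = unname(ht$statistic), p_value = unname(ht$p.value),
       expected = expected, small_expected = any(expected < 1))
}
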