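#' One-way ANOVA with shared error mean square
#'
#' Standard one-way decomposition of a balanced standardized table. The
#' pooled within-group mean square (`ms_error`) is the shared denominator
#' for all downstream standardized effect sizes of the assay.
#'
#' @param values a `standardized_table` (or a data frame with `variant` and
#'   `value` columns).
#' @return List with `k` (groups), `n` (replicates per group), `df_error`,
#'   `ms_error`, `grand_mean`, `F` and `p`. `F` is `NA` when `ms_error`
#'   is 0 (all values identical within groups).
#' @export
anova_oneway <- function(values) {
  d <- if (inherits(values, "standardized_table")) values$data else values
  stopifnot(all(c("variant", "value") %in% names(d)))
  sizes <- table(d$variant)
  if (length(sizes) < 2) stop("need at least two groups")
  if (length(unique(sizes)) != 1)
    stop("unbalanced design: equal replicates per group required")
  n <- unname(sizes[1]); k <- length(sizes)
  if (n < 2) stop("n = 1 leaves no error degrees of freedom")
  gm <- mean(d$value)
  means <- tapply(d$value, d$variant, mean)
  ss_between <- n * sum((means - gm)^2)
  ss_within <- sum((d$value - means[d$variant])^2)
  df_error <- k * (n - 1)
  ms_error <- ss_within / df_error
  f <- if (ms_error > 0) (ss_between / (k - 1)) / ms_error else NA_real_
  p <- if (is.na(f)) NA_real_ else stats::pf(f, k - 1, df_error,
                                             lower.tail = FALSE)
  list(k = k, n = n, df_error = df_error, ms_error = ms_error,
       grand_mean = gm, F = f, p = p)
}

#' Small-sample bias correction factor J(n)
#'
#' Gamma-function correction applied to the standardized mean difference of
#' two groups of `n` replicates each (error df = 2n - 2):
#' J(n) = Gamma((2n-2)/2) / (Gamma((2n-3)/2) * sqrt((2n-2)/2)).
#' J(3) = 0.797885.
#'
#' @param n replicates per group (>= 2).
#' @return Correction factor in (0, 1].
#' @export
hedges_j <- function(n) {
  stopifnot(n >= 2)
  df <- 2 * n - 2
  gamma(df / 2) / (gamma((df - 1) / 2) * sqrt(df / 2))
}

#' Bias-corrected Hedges g
#'
#' Standardized difference of a group mean from the control mean, in units
#' of the square root of the assay's shared ANOVA error mean square, with
#' the gamma-function small-sample correction [hedges_j()]:
#' g = (m_j - m_c) / sqrt(ms_error) * J(n).
#'
#' @param m_j group mean.
#' @param m_c control mean.
#' @param ms_error shared ANOVA error mean square (> 0).
#' @param n replicates per group.
#' @return Dimensionless standardized difference.
#' @examples
#' hedges_g(-1.76, 0, 0.289^2, n = 3)  # approx -4.86
#' @export
hedges_g <- function(m_j, m_c, ms_error, n) {
  if (!is.finite(ms_error) || ms_error <= 0)
    stop("undefined effect: ms_error must be > 0")
  (m_j - m_c) / sqrt(ms_error) * hedges_j(n)
}

#' Approximate standard error of Hedges g
#'
#' Delta-method approximation sqrt(2/n + g^2 / (2 * df_error)).
#'
#' @param g effect size.
#' @param n replicates per group.
#' @param df_error error degrees of freedom of the shared ANOVA.
#' @export
hedges_g_se <- function(g, n, df_error) {
  sqrt(2 / n + g^2 / (2 * df_error))
}

#' Recover the error mean square from a reported mean and g
#'
#' Reproduction utility for published effect-size tables that print
#' control-relative means and g but not the error mean square: inverts
#' [hedges_g()] for one variant, giving the shared `ms_error` implied by
#' its (mean, g) pair.
#'
#' @param m_j,m_c group and control means.
#' @param g reported bias-corrected effect size (nonzero).
#' @param n replicates per group.
#' @return The implied `ms_error`.
#' @export
ms_error_from_g <- function(m_j, m_c, g, n) {
  stopifnot(g != 0)
  ((m_j - m_c) * hedges_j(n) / g)^2
}

#' Root-mean-square standardized effect (Psi)
#'
#' Assay-level effect size expressing the spread of the k group means in
#' units of the shared error mean square, with the same small-sample bias
#' correction as the pairwise effect sizes:
#' Psi = J(n) * sqrt( sum_j (m_j - GM)^2 / ((k - 1) * ms_error) ).
#' Psi is 0 exactly when all group means are equal and is comparable in
#' scale to the pairwise g.
#'
#' @param means vector of group means (length k).
#' @param ms_error shared ANOVA error mean square (> 0).
#' @param k number of groups; defaults to `length(means)`.
#' @param n replicates per group.
#' @return Non-negative standardized effect.
#' @export
rmsse_psi <- function(means, ms_error, k = length(means), n) {
  if (!is.finite(ms_error) || ms_error <= 0)
    stop("undefined effect: ms_error must be > 0")
  stopifnot(k >= 2, length(means) == k)
  gm <- mean(means)
  hedges_j(n) * sqrt(sum((means - gm)^2) / ((k - 1) * ms_error))
}
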