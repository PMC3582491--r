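.dunnett_cache <- new.env(parent = emptyenv())

#' Dunnett equicoordinate critical value
#'
#' Two-sided critical value for k - 1 simultaneous comparisons of treatment
#' means against a shared control in a balanced one-way layout. Under equal
#' group sizes the comparison statistics are equicorrelated with rho = 1/2;
#' the family-wise coverage probability
#' P(max_i |T_i| <= c) is computed by numerical integration over the shared
#' control variate and the studentizing chi factor:
#'
#' P(c) = Int_s Int_z phi(z) \[Phi(z + c sqrt(2) s) - Phi(z - c sqrt(2) s)\]^(k-1)
#'        f_S(s) dz ds,
#'
#' with S = sqrt(chi^2_df / df). The root of P(c) = 1 - alpha is found to
#' absolute tolerance 1e-4. At k = 2 the value collapses to the two-sided
#' Student t quantile.
#'
#' @param k total number of groups including the control (>= 2).
#' @param df error degrees of freedom of the pooled mean square.
#' @param alpha family-wise error rate.
#' @param two_sided two-sided comparisons (default) or one-sided.
#' @return The critical value c.
#' @examples
#' dunnett_critical(2, 4)            # 2.776, the t quantile
#' dunnett_critical(8, 16)           # approx 2.92
#' @export
dunnett_critical <- function(k, df, alpha = 0.05, two_sided = TRUE) {
  if (k < 2) stop("design error: k must be >= 2")
  stopifnot(df >= 1, alpha > 0, alpha < 1)
  key <- paste(k, df, alpha, two_sided, sep = "|")
  hit <- get0(key, envir = .dunnett_cache, inherits = FALSE)
  if (!is.null(hit)) return(hit)
  m <- k - 1
  coverage <- function(cc) {
    outer_f <- function(s) {
      vapply(s, function(si) {
        inner <- function(z) {
          band <- if (two_sided)
            stats::pnorm(z + cc * sqrt(2) * si) -
              stats::pnorm(z - cc * sqrt(2) * si)
          else
            stats::pnorm(z + cc * sqrt(2) * si)
          stats::dnorm(z) * band^m
        }
        stats::integrate(inner, -Inf, Inf, rel.tol = 1e-9)$value
      }, numeric(1)) * stats::dchisq(df * s^2, df) * 2 * df * s
    }
    stats::integrate(outer_f, 0, Inf, rel.tol = 1e-8)$value
  }
  out <- stats::uniroot(function(cc) coverage(cc) - (1 - alpha),
                        interval = c(0.5, 15), tol = 1e-5)$root
  assign(key, out, envir = .dunnett_cache)
  out
}

#' Dunnett's multiple t against a control
#'
#' Flags every treatment mean whose distance from the control mean, in
#' units of sqrt(2 * ms_error / n), exceeds the equicoordinate critical
#' value from [dunnett_critical()].
#'
#' @param means named vector of group means, control included.
#' @param ms_error shared ANOVA error mean square (> 0).
#' @param n replicates per group.
#' @param control name (or index) of the control group in `means`.
#' @param alpha family-wise error rate.
#' @param two_sided logical.
#' @return List with per-variant `statistic`, logical `flagged`
#'   (control entry is `FALSE`), `critical`, `df` and `alpha`.
#' @export
dunnett_test <- function(means, ms_error, n, control = 1, alpha = 0.05,
                         two_sided = TRUE) {
  k <- length(means)
  if (k < 2) stop("design error: need a control plus >= 1 treatment")
  if (!is.finite(ms_error) || ms_error <= 0)
    stop("undefined effect: ms_error must be > 0")
  if (is.character(control)) control <- match(control, names(means))
  stopifnot(!is.na(control))
  df <- k * (n - 1)
  crit <- dunnett_critical(k, df, alpha, two_sided)
  delta <- (means - means[control]) / sqrt(2 * ms_error / n)
  stat <- if (two_sided) abs(delta) else delta
  flagged <- stat > crit
  flagged[control] <- FALSE
  list(statistic = delta, flagged = flagged, critical = crit,
       df = df, alpha = alpha, two_sided = two_sided)
}
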