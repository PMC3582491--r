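#' Standardize densitometry signals within each film
#'
#' Film-to-film offset and exposure differences are removed by z-scoring
#' each film: every signal becomes (x - film mean) / film SD. The control
#' (wildtype) variant's standardized value within each film (averaged over
#' its replicates if it was run more than once per film) is then subtracted
#' from all values of that film, so the control's adjusted mean is exactly 0
#' and every other mean is control-relative.
#'
#' @param table an [assay_table()] of kind `"subtractive"`.
#' @return A `standardized_table`: the per-record adjusted values plus
#'   per-variant adjusted means and standard errors.
#' @examples
#' rec <- data.frame(film = 1, variant = c("PRE", "A", "B"),
#'                   replicate = 1, signal = c(2, 1, 3))
#' standardize_by_film(assay_table(rec, "subtractive", control = "PRE"))
#' @export
standardize_by_film <- function(table) {
  stopifnot(inherits(table, "assay_table"))
  if (table$kind != "subtractive")
    stop("standardize_by_film() applies to subtractive-scale assays")
  rec <- table$records
  rec$value <- NA_real_
  for (f in unique(rec$film)) {
    i <- rec$film == f
    s <- stats::sd(rec$signal[i])
    if (!is.finite(s) || s == 0)
      stop("degenerate film '", f, "': film SD is zero")
    z <- (rec$signal[i] - mean(rec$signal[i])) / s
    anchor <- mean(z[rec$variant[i] == table$control])
    rec$value[i] <- z - anchor
  }
  new_standardized(rec, table, kind = "subtractive", control_mean = 0)
}

#' Normalize ratio-scale reporter signals
#'
#' Each signal is divided by its per-record positive covariate (e.g. the
#' cotransfected beta-galactosidase level) when one is present, and all
#' adjusted values are then divided by the control variant's mean so that
#' the control mean is exactly 1.
#'
#' @param table an [assay_table()] of kind `"ratio"`.
#' @param covariate optional per-record positive covariate; defaults to the
#'   table's `covariate` column, or no adjustment if absent.
#' @return A `standardized_table` with control mean exactly 1.
#' @export
normalize_ratio <- function(table, covariate = NULL) {
  stopifnot(inherits(table, "assay_table"))
  if (table$kind != "ratio")
    stop("normalize_ratio() applies to ratio-scale assays")
  rec <- table$records
  if (is.null(covariate)) covariate <- rec$covariate
  if (is.null(covariate)) covariate <- rep(1, nrow(rec))
  if (length(covariate) != nrow(rec))
    stop("covariate must have one value per record")
  if (any(covariate <= 0) || any(rec$signal <= 0))
    stop("signals and covariates must be strictly positive")
  v <- rec$signal / covariate
  rec$value <- v / mean(v[rec$variant == table$control])
  new_standardized(rec, table, kind = "ratio", control_mean = 1)
}

new_standardized <- function(rec, table, kind, control_mean,
                             transform_lambda = NULL) {
  means <- c(tapply(rec$value, rec$variant, mean))
  ses <- c(tapply(rec$value, rec$variant,
                  function(x) stats::sd(x) / sqrt(length(x))))
  structure(list(assay_id = table$assay_id, kind = kind,
                 control = table$control, data = rec,
                 means = means, se = ses, control_mean = control_mean,
                 transform_lambda = transform_lambda),
            class = "standardized_table")
}

#' Normality gate and Box-Cox transformation
#'
#' Applies the Anderson-Darling test to the residuals of the one-way layout
#' (value ~ variant). If residual normality is rejected at `alpha`, a
#' Box-Cox power transformation with lambda estimated by profile maximum
#' likelihood on a grid (default -3..3, step 0.01) is applied to the
#' values before downstream ANOVA / Dunnett analysis. Reported group means
#' are back-transformed. Only strictly positive (ratio-scale) values can be
#' transformed.
#'
#' @param values a `standardized_table`.
#' @param alpha gate level for the Anderson-Darling p-value.
#' @param lambda_grid candidate Box-Cox exponents.
#' @return The input table, possibly with transformed `value` column,
#'   `transform_lambda` set, and `back_means` holding back-transformed
#'   group means.
#' @export
gate_and_transform <- function(values, alpha = 0.05,
                               lambda_grid = seq(-3, 3, by = 0.01)) {
  stopifnot(inherits(values, "standardized_table"))
  res <- stats::residuals(stats::lm(value ~ variant, data = values$data))
  p <- nortest::ad.test(res)$p.value
  if (is.na(p) || p >= alpha) {
    values$transform_lambda <- NULL
    values$ad_p <- p
    return(values)
  }
  if (any(values$data$value <= 0))
    stop("Box-Cox transformation requested on non-positive values")
  bc_data <- values$data
  bc <- MASS::boxcox(value ~ variant, data = bc_data,
                     lambda = lambda_grid, plotit = FALSE)
  lam <- bc$x[which.max(bc$y)]
  y <- values$data$value
  values$data$value <- if (abs(lam) < 1e-12) log(y) else (y^lam - 1) / lam
  values$means <- c(tapply(values$data$value, values$data$variant, mean))
  values$se <- c(tapply(values$data$value, values$data$variant,
                        function(x) stats::sd(x) / sqrt(length(x))))
  values$back_means <- boxcox_invert(values$means, lam)
  values$transform_lambda <- lam
  values$ad_p <- p
  values
}

boxcox_invert <- function(z, lambda) {
  if (abs(lambda) < 1e-12) exp(z) else (lambda * z + 1)^(1 / lambda)
}

#' @export
print.standardized_table <- function(x, ...) {
  cat("Standardized table '", x$assay_id, "' (", x$kind, ")\n", sep = "")
  if (!is.null(x$transform_lambda))
    cat("  Box-Cox lambda =", format(x$transform_lambda), "\n")
  print(round(x$means, 3))
  invisible(x)
}
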