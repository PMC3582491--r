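#' Paired effect sizes from two assays
#'
#' Pairs per-variant standardized effects from two assays (e.g. an EMSA
#' band and the reporter ELISA) for correlation meta-analysis. The control
#' variant contributes the (0, 0) pair by construction and is included by
#' default.
#'
#' @param g_x,g_y effect sizes from the two assays (same variant order).
#' @param labels optional variant labels.
#' @param include_control keep the control's (0, 0) pair (default `TRUE`);
#'   if `FALSE` the pair equal to (0, 0) is dropped.
#' @return An `effect_pairs` data frame.
#' @export
effect_pairs <- function(g_x, g_y, labels = NULL, include_control = TRUE) {
  stopifnot(length(g_x) == length(g_y))
  if (is.null(labels)) labels <- paste0("v", seq_along(g_x))
  d <- data.frame(label = labels, g_x = g_x, g_y = g_y)
  if (!include_control) d <- d[!(d$g_x == 0 & d$g_y == 0), ]
  class(d) <- c("effect_pairs", "data.frame")
  d
}

#' Pearson correlation of paired effect sizes
#'
#' @param pairs an [effect_pairs()] object (or data frame with `g_x`,
#'   `g_y`).
#' @return Product-moment correlation coefficient.
#' @export
pearson_r <- function(pairs) {
  if (nrow(pairs) < 3) stop("need at least 3 pairs for a correlation")
  if (stats::sd(pairs$g_x) == 0 || stats::sd(pairs$g_y) == 0)
    stop("undefined correlation: zero variance on an axis")
  stats::cor(pairs$g_x, pairs$g_y)
}

#' Bootstrap inference for the effect-size correlation
#'
#' Resamples the variant pairs with replacement (same size), recomputing
#' the Pearson correlation each time. Significance is reported as the
#' chance that r has the opposite sign to the observed correlation
#' (one-sided sign-crossing fraction); bootstrap replicates with zero
#' variance on an axis are skipped and counted, and exact zeros count
#' half to either side.
#'
#' @param pairs an [effect_pairs()] object.
#' @param B number of bootstrap repetitions (>= 1000).
#' @param seed mandatory integer seed.
#' @return A `bootstrap_result` list: `r_observed`, `r` (the bootstrap
#'   distribution), `p`, `B`, `n_degenerate`, `seed`.
#' @export
bootstrap_r <- function(pairs, B = 100000, seed) {
  if (missing(seed)) stop("a seed is required for bootstrap_r()")
  stopifnot(B >= 1000)
  r_obs <- pearson_r(pairs)
  x <- pairs$g_x; y <- pairs$g_y; n <- length(x)
  set.seed(seed)
  rs <- numeric(B)
  done <- 0L
  chunk <- 20000L
  while (done < B) {
    b <- min(chunk, B - done)
    idx <- matrix(sample.int(n, n * b, replace = TRUE), nrow = n)
    xm <- matrix(x[idx], nrow = n)
    ym <- matrix(y[idx], nrow = n)
    sx <- colSums(xm); sy <- colSums(ym)
    sxx <- colSums(xm^2) - sx^2 / n
    syy <- colSums(ym^2) - sy^2 / n
    sxy <- colSums(xm * ym) - sx * sy / n
    den <- sxx * syy
    r <- ifelse(den > 0, pmax(-1, pmin(1, sxy / sqrt(den))), NA_real_)
    rs[(done + 1):(done + b)] <- r
    done <- done + b
  }
  n_deg <- sum(is.na(rs))
  if (n_deg > 0)
    message(n_deg, " degenerate bootstrap resample(s) skipped")
  valid <- rs[!is.na(rs)]
  opp <- if (r_obs >= 0) sum(valid < 0) else sum(valid > 0)
  p <- (opp + 0.5 * sum(valid == 0)) / length(valid)
  structure(list(r_observed = r_obs, r = rs, p = p, B = B,
                 n_degenerate = n_deg, seed = seed),
            class = "bootstrap_result")
}

#' @export
print.bootstrap_result <- function(x, ...) {
  cat(sprintf("Bootstrap correlation: r = %.3f (p = %.3g), B = %d, seed = %d\n",
              x$r_observed, x$p, x$B, x$seed))
  invisible(x)
}

#' Percent overlap of two bootstrap distributions
#'
#' Builds relative-frequency histograms of both samples on a shared
#' equal-width bin grid spanning their pooled range and returns
#' 100 * sum over bins of min(f_a, f_b). Identical distributions give
#' 100, disjoint supports give 0.
#'
#' @param dist_a,dist_b numeric samples (non-empty).
#' @param bins number of equal-width bins (default 50).
#' @return Overlap in percent, within \[0, 100\].
#' @export
overlap_pct <- function(dist_a, dist_b, bins = 50) {
  dist_a <- dist_a[is.finite(dist_a)]
  dist_b <- dist_b[is.finite(dist_b)]
  if (!length(dist_a) || !length(dist_b)) stop("empty distribution")
  rng <- range(c(dist_a, dist_b))
  if (rng[1] == rng[2]) return(100)
  breaks <- seq(rng[1], rng[2], length.out = bins + 1)
  fa <- tabulate(findInterval(dist_a, breaks, rightmost.closed = TRUE,
                              all.inside = TRUE), bins) / length(dist_a)
  fb <- tabulate(findInterval(dist_b, breaks, rightmost.closed = TRUE,
                              all.inside = TRUE), bins) / length(dist_b)
  100 * sum(pmin(fa, fb))
}
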