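# Independent oracles used across the suite.

# Brute-force one-way ANOVA from explicit sums of squares.
oracle_anova_f <- function(values, groups) {
  gm <- mean(values)
  ms <- tapply(values, groups, mean)
  n <- unname(table(groups)[1]); k <- length(ms)
  ssb <- n * sum((ms - gm)^2)
  ssw <- sum((values - ms[groups])^2)
  (ssb / (k - 1)) / (ssw / (k * (n - 1)))
}

# Monte-Carlo equicoordinate critical value of the Dunnett statistic:
# max_i |(Z_i - Z_0)| / (sqrt(2) S), S^2 ~ chi^2_df / df.
oracle_dunnett_mc <- function(k, df, alpha = 0.05, draws = 1e6,
                              seed = 99) {
  set.seed(seed)
  q <- numeric(0)
  chunk <- 250000
  maxes <- numeric(draws)
  done <- 0
  while (done < draws) {
    b <- min(chunk, draws - done)
    z0 <- rnorm(b)
    s <- sqrt(rchisq(b, df) / df)
    mx <- rep(0, b)
    for (i in seq_len(k - 1))
      mx <- pmax(mx, abs(rnorm(b) - z0))
    maxes[(done + 1):(done + b)] <- mx / (sqrt(2) * s)
    done <- done + b
  }
  unname(quantile(maxes, 1 - alpha))
}

# Fine-grid numerical integration of the overlap of two normal densities.
oracle_normal_overlap <- function(mu1, mu2, sd1 = 1, sd2 = 1) {
  grid <- seq(min(mu1, mu2) - 6 * max(sd1, sd2),
              max(mu1, mu2) + 6 * max(sd1, sd2), length.out = 200001)
  h <- diff(grid[1:2])
  100 * sum(pmin(dnorm(grid, mu1, sd1), dnorm(grid, mu2, sd2))) * h
}

# All tip-to-tip path lengths via the tree's cophenetic matrix.
oracle_tip_distances <- function(tree) ape::cophenetic.phylo(tree)

# Effect tables bundled with the package, with the error mean square
# recovered from the M1 row of each assay column.
table_with_recovered_ms <- function(cell_line) {
  tab <- pre_effect_table(cell_line)
  lapply(split(tab, tab$assay), function(d) {
    d <- d[match(c("PRE", paste0("M", 1:7)), d$variant), ]
    m_c <- if (d$mean[d$variant == "PRE"] == 1) 1 else 0
    ms <- ms_error_from_g(d$mean[d$variant == "M1"], m_c,
                          d$g[d$variant == "M1"], n = 3)
    list(table = d, m_c = m_c, ms_error = ms)
  })
}
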