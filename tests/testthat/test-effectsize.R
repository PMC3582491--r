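test_that("film standardization removes film effects and anchors the control", {
  rec <- data.frame(film = "f1", variant = c("PRE", "A", "B"),
                    replicate = 1, signal = c(2, 1, 3))
  st <- standardize_by_film(assay_table(rec, "subtractive", "PRE"))
  expect_equal(unname(st$means[c("PRE", "A", "B")]), c(0, -1, 1))

  # two films with opposite offsets and a scale change: identical
  # underlying signals must give identical adjusted values per variant
  base <- c(PRE = 1.2, A = 0.4, B = 2.5, C = 1.9)
  rec2 <- rbind(
    data.frame(film = "f1", variant = names(base), replicate = 1,
               signal = base + 10),
    data.frame(film = "f2", variant = names(base), replicate = 1,
               signal = 3 * base - 10))
  st2 <- standardize_by_film(assay_table(rec2, "subtractive", "PRE"))
  v1 <- st2$data$value[st2$data$film == "f1"]
  v2 <- st2$data$value[st2$data$film == "f2"]
  expect_equal(v1, v2)
  expect_equal(unname(st2$means["PRE"]), 0)

  # degenerate film and missing control are hard errors naming the design
  recz <- data.frame(film = "f1", variant = c("PRE", "A"), replicate = 1,
                     signal = c(1, 1))
  expect_error(assay_table(recz, "subtractive", "PRE"), "degenerate")
  recm <- rbind(rec, data.frame(film = "f2", variant = c("A", "B"),
                                replicate = 1, signal = c(1, 2)))
  expect_error(assay_table(recm, "subtractive", "PRE"), "design error")
})

test_that("ratio normalization sets the control mean to 1 and is covariate-scale invariant", {
  rec <- data.frame(film = "b1", variant = rep(c("PRE", "A"), each = 3),
                    replicate = rep(1:3, 2),
                    signal = c(4, 5, 6, 9, 10, 11),
                    covariate = c(2, 2.5, 3, 3, 2, 2.5))
  tab <- assay_table(rec, "ratio", "PRE")
  st <- normalize_ratio(tab)
  expect_equal(unname(st$means["PRE"]), 1)
  # doubling every covariate leaves adjusted means unchanged
  st2 <- normalize_ratio(tab, covariate = rec$covariate * 2)
  expect_equal(st$means, st2$means)
  # identical variants give all means 1
  rec$signal <- rec$covariate * 5
  expect_equal(unname(normalize_ratio(assay_table(rec, "ratio", "PRE"))$means),
               c(1, 1))
  rec$signal[1] <- -1
  expect_error(assay_table(rec, "ratio", "PRE"), "positive")
})

test_that("one-way ANOVA matches the sum-of-squares oracle and the t^2 identity", {
  set.seed(11)
  d <- data.frame(variant = rep(letters[1:5], each = 4),
                  value = rnorm(20))
  an <- anova_oneway(d)
  expect_equal(an$F, oracle_anova_f(d$value, d$variant), tolerance = 1e-10)
  expect_equal(an$df_error, 5 * 3)

  # two balanced groups: F equals the squared pooled-variance t statistic
  d2 <- data.frame(variant = rep(c("a", "b"), each = 6),
                   value = rnorm(12))
  an2 <- anova_oneway(d2)
  tt <- t.test(value ~ variant, data = d2, var.equal = TRUE)
  expect_equal(an2$F, unname(tt$statistic)^2, tolerance = 1e-10)

  # all values identical: zero error mean square, F undefined
  d3 <- data.frame(variant = rep(c("a", "b"), each = 3), value = 1)
  an3 <- anova_oneway(d3)
  expect_equal(an3$ms_error, 0)
  expect_true(is.na(an3$F))
  expect_error(anova_oneway(data.frame(variant = c("a", "b"),
                                       value = 1:2)), "df|degrees")
})

test_that("Hedges g uses the gamma correction and is antisymmetric", {
  expect_equal(hedges_j(3), gamma(2) / (gamma(1.5) * sqrt(2)))
  expect_equal(hedges_j(3), 0.797885, tolerance = 1e-6)
  expect_equal(hedges_g(1, 1, 0.5, 3), 0)
  # published worked value: mean difference -1.76, sqrt(MSerror) 0.2890
  expect_lt(abs(hedges_g(-1.76, 0, 0.2890^2, 3) - (-4.86)), 0.02)
  g1 <- hedges_g(2.3, 0.7, 0.9, 4)
  expect_equal(hedges_g(0.7, 2.3, 0.9, 4), -g1)
  expect_error(hedges_g(1, 0, 0, 3), "undefined effect")
  # recovery helper inverts the formula
  ms <- ms_error_from_g(-1.76, 0, -4.86, 3)
  expect_equal(hedges_g(-1.76, 0, ms, 3), -4.86)
})

test_that("the RMSSE is zero for equal means and reproduces published assay effects", {
  expect_equal(rmsse_psi(rep(0.7, 6), 1, n = 3), 0)
  tabs <- table_with_recovered_ms("NB")
  bII <- tabs$band_II
  expect_lt(abs(rmsse_psi(bII$table$mean, bII$ms_error, n = 3) - 2.72), 0.02)
  pc <- table_with_recovered_ms("PC12")$band_II
  expect_lt(abs(rmsse_psi(pc$table$mean, pc$ms_error, n = 3) - 4.05), 0.02)
  expect_error(rmsse_psi(1:3, 0, n = 3), "undefined effect")
})

test_that("shared-MSerror identity holds across printed effect columns", {
  # |m_j - m_c| / |g| constant across variants of an untransformed column
  for (cl in c("NB", "PC12")) {
    tabs <- table_with_recovered_ms(cl)
    for (nm in c("band_I", "band_II")) {
      d <- tabs[[nm]]$table
      sel <- d$g != 0
      ratio <- abs(d$mean[sel] - tabs[[nm]]$m_c) / abs(d$g[sel])
      expect_lt(diff(range(ratio)) / mean(ratio), 0.12)
    }
  }
})

test_that("the Box-Cox gate passes normal residuals and fixes lognormal ones", {
  # well-behaved ratio data: identity transform
  tab <- gen_reporter(seed = 4, sigma = 0.05)
  st <- gate_and_transform(normalize_ratio(tab))
  expect_null(st$transform_lambda)

  # strongly lognormal ratios with heavy noise: the gate triggers and
  # residual normality improves after transformation
  tab2 <- gen_reporter(seed = 8, ratios = c(1, 0.1, 5, 0.3, 2, 8, 0.05, 1),
                       sigma = 1.1, n = 6)
  st0 <- normalize_ratio(tab2)
  p_before <- nortest::ad.test(
    residuals(lm(value ~ variant, data = st0$data)))$p.value
  st2 <- gate_and_transform(st0)
  expect_false(is.null(st2$transform_lambda))
  p_after <- nortest::ad.test(
    residuals(lm(value ~ variant, data = st2$data)))$p.value
  expect_lt(p_before, 0.05)
  expect_gt(p_after, p_before)
  # back-transformed means are on the original ratio scale
  expect_true(all(st2$back_means > 0))
})
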