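test_that("subgroup summaries match hand-computed t intervals", {
  s <- subgroup_summary(list(a = c(0.5, 0.5, 0.5), b = c(0.2, 0.4)))
  expect_equal(s$k_mean, c(0.5, 0.3))
  expect_equal(s$ci_low[1], 0.5)
  expect_equal(s$ci_high[1], 0.5)
  half <- qt(0.975, df = 1) * sd(c(0.2, 0.4)) / sqrt(2)  # 12.706 * 0.1
  expect_equal(s$ci_low[2], 0.3 - half)
  expect_equal(s$ci_high[2], 0.3 + half)
  expect_true(all(s$ci_low <= s$k_mean & s$k_mean <= s$ci_high))
  expect_error(subgroup_summary(list(a = c(1, 2), b = 3)), "fewer than 2.*b")
})

test_that("one-way ANOVA matches hand computation and stats::aov", {
  a <- one_way_anova(list(g1 = c(1, 2, 3), g2 = c(2, 3, 4)))
  expect_equal(a$f_stat, 1.5)
  expect_identical(c(a$df_between, a$df_within), c(1L, 4L))
  expect_equal(a$mse, 1)

  # equal means, nonzero within-variance: F = 0
  a0 <- one_way_anova(list(g1 = c(1, 3), g2 = c(0, 4)))
  expect_equal(a0$f_stat, 0)
  expect_equal(a0$p_value, 1)

  # cross-check against the reference implementation on random unbalanced data
  set.seed(21)
  x <- rnorm(60, mean = rep(c(0, 0.5, 1), times = c(10, 20, 30)))
  g <- rep(c("a", "b", "c"), times = c(10, 20, 30))
  mine <- one_way_anova(x, g)
  ref <- anova(stats::aov(x ~ g))
  expect_equal(mine$f_stat, ref[["F value"]][1])
  expect_equal(mine$p_value, ref[["Pr(>F)"]][1])
  expect_equal(mine$mse, ref[["Mean Sq"]][2])

  expect_error(one_way_anova(list(a = c(1, 1), b = c(1, 1))), "degenerate")
})

test_that("two-group ANOVA is the squared pooled t-test", {
  set.seed(22)
  for (i in 1:5) {
    x1 <- rnorm(8)
    x2 <- rnorm(13, mean = 0.3)
    a <- one_way_anova(list(x1 = x1, x2 = x2))
    tt <- t.test(x1, x2, var.equal = TRUE)
    expect_equal(a$f_stat, unname(tt$statistic)^2)
    expect_equal(a$p_value, tt$p.value)
  }
})

test_that("SMM survival function has its limit and monotonicity properties", {
  # single comparison: exactly the two-sided t tail
  for (nu in c(1, 5, 40, 1129)) {
    for (m in c(0.5, 1.7, 2.5)) {
      expect_equal(smm_sf(m, 1, nu), 2 * pt(m, nu, lower.tail = FALSE),
                   tolerance = 1e-7)
    }
  }
  expect_equal(smm_sf(0, 7, 30), 1)
  # decreasing in m, increasing in k_star
  p_m <- smm_sf(c(1, 2, 3, 4), 15, 100)
  expect_true(all(diff(p_m) < 0))
  p_k <- vapply(c(1, 3, 10, 28), function(k) smm_sf(2.5, k, 100), numeric(1))
  expect_true(all(diff(p_k) > 0))
  expect_error(smm_sf(Inf, 3, 10), "finite")
  expect_error(smm_sf(2, 0, 10), "k_star")
})

test_that("SMM quadrature agrees with a Monte-Carlo oracle on a small grid", {
  set.seed(23)
  n_draw <- 2e5
  for (case in list(c(k = 3, nu = 8), c(k = 10, nu = 60))) {
    k <- case[["k"]]; nu <- case[["nu"]]
    z <- matrix(abs(rnorm(n_draw * k)), ncol = k)
    mmax <- do.call(pmax, as.data.frame(z))
    tstat <- mmax / sqrt(rchisq(n_draw, nu) / nu)
    for (m in c(2, 3)) {
      p_mc <- mean(tstat >= m)
      se <- sqrt(p_mc * (1 - p_mc) / n_draw)
      expect_lt(abs(smm_sf(m, k, nu) - p_mc), 3 * se + 1e-6)
    }
  }
})

test_that("GT2 post hoc reduces to the pooled t-test with two groups", {
  set.seed(24)
  x1 <- rnorm(9)
  x2 <- rnorm(14, mean = 0.4)
  gt2 <- hochberg_gt2(list(a = x1, b = x2))
  tt <- t.test(x1, x2, var.equal = TRUE)
  expect_identical(gt2$k_star, 1)
  expect_equal(gt2$pairs$adjusted_p, tt$p.value, tolerance = 1e-7)
})

test_that("GT2 returns near-1 adjusted p for identical group means", {
  set.seed(25)
  base <- rnorm(12)
  gt2 <- hochberg_gt2(list(a = base + 1, b = base + 1, c = base + 1))
  expect_true(all(gt2$pairs$adjusted_p > 0.999999))
  expect_true(all(!gt2$pairs$significant))
  # adjusted p never below the unadjusted pairwise t p-value (conservatism)
  x <- rnorm(30, rep(c(0, 0.5, 1.5), each = 10))
  g <- rep(c("a", "b", "c"), each = 10)
  gt2b <- hochberg_gt2(x, g)
  raw_p <- 2 * pt(gt2b$pairs$t, gt2b$nu, lower.tail = FALSE)
  expect_true(all(gt2b$pairs$adjusted_p >= raw_p - 1e-10))
  expect_error(hochberg_gt2(list(a = c(1, 2))), "at least 2 groups")
})

test_that("GT2 p-value matrix has the publication shape", {
  set.seed(26)
  gt2 <- hochberg_gt2(list(a = rnorm(10), b = rnorm(10, 2), c = rnorm(10)))
  m <- posthoc_matrix(gt2)
  expect_true(isSymmetric(m))
  expect_equal(diag(m), c(a = 1, b = 1, c = 1))
  ch <- posthoc_matrix(gt2, digits = 3)
  expect_identical(ch["b", "a"], "-")
  expect_identical(ch["a", "a"], ">.99")
})

test_that("Hartley F-max is the variance ratio with a calibrated p-value", {
  h <- hartley_fmax(list(a = c(0, 2, 4), b = c(0, 1, 2)), n_rep = 2000,
                    seed = 5)
  expect_equal(h$f_max, 4)
  expect_gte(h$f_max, 1)

  set.seed(27)
  same <- hartley_fmax(list(a = rnorm(40), b = rnorm(40), c = rnorm(40)),
                       n_rep = 2000, seed = 5)
  expect_lt(same$f_max, 2.5)
  expect_gt(same$p_value, 0.05)

  degen <- hartley_fmax(list(a = c(1, 1, 1), b = rnorm(3)), n_rep = 100)
  expect_true(degen$degenerate)
  expect_identical(degen$f_max, Inf)
})

test_that("Monte-Carlo F-max p-values are near-uniform under the null", {
  set.seed(28)
  sizes <- c(8, 15, 25)
  pvals <- replicate(300, {
    groups <- lapply(sizes, rnorm)
    hartley_fmax(groups, n_rep = 1500)$p_value
  })
  ks <- suppressWarnings(ks.test(pvals, "punif"))
  expect_gt(ks$p.value, 0.01)
})

test_that("ANOVA p-values are uniform under the global null", {
  set.seed(29)
  pvals <- replicate(400, {
    one_way_anova(rnorm(45), rep(c("a", "b", "c"), times = c(10, 15, 20)))$p_value
  })
  ks <- ks.test(pvals, "punif")
  expect_gt(ks$p.value, 0.01)
})

test_that("the two-proportion z-test matches its reference and is antisymmetric", {
  z0 <- two_prop_ztest(30, 100, 30, 100)
  expect_equal(z0$z, 0)
  expect_equal(z0$p_value, 1)

  zt <- two_prop_ztest(30, 100, 5, 100)
  # oracle: z^2 equals the uncorrected chi-squared statistic
  ref <- suppressWarnings(prop.test(c(30, 5), c(100, 100), correct = FALSE))
  expect_equal(zt$z^2, unname(ref$statistic))
  expect_equal(zt$p_value, ref$p.value)

  swapped <- two_prop_ztest(5, 100, 30, 100)
  expect_equal(swapped$z, -zt$z)
  expect_equal(swapped$p_value, zt$p_value)

  degen <- two_prop_ztest(0, 50, 0, 70)
  expect_true(degen$degenerate)
  expect_error(two_prop_ztest(5, 3, 1, 10), "successes")

  unpooled <- two_prop_ztest(30, 100, 5, 100, pooled = FALSE)
  expect_false(isTRUE(all.equal(unpooled$z, zt$z)))
})
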