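test_that("the normality gate routes normal and skewed samples correctly", {
  set.seed(101)
  # normal draws keep the parametric route about 95% of the time
  routes <- replicate(400, normality_gate(rnorm(50))$route)
  expect_gt(mean(routes == "parametric"), 0.9)
  # heavy skew is caught essentially always
  routes <- replicate(200, normality_gate(rexp(50))$route)
  expect_gte(mean(routes == "nonparametric"), 0.95)
  expect_error(normality_gate(c(1, 2)), "n >= 3")
  expect_warning(g <- normality_gate(rep(2, 10)), "constant")
  expect_equal(g$route, "nonparametric")
})

test_that("the paired t statistic matches its closed form", {
  pre <- c(10, 10, 10, 10, 10)
  post <- pre + c(1, 2, 3, 4, 5)
  r <- paired_compare(pre, post)
  d <- post - pre
  expect_equal(r$test, "paired t-test")
  expect_equal(r$statistic, mean(d) / (sd(d) / sqrt(5)), tolerance = 1e-12)
  expect_equal(r$effect_size, mean(d) / sd(d), tolerance = 1e-12)
  expect_match(r$summary_pre, "±")
})

test_that("identical pre and post collapse to t = 0, p = 1", {
  r <- paired_compare(c(1, 2, 3, 4), c(1, 2, 3, 4))
  expect_equal(r$statistic, 0)
  expect_equal(r$p_value, 1)
  expect_false(r$significant)
})

test_that("non-normal differences route to the exact Wilcoxon signed-rank", {
  set.seed(7)
  pre <- rnorm(12)
  post <- pre + rexp(12)^3          # heavily skewed differences
  r <- paired_compare(pre, post)
  if (r$route == "nonparametric") {
    expect_equal(r$test, "Wilcoxon signed-rank")
    expect_match(r$summary_pre, "\\(")
    ref <- suppressWarnings(wilcox.test(post, pre, paired = TRUE, exact = TRUE))
    expect_equal(r$p_value, ref$p.value)
  }
})

test_that("paired-test power matches the rejection rate of simulation", {
  # shift of 1 sd at n = 7
  set.seed(55)
  rej <- mean(replicate(2000, {
    d <- rnorm(7, mean = 1)
    t.test(d)$p.value <= 0.05
  }))
  expect_lt(abs(rej - power_paired(1, n = 7)$power), 0.03)
})

test_that("noncentral-t power and required n behave as published references", {
  expect_equal(power_paired(0.5, n = 34)$power, 0.80, tolerance = 0.01)
  expect_equal(power_paired(0.5, power = 0.8)$n, 34)
  # d -> infinity drives power to 1
  expect_gt(power_paired(50, n = 3)$power, 0.9999)
  # minute effect sizes need n of order 1e5..1e6
  n <- power_paired(0.003, power = 0.8)$n
  expect_gt(n, 1e5); expect_lt(n, 2e6)
  expect_error(power_paired(0.5), "exactly one")
  expect_error(power_paired(0.5, n = 10, power = 0.8), "exactly one")
  expect_error(power_paired(0, power = 0.8), "unbounded")
})

test_that("the repeated-measures ANOVA matches a hand-computed oracle", {
  # balanced 2 x 2 within-subject design, 4 subjects; sums of squares by hand
  set.seed(31)
  ns <- 4; nk <- 2; nc <- 2
  df <- expand.grid(specimen = 1:ns, space = 1:nk, condition = c("pre", "post"))
  df$value <- rnorm(nrow(df), mean = 2 * (df$space == 2) + (df$condition == "post"))
  fit <- rm_anova_spaces(df)

  g <- mean(df$value)
  m_s <- tapply(df$value, df$specimen, mean)
  m_k <- tapply(df$value, df$space, mean)
  m_c <- tapply(df$value, df$condition, mean)
  m_sk <- tapply(df$value, list(df$specimen, df$space), mean)
  m_sc <- tapply(df$value, list(df$specimen, df$condition), mean)
  ss_k <- ns * nc * sum((m_k - g)^2)
  ss_c <- ns * nk * sum((m_c - g)^2)
  ss_sk <- nc * sum((m_sk - outer(m_s, m_k, "+") + g)^2)
  ss_sc <- nk * sum((m_sc - outer(m_s, m_c, "+") + g)^2)
  F_k <- (ss_k / (nk - 1)) / (ss_sk / ((ns - 1) * (nk - 1)))
  F_c <- (ss_c / (nc - 1)) / (ss_sc / ((ns - 1) * (nc - 1)))

  tb <- fit$table
  expect_equal(tb$F[tb$effect == "space"], F_k, tolerance = 1e-6)
  expect_equal(tb$F[tb$effect == "condition"], F_c, tolerance = 1e-6)
  expect_equal(tb$p[tb$effect == "space"],
               pf(F_k, nk - 1, (ns - 1) * (nk - 1), lower.tail = FALSE),
               tolerance = 1e-6)
  # 2-level factors admit no sphericity violation: epsilon = 1
  expect_equal(tb$epsilon_gg[tb$effect == "condition"], 1, tolerance = 1e-9)
  # Tukey on 2 levels reduces to the F test's p-value
  expect_equal(fit$tukey$condition$p_adj,
               pf(F_c, 1, ns - 1, lower.tail = FALSE), tolerance = 1e-6)
})

test_that("incomplete or unbalanced tables are refused without imputation", {
  df <- expand.grid(specimen = 1:3, space = 1:2, condition = c("pre", "post"))
  df$value <- rnorm(nrow(df))
  expect_error(rm_anova_spaces(df[-1, ]), "unbalanced|incomplete")
  expect_error(rm_anova_spaces(df[, -4]), "columns")
})

test_that("injected per-space heterogeneity is detected by the space factor", {
  set.seed(77)
  hits <- replicate(40, {
    df <- expand.grid(specimen = 1:7, space = 1:8, condition = c("pre", "post"))
    offs <- seq(-1.5, 1.5, length.out = 8)   # 3 sd span across spaces
    df$value <- rnorm(nrow(df), mean = offs[df$space], sd = 1)
    tb <- rm_anova_spaces(df)$table
    tb$p[tb$effect == "space"] < 0.01
  })
  expect_gte(mean(hits), 0.95)
})
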