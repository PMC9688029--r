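test_that("KS statistic matches its brute-force definition", {
  expect_equal(ks_two_sample(c(1, 5, 9), c(1, 5, 9))$statistic, 0)
  expect_equal(ks_two_sample(1:5, 6:10)$statistic, 1)
  expect_equal(ks_two_sample(c(1, 2, 3), c(2, 3, 4))$statistic, 1 / 3,
               tolerance = 1e-12)
  # against the reference implementation's asymptotic p-value
  set.seed(4)
  x <- stats::rnorm(80)
  y <- stats::rnorm(90, 0.3)
  ours <- ks_two_sample(x, y)
  ref <- suppressWarnings(stats::ks.test(x, y, exact = FALSE))
  expect_equal(ours$statistic, unname(ref$statistic), tolerance = 1e-12)
  expect_equal(ours$p_value, ref$p.value, tolerance = 1e-6)
  expect_error(ks_two_sample(numeric(0), 1:3), "non-empty")
})

test_that("KS test is symmetric and invariant to monotone transforms", {
  set.seed(11)
  for (i in 1:5) {
    x <- stats::rlnorm(40)
    y <- stats::rlnorm(50, 0.4)
    a <- ks_two_sample(x, y)
    b <- ks_two_sample(y, x)
    expect_equal(a$statistic, b$statistic)
    expect_equal(a$p_value, b$p_value)
    tr <- ks_two_sample(log(x), log(y))
    expect_equal(a$statistic, tr$statistic)
  }
})

test_that("Welch's F collapses to t-squared and to classical ANOVA", {
  set.seed(7)
  g2 <- list(a = stats::rnorm(25, 0, 1), b = stats::rnorm(35, 0.5, 2))
  w <- welch_anova(g2)
  tt <- stats::t.test(g2$a, g2$b)
  expect_equal(w$statistic, unname(tt$statistic)^2, tolerance = 1e-10)
  expect_equal(w$p_value, tt$p.value, tolerance = 1e-10)
  expect_equal(w$df2, unname(tt$parameter), tolerance = 1e-8)

  # identical groups: no effect at all
  same <- list(a = c(1, 2, 3, 4), b = c(1, 2, 3, 4))
  w0 <- welch_anova(same)
  expect_equal(w0$statistic, 0)
  expect_equal(w0$p_value, 1)

  # equal variances and sizes: Welch F approaches the classical one-way F
  # (the Satterthwaite correction leaves a small finite-sample gap)
  g3 <- list(a = stats::rnorm(40), b = stats::rnorm(40, 0.3),
             c = stats::rnorm(40, 0.6))
  g3 <- lapply(g3, function(v) (v - mean(v)) / stats::sd(v) + mean(v))
  w3 <- welch_anova(g3)
  d <- data.frame(value = unlist(g3),
                  group = rep(names(g3), lengths(g3)))
  f_classic <- summary(stats::aov(value ~ group, d))[[1]]$`F value`[1]
  expect_equal(w3$statistic, f_classic, tolerance = 0.02)

  expect_error(welch_anova(list(a = c(1, 1, 1), b = c(1, 2, 3))),
               "zero-variance")
  expect_error(welch_anova(list(a = 1:3)), "two groups")
})

test_that("Games-Howell reduces to the Welch pairwise test for two groups", {
  set.seed(9)
  g2 <- list(a = stats::rnorm(20), b = stats::rnorm(30, 1, 2))
  gh <- games_howell(g2)
  tt <- stats::t.test(g2$a, g2$b)
  expect_equal(nrow(gh), 1L)
  expect_equal(gh$p_adj, tt$p.value, tolerance = 1e-8)
  expect_equal(gh$df, unname(tt$parameter), tolerance = 1e-8)
  expect_equal(gh$diff, unname(diff(rev(tt$estimate))), tolerance = 1e-12)
})

test_that("Games-Howell flags only truly shifted groups", {
  set.seed(15)
  groups <- list(a = stats::rnorm(50), b = stats::rnorm(50),
                 c = stats::rnorm(50, 10))  # c shifted by 10 SD
  gh <- games_howell(groups)
  with_c <- gh$group1 == "c" | gh$group2 == "c"
  expect_true(all(gh$p_adj[with_c] < 0.05))
  expect_true(all(gh$p_adj[!with_c] > 0.05))
  # identical groups: all adjusted p at 1
  same <- list(a = c(1, 2, 3, 4, 5), b = c(1, 2, 3, 4, 5),
               c = c(1, 2, 3, 4, 5))
  gh0 <- games_howell(same)
  expect_true(all(gh0$p_adj > 1 - 1e-9))
  expect_true(all(abs(gh0$diff) < 1e-12))
})

test_that("sex-ratio chi-square follows its closed forms", {
  r0 <- sex_ratio_test(100, 100)
  expect_equal(r0$ratio, 1)
  expect_equal(r0$chi_square, 0)
  # total asymmetry: chi-square equals the sample size
  r1 <- sex_ratio_test(0, 80)
  expect_equal(r1$chi_square, 80)
  expect_equal(r1$ratio, 0)
  # the study's ratio at smaller n: 54^2/146 * 2 halves... = 1458/73
  r2 <- sex_ratio_test(46, 100)
  expect_equal(r2$ratio, 0.46)
  expect_equal(r2$chi_square, (46 - 73)^2 / 73 + (100 - 73)^2 / 73,
               tolerance = 1e-12)
  expect_equal(r2$chi_square, 19.97, tolerance = 1e-2)
  # swapping sexes leaves the statistic unchanged
  expect_equal(sex_ratio_test(30, 70)$chi_square,
               sex_ratio_test(70, 30)$chi_square)
  # all-male stratum: infinite ratio, test still computed
  r3 <- sex_ratio_test(12, 0)
  expect_true(is.infinite(r3$ratio))
  expect_equal(r3$chi_square, 12)
  expect_error(sex_ratio_test(0, 0), "> 0")
})

test_that("stratified sex-ratio table flags low-n strata", {
  tab <- sex_ratio_by_stratum(data.frame(
    stratum = c("0-50", "51-100", "101-150"),
    males = c(3, 40, 25), females = c(4, 60, 50)))
  expect_equal(tab$low_n, c(TRUE, FALSE, FALSE))
  expect_equal(tab$ratio[2], 40 / 60)
})
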