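test_that("min-max normalization follows its definition", {
  expect_equal(minmax_normalize(c(2, 4, 6)), c(0, 0.5, 1))
  expect_equal(minmax_normalize(c(0.47, 0.25, 0.22)), c(1, 0.12, 0),
               tolerance = 1e-12)
  # affine invariance and idempotence
  x <- c(3.2, 9.1, 4.4, 7.7)
  expect_equal(minmax_normalize(5 * x - 2), minmax_normalize(x))
  expect_equal(minmax_normalize(minmax_normalize(x)), minmax_normalize(x))
  expect_warning(const <- minmax_normalize(c(2, 2, 2)), "constant")
  expect_equal(const, c(0.5, 0.5, 0.5))
  expect_error(minmax_normalize(numeric(0)), "non-empty")
  expect_error(minmax_normalize(c(1, NA)), "finite")
})

test_that("balanced noiseless design returns injected year effects exactly", {
  fp <- fleet_params(year_effects = c(`2000` = 1, `2001` = 2, `2002` = 4),
                     lognormal_sd = 0, p_zero = 0)
  tr <- simulate_trip_records(fp, 4000, 3)
  idx <- standardize_cpue_hurdle(tr)
  expect_equal(idx$index / idx$index[1], c(1, 2, 4), tolerance = 1e-9)
  expect_equal(idx$norm, c(0, 1 / 3, 1))
})

test_that("hurdle path produces finite indices and sensible attributes", {
  fp <- fleet_params(year_effects = c(`2000` = 1, `2001` = 2, `2002` = 4))
  tr <- simulate_trip_records(fp, 5000, 4)
  idx <- standardize_cpue_hurdle(tr, index_name = "LPUE")
  expect_s3_class(idx, "abundance_index")
  expect_true(all(is.finite(idx$index)))
  expect_true(all(idx$se > 0))
  expect_equal(range(idx$norm), c(0, 1))
  expect_equal(attr(idx, "index_name"), "LPUE")
  # ordering of the standardized index follows the injected effects
  expect_true(all(diff(idx$index) > 0))
})

test_that("single-year data yield a defined one-point series", {
  fp <- fleet_params(year_effects = c(`2005` = 1), lognormal_sd = 0.2,
                     p_zero = 0.2)
  tr <- simulate_trip_records(fp, 400, 6)
  expect_message(idx <- standardize_cpue_hurdle(tr), "single year")
  expect_equal(nrow(idx), 1L)
  expect_equal(idx$norm, 0.5)
})

test_that("standardization validates its inputs", {
  fp <- fleet_params()
  tr <- simulate_trip_records(fp, 200, 1)
  expect_error(standardize_cpue_hurdle(tr, factors = c("quarter")), "year")
  expect_error(standardize_cpue_hurdle(tr, effort_col = "days"), "effort")
  bad <- tr; bad$catch[1] <- -5
  expect_error(standardize_cpue_hurdle(bad), "catch")
})

test_that("identical series give a null ANCOVA comparison", {
  yrs <- 2000:2009
  base <- 1 - 0.05 * seq_along(yrs) + 0.1 * sin(seq_along(yrs))
  d <- data.frame(index = rep(c("A", "B", "C"), each = length(yrs)),
                  year = rep(yrs, 3), value = rep(base, 3))
  tc <- compare_trends_ancova(d)
  expect_lt(tc$ancova["year:index", "F value"], 1e-10)
  expect_true(tc$parallel)
  expect_true(all(abs(tc$tukey$estimate) < 1e-10))
  expect_true(all(tc$tukey$p_adj > 0.999))
  # degrees of freedom account for every observation
  expect_equal(sum(tc$ancova$Df), nrow(d) - 1)
})

test_that("a parallel offset is found in the intercepts, not the slopes", {
  set.seed(2)
  yrs <- 2000:2012
  base <- 1 - 0.04 * seq_along(yrs)
  # noise residualized against year within each index, so the three lines
  # are exactly parallel and only the intercepts differ
  mk <- function(nm, off) {
    e <- stats::rnorm(length(yrs), 0, 0.02)
    e <- stats::resid(stats::lm(e ~ yrs))
    data.frame(index = nm, year = yrs, value = base + off + e)
  }
  d <- rbind(mk("CPUE", 0), mk("LPUE", 0), mk("RPN", 0.3))
  tc <- compare_trends_ancova(d)
  expect_gte(tc$interaction_p, 0.05)
  rpn_rows <- grepl("RPN", tc$tukey$contrast)
  expect_true(all(tc$tukey$p_adj[rpn_rows] < 0.05))
  expect_true(all(tc$tukey$p_adj[!rpn_rows] > 0.05))
})

test_that("opposite slopes break parallelism", {
  yrs <- 2000:2009
  set.seed(3)
  d <- rbind(
    data.frame(index = "up", year = yrs,
               value = 0.1 * seq_along(yrs) + stats::rnorm(10, 0, 1e-3)),
    data.frame(index = "down", year = yrs,
               value = 1 - 0.1 * seq_along(yrs) + stats::rnorm(10, 0, 1e-3)))
  tc <- compare_trends_ancova(d)
  expect_lt(tc$interaction_p, 0.05)
  expect_false(tc$parallel)
  expect_null(tc$tukey)
})

test_that("trend comparison enforces overlap and length preconditions", {
  d_short <- data.frame(index = rep(c("A", "B"), each = 2),
                        year = c(2000, 2001, 2000, 2001),
                        value = c(1, 2, 2, 3))
  expect_error(compare_trends_ancova(d_short), "3 years")
  d_disjoint <- data.frame(index = rep(c("A", "B"), each = 4),
                           year = c(2000:2003, 2010:2013),
                           value = stats::runif(8))
  expect_error(compare_trends_ancova(d_disjoint), "disjoint")
})
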