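# noiseless counts constructed as N ~ exp(-Z t_mid) * dt over 5 cm bins
construct_counts <- function(z, p, lower = seq(40, 160, by = 5), scale = 1e6) {
  mid <- lower + 2.5
  tm <- inverse_vbgf_age_at_length(p, mid)
  dt <- inverse_vbgf_age_at_length(p, lower + 5) -
    inverse_vbgf_age_at_length(p, lower)
  stats::setNames(scale * exp(-z * tm) * dt, lower)
}

test_that("catch curve inverts its own construction exactly", {
  p <- vbgf_params(171.62, 0.12)
  cc <- length_converted_catch_curve(construct_counts(0.47, p), p,
                                     bin_width = 5)
  expect_equal(cc$z, 0.47, tolerance = 1e-9)
  # flat construction: counts proportional to dt alone -> slope ~ 0
  cc0 <- length_converted_catch_curve(construct_counts(0, p), p,
                                      bin_width = 5)
  expect_lt(abs(cc0$z), 1e-10)
})

test_that("catch curve Z is invariant to count rescaling", {
  p <- vbgf_params(171.62, 0.12)
  n1 <- construct_counts(0.6, p)
  cc1 <- length_converted_catch_curve(n1, p, bin_width = 5)
  cc3 <- length_converted_catch_curve(n1 * 37, p, bin_width = 5)
  expect_equal(cc1$z, cc3$z, tolerance = 1e-12)
  expect_equal(cc1$points$selected, cc3$points$selected)
})

test_that("catch curve enforces its preconditions and warnings", {
  p <- vbgf_params(100, 0.3)
  counts <- stats::setNames(c(5, 50, 20, 0, 8, 6), seq(40, 65, 5))
  expect_warning(length_converted_catch_curve(counts, p, bin_width = 5),
                 "zero-count")
  few <- stats::setNames(c(10, 5, 2), seq(40, 50, 5))
  expect_error(
    suppressWarnings(length_converted_catch_curve(few, p, bin_width = 5)),
    "fewer than 3")
  # bins above linf are dropped with a warning
  high <- stats::setNames(exp(seq(5, 1, length.out = 14)), seq(40, 105, 5))
  expect_warning(length_converted_catch_curve(high, p, bin_width = 5),
                 "above linf")
})

test_that("catch curve recovers the generator's total mortality", {
  pp <- population_params(linf_mean = 171.62, linf_cv = 0.025, k = 0.12,
                          z = 0.5, recruits_per_pulse = 5000, n_years = 25)
  pop <- simulate_population(pp, 13)
  expect_gte(nrow(pop), 1e5)
  x <- sample_lfq(pop, selectivity = c(l50 = 40, slope = Inf),
                  dates = monthly_dates(12, "2014-01-01"), seed = 2)
  cc <- suppressWarnings(
    length_converted_catch_curve(x, vbgf_params(171.62, 0.12)))
  expect_lt(abs(cc$z - 0.5) / 0.5, 0.1)
})

test_that("natural-mortality battery reproduces closed-form rows", {
  nm <- natural_mortality_battery(171.62, 0.12)
  tab <- stats::setNames(nm$table$m, nm$table$method)
  expect_equal(unname(tab["Jensen (1996) 1.6k"]), 0.192)
  expect_equal(unname(tab["Hoenig (1983)"]), 3 / 25, tolerance = 1e-12)
  expect_equal(unname(tab["Cubillos et al. (1999)"]), 1.4 * 0.12)
  expect_equal(nm$inputs$tmax, 25)
  expect_equal(nm$mean_m, mean(nm$table$m))
  expect_equal(nrow(nm$table), 14L)
  # the canonical log10 form of Pauly (1980) is available as an option
  nm10 <- natural_mortality_battery(171.62, 0.13, pauly = "log10")
  lin <- -0.0066 - 0.279 * log10(171.62) + 0.6543 * log10(0.13) +
    0.4634 * log10(18)
  expect_equal(nm10$table$m[5], 10^lin, tolerance = 1e-12)
  expect_error(natural_mortality_battery(-1, 0.1), "positive")
})

test_that("the tmax-only estimators keep their numerator ordering", {
  for (tmax in c(3, 12.5, 60)) {
    nm <- natural_mortality_battery(150, 0.2, tmax = tmax)
    tab <- stats::setNames(nm$table$m, nm$table$method)
    expect_true(tab["Taylor (1960)"] <= tab["Tanaka (1960)"])
    expect_true(tab["Tanaka (1960)"] <= tab["Frisk (2001)"])
    expect_true(tab["Frisk (2001)"] <= tab["Alagaraja (1984)"])
    expect_true(tab["Alagaraja (1984)"] <= tab["Beverton and Holt (1959)"])
  }
})

test_that("F = Z - M with an explicit implausibility flag", {
  f <- fishing_mortality(0.47, 0.22)
  expect_equal(as.numeric(f), 0.25)
  expect_false(attr(f, "implausible"))
  expect_equal(as.numeric(fishing_mortality(0.3, 0.3)), 0)
  expect_warning(f_neg <- fishing_mortality(0.2, 0.3), "implausible")
  expect_equal(as.numeric(f_neg), -0.1)
  expect_true(attr(f_neg, "implausible"))
})

test_that("exploitation rate maps F = M to one half and is monotone", {
  expect_equal(exploitation_rate(0.25, 0.22), 0.25 / 0.47, tolerance = 1e-12)
  expect_equal(exploitation_rate(0, 0.2), 0)
  expect_equal(exploitation_rate(0.31, 0.31), 0.5)
  e <- vapply(seq(0, 2, by = 0.1), exploitation_rate, numeric(1), m = 0.22)
  expect_true(all(diff(e) > 0))
  expect_error(exploitation_rate(0, 0), "positive")
  expect_error(exploitation_rate(-0.1, 0.2), ">= 0")
})
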