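test_that("generators are pure functions of parameters and seed", {
  pp <- population_params(recruits_per_pulse = 200, n_years = 5)
  expect_identical(simulate_population(pp, 3), simulate_population(pp, 3))
  sp <- spatial_field_params()
  expect_identical(simulate_survey_records(sp, 100, 9),
                   simulate_survey_records(sp, 100, 9))
  fp <- fleet_params()
  expect_identical(simulate_trip_records(fp, 100, 5),
                   simulate_trip_records(fp, 100, 5))
})

test_that("without mortality every annual cohort survives intact", {
  pp <- population_params(z = 0, recruits_per_pulse = 150, n_years = 8)
  pop <- simulate_population(pp, 1)
  expect_true(all(pop$alive))
  counts <- table(floor(pop$age))
  expect_true(all(counts == 150))
})

test_that("mean length at age matches the VBGF and survival is exponential", {
  pp <- population_params(linf_mean = 171.62, k = 0.12, z = 0.47,
                          recruits_per_pulse = 20000, n_years = 10)
  pop <- simulate_population(pp, 11)
  expect_gte(nrow(pop), 1e5)
  # alive fish of the age-5 cohort: selection is independent of length
  age5 <- pop[abs(pop$age - 5) < 1e-9 & pop$alive, ]
  expect_gt(nrow(age5), 1000)
  expect_equal(mean(age5$length), 171.62 * (1 - exp(-0.12 * 5)),
               tolerance = 0.005)
  # no fish exceeds its individual asymptote
  expect_true(all(pop$length <= pop$linf_i + 1e-12))
  # empirical survival vs exp(-z t), within binomial error
  for (a in c(2, 5, 8)) {
    coh <- pop[abs(pop$age - a) < 1e-9, ]
    p_hat <- mean(coh$alive)
    p_true <- exp(-0.47 * a)
    expect_lt(abs(p_hat - p_true),
              4 * sqrt(p_true * (1 - p_true) / nrow(coh)))
  }
})

test_that("length sampling bins, selects and conserves counts correctly", {
  # a single fish of 87 cm lands in the [85, 90) bin
  ind <- manual_individuals(87, "2000-06-01")
  x <- sample_lfq(ind, selectivity = c(l50 = 0, slope = Inf), bin_width = 5,
                  dates = as.Date("2000-06-01"), k = 1,
                  bins = seq(85, 95, by = 5), seed = 1)
  expect_equal(unname(x$counts[, 1]), c(1, 0, 0))
  expect_equal(x$bin_lower, c(85, 90, 95))

  # knife edge at 0 counts every fish alive at the date
  pop <- light_pop()
  d1 <- monthly_dates(1)
  full <- sample_lfq(pop, selectivity = c(l50 = 0, slope = Inf),
                     dates = d1, seed = 3)
  dy <- 2018
  n_alive <- sum(pop$birth_time < dy & dy - pop$birth_time <= pop$death_age)
  expect_equal(sum(full$counts), n_alive)

  # knife edge at 100 retains the above-100 fraction of the same population
  above <- sample_lfq(pop, selectivity = c(l50 = 100, slope = Inf),
                      dates = d1, seed = 3)
  alive_len <- pop$linf_i[pop$birth_time < dy &
                            dy - pop$birth_time <= pop$death_age] *
    (1 - exp(-0.12 * (dy - pop$birth_time[pop$birth_time < dy &
                                            dy - pop$birth_time <= pop$death_age])))
  expect_equal(sum(above$counts) / n_alive, mean(alive_len >= 100),
               tolerance = 1e-12)

  # logistic retention conserves counts across bins and dates
  x24 <- light_lfq()
  expect_true(all(x24$counts >= 0))
  expect_true(all(x24$counts == round(x24$counts)))

  # empty table with declared bins is an all-zero table, not an error
  empty <- sample_lfq(manual_individuals(numeric(0), "2000-06-01"),
                      selectivity = c(l50 = 0, slope = Inf),
                      dates = as.Date("2000-06-01"), k = 1,
                      bins = seq(40, 60, 5), seed = 1)
  expect_true(all(empty$counts == 0))
  expect_equal(length(empty$bin_lower), 5)
})

test_that("survey generator produces the declared spatial structure", {
  # deterministic positives when noise and zero inflation are off
  sp0 <- spatial_field_params(zero_inflation = 0, noise_sd = 0)
  sv0 <- simulate_survey_records(sp0, 400, 2)
  g <- -(sv0$depth - sp0$depth_opt)^2 / (2 * sp0$depth_sd^2) +
    sp0$substrate_effects[sv0$substrate]
  expect_equal(sv0$rpn, unname(exp(log(sp0$mean_positive_rpn) + g)),
               tolerance = 1e-12)

  # higher presence at the depth optimum than 4 SDs away
  sp <- spatial_field_params()
  sv <- simulate_survey_records(sp, 30000, 4)
  at_opt <- sv$depth > 250 & sv$depth < 350
  far <- sv$depth > 550
  expect_gt(mean(sv$rpn[at_opt] > 0), mean(sv$rpn[far] > 0))
  expect_gt(mean(sv$rpn[at_opt] > 0), 0.15)
  expect_lt(mean(sv$rpn[far] > 0), 0.02)

  expect_error(spatial_field_params(substrate_effects = c(Lava = 1)),
               "categories")
  expect_error(spatial_field_params(depth_opt = 700), "surveyed range")
})

test_that("trip generator injects multiplicative factor effects", {
  # degenerate fleet: every positive catch rate identical
  fp0 <- fleet_params(year_effects = c(`2000` = 1, `2001` = 1),
                      quarter_effects = c(`1` = 1), vessel_effects = c(a = 1),
                      gear_effects = c(g = 1), lognormal_sd = 0, p_zero = 0)
  tr0 <- simulate_trip_records(fp0, 500, 6)
  expect_equal(length(unique(round(tr0$catch / tr0$effort, 10))), 1L)

  # year effects doubling -> annual geometric means of positive cpue double
  fp2 <- fleet_params(year_effects = c(`2000` = 1, `2001` = 2, `2002` = 4),
                      lognormal_sd = 0.4, p_zero = 0.2)
  tr2 <- simulate_trip_records(fp2, 30000, 8)
  pos <- tr2[tr2$catch > 0, ]
  gm <- tapply(log(pos$catch / pos$effort), pos$year, mean)
  expect_equal(as.numeric(exp(diff(as.vector(gm)))), c(2, 2),
               tolerance = 0.05)

  expect_error(fleet_params(year_effects = numeric(0)), "non-empty")
})
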