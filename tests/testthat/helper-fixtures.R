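# shared fixtures, built in code

# small simulated population + monthly samples, memoized per test run
fixture_env <- new.env(parent = emptyenv())

light_pop <- function() {
  if (is.null(fixture_env$pop)) {
    fixture_env$pop <- simulate_population(
      population_params(linf_mean = 170, k = 0.12, z = 0.22,
                        recruits_per_pulse = 3000),
      seed = 42)
  }
  fixture_env$pop
}

monthly_dates <- function(n = 24, from = "2018-01-01")
  seq(as.Date(from), by = "month", length.out = n)

light_lfq <- function() {
  if (is.null(fixture_env$lfq)) {
    fixture_env$lfq <- sample_lfq(light_pop(),
                                  selectivity = c(l50 = 40, slope = 0.3),
                                  dates = monthly_dates(), seed = 7)
  }
  fixture_env$lfq
}

# hand-built restructured table with prescribed scores (for scoring oracles)
manual_restructured <- function(scores, bin_lower, dates) {
  scores <- as.matrix(scores)
  structure(list(counts = pmax(scores, 0), bin_lower = bin_lower,
                 bin_width = diff(bin_lower)[1], dates = as.Date(dates),
                 scores = scores, asp = sum(scores[scores > 0]), ma = 5),
            class = c("lfq_restructured", "lfq"))
}

# individuals table for hand-placed fish (k = 1, length via individual linf)
manual_individuals <- function(lengths_at_date, date, linf_i = 100, k = 1) {
  dy <- as.integer(format(as.Date(date), "%Y")) +
    (as.integer(format(as.Date(date), "%m")) - 1) / 12
  age <- -log(1 - lengths_at_date / linf_i) / k
  data.frame(birth_time = dy - age,
             linf_i = rep(linf_i, length.out = length(age)),
             death_age = rep(Inf, length.out = length(age)))
}
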