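#' Parameters of the simulated population
#'
#' Defines the generative population that the growth and mortality analyses
#' are tested against: annual recruitment pulses, individual von Bertalanffy
#' growth with lognormal variability on the asymptotic length (k shared so
#' growth curves do not cross in expectation), exponential survival at total
#' mortality rate `z`, logistic gear selectivity and a female-biased sex
#' ratio. Defaults are the study conditions for the Azorean silver
#' scabbardfish: `linf_mean = 171.62` cm, `k = 0.12` year^-1, `z = 0.47`
#' year^-1 and a 0.46:1 male:female ratio (`prop_female = 0.685`).
#'
#' @param linf_mean Mean asymptotic length (cm) of the individual L-infinity
#'   distribution.
#' @param linf_cv Coefficient of variation of individual L-infinity
#'   (dimensionless). Individual `linf` ~ lognormal with this mean and CV.
#' @param k Shared growth coefficient (year^-1).
#' @param z Total mortality rate (year^-1); age at death ~ Exponential(z).
#' @param recruits_per_pulse Recruits entering at each annual pulse.
#' @param pulse_month Calendar month (1-12) of the recruitment pulse.
#' @param n_years Years simulated before the reference sampling time.
#' @param selectivity_l50 Length at 50% gear retention (cm).
#' @param selectivity_slope Steepness of the logistic retention curve (cm^-1).
#' @param prop_female Fraction of recruits that are female, in `[0, 1]`.
#' @param start_year First calendar year of the simulation.
#' @return An object of class `"population_params"`.
#' @export
population_params <- function(linf_mean = 171.62, linf_cv = 0.025, k = 0.12,
                              z = 0.47, recruits_per_pulse = 4000,
                              pulse_month = 1, n_years = 30,
                              selectivity_l50 = 85, selectivity_slope = 0.3,
                              prop_female = 0.685, start_year = 1990) {
  p <- list(linf_mean = linf_mean, linf_cv = linf_cv, k = k, z = z,
            recruits_per_pulse = recruits_per_pulse,
            pulse_month = pulse_month, n_years = n_years,
            selectivity_l50 = selectivity_l50,
            selectivity_slope = selectivity_slope,
            prop_female = prop_female, start_year = start_year)
  num <- vapply(p, function(v) is.numeric(v) && length(v) == 1L && is.finite(v),
                logical(1))
  if (!all(num)) stop("all population parameters must be finite scalars")
  if (linf_mean <= 0 || k <= 0) stop("'linf_mean' and 'k' must be positive")
  if (z < 0) stop("'z' must be >= 0")
  if (linf_cv < 0) stop("'linf_cv' must be >= 0")
  if (prop_female < 0 || prop_female > 1) stop("'prop_female' must be in [0, 1]")
  if (selectivity_slope <= 0) stop("'selectivity_slope' must be positive")
  if (pulse_month < 1 || pulse_month > 12) stop("'pulse_month' must be 1-12")
  if (recruits_per_pulse < 1 || n_years < 1)
    stop("'recruits_per_pulse' and 'n_years' must be >= 1")
  structure(p, class = "population_params")
}

#' Simulate an age-structured fish population
#'
#' Generates one individual row per recruit over `n_years` annual pulses.
#' Individual asymptotic length is lognormal with mean `linf_mean` and CV
#' `linf_cv`; age at death is Exponential(`z`) so survival to age t is
#' proportional to `exp(-z t)`; sex is Bernoulli(`prop_female`). Ages,
#' lengths and the alive flag are evaluated at the reference time
#' `start_year + n_years` (start of year). Deterministic given `seed`.
#'
#' @param params A [population_params()] object.
#' @param seed Integer seed.
#' @return A data frame with columns `id`, `cohort` (birth year),
#'   `birth_time` (decimal year), `sex` (`"F"`/`"M"`), `linf_i` (individual
#'   asymptotic length, cm), `death_age` (years), `age` (years at the
#'   reference time), `length` (cm at `min(age, death_age)`) and `alive`
#'   (alive at the reference time). Attributes `params` and `ref_time` are
#'   attached.
#' @export
simulate_population <- function(params, seed) {
  stopifnot(inherits(params, "population_params"))
  set.seed(seed)
  R <- params$recruits_per_pulse
  births <- rep(params$start_year + seq_len(params$n_years) - 1 +
                  (params$pulse_month - 1) / 12, each = R)
  n <- length(births)
  sdlog <- sqrt(log(1 + params$linf_cv^2))
  meanlog <- log(params$linf_mean) - sdlog^2 / 2
  linf_i <- if (sdlog > 0) stats::rlnorm(n, meanlog, sdlog) else
    rep(params$linf_mean, n)
  death_age <- if (params$z > 0) stats::rexp(n, params$z) else rep(Inf, n)
  sex <- ifelse(stats::runif(n) < params$prop_female, "F", "M")
  ref <- params$start_year + params$n_years
  age <- ref - births
  out <- data.frame(
    id = seq_len(n), cohort = floor(births), birth_time = births, sex = sex,
    linf_i = linf_i, death_age = death_age, age = age,
    length = linf_i * (1 - exp(-params$k * pmin(age, death_age))),
    alive = age > 0 & age <= death_age)
  attr(out, "params") <- params
  attr(out, "ref_time") <- ref
  out
}

# logistic retention; slope = Inf means knife edge at l50
retention_prob <- function(L, l50, slope) {
  if (is.infinite(slope)) as.numeric(L >= l50) else stats::plogis(slope * (L - l50))
}

#' Sample length frequencies from a simulated population
#'
#' For each sampling date, individuals alive on that date are grown to the
#' date with their individual VBGF curve, retained with logistic gear
#' selectivity probability `plogis(slope * (L - l50))`, and binned into
#' uniform left-closed, right-open length classes labelled by lower edge.
#'
#' @param individuals A data frame from [simulate_population()] (columns
#'   `birth_time`, `linf_i`, `death_age` are required).
#' @param selectivity Named vector `c(l50 = , slope = )`; `slope = Inf`
#'   gives a knife edge at `l50`.
#' @param bin_width Bin width in cm (default 5, the study's class interval).
#' @param dates `Date` vector of sampling occasions (month resolution).
#' @param k Growth coefficient; taken from the population's parameters when
#'   `NULL`.
#' @param bins Optional declared lower bin edges; when `NULL`, bins are
#'   aligned to multiples of `bin_width` and span the retained lengths. An
#'   empty individual table with declared `bins` yields an all-zero table.
#' @param seed Integer seed for the retention draws.
#' @return An [lfq()] object.
#' @export
sample_lfq <- function(individuals, selectivity = c(l50 = 85, slope = 0.3),
                       bin_width = 5, dates, k = NULL, bins = NULL,
                       seed = 1) {
  stopifnot(length(dates) >= 1L, bin_width > 0)
  dates <- sort(as.Date(dates))
  if (is.null(k)) {
    pp <- attr(individuals, "params")
    if (is.null(pp)) stop("'k' must be given when 'individuals' carries no parameters")
    k <- pp$k
  }
  set.seed(seed)
  dy <- decimal_date(dates)
  keepL <- vector("list", length(dates))
  for (j in seq_along(dates)) {
    a <- dy[j] - individuals$birth_time
    alive <- a > 0 & a <= individuals$death_age
    L <- individuals$linf_i[alive] * (1 - exp(-k * a[alive]))
    p <- retention_prob(L, selectivity[["l50"]], selectivity[["slope"]])
    keepL[[j]] <- L[stats::runif(length(L)) < p]
  }
  allL <- unlist(keepL)
  if (is.null(bins)) {
    if (!length(allL))
      stop("no individuals retained and no declared 'bins' to report")
    lo <- floor(min(allL) / bin_width) * bin_width
    hi <- floor(max(allL) / bin_width) * bin_width
    bins <- seq(lo, hi, by = bin_width)
  }
  if (length(bins) < 2L)
    bins <- c(bins, bins[length(bins)] + bin_width)
  counts <- matrix(0, length(bins), length(dates))
  for (j in seq_along(dates)) {
    i <- floor((keepL[[j]] - bins[1]) / bin_width) + 1
    i <- i[i >= 1 & i <= length(bins)]
    if (length(i)) counts[, j] <- tabulate(i, nbins = length(bins))
  }
  lfq(counts, bins, dates)
}

#' Seven-level substrate classification used by the survey
#' @format Character vector of the seven seabed substrate categories.
#' @export
substrate_levels <- c("C.Sed", "Mix.Sed", "Mud", "Mud.S", "Rock", "Sand", "Sand.M")

#' Parameters of the zero-inflated spatial abundance field
#'
#' The survey generator places stations over a depth-stratified design and
#' draws presence from a Bernoulli whose logit is a Gaussian bump in depth
#' plus a substrate effect; positive catch rates are lognormal around the
#' same depth/substrate surface. `zero_inflation` is the zero fraction at
#' the depth optimum on the reference substrate; away from the optimum the
#' zero fraction rises, so the defaults (0.75 at a 300 m optimum) give
#' roughly 90% zeros over a uniform 0-600 m design, matching the
#' zero-heaviness of deep-water longline surveys.
#'
#' @param depth_opt Depth of peak abundance (m), within the surveyed 0-600 m.
#' @param depth_sd Gaussian width of the depth response (m).
#' @param substrate_effects Named log-scale effects for the seven substrate
#'   categories of [substrate_levels]; by default only `Sand` is non-zero.
#' @param zero_inflation Zero fraction at the depth optimum, in `[0, 1)`.
#' @param noise_sd Lognormal SD (log scale) of positive catch rates.
#' @param mean_positive_rpn Median positive catch rate at the optimum
#'   (individuals per 10^3 hooks).
#' @return An object of class `"spatial_field_params"`.
#' @export
spatial_field_params <- function(depth_opt = 300, depth_sd = 75,
                                 substrate_effects = c(C.Sed = 0, Mix.Sed = 0,
                                                       Mud = 0, Mud.S = 0,
                                                       Rock = 0, Sand = 0.8,
                                                       Sand.M = 0),
                                 zero_inflation = 0.75, noise_sd = 0.6,
                                 mean_positive_rpn = 25) {
  if (depth_opt < 0 || depth_opt > 600)
    stop("'depth_opt' must lie in the surveyed range [0, 600] m")
  if (zero_inflation < 0 || zero_inflation >= 1)
    stop("'zero_inflation' must be in [0, 1)")
  if (noise_sd < 0 || depth_sd <= 0 || mean_positive_rpn <= 0)
    stop("'noise_sd' >= 0, 'depth_sd' > 0, 'mean_positive_rpn' > 0 required")
  if (is.null(names(substrate_effects)) ||
      !all(names(substrate_effects) %in% substrate_levels))
    stop("'substrate_effects' must be named with categories among: ",
         paste(substrate_levels, collapse = ", "))
  eff <- stats::setNames(rep(0, length(substrate_levels)), substrate_levels)
  eff[names(substrate_effects)] <- substrate_effects
  structure(list(depth_opt = depth_opt, depth_sd = depth_sd,
                 substrate_effects = eff, zero_inflation = zero_inflation,
                 noise_sd = noise_sd, mean_positive_rpn = mean_positive_rpn),
            class = "spatial_field_params")
}

#' Simulate bottom-longline survey station records
#'
#' Stations are placed by a stratified random design (equal effort in 50 m
#' depth strata down to 600 m, uniform positions in a lon/lat box, substrate
#' drawn uniformly from the seven categories). Presence at a station is
#' Bernoulli with logit `qlogis(1 - zero_inflation) - (depth - depth_opt)^2 /
#' (2 depth_sd^2) + substrate effect`; positive catch rates are lognormal
#' around the same surface. Deterministic given `seed`.
#'
#' @param spatial A [spatial_field_params()] object.
#' @param n_stations Number of stations (> 0).
#' @param seed Integer seed.
#' @param lon_range,lat_range Bounding box of station positions (decimal
#'   degrees); defaults roughly cover the Azores EEZ.
#' @return Data frame with columns `station`, `longitude`, `latitude`,
#'   `depth` (m), `substrate` and `rpn` (individuals per 10^3 hooks, >= 0).
#' @export
simulate_survey_records <- function(spatial, n_stations, seed,
                                    lon_range = c(-32, -24.5),
                                    lat_range = c(36.5, 40)) {
  stopifnot(inherits(spatial, "spatial_field_params"), n_stations > 0)
  set.seed(seed)
  stratum <- sample.int(12, n_stations, replace = TRUE) - 1L
  depth <- stratum * 50 + stats::runif(n_stations, 0, 50)
  longitude <- stats::runif(n_stations, lon_range[1], lon_range[2])
  latitude <- stats::runif(n_stations, lat_range[1], lat_range[2])
  substrate <- sample(substrate_levels, n_stations, replace = TRUE)
  g <- -(depth - spatial$depth_opt)^2 / (2 * spatial$depth_sd^2) +
    spatial$substrate_effects[substrate]
  eta <- stats::qlogis(1 - spatial$zero_inflation) + g
  present <- stats::runif(n_stations) < stats::plogis(eta)
  mu <- log(spatial$mean_positive_rpn) + g
  noise <- if (spatial$noise_sd > 0)
    stats::rnorm(n_stations, 0, spatial$noise_sd) else 0
  rpn <- ifelse(present, exp(mu + noise), 0)
  data.frame(station = seq_len(n_stations), longitude = longitude,
             latitude = latitude, depth = depth, substrate = substrate,
             rpn = as.numeric(rpn))
}

#' Parameters of the simulated commercial fleet
#'
#' Trip-level catches are a product of year, quarter, vessel-class and gear
#' multipliers with lognormal noise, zeroed with probability `p_zero`, so
#' the standardization model's assumed structure is exactly generated.
#' Default year effects decline linearly over 1990-2017, emulating the
#' falling abundance of the fishery the trip records mimic.
#'
#' @param year_effects Named positive multipliers, one per year.
#' @param quarter_effects,vessel_effects,gear_effects Named positive
#'   multipliers for the categorical factor levels.
#' @param lognormal_sd Log-scale SD of the trip noise (>= 0).
#' @param p_zero Probability a trip records zero catch, in `[0, 1)`.
#' @param base_cpue Baseline catch rate (kg per unit effort) multiplied by
#'   the factor effects.
#' @param confound_vessel_year Strength (>= 0) of a deliberate confounding
#'   of vessel class with year: at 0 vessel classes are assigned uniformly;
#'   larger values concentrate high-multiplier classes in late years, the
#'   bias the standardization must remove.
#' @return An object of class `"fleet_params"`.
#' @export
fleet_params <- function(year_effects = stats::setNames(seq(1, 0.4, length.out = 28),
                                                        1990:2017),
                         quarter_effects = c(`1` = 1, `2` = 1.2, `3` = 1.1, `4` = 0.9),
                         vessel_effects = c(small = 0.7, medium = 1, large = 1.6),
                         gear_effects = c(bottom_longline = 1, handline = 0.6),
                         lognormal_sd = 0.5, p_zero = 0.3, base_cpue = 100,
                         confound_vessel_year = 0) {
  if (length(year_effects) < 1L || is.null(names(year_effects)))
    stop("'year_effects' must be a non-empty named vector")
  for (v in list(year_effects, quarter_effects, vessel_effects, gear_effects))
    if (any(v <= 0) || any(!is.finite(v))) stop("all multipliers must be positive")
  if (p_zero < 0 || p_zero >= 1) stop("'p_zero' must be in [0, 1)")
  if (lognormal_sd < 0 || base_cpue <= 0 || confound_vessel_year < 0)
    stop("invalid noise, baseline or confounding parameter")
  structure(list(year_effects = year_effects, quarter_effects = quarter_effects,
                 vessel_effects = vessel_effects, gear_effects = gear_effects,
                 lognormal_sd = lognormal_sd, p_zero = p_zero,
                 base_cpue = base_cpue,
                 confound_vessel_year = confound_vessel_year),
            class = "fleet_params")
}

#' Simulate commercial trip records
#'
#' Each trip draws factor levels from the declared level sets (vessel class
#' optionally confounded with year, see [fleet_params()]), an effort in days
#' at sea, and a catch equal to `effort * base_cpue * year * quarter *
#' vessel * gear * exp(N(0, lognormal_sd))`, zeroed with probability
#' `p_zero`. Deterministic given `seed`.
#'
#' @param fleet A [fleet_params()] object.
#' @param n_trips Number of trips (> 0).
#' @param seed Integer seed.
#' @return Data frame with columns `year` (integer), `quarter`, `vessel`,
#'   `gear`, `depth_zone`, `target` (catch fraction of the species in the
#'   trip, in `[0, 1]`), `catch` (kg) and `effort` (days at sea).
#' @export
simulate_trip_records <- function(fleet, n_trips, seed) {
  stopifnot(inherits(fleet, "fleet_params"), n_trips > 0)
  set.seed(seed)
  years <- names(fleet$year_effects)
  year <- sample(years, n_trips, replace = TRUE)
  quarter <- sample(names(fleet$quarter_effects), n_trips, replace = TRUE)
  vclasses <- names(fleet$vessel_effects)
  if (fleet$confound_vessel_year > 0 && length(years) > 1L) {
    # tilt class probabilities along the year axis, larger classes later
    s <- (match(year, years) - 1) / (length(years) - 1) * 2 - 1
    rank_v <- rank(fleet$vessel_effects)
    vessel <- vapply(s, function(si) {
      w <- exp(fleet$confound_vessel_year * si * rank_v)
      sample(vclasses, 1L, prob = w / sum(w))
    }, character(1))
  } else {
    vessel <- sample(vclasses, n_trips, replace = TRUE)
  }
  gear <- sample(names(fleet$gear_effects), n_trips, replace = TRUE)
  depth_zone <- sample(c("0-200", "200-400", "400-600"), n_trips, replace = TRUE)
  target <- stats::runif(n_trips)
  effort <- sample(1:10, n_trips, replace = TRUE)
  mult <- fleet$year_effects[year] * fleet$quarter_effects[quarter] *
    fleet$vessel_effects[vessel] * fleet$gear_effects[gear]
  noise <- if (fleet$lognormal_sd > 0)
    exp(stats::rnorm(n_trips, 0, fleet$lognormal_sd)) else 1
  catch <- effort * fleet$base_cpue * as.numeric(mult) * noise
  if (fleet$p_zero > 0)
    catch[stats::runif(n_trips) < fleet$p_zero] <- 0
  data.frame(year = as.integer(year), quarter = as.integer(quarter),
             vessel = vessel, gear = gear, depth_zone = depth_zone,
             target = target, catch = catch, effort = effort)
}
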