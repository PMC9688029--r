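#' Read and write survey station records
#'
#' CSV dialect with columns `station`, `longitude`, `latitude`, `depth`,
#' `substrate`, `rpn`. Validation errors name the offending rows.
#'
#' @param path CSV path.
#' @return Data frame of survey records.
#' @export
read_survey <- function(path) {
  d <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("station", "longitude", "latitude", "depth", "substrate", "rpn")
  if (!all(need %in% names(d)))
    stop("survey CSV must have columns: ", paste(need, collapse = ", "))
  bad <- which(!d$substrate %in% substrate_levels)
  if (length(bad))
    stop("unknown substrate at row(s): ", paste(bad, collapse = ", "))
  bad <- which(!is.finite(d$rpn) | d$rpn < 0)
  if (length(bad))
    stop("invalid rpn at row(s): ", paste(bad, collapse = ", "))
  bad <- which(!is.finite(d$depth) | d$depth < 0 | d$depth > 600)
  if (length(bad))
    stop("depth outside [0, 600] m at row(s): ", paste(bad, collapse = ", "))
  d
}

#' @param x Survey record data frame.
#' @rdname read_survey
#' @export
write_survey <- function(x, path) {
  utils::write.csv(x, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read and write commercial trip records
#'
#' CSV dialect with columns `year`, `quarter`, `vessel`, `gear`,
#' `depth_zone`, `target`, `catch`, `effort`.
#'
#' @param path CSV path.
#' @return Data frame of trip records.
#' @export
read_trips <- function(path) {
  d <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("year", "quarter", "vessel", "gear", "catch", "effort")
  if (!all(need %in% names(d)))
    stop("trip CSV must have columns: ", paste(need, collapse = ", "))
  bad <- which(!is.finite(d$catch) | d$catch < 0)
  if (length(bad))
    stop("invalid catch at row(s): ", paste(bad, collapse = ", "))
  bad <- which(!is.finite(d$effort) | d$effort <= 0)
  if (length(bad))
    stop("non-positive effort at row(s): ", paste(bad, collapse = ", "))
  d
}

#' @param x Trip record data frame.
#' @rdname read_trips
#' @export
write_trips <- function(x, path) {
  utils::write.csv(x, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Run configuration
#'
#' Collects every tunable of the pipeline with its default: 5 cm length
#' bins, MA window 5, 1000 bootstrap resamples, depth-smooth basis
#' dimension 4, 18 deg C water temperature, `tmax = 3/k`, and alpha 0.05.
#' Every value left at its default is logged (via `message`) when the
#' configuration is built, so a run records exactly what it used.
#'
#' @param ... Overrides of the defaults; unknown keys are an error.
#' @param config_file Optional YAML file of flat key-value overrides
#'   (applied before `...`).
#' @param quiet Suppress the defaults log.
#' @return An object of class `"run_config"` (named list).
#' @export
run_config <- function(..., config_file = NULL, quiet = FALSE) {
  defaults <- list(
    lfq = NULL, survey = NULL, trips = NULL, out_dir = NULL,
    bin_width = 5, ma = 5, n_bootstrap = 1000,
    ga = ga_settings(), depth_k = 4, temp = 18,
    tmax_rule = "3/k", alpha = 0.05, seed = 1,
    linf = NULL, k = NULL, combine = "product",
    factors = c("year", "quarter", "vessel", "gear"))
  cfg <- defaults
  if (!is.null(config_file)) {
    yml <- yaml::read_yaml(config_file)
    unknown <- setdiff(names(yml), names(defaults))
    if (length(unknown))
      stop("unknown configuration key(s): ", paste(unknown, collapse = ", "))
    cfg[names(yml)] <- yml
  }
  dots <- list(...)
  unknown <- setdiff(names(dots), names(defaults))
  if (length(unknown))
    stop("unknown configuration key(s): ", paste(unknown, collapse = ", "))
  cfg[names(dots)] <- dots
  if (!inherits(cfg$ga, "ga_settings")) cfg$ga <- do.call(ga_settings, cfg$ga)
  touched <- union(names(dots), if (is.null(config_file)) character() else
    names(yaml::read_yaml(config_file)))
  defaulted <- setdiff(names(defaults), touched)
  if (!quiet && length(defaulted))
    message("configuration defaults applied: ",
            paste(defaulted, collapse = ", "))
  structure(cfg, class = "run_config")
}

#' Run the full length-based assessment pipeline
#'
#' Executes, in order and as far as the configured inputs allow: growth
#' (ELEFAN-GA on the length-frequency table), mortality (catch curve +
#' natural-mortality battery + F and E), spatial distribution (hurdle
#' GAM on the survey records), and abundance standardization (hurdle
#' GLM on the trip records). A failed stage aborts only the stages that
#' depend on it; every stage reports a machine-readable status. All
#' randomness derives from `config$seed`. When `out_dir` is set, a JSON
#' summary and per-stage CSVs are written there; the summary carries no
#' timestamps, so identical configurations produce identical files.
#'
#' @param config A [run_config()] object. Inputs `lfq`, `survey`, `trips`
#'   may each be a file path or an already-loaded object.
#' @return A list with `status` (named character per stage: `"ok"`,
#'   `"skipped"` or `"error: ..."`), per-stage results (`growth`,
#'   `mortality`, `sdm`, `abundance`) and `summary` (the JSON-ready list).
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "run_config"))
  status <- c(growth = "skipped", mortality = "skipped", sdm = "skipped",
              abundance = "skipped")
  res <- list()
  summ <- list(seed = config$seed)

  run_stage <- function(name, expr) {
    out <- tryCatch(list(ok = TRUE, value = expr),
                    error = function(e) list(ok = FALSE,
                                             msg = conditionMessage(e)))
    if (out$ok) {
      status[name] <<- "ok"
      out$value
    } else {
      status[name] <<- paste0("error: ", out$msg)
      NULL
    }
  }

  x_lfq <- if (is.character(config$lfq))
    read_lfq(config$lfq, bin_width = config$bin_width) else config$lfq
  if (!is.null(x_lfq)) {
    res$growth <- run_stage("growth", {
      g <- fit_growth_ga(x_lfq, ga = config$ga, ma = config$ma,
                         n_bootstrap = config$n_bootstrap,
                         seed = config$seed)
      g
    })
  }

  linf <- config$linf
  k <- config$k
  if (is.null(linf) && !is.null(res$growth)) linf <- res$growth$par$linf
  if (is.null(k) && !is.null(res$growth)) k <- res$growth$par$k
  if (!is.null(x_lfq)) {
    res$mortality <- run_stage("mortality", {
      if (is.null(linf) || is.null(k))
        stop("mortality needs growth output or explicit 'linf' and 'k' in the configuration")
      cc <- length_converted_catch_curve(x_lfq, vbgf_params(linf, k))
      tmax <- if (identical(config$tmax_rule, "3/k")) 3 / k else
        as.numeric(config$tmax_rule)
      nm <- natural_mortality_battery(linf, k, tmax = tmax, temp = config$temp)
      est <- mortality_estimates(cc$z, nm$mean_m, z_se = cc$se)
      list(catch_curve = cc, m_battery = nm, estimates = est)
    })
  }

  survey <- if (is.character(config$survey)) read_survey(config$survey) else
    config$survey
  if (!is.null(survey)) {
    res$sdm <- run_stage("sdm", {
      fit <- fit_hurdle_sdm(survey, basis_dim_depth = config$depth_k)
      fit
    })
  }

  trips <- if (is.character(config$trips)) read_trips(config$trips) else
    config$trips
  if (!is.null(trips)) {
    res$abundance <- run_stage("abundance", {
      idx <- standardize_cpue_hurdle(trips, factors = config$factors,
                                     combine = config$combine)
      idx
    })
  }

  summ$status <- as.list(status)
  if (!is.null(res$growth))
    summ$growth <- list(linf = res$growth$par$linf, k = res$growth$par$k,
                        t_anchor = res$growth$par$t_anchor,
                        rn = res$growth$rn_score,
                        phi_prime = res$growth$phi_prime)
  if (!is.null(res$mortality))
    summ$mortality <- list(z = res$mortality$estimates$z,
                           z_se = res$mortality$estimates$z_se,
                           m = res$mortality$estimates$m,
                           f = res$mortality$estimates$f,
                           e = res$mortality$estimates$e)
  if (!is.null(res$sdm))
    summ$sdm <- list(dev_expl_binomial = unname(res$sdm$dev_expl["binomial"]),
                     dev_expl_gaussian = unname(res$sdm$dev_expl["gaussian"]))
  if (!is.null(res$abundance))
    summ$abundance <- list(years = res$abundance$year,
                           index = res$abundance$index,
                           norm = res$abundance$norm)

  if (!is.null(config$out_dir)) {
    dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
    jsonlite::write_json(summ, file.path(config$out_dir, "summary.json"),
                         auto_unbox = TRUE, digits = 10, pretty = TRUE)
    if (!is.null(res$mortality))
      utils::write.csv(res$mortality$catch_curve$points,
                       file.path(config$out_dir, "catch_curve_points.csv"),
                       row.names = FALSE)
    if (!is.null(res$mortality))
      utils::write.csv(res$mortality$m_battery$table,
                       file.path(config$out_dir, "natural_mortality.csv"),
                       row.names = FALSE)
    if (!is.null(res$abundance))
      utils::write.csv(as.data.frame(res$abundance),
                       file.path(config$out_dir, "abundance_index.csv"),
                       row.names = FALSE)
    if (!is.null(res$growth) && !is.null(res$growth$boot))
      utils::write.csv(as.data.frame(res$growth$boot),
                       file.path(config$out_dir, "growth_bootstrap.csv"),
                       row.names = FALSE)
  }
  list(status = status, growth = res$growth, mortality = res$mortality,
       sdm = res$sdm, abundance = res$abundance, summary = summ)
}
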