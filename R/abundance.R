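#' Min-max normalize an abundance series
#'
#' Rescales a series to `[0, 1]` by `(x - min) / (max - min)`, so the
#' smallest year maps to 0 and the largest to 1. A constant series has no
#' range; it is mapped to 0.5 with a warning so degenerate simulations do
#' not abort a pipeline.
#'
#' @param x Non-empty finite numeric vector.
#' @return Normalized vector of the same length.
#' @examples
#' minmax_normalize(c(2, 4, 6))
#' @export
minmax_normalize <- function(x) {
  x <- as.numeric(x)
  if (!length(x)) stop("series must be non-empty")
  if (any(!is.finite(x))) stop("series must be finite")
  rng <- range(x)
  if (rng[1] == rng[2]) {
    warning("constant series: min-max normalization undefined, mapping to 0.5")
    return(rep(0.5, length(x)))
  }
  (x - rng[1]) / (rng[2] - rng[1])
}

#' Standardize catch rates with a hurdle-lognormal GLM
#'
#' Removes fleet effects from fishery-dependent catch rates in two parts:
#' a binomial GLM on whether a trip caught anything, and a Gaussian GLM on
#' `log(catch/effort)` for the positive trips, both with the same
#' categorical factors. The annual index is the least-squares mean of the
#' year factor (all other factors balanced at equal level weights,
#' computed with emmeans), and the two parts are combined as
#' `exp(LSM_positive) * plogis(LSM_binomial)` - standard delta-lognormal
#' practice - with the positive part alone available via
#' `combine = "positive"`. Standard errors come from the delta method
#' assuming independent parts. When every trip is positive the binomial
#' part is dropped and the presence probability is 1.
#'
#' Factors with a single observed level are dropped with a message. A
#' continuous `target` covariate (species share of the trip catch) is
#' binned to quartile categories when requested among `factors`. A year
#' with no positive trips gets an `NA` index and is flagged.
#'
#' @param trips Data frame of trip records with columns `catch` (kg,
#'   >= 0), an effort column, `year`, and the requested factor columns.
#' @param factors Character vector of standardization factors; must
#'   include `"year"`.
#' @param effort_col Name of the effort column (days at sea for CPUE,
#'   landing events for LPUE - treated identically).
#' @param combine `"product"` (default) or `"positive"`.
#' @param index_name Label stored on the result (`"CPUE"`, `"LPUE"`, ...).
#' @return An object of class `"abundance_index"`: a data frame with one
#'   row per year (`year`, `index`, `se`, `norm`, `n_trips`,
#'   `n_positive`), with the fitted parts and settings as attributes.
#' @export
standardize_cpue_hurdle <- function(trips,
                                    factors = c("year", "quarter", "vessel",
                                                "gear"),
                                    effort_col = "effort",
                                    combine = c("product", "positive"),
                                    index_name = "CPUE") {
  combine <- match.arg(combine)
  if (!"year" %in% factors) stop("'factors' must include \"year\"")
  if (!effort_col %in% names(trips)) stop("missing effort column: ", effort_col)
  missing_f <- setdiff(factors, names(trips))
  if (length(missing_f))
    stop("missing factor column(s): ", paste(missing_f, collapse = ", "))
  if (any(trips$catch < 0)) stop("'catch' must be >= 0")
  if (any(trips[[effort_col]] <= 0)) stop("effort must be > 0")
  if (length(unique(trips$year)) < 2L) {
    if (nrow(trips) == 0L) stop("no trips")
    message("single year of data: index is a one-point series")
  }
  d <- trips
  if ("target" %in% factors && is.numeric(d$target)) {
    qs <- unique(stats::quantile(d$target, probs = seq(0, 1, 0.25)))
    d$target <- cut(d$target, breaks = qs, include.lowest = TRUE,
                    labels = paste0("Q", seq_len(length(qs) - 1)))
  }
  for (f in factors) d[[f]] <- factor(d[[f]])
  keep <- factors[vapply(factors, function(f) nlevels(droplevels(d[[f]])) > 1L,
                         logical(1))]
  keep <- union("year", keep)
  dropped <- setdiff(factors, keep)
  if (length(dropped))
    message("factor(s) with a single level dropped: ",
            paste(dropped, collapse = ", "))
  d$cpue <- d$catch / d[[effort_col]]
  d$positive <- d$cpue > 0
  pos <- droplevels(d[d$positive, , drop = FALSE])
  if (nrow(pos) < length(keep) + 1L)
    stop("too few positive trips to fit the positive part")
  all_years <- levels(d$year)
  # a single year (or a factor that lost its second level in the positive
  # subset) cannot enter the linear predictor; drop it and take the overall
  # least-squares mean for that part instead
  year_lsm <- function(mod, spec_ok) {
    if (spec_ok) {
      em <- as.data.frame(emmeans::emmeans(mod, "year"))
      i <- match(all_years, as.character(em$year))
      list(est = em$emmean[i], se = em$SE[i])
    } else {
      em <- as.data.frame(emmeans::emmeans(mod, ~1))
      list(est = rep(em$emmean, length(all_years)),
           se = rep(em$SE, length(all_years)))
    }
  }
  part_formula <- function(resp, data) {
    usable <- keep[vapply(keep, function(f)
      nlevels(droplevels(data[[f]])) > 1L, logical(1))]
    list(formula = stats::as.formula(paste(
      resp, "~", if (length(usable)) paste(usable, collapse = " + ") else "1")),
      year_in = "year" %in% usable)
  }
  pf <- part_formula("log(cpue)", pos)
  gau <- stats::glm(pf$formula, data = pos, family = stats::gaussian())
  lg <- year_lsm(gau, pf$year_in)
  mu <- lg$est
  se_mu <- lg$se
  idx <- data.frame(year = as.integer(all_years))
  hurdle <- any(!d$positive)
  bin <- NULL
  if (hurdle) {
    bf <- part_formula("positive", d)
    bin <- stats::glm(bf$formula, data = d, family = stats::binomial())
    lb <- year_lsm(bin, bf$year_in)
    p <- stats::plogis(lb$est)
    se_eta <- lb$se
  } else {
    p <- rep(1, length(all_years))
    se_eta <- rep(0, length(all_years))
  }
  if (combine == "product") {
    idx$index <- exp(mu) * p
    # delta method on independent parts: d/dmu = index, d/deta = index*(1-p)
    idx$se <- idx$index * sqrt(se_mu^2 + ((1 - p) * se_eta)^2)
  } else {
    idx$index <- exp(mu)
    idx$se <- exp(mu) * se_mu
  }
  idx$n_trips <- as.integer(table(d$year)[all_years])
  idx$n_positive <- as.integer(table(factor(pos$year, levels = all_years)))
  no_pos <- idx$n_positive == 0
  if (any(no_pos))
    warning("year(s) with no positive trips, index undefined: ",
            paste(idx$year[no_pos], collapse = ", "))
  ok <- is.finite(idx$index)
  idx$norm <- NA_real_
  if (sum(ok) == 1L) {
    idx$norm[ok] <- 0.5
  } else if (any(ok)) {
    idx$norm[ok] <- minmax_normalize(idx$index[ok])
  }
  structure(idx, class = c("abundance_index", "data.frame"),
            index_name = index_name, combine = combine,
            factors = keep, gaussian = gau, binomial = bin)
}

#' Build an abundance index from a plain annual series
#'
#' For survey-derived series (e.g. RPN from a standardized design) no GLM
#' standardization is needed; this wraps annual values into the same
#' `abundance_index` structure, min-max normalized.
#'
#' @param year Integer years.
#' @param value Annual index values.
#' @param se Optional standard errors.
#' @param index_name Label (`"RPN"`, ...).
#' @return An `abundance_index` data frame.
#' @export
abundance_index <- function(year, value, se = NA_real_, index_name = "RPN") {
  stopifnot(length(year) == length(value))
  idx <- data.frame(year = as.integer(year), index = as.numeric(value),
                    se = se, n_trips = NA_integer_, n_positive = NA_integer_)
  idx$norm <- if (length(value) == 1L) 0.5 else minmax_normalize(idx$index)
  structure(idx, class = c("abundance_index", "data.frame"),
            index_name = index_name)
}

#' @export
print.abundance_index <- function(x, ...) {
  cat(sprintf("Standardized abundance index %s (%d years)\n",
              attr(x, "index_name"), nrow(x)))
  print.data.frame(x, row.names = FALSE, digits = 4)
  invisible(x)
}

#' @param x An `abundance_index`.
#' @param ... Passed to [graphics::plot()].
#' @rdname standardize_cpue_hurdle
#' @export
plot.abundance_index <- function(x, ...) {
  graphics::plot(x$year, x$norm, type = "b", xlab = "Year",
                 ylab = paste("Normalized", attr(x, "index_name")), ...)
  invisible(x)
}

#' Compare abundance-index trends by ANCOVA
#'
#' Stacks two or more normalized annual indices and fits
#' `value ~ year + index + year:index` (year continuous, index
#' categorical). The interaction term tests parallelism of the linear
#' trends; when it is non-significant at `alpha` the model is refit
#' without the interaction and Tukey contrasts (single-step, via
#' multcomp) compare the index intercepts, mirroring the sequential
#' parallelism-then-intercepts logic of abundance-trend comparisons.
#'
#' @param indices List of `abundance_index` objects (>= 2, each with >= 3
#'   years), or a data frame with columns `index`, `year`, `value`.
#' @param alpha Significance level for the parallelism decision
#'   (default 0.05).
#' @return An object of class `"trend_comparison"`: `slopes` (per-index
#'   slope and intercept), `ancova` (car type-II ANCOVA table),
#'   `interaction_p`, `parallel`, and `tukey` (intercept contrasts, or
#'   `NULL` when slopes differ).
#' @export
compare_trends_ancova <- function(indices, alpha = 0.05) {
  if (is.data.frame(indices)) {
    stopifnot(all(c("index", "year", "value") %in% names(indices)))
    d <- indices
  } else {
    stopifnot(length(indices) >= 2L)
    d <- do.call(rbind, lapply(indices, function(ix) {
      stopifnot(inherits(ix, "abundance_index"))
      ok <- is.finite(ix$norm)
      data.frame(index = attr(ix, "index_name"), year = ix$year[ok],
                 value = ix$norm[ok])
    }))
  }
  d$index <- factor(d$index)
  if (nlevels(d$index) < 2L) stop("at least two indices are required")
  per_n <- tapply(d$year, d$index, function(y) length(unique(y)))
  if (any(per_n < 3L))
    stop("each index needs at least 3 years: ",
         paste(names(per_n)[per_n < 3], collapse = ", "))
  yr_rng <- tapply(d$year, d$index, range)
  span <- Reduce(function(a, b) c(max(a[1], b[1]), min(a[2], b[2])), yr_rng)
  if (span[1] > span[2])
    stop("indices cover disjoint year ranges; trends are not comparable")
  full <- stats::lm(value ~ year * index, data = d)
  tab <- car::Anova(full, type = 2)
  ip <- tab["year:index", "Pr(>F)"]
  parallel <- is.finite(ip) && ip >= alpha
  slopes <- do.call(rbind, lapply(levels(d$index), function(l) {
    cf <- stats::coef(stats::lm(value ~ year, data = d[d$index == l, ]))
    data.frame(index = l, intercept = unname(cf[1]), slope = unname(cf[2]))
  }))
  tukey <- NULL
  if (parallel) {
    reduced <- stats::lm(value ~ year + index, data = d)
    gl <- multcomp::glht(reduced, linfct = multcomp::mcp(index = "Tukey"))
    sm <- summary(gl)
    tukey <- data.frame(contrast = names(sm$test$coefficients),
                        estimate = unname(sm$test$coefficients),
                        t = unname(sm$test$tstat),
                        p_adj = unname(sm$test$pvalues))
  }
  structure(list(slopes = slopes, ancova = tab, interaction_p = ip,
                 parallel = parallel, tukey = tukey, alpha = alpha,
                 data = d),
            class = "trend_comparison")
}

#' @export
print.trend_comparison <- function(x, ...) {
  cat("Abundance-trend comparison (ANCOVA)\n")
  print(x$slopes, row.names = FALSE, digits = 4)
  cat(sprintf("Interaction (parallelism) p = %.4g -> slopes %s\n",
              x$interaction_p,
              if (x$parallel) "parallel; comparing intercepts" else "differ"))
  if (!is.null(x$tukey)) {
    cat("Tukey intercept contrasts:\n")
    print(x$tukey, row.names = FALSE, digits = 4)
  }
  invisible(x)
}
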