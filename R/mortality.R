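#' Total mortality from the linearized length-converted catch curve
#'
#' Pools the length-frequency table over dates, converts bin midpoints to
#' relative ages with the inverse VBGF, and regresses `ln(N/dt)` on
#' relative age over the descending limb; total mortality `Z` is the
#' negative slope, reported with its OLS standard error.
#'
#' Bins whose upper edge reaches `linf` are dropped (their relative age is
#' undefined), as are zero-count bins (with a warning when they fall inside
#' the selected limb). The default limb selection is automatic: the points
#' after the maximum of `ln(N/dt)` up to the last non-empty bin with
#' midpoint below `0.9 * linf`. Because `Z` depends on this choice, the
#' selection is recorded in the returned object and can be overridden.
#'
#' @param x An [lfq()] object or a named numeric vector of pooled counts
#'   (names = lower bin edges) with attribute-free uniform spacing.
#' @param p A [vbgf_params()] object; `linf` must exceed the upper edge of
#'   every used bin.
#' @param limb `"auto"` or an integer vector of bin indices (into the used
#'   bins) to regress on; at least 3 points.
#' @param bin_width Needed only when `x` is a plain vector.
#' @return An object of class `"catch_curve"`: data frame `points` (bin
#'   midpoint, relative age `t`, `dt`, `ln_n_dt`, `selected`), `z`, `se`,
#'   `slope`, `intercept`, and the fitted `lm`.
#' @export
length_converted_catch_curve <- function(x, p, limb = "auto", bin_width = NULL) {
  if (inherits(x, "lfq")) {
    counts <- rowSums(x$counts)
    lower <- x$bin_lower
    w <- x$bin_width
  } else {
    counts <- as.numeric(x)
    lower <- as.numeric(names(x))
    if (any(is.na(lower))) stop("pooled counts must be named by lower bin edges")
    w <- if (!is.null(bin_width)) bin_width else min(diff(sort(lower)))
  }
  upper <- lower + w
  usable <- upper < p$linf
  if (!all(usable)) {
    dropped <- sum(counts[!usable])
    if (dropped > 0)
      warning(sum(!usable), " bin(s) at or above linf dropped (",
              dropped, " individuals)")
    counts <- counts[usable]; lower <- lower[usable]; upper <- upper[usable]
  }
  mid <- lower + w / 2
  t_mid <- inverse_vbgf_age_at_length(p, mid)
  dt <- inverse_vbgf_age_at_length(p, upper) - inverse_vbgf_age_at_length(p, lower)
  ln_n_dt <- ifelse(counts > 0, log(counts / dt), NA_real_)
  if (identical(limb, "auto")) {
    pk <- which.max(ln_n_dt)
    last <- max(which(mid < 0.9 * p$linf & counts > 0))
    sel_idx <- seq(pk + 1, last)
    sel_idx <- sel_idx[sel_idx <= length(mid)]
  } else {
    sel_idx <- as.integer(limb)
    if (any(sel_idx < 1 | sel_idx > length(mid)))
      stop("'limb' indices outside the usable bins")
  }
  zero_in <- sel_idx[counts[sel_idx] == 0]
  if (length(zero_in)) {
    warning("zero-count bin(s) excluded from the regression: ",
            paste(format(mid[zero_in]), collapse = ", "), " cm")
    sel_idx <- setdiff(sel_idx, zero_in)
  }
  if (length(sel_idx) < 3L)
    stop("fewer than 3 selectable points on the descending limb")
  selected <- seq_along(mid) %in% sel_idx
  fit <- stats::lm(ln_n_dt[selected] ~ t_mid[selected])
  cf <- summary(fit)$coefficients
  structure(list(
    points = data.frame(midpoint = mid, t = t_mid, dt = dt, count = counts,
                        ln_n_dt = ln_n_dt, selected = selected),
    slope = unname(cf[2, 1]), intercept = unname(cf[1, 1]),
    slope_se = unname(cf[2, 2]),
    z = -unname(cf[2, 1]), se = unname(cf[2, 2]),
    vbgf = p, limb = sel_idx, lm = fit),
    class = "catch_curve")
}

#' @export
print.catch_curve <- function(x, ...) {
  cat(sprintf("Length-converted catch curve: Z = %.4f +/- %.4f year^-1 (%d regression points)\n",
              x$z, x$se, sum(x$points$selected)))
  invisible(x)
}

#' @export
coef.catch_curve <- function(object, ...) {
  c(intercept = object$intercept, slope = object$slope)
}

#' @param x A `catch_curve` object.
#' @param ... Passed to [graphics::plot()].
#' @rdname length_converted_catch_curve
#' @export
plot.catch_curve <- function(x, ...) {
  pt <- x$points
  graphics::plot(pt$t, pt$ln_n_dt, xlab = "Relative age (years)",
                 ylab = "ln(N / dt)",
                 pch = ifelse(pt$selected, 19, 1), ...)
  graphics::abline(x$intercept, x$slope, lty = 2)
  invisible(x)
}

#' Battery of empirical natural-mortality estimators
#'
#' Computes natural mortality (`M`, year^-1) from fourteen empirical
#' relationships driven by the asymptotic length, growth coefficient,
#' approximate maximum age (`tmax`, by default `3/k`) and water
#' temperature, and their arithmetic mean. The formulas are implemented as
#' printed in the source battery: in particular the Pauly (1980)
#' relationship is the exponential of a base-10-log linear combination and
#' the Alverson-Carney denominator is `exp(0.38 tmax k - 1)`; set
#' `pauly = "log10"` for the canonical `10^` form of Pauly (1980).
#'
#' @param linf Asymptotic length (cm), positive.
#' @param k Growth coefficient (year^-1), positive.
#' @param tmax Approximate maximum age (years); default `3/k`, carried at
#'   full precision.
#' @param temp Mean water temperature (deg C); default 18.
#' @param pauly `"as-printed"` (default) or `"log10"`.
#' @return An object of class `"m_battery"`: data frame `table`
#'   (`method`, `m`) and `mean_m` (arithmetic mean of the 14 estimates).
#' @examples
#' nm <- natural_mortality_battery(171.62, 0.13)
#' nm$mean_m
#' @export
natural_mortality_battery <- function(linf, k, tmax = 3 / k, temp = 18,
                                      pauly = c("as-printed", "log10")) {
  pauly <- match.arg(pauly)
  stopifnot(is.numeric(linf), is.numeric(k), is.numeric(tmax), is.numeric(temp))
  if (linf <= 0 || k <= 0 || tmax <= 0 || temp <= 0)
    stop("all inputs must be positive")
  pauly_lin <- -0.0066 - 0.279 * log10(linf) + 0.6543 * log10(k) +
    0.4634 * log10(temp)
  m <- c(
    `Beverton and Holt (1959)`   = 5 / tmax,
    `Taylor (1960)`              = 2.996 / tmax,
    `Tanaka (1960)`              = 3 / tmax,
    `Alverson and Carney (1975)` = 3 * k / exp(0.38 * tmax * k - 1),
    `Pauly (1980)`               = if (pauly == "as-printed") exp(pauly_lin)
                                   else 10^pauly_lin,
    `Hoenig (1983)`              = 3 / tmax,
    `Alagaraja (1984)`           = 4.6 / tmax,
    `Djabali (1993)`             = 1.0661 * linf^-0.1172 * k^0.5092,
    `Pauly and Binohlan (1996)`  = -0.1778 + 3.1687 * k,
    `Jensen (1996) 1.6k`         = 1.6 * k,
    `Jensen (1996) 1.5k`         = 1.5 * k,
    `Cubillos et al. (1999)`     = 1.4 * k,
    `Frisk (2001)`               = 4.22 / tmax,
    `Hewitt and Hoenig (2005)`   = 4.22 / tmax)
  structure(list(table = data.frame(method = names(m), m = unname(m)),
                 mean_m = mean(m),
                 inputs = list(linf = linf, k = k, tmax = tmax, temp = temp,
                               pauly = pauly)),
            class = "m_battery")
}

#' @export
print.m_battery <- function(x, ...) {
  cat(sprintf("Empirical natural mortality (linf = %.2f cm, k = %.3f year^-1, tmax = %.2f years, T = %g C):\n",
              x$inputs$linf, x$inputs$k, x$inputs$tmax, x$inputs$temp))
  tab <- x$table
  tab$m <- round(tab$m, 2)
  print(tab, row.names = FALSE)
  cat(sprintf("Mean M = %.2f year^-1\n", x$mean_m))
  invisible(x)
}

#' Fishing mortality from total and natural mortality
#'
#' `F = Z - M`. A negative result (natural mortality exceeding total
#' mortality) is returned as-is, flagged via the `"implausible"` attribute
#' and a warning, never silently clipped.
#'
#' @param z Total mortality (year^-1), >= 0.
#' @param m Natural mortality (year^-1), >= 0.
#' @return Fishing mortality (year^-1) with logical attribute
#'   `implausible`.
#' @export
fishing_mortality <- function(z, m) {
  stopifnot(is.numeric(z), is.numeric(m))
  if (z < 0 || m < 0) stop("'z' and 'm' must be >= 0")
  f <- z - m
  implausible <- f < 0
  if (implausible)
    warning("implausible (M > Z): fishing mortality is negative")
  structure(f, implausible = implausible)
}

#' Exploitation rate
#'
#' `E = F / (F + M)`: the fraction of total deaths attributable to
#' fishing. `E = 0.5` is the conventional optimal-exploitation benchmark;
#' values above it indicate exploitation beyond that optimum.
#'
#' @param f Fishing mortality (year^-1), >= 0.
#' @param m Natural mortality (year^-1), > 0 unless `f > 0`.
#' @return Exploitation rate in `[0, 1)`.
#' @examples
#' exploitation_rate(0.25, 0.22)
#' @export
exploitation_rate <- function(f, m) {
  stopifnot(is.numeric(f), is.numeric(m))
  if (f < 0) stop("'f' must be >= 0")
  if (m < 0) stop("'m' must be >= 0")
  if (f + m == 0) stop("'f + m' must be positive")
  as.numeric(f) / (as.numeric(f) + as.numeric(m))
}

#' Combined mortality estimates
#'
#' Convenience wrapper assembling total, natural and fishing mortality and
#' the exploitation rate into one object.
#'
#' @param z Total mortality (year^-1).
#' @param z_se Standard error of `z` (optional).
#' @param m Natural mortality (year^-1), e.g. the battery mean.
#' @return An object of class `"mortality_estimates"` with fields `z`,
#'   `z_se`, `m`, `f`, `e` and `implausible`.
#' @export
mortality_estimates <- function(z, m, z_se = NA_real_) {
  f <- fishing_mortality(z, m)
  e <- if (f >= 0) exploitation_rate(as.numeric(f), m) else NA_real_
  structure(list(z = z, z_se = z_se, m = m, f = as.numeric(f), e = e,
                 implausible = attr(f, "implausible")),
            class = "mortality_estimates")
}

#' @export
print.mortality_estimates <- function(x, ...) {
  cat(sprintf("Mortality: Z = %.3f%s, M = %.3f, F = %.3f year^-1; E = %s\n",
              x$z, if (is.finite(x$z_se)) sprintf(" +/- %.3f", x$z_se) else "",
              x$m, x$f,
              if (is.finite(x$e)) sprintf("%.3f", x$e) else "undefined"))
  if (isTRUE(x$implausible)) cat("  flag: implausible (M > Z)\n")
  invisible(x)
}
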