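#' von Bertalanffy growth parameters
#'
#' Bundle of von Bertalanffy growth function (VBGF) parameters in the
#' t0-free form used throughout the package,
#' \deqn{L(t) = L_\infty (1 - e^{-k t}),}
#' where `linf` is the asymptotic length (cm), `k` the growth coefficient
#' (year^-1) and `t_anchor` the within-year birth fraction that anchors
#' cohorts on the calendar axis (it replaces the theoretical age at length
#' zero, which the t0-free form removes).
#'
#' @param linf Asymptotic length in cm; must be positive.
#' @param k Growth coefficient in year^-1; must be positive.
#' @param t_anchor Cohort birth time as a fraction of the year, in `[0, 1)`.
#' @return An object of class `"vbgf_params"`: a named list with elements
#'   `linf`, `k`, `t_anchor`.
#' @examples
#' p <- vbgf_params(linf = 171.62, k = 0.12)
#' vbgf_length_at_age(p, 5)
#' @export
vbgf_params <- function(linf, k, t_anchor = 0) {
  stopifnot(is.numeric(linf), length(linf) == 1L, is.finite(linf),
            is.numeric(k), length(k) == 1L, is.finite(k),
            is.numeric(t_anchor), length(t_anchor) == 1L, is.finite(t_anchor))
  if (linf <= 0) stop("'linf' must be positive")
  if (k <= 0) stop("'k' must be positive")
  if (t_anchor < 0 || t_anchor >= 1) stop("'t_anchor' must be in [0, 1)")
  structure(list(linf = linf, k = k, t_anchor = t_anchor),
            class = "vbgf_params")
}

#' @export
print.vbgf_params <- function(x, ...) {
  cat(sprintf("VBGF parameters: Linf = %.2f cm, k = %.4f year^-1, t_anchor = %.3f\n",
              x$linf, x$k, x$t_anchor))
  invisible(x)
}

#' Mean length at age under the von Bertalanffy growth function
#'
#' Evaluates the t0-free VBGF `L(t) = linf * (1 - exp(-k * t))`.
#'
#' @param p A [vbgf_params()] object (or any list with `linf` and `k`).
#' @param t Age(s) in years; must be non-negative.
#' @return Length(s) in cm, non-decreasing in `t` and bounded by `linf`.
#' @export
vbgf_length_at_age <- function(p, t) {
  stopifnot(is.numeric(t))
  if (any(!is.finite(t)) || any(t < 0)) stop("ages 't' must be finite and >= 0")
  p$linf * (1 - exp(-p$k * t))
}

#' Relative age at length (inverse VBGF)
#'
#' Inverts the t0-free VBGF: `t = -log(1 - L/linf) / k`. Used by the
#' length-converted catch curve to turn length bins into relative ages.
#'
#' @param p A [vbgf_params()] object.
#' @param L Length(s) in cm; each must satisfy `0 <= L < linf`.
#' @return Relative age(s) in years.
#' @export
inverse_vbgf_age_at_length <- function(p, L) {
  stopifnot(is.numeric(L))
  if (any(!is.finite(L)) || any(L < 0)) stop("lengths must be finite and >= 0")
  if (any(L >= p$linf))
    stop("length at or above 'linf': age undefined under the VBGF")
  -log(1 - L / p$linf) / p$k
}

#' Growth performance index phi-prime
#'
#' Computes the growth performance index
#' \deqn{\Phi' = 2 \log_{10} L_\infty + \log_{10} k,}
#' which allows growth fits to be compared across studies and stocks.
#'
#' @param linf Asymptotic length (cm), positive.
#' @param k Growth coefficient (year^-1), positive.
#' @return The scalar index (dimensionless).
#' @examples
#' growth_performance_phi(100, 0.1) # 3
#' @export
growth_performance_phi <- function(linf, k) {
  stopifnot(is.numeric(linf), is.numeric(k))
  if (any(linf <= 0) || any(k <= 0))
    stop("'linf' and 'k' must be positive")
  2 * log10(linf) + log10(k)
}
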