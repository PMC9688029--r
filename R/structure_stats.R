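#' Two-sample Kolmogorov-Smirnov test
#'
#' Compares two length-frequency samples through the supremum distance
#' between their empirical distribution functions,
#' `D = sup |ECDF_x - ECDF_y|`, evaluated at every observed point (which
#' handles ties deterministically), with the asymptotic Kolmogorov
#' p-value. An exact p-value (no ties, small n) is available via
#' `exact = TRUE`, delegated to [stats::ks.test()].
#'
#' @param x,y Numeric samples, both non-empty.
#' @param exact Use the exact small-sample p-value instead of the
#'   asymptotic one.
#' @return List with `statistic` (D), `p_value`, and the sample sizes.
#' @examples
#' ks_two_sample(c(1, 2, 3), c(2, 3, 4))$statistic # 1/3
#' @export
ks_two_sample <- function(x, y, exact = FALSE) {
  x <- as.numeric(x); y <- as.numeric(y)
  if (!length(x) || !length(y)) stop("both samples must be non-empty")
  if (any(!is.finite(c(x, y)))) stop("samples must be finite")
  pts <- sort(unique(c(x, y)))
  d <- max(abs(stats::ecdf(x)(pts) - stats::ecdf(y)(pts)))
  n1 <- length(x); n2 <- length(y)
  if (exact) {
    p <- suppressWarnings(stats::ks.test(x, y, exact = TRUE)$p.value)
  } else {
    lambda <- sqrt(n1 * n2 / (n1 + n2)) * d
    p <- kolmogorov_sf(lambda)
  }
  list(statistic = d, p_value = p, n = c(n1 = n1, n2 = n2))
}

# asymptotic Kolmogorov survival function 2*sum (-1)^(j-1) exp(-2 j^2 t^2)
kolmogorov_sf <- function(t) {
  if (t <= 0) return(1)
  j <- seq_len(101)
  min(1, max(0, 2 * sum((-1)^(j - 1) * exp(-2 * j^2 * t^2))))
}

# validate a list of groups for the heteroscedastic procedures
check_groups <- function(groups, need_var = TRUE) {
  if (is.null(names(groups)))
    names(groups) <- paste0("group", seq_along(groups))
  groups <- lapply(groups, as.numeric)
  if (length(groups) < 2L) stop("at least two groups are required")
  ns <- vapply(groups, length, integer(1))
  if (any(ns < 2L)) stop("each group needs n >= 2")
  if (need_var) {
    vs <- vapply(groups, stats::var, numeric(1))
    if (any(vs <= 0))
      stop("zero-variance group(s): ",
           paste(names(groups)[vs <= 0], collapse = ", "),
           " - the heteroscedastic tests require positive within-group variance")
  }
  groups
}

#' Welch's heteroscedastic one-way F test
#'
#' One-way comparison of group means that does not assume equal variances:
#' groups are weighted by `n/s^2` and the denominator degrees of freedom
#' are of Satterthwaite type. Wraps [stats::oneway.test()] with
#' `var.equal = FALSE` after validating the groups.
#'
#' @param groups Named list of numeric vectors (fork lengths by stratum);
#'   each group needs `n >= 2` and positive variance.
#' @return List with `statistic` (F), `df1`, `df2`, `p_value`.
#' @export
welch_anova <- function(groups) {
  groups <- check_groups(groups)
  d <- data.frame(
    value = unlist(groups, use.names = FALSE),
    group = factor(rep(names(groups), vapply(groups, length, integer(1)))))
  ft <- stats::oneway.test(value ~ group, data = d, var.equal = FALSE)
  list(statistic = unname(ft$statistic), df1 = unname(ft$parameter[1]),
       df2 = unname(ft$parameter[2]), p_value = unname(ft$p.value))
}

#' Games-Howell post hoc comparisons
#'
#' All pairwise mean comparisons under unequal variances: each pair uses
#' the Welch standard error and Welch-Satterthwaite degrees of freedom,
#' with the p-value and confidence interval taken from the studentized
#' range distribution with the full number of groups (computed
#' numerically via [stats::ptukey()]/[stats::qtukey()], no Monte Carlo).
#' With two groups it reduces to the unadjusted Welch pairwise test.
#'
#' @param groups Named list of numeric vectors, as [welch_anova()].
#' @param conf_level Confidence level of the intervals (default 0.95).
#' @return Data frame with one row per pair: `group1`, `group2`, `diff`
#'   (mean difference), `se`, `df`, `t`, `p_adj`, `lower`, `upper`.
#' @export
games_howell <- function(groups, conf_level = 0.95) {
  groups <- check_groups(groups)
  k <- length(groups)
  nm <- names(groups)
  m <- vapply(groups, mean, numeric(1))
  v <- vapply(groups, stats::var, numeric(1))
  n <- vapply(groups, length, numeric(1))
  pairs <- utils::combn(k, 2)
  out <- data.frame(group1 = nm[pairs[1, ]], group2 = nm[pairs[2, ]],
                    diff = NA_real_, se = NA_real_, df = NA_real_,
                    t = NA_real_, p_adj = NA_real_,
                    lower = NA_real_, upper = NA_real_)
  for (c_idx in seq_len(ncol(pairs))) {
    i <- pairs[1, c_idx]; j <- pairs[2, c_idx]
    se <- sqrt(v[i] / n[i] + v[j] / n[j])
    df <- se^4 / ((v[i] / n[i])^2 / (n[i] - 1) + (v[j] / n[j])^2 / (n[j] - 1))
    tt <- (m[i] - m[j]) / se
    p <- stats::ptukey(abs(tt) * sqrt(2), nmeans = k, df = df,
                       lower.tail = FALSE)
    hw <- stats::qtukey(conf_level, nmeans = k, df = df) / sqrt(2) * se
    out[c_idx, 3:9] <- c(m[i] - m[j], se, df, tt, p,
                         m[i] - m[j] - hw, m[i] - m[j] + hw)
  }
  out
}

#' Chi-square goodness-of-fit sex-ratio test
#'
#' Tests an observed male:female count against the expected 1:1 ratio
#' with the chi-square goodness-of-fit test (df = 1). The ratio is
#' reported as males per female ("x:1"); an all-male stratum yields an
#' infinite ratio and the test is still computed. Strata with fewer than
#' 10 fish are flagged `low_n` rather than suppressed.
#'
#' @param males,females Non-negative counts with `males + females > 0`.
#' @param stratum Optional stratum label carried through to the output.
#' @return List with `ratio` (males/females), `chi_square`, `p_value`,
#'   `n`, `low_n` and `stratum`.
#' @examples
#' sex_ratio_test(46, 100)
#' @export
sex_ratio_test <- function(males, females, stratum = NA_character_) {
  stopifnot(is.numeric(males), is.numeric(females))
  if (males < 0 || females < 0) stop("counts must be >= 0")
  n <- males + females
  if (n == 0) stop("males + females must be > 0")
  cs <- suppressWarnings(stats::chisq.test(c(males, females), p = c(0.5, 0.5)))
  list(ratio = males / females, chi_square = unname(cs$statistic),
       p_value = unname(cs$p.value), n = n, low_n = n < 10,
       stratum = stratum)
}

#' Sex-ratio tests across strata
#'
#' Applies [sex_ratio_test()] to each row of a counts table (e.g. by
#' length class, depth stratum, year or area).
#'
#' @param counts Data frame with columns `males`, `females` and optionally
#'   `stratum`.
#' @return Data frame with one row per stratum: `stratum`, `males`,
#'   `females`, `ratio`, `chi_square`, `p_value`, `low_n`.
#' @export
sex_ratio_by_stratum <- function(counts) {
  stopifnot(all(c("males", "females") %in% names(counts)))
  strata <- if ("stratum" %in% names(counts)) counts$stratum else
    seq_len(nrow(counts))
  res <- lapply(seq_len(nrow(counts)), function(i)
    sex_ratio_test(counts$males[i], counts$females[i], strata[i]))
  data.frame(stratum = strata, males = counts$males, females = counts$females,
             ratio = vapply(res, `[[`, numeric(1), "ratio"),
             chi_square = vapply(res, `[[`, numeric(1), "chi_square"),
             p_value = vapply(res, `[[`, numeric(1), "p_value"),
             low_n = vapply(res, `[[`, logical(1), "low_n"))
}
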