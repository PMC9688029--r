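#' Restructure a length-frequency table for ELEFAN scoring
#'
#' Applies the moving-average restructuring that turns raw counts into
#' peak/trough scores, column by column (per sampling date):
#' \enumerate{
#'   \item each count is divided by the centred moving average over `ma`
#'     bins (the window is truncated at the table edges) and 1 is
#'     subtracted, so bins above the local average score positive and bins
#'     below score negative; an all-zero window scores 0;
#'   \item isolated peaks are deflated: each positive score is divided by
#'     `2^nz`, where `nz` is the number of zero-count bins among its window
#'     neighbours;
#'   \item positive scores are rescaled so that, within the column, the
#'     summed positives balance the summed negatives in absolute value.
#' }
#' The available sum of peaks (ASP) is the sum of all positive scores in
#' the restructured matrix.
#'
#' @param x An [lfq()] object.
#' @param ma Moving-average window in bins; odd, >= 3, at most the number
#'   of bins. Default 5.
#' @return An object of class `"lfq_restructured"`: the `lfq` fields plus
#'   `scores` (same shape as `counts`), `asp` and `ma`.
#' @export
restructure_lfq <- function(x, ma = 5) {
  stopifnot(inherits(x, "lfq"))
  if (ma < 3 || ma %% 2 == 0) stop("'ma' must be an odd integer >= 3")
  nb <- nrow(x$counts)
  if (ma > nb) stop("'ma' (", ma, ") exceeds the number of bins (", nb, ")")
  half <- (ma - 1) / 2
  scores <- matrix(0, nb, ncol(x$counts), dimnames = dimnames(x$counts))
  for (j in seq_len(ncol(x$counts))) {
    cnt <- x$counts[, j]
    sc <- numeric(nb)
    for (i in seq_len(nb)) {
      win <- max(1, i - half):min(nb, i + half)
      mav <- mean(cnt[win])
      sc[i] <- if (mav > 0) cnt[i] / mav - 1 else 0
    }
    pos <- which(sc > 0)
    if (length(pos)) {
      nz <- vapply(pos, function(i) {
        win <- setdiff(max(1, i - half):min(nb, i + half), i)
        sum(cnt[win] == 0)
      }, numeric(1))
      sc[pos] <- sc[pos] / 2^nz
      sp <- sum(sc[sc > 0])
      sn <- -sum(sc[sc < 0])
      if (sp > 0 && sn > 0) sc[sc > 0] <- sc[sc > 0] * sn / sp
    }
    scores[, j] <- sc
  }
  out <- unclass(x)
  out$scores <- scores
  out$asp <- sum(scores[scores > 0])
  out$ma <- ma
  class(out) <- c("lfq_restructured", "lfq")
  out
}

#' @export
print.lfq_restructured <- function(x, ...) {
  cat(sprintf("Restructured length-frequency table (MA = %d): %d bins x %d dates, ASP = %.3f\n",
              x$ma, nrow(x$scores), ncol(x$scores), x$asp))
  invisible(x)
}

#' ELEFAN goodness-of-fit score Rn
#'
#' Traces the set of VBGF growth curves implied by `p` (one cohort per
#' year, anchored at `t_anchor`) across the sampling dates, collects every
#' restructured-score cell (bin, date) crossed by any curve (each cell
#' counted once), and sums those scores into the explained sum of peaks
#' (ESP). The score is `Rn = 10^(ESP/ASP) / 10`, in `(0, 1]`; a parameter
#' set whose curves pass through all peaks and no troughs reaches 1, one
#' that explains nothing scores 0.1.
#'
#' @param r An [restructure_lfq()] object with `asp > 0`.
#' @param p A [vbgf_params()] object.
#' @return The scalar score.
#' @export
elefan_score <- function(r, p) {
  stopifnot(inherits(r, "lfq_restructured"))
  if (r$asp <= 0) stop("ASP is zero: no peaks for growth curves to explain")
  esp <- elefan_esp(r, p)
  10^(esp / r$asp) / 10
}

# explained sum of peaks: union of cells crossed by the cohort curves
elefan_esp <- function(r, p) {
  dy <- decimal_date(r$dates)
  nb <- length(r$bin_lower)
  e0 <- r$bin_lower[1]
  w <- r$bin_width
  top <- min(r$bin_lower[nb] + w, 0.999 * p$linf)
  if (top <= max(0, e0)) return(0) # curves never reach the binned range
  # cohorts are traced to the approximate maximum age 3/k (the same tmax
  # convention the natural-mortality battery uses); beyond it the curve is
  # flat against the asymptote and the cohort effectively extinct
  amax <- min(-log(1 - top / p$linf) / p$k, 3 / p$k)
  births <- seq(floor(min(dy)) - ceiling(amax) - 1, floor(max(dy))) + p$t_anchor
  A <- outer(births, dy, function(b, d) d - b)
  L <- p$linf * (1 - exp(-p$k * A))
  L[A <= 0] <- NA
  bi <- floor((L - e0) / w) + 1
  bi[bi < 1 | bi > nb] <- NA
  ok <- which(!is.na(bi))
  if (!length(ok)) return(0)
  cells <- unique(bi[ok] + (col(bi)[ok] - 1) * nb)
  sum(r$scores[cells])
}

#' Genetic-algorithm settings for the ELEFAN search
#'
#' Real-coded GA with tournament selection, arithmetic crossover, Gaussian
#' mutation with a linearly decaying step, and elitism. All settings are
#' overridable; the defaults (population 50, 100 generations) are a
#' practical budget for the three-parameter ELEFAN surface.
#'
#' @param pop_size Population size.
#' @param generations Number of generations.
#' @param tournament_size Tournament size for parent selection.
#' @param p_crossover Per-offspring crossover probability.
#' @param p_mutation Per-gene mutation probability.
#' @param mutation_sd Initial mutation SD on the unit-scaled parameter
#'   space; decays linearly to 10% of itself over the run.
#' @param elitism Number of best individuals copied unchanged.
#' @return An object of class `"ga_settings"`.
#' @export
ga_settings <- function(pop_size = 50, generations = 100, tournament_size = 2,
                        p_crossover = 0.8, p_mutation = 0.3,
                        mutation_sd = 0.15, elitism = 2) {
  stopifnot(pop_size >= 4, generations >= 1, tournament_size >= 1,
            elitism >= 0, elitism < pop_size,
            p_crossover >= 0, p_crossover <= 1,
            p_mutation >= 0, p_mutation <= 1, mutation_sd > 0)
  structure(list(pop_size = pop_size, generations = generations,
                 tournament_size = tournament_size,
                 p_crossover = p_crossover, p_mutation = p_mutation,
                 mutation_sd = mutation_sd, elitism = elitism),
            class = "ga_settings")
}

# maximize fn over a box; ties in fitness broken by smaller first parameter
# (linf) for determinism. Operates on the current RNG stream.
ga_optimize <- function(fn, lower, upper, ctrl) {
  d <- length(lower)
  decode <- function(u) lower + u * (upper - lower)
  evalu <- function(U) apply(U, 1, function(u) fn(decode(u)))
  P <- matrix(stats::runif(ctrl$pop_size * d), ctrl$pop_size, d)
  fit <- evalu(P)
  better <- function(fa, ua, fb, ub) fa > fb || (fa == fb && ua[1] < ub[1])
  ord <- order(-fit, P[, 1])
  best_u <- P[ord[1], ]; best_f <- fit[ord[1]]
  for (g in seq_len(ctrl$generations)) {
    sdg <- ctrl$mutation_sd * (1 - 0.9 * g / ctrl$generations)
    ord <- order(-fit, P[, 1])
    Pn <- matrix(0, ctrl$pop_size, d)
    ne <- ctrl$elitism
    if (ne > 0) Pn[seq_len(ne), ] <- P[ord[seq_len(ne)], , drop = FALSE]
    for (i in seq(ne + 1, ctrl$pop_size)) {
      pick <- function() {
        cand <- sample.int(ctrl$pop_size, ctrl$tournament_size, replace = TRUE)
        cand[order(-fit[cand], P[cand, 1])[1]]
      }
      p1 <- P[pick(), ]
      child <- if (stats::runif(1) < ctrl$p_crossover) {
        p2 <- P[pick(), ]
        a <- stats::runif(d)
        a * p1 + (1 - a) * p2
      } else p1
      mut <- stats::runif(d) < ctrl$p_mutation
      if (any(mut))
        child[mut] <- child[mut] + stats::rnorm(sum(mut), 0, sdg)
      Pn[i, ] <- pmin(pmax(child, 0), 1)
    }
    P <- Pn
    fit <- evalu(P)
    ord <- order(-fit, P[, 1])
    if (better(fit[ord[1]], P[ord[1], ], best_f, best_u)) {
      best_u <- P[ord[1], ]; best_f <- fit[ord[1]]
    }
  }
  list(par = decode(best_u), value = best_f,
       evaluations = ctrl$pop_size * (ctrl$generations + 1))
}

#' Fit VBGF growth parameters by ELEFAN with a genetic algorithm
#'
#' Restructures the length-frequency table ([restructure_lfq()]), then
#' maximizes the ELEFAN score [elefan_score()] over `(linf, k, t_anchor)`
#' with a real-coded genetic algorithm. Confidence intervals come from a
#' non-parametric bootstrap that resamples each date's counts
#' multinomially (preserving per-date sample sizes), refits, and takes
#' 0.95 percentile intervals of `linf`, `k` and the growth performance
#' index. Deterministic given `seed`.
#'
#' The default search space is `linf` in `[0.8, 1.3] * Lmax` (with `Lmax`
#' the largest observed bin midpoint with a positive count), `k` in
#' `[0.01, 1]` year^-1 and `t_anchor` in `[0, 1)`.
#'
#' @param x An [lfq()] object with at least two sampling dates.
#' @param search_space Optional list with two-element `linf` and `k`
#'   ranges (and optionally `t_anchor`).
#' @param ga A [ga_settings()] object.
#' @param ma Restructuring window, passed to [restructure_lfq()].
#' @param n_bootstrap Number of bootstrap refits (0 = point estimate only).
#' @param seed Integer seed.
#' @return An object of class `"elefan_fit"` with elements `par`
#'   ([vbgf_params()] point estimate), `rn_score`, `phi_prime`, `ci`
#'   (matrix of 0.95 percentile bounds for `linf`, `k`, `phi_prime`),
#'   `boot` (bootstrap draws), `n_bootstrap`, `search_space`, `ga`, `ma`
#'   and the restructured data.
#' @export
fit_growth_ga <- function(x, search_space = NULL, ga = ga_settings(), ma = 5,
                          n_bootstrap = 0, seed = 1) {
  stopifnot(inherits(x, "lfq"), inherits(ga, "ga_settings"))
  if (ncol(x$counts) < 2L)
    stop("growth fitting needs at least two sampling dates")
  r <- restructure_lfq(x, ma)
  if (is.null(search_space)) {
    mids <- x$bin_lower + x$bin_width / 2
    lmax <- max(mids[rowSums(x$counts) > 0])
    search_space <- list(linf = c(0.8, 1.3) * lmax, k = c(0.01, 1))
  }
  if (is.null(search_space$t_anchor)) search_space$t_anchor <- c(0, 1)
  lower <- c(search_space$linf[1], search_space$k[1], search_space$t_anchor[1])
  upper <- c(search_space$linf[2], search_space$k[2], search_space$t_anchor[2])
  stopifnot(all(is.finite(c(lower, upper))), all(lower < upper))
  score_fn <- function(rr) function(v)
    elefan_score(rr, vbgf_params(v[1], v[2], min(v[3], 1 - 1e-9)))
  set.seed(seed)
  opt <- ga_optimize(score_fn(r), lower, upper, ga)
  point <- vbgf_params(opt$par[1], opt$par[2], min(opt$par[3], 1 - 1e-9))
  boot <- NULL
  ci <- NULL
  if (n_bootstrap > 0) {
    boot <- matrix(NA_real_, n_bootstrap, 3,
                   dimnames = list(NULL, c("linf", "k", "phi_prime")))
    for (b in seq_len(n_bootstrap)) {
      set.seed((seed + b) %% .Machine$integer.max)
      cb <- x$counts
      for (j in seq_len(ncol(cb))) {
        n_j <- sum(cb[, j])
        if (n_j > 0)
          cb[, j] <- stats::rmultinom(1, n_j, cb[, j] / n_j)
      }
      rb <- restructure_lfq(lfq(cb, x$bin_lower, x$dates), ma)
      ob <- if (rb$asp > 0) ga_optimize(score_fn(rb), lower, upper, ga) else
        list(par = c(NA, NA, NA))
      boot[b, ] <- c(ob$par[1], ob$par[2],
                     growth_performance_phi(ob$par[1], ob$par[2]))
    }
    ci <- apply(boot, 2, stats::quantile, probs = c(0.025, 0.975), na.rm = TRUE)
  }
  structure(list(par = point, rn_score = opt$value,
                 phi_prime = growth_performance_phi(point$linf, point$k),
                 ci = ci, boot = boot, n_bootstrap = n_bootstrap,
                 search_space = search_space, ga = ga, ma = ma,
                 restructured = r, seed = seed),
            class = "elefan_fit")
}

#' @export
print.elefan_fit <- function(x, ...) {
  cat("ELEFAN growth fit (genetic algorithm)\n")
  cat(sprintf("  Linf = %.2f cm, k = %.4f year^-1, t_anchor = %.3f\n",
              x$par$linf, x$par$k, x$par$t_anchor))
  cat(sprintf("  Rn = %.4f, phi' = %.3f\n", x$rn_score, x$phi_prime))
  if (!is.null(x$ci)) {
    cat(sprintf("  0.95 bootstrap CIs (%d resamples):\n", x$n_bootstrap))
    cat(sprintf("    Linf [%.2f, %.2f]  k [%.4f, %.4f]  phi' [%.3f, %.3f]\n",
                x$ci[1, "linf"], x$ci[2, "linf"], x$ci[1, "k"], x$ci[2, "k"],
                x$ci[1, "phi_prime"], x$ci[2, "phi_prime"]))
  }
  invisible(x)
}

#' @export
summary.elefan_fit <- function(object, ...) {
  print(object)
  cat(sprintf("  search space: Linf [%.1f, %.1f], k [%.3f, %.3f]; MA = %d; GA %d x %d\n",
              object$search_space$linf[1], object$search_space$linf[2],
              object$search_space$k[1], object$search_space$k[2],
              object$ma, object$ga$pop_size, object$ga$generations))
  invisible(object)
}

#' @export
coef.elefan_fit <- function(object, ...) {
  c(linf = object$par$linf, k = object$par$k, t_anchor = object$par$t_anchor)
}

#' @param object,x An `elefan_fit`.
#' @param t Ages (years) at which to predict mean length.
#' @param ... Unused.
#' @rdname fit_growth_ga
#' @export
predict.elefan_fit <- function(object, t, ...) {
  vbgf_length_at_age(object$par, t)
}

#' @rdname fit_growth_ga
#' @export
plot.elefan_fit <- function(x, ...) {
  r <- x$restructured
  graphics::image(x = as.numeric(r$dates), y = r$bin_lower + r$bin_width / 2,
                  z = t(r$scores),
                  col = grDevices::hcl.colors(21, "Blue-Red 2"),
                  xlab = "Date", ylab = "Fork length (cm)", ...)
  dy <- decimal_date(r$dates)
  amax <- -log(1 - min(0.999, (max(r$bin_lower) + r$bin_width) / x$par$linf)) / x$par$k
  births <- seq(floor(min(dy)) - ceiling(amax) - 1, floor(max(dy))) + x$par$t_anchor
  tt <- seq(min(dy) - 0.05, max(dy) + 0.05, length.out = 200)
  for (b in births) {
    a <- tt - b
    L <- ifelse(a > 0, x$par$linf * (1 - exp(-x$par$k * a)), NA)
    dts <- as.numeric(as.Date(paste0(floor(tt), "-01-01"))) +
      (tt - floor(tt)) * 365.25
    graphics::lines(dts, L, lwd = 1.2)
  }
  invisible(x)
}
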