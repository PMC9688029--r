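#' Fit a two-part (hurdle) additive species distribution model
#'
#' Fits the zero-inflated survey catch rates in two parts:
#' a binomial GAM (logit link) on presence/absence of all records, and a
#' Gaussian GAM (identity link) on the natural log of the positive catch
#' rates. Both parts share the additive structure
#' `s(longitude, latitude) + s(depth, k = basis_dim_depth) + substrate`,
#' with thin-plate regression splines and smoothness selected by REML
#' (GCV available). Records with `rpn = 0` contribute only to the binomial
#' part - the defining hurdle property.
#'
#' The reference substrate level is `C.Sed` (first alphabetically).
#' Substrate is dropped with a warning when only one level is present; a
#' non-converged or separated binomial part is reported through mgcv's
#' diagnostics, not an error.
#'
#' @param records Data frame of survey records with columns `longitude`,
#'   `latitude`, `depth` (m, in `[0, 600]`), `substrate` (one of
#'   [substrate_levels]) and `rpn` (>= 0, individuals per 10^3 hooks).
#' @param basis_dim_depth Basis dimension of the depth smooth (default 4).
#' @param basis_dim_space Basis dimension of the bivariate smooth; `NULL`
#'   (default) lets it shrink to fit small positive subsets.
#' @param method Smoothness-selection criterion, `"REML"` (default) or
#'   `"GCV.Cp"`.
#' @return An object of class `"hurdle_sdm"` with the two fitted
#'   [mgcv::gam()] parts (`binomial`, `gaussian`), per-part deviance
#'   explained and adjusted R^2, coefficient and smooth-term summaries,
#'   and the training covariate ranges.
#' @export
fit_hurdle_sdm <- function(records, basis_dim_depth = 4,
                           basis_dim_space = NULL,
                           method = c("REML", "GCV.Cp")) {
  method <- match.arg(method)
  need <- c("longitude", "latitude", "depth", "substrate", "rpn")
  if (!all(need %in% names(records)))
    stop("records must have columns: ", paste(need, collapse = ", "))
  bad <- setdiff(unique(as.character(records$substrate)), substrate_levels)
  if (length(bad))
    stop("unknown substrate level(s): ", paste(bad, collapse = ", "))
  if (any(records$rpn < 0)) stop("'rpn' must be >= 0")
  if (any(records$depth < 0 | records$depth > 600))
    stop("'depth' outside the surveyed range [0, 600] m")
  records$substrate <- droplevels(factor(as.character(records$substrate),
                                         levels = substrate_levels))
  records$present <- as.integer(records$rpn > 0)
  if (sum(records$present) < 2L || sum(!records$present) < 2L)
    stop("binomial part needs at least 2 presence and 2 absence records")
  pos <- records[records$rpn > 0, , drop = FALSE]
  if (nrow(pos) < 10L)
    stop("Gaussian part needs at least 10 positive records")
  pos$log_rpn <- log(pos$rpn)

  form_for <- function(resp, data) {
    sub_ok <- nlevels(droplevels(data$substrate)) > 1L
    if (!sub_ok)
      warning("substrate has a single level; factor dropped from the ", resp,
              " part")
    ks <- basis_dim_space
    if (is.null(ks))
      ks <- max(10, min(30, nrow(data) - basis_dim_depth -
                          nlevels(droplevels(data$substrate)) - 5))
    stats::as.formula(paste0(
      resp, " ~ s(longitude, latitude, k = ", ks, ") + s(depth, k = ",
      basis_dim_depth, ")", if (sub_ok) " + substrate" else ""))
  }
  bin <- mgcv::gam(form_for("present", records), family = stats::binomial(),
                   data = records, method = method)
  pos$substrate <- droplevels(pos$substrate)
  gau <- mgcv::gam(form_for("log_rpn", pos), family = stats::gaussian(),
                   data = pos, method = method)
  sb <- summary(bin); sg <- summary(gau)
  structure(list(
    binomial = bin, gaussian = gau,
    dev_expl = c(binomial = sb$dev.expl, gaussian = sg$dev.expl),
    r_sq = c(binomial = sb$r.sq, gaussian = sg$r.sq),
    coef_table = list(binomial = sb$p.table, gaussian = sg$p.table),
    smooth_table = list(binomial = sb$s.table, gaussian = sg$s.table),
    reference_substrate = "C.Sed", method = method,
    n = c(all = nrow(records), positive = nrow(pos)),
    ranges = list(longitude = range(records$longitude),
                  latitude = range(records$latitude),
                  depth = range(records$depth),
                  substrate = levels(droplevels(records$substrate)))),
    class = "hurdle_sdm")
}

#' @export
print.hurdle_sdm <- function(x, ...) {
  cat("Hurdle (two-part) additive species distribution model\n")
  cat(sprintf("  binomial part (presence, n = %d): deviance explained %.1f%%, adj. R^2 %.3f\n",
              x$n["all"], 100 * x$dev_expl["binomial"], x$r_sq["binomial"]))
  cat(sprintf("  Gaussian part (log abundance, n = %d positives): deviance explained %.1f%%, adj. R^2 %.3f\n",
              x$n["positive"], 100 * x$dev_expl["gaussian"], x$r_sq["gaussian"]))
  cat(sprintf("  smoothing: %s; reference substrate: %s\n", x$method,
              x$reference_substrate))
  invisible(x)
}

#' @export
summary.hurdle_sdm <- function(object, ...) {
  print(object)
  cat("\nBinomial part:\n")
  print(object$coef_table$binomial)
  print(object$smooth_table$binomial)
  cat("\nGaussian part:\n")
  print(object$coef_table$gaussian)
  print(object$smooth_table$gaussian)
  invisible(object)
}

#' Predict from a hurdle species distribution model
#'
#' Returns the presence probability (binomial part), the conditional
#' abundance on the positive scale (`exp` back-transform of the Gaussian
#' part, no bias correction), and optionally their product, the
#' unconditional expected catch rate. Records outside the training
#' covariate ranges are flagged as extrapolation, and unknown substrate
#' levels are an error.
#'
#' @param object A fitted [fit_hurdle_sdm()] model.
#' @param newdata Data frame with `longitude`, `latitude`, `depth`,
#'   `substrate`.
#' @param type `"parts"` (default) or `"combined"` to add the product
#'   column.
#' @param ... Unused.
#' @return Data frame with `p_presence`, `abundance_positive` and (for
#'   `type = "combined"`) `expected_rpn`; logical attribute
#'   `extrapolated` marks out-of-range rows.
#' @export
predict.hurdle_sdm <- function(object, newdata, type = c("parts", "combined"),
                               ...) {
  type <- match.arg(type)
  gau_levels <- levels(object$gaussian$model$substrate)
  seen <- if (is.null(gau_levels)) object$ranges$substrate else
    intersect(object$ranges$substrate, gau_levels)
  bad <- setdiff(unique(as.character(newdata$substrate)), seen)
  if (length(bad))
    stop("substrate level(s) not seen in training: ", paste(bad, collapse = ", "))
  extra <- newdata$depth < object$ranges$depth[1] |
    newdata$depth > object$ranges$depth[2] |
    newdata$longitude < object$ranges$longitude[1] |
    newdata$longitude > object$ranges$longitude[2] |
    newdata$latitude < object$ranges$latitude[1] |
    newdata$latitude > object$ranges$latitude[2]
  if (any(extra))
    warning(sum(extra), " record(s) outside the training covariate ranges ",
            "(extrapolation)")
  nd_bin <- newdata
  nd_bin$substrate <- factor(as.character(newdata$substrate),
                             levels = levels(object$binomial$model$substrate))
  nd_gau <- newdata
  nd_gau$substrate <- factor(as.character(newdata$substrate),
                             levels = levels(object$gaussian$model$substrate))
  p <- as.numeric(mgcv::predict.gam(object$binomial, nd_bin, type = "response"))
  mu <- as.numeric(mgcv::predict.gam(object$gaussian, nd_gau))
  out <- data.frame(p_presence = p, abundance_positive = exp(mu))
  if (type == "combined") out$expected_rpn <- out$p_presence * out$abundance_positive
  attr(out, "extrapolated") <- extra
  out
}

#' Depth response profile of a fitted hurdle model
#'
#' Evaluates one part of the model along a depth grid with position held
#' at the training medians and substrate at the reference level, isolating
#' the fitted depth response (useful to locate the depth optimum).
#'
#' @param object A fitted [fit_hurdle_sdm()] model.
#' @param part `"gaussian"` (default) or `"binomial"`.
#' @param depths Depth grid in m.
#' @return Data frame `depth`, `fit` (link scale).
#' @export
depth_profile <- function(object, part = c("gaussian", "binomial"),
                          depths = seq(0, 600, by = 5)) {
  part <- match.arg(part)
  mod <- object[[part]]
  nd <- data.frame(
    depth = depths,
    longitude = stats::median(mod$model$longitude),
    latitude = stats::median(mod$model$latitude))
  if (!is.null(mod$model$substrate)) {
    lev <- levels(mod$model$substrate)
    ref <- if (object$reference_substrate %in% lev)
      object$reference_substrate else lev[1]
    nd$substrate <- factor(ref, levels = lev)
  }
  data.frame(depth = depths,
             fit = as.numeric(mgcv::predict.gam(mod, nd)))
}

#' @param x A `hurdle_sdm` object.
#' @param ... Unused.
#' @rdname fit_hurdle_sdm
#' @export
plot.hurdle_sdm <- function(x, ...) {
  op <- graphics::par(mfrow = c(1, 2))
  on.exit(graphics::par(op))
  pb <- depth_profile(x, "binomial")
  graphics::plot(pb$depth, stats::plogis(pb$fit), type = "l",
                 xlab = "Depth (m)", ylab = "P(presence)")
  pg <- depth_profile(x, "gaussian")
  graphics::plot(pg$depth, exp(pg$fit), type = "l",
                 xlab = "Depth (m)", ylab = "Abundance | presence")
  invisible(x)
}
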