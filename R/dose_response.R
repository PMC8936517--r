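#' Construct a dose-response curve object
#'
#' Container for a fitted (or ground-truth) concentration-response model.
#' For `model = "LL4"` the midpoint `e` is a concentration in nM (see
#' [ll4_viability()]); for `model = "L4"` it is in log10 nM (see
#' [l4_viability()]). Curves are canonicalized so `d >= c` (top above
#' bottom).
#'
#' @param model `"LL4"` or `"L4"`.
#' @param b slope; `c` lower asymptote (%); `d` upper asymptote (%);
#'   `e` midpoint (nM for LL4, log10 nM for L4).
#' @param c,d,e see `b`.
#' @param conc_range tested concentration range `(c_min, c_max)` in nM.
#' @param converged logical fit status.
#' @param rss residual sum of squares.
#' @param n_points number of points used in the fit.
#' @return object of class `dose_response_curve`.
#' @export
dose_response_curve <- function(model = c("LL4", "L4"), b, c, d, e,
                                conc_range, converged = TRUE, rss = NA_real_,
                                n_points = NA_integer_) {
  model <- match.arg(model)
  stopifnot(length(conc_range) == 2, conc_range[1] > 0,
            conc_range[1] < conc_range[2])
  if (d < c) {  # canonicalize: top >= bottom, flipping the slope sign
    tmp <- c; c <- d; d <- tmp; b <- -b
  }
  structure(list(model = model, b = b, c = c, d = d, e = e,
                 conc_range = as.numeric(conc_range), converged = converged,
                 rss = rss, n_points = n_points),
            class = "dose_response_curve")
}

#' @export
print.dose_response_curve <- function(x, ...) {
  mid <- if (x$model == "LL4") paste0(signif(x$e, 4), " nM")
         else paste0(signif(x$e, 4), " log10 nM")
  cat(sprintf("<%s curve> top %.4g%%, bottom %.4g%%, slope %.4g, midpoint %s%s\n",
              x$model, x$d, x$c, x$b, mid,
              if (x$converged) "" else " [not converged]"))
  invisible(x)
}

#' Predict viability from a fitted curve
#'
#' @param curve a [dose_response_curve()].
#' @param conc concentrations in nM.
#' @return viability in percent.
#' @export
predict_viability <- function(curve, conc) {
  if (curve$model == "LL4") {
    ll4_viability(conc, curve$b, curve$c, curve$d, curve$e)
  } else {
    l4_viability(conc, curve$b, curve$c, curve$d, curve$e)
  }
}

#' Predicted inhibition (percent)
#'
#' `I(x) = 100 - V(x)`.
#' @inheritParams predict_viability
#' @return inhibition in percent (unclamped).
#' @export
predict_inhibition <- function(curve, conc) 100 - predict_viability(curve, conc)

# Parameter bounds keep 4-parameter asymptotes identifiable on 6-point data:
# bottom in [-20, 50], top in [50, 150], slope in [0.1, 10], midpoint within
# the tested range +/- 2 decades.
fit_bounds <- function(conc_range) {
  list(lower_c = -20, upper_c = 50, lower_d = 50, upper_d = 150,
       lower_b = 0.1, upper_b = 10,
       lower_e = conc_range[1] / 100, upper_e = conc_range[2] * 100)
}

# One bounded Levenberg-Marquardt run; returns list(par, rss, ok).
nlslm_run <- function(resid_fn, start, lower, upper) {
  fit <- try(minpack.lm::nls.lm(
    par = start, fn = resid_fn, lower = lower, upper = upper,
    control = minpack.lm::nls.lm.control(maxiter = 200)
  ), silent = TRUE)
  if (inherits(fit, "try-error")) return(list(ok = FALSE))
  rss <- sum(fit$fvec^2)
  ok <- fit$info %in% 1:3 && is.finite(rss) && all(is.finite(unlist(fit$par)))
  list(par = fit$par, rss = rss, ok = ok)
}

constant_curve <- function(conc, viability, model = "LL4", converged = TRUE) {
  m <- mean(viability)
  dose_response_curve(model, b = 0, c = m, d = m,
                      e = if (model == "LL4") sqrt(prod(range(conc))) else
                        mean(log10(range(conc))),
                      conc_range = range(conc), converged = converged,
                      rss = sum((viability - m)^2),
                      n_points = length(conc))
}

#' Fit a concentration-response curve
#'
#' Bounded nonlinear least squares (Levenberg-Marquardt) of the
#' four-parameter log-logistic model LL4, with the midpoint optimized on the
#' natural concentration scale and three starts (midpoint at the lowest,
#' geometric-mid and highest tested concentration; slope 1; asymptotes at
#' the observed extremes). On convergence failure — solver failure,
#' non-finite parameters, or the midpoint pinned at a bound with a residual
#' sum of squares no better than the constant model — the logistic model L4
#' is refitted on the log10-concentration axis. All-identical responses
#' yield a degenerate constant curve.
#'
#' @param conc concentrations in nM.
#' @param viability normalized viabilities in percent (unclamped).
#' @param flagged optional logical vector; flagged points are excluded.
#' @return a [dose_response_curve()].
#' @export
fit_curve <- function(conc, viability, flagged = NULL) {
  stopifnot(length(conc) == length(viability))
  if (!is.null(flagged)) {
    conc <- conc[!flagged]
    viability <- viability[!flagged]
  }
  keep <- is.finite(conc) & is.finite(viability) & conc > 0
  conc <- conc[keep]; viability <- viability[keep]
  n_distinct <- length(unique(conc))
  if (n_distinct < 3) {
    stop("need >= 3 distinct concentrations to fit a curve", call. = FALSE)
  }
  cr <- range(conc)
  if (stats::sd(viability) == 0) return(constant_curve(conc, viability))
  bounds <- fit_bounds(cr)
  rss_const <- sum((viability - mean(viability))^2)
  c0 <- clamp(min(viability), bounds$lower_c, bounds$upper_c)
  d0 <- clamp(max(viability), bounds$lower_d, bounds$upper_d)

  if (n_distinct == 3) {
    # too few doses for 4 free parameters: asymptotes fixed at 0/100
    resid_fn <- function(p) viability - ll4_viability(conc, p[["b"]], 0, 100, p[["e"]])
    best <- NULL
    for (e0 in c(cr[1], sqrt(prod(cr)), cr[2])) {
      r <- nlslm_run(resid_fn, c(b = 1, e = e0),
                     lower = c(bounds$lower_b, bounds$lower_e),
                     upper = c(bounds$upper_b, bounds$upper_e))
      if (r$ok && (is.null(best) || r$rss < best$rss)) best <- r
    }
    if (!is.null(best)) {
      return(dose_response_curve("LL4", b = best$par[["b"]], c = 0, d = 100,
                                 e = best$par[["e"]], conc_range = cr,
                                 converged = TRUE, rss = best$rss,
                                 n_points = length(conc)))
    }
    return(constant_curve(conc, viability, converged = FALSE))
  }

  # LL4: midpoint on the natural concentration scale
  resid_ll4 <- function(p) {
    viability - ll4_viability(conc, p[["b"]], p[["c"]], p[["d"]], p[["e"]])
  }
  lower <- c(b = bounds$lower_b, c = bounds$lower_c, d = bounds$lower_d,
             e = bounds$lower_e)
  upper <- c(b = bounds$upper_b, c = bounds$upper_c, d = bounds$upper_d,
             e = bounds$upper_e)
  best <- NULL
  for (e0 in c(cr[1], sqrt(prod(cr)), cr[2])) {
    for (c0i in unique(c(c0, 0))) {  # weak responders clamp min(v) at the bound
      r <- nlslm_run(resid_ll4, c(b = 1, c = c0i, d = d0, e = e0), lower, upper)
      if (r$ok && (is.null(best) || r$rss < best$rss)) best <- r
    }
  }
  if (!is.null(best)) {
    e_hat <- best$par[["e"]]
    pinned <- e_hat <= bounds$lower_e * 1.0001 || e_hat >= bounds$upper_e * 0.9999
    if (!(pinned && best$rss >= rss_const)) {
      return(dose_response_curve("LL4", b = best$par[["b"]], c = best$par[["c"]],
                                 d = best$par[["d"]], e = e_hat,
                                 conc_range = cr, converged = TRUE,
                                 rss = best$rss, n_points = length(conc)))
    }
  }

  # L4 fallback: logistic on the log10-concentration axis
  resid_l4 <- function(p) {
    viability - l4_viability(conc, p[["b"]], p[["c"]], p[["d"]], p[["m"]])
  }
  lcr <- log10(cr)
  lower_l4 <- c(b = 0.1, c = bounds$lower_c, d = bounds$lower_d, m = lcr[1] - 2)
  upper_l4 <- c(b = 25, c = bounds$upper_c, d = bounds$upper_d, m = lcr[2] + 2)
  best <- NULL
  for (m0 in c(lcr[1], mean(lcr), lcr[2])) {
    r <- nlslm_run(resid_l4, c(b = 2, c = c0, d = d0, m = m0),
                   lower_l4, upper_l4)
    if (r$ok && (is.null(best) || r$rss < best$rss)) best <- r
  }
  if (!is.null(best)) {
    return(dose_response_curve("L4", b = best$par[["b"]], c = best$par[["c"]],
                               d = best$par[["d"]], e = best$par[["m"]],
                               conc_range = cr, converged = TRUE,
                               rss = best$rss, n_points = length(conc)))
  }
  constant_curve(conc, viability, model = "L4", converged = FALSE)
}

#' Inhibitory concentration at a given inhibition level
#'
#' Solves `I(x) = level` on the fitted curve, restricted to the tested
#' concentration range extended one log-decade on each side (reported
#' concentrations beyond that would be wild extrapolations). Returns
#' `NA_real_` ("not reached") when the curve's maximum inhibition over that
#' span stays below `level`.
#'
#' @param curve a [dose_response_curve()].
#' @param level target inhibition in percent, strictly inside (0, 100).
#' @return concentration in nM, or `NA_real_` when not reached.
#' @export
ic_value <- function(curve, level) {
  if (level <= 0 || level >= 100) {
    stop("level must be strictly inside (0, 100)", call. = FALSE)
  }
  span <- log10(curve$conc_range) + c(-1, 1)
  xs <- seq(span[1], span[2], length.out = 512)
  inh <- predict_inhibition(curve, 10^xs)
  if (max(inh) < level) return(NA_real_)
  i <- which(inh >= level)[1]
  if (i == 1) return(10^xs[1])
  root <- stats::uniroot(function(x) predict_inhibition(curve, 10^x) - level,
                         lower = xs[i - 1], upper = xs[i],
                         tol = .Machine$double.eps^0.5)
  10^root$root
}

#' Cohort-average IC20 (priming concentration)
#'
#' Geometric mean of the reached IC20 values for one drug across a cohort's
#' fitted curves; samples whose curves never reach 20% inhibition are
#' excluded and counted. This average is the fixed priming concentration fed
#' to the combination designs.
#'
#' @param curves list of [dose_response_curve()] objects for one drug.
#' @param level inhibition level in percent (default 20).
#' @return list with `ic` (nM), `n_used`, `n_excluded`.
#' @export
cohort_ic20 <- function(curves, level = 20) {
  ics <- vapply(curves, ic_value, numeric(1), level = level)
  used <- ics[!is.na(ics)]
  if (length(used) == 0) {
    stop("no sample reaches ", level, "% inhibition", call. = FALSE)
  }
  list(ic = exp(mean(log(used))), n_used = length(used),
       n_excluded = sum(is.na(ics)))
}
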