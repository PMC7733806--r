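#' @title Functional-assay computations
#' @name kinetics_chem
#' @description
#' Two-phase exponential association fits of fluorescence binding
#' transients with a parameter-free half-time, enzyme-coupled ATPase
#' specific activity from NADH absorbance slopes, activity ratios, and
#' 1:1 Ca/EGTA speciation with an apparent dissociation constant.
NULL

#' Two-phase association model
#'
#' `F(t) = F0 + A1 (1 - exp(-k1 t)) + A2 (1 - exp(-k2 t))`
#'
#' @param t time, s
#' @param F0 baseline intensity
#' @param A1,A2 phase amplitudes
#' @param k1,k2 rate constants, 1/s
#' @return model intensity at `t`
#' @export
two_phase_model <- function(t, F0, A1, k1, A2, k2) {
  F0 + A1 * (1 - exp(-k1 * t)) + A2 * (1 - exp(-k2 * t))
}

#' Half-time of a two-phase association curve
#'
#' The time at which the curve has covered half of its total fitted
#' amplitude, `F(t) = F0 + (A1 + A2) / 2`, solved numerically by
#' bisection (uniroot). For a single phase this reduces to `log(2)/k`.
#' Defined for curves with positive total amplitude; the half-time of a
#' monotone two-phase rise always lies between `log(2)/max(k1,k2)` and
#' `log(2)/min(k1,k2)`.
#'
#' @param F0,A1,k1,A2,k2 model parameters
#' @return half-time in s
#' @export
two_phase_half_time <- function(F0, A1, k1, A2, k2) {
  total <- A1 + A2
  if (total == 0) stop("zero total amplitude; half-time undefined")
  target <- F0 + total / 2
  f <- function(t) two_phase_model(t, F0, A1, k1, A2, k2) - target
  upper <- log(2) / min(k1, k2)
  # widen until bracketed (mixed-sign amplitudes can shift the crossing)
  lo <- 0
  hi <- upper
  tries <- 0
  while (f(lo) * f(hi) > 0 && tries < 60) {
    hi <- hi * 2
    tries <- tries + 1
  }
  if (f(lo) * f(hi) > 0) stop("could not bracket the half-amplitude crossing")
  stats::uniroot(f, c(lo, hi), tol = 1e-12)$root
}

#' Fit a two-phase association law to a fluorescence trace
#'
#' Least-squares (Levenberg-Marquardt) fit of the two-phase association
#' model to the points with `t <= window`, using deterministic
#' multi-start initialization over rate pairs spanning 0.01-10 1/s.
#' The half-time (time to half of the total fitted amplitude) is solved
#' numerically from the fitted curve.
#'
#' @param t time values, s (increasing)
#' @param F intensity values
#' @param window fit window in s (default 60, i.e. only the first 60 s
#'   of the transient are fitted)
#' @return object of class `kinetics_fit`: list with `F0`, `A1`, `k1`,
#'   `A2`, `k2` (ordered so `k1 >= k2`), `t_half`, `rss`, `window`,
#'   `n_points`, `single_phase_warning`
#' @export
fit_two_phase_association <- function(t, F, window = 60) {
  keep <- t <= window
  t <- t[keep]
  F <- F[keep]
  if (length(t) < 8) stop("need at least 8 points inside the fit window")
  if (any(diff(t) <= 0)) stop("time values must be increasing")

  amp <- max(F) - F[1]
  if (amp == 0) amp <- max(abs(F), 1e-6)
  ks <- exp(seq(log(0.01), log(10), length.out = 4))
  # 8 deterministic starts: fast/slow rate pairs across the grid
  starts <- list()
  for (i in 2:4) for (j in 1:(i - 1)) {
    starts[[length(starts) + 1]] <- c(k1 = ks[i], k2 = ks[j])
  }
  starts[[7]] <- c(k1 = ks[4], k2 = ks[4] / 2)
  starts[[8]] <- c(k1 = ks[1] * 2, k2 = ks[1])

  resid_fn <- function(par) {
    two_phase_model(t, par[1], par[2], par[3], par[4], par[5]) - F
  }
  best <- NULL
  best_rss <- Inf
  diagnostics <- character(0)
  for (s in starts) {
    fit <- tryCatch(
      suppressWarnings(minpack.lm::nls.lm(
        par = c(F0 = F[1], A1 = amp / 2, k1 = s[["k1"]],
                A2 = amp / 2, k2 = s[["k2"]]),
        lower = c(-Inf, -Inf, 1e-6, -Inf, 1e-6),
        fn = resid_fn,
        control = minpack.lm::nls.lm.control(maxiter = 500))),
      error = function(e) e)
    if (inherits(fit, "error")) {
      diagnostics <- c(diagnostics, conditionMessage(fit))
      next
    }
    rss <- sum(fit$fvec^2)
    if (rss < best_rss) {
      best <- fit
      best_rss <- rss
    }
  }
  if (is.null(best)) {
    stop("two-phase fit failed to converge from any start; diagnostics: ",
         paste(unique(diagnostics), collapse = "; "))
  }
  p <- best$par
  # order phases so k1 is the faster rate
  if (p[["k1"]] < p[["k2"]]) {
    p <- c(F0 = p[["F0"]], A1 = p[["A2"]], k1 = p[["k2"]],
           A2 = p[["A1"]], k2 = p[["k1"]])
  }
  single_phase <- p[["k1"]] / p[["k2"]] < 1.05
  if (single_phase) {
    warning("fitted rates nearly equal (k1/k2 < 1.05); ",
            "data may be single-phase")
  }
  t_half <- two_phase_half_time(p[["F0"]], p[["A1"]], p[["k1"]],
                                p[["A2"]], p[["k2"]])
  structure(list(F0 = p[["F0"]], A1 = p[["A1"]], k1 = p[["k1"]],
                 A2 = p[["A2"]], k2 = p[["k2"]],
                 t_half = t_half, rss = best_rss, window = window,
                 n_points = length(t),
                 single_phase_warning = single_phase),
            class = "kinetics_fit")
}

#' @export
print.kinetics_fit <- function(x, ...) {
  cat(sprintf(
    "<kinetics_fit> F0=%.4g A1=%.4g k1=%.4g/s A2=%.4g k2=%.4g/s | t1/2=%.3g s (rss %.3g, %d pts <= %g s)\n",
    x$F0, x$A1, x$k1, x$A2, x$k2, x$t_half, x$rss, x$n_points, x$window))
  invisible(x)
}

#' ATPase specific activity from an enzyme-coupled NADH assay
#'
#' In the coupled assay each ATP hydrolysed regenerates via pyruvate
#' kinase/lactate dehydrogenase at the cost of one NADH, so the NADH
#' absorbance decay at 340 nm reads out ATP turnover directly:
#' `activity = |slope| / (epsilon * path) / protein * volume_factor`,
#' in umol ATP per mg protein per minute.
#'
#' @param slope_A340_per_min absorbance change per minute (negative for
#'   NADH oxidation; the magnitude is used)
#' @param epsilon_mM NADH molar extinction coefficient at 340 nm,
#'   1/(mM cm) (default 6.22)
#' @param path_cm optical path length, cm
#' @param protein_mg_per_ml protein concentration in the cuvette, mg/mL
#' @param volume_factor optional dilution correction (default 1)
#' @return specific activity, umol ATP / mg / min
#' @export
specific_activity <- function(slope_A340_per_min, epsilon_mM = 6.22,
                              path_cm = 1, protein_mg_per_ml,
                              volume_factor = 1) {
  if (protein_mg_per_ml <= 0) stop("protein concentration must be positive")
  stopifnot(epsilon_mM > 0, path_cm > 0)
  # |dA/dt| / (eps * l) is mM/min = umol/mL/min; divide by mg/mL
  abs(slope_A340_per_min) / (epsilon_mM * path_cm) /
    protein_mg_per_ml * volume_factor
}

#' Activity ratio in percent
#' @param a,b activities in the same unit; `b` must be positive
#' @return `100 * a / b`
#' @export
activity_ratio <- function(a, b) {
  if (b <= 0) stop("reference activity must be positive")
  100 * a / b
}

#' Free calcium in a Ca/EGTA buffer (1:1 binding)
#'
#' Solves the 1:1 binding equilibrium
#' `free^2 + (Kd + EGTA_tot - Ca_tot) free - Kd Ca_tot = 0`
#' for the free Ca2+ concentration (positive root), with an apparent,
#' pH-dependent dissociation constant supplied by the caller. Mass is
#' conserved: `free + bound = Ca_tot`, and `bound <= min(Ca_tot,
#' EGTA_tot)`.
#'
#' @param ca_total total calcium, molar
#' @param egta_total total EGTA, molar
#' @param Kd_app apparent Ca-EGTA dissociation constant at the working
#'   pH, molar
#' @return object of class `speciation_result`: list with `free_ca`,
#'   `bound_ca`, `free_egta`, `Kd_app` (molar)
#' @export
free_calcium <- function(ca_total, egta_total, Kd_app) {
  if (ca_total < 0 || egta_total < 0) stop("concentrations must be non-negative")
  if (Kd_app <= 0) stop("Kd_app must be positive")
  b <- Kd_app + egta_total - ca_total
  free <- (-b + sqrt(b^2 + 4 * Kd_app * ca_total)) / 2
  free <- min(max(free, 0), ca_total)
  bound <- ca_total - free
  structure(list(free_ca = free, bound_ca = bound,
                 free_egta = egta_total - bound, Kd_app = Kd_app),
            class = "speciation_result")
}

#' @export
print.speciation_result <- function(x, ...) {
  cat(sprintf(
    "<speciation_result> free Ca %.4g M, bound %.4g M, free EGTA %.4g M (Kd_app %.3g M)\n",
    x$free_ca, x$bound_ca, x$free_egta, x$Kd_app))
  invisible(x)
}
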