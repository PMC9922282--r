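#' Initial-rate slope of an enzymatic progress curve
#'
#' Enzyme activity is read out as the slope of product fluorescence versus
#' time over the initial, linear part of the progress curve (ordinary least
#' squares). The default window mirrors a plate-reader schedule of eight reads
#' at 15 s spacing (0-105 s).
#'
#' @param time Time points, seconds.
#' @param signal Fluorescence readings (same length as `time`).
#' @param n_reads Number of leading reads to use; default 8.
#' @return Slope in signal units per second.
#' @export
activity_slope <- function(time, signal, n_reads = 8L) {
  stopifnot(length(time) == length(signal))
  n <- min(n_reads, length(time))
  if (n < 2L) stop("need at least 2 points to fit a slope")
  ord <- order(time)
  t <- time[ord][seq_len(n)]
  y <- signal[ord][seq_len(n)]
  unname(stats::coef(stats::lm(y ~ t))[2L])
}

#' Fit Hill (or Michaelis-Menten) kinetics to an initial-rate titration
#'
#' Least-squares fit of `v = Vmax * S^n / (K^n + S^n)` to initial rates over
#' a substrate titration; with the exponent pinned at 1 this is the
#' Michaelis-Menten hyperbola. Replicates enter as independent points.
#'
#' @param conc Substrate concentrations (µM), >= 4 distinct values.
#' @param rate Initial rates (signal/s), same length.
#' @param fix_hill `NULL` (default) to fit the Hill exponent freely, or a
#'   number (typically 1) to pin it.
#' @return One-row tibble: `km` (µM), `vmax`, `hill`, `km_se`, `vmax_se`,
#'   `hill_se`, `r_squared`, `converged`, `flag` (`"extrapolated_km"` when the
#'   fitted Km falls outside 100x the titration range).
#' @export
fit_hill_kinetics <- function(conc, rate, fix_hill = NULL) {
  stopifnot(length(conc) == length(rate), all(conc > 0))
  if (length(unique(conc)) < 4L) {
    stop("need >= 4 distinct substrate concentrations")
  }
  out <- function(km, vmax, hill, km_se, vmax_se, hill_se, r2, conv, flag) {
    tibble::tibble(km = km, vmax = vmax, hill = hill, km_se = km_se,
                   vmax_se = vmax_se, hill_se = hill_se, r_squared = r2,
                   converged = conv, flag = flag)
  }
  vmax0 <- max(rate) * 1.2
  km0 <- stats::approx(rate, conc, xout = max(rate) / 2, ties = mean)$y
  if (!is.finite(km0) || km0 <= 0) km0 <- exp(mean(log(range(conc))))

  fit <- if (is.null(fix_hill)) {
    .lm_fit(list(vmax = vmax0, km = km0, n = 1),
            function(p) rate - p$vmax * conc^p$n / (p$km^p$n + conc^p$n),
            lower = c(1e-9, 1e-9, 0.1), upper = c(Inf, Inf, 10))
  } else {
    stopifnot(fix_hill > 0)
    .lm_fit(list(vmax = vmax0, km = km0),
            function(p) rate - p$vmax * conc^fix_hill /
              (p$km^fix_hill + conc^fix_hill),
            lower = c(1e-9, 1e-9), upper = c(Inf, Inf))
  }
  if (is.null(fit)) {
    return(out(NA_real_, NA_real_, NA_real_, NA_real_, NA_real_, NA_real_,
               NA_real_, FALSE, "non_convergence"))
  }
  r2 <- 1 - fit$deviance / sum((rate - mean(rate))^2)
  km <- unname(fit$coef["km"])
  flag <- if (km > 100 * max(conc) || km < min(conc) / 100) "extrapolated_km"
          else NA_character_
  out(km, unname(fit$coef["vmax"]),
      if (is.null(fix_hill)) unname(fit$coef["n"]) else fix_hill,
      unname(fit$se["km"]), unname(fit$se["vmax"]),
      if (is.null(fix_hill)) unname(fit$se["n"]) else NA_real_,
      r2, TRUE, flag)
}

#' Percent inhibition relative to an uninhibited reference
#'
#' `100 * (1 - slope_drug / slope_reference)`, clamped to `[-10, 110]`
#' (out-of-range inputs are clamped with a warning; small negative values
#' arise from replicate noise at zero inhibition).
#'
#' @param slope_drug Initial-rate slope(s) with inhibitor.
#' @param slope_reference Uninhibited reference slope (> 0).
#' @return Percent inhibition, same length as `slope_drug`.
#' @export
percent_inhibition <- function(slope_drug, slope_reference) {
  if (length(slope_reference) != 1L || !is.finite(slope_reference) ||
      slope_reference <= 0) {
    stop("slope_reference must be a single positive value")
  }
  p <- 100 * (1 - slope_drug / slope_reference)
  oob <- p < -10 | p > 110
  if (any(oob)) {
    warning(sum(oob), " percent-inhibition value(s) outside [-10, 110]; clamped")
    p <- pmin(pmax(p, -10), 110)
  }
  p
}

#' Fit a three-parameter logistic dose-response (IC50) curve
#'
#' Percent inhibition versus inhibitor concentration is fitted to the
#' three-parameter logistic with unit Hill slope,
#' `y = bottom + (top - bottom) / (1 + IC50 / x)` (the GraphPad
#' "dose-response (three parameters)" model). IC50 inherits the unit of the
#' concentration axis.
#'
#' @param conc Inhibitor concentrations (> 0), >= 5 values spanning the
#'   transition, typically log-spaced.
#' @param inhibition Percent inhibition values, same length.
#' @param pin_limits If `TRUE`, fix `bottom = 0` and `top = 100`.
#' @param min_span Minimum observed response span (percent) below which the
#'   data are flagged as showing no transition; default 10.
#' @return One-row tibble: `ic50`, `top`, `bottom`, `ic50_se`, `top_se`,
#'   `bottom_se`, `r_squared`, `converged`, `flag` (`"no_transition"` or
#'   `"unbounded"` when the IC50 falls outside the tested range).
#' @export
fit_ic50 <- function(conc, inhibition, pin_limits = FALSE, min_span = 10) {
  stopifnot(length(conc) == length(inhibition), all(conc > 0))
  if (length(unique(conc)) < 5L) stop("need >= 5 inhibitor concentrations")
  out <- function(ic50, top, bottom, ic50_se, top_se, bottom_se, r2, conv, flag) {
    tibble::tibble(ic50 = ic50, top = top, bottom = bottom, ic50_se = ic50_se,
                   top_se = top_se, bottom_se = bottom_se, r_squared = r2,
                   converged = conv, flag = flag)
  }
  span <- diff(range(inhibition))
  if (span < min_span) {
    return(out(NA_real_, NA_real_, NA_real_, NA_real_, NA_real_, NA_real_,
               NA_real_, FALSE, "no_transition"))
  }
  mid <- (max(inhibition) + min(inhibition)) / 2
  ord <- order(conc)
  ic0 <- stats::approx(inhibition[ord], conc[ord], xout = mid, ties = mean)$y
  if (!is.finite(ic0) || ic0 <= 0) ic0 <- exp(mean(log(range(conc))))
  # fitted on log(IC50) for numerical conditioning; back-transformed below
  lx <- log(conc)
  fit <- if (pin_limits) {
    .lm_fit(list(lic = log(ic0)),
            function(p) inhibition - 100 / (1 + exp(p$lic - lx)))
  } else {
    .lm_fit(list(lic = log(ic0), top = max(inhibition),
                 bottom = min(inhibition)),
            function(p) inhibition - p$bottom -
              (p$top - p$bottom) / (1 + exp(p$lic - lx)))
  }
  if (is.null(fit)) {
    return(out(NA_real_, NA_real_, NA_real_, NA_real_, NA_real_, NA_real_,
               NA_real_, FALSE, "non_convergence"))
  }
  cf <- fit$coef
  ses <- fit$se
  r2 <- 1 - fit$deviance / sum((inhibition - mean(inhibition))^2)
  ic50 <- exp(unname(cf["lic"]))
  ic50_se <- ic50 * unname(ses["lic"])   # delta method
  flag <- if (ic50 < min(conc) || ic50 > max(conc)) "unbounded" else NA_character_
  out(ic50,
      if (pin_limits) 100 else unname(cf["top"]),
      if (pin_limits) 0 else unname(cf["bottom"]),
      ic50_se,
      if (pin_limits) NA_real_ else unname(ses["top"]),
      if (pin_limits) NA_real_ else unname(ses["bottom"]),
      r2, TRUE, flag)
}
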