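#' Fraction unmodified from integrated peak areas
#'
#' For a site observed at one exposure/replicate, the fraction of the peptide
#' population that escaped oxidative modification is computed from integrated
#' MS peak areas: for modified species `j`,
#' `F_u = 1 - A_m[j] / (A_u + sum(A_m))`, and the site-level aggregate is
#' `F_u = 1 - sum(A_m) / (A_u + sum(A_m))`.
#'
#' @param area_unmodified Integrated area of the unmodified peptide (`A_u`).
#' @param areas_modified Numeric vector of integrated areas, one per modified
#'   species (`A_m`).
#' @param species Integer index of a single modified species, or `NULL`
#'   (default) for the site-level aggregate over all modified species.
#' @return Fraction unmodified in `[0, 1]`.
#' @export
fraction_unmodified <- function(area_unmodified, areas_modified, species = NULL) {
  if (length(area_unmodified) != 1L || !is.finite(area_unmodified)) {
    stop("area_unmodified must be a single finite value")
  }
  if (area_unmodified < 0 || any(areas_modified < 0)) {
    stop("malformed input: negative peak area")
  }
  total <- area_unmodified + sum(areas_modified)
  if (total <= 0) {
    stop("unquantifiable record: all peak areas are zero")
  }
  if (is.null(species)) {
    1 - sum(areas_modified) / total
  } else {
    if (species < 1L || species > length(areas_modified)) {
      stop("species index out of range")
    }
    1 - areas_modified[species] / total
  }
}

#' Assemble a per-site exposure series of fraction-unmodified points
#'
#' Collapses a long peak-area table (one modified species per row) into one
#' fraction-unmodified point per (exposure time, replicate) cell for a site.
#' Replicates are kept as independent observations and never averaged, so the
#' standard duplicate-reactions-at-four-time-points design yields eight
#' independent data elements per site.
#'
#' @param table Peak-area table as returned by [read_peak_area_csv()] or
#'   [gen_hrf_dataset()]: columns `site_id`, `exposure_time` (seconds),
#'   `replicate_id`, `area_unmodified`, `area_modified` (one row per modified
#'   species).
#' @param site One `site_id` to extract.
#' @param species Optional modified-species label to restrict to a single
#'   species; default uses the site-level aggregate.
#' @return A tibble with columns `site_id`, `exposure_time`, `replicate_id`,
#'   `fraction_unmodified`.
#' @export
build_exposure_series <- function(table, site, species = NULL) {
  sub <- dplyr::filter(table, .data$site_id == site)
  if (nrow(sub) == 0L) {
    stop("site not present in table: ", site)
  }
  if (!is.null(species)) {
    sub <- dplyr::filter(sub, .data$species_label == species)
    if (nrow(sub) == 0L) stop("species not present for site ", site, ": ", species)
  }
  series <- sub |>
    dplyr::group_by(.data$site_id, .data$exposure_time, .data$replicate_id) |>
    dplyr::summarise(
      fraction_unmodified = fraction_unmodified(
        .data$area_unmodified[1L], .data$area_modified
      ),
      .groups = "drop"
    ) |>
    dplyr::arrange(.data$exposure_time, .data$replicate_id)
  n_times <- length(unique(series$exposure_time))
  if (n_times < 3L) {
    stop("underdetermined series for site ", site, ": only ", n_times,
         " distinct exposure times (need >= 3)")
  }
  series
}

#' Fit first-order decay of fraction unmodified versus exposure time
#'
#' Nonlinear least squares of `F_u(t) = F_u(0) * exp(-k * t)`, unweighted,
#' with replicates entering as independent points. `F_u(0)` is fitted as a
#' free parameter bounded in `(0, f0_upper]` by default (accommodating
#' baseline oxidation of the unexposed control) or pinned to 1.
#'
#' @param series Exposure series from [build_exposure_series()] (columns
#'   `exposure_time` in seconds, `fraction_unmodified`; `site_id` optional).
#' @param fix_f0 If `TRUE`, pin `F_u(0) = 1` and fit only the rate.
#' @param f0_upper Upper bound for the fitted intercept (default 1.2).
#' @return One-row tibble: `site_id`, `rate_constant` (per second), `f0`,
#'   `rate_se`, `r_squared`, `n_obs`, `converged`, `flag`.
#' @export
fit_first_order_decay <- function(series, fix_f0 = FALSE, f0_upper = 1.2) {
  t <- series$exposure_time
  fu <- series$fraction_unmodified
  ok <- is.finite(t) & is.finite(fu)
  t <- t[ok]; fu <- fu[ok]
  site <- if ("site_id" %in% names(series)) series$site_id[1L] else NA_character_
  n <- length(t)
  out <- function(k, f0, se, r2, converged, flag) {
    tibble::tibble(
      site_id = site, rate_constant = k, f0 = f0, rate_se = se,
      r_squared = r2, n_obs = n, converged = converged, flag = flag
    )
  }
  if (n < 3L) {
    return(out(NA_real_, NA_real_, NA_real_, NA_real_, FALSE, "too_few_points"))
  }
  if (all(abs(fu - 1) < 1e-12)) {
    return(out(0, 1, 0, NA_real_, TRUE, "no_detectable_modification"))
  }

  # log-linear start values (fu > 0 points only)
  pos <- fu > 0
  start_fit <- stats::lm(log(fu[pos]) ~ t[pos])
  k0 <- max(-unname(stats::coef(start_fit)[2L]), 0)
  f00 <- min(max(exp(unname(stats::coef(start_fit)[1L])), 1e-3), f0_upper)
  if (!is.finite(k0)) k0 <- 1
  if (!is.finite(f00)) f00 <- 1

  fit <- if (fix_f0) {
    .lm_fit(list(k = k0), function(p) fu - exp(-p$k * t),
            lower = 0, upper = Inf)
  } else {
    .lm_fit(list(k = k0, f0 = f00),
            function(p) fu - p$f0 * exp(-p$k * t),
            lower = c(0, 1e-6), upper = c(Inf, f0_upper))
  }
  if (is.null(fit)) {
    return(out(NA_real_, NA_real_, NA_real_, NA_real_, FALSE, "non_convergence"))
  }
  ss_tot <- sum((fu - mean(fu))^2)
  r2 <- if (ss_tot > 0) 1 - fit$deviance / ss_tot else NA_real_
  out(unname(fit$coef["k"]), if (fix_f0) 1 else unname(fit$coef["f0"]),
      unname(fit$se["k"]), r2, TRUE, NA_character_)
}

#' Read or build an intrinsic-reactivity table
#'
#' Per-residue-type intrinsic hydroxyl-radical reactivities `R_i` (per second,
#' relative scale) used to normalise observed modification rates across
#' amino-acid chemistry. The package hard-codes no literature values: the
#' table is a user-editable two-column CSV (`restype`, `reactivity`). A small
#' synthetic example ships in
#' `system.file("extdata", "reactivity_synthetic.csv", package = "hrfassay")`.
#'
#' @param path CSV file with columns `restype` (one-letter code) and
#'   `reactivity` (> 0).
#' @return Tibble with columns `restype`, `reactivity`.
#' @export
read_reactivity_csv <- function(path) {
  tab <- readr::read_csv(path, show_col_types = FALSE)
  need <- c("restype", "reactivity")
  miss <- setdiff(need, names(tab))
  if (length(miss)) stop("reactivity table missing column(s): ",
                         paste(miss, collapse = ", "))
  if (any(!is.finite(tab$reactivity)) || any(tab$reactivity <= 0)) {
    stop("all intrinsic reactivities must be finite and > 0")
  }
  if (anyDuplicated(tab$restype)) stop("duplicated restype in reactivity table")
  tibble::as_tibble(tab[need])
}

#' Protection factors from fitted modification rates
#'
#' The protection factor of residue `i` is `PF_i = R_i / k_i`, the intrinsic
#' reactivity of its residue type divided by the observed footprinting rate;
#' higher PF means more buried. Sites whose fitted rate is zero (no detectable
#' modification) have a PF that is only bounded from below: they are reported
#' with the configurable minimum resolvable rate `min_rate` substituted and
#' flagged `censored = TRUE`. Sites whose residue type is absent from the
#' reactivity table are returned in the `unscorable` component.
#'
#' @param fits Tibble of decay fits (rows from [fit_first_order_decay()]),
#'   with `restype` either as a column or recoverable from `site_id`.
#' @param reactivity Reactivity table ([read_reactivity_csv()]).
#' @param state_label Experimental state the rates were measured in
#'   (e.g. `"apo"`, `"bound"`).
#' @param min_rate Minimum resolvable rate (per second) substituted for
#'   censored (k = 0) sites; default 0.5.
#' @return A list with `records` (tibble: `site_id`, `state_label`,
#'   `rate_constant`, `rate_se`, `intrinsic_reactivity`, `pf`, `ln_pf`,
#'   `ln_pf_se`, `censored`) and `unscorable` (tibble: `site_id`, `reason`).
#' @export
compute_protection_factor <- function(fits, reactivity, state_label = "state",
                                      min_rate = 0.5) {
  stopifnot(min_rate > 0)
  if (!"restype" %in% names(fits)) {
    fits <- dplyr::left_join(fits, parse_site_id(fits$site_id)[c("site_id", "restype")],
                             by = "site_id")
  }
  fits <- dplyr::left_join(fits, reactivity, by = "restype")

  bad_fit <- !fits$converged | !is.finite(fits$rate_constant)
  no_r <- !is.finite(fits$reactivity)
  unscorable <- tibble::tibble(
    site_id = fits$site_id[bad_fit | no_r],
    reason = dplyr::case_when(
      bad_fit[bad_fit | no_r] ~ "unconverged_fit",
      TRUE ~ "missing_intrinsic_reactivity"
    )
  )
  ok <- fits[!(bad_fit | no_r), ]
  censored <- ok$rate_constant <= 0
  k_eff <- ifelse(censored, min_rate, ok$rate_constant)
  records <- tibble::tibble(
    site_id = ok$site_id,
    state_label = state_label,
    rate_constant = ok$rate_constant,
    rate_se = ok$rate_se,
    intrinsic_reactivity = ok$reactivity,
    pf = ok$reactivity / k_eff,
    ln_pf = log(ok$reactivity / k_eff),
    # lnPF = ln R - ln k, so SE(lnPF) = SE(k)/k (delta method)
    ln_pf_se = ifelse(censored, NA_real_, ok$rate_se / k_eff),
    censored = censored
  )
  list(records = records, unscorable = unscorable)
}

#' Batch pipeline: peak-area table to protection factors
#'
#' Runs [build_exposure_series()], [fit_first_order_decay()] and
#' [compute_protection_factor()] over every site in a peak-area table.
#' Output rows are ordered deterministically by chain and residue number.
#'
#' @inheritParams build_exposure_series
#' @inheritParams fit_first_order_decay
#' @inheritParams compute_protection_factor
#' @param table Long peak-area table (see [read_peak_area_csv()]).
#' @return A list with `records` (protection records joined with fit
#'   diagnostics), `fits` (all decay fits, including failed ones) and
#'   `unscorable` (side report of sites without a usable PF).
#' @export
summarize_rates <- function(table, reactivity, state_label = "state",
                            fix_f0 = FALSE, f0_upper = 1.2, min_rate = 0.5) {
  if (nrow(table) == 0L) {
    warning("empty peak-area table")
    return(list(records = tibble::tibble(), fits = tibble::tibble(),
                unscorable = tibble::tibble()))
  }
  sites <- parse_site_id(unique(table$site_id)) |>
    dplyr::arrange(.data$chain, .data$resnum)
  fits <- dplyr::bind_rows(lapply(sites$site_id, function(s) {
    fit <- tryCatch(
      fit_first_order_decay(build_exposure_series(table, s),
                            fix_f0 = fix_f0, f0_upper = f0_upper),
      error = function(e) tibble::tibble(
        site_id = s, rate_constant = NA_real_, f0 = NA_real_,
        rate_se = NA_real_, r_squared = NA_real_, n_obs = 0L,
        converged = FALSE, flag = conditionMessage(e)
      )
    )
    fit
  }))
  fits <- dplyr::left_join(fits, sites, by = "site_id")
  pf <- compute_protection_factor(fits, reactivity, state_label = state_label,
                                  min_rate = min_rate)
  records <- dplyr::left_join(
    pf$records,
    fits[c("site_id", "chain", "resnum", "restype", "f0", "r_squared", "n_obs", "flag")],
    by = "site_id"
  )
  list(records = records, fits = fits, unscorable = pf$unscorable)
}
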