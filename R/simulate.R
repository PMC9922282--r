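#' Default synthetic HRF site panel
#'
#' Ten probe residues on one chain with apo-state modification rates spread
#' over 2-80 per second, so every site decays measurably within a 0-75 ms
#' X-ray exposure window (k * t_max from 0.15 to 6). Buried residues carry
#' slow rates (high protection), exposed ones fast rates. The default
#' protected set used by two-state simulations comprises the mid-rate
#' drug-contact probes F185, I190 and Y217, whose rates stay quantifiable
#' after an e^2-fold protection.
#'
#' @return Tibble `site_id`, `chain`, `resnum`, `restype`, `k_apo` (per s).
#' @export
default_hrf_sites <- function() {
  sites <- tibble::tibble(
    chain   = "A",
    resnum  = c(21L, 116L, 117L, 138L, 151L, 185L, 190L, 191L, 217L, 256L),
    restype = c("F", "Y", "L", "S", "Y", "F", "I", "L", "Y", "Y"),
    k_apo   = c(2, 12, 8, 5, 15, 30, 40, 20, 25, 80)
  )
  sites$site_id <- make_site_id(sites$chain, sites$restype, sites$resnum)
  sites[c("site_id", "chain", "resnum", "restype", "k_apo")]
}

#' Synthetic intrinsic-reactivity table for the default site panel
#'
#' Synthetic per-residue-type reactivities on a plausible relative scale
#' (aromatic and sulfur-free aliphatic ordering); NOT literature values.
#' Matches the file shipped at `inst/extdata/reactivity_synthetic.csv`.
#'
#' @return Tibble `restype`, `reactivity` (per s, relative).
#' @export
synthetic_reactivity <- function() {
  tibble::tibble(
    restype    = c("F", "Y", "W", "L", "I", "V", "M", "H", "P", "S", "T"),
    reactivity = c(60, 100, 150, 20, 15, 12, 120, 80, 10, 5, 8)
  )
}

#' Design for a synthetic HRF peak-area dataset
#'
#' Defaults mirror the synchrotron footprinting design the pipeline targets:
#' exposures of 0, 25, 50 and 75 ms, duplicate reactions (eight independent
#' data elements per site), and multiplicative log-normal peak-area noise
#' with a 10% coefficient of variation.
#'
#' @param seed Integer RNG seed.
#' @param sites Site panel with true rates (see [default_hrf_sites()]).
#' @param times_ms Exposure times in milliseconds.
#' @param replicates Reactions per time point.
#' @param noise_cv Coefficient of variation of multiplicative log-normal
#'   peak-area noise (0 = noiseless).
#' @param total_intensity Total MS intensity per (site, time, replicate).
#' @param f0 True unexposed unmodified fraction (default 1).
#' @param two_state Also generate a ligand-bound state?
#' @param protected_sites Site ids whose rate is divided by
#'   `protection_multiplier` in the bound state (default: F185, I190, Y217).
#' @param protection_multiplier Fold-protection in the bound state
#'   (default `exp(2)`).
#' @return A design list for [gen_hrf_dataset()].
#' @export
hrf_design <- function(seed = 1L,
                       sites = default_hrf_sites(),
                       times_ms = c(0, 25, 50, 75),
                       replicates = 2L,
                       noise_cv = 0.1,
                       total_intensity = 1e6,
                       f0 = 1,
                       two_state = FALSE,
                       protected_sites = c("A:F185", "A:I190", "A:Y217"),
                       protection_multiplier = exp(2)) {
  stopifnot(noise_cv >= 0, total_intensity > 0, replicates >= 1L,
            f0 > 0, protection_multiplier > 0)
  if (any(sites$k_apo < 0)) stop("modification rates must be >= 0")
  if (two_state && !all(protected_sites %in% sites$site_id)) {
    stop("protected_sites must be a subset of the site panel")
  }
  list(seed = as.integer(seed), sites = sites, times_ms = times_ms,
       replicates = as.integer(replicates), noise_cv = noise_cv,
       total_intensity = total_intensity, f0 = f0, two_state = two_state,
       protected_sites = protected_sites,
       protection_multiplier = protection_multiplier)
}

#' Generate a synthetic HRF peak-area dataset
#'
#' For each site, state, exposure time and replicate, the expected unmodified
#' fraction is `f0 * exp(-k * t)`; unmodified and (single-species) modified
#' peak areas are drawn as `total_intensity x fraction x noise` with
#' independent multiplicative log-normal noise per area. In two-state mode
#' the designated protected sites have their rate divided by the protection
#' multiplier in the bound state; all other sites share the apo rate.
#'
#' @param design Design list from [hrf_design()].
#' @return List with `records` (long peak-area table in the schema of
#'   [read_peak_area_csv()], plus a `state` column) and `truth` (tibble
#'   `site_id`, `state`, `k_true`, `f0_true`).
#' @export
gen_hrf_dataset <- function(design = hrf_design()) {
  states <- if (design$two_state) c("apo", "bound") else "apo"
  truth <- dplyr::bind_rows(lapply(states, function(st) {
    k <- design$sites$k_apo
    if (st == "bound") {
      prot <- design$sites$site_id %in% design$protected_sites
      k[prot] <- k[prot] / design$protection_multiplier
    }
    tibble::tibble(site_id = design$sites$site_id, state = st, k_true = k,
                   f0_true = design$f0)
  }))
  grid <- tidyr::expand_grid(
    truth,
    exposure_time = design$times_ms,
    replicate_id = paste0("rep", seq_len(design$replicates))
  )
  grid <- dplyr::left_join(
    grid, design$sites[c("site_id", "chain", "resnum", "restype")],
    by = "site_id"
  )
  sdlog <- sqrt(log(1 + design$noise_cv^2))
  records <- withr::with_seed(design$seed, {
    fu <- pmin(design$f0 * exp(-grid$k_true * grid$exposure_time * 1e-3), 1)
    noise <- function(n) if (sdlog == 0) rep(1, n) else
      stats::rlnorm(n, meanlog = -sdlog^2 / 2, sdlog = sdlog)
    n <- nrow(grid)
    tibble::tibble(
      site_id = grid$site_id, chain = grid$chain, resnum = grid$resnum,
      restype = grid$restype, state = grid$state,
      exposure_time = grid$exposure_time, time_unit = "ms",
      replicate_id = grid$replicate_id,
      area_unmodified = design$total_intensity * fu * noise(n),
      species_label = "ox",
      area_modified = design$total_intensity * (1 - fu) * noise(n)
    )
  })
  list(records = records, truth = truth)
}

#' Design for a synthetic thermal-shift melt curve
#'
#' Two-state unfolding read out by dye fluorescence: linear pre- and
#' post-transition baselines joined by a logistic transition, plus Gaussian
#' noise. Defaults: 25-95 deg C scan sampled every 0.5 deg C (a 2 deg C/min
#' gradient read once per 15 s), transition width 1.2 deg C, noise SD 20 RFU
#' on a ~3200 RFU amplitude.
#'
#' @param seed Integer RNG seed.
#' @param tm True melting temperature (deg C), inside the scan range.
#' @param width Logistic transition width (deg C).
#' @param t_min,t_max,step Scan range and sampling step (deg C).
#' @param pre_level,post_level Baseline fluorescence before/after unfolding.
#' @param pre_slope,post_slope Baseline slopes (RFU per deg C).
#' @param noise_sd Gaussian noise SD (RFU).
#' @return Design list for [gen_melt_curve()].
#' @export
melt_design <- function(seed = 1L, tm = 51.6, width = 1.2,
                        t_min = 25, t_max = 95, step = 0.5,
                        pre_level = 300, post_level = 3500,
                        pre_slope = 0, post_slope = 0, noise_sd = 20) {
  stopifnot(noise_sd >= 0, width > 0, step > 0)
  if (tm <= t_min || tm >= t_max) stop("tm must lie inside the scan range")
  list(seed = as.integer(seed), tm = tm, width = width, t_min = t_min,
       t_max = t_max, step = step, pre_level = pre_level,
       post_level = post_level, pre_slope = pre_slope,
       post_slope = post_slope, noise_sd = noise_sd)
}

#' Generate a synthetic melt curve
#'
#' @param design Design list from [melt_design()].
#' @return List with `curve` (tibble `temperature`, `rfu`) and `truth`
#'   (tibble `tm_true`, `width`).
#' @export
gen_melt_curve <- function(design = melt_design()) {
  temperature <- seq(design$t_min, design$t_max, by = design$step)
  theta <- 1 / (1 + exp(-(temperature - design$tm) / design$width))
  pre <- design$pre_level + design$pre_slope * temperature
  post <- design$post_level + design$post_slope * temperature
  rfu <- withr::with_seed(design$seed, {
    y <- pre * (1 - theta) + post * theta
    if (design$noise_sd > 0) y <- y + stats::rnorm(length(y), 0, design$noise_sd)
    y
  })
  list(curve = tibble::tibble(temperature = temperature, rfu = rfu),
       truth = tibble::tibble(tm_true = design$tm, width = design$width))
}

#' Design for synthetic enzymatic progress curves
#'
#' Defaults mirror the NADH-fluorescence kinetics design: a six-point twofold
#' substrate titration from 1.25 to 40 µM, eight reads at 15 s spacing,
#' triplicate wells, and initial-rate slopes following Hill kinetics
#' (default Km 2.2 µM, unit Hill coefficient).
#'
#' @param seed Integer RNG seed.
#' @param km Michaelis constant (µM).
#' @param vmax Maximal rate (RFU/s).
#' @param hill Hill coefficient.
#' @param conc Substrate titration (µM).
#' @param reads Reads per progress curve.
#' @param dt Read spacing (s).
#' @param replicates Wells per concentration.
#' @param y0 Fluorescence at time zero (RFU).
#' @param noise_sd Gaussian read noise SD (RFU).
#' @return Design list for [gen_progress_curves()].
#' @export
kinetics_design <- function(seed = 1L, km = 2.2, vmax = 50, hill = 1,
                            conc = c(1.25, 2.5, 5, 10, 20, 40),
                            reads = 8L, dt = 15, replicates = 3L,
                            y0 = 100, noise_sd = 5) {
  stopifnot(km > 0, vmax > 0, hill > 0, all(conc > 0), noise_sd >= 0)
  list(seed = as.integer(seed), km = km, vmax = vmax, hill = hill,
       conc = conc, reads = as.integer(reads), dt = dt,
       replicates = as.integer(replicates), y0 = y0, noise_sd = noise_sd)
}

#' Generate synthetic progress curves across a substrate titration
#'
#' Each well's fluorescence rises linearly at the Hill-kinetics rate
#' `v(S) = Vmax * S^n / (Km^n + S^n)` plus Gaussian read noise.
#'
#' @param design Design list from [kinetics_design()].
#' @return List with `curves` (tibble `conc`, `replicate`, `time`, `rfu`) and
#'   `truth` (tibble `conc`, `v_true`, plus `km`, `vmax`, `hill` attributes
#'   as columns).
#' @export
gen_progress_curves <- function(design = kinetics_design()) {
  v <- design$vmax * design$conc^design$hill /
    (design$km^design$hill + design$conc^design$hill)
  truth <- tibble::tibble(conc = design$conc, v_true = v,
                          km = design$km, vmax = design$vmax,
                          hill = design$hill)
  grid <- tidyr::expand_grid(
    conc = design$conc,
    replicate = seq_len(design$replicates),
    time = (seq_len(design$reads) - 1L) * design$dt
  )
  grid <- dplyr::left_join(grid, truth[c("conc", "v_true")], by = "conc")
  curves <- withr::with_seed(design$seed, {
    y <- design$y0 + grid$v_true * grid$time
    if (design$noise_sd > 0) y <- y + stats::rnorm(length(y), 0, design$noise_sd)
    tibble::tibble(conc = grid$conc, replicate = grid$replicate,
                   time = grid$time, rfu = y)
  })
  list(curves = curves, truth = truth)
}

#' Design for a synthetic inhibitor dose-response experiment
#'
#' Defaults mirror a 13-point twofold inhibitor ladder from 0.078 to 320 nM
#' (anchored at the low end of the 0.078-500 nM range the assay targets; no
#' twofold series contains both printed endpoints exactly), a three-parameter
#' logistic truth with unit Hill slope, and Gaussian noise on the percent
#' scale.
#'
#' @param seed Integer RNG seed.
#' @param ic50 True IC50 (nM).
#' @param bottom,top Lower/upper plateaus (percent inhibition).
#' @param conc Inhibitor ladder (nM).
#' @param replicates Wells per concentration.
#' @param noise_sd Gaussian noise SD (percentage points).
#' @return Design list for [gen_dose_response()].
#' @export
inhibition_design <- function(seed = 1L, ic50 = 1.2, bottom = 0, top = 100,
                              conc = 0.078125 * 2^(0:12),
                              replicates = 1L, noise_sd = 3) {
  stopifnot(ic50 > 0, bottom <= top, all(conc > 0), noise_sd >= 0)
  list(seed = as.integer(seed), ic50 = ic50, bottom = bottom, top = top,
       conc = conc, replicates = as.integer(replicates), noise_sd = noise_sd)
}

#' Generate a synthetic dose-response curve
#'
#' Percent inhibition follows the three-parameter logistic
#' `y = bottom + (top - bottom) / (1 + IC50 / x)` plus Gaussian noise.
#'
#' @param design Design list from [inhibition_design()].
#' @return List with `curve` (tibble `conc`, `replicate`, `inhibition`) and
#'   `truth` (tibble `ic50_true`, `bottom`, `top`).
#' @export
gen_dose_response <- function(design = inhibition_design()) {
  grid <- tidyr::expand_grid(conc = design$conc,
                             replicate = seq_len(design$replicates))
  curve <- withr::with_seed(design$seed, {
    y <- design$bottom + (design$top - design$bottom) / (1 + design$ic50 / grid$conc)
    if (design$noise_sd > 0) y <- y + stats::rnorm(length(y), 0, design$noise_sd)
    tibble::tibble(conc = grid$conc, replicate = grid$replicate, inhibition = y)
  })
  list(curve = curve,
       truth = tibble::tibble(ic50_true = design$ic50, bottom = design$bottom,
                              top = design$top))
}
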