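#' Melting temperature from a dye-fluorescence melt curve
#'
#' The melt curve is smoothed with a Savitzky-Golay filter, its first
#' derivative with respect to temperature is computed, and the melting
#' temperature is taken as the temperature of the extremum of `-d(RFU)/dT`
#' in the interior of the scan (the transition midpoint of a two-state
#' unfolding). The extremum is refined to sub-grid precision by the vertex of
#' a least-squares quadratic fitted to the derivative magnitude over one
#' filter window around the discrete peak.
#'
#' @param temperature Monotone increasing, (near-)uniform temperature grid
#'   (deg C), >= 20 points.
#' @param rfu Fluorescence readings, same length.
#' @param sg_window Savitzky-Golay window length in points (odd; default 7,
#'   suited to 0.5 deg C sampling).
#' @param sg_order Savitzky-Golay polynomial order (default 3).
#' @return One-row tibble: `tm` (deg C), `derivative_extremum` (value of
#'   `-d(RFU)/dT` at the extremum), `sg_window`, `sg_order`, `flag`
#'   (`"no_transition"`, `"boundary"`, or `"multimodal"`).
#' @export
melt_tm <- function(temperature, rfu, sg_window = 7L, sg_order = 3L) {
  stopifnot(length(temperature) == length(rfu))
  n <- length(temperature)
  if (n < 20L) stop("need >= 20 temperature points")
  dT <- diff(temperature)
  if (any(dT <= 0)) stop("temperature grid must be strictly increasing")
  step <- stats::median(dT)
  if (max(abs(dT - step)) > 0.05 * step) {
    stop("temperature grid must be (near-)uniform for derivative filtering")
  }
  out <- function(tm, ext, flag) {
    tibble::tibble(tm = tm, derivative_extremum = ext,
                   sg_window = sg_window, sg_order = sg_order, flag = flag)
  }
  smoothed <- signal::sgolayfilt(rfu, p = sg_order, n = sg_window)
  neg_deriv <- -signal::sgolayfilt(rfu, p = sg_order, n = sg_window,
                                   m = 1L, ts = step)
  amplitude <- diff(range(smoothed))
  if (amplitude <= 1e-8 * max(abs(smoothed), 1) ||
      max(abs(neg_deriv)) * diff(range(temperature)) < 0.05 * amplitude) {
    return(out(NA_real_, NA_real_, "no_transition"))
  }
  # drop the half-window at each edge where the filter is one-sided
  edge <- (sg_window - 1L) %/% 2L
  interior <- (edge + 1L):(n - edge)
  mag <- abs(neg_deriv)
  i <- interior[which.max(mag[interior])]

  flag <- NA_character_
  if (i <= interior[1L] || i >= interior[length(interior)]) flag <- "boundary"

  # competing local extrema beyond a window away -> multimodal
  loc <- interior[-c(1L, length(interior))]
  is_peak <- mag[loc] >= mag[loc - 1L] & mag[loc] >= mag[loc + 1L]
  peaks <- loc[is_peak]
  rivals <- peaks[abs(peaks - i) > sg_window & mag[peaks] >= 0.5 * mag[i]]
  if (length(rivals) && is.na(flag)) flag <- "multimodal"

  tm <- temperature[i]
  idx <- max(1L, i - edge):min(n, i + edge)
  x <- temperature[idx] - temperature[i]
  cf <- stats::coef(stats::lm(mag[idx] ~ x + I(x^2)))
  if (all(is.finite(cf)) && cf[3L] < 0) {
    vertex <- -cf[2L] / (2 * cf[3L])
    if (abs(vertex) <= edge * step) tm <- temperature[i] + vertex
  }
  out(tm, neg_deriv[i], flag)
}

#' Tm increments along a condition ladder
#'
#' Computes successive melting-temperature increments for each protein variant
#' along an ordered ladder of conditions (typically apo, +cofactor,
#' +cofactor+drug). Increments along the ladder sum to the total Tm change.
#'
#' @param tms Tibble with columns `variant`, `condition`, `tm`.
#' @param ladder Character vector of conditions in ladder order.
#' @return Tibble `variant`, `step` (`"<from> -> <to>"`), `condition` (the
#'   rung reached), `increment` (deg C; NA when a rung is missing).
#' @export
delta_tm <- function(tms, ladder) {
  stopifnot(length(ladder) >= 2L)
  dplyr::bind_rows(lapply(split(tms, tms$variant), function(v) {
    tm_at <- function(cond) {
      x <- v$tm[v$condition == cond]
      if (length(x) == 0L) NA_real_ else mean(x)
    }
    tibble::tibble(
      variant = v$variant[1L],
      step = paste(ladder[-length(ladder)], "->", ladder[-1L]),
      condition = ladder[-1L],
      increment = vapply(seq_along(ladder)[-1L], function(i) {
        tm_at(ladder[i]) - tm_at(ladder[i - 1L])
      }, numeric(1))
    )
  }))
}

#' Stabilization loss of mutants relative to a reference variant
#'
#' For each ladder step, the loss is the reference (wild-type) increment minus
#' the mutant's increment: how much ligand-induced thermal stabilization the
#' mutation removed.
#'
#' @param increments Output of [delta_tm()].
#' @param reference Variant used as reference (default `"WT"`).
#' @return Tibble `variant`, `step`, `condition`, `increment`,
#'   `reference_increment`, `loss` for non-reference variants.
#' @export
stabilization_loss <- function(increments, reference = "WT") {
  ref <- increments[increments$variant == reference, ]
  if (nrow(ref) == 0L) stop("reference variant not found: ", reference)
  mut <- increments[increments$variant != reference, ]
  mut$reference_increment <- ref$increment[match(mut$step, ref$step)]
  mut$loss <- mut$reference_increment - mut$increment
  mut
}
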