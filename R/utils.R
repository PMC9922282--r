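#' Build a canonical site identifier
#'
#' Site identifiers follow author (PDB) numbering: `"<chain>:<restype><resnum>"`,
#' e.g. `"A:F185"` for phenylalanine 185 on chain A. Residue type is the
#' one-letter amino-acid code.
#'
#' @param chain Chain identifier (single character).
#' @param restype One-letter residue type.
#' @param resnum Author residue number.
#' @return Character vector of site identifiers.
#' @export
make_site_id <- function(chain, restype, resnum) {
  paste0(chain, ":", restype, resnum)
}

#' Split site identifiers back into chain / residue type / number
#'
#' @param site_id Identifiers produced by [make_site_id()].
#' @return A tibble with columns `site_id`, `chain`, `restype`, `resnum`.
#' @export
parse_site_id <- function(site_id) {
  m <- regmatches(site_id, regexec("^([^:]+):([A-Za-z])([0-9]+)$", site_id))
  bad <- vapply(m, length, 1L) != 4L
  if (any(bad)) {
    stop("malformed site_id: ", paste(site_id[bad], collapse = ", "))
  }
  tibble::tibble(
    site_id = site_id,
    chain   = vapply(m, `[`, "", 2L),
    restype = vapply(m, `[`, "", 3L),
    resnum  = as.integer(vapply(m, `[`, "", 4L))
  )
}

# Bounded Levenberg-Marquardt least squares via minpack.lm::nls.lm.
# fn(par) returns residuals. SEs come from the J'J approximation of the
# Hessian at the solution, so exact (zero-residual) fits pose no problem.
.lm_fit <- function(par, fn, lower = NULL, upper = NULL) {
  if (is.null(lower)) lower <- rep(-Inf, length(par))
  if (is.null(upper)) upper <- rep(Inf, length(par))
  res <- tryCatch(
    minpack.lm::nls.lm(par = par, fn = fn, lower = lower, upper = upper,
                       control = minpack.lm::nls.lm.control(maxiter = 500)),
    error = function(e) NULL
  )
  if (is.null(res) || !(res$info %in% 1:4)) return(NULL)
  cf <- unlist(res$par)
  n <- length(res$fvec)
  p <- length(cf)
  sigma2 <- res$deviance / max(n - p, 1)
  covm <- tryCatch(sigma2 * solve(res$hessian), error = function(e) NULL)
  se <- if (is.null(covm)) rep(NA_real_, p) else sqrt(pmax(diag(covm), 0))
  list(coef = cf, se = stats::setNames(se, names(cf)), deviance = res$deviance)
}

# exposure-time unit -> seconds multiplier
.time_unit_factor <- function(unit) {
  fac <- c(s = 1, sec = 1, seconds = 1, ms = 1e-3, milliseconds = 1e-3)
  unit <- tolower(unit)
  unknown <- !unit %in% names(fac)
  if (any(unknown)) {
    stop("unknown time unit: ", paste(unique(unit[unknown]), collapse = ", "))
  }
  unname(fac[unit])
}
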