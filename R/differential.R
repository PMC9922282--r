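#' Differential protection between two experimental states
#'
#' Joins per-residue protection records from two states (e.g. cofactor-bound
#' apo vs inhibitor-bound) and computes `delta_ln_pf = ln_pf_b - ln_pf_a` for
#' every site quantified in both. Positive deltas mean the site became more
#' protected (more buried) in state b. Sites quantified in only one state are
#' reported separately, as are sites censored (no detectable modification) in
#' exactly one state, which are qualitatively but not numerically comparable.
#'
#' @param pfs_a Protection records for the reference state
#'   (`$records` from [summarize_rates()] or [compute_protection_factor()]).
#' @param pfs_b Protection records for the comparison state.
#' @return A list with:
#'   * `diffs` — tibble `site_id`, `ln_pf_a`, `ln_pf_b`, `delta_ln_pf`,
#'     `delta_se` (propagated, NA if either SE missing);
#'   * `only_a`, `only_b` — site ids quantified in one state only;
#'   * `qualitative` — tibble of sites censored in exactly one state, with a
#'     `direction` column (`"more_protected_in_b"` / `"more_protected_in_a"`).
#' @export
compare_states <- function(pfs_a, pfs_b) {
  shared <- intersect(pfs_a$site_id, pfs_b$site_id)
  if (length(shared) == 0L) stop("no shared quantified sites between states")
  a <- pfs_a[match(shared, pfs_a$site_id), ]
  b <- pfs_b[match(shared, pfs_b$site_id), ]

  cens_a <- isTRUE_vec(a$censored)
  cens_b <- isTRUE_vec(b$censored)
  quali <- xor(cens_a, cens_b)
  qualitative <- tibble::tibble(
    site_id = shared[quali],
    direction = ifelse(cens_b[quali], "more_protected_in_b", "more_protected_in_a")
  )
  keep <- !quali
  diffs <- tibble::tibble(
    site_id = shared[keep],
    ln_pf_a = a$ln_pf[keep],
    ln_pf_b = b$ln_pf[keep],
    delta_ln_pf = b$ln_pf[keep] - a$ln_pf[keep],
    delta_se = sqrt(a$ln_pf_se[keep]^2 + b$ln_pf_se[keep]^2)
  )
  list(
    diffs = diffs,
    only_a = setdiff(pfs_a$site_id, shared),
    only_b = setdiff(pfs_b$site_id, shared),
    qualitative = qualitative
  )
}

isTRUE_vec <- function(x) if (is.null(x)) FALSE else x %in% TRUE

#' Classify residues by differential protection
#'
#' A site is called `more_protected` when `delta_ln_pf >= threshold` and the
#' change exceeds `min_separation` propagated standard errors; symmetrically
#' `less_protected`; otherwise `unchanged`. When a delta's SE is missing, the
#' call falls back to the threshold alone (with a warning).
#'
#' @param diffs Differential tibble (`$diffs` from [compare_states()]).
#' @param threshold Minimum absolute `delta_ln_pf` (natural-log units) for a
#'   call; default 1.0.
#' @param min_separation Required separation in multiples of `delta_se`;
#'   default 2.
#' @return `diffs` with an added `protection_class` factor column.
#' @export
classify_residues <- function(diffs, threshold = 1.0, min_separation = 2) {
  stopifnot(threshold > 0, min_separation >= 0)
  se <- diffs$delta_se
  if (any(!is.finite(se))) {
    warning("missing SE for ", sum(!is.finite(se)),
            " site(s); classifying on threshold alone")
  }
  sep_ok <- ifelse(is.finite(se),
                   abs(diffs$delta_ln_pf) >= min_separation * se,
                   TRUE)
  cls <- dplyr::case_when(
    diffs$delta_ln_pf >= threshold & sep_ok ~ "more_protected",
    diffs$delta_ln_pf <= -threshold & sep_ok ~ "less_protected",
    TRUE ~ "unchanged"
  )
  diffs$protection_class <- factor(cls, levels = c("unchanged", "more_protected",
                                                   "less_protected"))
  diffs
}

#' Plot-ready lnPF-vs-lnPF scatter table
#'
#' Rearranges classified differential results into the table behind the
#' canonical protection-factor scatter (lnPF with ligand on the y axis, without
#' on the x axis; points above the diagonal are more protected when bound),
#' attaching user-supplied annotation labels (e.g. drug/cofactor-contact or
#' dimer-interface residue sets).
#'
#' @param diffs Classified differential tibble ([classify_residues()]).
#' @param annotations Optional named list of character vectors of `site_id`s
#'   (see [read_annotation_sets()]); the first matching set labels a site.
#' @return Tibble `site_id`, `ln_pf_without`, `ln_pf_with`, `class`,
#'   `annotation` (NA where no set matches). The `y = x` reference needs no
#'   column: it is the `ln_pf_without` axis itself.
#' @export
scatter_table <- function(diffs, annotations = NULL) {
  if (nrow(diffs) == 0L) stop("no differential results to tabulate")
  ann <- rep(NA_character_, nrow(diffs))
  if (!is.null(annotations)) {
    unknown <- setdiff(unlist(annotations, use.names = FALSE), diffs$site_id)
    if (length(unknown)) {
      warning("annotation residues not in differential results: ",
              paste(unknown, collapse = ", "))
    }
    for (label in names(annotations)) {
      hit <- diffs$site_id %in% annotations[[label]] & is.na(ann)
      ann[hit] <- label
    }
  }
  tibble::tibble(
    site_id = diffs$site_id,
    ln_pf_without = diffs$ln_pf_a,
    ln_pf_with = diffs$ln_pf_b,
    class = diffs$protection_class,
    annotation = ann
  )
}

#' Read annotation sets from JSON or two-column CSV
#'
#' Annotation sets name groups of residues (e.g. `"binding"`,
#' `"interface"`) used to colour the scatter table. JSON input is an object of
#' arrays of site ids; CSV input has columns `set` and `site_id`.
#'
#' @param path `.json` or `.csv` file.
#' @return Named list of character vectors of site ids.
#' @export
read_annotation_sets <- function(path) {
  if (grepl("\\.json$", path, ignore.case = TRUE)) {
    sets <- jsonlite::read_json(path, simplifyVector = TRUE)
    lapply(sets, as.character)
  } else {
    tab <- readr::read_csv(path, show_col_types = FALSE)
    miss <- setdiff(c("set", "site_id"), names(tab))
    if (length(miss)) stop("annotation CSV missing column(s): ",
                           paste(miss, collapse = ", "))
    split(as.character(tab$site_id), tab$set)
  }
}
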