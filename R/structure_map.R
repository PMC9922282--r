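#' Write per-residue scores into a structure's B-factor column
#'
#' Maps per-residue scores (e.g. delta-lnPF) onto a protein structure so that
#' molecular-graphics software can colour by the B-factor channel. Residues
#' are matched by chain + author residue number; the residue type recorded in
#' the score's site id must agree with the structure (a mismatch is an error,
#' guarding against numbering drift). Every atom of a matched residue gets the
#' residue's score; unmatched residues keep the sentinel value.
#'
#' @param structure_file Input structure, PDB (`.pdb`) or mmCIF (`.cif`).
#' @param scores Named numeric vector (names are `site_id`s from
#'   [make_site_id()]) or a tibble with columns `site_id`, `score`.
#' @param out_file Output PDB path (fixed-column PDB format; B-factors are
#'   written with two decimals).
#' @param sentinel B-factor for residues without a score (default 0).
#' @return Invisibly, a tibble of the sites written (`site_id`, `score`,
#'   `n_atoms`); sites absent from the structure are reported with a warning
#'   and `n_atoms = 0`.
#' @export
map_to_structure <- function(structure_file, scores, out_file, sentinel = 0) {
  if (is.data.frame(scores)) {
    scr <- stats::setNames(scores$score, scores$site_id)
  } else {
    scr <- scores
  }
  if (is.null(names(scr)) || any(!nzchar(names(scr)))) {
    stop("scores must be named by site_id")
  }
  pdb <- if (grepl("\\.cif$", structure_file, ignore.case = TRUE)) {
    bio3d::read.cif(structure_file)
  } else {
    bio3d::read.pdb(structure_file)
  }
  sites <- parse_site_id(names(scr))
  atom_res3 <- pdb$atom$resid
  atom_res1 <- suppressWarnings(bio3d::aa321(atom_res3))

  pdb$atom$b <- rep(sentinel, nrow(pdb$atom))
  n_atoms <- integer(nrow(sites))
  for (i in seq_len(nrow(sites))) {
    sel <- pdb$atom$chain == sites$chain[i] & pdb$atom$resno == sites$resnum[i]
    if (!any(sel)) next
    found <- unique(atom_res1[sel])
    if (!identical(found, sites$restype[i])) {
      stop("residue type mismatch at ", sites$site_id[i],
           ": structure has ", paste(found, collapse = "/"),
           " at ", sites$chain[i], sites$resnum[i])
    }
    pdb$atom$b[sel] <- scr[i]
    n_atoms[i] <- sum(sel)
  }
  if (all(n_atoms == 0L)) {
    stop("no residues matched the structure; first unmatched sites: ",
         paste(utils::head(sites$site_id, 5L), collapse = ", "))
  }
  if (any(n_atoms == 0L)) {
    warning("sites absent from structure (sentinel left in place): ",
            paste(sites$site_id[n_atoms == 0L], collapse = ", "))
  }
  bio3d::write.pdb(pdb, file = out_file)
  invisible(tibble::tibble(site_id = sites$site_id, score = unname(scr),
                           n_atoms = n_atoms))
}

#' Read per-residue B-factors back from a structure file
#'
#' Convenience inverse of [map_to_structure()]: one value per residue (the
#' B-factor shared by its atoms).
#'
#' @param structure_file PDB or mmCIF file.
#' @return Tibble `site_id`, `score`.
#' @export
read_structure_scores <- function(structure_file) {
  pdb <- if (grepl("\\.cif$", structure_file, ignore.case = TRUE)) {
    bio3d::read.cif(structure_file)
  } else {
    bio3d::read.pdb(structure_file)
  }
  at <- pdb$atom[pdb$atom$type %in% c("ATOM", "HETATM"), ]
  key <- paste(at$chain, at$resno)
  first <- !duplicated(key)
  tibble::tibble(
    site_id = make_site_id(at$chain[first],
                           suppressWarnings(bio3d::aa321(at$resid[first])),
                           at$resno[first]),
    score = at$b[first]
  )
}
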