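# Chemical Component Dictionary support.
#
# A CCD components file is an mmCIF-dialect file with one data block per
# chemical component. Only three things are consumed from it: the parent
# component of modified residues (for one-letter codes), the component's own
# one-letter code when given, and which atoms form the polymer backbone
# (to pick the terminal N and C atoms for connectivity checks).

#' Read a CCD components file
#'
#' @param source path (plain or gzipped) or text of a components file in
#'   mmCIF dialect, possibly containing many data blocks.
#' @return object of class `ccd`: named list (by component id) of records
#'   with `one_letter`, `parent`, `n_atom`, `c_atom`.
#' @export
read_ccd <- function(source) {
  lines <- read_text_lines(source)
  starts <- grep("^data_", lines)
  if (!length(starts)) mmcif_parse_error("no data blocks in CCD source")
  ends <- c(starts[-1] - 1L, length(lines))
  comps <- list()
  for (b in seq_along(starts)) {
    blk <- read_mmcif(paste(lines[starts[b]:ends[b]], collapse = "\n"))
    cc <- mmcif_category(blk, "chem_comp")
    if (is.null(cc)) next
    id <- toupper(cc$id[1])
    one <- NA_character_
    if (!is.null(cc$one_letter_code) && !is.na(cc$one_letter_code[1]) &&
        nchar(cc$one_letter_code[1]) == 1L)
      one <- toupper(cc$one_letter_code[1])
    parent <- if (!is.null(cc$mon_nstd_parent_comp_id))
      toupper(cc$mon_nstd_parent_comp_id[1]) else NA_character_
    atoms <- mmcif_category(blk, "chem_comp_atom")
    n_atom <- c_atom <- NA_character_
    if (!is.null(atoms) && !is.null(atoms$atom_id)) {
      bb <- if (!is.null(atoms$pdbx_backbone_atom_flag))
        atoms[!is.na(atoms$pdbx_backbone_atom_flag) &
                atoms$pdbx_backbone_atom_flag == "Y", , drop = FALSE]
      else atoms
      sym <- toupper(bb$type_symbol %||% rep(NA_character_, nrow(bb)))
      ns <- bb$atom_id[!is.na(sym) & sym == "N"]
      cs <- bb$atom_id[!is.na(sym) & sym == "C"]
      if (length(ns)) n_atom <- ns[1]          # amide nitrogen listed first
      if (length(cs)) c_atom <- cs[length(cs)] # carbonyl carbon listed last
    }
    comps[[id]] <- list(one_letter = one, parent = parent,
                        n_atom = n_atom, c_atom = c_atom)
  }
  structure(comps, class = "ccd")
}

#' Resolve backbone terminal atoms for a component
#'
#' Returns the atom names used for the peptide-bond connectivity check: the
#' backbone nitrogen of the residue and its carbonyl carbon. Taken from the
#' CCD when available; standard amino acids fall back to `("N", "C")`;
#' unknown components fall back likewise with a warning.
#'
#' @param chem_comp_id chemical component identifier (e.g. "ALA", "MSE")
#' @param ccd optional [read_ccd()] object
#' @return character vector `c(n_atom, c_atom)`
#' @export
resolve_backbone_atoms <- function(chem_comp_id, ccd = NULL) {
  id <- toupper(chem_comp_id)
  if (!is.null(ccd) && !is.null(ccd[[id]])) {
    rec <- ccd[[id]]
    if (!is.na(rec$n_atom) && !is.na(rec$c_atom))
      return(c(rec$n_atom, rec$c_atom))
  }
  if (!(id %in% names(AA3TO1)))
    warning(sprintf("component %s not in CCD; assuming backbone atoms N/C", id),
            call. = FALSE)
  c("N", "C")
}

# one-letter code for a component: standard table, then the CCD's own code,
# then the parent component's code, else 'X'
ccd_one_letter <- function(chem_comp_id, ccd = NULL) {
  id <- toupper(chem_comp_id)
  if (id %in% names(AA3TO1)) return(AA3TO1[[id]])
  if (!is.null(ccd) && !is.null(ccd[[id]])) {
    rec <- ccd[[id]]
    if (!is.na(rec$one_letter) && rec$one_letter %in% AA_LETTERS)
      return(rec$one_letter)
    if (!is.na(rec$parent) && rec$parent %in% names(AA3TO1))
      return(AA3TO1[[rec$parent]])
  }
  "X"
}
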