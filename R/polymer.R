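# Polymer entities: the structure-side view of the mapping problem.
#
# An entity is one chemically distinct polymer with a sample sequence (the
# expressed construct, independent of which residues were observed in the
# coordinates) and one or more chain instances. Residue records keep both
# numbering schemes (1-based label_seq_id and author numbering), the
# observed flag, and the backbone N/C coordinates used by connectivity
# checks.

no_polymer_error <- function(msg) {
  stop(structure(class = c("siftsmapper_no_polymer", "error", "condition"),
                 list(message = msg, call = NULL)))
}

consistency_error <- function(msg) {
  stop(structure(class = c("siftsmapper_consistency_error", "error", "condition"),
                 list(message = msg, call = NULL)))
}

clean_one_letter_seq <- function(s) {
  s <- toupper(gsub("[[:space:]]", "", s))
  chars <- strsplit(s, "")[[1]]
  chars[!(chars %in% AA_LETTERS)] <- "X"
  paste(chars, collapse = "")
}

AA1TO3 <- stats::setNames(names(AA3TO1), unname(AA3TO1))

#' Parse polymer entities from a PDBx/mmCIF file
#'
#' Extracts one entity per polypeptide, with the sample polymer sequence
#' taken from `_entity_poly` (so unobserved flexible loops are represented),
#' per-chain residue records from `_pdbx_poly_seq_scheme` (synthesised from
#' the sample sequence when that category is absent, author numbering
#' defaulting to label numbering), observed flags and backbone N/C
#' coordinates from the first model of `_atom_site`.
#'
#' @param source mmCIF path (plain or gzipped) or text
#' @param ccd optional [read_ccd()] dictionary used to resolve one-letter
#'   codes of modified residues and their backbone atom names
#' @return list of `polymer_entity` objects with fields `entry_id`,
#'   `entity_id`, `sample_sequence`, `chains` (each with `auth_asym_id`,
#'   `struct_asym_id` and a `residues` data.frame)
#' @export
parse_polymer_entities <- function(source, ccd = NULL) {
  x <- read_mmcif(source)
  cats <- x$categories
  entry_id <- tolower((cats$entry$id[1] %||% x$block) %||% "xxxx")

  ep <- cats$entity_poly
  if (is.null(ep)) no_polymer_error("no _entity_poly category: no polypeptide entity")
  poly <- ep[grepl("polypeptide", ep$type %||% ""), , drop = FALSE]
  if (nrow(poly) == 0L) no_polymer_error("no polypeptide entity in file")

  eps <- cats$entity_poly_seq
  scheme <- cats$pdbx_poly_seq_scheme
  atoms <- cats$atom_site

  # first model only
  if (!is.null(atoms) && !is.null(atoms$pdbx_PDB_model_num)) {
    first <- atoms$pdbx_PDB_model_num[1]
    atoms <- atoms[atoms$pdbx_PDB_model_num %in% first, , drop = FALSE]
  }

  entities <- list()
  for (r in seq_len(nrow(poly))) {
    eid <- poly$entity_id[r]
    seq <- poly$pdbx_seq_one_letter_code_can[r] %||% NA_character_
    comp_ids <- NULL
    if (!is.null(eps)) {
      sub <- eps[eps$entity_id == eid, , drop = FALSE]
      if (nrow(sub)) comp_ids <- toupper(sub$mon_id[order(as.integer(sub$num))])
    }
    if (is.na(seq) || !nzchar(seq)) {
      if (is.null(comp_ids))
        mmcif_parse_error("entity has neither canonical sequence nor monomer list",
                          "entity_poly")
      seq <- paste(vapply(comp_ids, ccd_one_letter, character(1), ccd = ccd),
                   collapse = "")
    }
    seq <- clean_one_letter_seq(seq)
    L <- nchar(seq)
    letters1 <- strsplit(seq, "")[[1]]
    if (is.null(comp_ids))
      comp_ids <- unname(ifelse(letters1 %in% names(AA1TO3),
                                AA1TO3[letters1], "UNK"))

    # chain instances
    chains <- list()
    sch <- if (!is.null(scheme))
      scheme[scheme$entity_id == eid, , drop = FALSE] else NULL
    if (!is.null(sch) && nrow(sch)) {
      for (asym in unique(sch$asym_id)) {
        cs <- sch[sch$asym_id == asym, , drop = FALSE]
        o <- order(as.integer(cs$seq_id))
        cs <- cs[o, , drop = FALSE]
        if (nrow(cs) != L)
          consistency_error(sprintf(
            "chain %s of entity %s: %d scheme rows but sequence length %d",
            asym, eid, nrow(cs), L))
        res <- data.frame(
          label_seq_id = as.integer(cs$seq_id),
          auth_seq_id = suppressWarnings(as.integer(cs$pdb_seq_num)),
          ins_code = ifelse(is.na(cs$pdb_ins_code %||% rep(NA, nrow(cs))), "",
                            cs$pdb_ins_code %||% rep("", nrow(cs))),
          chem_comp_id = toupper(cs$mon_id),
          one_letter = vapply(toupper(cs$mon_id), ccd_one_letter, character(1),
                              ccd = ccd),
          stringsAsFactors = FALSE)
        chains[[length(chains) + 1L]] <- list(
          auth_asym_id = cs$pdb_strand_id[1] %||% asym,
          struct_asym_id = asym, residues = res)
      }
    } else {
      # synthesise from the sample sequence; auth numbering = label numbering
      strands <- strsplit(poly$pdbx_strand_id[r] %||% "A", ",")[[1]]
      strands <- trimws(strands)
      for (asym in strands) {
        res <- data.frame(
          label_seq_id = seq_len(L), auth_seq_id = seq_len(L),
          ins_code = "", chem_comp_id = comp_ids,
          one_letter = letters1, stringsAsFactors = FALSE)
        chains[[length(chains) + 1L]] <- list(
          auth_asym_id = asym, struct_asym_id = asym, residues = res)
      }
    }

    # observed flags + backbone coordinates
    for (k in seq_along(chains)) {
      res <- chains[[k]]$residues
      res$observed <- FALSE
      res$n_x <- res$n_y <- res$n_z <- NA_real_
      res$c_x <- res$c_y <- res$c_z <- NA_real_
      if (!is.null(atoms)) {
        aa <- atoms[atoms$label_asym_id == chains[[k]]$struct_asym_id &
                      !is.na(atoms$label_seq_id), , drop = FALSE]
        if (nrow(aa)) {
          asid <- as.integer(aa$label_seq_id)
          for (i in seq_len(nrow(res))) {
            rows <- which(asid == res$label_seq_id[i])
            if (!length(rows)) next
            res$observed[i] <- TRUE
            bb <- resolve_backbone_atoms(res$chem_comp_id[i], ccd)
            nrow_i <- rows[aa$label_atom_id[rows] == bb[1]]
            crow_i <- rows[aa$label_atom_id[rows] == bb[2]]
            if (length(nrow_i)) {
              res$n_x[i] <- as.numeric(aa$Cartn_x[nrow_i[1]])
              res$n_y[i] <- as.numeric(aa$Cartn_y[nrow_i[1]])
              res$n_z[i] <- as.numeric(aa$Cartn_z[nrow_i[1]])
            }
            if (length(crow_i)) {
              res$c_x[i] <- as.numeric(aa$Cartn_x[crow_i[1]])
              res$c_y[i] <- as.numeric(aa$Cartn_y[crow_i[1]])
              res$c_z[i] <- as.numeric(aa$Cartn_z[crow_i[1]])
            }
          }
        }
      }
      chains[[k]]$residues <- res
    }

    # source-organism taxid, when the file records one
    taxid <- NA_integer_
    for (src in list(c("entity_src_gen", "pdbx_gene_src_ncbi_taxonomy_id"),
                     c("entity_src_nat", "pdbx_ncbi_taxonomy_id"),
                     c("pdbx_entity_src_syn", "ncbi_taxonomy_id"))) {
      sc <- cats[[src[1]]]
      if (!is.null(sc) && src[2] %in% names(sc)) {
        row <- sc[sc$entity_id == eid, , drop = FALSE]
        if (nrow(row) && !is.na(row[[src[2]]][1])) {
          taxid <- suppressWarnings(as.integer(row[[src[2]]][1]))
          break
        }
      }
    }

    entities[[length(entities) + 1L]] <- structure(
      list(entry_id = entry_id, entity_id = eid, sample_sequence = seq,
           tax_id = taxid, chains = chains),
      class = "polymer_entity")
  }
  entities
}

#' @export
print.polymer_entity <- function(x, ...) {
  cat(sprintf("polymer entity %s/%s: %d aa, %d chain(s)\n", x$entry_id,
              x$entity_id, nchar(x$sample_sequence), length(x$chains)))
  invisible(x)
}

#' Write entity sample sequences to a multi-FASTA file
#'
#' One record per entity, header `pdb|<entry_id>|<entity_id>`. Sample
#' sequences are written in full, so unobserved residues (flexible loops)
#' are represented.
#'
#' @param entities list of `polymer_entity`
#' @param out output FASTA path
#' @return number of records written, invisibly
#' @export
write_fasta <- function(entities, out) {
  if (!length(entities)) stop("no entities to write", call. = FALSE)
  seqs <- vapply(entities, function(e) e$sample_sequence, character(1))
  names(seqs) <- vapply(entities, function(e)
    sprintf("pdb|%s|%s", e$entry_id, e$entity_id), character(1))
  set <- Biostrings::AAStringSet(seqs)
  Biostrings::writeXStringSet(set, out)
  invisible(length(seqs))
}

#' Write SIFTS annotation categories into an mmCIF file
#'
#' Populates `_pdbx_sifts_unp_segments` and `_pdbx_sifts_xref_db` from
#' segment- and residue-level mappings and extends `_atom_site` so every
#' atom of a best-mapped residue carries the reference accession and residue
#' number (`pdbx_sifts_xref_db_acc` / `_num` / `_res` / `_name` items of the
#' current PDBx/mmCIF dictionary). All pre-existing categories are
#' preserved. The written file is re-parsed as a round-trip check.
#'
#' @param mmcif_source source structure (path or text)
#' @param segments segment table as produced by [build_segments()]
#' @param residues residue table as produced by [residue_mapping()]
#' @param out output path
#' @return `out`, invisibly
#' @export
write_sifts_annotations <- function(mmcif_source, segments, residues, out) {
  segments <- data.table::as.data.table(segments)
  residues <- data.table::as.data.table(residues)
  if (nrow(residues) == 0L || nrow(segments) == 0L)
    stop("empty segment or residue mapping: nothing to write", call. = FALSE)
  x <- read_mmcif(mmcif_source)
  known <- x$categories$entity_poly$entity_id %||% character(0)
  bad <- setdiff(unique(segments$entity), known)
  if (length(bad))
    consistency_error(sprintf("segment references unknown entity: %s",
                              paste(bad, collapse = ", ")))

  segs <- data.table::copy(segments)
  segs[, segment_id := seq_len(.N), by = .(entry, entity, auth_asym_id)]

  lb <- function(x) ifelse(x, "y", "n")
  x$categories[["pdbx_sifts_unp_segments"]] <- data.frame(
    entity_id = segs$entity,
    asym_id = segs$struct_asym_id,
    unp_acc = segs$accession,
    segment_id = as.character(segs$segment_id),
    instance_id = segs$auth_asym_id,
    unp_start = as.character(segs$target_start),
    unp_end = as.character(segs$target_end),
    seq_id_start = as.character(segs$query_start),
    seq_id_end = as.character(segs$query_end),
    best_mapping = lb(segs$best_mapping),
    identity = sprintf("%.3f", segs$identity),
    stringsAsFactors = FALSE)

  res <- data.table::copy(residues)
  res <- merge(res,
               segs[, .(entry, entity, auth_asym_id, segment_id, accession)],
               by.x = c("entry", "entity", "auth_asym_id", "target_segment_id"),
               by.y = c("entry", "entity", "auth_asym_id", "segment_id"),
               all.x = TRUE, sort = FALSE)
  if (anyNA(res$accession))
    consistency_error("residue row references a segment that does not exist")
  data.table::setorder(res, entity, auth_asym_id, query_seq_id)

  x$categories[["pdbx_sifts_xref_db"]] <- data.frame(
    entity_id = res$entity,
    asym_id = res$struct_asym_id,
    auth_asym_id = res$auth_asym_id,
    seq_id = as.character(res$query_seq_id),
    auth_seq_id = as.character(res$auth_seq_id),
    auth_ins_code = ifelse(nzchar(res$auth_seq_id_ins_code),
                           res$auth_seq_id_ins_code, NA_character_),
    mon_id = res$chem_comp_id,
    one_letter_code = res$query_one_letter_code,
    observed = lb(res$observed),
    unp_acc = res$accession,
    unp_num = as.character(res$target_seq_id),
    unp_res = res$target_one_letter_code,
    unp_segment_id = as.character(res$target_segment_id),
    tax_id = as.character(res$tax_id),
    best_mapping = lb(res$best_mapping),
    stringsAsFactors = FALSE)

  atoms <- x$categories$atom_site
  if (!is.null(atoms)) {
    best <- res[res$best_mapping, , drop = FALSE]
    key <- paste(best$struct_asym_id, best$query_seq_id)
    akey <- paste(atoms$label_asym_id, as.integer(atoms$label_seq_id))
    idx <- match(akey, key)
    atoms$pdbx_sifts_xref_db_name <- ifelse(is.na(idx), NA_character_, "UNP")
    atoms$pdbx_sifts_xref_db_acc <- best$accession[idx]
    atoms$pdbx_sifts_xref_db_num <- as.character(best$target_seq_id[idx])
    atoms$pdbx_sifts_xref_db_res <- best$target_one_letter_code[idx]
    x$categories$atom_site <- atoms
  }

  write_mmcif(x, out)
  chk <- tryCatch(read_mmcif(out), error = function(e) e)
  if (inherits(chk, "error")) {
    unlink(out)
    stop("round-trip re-parse of written mmCIF failed: ",
         conditionMessage(chk), call. = FALSE)
  }
  invisible(out)
}
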