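# End-to-end pipeline steps shared by the CLI subcommands.

hits_table_columns <- c(
  "entry", "entity", "accession", "alignment_len", "query_len", "mismatch",
  "query_start", "query_end", "target_start", "target_end", "evalue",
  "bit_score", "identity", "coverage", "query_aligned", "target_aligned",
  "target_tax_id", "query_tax_id", "sifts_score", "pdb_cross_references",
  "adjusted_score", "tax_score", "dataset_score", "hit_rank")

#' Identify the best reference match for each entity
#'
#' Runs search, scoring and ranking per polymer entity. Entities with no
#' hit passing the identity cutoff are recorded as unmapped, not failed.
#'
#' @param entities list of `polymer_entity`
#' @param db a `reference_db`
#' @param lineages lineage table ([read_lineage_tsv()]); NULL disables
#'   taxonomy scoring (all taxonomy scores 0)
#' @param params a [search_params()]
#' @param out_dir optional directory: writes `hits.tsv` (original search
#'   output) and `ranked_hits.tsv` (hits-table column order)
#' @param store optional [mapping_store()]: ranked hits are appended
#' @param precomputed optional raw-hit table from [parse_search_tsv()]
#'   (external search adapter); used instead of the built-in search
#' @return list(ranked = combined ranked hits, unmapped = entity keys)
#' @export
sequence_match <- function(entities, db, lineages = NULL,
                           params = search_params(), out_dir = NULL,
                           store = NULL, precomputed = NULL) {
  if (is.null(lineages))
    lineages <- data.table::data.table(tax_id = integer(0),
                                       species_taxid = integer(0),
                                       genus_taxid = integer(0),
                                       family_taxid = integer(0),
                                       order_taxid = integer(0))
  ranked_all <- list()
  raw_all <- list()
  unmapped <- character(0)
  for (e in entities) {
    key <- sprintf("%s/%s", e$entry_id, e$entity_id)
    if (!is.null(precomputed)) {
      raw <- precomputed[precomputed$entry == e$entry_id &
                           precomputed$entity == e$entity_id, ]
      raw <- raw[!raw$filtered, ]
      raw$filtered <- NULL
    } else {
      raw <- search_reference(e$sample_sequence, e$tax_id %||% NA_integer_,
                              db, params, entry = e$entry_id,
                              entity = e$entity_id)
    }
    if (nrow(raw) == 0L) {
      unmapped <- c(unmapped, key)
      next
    }
    raw_all[[key]] <- raw
    ranked <- rank_hits(score_hits(raw, lineages, db))
    ranked_all[[key]] <- ranked
  }
  ranked <- data.table::rbindlist(ranked_all, fill = TRUE)
  raw <- data.table::rbindlist(raw_all, fill = TRUE)
  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    data.table::fwrite(raw, file.path(out_dir, "hits.tsv"), sep = "\t")
    out <- if (nrow(ranked))
      ranked[, intersect(hits_table_columns, names(ranked)), with = FALSE]
    else ranked
    data.table::fwrite(out, file.path(out_dir, "ranked_hits.tsv"), sep = "\t")
  }
  if (!is.null(store) && nrow(ranked))
    store_append_hits(store, ranked[, intersect(hits_table_columns,
                                                names(ranked)), with = FALSE])
  list(ranked = ranked, unmapped = unmapped)
}

# greedy multi-accession mapping of one entity: rank-1 hit first, further
# hits only where they claim an unclaimed query stretch (fusion constructs)
map_entity_segments <- function(entity, ranked, db,
                                refine_params = refinement_params(),
                                aln_params = alignment_params(),
                                min_chimera_run = 20L) {
  L <- nchar(entity$sample_sequence)
  seg_list <- list(); res_list <- list()
  for (chain in entity$chains) {
    claimed <- logical(L)
    chain_segs <- list()
    audits <- list()
    for (r in seq_len(nrow(ranked))) {
      hit <- ranked[r, ]
      ref <- db$records[db$records$accession == hit$accession, ][1, ]
      alns <- local_alignments(entity$sample_sequence, ref$sequence,
                               aln_params)
      keep <- list()
      for (a in alns) {
        span <- a$query_start:a$query_end
        if (hit$hit_rank == 1L) {
          if (!any(claimed[span])) keep[[length(keep) + 1L]] <- a
        } else {
          unclaimed <- sum(!claimed[span])
          if (unclaimed >= min_chimera_run &&
              unclaimed / length(span) >= 0.9)
            keep[[length(keep) + 1L]] <- a
        }
      }
      if (!length(keep)) next
      refined <- lapply(keep, function(a) {
        out <- refine_alignment(a, chain, refine_params)
        audits[[length(audits) + 1L]] <<- out$audit
        out$alignment
      })
      for (a in refined) claimed[a$query_start:a$query_end] <- TRUE
      segs <- build_segments(chain, refined, hit, as.list(ref),
                             entry = entity$entry_id,
                             entity = entity$entity_id,
                             params = refine_params, aln_params = aln_params)
      if (nrow(segs)) chain_segs[[length(chain_segs) + 1L]] <- segs
      if (hit$hit_rank == 1L && all(claimed)) break
    }
    if (!length(chain_segs)) next
    segs <- data.table::rbindlist(chain_segs)
    data.table::setorder(segs, query_start)
    res <- residue_mapping(segs, chain)
    seg_list[[length(seg_list) + 1L]] <- segs
    res_list[[length(res_list) + 1L]] <- res
  }
  segs <- flag_chimera(data.table::rbindlist(seg_list))
  list(segments = segs,
       residues = data.table::rbindlist(res_list),
       audit = data.table::rbindlist(list()))
}

#' Residue-level mapping for entities
#'
#' For each entity, aligns the sample sequence to its ranked reference
#' hits (or to a user-supplied bypass reference), refines each alignment
#' with backbone connectivity, builds segments and the one-to-one residue
#' mapping, and writes per-entry gzip CSVs under `out_root/<entry>/`.
#'
#' @param entities list of `polymer_entity`
#' @param ranked ranked hits ([sequence_match()]`$ranked`); ignored when
#'   `bypass_fasta` is given
#' @param db a `reference_db` (NULL allowed with `bypass_fasta`)
#' @param out_root output root directory (NULL skips writing)
#' @param bypass_fasta optional FASTA whose first record (or the record
#'   matching each entity key) is used directly as the reference
#' @param refine_params a [refinement_params()]
#' @param aln_params an [alignment_params()]
#' @return list(segments, residues) combined over entities
#' @export
run_segments <- function(entities, ranked = NULL, db = NULL, out_root = NULL,
                         bypass_fasta = NULL,
                         refine_params = refinement_params(),
                         aln_params = alignment_params()) {
  if (is.null(bypass_fasta) && (is.null(ranked) || nrow(ranked) == 0L))
    stop("no ranked hits and no bypass reference supplied", call. = FALSE)
  if (!is.null(bypass_fasta)) {
    seqs <- Biostrings::readAAStringSet(bypass_fasta)
    if (!length(seqs)) stop("bypass FASTA is empty", call. = FALSE)
    hdr <- lapply(names(seqs), parse_reference_header)
    rec <- data.table::data.table(
      accession = vapply(hdr, `[[`, character(1), "accession"),
      name = vapply(hdr, `[[`, character(1), "name"),
      seq_version = vapply(hdr, `[[`, integer(1), "seq_version"),
      sequence = toupper(as.character(seqs)),
      dataset = "other", tax_id = NA_integer_,
      annotation_score = 0L, pdb_xref_count = 0L)
    db <- structure(list(path = NA, records = rec,
                         total_residues = sum(nchar(rec$sequence))),
                    class = "reference_db")
  }
  seg_all <- list(); res_all <- list()
  for (e in entities) {
    if (!is.null(bypass_fasta)) {
      acc <- db$records$accession[1]
      er <- data.table::data.table(
        entry = e$entry_id, entity = e$entity_id, accession = acc,
        query_tax_id = NA_integer_, target_tax_id = NA_integer_,
        hit_rank = 1L, best = TRUE)
    } else {
      er <- ranked[ranked$entry == e$entry_id & ranked$entity == e$entity_id, ]
      if (nrow(er) == 0L) next
    }
    m <- map_entity_segments(e, er, db, refine_params, aln_params)
    if (nrow(m$segments) == 0L) next
    seg_all[[length(seg_all) + 1L]] <- m$segments
    res_all[[length(res_all) + 1L]] <- m$residues
    if (!is.null(out_root))
      write_entry_outputs(file.path(out_root, e$entry_id),
                          m$segments, m$residues)
  }
  segs <- data.table::rbindlist(seg_all, fill = TRUE)
  ress <- data.table::rbindlist(res_all, fill = TRUE)
  if (!is.null(out_root) && nrow(segs)) {
    # one entry directory may accumulate several entities: rewrite combined
    for (en in unique(segs$entry))
      write_entry_outputs(file.path(out_root, en),
                          segs[segs$entry == en, ],
                          ress[ress$entry == en, ])
  }
  list(segments = segs, residues = ress)
}
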