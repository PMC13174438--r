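# Bounded composite scoring of candidate hits.
#
#   BaseScore       = Coverage * Identity * 1000              in [0, 1000]
#   MismatchPenalty = 1 - mismatches / query_length           in [0, 1]
#   AdjustedScore   = BaseScore * MismatchPenalty             in [0, 1000]
#   SiftsScore      = AdjustedScore + TaxonomyScore + ProvenanceScore
#                                                             in [-50, 1300]
#
# Taxonomy: +200 for an exact species match, +100 / +50 / +25 when the
# lowest shared rank is genus / family / order; deeper shared ranks score 0.
# Provenance: reviewed entries get +20 x AnnotationScore (0-5); unreviewed
# entries get -50 + 10 x AnnotationScore; non-UniProtKB sets get 0.
# PDB cross-reference counts break ties in ranking but never enter the
# score, which keeps it bounded and comparable across proteins.

#' Base score of an alignment
#'
#' @param coverage fraction of the query (structure) sequence aligned, in
#'   \[0, 1\]
#' @param identity fraction of aligned residues identical, in \[0, 1\]
#' @return `coverage * identity * 1000`
#' @export
base_score <- function(coverage, identity) {
  if (any(coverage < 0 | coverage > 1) || any(identity < 0 | identity > 1))
    stop("coverage and identity must lie in [0, 1]", call. = FALSE)
  coverage * identity * 1000
}

#' Mismatch penalty
#'
#' `1 - mismatches / query_len`: a few mismatches in a short sequence
#' reduce the score strongly, the same number in a long sequence only
#' slightly. The denominator is the full query sequence length, not the
#' alignment length.
#'
#' @param mismatches number of aligned, non-identical, non-gap columns
#' @param query_len query sequence length (> 0)
#' @export
mismatch_penalty <- function(mismatches, query_len) {
  if (any(query_len <= 0)) stop("query_len must be positive", call. = FALSE)
  if (any(mismatches < 0 | mismatches > query_len))
    stop("mismatches must lie in [0, query_len]", call. = FALSE)
  1 - mismatches / query_len
}

#' Read a rank-annotated lineage table
#'
#' Tab-separated with header:
#' `tax_id species_taxid genus_taxid family_taxid order_taxid`; empty
#' fields mean the rank is absent (absent ranks never match anything).
#'
#' @param path TSV path
#' @return data.table lineage table
#' @export
read_lineage_tsv <- function(path) {
  lt <- data.table::fread(path, sep = "\t", header = TRUE,
                          na.strings = c("", "NA"))
  need <- c("tax_id", "species_taxid", "genus_taxid", "family_taxid",
            "order_taxid")
  miss <- setdiff(need, names(lt))
  if (length(miss))
    stop(sprintf("lineage table missing column(s): %s",
                 paste(miss, collapse = ", ")), call. = FALSE)
  for (cc in need) lt[[cc]] <- as.integer(lt[[cc]])
  lt
}

#' Taxonomy score between query and target taxa
#'
#' +200 when the taxa match at species level; otherwise +100, +50 or +25
#' when the lowest shared rank among genus, family and order is genus,
#' family or order respectively (one, two or three rank levels up to the
#' most recent common ancestor); 0 otherwise. Taxa missing from the
#' lineage table degrade to 0 with a warning.
#'
#' @param query_tax,target_tax NCBI taxids
#' @param lineages lineage table (see [read_lineage_tsv()])
#' @export
taxonomy_score <- function(query_tax, target_tax, lineages) {
  if (is.na(query_tax) || is.na(target_tax)) return(0)
  q <- lineages[lineages$tax_id == query_tax, ]
  t <- lineages[lineages$tax_id == target_tax, ]
  if (nrow(q) == 0L || nrow(t) == 0L) {
    warning(sprintf("no lineage record for taxid %s; taxonomy score 0",
                    if (nrow(q) == 0L) query_tax else target_tax),
            call. = FALSE)
    return(0)
  }
  rank_eq <- function(a, b) !is.na(a) && !is.na(b) && a == b
  if (query_tax == target_tax ||
      rank_eq(q$species_taxid[1], t$species_taxid[1])) return(200)
  if (rank_eq(q$genus_taxid[1], t$genus_taxid[1])) return(100)
  if (rank_eq(q$family_taxid[1], t$family_taxid[1])) return(50)
  if (rank_eq(q$order_taxid[1], t$order_taxid[1])) return(25)
  0
}

#' Dataset-provenance score
#'
#' @param dataset `"reviewed"`, `"unreviewed"` or `"other"`
#' @param annotation_score integer 0-5 (0 = unknown)
#' @export
provenance_score <- function(dataset, annotation_score) {
  if (!dataset %in% c("reviewed", "unreviewed", "other"))
    stop("dataset must be reviewed/unreviewed/other", call. = FALSE)
  if (annotation_score %% 1 != 0 || annotation_score < 0 || annotation_score > 5)
    stop("annotation_score must be an integer in [0, 5]", call. = FALSE)
  switch(dataset,
         reviewed = 20 * annotation_score,
         unreviewed = -50 + 10 * annotation_score,
         other = 0)
}

#' Composite score of one raw hit
#'
#' @param hit one-row raw hit (list or data.frame row) with `coverage`,
#'   `identity`, `mismatch`, `query_len`, `query_tax_id`, `target_tax_id`
#' @param lineages lineage table
#' @param reference matching reference record (list/row with `dataset`,
#'   `annotation_score`, `pdb_xref_count`)
#' @return the hit with score components appended (`base_score`,
#'   `mismatch_penalty`, `adjusted_score`, `tax_score`, `dataset_score`,
#'   `sifts_score`, `pdb_cross_references`)
#' @export
sifts_score <- function(hit, lineages, reference) {
  hit <- as.list(hit)
  bs <- base_score(hit$coverage, hit$identity)
  mp <- mismatch_penalty(hit$mismatch, hit$query_len)
  adj <- bs * mp
  ts <- taxonomy_score(hit$query_tax_id, hit$target_tax_id, lineages)
  ds <- provenance_score(reference$dataset, reference$annotation_score)
  hit$base_score <- bs
  hit$mismatch_penalty <- mp
  hit$adjusted_score <- adj
  hit$tax_score <- ts
  hit$dataset_score <- ds
  hit$sifts_score <- adj + ts + ds
  hit$pdb_cross_references <- reference$pdb_xref_count %||% 0L
  hit
}

#' Score a table of raw hits
#'
#' @param hits data.table of raw hits (one query)
#' @param lineages lineage table
#' @param db `reference_db` supplying provenance metadata
#' @return data.table of scored hits
#' @export
score_hits <- function(hits, lineages, db) {
  hits <- data.table::as.data.table(hits)
  if (nrow(hits) == 0L) return(hits)
  rec <- db$records
  rows <- lapply(seq_len(nrow(hits)), function(i) {
    ref <- rec[rec$accession == hits$accession[i], ]
    if (nrow(ref) == 0L)
      stop(sprintf("hit accession %s not in reference db", hits$accession[i]),
           call. = FALSE)
    data.table::as.data.table(
      sifts_score(hits[i, ], lineages, as.list(ref[1, ])))
  })
  data.table::rbindlist(rows)
}

#' Rank scored hits
#'
#' Deterministic total order: composite score descending, then PDB
#' cross-reference count descending (the tie-break that keeps repeated
#' structures of one protein mapped to the same accession), then accession
#' ascending. `hit_rank` is 1-based; the rank-1 hit is the best mapping.
#'
#' @param hits data.table of scored hits for one query
#' @return the hits sorted, with `hit_rank` and logical `best` columns
#' @export
rank_hits <- function(hits) {
  hits <- data.table::as.data.table(hits)
  if (nrow(hits) == 0L) {
    hits$hit_rank <- integer(0)
    hits$best <- logical(0)
    return(hits)
  }
  o <- order(-hits$sifts_score, -hits$pdb_cross_references, hits$accession)
  hits <- hits[o, ]
  hits$hit_rank <- seq_len(nrow(hits))
  hits$best <- hits$hit_rank == 1L
  hits
}
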