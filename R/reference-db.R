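# Reference sequence sets with taxonomy and provenance metadata.
#
# The index is a plain on-disk directory holding one TSV of records. The
# dataset of each record is inferred from the UniProtKB-style FASTA header
# (`sp|ACC|NAME` reviewed, `tr|ACC|NAME` unreviewed, anything else "other");
# a taxonomy map is mandatory because downstream ranking is taxonomy-aware.

parse_reference_header <- function(header) {
  m <- regmatches(header, regexec("^(sp|tr)\\|([^| ]+)\\|(\\S+)", header))[[1]]
  if (length(m) == 4L) {
    dataset <- if (m[2] == "sp") "reviewed" else "unreviewed"
    acc <- m[3]; name <- m[4]
  } else {
    dataset <- "other"
    acc <- strsplit(header, "\\s+")[[1]][1]
    name <- acc
  }
  sv <- regmatches(header, regexec("\\bSV=(\\d+)", header))[[1]]
  list(accession = acc, name = name, dataset = dataset,
       seq_version = if (length(sv) == 2L) as.integer(sv[2]) else 1L)
}

#' Build an indexed reference sequence database
#'
#' Reads a UniProtKB-convention FASTA file plus a mandatory
#' `identifier<TAB>taxid` taxonomy map and optional annotation-score and
#' PDB-cross-reference count tables, and writes a single on-disk index.
#' Missing annotation scores and cross-reference counts default to 0
#' (annotation 0 means "unknown" and is the least-trusted value).
#'
#' @param fasta path to the reference FASTA
#' @param taxonomy_tsv path to `identifier<TAB>taxid`
#' @param annotation_tsv optional `accession<TAB>score` (0-5)
#' @param xref_tsv optional `accession<TAB>count`
#' @param out index directory to create
#' @return a `reference_db` handle
#' @export
build_reference_db <- function(fasta, taxonomy_tsv, annotation_tsv = NULL,
                               xref_tsv = NULL, out) {
  seqs <- Biostrings::readAAStringSet(fasta)
  if (!length(seqs)) stop("reference FASTA is empty", call. = FALSE)
  hdr <- lapply(names(seqs), parse_reference_header)
  rec <- data.table::data.table(
    accession = vapply(hdr, `[[`, character(1), "accession"),
    name = vapply(hdr, `[[`, character(1), "name"),
    seq_version = vapply(hdr, `[[`, integer(1), "seq_version"),
    sequence = toupper(as.character(seqs)),
    dataset = vapply(hdr, `[[`, character(1), "dataset"))
  dup <- rec$accession[duplicated(rec$accession)]
  if (length(dup))
    stop(sprintf("duplicate accession in FASTA: %s",
                 paste(unique(dup), collapse = ", ")), call. = FALSE)

  tax <- read_kv_tsv(taxonomy_tsv, "tax_id")
  miss <- setdiff(rec$accession, tax$key)
  if (length(miss))
    stop(sprintf("identifier(s) missing from taxonomy map: %s",
                 paste(miss, collapse = ", ")), call. = FALSE)
  rec$tax_id <- tax$tax_id[match(rec$accession, tax$key)]

  rec$annotation_score <- 0L
  if (!is.null(annotation_tsv)) {
    ann <- read_kv_tsv(annotation_tsv, "score")
    hit <- match(rec$accession, ann$key)
    rec$annotation_score[!is.na(hit)] <- ann$score[hit[!is.na(hit)]]
  }
  rec$pdb_xref_count <- 0L
  if (!is.null(xref_tsv)) {
    xr <- read_kv_tsv(xref_tsv, "count")
    hit <- match(rec$accession, xr$key)
    rec$pdb_xref_count[!is.na(hit)] <- xr$count[hit[!is.na(hit)]]
  }

  dir.create(out, recursive = TRUE, showWarnings = FALSE)
  data.table::fwrite(rec, file.path(out, "records.tsv"), sep = "\t")
  writeLines(c("siftsmapper reference index v1",
               sprintf("records\t%d", nrow(rec)),
               sprintf("residues\t%d", sum(nchar(rec$sequence)))),
             file.path(out, "index.txt"))
  structure(list(path = out, records = rec,
                 total_residues = sum(nchar(rec$sequence))),
            class = "reference_db")
}

#' Open an existing reference index
#' @param path index directory created by [build_reference_db()]
#' @return a `reference_db` handle
#' @export
read_reference_db <- function(path) {
  f <- file.path(path, "records.tsv")
  if (!file.exists(f)) stop(sprintf("no reference index at %s", path),
                            call. = FALSE)
  rec <- data.table::fread(f, sep = "\t",
                           colClasses = list(character = c("accession", "name",
                                                           "sequence", "dataset")))
  structure(list(path = path, records = rec,
                 total_residues = sum(nchar(rec$sequence))),
            class = "reference_db")
}

#' @export
print.reference_db <- function(x, ...) {
  cat(sprintf("reference db: %d records, %d residues (%s)\n",
              nrow(x$records), x$total_residues, x$path))
  invisible(x)
}

#' Search parameters
#'
#' @param min_identity minimum alignment identity retained (default 0.9,
#'   the standard cutoff accounting for sequence differences such as point
#'   mutations between construct and reference)
#' @param aligner an [alignment_params()] for the built-in backend; search
#'   uses BLAST-like conventions (gap open 11, extend 1)
#' @export
search_params <- function(min_identity = 0.9,
                          aligner = alignment_params(gap_open = 11L,
                                                     gap_extend = 1L,
                                                     max_alignments = 1L,
                                                     min_score = 1L)) {
  stopifnot(min_identity >= 0, min_identity <= 1)
  structure(list(min_identity = min_identity, aligner = aligner),
            class = "search_params")
}

# gapped Karlin-Altschul constants for BLOSUM62 11/1
KA_LAMBDA <- 0.267
KA_K <- 0.041

raw_hit_columns <- c("entry", "entity", "accession", "alignment_len",
                     "query_len", "mismatch", "query_start", "query_end",
                     "target_start", "target_end", "evalue", "bit_score",
                     "identity", "coverage", "query_aligned", "target_aligned",
                     "query_tax_id", "target_tax_id")

#' Exhaustive search of a query against a reference database
#'
#' Runs the built-in local aligner against every record, keeps the single
#' best alignment per record, computes identity (identical columns /
#' alignment length), coverage (aligned query residues / query length),
#' BLAST-style bit score and e-value against the database residue count,
#' and discards hits below `min_identity`. Ordering is deterministic:
#' bit score descending, then accession ascending.
#'
#' @param query amino-acid sequence of the structure chain
#' @param query_taxid NCBI taxid of the query (NA allowed)
#' @param db a `reference_db`
#' @param params a [search_params()]
#' @param entry,entity identifiers copied into the hit rows
#' @return data.table of raw hits (possibly zero rows)
#' @export
search_reference <- function(query, query_taxid = NA_integer_, db,
                             params = search_params(), entry = "", entity = "") {
  assert_aa_string(query, "query")
  rec <- db$records
  qlen <- nchar(query)
  rows <- vector("list", nrow(rec))
  for (i in seq_len(nrow(rec))) {
    alns <- local_alignments(query, rec$sequence[i], params$aligner)
    if (!length(alns)) next
    a <- alns[[1]]
    identity <- a$n_identical / a$alignment_len
    if (identity < params$min_identity) next
    bit <- (KA_LAMBDA * a$score - log(KA_K)) / log(2)
    evalue <- qlen * db$total_residues * 2^(-bit)
    rows[[i]] <- data.table::data.table(
      entry = entry, entity = entity, accession = rec$accession[i],
      alignment_len = a$alignment_len, query_len = qlen,
      mismatch = a$n_mismatch, query_start = a$query_start,
      query_end = a$query_end, target_start = a$target_start,
      target_end = a$target_end, evalue = evalue, bit_score = bit,
      identity = identity, coverage = a$n_aligned / qlen,
      query_aligned = a$query_aligned, target_aligned = a$target_aligned,
      query_tax_id = as.integer(query_taxid),
      target_tax_id = rec$tax_id[i], raw_score = a$score)
  }
  hits <- data.table::rbindlist(rows)
  if (nrow(hits) == 0L)
    return(data.table::setnames(
      data.table::as.data.table(stats::setNames(
        rep(list(character(0)), length(raw_hit_columns)), raw_hit_columns)),
      raw_hit_columns))
  data.table::setorder(hits, -bit_score, accession)
  hits
}

#' Parse a tabular search-hit file from an external search tool
#'
#' Adapter for precomputed hits in a fixed tab-separated column order:
#' entry, entity, accession, alignment_len, query_len, mismatch,
#' query_start, query_end, target_start, target_end, evalue, bit_score,
#' identity, coverage, query_aligned, target_aligned. Taxids are joined
#' from the reference index. Rows failing the identity cutoff are kept but
#' flagged in the `filtered` column, never silently dropped.
#'
#' @param path TSV path
#' @param db a `reference_db` (for taxids)
#' @param min_identity identity cutoff used for flagging (default 0.9)
#' @param query_taxid taxid assigned to the queries (NA allowed)
#' @return data.table of raw hits with a logical `filtered` column
#' @export
parse_search_tsv <- function(path, db, min_identity = 0.9,
                             query_taxid = NA_integer_) {
  cols <- raw_hit_columns[1:16]
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(lines)]
  if (!length(lines)) {
    empty <- data.table::as.data.table(stats::setNames(
      rep(list(character(0)), length(cols) + 3L),
      c(cols, "query_tax_id", "target_tax_id", "filtered")))
    return(empty)
  }
  parts <- strsplit(lines, "\t", fixed = TRUE)
  bad <- which(lengths(parts) != length(cols))
  if (length(bad))
    stop(sprintf("line %d: expected %d tab-separated columns, found %d",
                 bad[1], length(cols), lengths(parts)[bad[1]]), call. = FALSE)
  m <- do.call(rbind, parts)
  hits <- data.table::as.data.table(stats::setNames(
    as.data.frame(m, stringsAsFactors = FALSE), cols))
  intcols <- c("alignment_len", "query_len", "mismatch", "query_start",
               "query_end", "target_start", "target_end")
  for (cc in intcols) hits[[cc]] <- as.integer(hits[[cc]])
  for (cc in c("evalue", "bit_score", "identity", "coverage"))
    hits[[cc]] <- as.numeric(hits[[cc]])
  hits$query_tax_id <- as.integer(query_taxid)
  hits$target_tax_id <- db$records$tax_id[match(hits$accession,
                                                db$records$accession)]
  hits$filtered <- hits$identity < min_identity
  hits
}
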