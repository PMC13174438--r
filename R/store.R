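# Persistence: per-entry gzip CSVs plus a single-file mapping store.
#
# The store keeps three tables (hits, sifts_xref_segment,
# sifts_xref_residue). No embedded SQL engine is available in this
# environment, so the single-file store is a serialized list of data.tables
# written atomically (temp file + rename); the contract -- transactional
# bulk load, dedup keys, replace-by-entry on reload -- is unchanged.
# Hits live only in the store, never in per-entry CSVs.

hits_key <- c("entry", "entity", "accession", "hit_rank")
# the residue table has no accession column of its own: the segment id
# stands in for it in the uniqueness key
residue_key <- c("entry", "entity", "auth_asym_id", "residue_id",
                 "target_segment_id")

#' Open (or create) a mapping store
#'
#' @param path single-file store location
#' @return a `mapping_store` handle
#' @export
mapping_store <- function(path) {
  structure(list(path = path), class = "mapping_store")
}

store_read <- function(store) {
  if (file.exists(store$path)) {
    readRDS(store$path)
  } else {
    list(hits = data.table::data.table(),
         sifts_xref_segment = data.table::data.table(),
         sifts_xref_residue = data.table::data.table())
  }
}

store_write_atomic <- function(store, tables) {
  tmp <- paste0(store$path, ".tmp")
  saveRDS(tables, tmp)
  if (!file.rename(tmp, store$path)) {
    unlink(tmp)
    stop("could not replace store file (database locked?); retry",
         call. = FALSE)
  }
  invisible(store)
}

#' Tables currently in a store
#' @param store a [mapping_store()]
#' @param name one of "hits", "sifts_xref_segment", "sifts_xref_residue"
#' @export
store_table <- function(store, name) {
  tabs <- store_read(store)
  if (!name %in% names(tabs)) stop("unknown table: ", name, call. = FALSE)
  tabs[[name]]
}

#' Append ranked hits for one query to the store
#' @param store a [mapping_store()]
#' @param hits ranked hits table
#' @export
store_append_hits <- function(store, hits) {
  hits <- data.table::as.data.table(hits)
  tabs <- store_read(store)
  combined <- data.table::rbindlist(list(tabs$hits, hits), fill = TRUE)
  if (anyDuplicated(combined, by = hits_key))
    combined <- unique(combined, by = hits_key)
  tabs$hits <- combined
  store_write_atomic(store, tabs)
}

write_gz_csv <- function(df, path) {
  df <- data.table::as.data.table(df)
  for (cc in names(df))
    if (is.logical(df[[cc]]))
      df[[cc]] <- ifelse(df[[cc]], "true", "false")
  tmp <- paste0(path, ".part")
  ok <- FALSE
  on.exit(if (!ok) unlink(tmp))
  data.table::fwrite(df, tmp, na = "", quote = "auto", compress = "gzip")
  ok <- file.rename(tmp, path)
  if (!ok) stop("could not write ", path, call. = FALSE)
  invisible(path)
}

#' Write per-entry mapping CSVs
#'
#' Two gzip-compressed RFC 4180 CSVs (`segments.csv.gz`,
#' `residues.csv.gz`) with header rows, the canonical column order,
#' lowercase `true`/`false` booleans and empty string for missing values.
#' No partial file is left behind on failure.
#'
#' @param entry_dir directory for this entry (created if needed)
#' @param segments segment table
#' @param residues residue table
#' @return named character vector of file paths
#' @export
write_entry_outputs <- function(entry_dir, segments, residues) {
  dir.create(entry_dir, recursive = TRUE, showWarnings = FALSE)
  segments <- data.table::as.data.table(segments)
  residues <- data.table::as.data.table(residues)
  seg_out <- if (nrow(segments))
    segments[, intersect(segment_columns_order, names(segments)), with = FALSE]
  else data.table::as.data.table(stats::setNames(
    rep(list(character(0)), length(segment_columns_order)),
    segment_columns_order))
  res_out <- if (nrow(residues))
    residues[, intersect(residue_columns_order, names(residues)), with = FALSE]
  else data.table::as.data.table(stats::setNames(
    rep(list(character(0)), length(residue_columns_order)),
    residue_columns_order))
  paths <- c(segments = file.path(entry_dir, "segments.csv.gz"),
             residues = file.path(entry_dir, "residues.csv.gz"))
  write_gz_csv(seg_out, paths[["segments"]])
  write_gz_csv(res_out, paths[["residues"]])
  paths
}

read_entry_csv <- function(path, expected_cols) {
  dt <- tryCatch({
    con <- gzfile(path, "rt")
    on.exit(close(con))
    txt <- readLines(con, warn = FALSE)
    data.table::fread(text = txt, colClasses = "character", na.strings = NULL)
  }, error = function(e) e)
  if (inherits(dt, "error")) return(list(ok = FALSE, reason = conditionMessage(dt)))
  if (!identical(names(dt), expected_cols))
    return(list(ok = FALSE,
                reason = sprintf("schema mismatch: columns %s",
                                 paste(names(dt), collapse = ","))))
  for (cc in c("best_mapping", "canonical_acc", "chimera", "observed"))
    if (cc %in% names(dt)) dt[[cc]] <- dt[[cc]] == "true"
  intcols <- c("seq_version", "query_start", "query_end", "target_start",
               "target_end", "auth_start", "auth_end", "conflicts",
               "modifications", "target_segment_id", "auth_seq_id",
               "query_seq_id", "target_seq_id", "tax_id", "residue_id")
  for (cc in intersect(intcols, names(dt)))
    dt[[cc]] <- suppressWarnings(as.integer(dt[[cc]]))
  for (cc in intersect(c("identity", "score"), names(dt)))
    dt[[cc]] <- as.numeric(dt[[cc]])
  list(ok = TRUE, data = dt)
}

#' Bulk-load entry outputs into the store
#'
#' Scans `root` for entry directories holding `segments.csv.gz` +
#' `residues.csv.gz`, validates each pair against the schemas, and appends
#' all valid files in one transactional operation: either every valid
#' file's rows land, or none. Re-loading an entry replaces its previous
#' rows (replace-by-entry), so re-runs are idempotent. Invalid files are
#' reported, never partially loaded.
#'
#' @param root output root directory
#' @param store a [mapping_store()]
#' @return load report: list(entries_scanned, entries_loaded,
#'   segment_rows, residue_rows, rejects)
#' @export
db_load <- function(root, store) {
  if (!dir.exists(root)) stop("root directory does not exist: ", root,
                              call. = FALSE)
  seg_files <- list.files(root, pattern = "^segments\\.csv\\.gz$",
                          recursive = TRUE, full.names = TRUE)
  entries <- dirname(seg_files)
  rejects <- list()
  seg_new <- list(); res_new <- list()
  loaded <- character(0)
  for (ed in entries) {
    sf <- file.path(ed, "segments.csv.gz")
    rf <- file.path(ed, "residues.csv.gz")
    if (!file.exists(rf)) {
      rejects[[ed]] <- "missing residues.csv.gz"
      next
    }
    s <- read_entry_csv(sf, segment_columns_order)
    if (!s$ok) { rejects[[ed]] <- paste0(basename(sf), ": ", s$reason); next }
    r <- read_entry_csv(rf, residue_columns_order)
    if (!r$ok) { rejects[[ed]] <- paste0(basename(rf), ": ", r$reason); next }
    seg_new[[ed]] <- s$data
    res_new[[ed]] <- r$data
    loaded <- c(loaded, ed)
  }
  segs <- data.table::rbindlist(seg_new)
  ress <- data.table::rbindlist(res_new)
  tabs <- store_read(store)
  n_seg0 <- nrow(tabs$sifts_xref_segment)
  n_res0 <- nrow(tabs$sifts_xref_residue)
  if (nrow(segs)) {
    old <- tabs$sifts_xref_segment
    if (nrow(old)) old <- old[!old$entry %in% unique(segs$entry), ]
    tabs$sifts_xref_segment <- data.table::rbindlist(list(old, segs),
                                                     fill = TRUE)
  }
  if (nrow(ress)) {
    old <- tabs$sifts_xref_residue
    if (nrow(old)) old <- old[!old$entry %in% unique(ress$entry), ]
    combined <- data.table::rbindlist(list(old, ress), fill = TRUE)
    tabs$sifts_xref_residue <- unique(combined, by = residue_key)
  }
  store_write_atomic(store, tabs)
  list(entries_scanned = length(entries),
       entries_loaded = length(loaded),
       segment_rows = nrow(tabs$sifts_xref_segment) - n_seg0,
       residue_rows = nrow(tabs$sifts_xref_residue) - n_res0,
       rejects = rejects)
}

#' Best mapping for an entry/entity
#'
#' Single filtered scan of the segment table.
#'
#' @param store a [mapping_store()]
#' @param entry,entity identifiers
#' @export
best_mapping <- function(store, entry, entity) {
  segs <- store_table(store, "sifts_xref_segment")
  if (nrow(segs) == 0L) return(segs)
  segs[segs$entry == entry & segs$entity == entity & segs$best_mapping, ]
}
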