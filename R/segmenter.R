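# Residue-level mapping with backbone-connectivity refinement.
#
# Local alignments can park short isolated matches inside long gaps (e.g. a
# lone glycine aligned inside an unobserved loop). Such runs are detected by
# classifying alignment columns into continuous runs, extended gaps and
# isolated runs, then either merged into the adjacent continuous region
# (when the peptide bond to it is experimentally observed) or un-aligned so
# the unresolved region becomes a single contiguous gap.

#' Refinement parameters
#'
#' @param connect_threshold maximum C(i)-N(i+1) distance in angstroms for
#'   two residues to count as covalently connected; strictly-below test.
#'   The default 1.42 tolerates small coordinate deviations around the
#'   typical peptide-bond length (~1.33).
#' @param isolated_max_run aligned runs strictly shorter than this, bounded
#'   by extended gaps on both sides, are refinement candidates
#' @param continuous_min_run aligned runs of at least this length are
#'   always protected
#' @export
refinement_params <- function(connect_threshold = 1.42, isolated_max_run = 5L,
                              continuous_min_run = 5L) {
  stopifnot(connect_threshold > 0,
            isolated_max_run <= continuous_min_run + 1L)
  structure(list(connect_threshold = connect_threshold,
                 isolated_max_run = as.integer(isolated_max_run),
                 continuous_min_run = as.integer(continuous_min_run)),
            class = "refinement_params")
}

#' Backbone connectivity between two consecutive residues
#'
#' TRUE iff both residues are observed with the needed backbone atoms and
#' the distance from the backbone C atom of `prev` to the backbone N atom
#' of `next_` is strictly below the threshold.
#'
#' @param prev,next_ one-row residue records (with `observed`, `c_x..c_z`,
#'   `n_x..n_z`)
#' @param params a [refinement_params()]
#' @export
is_connected <- function(prev, next_, params = refinement_params()) {
  prev <- as.list(prev); next_ <- as.list(next_)
  if (!isTRUE(prev$observed) || !isTRUE(next_$observed)) return(FALSE)
  if (anyNA(c(prev$c_x, prev$c_y, prev$c_z, next_$n_x, next_$n_y, next_$n_z)))
    return(FALSE)
  d <- sqrt((prev$c_x - next_$n_x)^2 + (prev$c_y - next_$n_y)^2 +
              (prev$c_z - next_$n_z)^2)
  # compare at nanoangstrom precision so the strict threshold is not
  # blurred by floating-point round-off in coordinate arithmetic
  round(d, 9) < params$connect_threshold
}

# column view of a gapped alignment
alignment_columns <- function(alignment) {
  qc <- strsplit(alignment$query_aligned, "")[[1]]
  tc <- strsplit(alignment$target_aligned, "")[[1]]
  stopifnot(length(qc) == length(tc))
  qi <- ifelse(qc != "-", cumsum(qc != "-") + alignment$query_start - 1L, NA)
  ti <- ifelse(tc != "-", cumsum(tc != "-") + alignment$target_start - 1L, NA)
  data.frame(qc = qc, tc = tc, qi = as.integer(qi), ti = as.integer(ti),
             stringsAsFactors = FALSE)
}

columns_to_alignment <- function(cols, template) {
  a <- template
  a$query_aligned <- paste(cols$qc, collapse = "")
  a$target_aligned <- paste(cols$tc, collapse = "")
  aligned <- cols$qc != "-" & cols$tc != "-"
  a$n_aligned <- sum(aligned)
  a$n_identical <- sum(aligned & cols$qc == cols$tc)
  a$n_mismatch <- sum(aligned & cols$qc != cols$tc)
  a$alignment_len <- nrow(cols)
  a$identity <- a$n_identical / a$alignment_len
  a
}

#' Classify alignment columns into runs
#'
#' Aligned columns (residue opposite residue) form runs labelled
#' `continuous` or, when the run is strictly shorter than
#' `isolated_max_run` and bounded on both sides by extended gaps,
#' `isolated`. Gap columns are `extended_gap` when more than one
#' consecutive gap symbol separates aligned residues, else `gap`.
#' Runs touching the alignment boundary are never isolated.
#'
#' @param alignment a `local_alignment`
#' @param params a [refinement_params()]
#' @return character vector, one label per alignment column
#' @export
classify_runs <- function(alignment, params = refinement_params()) {
  cols <- alignment_columns(alignment)
  aligned <- cols$qc != "-" & cols$tc != "-"
  n <- length(aligned)
  runs <- rle(aligned)
  ends <- cumsum(runs$lengths)
  starts <- ends - runs$lengths + 1L
  labels <- character(n)
  nr <- length(runs$lengths)
  for (k in seq_len(nr)) {
    idx <- starts[k]:ends[k]
    if (!runs$values[k]) {
      labels[idx] <- if (runs$lengths[k] > 1L) "extended_gap" else "gap"
    }
  }
  for (k in seq_len(nr)) {
    if (!runs$values[k]) next
    idx <- starts[k]:ends[k]
    bounded <- k > 1L && k < nr &&
      runs$lengths[k - 1L] > 1L && runs$lengths[k + 1L] > 1L
    labels[idx] <- if (runs$lengths[k] < params$isolated_max_run && bounded)
      "isolated" else "continuous"
  }
  labels
}

#' Refine an alignment using backbone connectivity
#'
#' Each isolated run is merged into the adjacent continuous region when its
#' terminal residue is backbone-connected (peptide C-N bond observed) to
#' that region's terminal residue; otherwise -- in particular when its
#' residues are unobserved -- it is un-aligned and the whole region between
#' the flanking continuous runs is rewritten as one contiguous gap (query
#' letters first, then target letters). Continuous columns are never
#' altered. The operation is total and idempotent.
#'
#' @param alignment a `local_alignment` whose query positions index into
#'   `chain`
#' @param chain chain instance (list with `residues` data.frame)
#' @param params a [refinement_params()]
#' @return list with `alignment` (refined) and `audit` (data.frame of
#'   actions: merge / unalign, with query ranges and reasons)
#' @export
refine_alignment <- function(alignment, chain, params = refinement_params()) {
  labels <- classify_runs(alignment, params)
  cols <- alignment_columns(alignment)
  audit <- list()
  if (!any(labels == "isolated"))
    return(list(alignment = alignment,
                audit = data.frame(action = character(0),
                                   query_start = integer(0),
                                   query_end = integer(0),
                                   reason = character(0))))
  res <- chain$residues
  runs <- rle(labels)
  ends <- cumsum(runs$lengths)
  starts <- ends - runs$lengths + 1L
  drop_cols <- logical(nrow(cols))   # aligned pairs to un-align
  for (k in seq_along(runs$values)) {
    if (runs$values[k] != "isolated") next
    idx <- starts[k]:ends[k]
    qpos <- cols$qi[idx]
    qs <- min(qpos, na.rm = TRUE); qe <- max(qpos, na.rm = TRUE)
    # terminal aligned residues of the flanking continuous regions
    prev_cont <- which(labels == "continuous" & seq_along(labels) < starts[k])
    next_cont <- which(labels == "continuous" & seq_along(labels) > ends[k])
    qp <- if (length(prev_cont)) cols$qi[max(prev_cont)] else NA
    qn <- if (length(next_cont)) cols$qi[min(next_cont)] else NA
    merged <- FALSE
    if (!is.na(qp) && qs == qp + 1L &&
        is_connected(res[res$label_seq_id == qp, ],
                     res[res$label_seq_id == qs, ], params)) {
      merged <- TRUE
      reason <- "connected to preceding continuous region"
    } else if (!is.na(qn) && qn == qe + 1L &&
               is_connected(res[res$label_seq_id == qe, ],
                            res[res$label_seq_id == qn, ], params)) {
      merged <- TRUE
      reason <- "connected to following continuous region"
    }
    if (merged) {
      audit[[length(audit) + 1L]] <- data.frame(
        action = "merge", query_start = qs, query_end = qe, reason = reason)
    } else {
      drop_cols[idx] <- TRUE
      audit[[length(audit) + 1L]] <- data.frame(
        action = "unalign", query_start = qs, query_end = qe,
        reason = "not backbone-connected to an adjacent continuous region")
    }
  }
  if (any(drop_cols)) {
    keep_aligned <- (cols$qc != "-" & cols$tc != "-") & !drop_cols
    # rebuild: walk maximal regions between kept aligned columns and emit
    # their residues as one contiguous gap block
    out <- list()
    emit_gap_block <- function(idx) {
      if (!length(idx)) return(NULL)
      qlet <- cols$qc[idx][cols$qc[idx] != "-"]
      tlet <- cols$tc[idx][cols$tc[idx] != "-"]
      rbind(
        if (length(qlet)) data.frame(qc = qlet, tc = "-") else NULL,
        if (length(tlet)) data.frame(qc = "-", tc = tlet) else NULL)
    }
    pending <- integer(0)
    for (i in seq_len(nrow(cols))) {
      if (keep_aligned[i]) {
        out[[length(out) + 1L]] <- emit_gap_block(pending)
        pending <- integer(0)
        out[[length(out) + 1L]] <- data.frame(qc = cols$qc[i], tc = cols$tc[i])
      } else {
        pending <- c(pending, i)
      }
    }
    out[[length(out) + 1L]] <- emit_gap_block(pending)
    newcols <- do.call(rbind, out)
    newcols$qi <- as.integer(ifelse(newcols$qc != "-",
                                    cumsum(newcols$qc != "-") +
                                      alignment$query_start - 1L, NA))
    newcols$ti <- as.integer(ifelse(newcols$tc != "-",
                                    cumsum(newcols$tc != "-") +
                                      alignment$target_start - 1L, NA))
    alignment <- columns_to_alignment(newcols, alignment)
  }
  list(alignment = alignment, audit = do.call(rbind, audit))
}

segment_columns_order <- c(
  "entry", "entity", "auth_asym_id", "struct_asym_id", "accession", "name",
  "seq_version", "query_start", "query_end", "target_start", "target_end",
  "auth_start", "auth_end", "auth_code", "target_alignment",
  "query_alignment", "identity", "score", "conflicts", "modifications",
  "best_mapping", "canonical_acc", "chimera")

residue_columns_order <- c(
  "entry", "entity", "auth_asym_id", "struct_asym_id", "target_segment_id",
  "auth_seq_id", "auth_seq_id_ins_code", "query_seq_id", "target_seq_id",
  "observed", "query_one_letter_code", "target_one_letter_code",
  "chem_comp_id", "type", "tax_id", "best_mapping", "canonical_acc",
  "residue_id")

# raw score of an alignment slice under the segmenter's scoring model
score_alignment_slice <- function(qc, tc, aln_params) {
  sm <- aln_params$submat
  score <- 0L
  in_gap <- FALSE
  for (i in seq_along(qc)) {
    if (qc[i] != "-" && tc[i] != "-") {
      score <- score + sm[qc[i], tc[i]]
      in_gap <- FALSE
    } else {
      if (!in_gap) score <- score - aln_params$gap_open
      score <- score - aln_params$gap_extend
      in_gap <- TRUE
    }
  }
  as.integer(score)
}

#' Build mapping segments from refined alignments
#'
#' Segments are maximal runs of aligned residues that share one accession
#' and taxon (guaranteed here because each call maps one chain against one
#' reference) and whose consecutive observed residues pass the backbone
#' connectivity check. Segments split at observed chain breaks and at
#' extended gaps; single-gap columns are allowed inside a segment.
#'
#' @param chain chain instance of a `polymer_entity`
#' @param alignments list of refined `local_alignment`s, non-overlapping on
#'   the query
#' @param hit one scored hit row (accession, taxids, `best`/`hit_rank`)
#' @param reference reference record (list/row: `accession`, `name`,
#'   `seq_version`, `tax_id`)
#' @param entry,entity identifiers for the output rows
#' @param params [refinement_params()] for the connectivity check
#' @param aln_params [alignment_params()] used for per-segment scores
#' @return data.table with the segment-table columns (chimera is FALSE;
#'   see [flag_chimera()])
#' @export
build_segments <- function(chain, alignments, hit, reference,
                           entry = "", entity = "",
                           params = refinement_params(),
                           aln_params = alignment_params()) {
  if (length(alignments) > 1L) {
    iv <- t(vapply(alignments, function(a)
      c(a$query_start, a$query_end), numeric(2)))
    iv <- iv[order(iv[, 1]), , drop = FALSE]
    if (any(iv[-1, 1] <= iv[-nrow(iv), 2]))
      consistency_error("refined alignments overlap on the query")
  }
  res <- chain$residues
  hit <- as.list(hit)
  reference <- as.list(reference)
  best <- isTRUE(hit$best) || identical(hit$hit_rank, 1L)
  segs <- list()
  for (a in alignments) {
    cols <- alignment_columns(a)
    aligned_idx <- which(cols$qc != "-" & cols$tc != "-")
    if (!length(aligned_idx)) next
    # split points between consecutive aligned columns
    start_col <- aligned_idx[1]
    seg_bounds <- list()
    for (k in seq_along(aligned_idx)[-1]) {
      i0 <- aligned_idx[k - 1L]; i1 <- aligned_idx[k]
      ngap <- i1 - i0 - 1L
      split <- ngap >= 2L   # extended gap
      if (!split) {
        q0 <- cols$qi[i0]; q1 <- cols$qi[i1]
        if (!is.na(q0) && !is.na(q1) && q1 == q0 + 1L) {
          r0 <- res[res$label_seq_id == q0, ]
          r1 <- res[res$label_seq_id == q1, ]
          if (isTRUE(r0$observed) && isTRUE(r1$observed) &&
              !is_connected(r0, r1, params)) split <- TRUE
        }
      }
      if (split) {
        seg_bounds[[length(seg_bounds) + 1L]] <- c(start_col, i0)
        start_col <- i1
      }
    }
    seg_bounds[[length(seg_bounds) + 1L]] <- c(start_col,
                                               aligned_idx[length(aligned_idx)])
    for (b in seg_bounds) {
      idx <- b[1]:b[2]
      sc <- cols[idx, ]
      aligned <- sc$qc != "-" & sc$tc != "-"
      qs <- min(sc$qi, na.rm = TRUE); qe <- max(sc$qi, na.rm = TRUE)
      rs <- res[res$label_seq_id == qs, ]; re <- res[res$label_seq_id == qe, ]
      qres <- res[res$label_seq_id %in% sc$qi[!is.na(sc$qi)], ]
      segs[[length(segs) + 1L]] <- data.table::data.table(
        entry = entry, entity = entity,
        auth_asym_id = chain$auth_asym_id,
        struct_asym_id = chain$struct_asym_id,
        accession = reference$accession, name = reference$name,
        seq_version = as.integer(reference$seq_version %||% 1L),
        query_start = qs, query_end = qe,
        target_start = min(sc$ti, na.rm = TRUE),
        target_end = max(sc$ti, na.rm = TRUE),
        auth_start = rs$auth_seq_id[1], auth_end = re$auth_seq_id[1],
        auth_code = rs$ins_code[1],
        target_alignment = paste(sc$tc, collapse = ""),
        query_alignment = paste(sc$qc, collapse = ""),
        identity = sum(aligned & sc$qc == sc$tc) / length(idx),
        score = score_alignment_slice(sc$qc, sc$tc, aln_params),
        conflicts = sum(aligned & sc$qc != sc$tc),
        modifications = sum(!(qres$chem_comp_id %in% names(AA3TO1))),
        best_mapping = best,
        canonical_acc = !grepl("-\\d+$", reference$accession),
        chimera = FALSE,
        tax_id = as.integer(reference$tax_id %||% NA_integer_))
    }
  }
  out <- data.table::rbindlist(segs)
  if (nrow(out)) data.table::setorder(out, query_start)
  out
}

#' Flag chimeric entities
#'
#' Sets `chimera = TRUE` on every segment of an entity whose segments map
#' to two or more distinct reference accessions (fusion constructs).
#'
#' @param segments combined segment table
#' @return the table with `chimera` updated
#' @export
flag_chimera <- function(segments) {
  segments <- data.table::as.data.table(segments)
  if (nrow(segments) == 0L) return(segments)
  segments[, chimera := length(unique(accession)) >= 2L,
           by = .(entry, entity)]
  segments
}

#' Residue-level one-to-one mapping
#'
#' Expands segments into one row per aligned chain residue. Unobserved
#' residues are mapped (`observed = FALSE`) because the mapping operates on
#' the sample sequence. `target_segment_id` is the 1-based index of the
#' segment within its chain (row order of the segment table); `residue_id`
#' is the 1-based label sequence position.
#'
#' @param segments segment table for one chain ([build_segments()])
#' @param chain the chain instance
#' @return data.table with the residue-table columns
#' @export
residue_mapping <- function(segments, chain) {
  segments <- data.table::as.data.table(segments)
  res <- chain$residues
  rows <- list()
  for (s in seq_len(nrow(segments))) {
    seg <- segments[s, ]
    qc <- strsplit(seg$query_alignment, "")[[1]]
    tc <- strsplit(seg$target_alignment, "")[[1]]
    qi <- ifelse(qc != "-", cumsum(qc != "-") + seg$query_start - 1L, NA)
    ti <- ifelse(tc != "-", cumsum(tc != "-") + seg$target_start - 1L, NA)
    aligned <- qc != "-" & tc != "-"
    qpos <- as.integer(qi[aligned]); tpos <- as.integer(ti[aligned])
    tlet <- tc[aligned]
    ridx <- match(qpos, res$label_seq_id)
    rows[[s]] <- data.table::data.table(
      entry = seg$entry, entity = seg$entity,
      auth_asym_id = seg$auth_asym_id, struct_asym_id = seg$struct_asym_id,
      target_segment_id = s,
      auth_seq_id = res$auth_seq_id[ridx],
      auth_seq_id_ins_code = res$ins_code[ridx],
      query_seq_id = qpos, target_seq_id = tpos,
      observed = res$observed[ridx],
      query_one_letter_code = res$one_letter[ridx],
      target_one_letter_code = tlet,
      chem_comp_id = res$chem_comp_id[ridx],
      type = ifelse(res$chem_comp_id[ridx] %in% names(AA3TO1),
                    "standard", "modified"),
      tax_id = seg$tax_id,
      best_mapping = seg$best_mapping,
      canonical_acc = seg$canonical_acc,
      residue_id = qpos)
  }
  out <- data.table::rbindlist(rows)
  if (nrow(out)) {
    dupe <- out[out$best_mapping, ]
    if (anyDuplicated(dupe$query_seq_id))
      consistency_error("residue mapping is not injective within best mapping")
  }
  out
}
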