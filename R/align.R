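#' Aligner parameters
#'
#' Parameters of the built-in local aligner used for residue-level mapping.
#' Defaults follow conventional protein-alignment practice: BLOSUM62 with an
#' affine gap penalty (a gap of length k costs `gap_open + k * gap_extend`),
#' up to `max_alignments` suboptimal non-overlapping alignments, and a raw
#' score floor of `min_score` below which alignments are not reported.
#'
#' @param gap_open gap opening penalty (positive number)
#' @param gap_extend per-residue gap extension penalty
#' @param max_alignments maximum number of declumped alignments to report
#' @param min_score minimum raw alignment score
#' @param submat substitution matrix (integer matrix with one-letter dimnames)
#' @return a list of class `alignment_params`
#' @export
alignment_params <- function(gap_open = 10L, gap_extend = 1L,
                             max_alignments = 10L, min_score = 40L,
                             submat = NULL) {
  stopifnot(gap_open > 0, gap_extend >= 0, max_alignments >= 1, min_score >= 0)
  structure(list(gap_open = as.integer(gap_open),
                 gap_extend = as.integer(gap_extend),
                 max_alignments = as.integer(max_alignments),
                 min_score = as.integer(min_score),
                 submat = submat %||% blosum62_matrix()),
            class = "alignment_params")
}

#' Multiple non-overlapping local alignments
#'
#' Smith-Waterman local alignment with Waterman-Eggert-style declumping:
#' after each alignment is reported, the query residues it consumed are
#' excluded and the dynamic programme is re-run, so the reported alignments
#' are mutually non-overlapping on the query. This mirrors how a structure
#' chain containing, e.g., a tandem duplication or a fusion construct is
#' mapped piecewise onto one or more reference sequences.
#'
#' @param query query (structure-chain) amino-acid sequence
#' @param target target (reference) amino-acid sequence
#' @param params an [alignment_params()] object
#' @return list of `local_alignment` objects, descending score; fields:
#'   `query_aligned`/`target_aligned` (equal-length gapped strings),
#'   1-based inclusive `query_start/end`, `target_start/end`, `score`,
#'   `identity` (identical columns / alignment length), `n_identical`,
#'   `n_mismatch`, `n_aligned`, `alignment_len`.
#' @export
local_alignments <- function(query, target, params = alignment_params()) {
  assert_aa_string(query, "query")
  assert_aa_string(target, "target")
  raw <- .cpp_sw_align(query, target, params$submat,
                       params$gap_open, params$gap_extend,
                       params$max_alignments, params$min_score)
  lapply(raw, function(a) {
    a$identity <- a$n_identical / a$alignment_len
    class(a) <- "local_alignment"
    a
  })
}

#' @export
print.local_alignment <- function(x, ...) {
  cat(sprintf("local alignment: score %d, identity %.3f\n q %5d %s %d\n t %5d %s %d\n",
              x$score, x$identity, x$query_start, x$query_aligned,
              x$query_end, x$target_start, x$target_aligned, x$target_end))
  invisible(x)
}
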