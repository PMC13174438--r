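# convenience: chain with straight-line geometry at given inter-residue
# C-N distances (default peptide bonds everywhere)
toy_chain <- function(seq, observed = NULL, breaks = list(), offset = 0L) {
  spec <- structure_spec(seq, observed = observed, breaks = breaks,
                         auth_offset = offset)
  parse_polymer_entities(make_toy_structure(spec))[[1]]$chains[[1]]
}

ref_rec <- function(acc = "P00001", tax = 9606L)
  list(accession = acc, name = "SYNTH", seq_version = 1L, tax_id = tax)

test_that("connectivity is a strict threshold on the C-N distance", {
  mk <- function(d) toy_chain("ACDEF", breaks = list(list(pos = 2, dist = d)))
  r <- function(ch, i) ch$residues[i, ]
  ch <- mk(4.0)
  expect_true(is_connected(r(ch, 1), r(ch, 2)))   # 1.33 bond
  expect_false(is_connected(r(ch, 2), r(ch, 3)))  # 4.0 break
  ch <- mk(1.42)
  expect_false(is_connected(r(ch, 2), r(ch, 3)))  # boundary is exclusive
  ch <- mk(1.4199)
  expect_true(is_connected(r(ch, 2), r(ch, 3)))
  # unobserved residue is never connected
  ch <- toy_chain("ACDEF", observed = c(TRUE, FALSE, TRUE, TRUE, TRUE))
  expect_false(is_connected(r(ch, 1), r(ch, 2)))
  expect_false(is_connected(r(ch, 2), r(ch, 3)))
})

test_that("connectivity transition recovered by bisection at the threshold", {
  connected_at <- function(d) {
    ch <- toy_chain("ACD", breaks = list(list(pos = 1, dist = d)))
    is_connected(ch$residues[1, ], ch$residues[2, ])
  }
  lo <- 1.0; hi <- 2.0
  expect_true(connected_at(lo)); expect_false(connected_at(hi))
  for (k in 1:40) {
    mid <- (lo + hi) / 2
    if (connected_at(mid)) lo <- mid else hi <- mid
  }
  expect_equal((lo + hi) / 2, 1.42, tolerance = 1e-7)
})

fake_aln <- function(qa, ta, qs = 1L, ts = 1L) {
  a <- list(query_aligned = qa, target_aligned = ta, query_start = qs,
            target_start = ts,
            query_end = qs + sum(strsplit(qa, "")[[1]] != "-") - 1L,
            target_end = ts + sum(strsplit(ta, "")[[1]] != "-") - 1L,
            score = 0L)
  cols <- strsplit(qa, "")[[1]] != "-" & strsplit(ta, "")[[1]] != "-"
  a$n_aligned <- sum(cols)
  a$alignment_len <- nchar(qa)
  a$n_identical <- sum(cols & strsplit(qa, "")[[1]] == strsplit(ta, "")[[1]])
  a$n_mismatch <- a$n_aligned - a$n_identical
  a$identity <- a$n_identical / a$alignment_len
  class(a) <- "local_alignment"
  a
}

test_that("run classification labels continuous, extended gaps and isolates", {
  # 12 aligned | 6-gap | 12 aligned
  a <- fake_aln(paste0(strrep("A", 12), strrep("-", 6), strrep("A", 12)),
                strrep("A", 30))
  r <- rle(classify_runs(a))
  expect_equal(r$values, c("continuous", "extended_gap", "continuous"))
  expect_equal(r$lengths, c(12L, 6L, 12L))

  # 10 aligned | 4 gaps | 1 aligned | 5 gaps | 10 aligned -> lone isolate
  a2 <- fake_aln(paste0(strrep("A", 10), strrep("-", 4), "G", strrep("-", 5),
                        strrep("A", 10)),
                 strrep("A", 30))
  r2 <- rle(classify_runs(a2))
  expect_equal(r2$values, c("continuous", "extended_gap", "isolated",
                            "extended_gap", "continuous"))

  # a 6-residue aligned run between extended gaps is continuous
  a3 <- fake_aln(paste0(strrep("A", 10), strrep("-", 3), strrep("A", 6),
                        strrep("-", 3), strrep("A", 10)),
                 strrep("A", 32))
  expect_false(any(classify_runs(a3) == "isolated"))

  # exactly 5 aligned residues: protected (conservative side of the rule)
  a4 <- fake_aln(paste0(strrep("A", 10), strrep("-", 3), strrep("A", 5),
                        strrep("-", 3), strrep("A", 10)),
                 strrep("A", 31))
  expect_false(any(classify_runs(a4) == "isolated"))

  # 4 aligned residues between extended gaps: isolated
  a5 <- fake_aln(paste0(strrep("A", 10), strrep("-", 3), strrep("A", 4),
                        strrep("-", 3), strrep("A", 10)),
                 strrep("A", 30))
  expect_true(any(classify_runs(a5) == "isolated"))

  # single-gap columns do not create extended gaps
  a6 <- fake_aln(paste0(strrep("A", 10), "-", strrep("A", 10)),
                 strrep("A", 21))
  expect_equal(unique(classify_runs(a6)), c("continuous", "gap"))
})

test_that("refinement un-aligns unobserved isolates into one contiguous gap", {
  f5 <- make_fig5_case(seed = 2)
  e <- parse_polymer_entities(f5$structure)[[1]]
  aln <- local_alignments(e$sample_sequence, f5$target)[[1]]
  expect_equal(sum(rle(classify_runs(aln))$values == "isolated"), 1L)
  out <- refine_alignment(aln, e$chains[[1]])
  expect_equal(out$audit$action, "unalign")
  labs <- classify_runs(out$alignment)
  expect_false(any(labs == "isolated"))
  # the unresolved region is one contiguous gap: exactly one gap run
  runs <- rle(labs %in% c("gap", "extended_gap"))
  expect_equal(sum(runs$values), 1L)
})

test_that("refinement merges isolates that are backbone-connected", {
  # chain is fully connected; force an isolated 2-residue run adjacent to
  # the preceding continuous region
  ch <- toy_chain(strrep("A", 30))
  # columns: 10 aligned | 2-col target insertion | 2 aligned (query 11:12)
  # | 2-col target insertion | 10 aligned; the 2-residue run is isolated
  a <- fake_aln(paste0(strrep("A", 10), "--", "AA", "--", strrep("A", 10)),
                strrep("A", 26))
  expect_equal(sum(rle(classify_runs(a))$values == "isolated"), 1L)
  out <- refine_alignment(a, ch)
  expect_equal(out$audit$action, "merge")
  expect_equal(out$alignment$query_aligned, a$query_aligned)

  # same pattern but with the isolated residues unobserved -> unalign
  ch2 <- toy_chain(strrep("A", 30),
                   observed = c(rep(TRUE, 10), FALSE, FALSE, rep(TRUE, 18)))
  out2 <- refine_alignment(a, ch2)
  expect_equal(out2$audit$action, "unalign")
})

test_that("refinement is idempotent and never touches continuous columns", {
  f5 <- make_fig5_case(seed = 3)
  e <- parse_polymer_entities(f5$structure)[[1]]
  aln <- local_alignments(e$sample_sequence, f5$target)[[1]]
  once <- refine_alignment(aln, e$chains[[1]])$alignment
  twice <- refine_alignment(once, e$chains[[1]])$alignment
  expect_equal(twice$query_aligned, once$query_aligned)
  expect_equal(twice$target_aligned, once$target_aligned)
  # continuous columns in the original survive verbatim
  labs <- classify_runs(aln)
  orig <- alignment_pairs(aln)
  ref <- alignment_pairs(once)
  keep <- orig[labs[orig$col] == "continuous", ]
  expect_true(all(paste(keep$qi, keep$ti) %in% paste(ref$qi, ref$ti)))

  # alignment without extended gaps is returned unchanged
  plain <- local_alignments(e$sample_sequence, e$sample_sequence)[[1]]
  out <- refine_alignment(plain, e$chains[[1]])
  expect_equal(out$alignment$query_aligned, plain$query_aligned)
  expect_equal(nrow(out$audit), 0L)
})

test_that("segments split at physical chain breaks", {
  ch <- toy_chain(strrep("A", 20), breaks = list(list(pos = 10, dist = 4.0)))
  aln <- local_alignments(strrep("A", 20), strrep("A", 20))[[1]]
  segs <- build_segments(ch, list(aln), list(best = TRUE), ref_rec(),
                         entry = "tst1", entity = "1")
  expect_equal(nrow(segs), 2L)
  expect_equal(segs$query_start, c(1L, 11L))
  expect_equal(segs$query_end, c(10L, 20L))
  # fully connected chain stays one segment
  ch2 <- toy_chain(strrep("A", 20))
  segs2 <- build_segments(ch2, list(aln), list(best = TRUE), ref_rec(),
                          entry = "tst1", entity = "1")
  expect_equal(nrow(segs2), 1L)
  expect_equal(segs2$query_start, 1L)
})

test_that("two accessions on one entity are flagged chimeric", {
  ch <- toy_chain(strrep("A", 10))
  aln <- local_alignments(strrep("A", 10), strrep("A", 10))[[1]]
  s1 <- build_segments(ch, list(aln), list(best = TRUE), ref_rec("P1"),
                       entry = "e", entity = "1")
  s2 <- build_segments(ch, list(aln), list(best = FALSE), ref_rec("P2"),
                       entry = "e", entity = "1")
  both <- flag_chimera(rbind(s1, s2))
  expect_true(all(both$chimera))
  expect_false(any(flag_chimera(s1)$chimera))
})

test_that("residue mapping carries numbering offsets and observed flags", {
  # author numbering offset +115: structure residue label 1 = auth 116;
  # reference alignment offset +1 reproduces the classic off-by-one case
  ch <- toy_chain("DKLMN", offset = 115L)
  aln <- local_alignments("DKLMN", "ADKLMN",
                          alignment_params(min_score = 5L))[[1]]
  segs <- build_segments(ch, list(aln), list(best = TRUE), ref_rec("P29XXX"),
                         entry = "tst1", entity = "1")
  res <- residue_mapping(segs, ch)
  expect_equal(nrow(res), 5L)
  expect_equal(res$target_seq_id, res$query_seq_id + 1L)
  expect_equal(res$auth_seq_id, res$query_seq_id + 115L)
  expect_equal(res$auth_seq_id[1], 116L)
  expect_equal(res$target_seq_id[1], 2L)

  # identity mapping
  aln2 <- local_alignments("DKLMN", "DKLMN",
                           alignment_params(min_score = 5L))[[1]]
  segs2 <- build_segments(ch, list(aln2), list(best = TRUE), ref_rec(),
                          entry = "tst1", entity = "1")
  res2 <- residue_mapping(segs2, ch)
  expect_equal(res2$query_seq_id, res2$target_seq_id)

  # unobserved loop rows are present, observed = FALSE
  ch3 <- toy_chain("DKLMNPQRS", observed = c(rep(TRUE, 3), rep(FALSE, 3),
                                             rep(TRUE, 3)))
  aln3 <- local_alignments("DKLMNPQRS", "DKLMNPQRS")[[1]]
  segs3 <- build_segments(ch3, list(aln3), list(best = TRUE), ref_rec(),
                          entry = "tst1", entity = "1")
  res3 <- residue_mapping(segs3, ch3)
  expect_equal(nrow(res3), 9L)
  expect_equal(res3$observed, c(rep(TRUE, 3), rep(FALSE, 3), rep(TRUE, 3)))
})

test_that("residue rows sit inside exactly one segment range", {
  f5 <- make_fig5_case(seed = 4)
  e <- parse_polymer_entities(f5$structure)[[1]]
  ch <- e$chains[[1]]
  aln <- refine_alignment(local_alignments(e$sample_sequence, f5$target)[[1]],
                          ch)$alignment
  segs <- build_segments(ch, list(aln), list(best = TRUE), ref_rec(),
                         entry = "f", entity = "1")
  res <- residue_mapping(segs, ch)
  for (i in seq_len(nrow(res))) {
    inside <- which(res$query_seq_id[i] >= segs$query_start &
                      res$query_seq_id[i] <= segs$query_end)
    expect_length(inside, 1L)
    expect_equal(inside, res$target_segment_id[i])
  }
  expect_false(anyDuplicated(res$query_seq_id) > 0)
  expect_false(anyDuplicated(res$target_seq_id) > 0)
})

test_that("overlapping refined alignments are rejected", {
  ch <- toy_chain(strrep("A", 10))
  a1 <- local_alignments(strrep("A", 10), strrep("A", 10))[[1]]
  expect_error(build_segments(ch, list(a1, a1), list(best = TRUE), ref_rec(),
                              entry = "e", entity = "1"),
               class = "siftsmapper_consistency_error")
})
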