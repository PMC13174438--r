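test_that("toy structure with all residues observed parses as specified", {
  txt <- make_toy_structure(structure_spec("ACD"))
  ents <- parse_polymer_entities(txt)
  expect_length(ents, 1L)
  e <- ents[[1]]
  expect_equal(e$sample_sequence, "ACD")
  res <- e$chains[[1]]$residues
  expect_equal(nrow(res), 3L)
  expect_true(all(res$observed))
  expect_equal(res$chem_comp_id, c("ALA", "CYS", "ASP"))
})

test_that("unobserved residues stay in the residue list with observed=FALSE", {
  spec <- structure_spec("ACDEFGHIK",
                         observed = c(rep(TRUE, 3), rep(FALSE, 3), rep(TRUE, 3)))
  e <- parse_polymer_entities(make_toy_structure(spec))[[1]]
  res <- e$chains[[1]]$residues
  expect_equal(nrow(res), 9L)
  expect_equal(which(!res$observed), 4:6)
  expect_true(all(is.na(res$n_x[4:6])))
  expect_equal(nchar(e$sample_sequence), 9L)
})

test_that("modified residue resolves its one-letter code via the CCD parent", {
  ccd <- read_ccd(make_toy_ccd())
  spec <- structure_spec("AMC", modified = list(list(pos = 2, comp = "MSE")))
  e <- parse_polymer_entities(make_toy_structure(spec), ccd = ccd)[[1]]
  res <- e$chains[[1]]$residues
  expect_equal(res$chem_comp_id[2], "MSE")
  expect_equal(res$one_letter[2], "M")
  # without a CCD the modified residue falls back to X (with a backbone
  # atom warning for the unknown component)
  expect_warning(
    e2 <- parse_polymer_entities(make_toy_structure(spec))[[1]],
    "not in CCD")
  expect_equal(e2$chains[[1]]$residues$one_letter[2], "X")
})

test_that("gzip input is detected by magic bytes regardless of extension", {
  txt <- make_toy_structure(structure_spec("ACDEF"))
  f <- tempfile(fileext = ".cif")  # gz content behind a non-gz name
  con <- gzfile(f, "wt")
  writeLines(txt, con)
  close(con)
  e <- parse_polymer_entities(f)
  expect_equal(e[[1]]$sample_sequence, "ACDEF")
})

test_that("parse errors and no-polymer errors are distinct", {
  expect_error(read_mmcif("data_x\nloop_\n_a.b\n_a.c\nv1\n"),
               class = "mmcif_parse_error")
  expect_error(parse_polymer_entities("data_x\n_entry.id X\n"),
               class = "siftsmapper_no_polymer")
})

test_that("mmCIF writer round-trips quoting, loops and text fields", {
  x <- read_mmcif(paste(
    "data_demo",
    "_one.a 'two words'",
    "_one.b ?",
    "loop_", "_tab.x", "_tab.y",
    "1 'a b'", "2 .", sep = "\n"))
  f <- tempfile(fileext = ".cif")
  write_mmcif(x, f)
  y <- read_mmcif(f)
  expect_equal(y$categories, x$categories)
  expect_equal(y$block, x$block)
})

test_that("write_fasta writes full-length sample sequences per entity", {
  spec1 <- structure_spec("ACDEFGHIK", observed = c(rep(TRUE, 3), rep(FALSE, 3),
                                                    rep(TRUE, 3)),
                          entry_id = "aaa1")
  spec2 <- structure_spec("MKTAYIAK", entry_id = "bbb2")
  ents <- c(parse_polymer_entities(make_toy_structure(spec1)),
            parse_polymer_entities(make_toy_structure(spec2)))
  f <- tempfile(fileext = ".fasta")
  expect_equal(write_fasta(ents, f), 2L)
  back <- Biostrings::readAAStringSet(f)
  expect_equal(length(back), 2L)
  expect_equal(names(back), c("pdb|aaa1|1", "pdb|bbb2|1"))
  # unobserved loop letters are present
  expect_equal(as.character(back[[1]]), "ACDEFGHIK")
})

test_that("SIFTS annotation writer populates both categories and atom_site", {
  rs_seq <- "MKTAYIAKQRQISFVKSHFSRQ"
  spec <- structure_spec(rs_seq, entry_id = "tst9", auth_offset = 0L,
                         tax_id = 9606L)
  txt <- make_toy_structure(spec)
  e <- parse_polymer_entities(txt)[[1]]
  ref <- list(accession = "P12345", name = "TEST_HUMAN", seq_version = 1L,
              tax_id = 9606L)
  # identity mapping shifted by +1 on the reference numbering
  target <- paste0("A", rs_seq)
  aln <- local_alignments(rs_seq, target)[[1]]
  hit <- list(best = TRUE, hit_rank = 1L)
  segs <- build_segments(e$chains[[1]], list(aln), hit, ref,
                         entry = "tst9", entity = "1")
  res <- residue_mapping(segs, e$chains[[1]])
  out <- tempfile(fileext = ".cif")
  write_sifts_annotations(txt, segs, res, out)
  y <- read_mmcif(out)
  expect_equal(nrow(y$categories$pdbx_sifts_unp_segments), nrow(segs))
  expect_equal(nrow(y$categories$pdbx_sifts_xref_db), nrow(res))
  # +1 numbering offset: atom rows of residue n carry reference number n+1
  at <- y$categories$atom_site
  expect_equal(as.integer(at$pdbx_sifts_xref_db_num),
               as.integer(at$label_seq_id) + 1L)
  expect_true(all(at$pdbx_sifts_xref_db_acc == "P12345"))
  # round-trip preserves entity count, sequence and numbering
  e2 <- parse_polymer_entities(out)
  expect_length(e2, 1L)
  expect_equal(e2[[1]]$sample_sequence, e$sample_sequence)
  expect_equal(e2[[1]]$chains[[1]]$residues$auth_seq_id,
               e$chains[[1]]$residues$auth_seq_id)
})

test_that("annotation writer rejects unknown entities and empty mappings", {
  txt <- make_toy_structure(structure_spec("ACDEF", entry_id = "tst8"))
  e <- parse_polymer_entities(txt)[[1]]
  ref <- list(accession = "P1", name = "N", seq_version = 1L, tax_id = NA)
  aln <- local_alignments("ACDEF", "ACDEF",
                          alignment_params(min_score = 5L))[[1]]
  segs <- build_segments(e$chains[[1]], list(aln), list(best = TRUE), ref,
                         entry = "tst8", entity = "1")
  res <- residue_mapping(segs, e$chains[[1]])
  out <- tempfile(fileext = ".cif")
  bad <- data.table::copy(segs)
  bad$entity <- "99"
  expect_error(write_sifts_annotations(txt, bad, res, out),
               class = "siftsmapper_consistency_error")
  expect_error(write_sifts_annotations(txt, segs, res[0, ], out), "empty")
  expect_false(file.exists(out))
})

test_that("CCD backbone atoms come from the dictionary, else fall back", {
  ccd <- read_ccd(make_toy_ccd())
  expect_equal(resolve_backbone_atoms("ALA"), c("N", "C"))
  expect_equal(resolve_backbone_atoms("MSE", ccd), c("N", "C"))
  expect_warning(got <- resolve_backbone_atoms("ZZZ"), "not in CCD")
  expect_equal(got, c("N", "C"))
})
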