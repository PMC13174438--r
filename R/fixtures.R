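# Synthetic fixtures: toy structures, reference sets and edge-case
# alignment scenarios, so the full pipeline is testable without any
# download. Coordinates are idealised extended-chain geometry -- the only
# geometric property the pipeline reads is the C(i)-N(i+1) distance, which
# is 1.33 A (a typical peptide bond) everywhere except at declared breaks.

PEPTIDE_BOND <- 1.33
CA_C_SPAN <- 2.47  # intra-residue N -> C distance along the chain axis

#' Specification of a synthetic structure
#'
#' @param sequence canonical one-letter sample sequence
#' @param observed logical mask, one per residue (default all observed)
#' @param auth_offset added to label numbering to form author numbering
#' @param breaks list of `list(pos =, dist =)`: the C(pos)-N(pos+1)
#'   distance is set to `dist` angstroms instead of 1.33
#' @param modified list of `list(pos =, comp =)`: residue `pos` gets the
#'   given chemical component id (e.g. "MSE") instead of the standard one
#' @param entry_id,chain_id identifiers
#' @param tax_id source-organism taxid written into the file (NA omits)
#' @param seed retained for the generator contract (geometry is
#'   deterministic regardless)
#' @return a `structure_spec`
#' @export
structure_spec <- function(sequence, observed = NULL, auth_offset = 0L,
                           breaks = list(), modified = list(),
                           entry_id = "tst1", chain_id = "A",
                           tax_id = NA_integer_, seed = 1L) {
  assert_aa_string(sequence, "sequence")
  L <- nchar(sequence)
  if (is.null(observed)) observed <- rep(TRUE, L)
  stopifnot(length(observed) == L)
  for (b in breaks)
    if (b$pos < 1L || b$pos >= L)
      stop("break position outside sequence", call. = FALSE)
  for (m in modified)
    if (m$pos < 1L || m$pos > L)
      stop("modified position outside sequence", call. = FALSE)
  structure(list(sequence = sequence, observed = observed,
                 auth_offset = as.integer(auth_offset), breaks = breaks,
                 modified = modified, entry_id = entry_id,
                 chain_id = chain_id, tax_id = tax_id, seed = seed),
            class = "structure_spec")
}

#' Generate a toy mmCIF structure
#'
#' Extended-chain geometry with consecutive C-N distances of 1.33 A except
#' at declared breaks; unobserved residues appear in the sequence
#' categories but have no atom rows. Deterministic: same spec, same bytes.
#'
#' @param spec a [structure_spec()]
#' @return mmCIF text (single string)
#' @export
make_toy_structure <- function(spec) {
  stopifnot(inherits(spec, "structure_spec"))
  letters1 <- strsplit(spec$sequence, "")[[1]]
  L <- length(letters1)
  comp <- unname(ifelse(letters1 %in% names(AA1TO3), AA1TO3[letters1], "UNK"))
  for (m in spec$modified) comp[m$pos] <- toupper(m$comp)

  gap_after <- rep(PEPTIDE_BOND, L - 1L)
  for (b in spec$breaks) gap_after[b$pos] <- b$dist
  n_x <- numeric(L); c_x <- numeric(L)
  x <- 0
  for (i in seq_len(L)) {
    n_x[i] <- x
    c_x[i] <- x + CA_C_SPAN
    if (i < L) x <- c_x[i] + gap_after[i]
  }

  cats <- list()
  cats$entry <- data.frame(id = toupper(spec$entry_id))
  src <- if (!is.na(spec$tax_id))
    data.frame(entity_id = "1",
               pdbx_gene_src_ncbi_taxonomy_id = as.character(spec$tax_id))
  else NULL
  cats$entity_poly <- data.frame(
    entity_id = "1", type = "polypeptide(L)",
    pdbx_seq_one_letter_code_can = spec$sequence,
    pdbx_strand_id = spec$chain_id, stringsAsFactors = FALSE)
  if (!is.null(src)) cats$entity_src_gen <- src
  cats$entity_poly_seq <- data.frame(
    entity_id = "1", num = as.character(seq_len(L)), mon_id = comp,
    stringsAsFactors = FALSE)
  cats$pdbx_poly_seq_scheme <- data.frame(
    asym_id = spec$chain_id, entity_id = "1",
    seq_id = as.character(seq_len(L)), mon_id = comp,
    pdb_seq_num = as.character(seq_len(L) + spec$auth_offset),
    pdb_ins_code = NA_character_, pdb_strand_id = spec$chain_id,
    stringsAsFactors = FALSE)

  obs <- which(spec$observed)
  if (length(obs)) {
    rows <- list()
    aid <- 0L
    for (i in obs) {
      for (atom in c("N", "C")) {
        aid <- aid + 1L
        rows[[aid]] <- data.frame(
          group_PDB = "ATOM", id = as.character(aid), type_symbol = atom,
          label_atom_id = atom, label_comp_id = comp[i],
          label_asym_id = spec$chain_id, label_entity_id = "1",
          label_seq_id = as.character(i),
          Cartn_x = sprintf("%.9f", if (atom == "N") n_x[i] else c_x[i]),
          Cartn_y = "0.000", Cartn_z = "0.000",
          auth_seq_id = as.character(i + spec$auth_offset),
          auth_asym_id = spec$chain_id, pdbx_PDB_model_num = "1",
          stringsAsFactors = FALSE)
      }
    }
    cats$atom_site <- do.call(rbind, rows)
  }
  x <- structure(list(block = toupper(spec$entry_id), categories = cats),
                 class = "mmcif")
  paste(format_mmcif_lines(x), collapse = "\n")
}

#' Synthetic CCD components text
#'
#' Minimal components file covering the standard amino acids named plus
#' common modified residues (MSE with parent MET by default), with
#' backbone atoms flagged the way the real dictionary does.
#'
#' @param extra named list: component id -> list(parent =, one_letter =)
#' @return CCD text (mmCIF dialect, one data block per component)
#' @export
make_toy_ccd <- function(extra = list(MSE = list(parent = "MET",
                                                 one_letter = NA))) {
  blocks <- character(0)
  emit <- function(id, parent, one_letter, n_atom = "N", c_atom = "C") {
    c(sprintf("data_%s", id),
      sprintf("_chem_comp.id %s", id),
      sprintf("_chem_comp.mon_nstd_parent_comp_id %s",
              if (is.na(parent)) "?" else parent),
      sprintf("_chem_comp.one_letter_code %s",
              if (is.na(one_letter)) "?" else one_letter),
      "loop_",
      "_chem_comp_atom.comp_id",
      "_chem_comp_atom.atom_id",
      "_chem_comp_atom.type_symbol",
      "_chem_comp_atom.pdbx_backbone_atom_flag",
      sprintf("%s %s N Y", id, n_atom),
      sprintf("%s CA C Y", id),
      sprintf("%s %s C Y", id, c_atom),
      sprintf("%s O O Y", id),
      "#")
  }
  for (id in names(AA3TO1))
    blocks <- c(blocks, emit(id, NA, AA3TO1[[id]]))
  for (id in names(extra))
    blocks <- c(blocks, emit(toupper(id), extra[[id]]$parent %||% NA,
                             extra[[id]]$one_letter %||% NA))
  paste(blocks, collapse = "\n")
}

#' Built-in demonstration lineage table
#'
#' Real NCBI taxids for a handful of taxa with controlled relationships:
#' human (9606) / chimpanzee (9598) / bonobo (9597) share family Hominidae
#' and order Primates; chimpanzee and bonobo share genus Pan; rhesus
#' macaque (9544) shares only order Primates with the apes; mouse (10090)
#' shares no scored rank; Escherichia coli (562) is unrelated.
#'
#' @return lineage data.table (see [read_lineage_tsv()])
#' @export
demo_lineages <- function() {
  data.table::data.table(
    tax_id        = c(9606L, 9598L, 9597L, 9544L, 10090L, 562L),
    species_taxid = c(9606L, 9598L, 9597L, 9544L, 10090L, 562L),
    genus_taxid   = c(9605L, 9596L, 9596L, 9539L, 10088L, 561L),
    family_taxid  = c(9604L, 9604L, 9604L, 9528L, 10066L, 543L),
    order_taxid   = c(9443L, 9443L, 9443L, 9443L, 9989L, 91347L))
}

random_aa <- function(n, rng) {
  std <- setdiff(AA_LETTERS, "X")
  paste(std[floor(rng(n) * length(std)) + 1L], collapse = "")
}

#' Generate a synthetic reference set
#'
#' Records are mutated copies of one base sequence, so the identity of each
#' record to the base is controlled (to bracket the 0.9 search cutoff).
#' Mutations are substitutions placed uniformly without replacement; no
#' indels. Headers mix `sp|` and `tr|` conventions.
#'
#' @param n number of records
#' @param base_length length of the base sequence
#' @param mutation_rates per-record substitution fraction (recycled)
#' @param datasets per-record "reviewed"/"unreviewed"/"other" (recycled)
#' @param taxids per-record NCBI taxids (recycled); see [demo_lineages()]
#' @param annotation_scores,xref_counts per-record metadata (recycled)
#' @param dir directory to write into
#' @param seed RNG seed (deterministic outputs)
#' @return list of file paths plus the base sequence and the record table
#' @export
make_reference_set <- function(n, base_length = 120L, mutation_rates = 0,
                               datasets = "reviewed", taxids = 9606L,
                               annotation_scores = 5L, xref_counts = 0L,
                               dir = tempfile("refset"), seed = 1L) {
  stopifnot(n >= 1L)
  set.seed(seed)
  rng <- function(k) stats::runif(k)
  base <- random_aa(base_length, rng)
  std <- setdiff(AA_LETTERS, "X")
  rates <- rep_len(mutation_rates, n)
  ds <- rep_len(datasets, n)
  tx <- rep_len(as.integer(taxids), n)
  ann <- rep_len(as.integer(annotation_scores), n)
  xr <- rep_len(as.integer(xref_counts), n)
  recs <- list()
  for (i in seq_len(n)) {
    chars <- strsplit(base, "")[[1]]
    nmut <- round(rates[i] * base_length)
    if (nmut > 0) {
      pos <- sample.int(base_length, nmut)
      for (p in pos) {
        alt <- setdiff(std, chars[p])
        chars[p] <- alt[sample.int(length(alt), 1L)]
      }
    }
    acc <- sprintf("Q%05d", i)
    prefix <- switch(ds[i], reviewed = "sp", unreviewed = "tr", other = NULL)
    header <- if (is.null(prefix)) acc
    else sprintf("%s|%s|%s_SYNTH OS=synthetic OX=%d SV=1", prefix, acc, acc, tx[i])
    recs[[i]] <- list(accession = acc, header = header,
                      sequence = paste(chars, collapse = ""),
                      dataset = ds[i], tax_id = tx[i],
                      annotation_score = ann[i], xref_count = xr[i],
                      mutation_rate = rates[i])
  }
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  fasta <- file.path(dir, "refs.fasta")
  writeLines(unlist(lapply(recs, function(r)
    c(paste0(">", r$header), r$sequence))), fasta)
  tab <- function(fname, values)
    writeLines(sprintf("%s\t%s", vapply(recs, `[[`, character(1), "accession"),
                       values), file.path(dir, fname))
  tab("taxonomy.tsv", vapply(recs, `[[`, integer(1), "tax_id"))
  tab("annotation.tsv", vapply(recs, `[[`, integer(1), "annotation_score"))
  tab("xref.tsv", vapply(recs, `[[`, integer(1), "xref_count"))
  lin <- file.path(dir, "lineage.tsv")
  data.table::fwrite(demo_lineages(), lin, sep = "\t")
  list(fasta = fasta,
       taxonomy_tsv = file.path(dir, "taxonomy.tsv"),
       annotation_tsv = file.path(dir, "annotation.tsv"),
       xref_tsv = file.path(dir, "xref.tsv"),
       lineage_tsv = lin,
       base_sequence = base,
       records = data.table::rbindlist(lapply(recs, function(r)
         r[c("accession", "sequence", "dataset", "tax_id",
             "annotation_score", "xref_count", "mutation_rate")])))
}

#' Generate an isolated-residue refinement scenario
#'
#' Builds a structure chain with an internal unobserved residue and a
#' reference carrying an insertion around it, arranged so the naive
#' optimal local alignment places that single residue as an isolated match
#' inside an extended gap (verified against the aligner at build time).
#' Connectivity refinement must un-align it, leaving one contiguous
#' unmapped block. Ground truth for the refined mapping is attached.
#'
#' @param seed RNG seed; the structural property holds for any seed
#' @param flank flank length on either side
#' @param insert_len reference insertion length (odd, >= 5). With the
#'   default aligner the isolated residue must out-score an extra gap
#'   opening, so the scenario plants a tryptophan (the strongest-scoring
#'   match under BLOSUM62) in the centre of a short insertion -- the same
#'   artefact shape as a lone glycine aligned inside an unobserved loop.
#' @return list(structure = mmCIF text, spec, reference_fasta = FASTA
#'   text, query, target, ground_truth)
#' @export
make_fig5_case <- function(seed = 1L, flank = 25L, insert_len = 5L) {
  stopifnot(insert_len >= 5L, insert_len %% 2L == 1L)
  aln_par <- alignment_params()
  for (attempt in seq_len(60L)) {
    set.seed(seed * 1000L + attempt)
    rng <- function(k) stats::runif(k)
    std <- setdiff(AA_LETTERS, c("X", "W"))
    rnd <- function(n) paste(std[floor(stats::runif(n) * length(std)) + 1L],
                             collapse = "")
    left <- rnd(flank); right <- rnd(flank)
    half <- (insert_len - 1L) %/% 2L
    insert <- paste0(rnd(half), "W", rnd(half))
    query <- paste0(left, "W", right)
    target <- paste0(left, insert, right)
    alns <- local_alignments(query, target, aln_par)
    if (!length(alns)) next
    labels <- classify_runs(alns[[1]])
    runs <- rle(labels)
    iso <- sum(runs$values == "isolated")
    if (iso != 1L) next
    spec <- structure_spec(query,
                           observed = c(rep(TRUE, flank), FALSE,
                                        rep(TRUE, flank)),
                           entry_id = "fg5c", tax_id = 9606L,
                           seed = seed)
    gt <- data.table::data.table(
      query_seq_id = c(seq_len(flank), flank + 1L + seq_len(flank)),
      target_seq_id = c(seq_len(flank), flank + insert_len + seq_len(flank)))
    return(list(structure = make_toy_structure(spec), spec = spec,
                reference_fasta = paste0(">sp|P99999|FIG5_SYNTH OS=synthetic OX=9606 SV=1\n",
                                         target),
                query = query, target = target, ground_truth = gt))
  }
  stop("could not construct the refinement scenario after 60 attempts",
       call. = FALSE)
}
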