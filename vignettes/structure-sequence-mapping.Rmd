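---
title: "Mapping protein structures to reference sequences: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Mapping protein structures to reference sequences}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(siftsmapper)
```

## The problem

Every protein chain deposited in a structural archive was expressed from
some construct, and that construct usually corresponds to a record in a
reference sequence knowledgebase (UniProtKB or a custom set). Establishing
which record, and then which reference residue each structure residue
corresponds to, is the basis for transferring functional annotations,
variants and domain definitions onto 3D coordinates, and for giving all
structures of one protein a common residue numbering. `siftsmapper`
implements this structure-to-sequence cross-referencing as a library plus a
six-subcommand CLI (`build_db`, `fasta_build`, `sequence_match`,
`segments`, `db_load`, `sifts2mmcif`), producing SIFTS-annotated
PDBx/mmCIF, ranked-hit tables, and per-entry segment/residue mapping CSVs.

Two features distinguish the approach from plain pairwise alignment:

1. **A bounded, interpretable composite score** for choosing the reference
   record, combining sequence similarity with taxonomy agreement and
   dataset provenance.
2. **Backbone-connectivity refinement** of the residue-level alignment,
   which removes physically implausible isolated matches that local
   aligners place inside long gaps.

## The scoring model

For a candidate hit with coverage $c$ (fraction of the chain's sample
sequence aligned), identity $p$ (fraction of aligned residues identical),
$m$ mismatches and query length $L$:

$$\mathrm{Base} = c \cdot p \cdot 1000, \qquad
  \mathrm{Penalty} = 1 - m/L, \qquad
  \mathrm{Adjusted} = \mathrm{Base}\cdot\mathrm{Penalty}$$

$$\mathrm{Score} = \mathrm{Adjusted} + \mathrm{Tax} + \mathrm{Prov}
  \;\in\; [-50,\, 1300]$$

- **Taxonomy** adds +200 for an exact species match, and +100 / +50 / +25
  when the lowest shared rank of query and target organism is genus,
  family or order (one, two or three rank levels up to the most recent
  common ancestor). Deeper shared ranks (class and above) add nothing: the
  SIFTS taxonomy ladder enumerates only these four ranks, and we implement
  exactly those rather than a generic lowest-common-ancestor walk.
- **Provenance** adds $20 \times A$ for reviewed (curated) records and
  $-50 + 10 \times A$ for unreviewed ones, where $A \in [0,5]$ is the
  entry's annotation score; non-UniProtKB sets contribute 0. We treat a
  missing annotation score as 0 ("unknown"), which makes the −50 minimum
  reachable and treats unknown entries as least trusted.
- **Tie-breaking**: hits are ordered by score, then by the number of PDB
  cross-references of the accession (so repeated structures of one protein
  map consistently to the well-established accession), then by accession
  lexicographically. The third key is ours: the SIFTS ordering has two
  keys, but a reproducible pipeline needs a total order. The
  cross-reference count deliberately never enters the score itself, which
  keeps scores bounded and comparable.

A 90% sequence-identity cutoff is applied at search time (it accounts for
engineered mutations and construct differences while excluding paralogs).
We apply it inside `search_reference()` / `parse_search_tsv()`; rows from
external search tools that fail it are flagged, not dropped, so the
decision is auditable.

```{r score-example}
lin <- demo_lineages()
hit <- list(coverage = 0.9, identity = 0.95, mismatch = 5, query_len = 100,
            query_tax_id = 9598, target_tax_id = 9597)
ref <- list(dataset = "reviewed", annotation_score = 3, pdb_xref_count = 12)
sifts_score(hit, lin, ref)$sifts_score  # 855 * 0.95 + 100 + 60
```

## Search

The built-in backend is an exhaustive Smith–Waterman search of the query
against every record, with BLOSUM62, gap open 11, gap extension 1 (standard
protein-search defaults), bit scores from gapped Karlin–Altschul constants
($\lambda = 0.267$, $K = 0.041$) and e-values against the database residue
count. This backend is exact and is validated against an independent
quadratic dynamic-programming oracle in the test suite; for large reference
sets the intended route is a fast external search tool whose tabular output
enters through `parse_search_tsv()` (the adapter never shells out in the
tests). A gapless prefilter is a pass-through concern of the external tool,
not reimplemented here.

## Residue-level mapping

The chain's *sample sequence* (from `_entity_poly`, independent of which
residues were observed) is aligned to the chosen reference with the
built-in aligner in Waterman–Eggert mode: after each reported alignment the
query residues it consumed are excluded and the search repeats, so the
suboptimal alignments are mutually non-overlapping on the query (defaults:
BLOSUM62, gap open 10, extension 1, at most 10 alignments, minimum score
40 — the upstream SIFTS pipeline delegates to `lalign36` without stating its
parameters, so we chose conventional ones and made them configurable).

### Connectivity refinement

Local aligners sometimes place a short isolated match inside a long gap
(classically, a lone glycine "aligned" inside an unobserved loop).
Columns are classified into **continuous** aligned runs, **extended gaps**
(more than one consecutive gap column), and **isolated** runs (fewer than
5 aligned residues bounded by extended gaps on both sides). Runs of exactly
5 are protected: the SIFTS rule is "< 5" for isolation and "more than
five" for protection, leaving 5 ambiguous, and we resolve it to the
conservative, no-refinement side. Runs touching the alignment boundary are
never isolated.

Each isolated run is then tested against the experimentally observed
backbone: two consecutive residues are *connected* when the distance from
the backbone C atom of the first to the backbone N atom of the second is
strictly below 1.42 Å (a tolerance around the ~1.33 Å peptide bond; atom
names come from the CCD when one is supplied, with an `N`/`C` fallback for
standard residues). A connected isolated run is merged into the adjacent
continuous region (when connected to both, into the preceding one — a
deterministic, documented choice); a disconnected one — in particular an
unobserved one — is un-aligned, and the whole region is rewritten as one
contiguous gap. Mismatched (conflict) columns are never touched: only gap
structure is refined. The operation is total and idempotent.

Numerical note: distances are rounded to $10^{-9}$ Å before the strict
comparison so that the threshold is not blurred by floating-point round-off
in coordinate arithmetic; the boundary-recovery property test bisects the
transition to within $10^{-7}$ Å of 1.42.

### Segments and residues

Segments are maximal runs of aligned residues sharing one accession and
taxon whose consecutive observed residues pass the connectivity check;
they split at observed chain breaks and at extended gaps, while single-gap
columns may remain inside a segment. Pairs involving an unobserved residue
cannot be assessed and do not split the segment — otherwise every
unobserved loop would fragment its chain's mapping. Unobserved residues
are mapped (`observed = FALSE`) because mapping operates on the sample
sequence. `target_segment_id` in the residue table is the 1-based row
index of the segment within its chain, which is also how the two CSVs
reference each other (the SIFTS table schemas carry no explicit segment id
column). The residue `type` column distinguishes `standard` from
`modified` components. Entities whose segments map to two or more
accessions are flagged `chimera` (fusion constructs); the pipeline admits
lower-ranked accessions only for query stretches of at least 20 residues
that the rank-1 hit left unclaimed.

### mmCIF output

`write_sifts_annotations()` populates `_pdbx_sifts_unp_segments` and
`_pdbx_sifts_xref_db` and extends `_atom_site` with the
`pdbx_sifts_xref_db_name` / `_acc` / `_num` / `_res` items of the current
PDBx/mmCIF dictionary — the SIFTS category description does not name the
atom-site items, so we use the dictionary's SIFTS items and document that
choice here. The writer re-parses its own output as a round-trip check.

## Storage

Per-entry outputs are two gzip CSVs (RFC 4180, UTF-8, headers, lowercase
`true`/`false`, empty string for missing) and bulk-load transactionally
into a single-file store with three tables (`hits`,
`sifts_xref_segment`, `sifts_xref_residue`); hits live only in the store.
Re-loading an entry replaces its rows (weekly-regeneration semantics). No
embedded SQL engine is available in the supported environment, so the
store is a serialized table set written atomically (temp file + rename);
the contract — transactional load, dedup keys, single-scan best-mapping
queries — is unchanged, and swapping in an embedded columnar database
would be a drop-in change behind the same functions.

## The synthetic world

All tests run without downloads on generated fixtures:

- `make_toy_structure()` builds extended-chain mmCIF in which the only
  geometric property the pipeline reads — consecutive C–N distances — is
  1.33 Å everywhere except at declared breaks. No sidechains, no physical
  realism beyond the connectivity contract.
- `make_reference_set()` produces substitution-mutated copies of a base
  sequence (no indels), so record identities bracket the 0.9 cutoff by
  construction, with controlled `sp|`/`tr|` headers, taxids from a small
  real-taxid lineage table, and annotation/cross-reference metadata.
- `make_fig5_case()` engineers the isolated-match artefact: a reference
  insertion with a strong-scoring residue at its centre next to an
  unobserved structure residue. Under BLOSUM62 with gap open 10, a lone
  match must out-score an extra gap opening, which a glycine (+6) cannot;
  the generator therefore plants a tryptophan (+11) in a 5-residue
  insertion — the same artefact shape, attainable at these parameters. The
  generator verifies the property against the aligner at build time and
  retries deterministically.

A green test on this world establishes that the formulas, thresholds,
refinement logic and file contracts behave exactly as specified on inputs
whose ground truth is known by construction. It does not establish
archive-scale recovery rates, runtime characteristics, or behaviour on
real low-complexity/repeat-rich sequences; those require the real archives
and are out of scope here.

## Known limitations

- Nucleic-acid and branched entities, assembly generation and
  per-residue taxonomy overrides are out of scope.
- The exhaustive built-in search is quadratic and intended for reference
  sets of up to a few thousand sequences; beyond that, use the external
  search adapter.
- The mmCIF reader covers the subset of the STAR grammar that PDBx/mmCIF
  data files use (one data block; quote characters immediately followed by
  non-whitespace are not supported).
- Multi-model files use the first model's coordinates only; mapping is
  per-entity, not per-model.
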