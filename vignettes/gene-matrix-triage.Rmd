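---
title: "Heat-matrix curation and missing-protein triage with genemx"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Heat-matrix curation and missing-protein triage with genemx}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(genemx)
library(dplyr)
```

## The problem

Chromosome-centric proteome inventories ask, for every protein-coding gene
of one chromosome, whether its protein product has ever been confidently
observed — and if not, why not. The curation state of such a project is
naturally a **genes × descriptors heat matrix**: each row is a gene, each
column ("descriptor") one kind of evidence — protein-existence level (`PE`),
public repository experiment counts (`DB`), canonical-form expression
(`CF`), splice-form expression (`S2`–`S7`), antibody availability (`AB`),
interaction counts (`B`, `I`, `S9`/`S7`/`S4`), and so on. Cells hold a
non-negative number quantifying how much evidence a source holds for that
gene. genemx implements this matrix, its colour rendering, versioned
snapshots with diffing, the sort-and-select triage of undetected ("missing")
proteins, splice-isoform and guilt-by-association analytics, and a seeded
synthetic generator so that every analysis is testable fully offline.

Everything is tibble-in/tibble-out: user-facing functions take a data frame
first and return tibbles (or small S3 containers with `tidy()`/`glance()`
methods), so workflows chain with the pipe.

## Absence versus zero

A cell with **no record** means "no data"; a **stored 0** means a source
positively reported zero (e.g., an expression measurement of 0). The two are
deliberately distinct states:

* selection predicates treat them differently — `CF = 0` matches a stored
  zero but not an absent cell, and `ABSENT(CF)` is the only way to test for
  absence;
* version diffing reports a `0 → absent` transition as a change, preserving
  provenance;
* the colour quantizer renders **both** as black, matching the convention
  that a black box means "no data" and that zero evidence volume carries no
  colour.

## Colour quantization

The automatic scheme bins each present, positive value by its fraction of
the **per-descriptor column maximum** into five half-open intervals

$$(0,0.2],\;(0.2,0.4],\;(0.4,0.6],\;(0.6,0.8],\;(0.8,1.0],$$

open at the bottom (so 0 is excluded) and closed at the top (so the column
maximum always lands in the top bin). Column-local normalization is used
because descriptors carry incommensurate units — an RPKM column and an
antibody count column cannot share a maximum. The five bins are rendered as
a red-to-green ramp (`red`, `red`, `orange`, `yellow`, `green`): red means
relatively little data, green sufficient data, black absent. Fixed fractions
of the maximum (rather than quantiles of the column distribution) are the
simplest reading of "20% thresholds"; the quantile alternative would make a
cell's colour depend on the whole column's shape and is noted as a possible
variant, not implemented.

Descriptor owners can register **custom schemes** with raw-value boundaries
(strictly increasing, final bound may be `Inf`); `register_scheme()`
replaces on re-registration, and zeros stay black under every scheme.

```{r quantize}
quantize(c(NA, 0, 37, 100), max_value = 100)
```

## The triage rule table

Each (gene, biomaterial) evidence record is classified by the **first
matching rule** of a fixed, ordered table:

| order | condition | category |
|---|---|---|
| 1 | SRM signal observed | `PROTEIN_DETECTED` |
| 2 | no SRM, canonical form silent, some splice form expressed | `SPLICE_ONLY` |
| 3 | no SRM, no public transcript, PE level above the confident tier, proprietary expression > threshold | `PROTEOFORM_CANDIDATE` |
| 4 | no SRM, but PE-confident or enough repository experiments or a shotgun hit | `MISSING_WITH_EXTERNAL_EVIDENCE` |
| 5 | otherwise | `DARK` |

Three thresholds matter, all in `triage_config()`:

* `expression_threshold` (default **1.0**, strict `>`): the RPKM/FPKM level
  above which a gene counts as transcribed. RPKM and FPKM are treated as
  interchangeable magnitudes.
* `pride_min` (default **3**): how many public proteomics-repository
  experiments count as significant external evidence. No canonical value
  exists; 3 is a conservative small default and is exposed for tuning.
* `pe_confident_max` (default **1**): the highest protein-existence level
  that counts as protein-level evidence (PE1 only).

The precedence of rules 2–4 is a design choice, pinned by tests: the most
specific, actionable explanation wins. A splice-only expression pattern
explains *why* targeted assays against the canonical form fail and dictates
a different remedy (target the splice form) than generic external evidence
does, so it fires first; a proteoform candidate (invisible to all databases
yet clearly transcribed) similarly outranks the catch-all external-evidence
category.

Categories translate into recommendation codes: every
`MISSING_WITH_EXTERNAL_EVIDENCE` record is re-posted for peptide design,
plus `ADJUST_SRM_METHOD` when a SIS standard already exists (otherwise
`SYNTHESIZE_NEW_SIS`), `REVISE_SAMPLE_PREP` for membrane-bound targets and
`ALTERNATIVE_PROTEASE` when tryptic coverage is inadequate; `SPLICE_ONLY`
yields `TARGET_SPLICE_FORM` + `SYNTHESIZE_NEW_SIS`; `PROTEOFORM_CANDIDATE`
yields `PROTEOFORM_SEARCH`. `recommend()` re-derives the category from the
evidence and errors on any inconsistency, so recommendations are always
traceable to the rule that fired.

The gene-level rollup keeps the best category across biomaterials in the
order detected > splice-only > missing-with-evidence > proteoform candidate
> dark.

## Guilt-by-association scoring

The functional-annotation shortlist needs a monotone, deterministic reduction
of the annotation descriptors to one number. No canonical formula exists for
this, so the package uses the simplest additive form consistent with the
heat-matrix colour semantics:

$$\mathrm{score} = w_{ab}\,b(AB) + w_{pa}\,b(PA) + w_{sl}\,b(SL)
  + w_{int}\,\bigl(b(B) + b(I)\bigr) + w_{str}\,\mathrm{strbonus},$$

where $b(\cdot)$ is the 5-level auto-quantizer **bin index** (column-max
normalized within the input batch; absent or zero contributes 0) and the
STRING-confidence bonus is 3/2/1 for the S9/S7/S4 score bins (interaction
score > 0.9 / > 0.7 / > 0.4), 0 for none. All weights default to 1 and are
exposed. Scores are therefore deterministic *given the batch*; in
`select_annotation_targets()` normalization always happens over the full
input batch before any mode filter, so a row's score does not change when
the filter changes. `novel` mode keeps rows detected in-house but missing
from the worldwide MS databases; `hub` mode ranks everything. Ties break by
accession.

## Coverage accounting

`coverage_stats()` is deliberately plain set algebra: a gene is detected by
a source iff the source's accession set contains it; per-source fractions,
the union fraction and `missing = 1 − union` follow. Evidence quality
weighting is the triage engine's concern, not coverage's.

## Peptide susceptibility

SRM candidate peptides overlapping known single amino-acid polymorphisms or
modification sites are fragile targets. `rank_peptides()` orders peptides by
the weighted site count $w_{sap}\cdot\mathrm{SAP} + w_{ptm}\cdot\mathrm{PTM}$
(defaults 1, 1), least susceptible first, with ties preferring the longer
peptide (more transitions to choose from) and then lexicographic sequence
for determinism. Positional weighting inside the peptide is intentionally
out of scope.

## Versioned snapshots

`dataset_version()` freezes a matrix under a version id; `diff_versions()`
reports set differences of genes/descriptors and every cell whose **value**
differs (including absent↔present). The report additionally carries the full
added gene/descriptor rows and new cells' source/timestamp, making it a
self-contained patch: `apply_diff(old, diff_versions(old, new))` reproduces
the new version's logical content, a property enforced on randomized
matrices. Diffing is value-level: a cell whose source annotation alone
changed is not reported.

## The synthetic generator

`simulate_chromosome()` emulates the statistical structure the analytics
assume, not any real dataset:

* **Detection.** SRM detection is an independent Bernoulli draw per gene ×
  biomaterial at `detect_prob`; the public-database layer is an independent
  per-gene Bernoulli at `public_detect_prob`. Shotgun evidence is drawn
  conditionally on the SRM outcome (defaults 0.8 given detected, 0.05 given
  not), reflecting how strongly the two MS modes co-occur.
* **Ground-truth labels.** Splice-only and proteoform-candidate labels are
  assigned *only among genes undetected in every biomaterial* (with
  probabilities `splice_only_prob`, `proteoform_prob`, default 0.05 each —
  small minorities, as such genes are rare discoveries). Drawing detection
  first keeps the realized per-biomaterial detection fraction an unbiased
  binomial at the configured rate, which the calibration tests rely on.
  Labelled splice-only genes get a silent canonical form and at least one
  expressed splice form in every biomaterial; unlabelled genes can never
  show that pattern (their splice forms ride along an expressed canonical
  form), so the splice filter must recover the labelled set exactly.
  Proteoform candidates get no database transcript, a PE level above 1 and
  expression strictly above 1 RPKM.
* **The chromosome-18-like preset.** `chr18_preset()` fixes 275 genes and
  per-biomaterial detection rates 0.32 (plasma), 0.24 (HepG2), 0.13 (liver),
  and *solves* the public layer analytically so the expected union coverage
  under independence is 63%:
  $q = 1 - (1-0.63)/\bigl((1-0.32)(1-0.24)(1-0.13)\bigr) \approx 0.1771$.
  Independence between sources is the simplest null; no overlap structure is
  claimed, so the union coverage of a simulated dataset is a model-derived
  quantity, never an empirical finding about a real chromosome.
* **Determinism.** One base seed is split into five per-table streams in a
  fixed order (genes, evidence, splice, association, peptides), so adding a
  downstream table can never silently change earlier ones, and every output
  is bit-exact reproducible.
* **What it does not emulate.** Real peptide sequences (random 8–20-mers
  over the 20-letter alphabet), chromatography/spectra, correlated
  inter-gene structure, or database version drift. Tests passing on
  generated data therefore demonstrate the *logic* of the pipeline — rule
  totality, filter equivalences, calibration of rates — not performance on
  real curation data.

Expression is log-normal (default $\mu = 0.5$, $\sigma = 1$, median
≈ 1.6 RPKM — a plausible shape for detected transcripts); interaction and
annotation counts are Poisson with small means (2–4); the PE-level prior
(0.5, 0.2, 0.1, 0.05, 0.15) puts about half the genes at protein-level
evidence. These are realism choices made once; none is load-bearing for any
property the tests assert.

## Numerical and interface choices

* Sorting is always stable with accession as the final tie-break, so every
  ordering is deterministic regardless of input order.
* Predicates are a minimal infix grammar (`=`, `!=`, `<`, `<=`, `>`, `>=`,
  `AND`, `OR`, `NOT`, parentheses, `TRUE`/`FALSE`, `ABSENT(d)`); parse
  errors report the 1-based character position. Comparing an absent cell is
  `FALSE` in both directions — absence is not a number.
* Duplicate (gene, descriptor) values are an error, not last-write-wins, to
  surface adapter bugs at load time.
* TSV with a header and `"."` for absent fields is the canonical dialect;
  readers either accept a row or quarantine it with a reason
  (accepted + quarantined = input rows, checked by test).
* Adapter refresh is atomic: any contract violation (unrequested accession,
  unserved descriptor, negative value, duplicate cell) aborts before a new
  version exists.
* Coordinates are 1-based inclusive; strand is recorded but never used in
  logic.

## Scale of the test suite

The property suite runs at sizes chosen to finish in seconds on one core
while still being informative: $10^4$ random quantizer triples against a
linear-scan oracle, a ~4,600-point exhaustive grid plus $10^4$ random
records for triage totality and monotonicity, 500 random matrices for the
splice-filter/predicate equivalence, 200 random source collections for
coverage algebra, 200 random matrix perturbations for the diff/patch
property, 100 snapshots for serialization round-trips, and generator
calibration at $n = 10{,}000$ (3 binomial SE) plus 200 replicates at
$n = 1{,}000$. The replicate-mean calibration is asserted at the 1-SEM band;
note that this band has only ~68% coverage per biomaterial even for a
perfectly calibrated generator, so it is by far the strictest check in the
suite.

## Known limitations

* The heat matrix is value-level; cell-level provenance history (who set a
  value when, beyond the current source/timestamp) is not versioned inside a
  snapshot — only across snapshots.
* The guilt-by-association score is an ordinal heuristic; it supports
  ranking, not significance statements, and no enrichment testing is
  offered by design.
* Live database connectors are out of scope; the adapter contract plus
  fixture adapters stand in for them, and scheduling ("refresh every month")
  is recorded as metadata only.
* The triage rule table formalizes a narratively described workflow; the
  precedence of the middle rules is a documented interpretation, pinned by
  tests so any future change is deliberate.
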