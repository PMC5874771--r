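# genemx

Desk-scale tooling for **chromosome-centric proteome curation**. A
chromosome-centric inventory asks, for every protein-coding gene of one
chromosome, whether its protein product has been confidently observed — and
for the "missing proteins" that have not, what to do next in the lab. The
curation state of such a project is a **genes × descriptors heat matrix**:
rows are genes, columns are evidence descriptors (protein-existence level
`PE`, repository experiment counts `DB`, canonical-form expression `CF`,
splice forms `S2`–`S7`, antibody availability `AB`, interaction counts `B`,
`I`, `S9`/`S7`/`S4`, …), and each cell quantifies the volume of evidence a
source holds.

genemx implements, in tidyverse-native R:

* the heat matrix with row sorting, predicate selection
  (`CF = 0 AND S3 > 0`, `ABSENT(PE)`, …), versioned snapshots, diffing and
  a patch property (`apply_diff(old, diff) == new`);
* **colour quantization**: present positive values are binned by their
  fraction of the per-descriptor column maximum into five half-open
  intervals (0,0.2], …, (0.8,1.0] rendered red→green; absence *and* stored
  zeros render black; descriptor owners may register custom raw-value
  schemes;
* the **sort-and-select triage engine**: each (gene, biomaterial) evidence
  record is classified by an ordered rule table —
  1. SRM signal → `PROTEIN_DETECTED`
  2. canonical form silent but a splice form expressed → `SPLICE_ONLY`
  3. invisible to databases yet transcribed above 1 RPKM (strict `>`) →
     `PROTEOFORM_CANDIDATE`
  4. PE1, ≥ 3 repository experiments, or a shotgun hit →
     `MISSING_WITH_EXTERNAL_EVIDENCE`
  5. otherwise `DARK`

  and translated into actionable recommendation codes (re-post peptide
  design, adjust the SRM method, synthesize a new SIS standard, revise
  sample prep for membrane proteins, try another protease, target the
  splice form, run a proteoform search);
* analytics: the splice-only missing-protein filter, chromosome coverage
  accounting over detection sources, **guilt-by-association** target
  ranking `score = Σ wᵢ·bin(descriptorᵢ) + strbonus(S9/S7/S4)`, and SRM
  peptide ranking by SAP/PTM susceptibility;
* TSV/JSON readers and writers with quarantine validation, a source-adapter
  contract with atomic refresh, and a `gmx` command-line front end;
* a **seeded synthetic chromosome generator** (275 genes, detection rates
  0.32/0.24/0.13 across plasma/HepG2/liver, public layer solved so expected
  union coverage is 63% under independence) so the whole pipeline runs and
  is tested fully offline.

See `vignettes/gene-matrix-triage.Rmd` for the model, parameter defaults
and design rationale.

## Worked example

```r
library(genemx)
library(dplyr)

sim <- simulate_chromosome(chr18_preset(seed = 42))

# triage every gene x biomaterial record
triage <- batch_triage(sim$evidence)
glance(triage)
#>   n_records n_biomaterials  dark missing_with_external_evidence protein_detected
#> 1       825              3   155                            407              176
# (plus proteoform_candidate and splice_only columns)

# chromosome coverage: targeted detection per biomaterial + public layer
coverage_stats(sim$genes$accession, detection_sets(sim))
#> <coverage_report> 275 genes; union 61.5%, missing 38.5%
#>   source     n_detected fraction
#> 1 srm:plasma         80    0.291
#> 2 srm:HepG2          59    0.215
#> 3 srm:liver          37    0.135
#> 4 public             45    0.164

# genes missing because of splicing: canonical form silent, splice form on
find_missing_spliced(sim$splice_profiles) |> head(3)
#>   gene     biomaterial splice_forms
#> 1 SYN00008 plasma      <chr [4]>
#> 2 SYN00015 plasma      <chr [4]>
#> 3 SYN00019 plasma      <chr [1]>

# guilt-by-association shortlist: detected in-house, absent from global MS
select_annotation_targets(sim$association, mode = "novel") |>
  select(gene, string_bin, guilt_score, rank) |> head(3)
#>   gene     string_bin guilt_score  rank
#> 1 SYN00064 S9                  11     1
#> 2 SYN00020 S9                  10     2
#> 3 SYN00058 S9                  10     3

# the colour quantizer: absent and zero are black, the top bin is green
quantize(c(NA, 0, 37, 100), max_value = 100)
#>   value   bin color
#> 1    NA    NA black
#> 2     0    NA black
#> 3    37     1 red
#> 4   100     4 green
```

The coverage report reads: of 275 simulated genes, 29.1% were detected by
targeted MS in plasma, 21.5% in the HepG2 cell line and 13.5% in liver
tissue; together with the public-database layer, 61.5% of the chromosome is
covered, leaving 38.5% missing proteins at this seed (the generator's
expected union is 63%). The triage summary says 176 of the 825 gene ×
biomaterial records carry an SRM detection, while 407 have external
evidence but no in-house signal — each of those is re-posted for peptide
design with method-specific follow-ups.

The same pipeline is scriptable from a shell via the bundled CLI:

```sh
GMX=$(Rscript -e 'cat(system.file("cli/gmx.R", package="genemx"))')
Rscript $GMX simulate --preset chr18 --seed 42 --out sim/
Rscript $GMX build --genes sim/genes.tsv --descriptors sim/descriptors.tsv \
        --values sim/values.tsv --version-id v1 --out v1.json
Rscript $GMX triage --evidence sim/evidence.tsv --out decisions.tsv
```

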