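---
title: "Methods: comparative dysbiosis signatures and pathway completeness"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: comparative dysbiosis signatures and pathway completeness}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(dysbiosim)
```

## The analysis model

`dysbiosim` operates on *qualitative* dysbiosis evidence: curated
per-study reports that a taxon's population was elevated or reduced in
a disease, as exported from a Disbiome-style database. No abundances,
effect sizes or study weights exist in this data model. Everything the
pipeline computes is therefore set-valued: a disease's signature is a
pair of taxon-label sets, and cross-disease structure is captured by
the exact Venn partition of those sets and by pairwise intersection
sizes. This is a deliberate assumption, inherited from the data source:
two single-cohort 16S studies and one large shotgun study contribute
the same single membership each.

Three consequences shape the implementation:

* **Label identity is textual.** Comparisons use canonicalized labels
  (whitespace collapsed, binomial casing: first letter upper-cased,
  the rest lower-cased), not taxonomic identity. Mixed ranks — genus
  `Ruminococcus` and family `Ruminococcaceae` — are deliberately kept
  distinct, because the underlying reports list both. Deduplication
  prefers the NCBI taxid when a record carries one, since spellings
  vary across contributing studies while taxids do not.
* **Conflicts are data, not errors.** A taxon reported elevated by one
  study and reduced by another (e.g. *Blautia*) legally appears in
  both sets; `conflict_report()` surfaces these rather than resolving
  them.
* **Duplicate reports are collapsed but counted.** Whether the source
  collapsed multiple reports per taxon before counting is not
  documented; `dedupe_corpus()` collapses by
  (taxid-or-label, disease, condition) identity and logs the
  multiplicity of every collapsed group, so the information is kept
  without guessing an aggregation rule.

## Pathway completeness

The metabolic profiling step asks, for each taxon of interest and each
pathway in a user-supplied panel, how complete the pathway is in the
taxon's annotated genome:

$$\mathrm{PS} = \frac{\#\{\text{pathway reactions annotated in the genome}\}}
                     {\#\{\text{reactions constituting the pathway}\}}$$

PS is a ratio of set cardinalities, always $k/n$ for a pathway of $n$
reactions, bounded in $[0, 1]$: 1 means every enzyme needed for the
pathway is present, 0 means none is. Reactions annotated in the genome
but outside the pathway contribute nothing, and reaction identifiers
are opaque strings (MetaCyc-style ids pass through verbatim) — no
ontology reasoning is attempted, because the score needs only set
membership.

Two parameters matter:

* **Strain aggregation** (`policy`, default `"max"`). Pathway–genome
  databases annotate strain genomes while dysbiosis reports name
  genera or families. When several strains carry the same taxon
  label, the default takes the per-pathway maximum — "the best
  metabolic capability observed within the taxon" — with `"mean"`
  selectable for an average-capability reading. The choice is exposed
  rather than hard-coded because the source procedure does not state
  one.
* **Missing-annotation handling.** A taxon with no annotation record
  yields missing cells, reported and logged. For clustering only,
  `impute_missing_scores()` replaces them (default 0) with a warning:
  in this data model, absence of annotation evidence is what a low
  completeness score means, but the replacement is explicit and
  overridable, never silent.

The score-matrix panel is expected to carry three pathway families —
short-chain fatty acid fermentation routes (acetate, propionate,
butyrate), polyamine biosynthesis (putrescine I/II/III, spermidine
I/III) and neurotransmitter precursors (L-glutamate, L-tryptophan,
histamine). Pathway naming conventions differ between database
versions (the same putrescine route appears as "putrescine I" or
"putrescine III" in different sources), so names live entirely in the
panel file and are never hard-coded. Published per-organism PS values
depend on the database snapshot queried and are therefore not encoded
as fixtures; the packaged tests instead verify the scoring machinery
exactly (see *Synthetic data* below).

## Taxonomy trees

`build_common_tree()` reproduces the NCBI "common tree" construction:
resolved ranked lineages (superkingdom → species, from a packaged
offline table) are merged on shared prefixes and unary chains are
collapsed so that every internal node except the root has at least two
children. When a chain collapses, the *topmost* label survives — a
`Firmicutes → Bacilli → Lactobacillales` chain becomes a single node
labeled `Firmicutes` — because the phylum-level grouping is the one
the downstream analysis reads. The result is a cladogram: no branch
lengths exist in the source procedure, so none are invented.

Newick serialization is performed by the package's own compact
writer/parser rather than an external tree library, because the
pipeline requires properties those libraries do not guarantee
together: single-quoted labels with `''` escaping for labels containing
metacharacters, faithful one-leaf trees (`"A;"`), exact write→parse
round-trip identity, and parse errors that report character positions.
`ape` remains an independent cross-check in the test suite for plain
trees. Dendrograms exported from clustering reuse the same writer with
merge heights encoded as branch lengths (leaf at height 0, branch
length = parent height − child height).

## Clustering

The heatmap computation follows the conventional score-matrix recipe:

1. **Auto-scaling**: each feature column is standardized to zero mean
   and unit *sample* (n−1) standard deviation; zero-variance columns
   are mapped to all-zeros with a log note (tolerance for the
   scaled-property checks: 1e−9). At least two rows are required —
   a standard deviation of one point is undefined.
2. **Euclidean distances** between rows (`stats::dist`).
3. **Ward agglomeration** in the `ward.D2` form (`stats::hclust`):
   the minimum-variance criterion applied to squared distances, merge
   heights reported on the distance scale. On Euclidean input this
   produces monotone non-decreasing merge heights (no dendrogram
   inversions), which the suite asserts. `ward.D2` was chosen over
   `ward.D` to match the default of the analysis platforms commonly
   used for this kind of matrix.
4. **Leaf ordering**: at every merge the cluster created earlier in
   the merge sequence is placed on the left; leaves count as created
   before any merge, and between two leaves the smaller index goes
   left. Merge tie-breaking itself follows `hclust`'s deterministic
   convention. Together these make the exported layout bit-reproducible;
   on continuous data, ties between candidate merges have probability
   zero, and the naive-Ward oracle suite runs on such tie-free inputs.

Rows (taxa) and columns (pathways) are clustered independently with
the same procedure; column clustering is on by default and switchable,
since whether the original figures clustered one margin or both is not
documented — supporting both is a design choice, not a claim.

## Synthetic data and what the tests show

The generators produce inputs whose correct outputs are known by
construction:

* `gen_dysbiosis_corpus()` plants an exact Venn decomposition: for
  each disease subset, a chosen number of taxa belonging to exactly
  that subset. Labels are `<prefix><integer>` with globally unique
  integers, so cells cannot collide; the record order is shuffled
  deterministically by the seed. Running the real pipeline
  (signatures → partition) must recover the planted cells *exactly* —
  the suite checks 100 random specifications with up to 5 diseases
  and cell sizes up to 20.
* `gen_pathway_db()` plants completeness targets: for a target
  $k/n$ the generated annotation holds exactly $k$ of the pathway's
  $n$ reactions (which $k$ is seed-determined). Matrix assembly must
  recover every target exactly (100 random specifications, pathways
  of 1–12 reactions).
* `gen_lineage_table()` fabricates complete ranked lineages with
  seed-deterministic phylum assignment, for taxonomy-module tests at
  arbitrary scale.

The generators deliberately do *not* mimic abundance distributions,
study-level heterogeneity, annotation noise or rank mixing: the
analysis being exercised is purely set-valued, so planted set
structure is the complete ground truth for it. Passing these tests
shows the machinery is exact on its own data model; it says nothing
about curation quality or ecological validity of any real export.

Alongside the planted-recovery checks, independent brute-force oracles
guard the core computations: Venn partitioning against per-element
membership enumeration (200 random families, ≤5 sets over a 50-symbol
alphabet), pathway scores against per-reaction counting (500 trials),
Ward linkage against a naive $O(n^3)$ recompute-all-variances
implementation (50 trials, $n \le 8$), Euclidean distances against a
two-loop sum of squares, and Newick serialization against 100 random
trees (half with metacharacter labels, a third with branch lengths).
These problem sizes keep the default suite under half a minute while
enumerating every structural case the operations distinguish.

## Packaged fixtures

Two plain-text fixtures ship with the package:

* `extdata/table1_records.json` — the transcription of the published
  cross-disease table of commonly affected bacterial groups (13
  organism×condition entries expanded to 41 per-disease records, all
  stool samples), including its original case inconsistencies in
  disease names; disease matching is case-insensitive for exactly this
  reason.
* `extdata/lineages.tsv` — a hand-compiled ranked-lineage table
  covering every taxon named in the cross-disease analysis, using the
  classical phylum nomenclature (*Firmicutes*, *Bacteroidetes*,
  *Actinobacteria*, *Proteobacteria*) rather than the renamed 2021
  equivalents, to match the names used in the source reports. It is an
  offline stand-in for a live taxonomy service, not an NCBI export.

## Known limitations

* Published cross-database quantities — pairwise overlap counts from a
  live Disbiome snapshot, per-organism PS values from a MACADAM
  snapshot — are snapshot-dependent and cannot be reproduced offline;
  the pipeline reproduces the *method*, and its packaged corpus
  reproduces the published common-taxa table.
* Label-based set comparison inherits the source's spelling and rank
  conventions; no fuzzy matching against name services is attempted.
* The Venn partition is computed for any number of sets but is
  intended for small families (the motivating analysis compares four
  diseases); cells are exported as tables, never drawn.
* PS measures annotation completeness only — no flux, regulation or
  thermodynamics.
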