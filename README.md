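# dysbiosim

`dysbiosim` is an offline R pipeline for comparative analysis of
qualitative gut microbial dysbiosis reports across diseases. It targets
the kind of study in which a curated database export (one record per
published taxon–disease observation, tagged *elevated* or *reduced*) is
compared across several conditions — here, the neurodegenerative
diseases Alzheimer's disease (AD), Parkinson's disease (PD), Multiple
sclerosis (MS) and Amyotrophic lateral sclerosis (ALS) — and the
overlapping taxa are then profiled for their metabolic capabilities
against a pathway–genome database.

The pipeline has five stages, each usable on its own:

1. **records** — parse, validate, normalize and filter a
   Disbiome-style JSON record array (`parse_records()`,
   `filter_by_sample()`, `dedupe_corpus()`);
2. **signatures** — per-disease elevated/reduced taxon sets and the
   multi-list comparison: exact Venn partition, pairwise overlap
   counts, cross-disease intersections (`build_signatures()`,
   `venn_partition()`, `pairwise_overlap()`, `common_taxa()`);
3. **taxonomy** — ranked-lineage resolution from a packaged table,
   NCBI-style common-tree construction, faithful Newick
   serialization (`build_common_tree()`, `write_newick()`,
   `parse_newick()`);
4. **pathway scoring** — the Pathway Score, the completeness of a
   metabolic pathway in a genome:

   PS = (number of the pathway's reactions annotated in the genome) /
        (total number of reactions constituting the pathway),

   so PS ∈ [0, 1], with 1 meaning every enzyme needed for the pathway
   is present and 0 meaning none is (`pathway_score()`,
   `build_score_matrix()`);
5. **clustermap** — the heatmap computation: per-feature auto-scaling
   (zero mean, unit sample sd), Euclidean distances, Ward (`ward.D2`)
   agglomeration, deterministic leaf ordering and text export
   (`autoscale()`, `ward_linkage()`, `export_heatmap()`).

A synthetic-data module (`gen_dysbiosis_corpus()`, `gen_pathway_db()`,
`gen_lineage_table()`) generates corpora and pathway databases with
*planted* ground truth — known Venn cells and known pathway scores — so
every stage is testable without live access to Disbiome, NCBI or
MACADAM/MetaCyc. `run_all()` ties the stages into one reproducible run
with an MD5 manifest; `inst/cli/dysbiosim.R` is a thin command-line
front end (`extract`, `compare`, `tree`, `score`, `cluster`,
`simulate`, `run`).

## Worked example

The package ships a transcription of the published cross-disease
corpus: the taxa commonly reported as elevated or reduced in stool
across AD, PD, MS and ALS (13 organism×condition entries, 41
per-disease records).

```r
library(dysbiosim)

corpus <- filter_by_sample(load_table1_fixture(), "Feces")
diseases <- c("Alzheimer's disease", "Parkinson's disease",
              "Multiple sclerosis", "Amyotrophic lateral sclerosis")
sigs <- build_signatures(corpus, diseases)

pairwise_overlap(sigs, "reduced")
#>                               Alzheimer's disease Parkinson's disease Multiple sclerosis Amyotrophic lateral sclerosis
#> Alzheimer's disease                             6                   6                  6                             2
#> Parkinson's disease                             6                   6                  6                             2
#> Multiple sclerosis                              6                   6                  6                             2
#> Amyotrophic lateral sclerosis                   2                   2                  2                             2
```

The diagonal is each disease's own reduced-set size; off-diagonal cells
are intersection sizes. The two taxa reduced in **all four** diseases,
and the taxon reported in both directions for MS:

```r
common_taxa(sigs, diseases, "reduced")
#> [1] "Clostridium" "Dorea"
conflict_report(sigs[["Multiple sclerosis"]])
#> [1] "Blautia"
```

A common-taxonomy cladogram of the taxa elevated in AD, PD and MS,
using the packaged lineage table:

```r
tree <- build_common_tree(common_taxa(sigs, diseases[1:3], "elevated"),
                          load_lineage_fixture())
write_newick(tree)
#> ((Alistipes,Bacteroides)Bacteroidetes,Bifidobacterium,(Blautia,Lactobacillus)Firmicutes,Shigella)root;
```

And a pathway completeness score — a genome annotating 2 of a 3-reaction
acetate-fermentation pathway:

```r
pathway_score(c("ACETATEKIN-RXN", "PTAr-RXN"),
              c("ACETATEKIN-RXN", "PTAr-RXN", "ACKr-RXN"))
#> [1] 0.6666667
```

Score matrices over a pathway panel are built with
`build_score_matrix()` (one row per taxon×group, `max` or `mean`
aggregation over strains) and clustered/exported with
`cluster_matrix()` + `export_heatmap()`.

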