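# aftargets

Drug development for atrial fibrillation (AF) has stalled even as its
genetic-association literature has exploded. `aftargets` is an R package
for researchers working at that interface: it turns study-level gene
evidence — GWAS, whole-genome and exome-wide analyses, rare-variant
studies, and TWAS / eQTL-colocalization results in cardiac tissue — into a
ranked, druggability-annotated target list and a per-drug clinical-evidence
summary, as one reproducible pipeline.

## The scoring scheme at its core

For each gene *g* the package computes additive indicator scores:

* small-molecule druggability (0–2):
  `S_sm(g) = 1[druggable family] + 1[pocket score > 0]`
  (high-quality pocket ≥ 0.7 and medium-quality pocket in (0, 0.7) both
  earn the single pocket point);
* antibody accessibility (0–3): one point per source (UniProt, GO, HPA)
  with high-confidence accessible localisation;
* prioritisation score (0–7):
  `S(g) = |traits(g) ∩ {AF, PR, LA}| + |tissues(g) ∩ {LA, RA, LV}| + 1[RVAS]`
  counting each trait and each tissue once however many studies report it.

A gene is a priority target when `S(g) > 1`, and druggability-priority when
either druggability domain exceeds 1. Downstream, targets join to drugs
through mechanism-of-action records; salt formulations collapse to parent
drugs; clinical evidence per drug reduces under the lattice
Guideline > Systematic Review > RCT > Observational with effect
reconciliation at the top level; and the package builds the indication
co-occurrence matrix, the drug-action dendrogram for high-priority drugs,
and the trait partition of drugged targets.

The published 68-target and 72-row drug-evidence tables are packaged as
checksummed fixtures (`load_fixture()`), and a seeded synthetic-data
generator with planted ground truth (`generate_world()`) makes every stage
testable without any database downloads.

## Worked example

```r
library(aftargets)

world <- generate_world(generator_config(seed = 7, n_genes = 60,
                                         n_parent_drugs = 20))
run <- run_pipeline(world)
run
#> Prioritisation pipeline run
#>   reports in:          66 (32 V2G, 34 author-annotated)
#>   genes resolved:      53 (0 report(s) unresolved)
#>   priority targets:    12
#>   drugged targets:     17 via 52 links
#>   parent drugs:        20 (from 34 forms)
#>   drugs with evidence: 11
```

Of the 66 study-level reports, 32 had their variant in the variant-to-gene
table (source `V2G`) and the rest kept the original authors' annotation;
53 distinct genes survive symbol resolution, 12 of them exceed the
prioritisation bar, and the 34 drug formulations collapse to 20 parent
drugs, 11 of which carry clinical-evidence items. The ranked score table
shows the components per gene:

```r
head(rank_targets(run$scores)[, c("symbol", "trait_points", "tissue_points",
                                  "rvas_point", "prioritisation_score",
                                  "gene_priority")], 5)
#>     symbol trait_points tissue_points rvas_point prioritisation_score gene_priority
#> 1 ZZBESU39            2             0          1                    3          TRUE
#> 2  ZZBOSA7            1             2          0                    3          TRUE
#> 3 ZZDOME38            2             0          1                    3          TRUE
#> 4  ZZFUVA8            2             1          0                    3          TRUE
#> 5 ZZLORE34            1             2          0                    3          TRUE
```

The planted priority set is recovered exactly:

```r
setequal(run$scores$symbol[run$scores$gene_priority],
         world$truth$priority_genes)
#> [1] TRUE
```

The same `run_pipeline()` call accepts a bundle directory written by
`write_bundle()` or a YAML run configuration, and writes all stage
artefacts (TSV/JSON) plus an MD5 manifest and a run log when given an
`output_dir`. See the vignette (`vignettes/target-prioritisation.Rmd`) for
the model, its assumptions and the design decisions.

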