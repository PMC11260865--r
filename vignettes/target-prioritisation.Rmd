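---
title: "From genetic association evidence to drug targets: the prioritisation pipeline"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{From genetic association evidence to drug targets: the prioritisation pipeline}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(aftargets)
```

## The problem and the model

Atrial fibrillation (AF) has a rich genetic-association literature — genome-
wide association studies (GWAS) of AF itself and of its related traits (PR
segment indices, left-atrial size and function), exome-wide and rare-variant
analyses, and expression studies (TWAS and eQTL colocalization) in cardiac
tissue — but almost none of that evidence feeds back into drug development.
This package implements a transparent, additive evidence-integration scheme
that links study-level gene reports to drugs and druggability annotations,
so that the whole chain from published variant to repurposing candidate is a
reproducible computation.

The core quantities are three indicator scores per gene:

* **Small-molecule druggability** (0–2): one point for membership in a
  druggable protein family, one point for a usable structure-based binding
  pocket. The pocket tiers ("high" at a pocket score of at least 0.7,
  "medium" strictly between 0 and 0.7) both award the same single point, so
  only positivity of the score matters; a pocket score of exactly 0 means
  "no usable pocket" and earns nothing, as does a missing score (no
  structure assessed). The two readings are deliberately distinguished in
  the file format: missing is the `.` sentinel, not 0.
* **Antibody (biologic) accessibility** (0–3): one point per source
  (UniProt, Gene Ontology, Human Protein Atlas) reporting high confidence
  that the protein sits in an antibody-accessible compartment — plasma
  membrane, extracellular matrix or secreted. Accessibility, not absence of
  a localisation, is what makes a protein tractable to biologics, and that
  is the reading implemented.
* **Prioritisation score** (0–7): one point per trait (AF, PR indices, LA
  indices) with at least one association report, one point per cardiac
  tissue (LA, RA, LV) with at least one TWAS or eQTL-colocalization report,
  and one point for rare-variant (RVAS) support. Evidence is counted at set
  cardinality — "one per trait, one per tissue" — so replication across
  many studies of the same trait does not inflate the score, while
  replication across *kinds* of evidence does.

A gene is a **priority target** when its prioritisation score exceeds 1,
and **druggability-priority** when either druggability domain exceeds 1.
Both thresholds are exposed as arguments (`gene_threshold`,
`druggability_threshold`) for sensitivity analyses; 1 is the default
everywhere. Scores are presence-based by design: no effect sizes or
p-values are ingested, because the upstream literature reports them too
heterogeneously to pool honestly.

## Harmonisation before scoring

Published gene labels are messy. Two normalisation chains run before any
scoring:

1. **Symbol resolution** (`resolve_symbols()`): exact match against the
   registry symbol, then registry synonyms, then an explicit manual map
   (standing in for the per-symbol web searches a curator would do), else
   unresolved. Symbols are compared after trimming, case-folding and
   stripping trailing version suffixes. A synonym matching two distinct
   registry entries is never guessed: it is logged and excluded, because
   silent misassignment is worse than a smaller gene set.
2. **Variant annotation** (`annotate_variants()`): a variant present in the
   variant-to-gene lookup takes that assignment (source `V2G`); a variant
   absent from the lookup — or present with an empty gene — falls back to
   the original authors' annotation (source `AUTHOR`). Variant ids are
   opaque keys; no genomic coordinates are parsed, because nothing
   downstream needs them.

`collapse_reports()` then folds study-level reports into one profile per
gene (trait set, tissue set, rare-variant flag, per-analysis-class counts).
Identical duplicate rows are collapsed first, so profiles are invariant
under permutation and duplication of the input — a property the test suite
checks directly.

## Drug cross-referencing

Targets join to drugs through mechanism-of-action records
(`join_targets_to_drugs()`), with referential integrity enforced: a
mechanism naming an unknown drug id aborts the stage rather than producing
a partial join. Targets with no mechanism rows are reported separately as
druggable-but-undrugged development candidates.

Formulation collapse (`deduplicate_drugs()`) treats salt/ester variants as
duplicates of one parent drug by stripping trailing lexicon tokens
("hydrochloride", "tartrate", "succinate", ...) from the case-folded name,
applied repeatedly so stacked tokens ("dipropionate monohydrate") also
strip. The lexicon is data, not code — a packaged word list the user can
extend. Conjugates of two active moieties (many antibody-drug conjugates)
must stay distinct, and no parser can tell them from pharmacokinetic
conjugates, so they are an explicit whitelist, mirroring the manual
per-class decisions a curator makes.

Indication decoding uses a flat ontology-term-to-specialty mapping table
rather than live ontology lookups; DailyMed-sourced indication rows are
excluded (their coding is unreliable), and unmapped terms are kept with an
`UNMAPPED` specialty and logged rather than dropped. Literature queries are
built two per parent drug — a quoted MEDLINE conjunction and a trial-
registry (condition, intervention) pair — so the query-record count is
always exactly twice the parent count.

## Evidence synthesis

Per-drug clinical evidence reduces under the lattice
**Guideline > Systematic Review > RCT > Observational**
(`max_evidence_level()` is the supremum; `evidence_levels()` exposes the
order). Effects are reconciled at the maximum level only — a lower-level
contradiction does not dilute the top level, matching the one-label-per-
drug convention of evidence tables. The reconciliation rules, in order:
guideline membership gives `EXISTING_TREATMENT`; a unanimous direction is
kept; beneficial and harmful at the same level give `MIXED`; harm supported
only observationally is downgraded to `POTENTIAL_HARM`. "Neutral compared
with another drug in the same class" is `NEUTRAL` plus a comparator
annotation, not a separate category. A drug's `high_priority` flag is the
disjunction of its targets' priority flags.

The packaged transcription of the published drug-evidence table is the
test oracle for this stage. Two of its 72 printed rows are internally
inconsistent with the any-priority-target rule (one drug printed bold with
no priority target, one printed plain despite one); the reconstruction test
names them explicitly rather than forcing agreement.

## Summary structures

* `indication_adjacency()`: the square symmetric matrix behind the
  indication chord diagram. Co-occurrence is counted per *drug*, not per
  indication record, to avoid double counting multi-trial indications.
  Category order is descending diagonal then alphabetical — the rendering
  order is part of the artifact, so it must be deterministic.
* `action_dendrogram()`: action type → target class → target → drug leaves,
  restricted to high-priority drugs, with per-action leaf counts and the
  inhibitor share reported; serialisable as JSON or a Newick-like string.
  Rendering is deliberately out of scope — the tested artifact is the
  structure.
* `partition_by_trait()`: mutually exclusive counts of drugged targets over
  the seven non-empty trait combinations plus a `NONE` cell, so the cells
  always sum exactly to the drugged-target count. (The analogous published
  partition sums to 69 over 68 targets; the identity is enforced here
  rather than reproduced.)

## The synthetic-data generator

`generate_world()` emits every input table with known ground truth:
per-gene trait/tissue/rare-variant patterns with a planted priority subset,
tiered tractability, a variant-to-gene table covering a set fraction of
variants, parent drugs expanded into salt forms (plus whitelisted
conjugates), many-to-many mechanisms, ontology-coded indications with a
DailyMed minority, and per-drug evidence items with at most one guideline
flag per drug. Defaults (200 genes over 40 studies, 20% planted priority,
70% variant-to-gene coverage, 60 parent drugs with a 0.6/0.3/0.1
distribution over 1–3 formulations) are chosen to exercise every code path
at interactive speed while keeping the statistical shape of the real
inputs: sparse evidence, score mass concentrated at 0–1, most parents
single-form.

One structural fact the generator respects: because rare-variant analyses
are trait associations, any gene with RVAS support necessarily also has a
trait point, so its score is at least 2. Planted non-priority genes
therefore never carry RVAS evidence.

Names come from a pronounceable-token scheme (uppercase `ZZ…`-prefixed
symbols, `SYNG`/`SDRG` ids) disjoint from real nomenclature, so a synthetic
world can never collide with the packaged published fixtures. Generation is
fully deterministic under the config seed and restores the caller's RNG
state. `corrupt()` provides four targeted perturbations (dropped
variant-to-gene rows, synonym-scrambled symbols, injected DailyMed rows, a
dangling mechanism) for negative-path testing; the ground-truth ledger is
updated where the perturbation changes it.

What the generator does *not* emulate: the real marginal sizes (1043 genes,
613 drugs depend on external database snapshots), correlated evidence
across related genes, misannotated variant-to-gene rows, and real synonym
collisions. Passing recovery tests therefore demonstrates that the
pipeline's logic is faithful, not that real-world inputs are this clean.

## Numerical and design choices

* Thresholds are strict inequalities (`> 1`), matching the stated priority
  rule; ties at exactly 1 are not priority.
* Ranking ties break alphabetically by symbol, so output order is a pure
  function of the scores.
* Degenerate inputs are defined, not errors: empty report sets give empty
  profiles, empty evidence gives level `NONE`, an empty indication table
  gives a 0 x 0 adjacency matrix.
* All tables are tab-separated UTF-8 with mandatory headers; enums are
  stored canonical upper-case and read case-insensitively; a read/write
  round trip of a canonical file is byte-identical.
* Packaged fixtures are checksummed against a manifest at load time, so a
  corrupted install fails loudly.

## Problem sizes

The test suite runs synthetic worlds of 15–120 genes and 8–40 parent
drugs; the structural-invariant suite draws 100 worlds of 15 genes. The
acceptance script uses a 120-gene, 40-parent world under the caller's
seed. These sizes keep the full suite under a minute while leaving every
recovery check exact rather than approximate.

## Known limitations

* Scores weight all evidence sources equally; no learning or calibration.
* Salt stripping is lexicon-based; an exotic counter-ion absent from the
  lexicon leaves a formulation ungrouped (extend the lexicon file, not the
  code).
* Effect reconciliation sees only the categorical effect labels, not
  effect sizes or populations; drugs with genuinely heterogeneous evidence
  at the top level simply become `MIXED`.
* The symbol resolver assumes the registry is internally consistent; it
  arbitrates reported-vs-registry conflicts but not registry-vs-registry
  ones.
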