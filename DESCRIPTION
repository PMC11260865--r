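Package: aftargets
Title: Prioritising Drug Targets for Atrial Fibrillation from Human Genetic Association Evidence
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A reproducible pipeline linking gene-level evidence from genetic
    association studies of atrial fibrillation and its related traits (PR
    interval and left-atrial indices) to drug-development opportunities.
    Harmonises reported gene symbols against a target registry with synonym
    and manual fallbacks, applies a variant-to-gene annotation chain with
    author-annotation fallback, computes small-molecule and antibody
    druggability scores and an additive multi-domain prioritisation score,
    joins prioritised targets to drugs with salt-form deduplication and
    indication decoding, synthesises per-drug clinical evidence under a
    guideline > systematic review > RCT > observational lattice, and builds
    indication co-occurrence matrices and drug-action dendrograms. Includes
    seeded synthetic-data generators with planted ground truth for end-to-end
    validation, plus transcriptions of the published target and drug-evidence
    tables as fixtures.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    jsonlite,
    stats,
    tools,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
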