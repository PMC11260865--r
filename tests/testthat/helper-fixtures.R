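# Shared builders for small in-code fixtures.

make_registry <- function(symbols, synonyms = rep("", length(symbols)),
                          target_class = rep("Enzyme", length(symbols))) {
  data.frame(
    ensembl_id = sprintf("SYNG%05d", seq_along(symbols)),
    hgnc_symbol = symbols,
    approved_name = paste("protein", symbols),
    biotype = "protein_coding",
    synonyms = synonyms,
    subcellular_locations = "Cell membrane",
    target_class = target_class,
    stringsAsFactors = FALSE
  )
}

make_report <- function(symbol, analysis_class = "GWAS_SNP", trait = "AF",
                        tissue = "NONE", study = "S1", variant = "") {
  data.frame(study_id = study, analysis_class = analysis_class,
             trait = trait, tissue = tissue, variant_id = variant,
             reported_symbol = symbol, annotation_source = "AUTHOR",
             stringsAsFactors = FALSE)
}

make_profile <- function(symbol, traits = character(0),
                         tissues = character(0), rvas = FALSE) {
  data.frame(symbol = symbol,
             traits = paste(sort(traits), collapse = ";"),
             tissues = paste(sort(tissues), collapse = ";"),
             rvas = rvas, stringsAsFactors = FALSE)
}

make_tractability <- function(ensembl_id, family = FALSE, pocket = NA_real_,
                              uniprot = FALSE, go = FALSE, hpa = FALSE) {
  data.frame(ensembl_id = ensembl_id, druggable_family = family,
             pocket_score = pocket, accessible_uniprot = uniprot,
             accessible_go = go, accessible_hpa = hpa,
             stringsAsFactors = FALSE)
}

make_drugs <- function(names, ids = sprintf("SDRG%04d", seq_along(names))) {
  data.frame(drug_id = ids, name = names, drug_type = "Small molecule",
             max_phase = 4L, approved = TRUE, black_box = "",
             withdrawn = FALSE, synonyms = "", stringsAsFactors = FALSE)
}

make_mechanisms <- function(drug_id, target_ensembl_id,
                            action_type = "INHIBITOR") {
  data.frame(drug_id = drug_id, action_type = action_type,
             target_ensembl_id = target_ensembl_id,
             target_name = target_ensembl_id,
             target_molecule_type = "Protein", stringsAsFactors = FALSE)
}
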