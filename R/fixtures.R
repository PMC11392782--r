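# Bundled worked-example evidence tables for a type-2-diabetes
# multi-omics analysis (blood mQTL/eQTL/pQTL against a large T2DM GWAS).
# They carry printed, already-computed evidence values — FDR-adjusted SMR
# p-values, HEIDI p-values, colocalization PP.H4 — so the classification
# and screening rules can be exercised and checked without cohort data.

momicsmr_extdata <- function(name) {
  path <- system.file("extdata", name, package = "momicsmr")
  if (!nzchar(path)) stop("bundled file not found: ", name)
  path
}

#' Worked-example multi-omics evidence table
#'
#' Per (gene, layer, probe) evidence for 18 genes against type 2
#' diabetes: odds ratio with 95% CI, FDR-adjusted SMR p (`q_smr`),
#' HEIDI p and colocalization PP.H4, plus the expected evidence tier.
#' Rows were pre-screened for pleiotropy upstream, so `p_heidi` is coded
#' as 1 (the source table does not print it); `b_xy` is recovered as
#' `log(or_xy)`.
#'
#' @return data.frame suitable for [classify_tiers()].
#' @export
multiomics_evidence_example <- function() {
  df <- as.data.frame(data.table::fread(
    momicsmr_extdata("t2dm_multiomics_evidence.tsv")))
  df$b_xy <- log(df$or_xy)
  df
}

#' Worked-example tissue-validation table
#'
#' Per (gene, tissue) SMR p, HEIDI p and PP.H4 for blood-identified
#' causal genes re-tested in GTEx-style tissue eQTL data.
#'
#' @return data.frame suitable for [tissue_validate()].
#' @export
tissue_validation_example <- function() {
  df <- as.data.frame(data.table::fread(
    momicsmr_extdata("t2dm_tissue_validation.tsv")))
  df$b_xy <- log(df$or_xy)
  df
}

#' Worked-example phenome-wide screen table
#'
#' The FDR-significant gene-phenotype Wald-ratio associations of the
#' worked example (instrument SNP, alleles, odds ratio with CI, FDR).
#'
#' @return data.frame with columns `gene_id, phenotype, snp, ea, oa,
#'   or_xy, ci_low, ci_high, fdr`.
#' @export
phemr_screen_example <- function() {
  as.data.frame(data.table::fread(
    momicsmr_extdata("t2dm_phemr_significant.tsv")))
}
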