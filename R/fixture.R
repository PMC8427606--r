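#' Reported miRNA-cancer associations (worked-example fixture)
#'
#' The package ships a small reference table of TWAS-significant
#' miRNA-cancer risk associations reported by a published SMR-HEIDI study
#' of five hormone-dependent cancers (prostate, breast including ER
#' subtypes, ovarian, colorectal, endometrial): for each association the
#' top cis-eQTL SNP, the SMR effect size and standard error, the
#' FDR-adjusted SMR p-value and the HEIDI p-value. It serves as a worked
#' example and regression fixture for the classification and filtering
#' stages — all 13 rows survive the full `FDR < 0.05` and
#' `P_HEIDI > 0.01` filter.
#'
#' @return `data.frame` with columns `cancer`, `top_snp_chr`, `top_snp_bp`,
#'   `top_snp`, `mirna`, `b_smr`, `se_smr`, `fdr_smr`, `p_heidi`.
#' @seealso [rescore_associations()]
#' @export
hdc_twas_fixture <- function() {
  path <- system.file("extdata", "hdc_twas_associations.tsv",
                      package = "mirsmr", mustWork = TRUE)
  df <- utils::read.table(path, header = TRUE, sep = "\t",
                          stringsAsFactors = FALSE, check.names = TRUE)
  df$top_snp_chr <- as.character(df$top_snp_chr)
  df
}

#' Re-score reported associations through the classification stages
#'
#' Applies the pipeline's model and role classification and the
#' significance filter to a table of per-association statistics (such as
#' [hdc_twas_fixture()]): `model_call` from the HEIDI p-value,
#' `role_call` from the sign of the effect, and
#' `significant = fdr_smr < fdr_alpha & p_heidi > heidi_threshold &
#' model_call == "non_linkage"`. A `cancer_group` column merges
#' estrogen-receptor subtype labels (`"Breast ER+"`, `"Breast ER-"`) into
#' their parent cancer for per-cancer counting.
#'
#' @param df `data.frame` with columns `cancer`, `b_smr`, `fdr_smr`,
#'   `p_heidi`.
#' @param fdr_alpha FDR significance level.
#' @param heidi_threshold HEIDI retention threshold.
#' @return `df` with added `model_call`, `role_call`, `significant`,
#'   `cancer_group` columns.
#' @export
rescore_associations <- function(df, fdr_alpha = 0.05,
                                 heidi_threshold = 0.01) {
  df$model_call <- classify_model(df$p_heidi, heidi_threshold)
  df$role_call <- classify_role(df$b_smr)
  df$significant <- !is.na(df$fdr_smr) & df$fdr_smr < fdr_alpha &
    !is.na(df$p_heidi) & df$p_heidi > heidi_threshold &
    df$model_call == "non_linkage"
  df$cancer_group <- sub(" ER[+-]$", "", df$cancer)
  df
}
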