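#' Published reference values for TP53 coding sequences of eight mammals
#'
#' Reference tables transcribed from a published comparative codon-usage
#' study of the TP53 tumor-suppressor gene in eight mammalian species
#' (GenBank CDS accessions KF921494.1, AB571118.1, KJ511263.1, KJ511265.1,
#' AB033632.1, BC098663.1, HM104191.1, U94788.1). They serve as regression
#' inputs for the summary statistics: per-species base composition
#' (overall and third-position counts, GC percentages by codon position),
#' pooled codon counts with per-species-mean RSCU values, and the
#' per-species bias indices (RCBS, ENC, GC3s, Fop, highest-RSCU codon,
#' GC and GC3 skews — GC3 skew printed in the C3-G3 orientation).
#'
#' The underlying sequences are not shipped; `scripts/fetch_tp53.R` in the
#' source repository documents how to retrieve and align them for the
#' optional sequence-level integration checks.
#'
#' @param table One of `"composition"`, `"indices"`, `"rscu"`.
#' @return A data.frame.
#' @examples
#' comp <- tp53_reference("composition")
#' mean(comp$C)  # 361.5
#' @export
tp53_reference <- function(table = c("composition", "indices", "rscu")) {
  table <- match.arg(table)
  path <- system.file("extdata",
                      sprintf("tp53_reference_%s.tsv", table),
                      package = "codonbias", mustWork = TRUE)
  utils::read.delim(path, stringsAsFactors = FALSE, check.names = FALSE)
}
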