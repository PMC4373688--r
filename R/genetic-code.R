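# package-local cache for the genetic code tables
.cb_env <- new.env(parent = emptyenv())

#' Standard genetic code tables
#'
#' Builds (once, then caches) the lookup tables used throughout the package:
#' the standard nuclear genetic code (NCBI translation table 1), the
#' synonymous-codon families, and their degeneracies. Stop codons (TAA, TAG,
#' TGA) and the two non-degenerate codons (ATG for Met, TGG for Trp) are
#' excluded from the degenerate families, leaving the 59 codons over which
#' RSCU, ENC, Fop and GC3s are defined.
#'
#' @return A list with components:
#'   \describe{
#'     \item{codon_to_aa}{named character(64), codon to one-letter amino
#'       acid, `"*"` for stops.}
#'     \item{families}{named list, one-letter amino acid to its codons
#'       (stops excluded).}
#'     \item{degeneracy}{named integer, amino acid to family size
#'       (1, 2, 3, 4 or 6).}
#'     \item{degenerate_families}{`families` restricted to degeneracy >= 2.}
#'     \item{degenerate_codons}{sorted character(59).}
#'     \item{stop_codons}{`c("TAA","TAG","TGA")`.}
#'     \item{nondegenerate_codons}{`c("ATG","TGG")`.}
#'     \item{aa3}{named character, one-letter to three-letter amino acid.}
#'   }
#' @examples
#' gc <- genetic_code()
#' length(gc$degenerate_codons)  # 59
#' gc$degeneracy[c("L", "S", "R", "I")]
#' @export
genetic_code <- function() {
  if (!is.null(.cb_env$code)) {
    return(.cb_env$code)
  }
  c2a <- Biostrings::GENETIC_CODE
  codons <- names(c2a)
  stop_codons <- sort(codons[c2a == "*"])
  coding <- c2a[c2a != "*"]
  families <- split(names(coding), coding)
  families <- lapply(families, sort)
  degeneracy <- vapply(families, length, integer(1L))
  degenerate_families <- families[degeneracy >= 2L]
  aa3 <- c(
    A = "Ala", R = "Arg", N = "Asn", D = "Asp", C = "Cys", Q = "Gln",
    E = "Glu", G = "Gly", H = "His", I = "Ile", L = "Leu", K = "Lys",
    M = "Met", F = "Phe", P = "Pro", S = "Ser", T = "Thr", W = "Trp",
    Y = "Tyr", V = "Val"
  )
  .cb_env$code <- list(
    codon_to_aa = c2a,
    families = families,
    degeneracy = degeneracy,
    degenerate_families = degenerate_families,
    degenerate_codons = sort(unlist(degenerate_families, use.names = FALSE)),
    stop_codons = stop_codons,
    nondegenerate_codons = sort(unlist(families[degeneracy == 1L],
                                       use.names = FALSE)),
    aa3 = aa3
  )
  .cb_env$code
}

#' All 64 codons in alphabetical order
#' @return character(64)
#' @keywords internal
all_codons <- function() sort(names(Biostrings::GENETIC_CODE))
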