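#' Relative synonymous codon usage (RSCU)
#'
#' RSCU of a codon is its observed count divided by the count expected if
#' all codons of its synonymous family were used equally:
#' `RSCU(c) = g_c * n_i / sum(g over the family)`, where `n_i` is the
#' family degeneracy. Only the 59 codons of degenerate families are scored;
#' stops, ATG and TGG are excluded. A family with zero occurrences yields
#' `NA` (missing), not zeros.
#'
#' @param x A `cds` object, CDS string, or a 64-codon count vector from
#'   [count_codons()]. For a `cds` the terminal stop codon is excluded.
#' @return A data.frame of class `rscu_table` with columns `amino_acid`
#'   (three-letter), `aa` (one-letter), `codon`, `count`, `degeneracy`,
#'   `rscu`, `preferred` (RSCU > 1) and `over_represented` (RSCU > 1.6),
#'   ordered by amino acid then codon.
#' @examples
#' rt <- rscu(validate_cds("ATGAAAAAGAAATAA"))
#' rt[rt$amino_acid == "Lys", c("codon", "count", "rscu")]
#' @export
rscu <- function(x) {
  counts <- as_codon_counts(x)
  code <- genetic_code()
  fams <- code$degenerate_families
  rows <- lapply(names(fams), function(aa) {
    codons <- fams[[aa]]
    g <- as.numeric(counts[codons])
    k <- length(codons)
    tot <- sum(g)
    val <- if (tot > 0) g * k / tot else rep(NA_real_, k)
    data.frame(amino_acid = code$aa3[[aa]], aa = aa, codon = codons,
               count = g, degeneracy = k, rscu = val,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out <- out[order(out$amino_acid, out$codon), ]
  rownames(out) <- NULL
  out$preferred <- !is.na(out$rscu) & out$rscu > 1
  out$over_represented <- !is.na(out$rscu) & out$rscu > 1.6
  class(out) <- c("rscu_table", "data.frame")
  out
}

# normalise x to a 64-codon count vector; cds -> stop excluded
as_codon_counts <- function(x) {
  if (inherits(x, "cds")) {
    return(count_codons(x, include_stop = FALSE))
  }
  if (is.numeric(x) && !is.null(names(x))) {
    counts <- numeric(64L)
    names(counts) <- all_codons()
    idx <- intersect(names(x), names(counts))
    counts[idx] <- x[idx]
    attr(counts, "total") <- sum(counts)
    return(counts)
  }
  if (is.character(x)) {
    return(count_codons(validate_cds(x), include_stop = FALSE))
  }
  stop("cannot interpret 'x' as codon counts")
}

#' Effective number of codons (ENC)
#'
#' Wright's gene-level measure of codon usage bias:
#' `ENC = 2 + 9/F2 + 1/F3 + 5/F4 + 3/F6`, where `F_k` is the mean codon
#' homozygosity of the amino-acid families with degeneracy `k` that occur
#' in the gene. ENC runs from 20 (a single synonymous codon used per
#' family) to 61 (all synonymous codons used equally).
#'
#' The default homozygosity estimator is the with-replacement form
#' `F = sum(p^2)`, under which the 20 and 61 endpoints are exact at any
#' gene length. Wright's bias-corrected estimator
#' `F = (n*sum(p^2) - 1)/(n - 1)` is available via `estimator = "wright"`
#' (families with fewer than 2 codon occurrences are then skipped).
#' A gene with no 3-fold (Ile) usage has `F3` imputed as `(F2 + F4)/2`,
#' flagged in the attributes.
#'
#' @param x A `cds`, CDS string, or codon count vector (stop excluded for
#'   `cds`/string input).
#' @param estimator `"sum_p2"` (default) or `"wright"`.
#' @return ENC value (numeric, clamped to at most 61) with attributes
#'   `F` (named numeric F2/F3/F4/F6), `n_families` (families contributing
#'   per class) and `imputed_F3` (logical).
#' @examples
#' # one codon per family -> maximal bias
#' enc(make_extreme_cds("single_codon"))  # 20
#' enc(make_extreme_cds("equal_usage"))   # 61
#' @export
enc <- function(x, estimator = c("sum_p2", "wright")) {
  estimator <- match.arg(estimator)
  counts <- as_codon_counts(x)
  code <- genetic_code()
  fams <- code$degenerate_families
  deg <- code$degeneracy[names(fams)]

  f_vals <- numeric(0)
  f_deg <- integer(0)
  for (aa in names(fams)) {
    g <- as.numeric(counts[fams[[aa]]])
    n <- sum(g)
    if (n < 1) next
    p <- g / n
    f <- if (estimator == "sum_p2") {
      sum(p^2)
    } else {
      if (n < 2) next
      (n * sum(p^2) - 1) / (n - 1)
    }
    f_vals <- c(f_vals, f)
    f_deg <- c(f_deg, deg[[aa]])
  }
  if (length(f_vals) == 0L) {
    stop("no codon usage in any degenerate family; ENC undefined")
  }
  classes <- c(2L, 3L, 4L, 6L)
  Fk <- vapply(classes, function(k) {
    v <- f_vals[f_deg == k]
    if (length(v) == 0L) NA_real_ else mean(v)
  }, numeric(1L))
  names(Fk) <- paste0("F", classes)
  nk <- vapply(classes, function(k) sum(f_deg == k), integer(1L))
  names(nk) <- names(Fk)

  imputed <- FALSE
  if (is.na(Fk[["F3"]])) {
    if (is.na(Fk[["F2"]]) || is.na(Fk[["F4"]])) {
      stop("cannot impute F3: F2 or F4 class absent")
    }
    Fk[["F3"]] <- (Fk[["F2"]] + Fk[["F4"]]) / 2
    imputed <- TRUE
  }
  if (anyNA(Fk)) {
    stop("degeneracy class absent (", paste(names(Fk)[is.na(Fk)],
         collapse = ", "), "); ENC undefined")
  }
  if (any(Fk == 0)) {
    stop("homozygosity of zero in a degeneracy class; ENC undefined")
  }
  val <- 2 + 9 / Fk[["F2"]] + 1 / Fk[["F3"]] + 5 / Fk[["F4"]] + 3 / Fk[["F6"]]
  val <- min(val, 61)
  structure(val, F = Fk, n_families = nk, imputed_F3 = imputed)
}

#' Frequency of optimal codons (Fop)
#'
#' The fraction of codon occurrences (over degenerate families) that use
#' each family's optimal codon. By default the optimal codon of a family
#' is its most frequent codon in this gene, ties broken alphabetically; an
#' explicit reference set of optimal codons can be supplied instead.
#'
#' @param x A `cds`, CDS string, or codon count vector (stop excluded for
#'   `cds`/string input).
#' @param optimal_set Optional character vector of codons to treat as
#'   optimal (codons outside degenerate families are ignored).
#' @return Fop in `[0, 1]`, with attribute `optimal` (the codon set used).
#' @export
fop <- function(x, optimal_set = NULL) {
  counts <- as_codon_counts(x)
  code <- genetic_code()
  fams <- code$degenerate_families
  syn <- code$degenerate_codons
  denom <- sum(counts[syn])
  if (denom == 0) {
    stop("no codon usage in any degenerate family; Fop undefined")
  }
  if (is.null(optimal_set)) {
    optimal_set <- vapply(fams, function(codons) {
      g <- counts[codons]           # codons sorted, so which.max is the
      codons[which.max(g)]          # alphabetically first on ties
    }, character(1L))
  } else {
    optimal_set <- intersect(optimal_set, syn)
  }
  structure(sum(counts[optimal_set]) / denom,
            optimal = sort(unname(optimal_set)))
}

#' Relative codon bias score (RCBS)
#'
#' A gene-expression proxy built from each codon's enrichment over the
#' expectation implied by the gene's own position-specific base
#' frequencies. For codon `c = b1 b2 b3` with observed count `O_c`:
#' `E[O_c] = O_tot * f1(b1) * f2(b2) * f3(b3)` and
#' `w_c = (O_c - E[O_c]) / E[O_c]`; the gene score is
#' `RCBS = exp( (1/O_tot) * sum_c O_c * log(1 + w_c) ) - 1`,
#' an observed-count-weighted geometric mean of `O_c / E[O_c]` minus one.
#' Codons with `O_c = 0` contribute nothing. The terminal stop codon is
#' excluded (both from counts and from the positional frequencies).
#'
#' @param x A `cds` object or valid CDS string.
#' @return RCBS (numeric, > -1), with attribute `n_codons`.
#' @examples
#' rcbs(validate_cds("ATGAAAAAATAA"))
#' @export
rcbs <- function(x) {
  if (!inherits(x, "cds")) x <- validate_cds(x)
  codons <- x$codons
  if (codons[length(codons)] %in% genetic_code()$stop_codons) {
    codons <- codons[-length(codons)]
  }
  counts <- count_codons(paste(codons, collapse = ""), include_stop = TRUE)
  bases <- c("A", "C", "G", "T")
  f <- matrix(0, nrow = 3L, ncol = 4L, dimnames = list(NULL, bases))
  for (p in 1:3) {
    f[p, ] <- as.numeric(table(factor(substr(codons, p, p),
                                      levels = bases))) / length(codons)
  }
  rcbs_from_counts(counts, f)
}

#' RCBS from counts and positional base frequencies
#'
#' Low-level form of [rcbs()] for precomputed inputs.
#'
#' @param counts 64-codon count vector (see [count_codons()]).
#' @param pos_freq 3 x 4 matrix of base frequencies (rows = codon
#'   positions, columns A/C/G/T), each row summing to 1.
#' @return RCBS value with attribute `n_codons`.
#' @export
rcbs_from_counts <- function(counts, pos_freq) {
  counts <- as_codon_counts(counts)
  o_tot <- sum(counts)
  if (o_tot == 0) stop("empty count table")
  used <- names(counts)[counts > 0]
  b <- function(p, codon) substr(codon, p, p)
  log_terms <- vapply(used, function(cd) {
    e <- o_tot * pos_freq[1L, b(1L, cd)] * pos_freq[2L, b(2L, cd)] *
      pos_freq[3L, b(3L, cd)]
    if (e == 0) {
      stop("expected count of zero for used codon ", cd)
    }
    counts[[cd]] * log(counts[[cd]] / e)
  }, numeric(1L))
  structure(exp(sum(log_terms) / o_tot) - 1, n_codons = o_tot)
}

#' Per-gene codon usage bias indices
#'
#' Assembles the scalar bias indices of one CDS into a one-row data frame:
#' RCBS, ENC, GC3s, Fop, the highest-RSCU codon (with amino acid; ties
#' broken alphabetically), and the GC and GC3 skews (GC3 skew in both
#' orientations).
#'
#' @param cds A `cds` object or valid CDS string.
#' @param enc_estimator Passed to [enc()].
#' @return One-row data.frame with columns `id`, `species`, `length_bp`,
#'   `rcbs`, `enc`, `gc3s`, `fop`, `highest_rscu_codon`,
#'   `highest_rscu_aa`, `highest_rscu`, `gc_skew`, `gc3_skew_gc`,
#'   `gc3_skew_cg`.
#' @export
cub_indices <- function(cds, enc_estimator = "sum_p2") {
  if (!inherits(cds, "cds")) cds <- validate_cds(cds)
  comp <- composition_profile(cds, include_stop = TRUE)
  rt <- rscu(cds)
  scored <- rt[!is.na(rt$rscu), ]
  scored <- scored[order(scored$codon), ]    # ties break to alphabetically first codon
  top <- scored[which.max(scored$rscu), ]
  data.frame(
    id = cds$id, species = cds$species, length_bp = cds$length_bp,
    rcbs = as.numeric(rcbs(cds)),
    enc = as.numeric(enc(cds, estimator = enc_estimator)),
    gc3s = comp[["GC3s"]],
    fop = as.numeric(fop(cds)),
    highest_rscu_codon = top$codon,
    highest_rscu_aa = top$amino_acid,
    highest_rscu = top$rscu,
    gc_skew = comp[["gc_skew"]],
    gc3_skew_gc = comp[["gc3_skew_gc"]],
    gc3_skew_cg = comp[["gc3_skew_cg"]],
    stringsAsFactors = FALSE
  )
}
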