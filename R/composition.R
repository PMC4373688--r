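#' Overall and position-wise base counts
#'
#' Counts A/C/G/T overall and at each of the three codon positions of a CDS.
#'
#' @param x A `cds` object or in-frame DNA string.
#' @param include_stop Keep the terminal stop codon? Default `TRUE`
#'   (composition tables reconcile with full CDS length only then).
#' @return Object of class `base_counts`: list with `overall` (named
#'   integer, A/C/G/T), `by_position` (3 x 4 integer matrix, rows =
#'   codon positions, columns = A/C/G/T), `n_bases`, `n_codons`.
#' @examples
#' bc <- base_counts("ATGAAATAA")
#' bc$overall          # A=6 C=0 G=1 T=2
#' bc$by_position[3, ] # third-position counts: A3=2, G3=1
#' @export
base_counts <- function(x, include_stop = TRUE) {
  codons <- as_codons(x)
  if (!include_stop &&
      codons[length(codons)] %in% genetic_code()$stop_codons) {
    codons <- codons[-length(codons)]
  }
  if (length(codons) == 0L) {
    stop("no codons to count")
  }
  bases <- c("A", "C", "G", "T")
  by_pos <- matrix(0L, nrow = 3L, ncol = 4L,
                   dimnames = list(paste0("pos", 1:3), bases))
  for (p in 1:3) {
    tab <- table(factor(substr(codons, p, p), levels = bases))
    by_pos[p, ] <- as.integer(tab)
  }
  as_base_counts(overall = colSums(by_pos), by_position = by_pos)
}

#' Construct a base-count table from raw counts
#'
#' Lets positional GC statistics be computed from published count tables
#' when the underlying sequence is unavailable. Unknown positions may be
#' left `NULL`; the corresponding positional metrics come back `NA`.
#'
#' @param overall Named numeric of overall A/C/G/T counts (any order).
#' @param pos1,pos2,pos3 Optional named numerics of per-position counts.
#' @param by_position Alternatively, a complete 3 x 4 matrix.
#' @return A `base_counts` object (see [base_counts()]).
#' @export
as_base_counts <- function(overall, pos1 = NULL, pos2 = NULL, pos3 = NULL,
                           by_position = NULL) {
  bases <- c("A", "C", "G", "T")
  overall <- overall[bases]
  names(overall) <- bases
  if (is.null(by_position)) {
    by_position <- matrix(NA_real_, nrow = 3L, ncol = 4L,
                          dimnames = list(paste0("pos", 1:3), bases))
    for (p in 1:3) {
      v <- switch(p, pos1, pos2, pos3)
      if (!is.null(v)) by_position[p, ] <- v[bases]
    }
  } else {
    by_position <- by_position[, bases, drop = FALSE]
  }
  n_codons <- if (all(is.finite(by_position[3L, ]))) {
    sum(by_position[3L, ])
  } else {
    sum(overall) / 3
  }
  structure(list(overall = overall, by_position = by_position,
                 n_bases = sum(overall), n_codons = n_codons),
            class = "base_counts")
}

#' GC metrics from base counts
#'
#' Computes the positional GC statistics: overall GC and AT percentages,
#' GC1/GC2/GC3 (percent G+C at each codon position, over all counted
#' codons), GC12 = mean(GC1, GC2), and AT3 = 100 - GC3.
#'
#' Note GC3 here runs over all third positions of the counted codons
#' (including the stop codon when it was counted); the synonymous-only
#' variant GC3s is sequence-dependent and computed by
#' [composition_profile()].
#'
#' @param bc A `base_counts` object.
#' @return Named numeric: `GC_pct`, `AT_pct`, `GC1`, `GC2`, `GC3`, `GC12`,
#'   `AT3_pct` (all percent).
#' @examples
#' # from published per-position counts, no sequence needed:
#' bc <- as_base_counts(overall = c(A = 262, T = 224, G = 308, C = 358),
#'                      pos3 = c(A = 55, T = 69, G = 122, C = 138))
#' round(gc_metrics(bc)[c("GC_pct", "GC3")], 1)  # 57.8, 67.7
#' @export
gc_metrics <- function(bc) {
  stopifnot(inherits(bc, "base_counts"))
  if (bc$n_bases == 0) stop("zero-length input")
  pct <- function(v) 100 * (v[["G"]] + v[["C"]]) / sum(v)
  gc_all <- pct(bc$overall)
  gc_pos <- rep(NA_real_, 3L)
  for (p in 1:3) {
    v <- bc$by_position[p, ]
    if (all(is.finite(v))) gc_pos[p] <- pct(v)
  }
  c(GC_pct = gc_all,
    AT_pct = 100 - gc_all,
    GC1 = gc_pos[1L], GC2 = gc_pos[2L], GC3 = gc_pos[3L],
    GC12 = mean(gc_pos[1:2]),
    AT3_pct = 100 - gc_pos[3L])
}

#' Compositional skew
#'
#' The signed ratio `(x - y) / (x + y)`, bounded in `[-1, 1]`. AT skew uses
#' `(A, T)`, GC skew `(G, C)`; the GC3 skew uses third-position counts in
#' either orientation (both are reported by [composition_profile()], with
#' column names stating the orientation).
#'
#' @param x,y Nonnegative counts.
#' @return `(x - y) / (x + y)`; defined as 0 (with a warning) when
#'   `x + y == 0`.
#' @examples
#' skew(294, 366)  # -0.109
#' @export
skew <- function(x, y) {
  stopifnot(length(x) == 1L, length(y) == 1L, x >= 0, y >= 0)
  if (x + y == 0) {
    warning("skew undefined for zero totals; returning 0")
    return(0)
  }
  (x - y) / (x + y)
}

#' Full composition profile of one CDS
#'
#' Assembles all base-composition statistics for one coding sequence:
#' overall and third-position counts, GC/AT percentages, positional GC,
#' GC3s (proportion of G+C at synonymous third positions, i.e. third
#' positions of codons in degenerate families; stops, ATG and TGG never
#' enter), and the AT, GC and GC3 skews (GC3 skew in both orientations).
#'
#' @param cds A `cds` object (or valid CDS string).
#' @param include_stop Keep the terminal stop codon in the positional
#'   counts? Default `TRUE`. GC3s is unaffected (stops are never
#'   synonymous).
#' @return Named numeric vector of class-free composition statistics:
#'   counts `A`, `T`, `G`, `C`, `A3`, `T3`, `G3`, `C3`; percentages
#'   `AT_pct`, `GC_pct`, `GC1`, `GC2`, `GC3`, `AT3_pct`, `GC12`;
#'   proportion `GC3s`; skews `at_skew`, `gc_skew`, `gc3_skew_gc`
#'   (G3 - C3 orientation) and `gc3_skew_cg` (its negation).
#' @export
composition_profile <- function(cds, include_stop = TRUE) {
  if (!inherits(cds, "cds")) cds <- validate_cds(cds)
  bc <- base_counts(cds, include_stop = include_stop)
  gm <- gc_metrics(bc)
  code <- genetic_code()

  counts_nostop <- count_codons(cds, include_stop = FALSE)
  syn <- code$degenerate_codons
  syn_counts <- counts_nostop[syn]
  third <- substr(syn, 3L, 3L)
  syn_total <- sum(syn_counts)
  gc3s <- if (syn_total > 0) {
    sum(syn_counts[third %in% c("G", "C")]) / syn_total
  } else {
    NA_real_
  }

  ov <- bc$overall
  p3 <- bc$by_position[3L, ]
  g3 <- p3[["G"]]; c3 <- p3[["C"]]
  gc3_skew_gc <- skew(g3, c3)
  c(A = ov[["A"]], T = ov[["T"]], G = ov[["G"]], C = ov[["C"]],
    A3 = p3[["A"]], T3 = p3[["T"]], G3 = g3, C3 = c3,
    gm,
    GC3s = gc3s,
    at_skew = skew(ov[["A"]], ov[["T"]]),
    gc_skew = skew(ov[["G"]], ov[["C"]]),
    gc3_skew_gc = gc3_skew_gc,
    gc3_skew_cg = -gc3_skew_gc)
}
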