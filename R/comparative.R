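#' Column means and sample standard deviations
#'
#' Mean and n-1 standard deviation for each numeric column of a
#' gene-by-metric table. Percent-scale columns can be summarised with
#' their SD on the proportion scale (SD of `x/100`), the convention used
#' in published composition tables where means are printed in percent but
#' SDs as proportions.
#'
#' @param x Data frame or matrix with at least 2 rows.
#' @param proportion_sd_cols Character vector of column names whose SD is
#'   computed on `x/100`.
#' @return Data frame with rows `mean` and `sd`.
#' @examples
#' m <- data.frame(C = c(358, 366, 360, 351, 384, 341, 367, 365))
#' summary_table(m)  # mean 361.5
#' @export
summary_table <- function(x, proportion_sd_cols = character(0)) {
  x <- as.data.frame(x)
  num <- vapply(x, is.numeric, logical(1L))
  x <- x[, num, drop = FALSE]
  if (nrow(x) < 2L) {
    stop("need at least 2 rows for a sample SD")
  }
  means <- vapply(x, mean, numeric(1L))
  sds <- vapply(names(x), function(nm) {
    v <- x[[nm]]
    if (nm %in% proportion_sd_cols) v <- v / 100
    stats::sd(v)
  }, numeric(1L))
  out <- rbind(mean = means, sd = sds)
  as.data.frame(out)
}

#' Pearson correlation with two-sided p-value
#'
#' Product-moment correlation via [stats::cor.test()]; refuses degenerate
#' input instead of returning `NA`.
#'
#' @param x,y Numeric vectors of equal length >= 3 with nonzero variance.
#' @return List with `r`, `p` (two-sided), `n`.
#' @export
pearson <- function(x, y) {
  if (length(x) != length(y)) stop("x and y differ in length")
  if (length(x) < 3L) stop("need at least 3 observations")
  if (stats::sd(x) == 0 || stats::sd(y) == 0) {
    stop("zero variance; correlation undefined")
  }
  ct <- stats::cor.test(x, y, method = "pearson", alternative = "two.sided")
  list(r = unname(ct$estimate), p = ct$p.value, n = length(x))
}

#' Per-codon correlation with GC3s across genes
#'
#' For each codon column of a gene-by-codon usage matrix (typically RSCU
#' values), the Pearson correlation against the genes' GC3s (or GC3)
#' values, with two-sided p-values from the t transform on n-2 degrees of
#' freedom. Codons with zero variance across genes (or with fewer than 3
#' complete pairs) are flagged not-computable rather than erroring, the
#' way an all-absent codon is masked out of a correlation heat map.
#' Benjamini-Hochberg adjusted p-values are emitted alongside the raw
#' ones.
#'
#' @param usage_matrix Numeric matrix, rows = genes, columns = codons.
#' @param gc3 Numeric vector of per-gene GC3s (one per row).
#' @return Data frame with columns `codon`, `r`, `p`, `p_bh`, `n`,
#'   `sig_05`, `sig_01`, `computable`.
#' @export
codon_gc3_correlation <- function(usage_matrix, gc3) {
  usage_matrix <- as.matrix(usage_matrix)
  if (nrow(usage_matrix) != length(gc3)) {
    stop("number of rows of usage_matrix must match length of gc3")
  }
  if (nrow(usage_matrix) < 3L) stop("need at least 3 genes")
  res <- lapply(colnames(usage_matrix), function(cd) {
    v <- usage_matrix[, cd]
    keep <- is.finite(v) & is.finite(gc3)
    if (sum(keep) < 3L || stats::sd(v[keep]) == 0 ||
        stats::sd(gc3[keep]) == 0) {
      return(data.frame(codon = cd, r = NA_real_, p = NA_real_,
                        n = sum(keep), computable = FALSE,
                        stringsAsFactors = FALSE))
    }
    ct <- stats::cor.test(v[keep], gc3[keep], method = "pearson")
    data.frame(codon = cd, r = unname(ct$estimate), p = ct$p.value,
               n = sum(keep), computable = TRUE, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, res)
  out$p_bh <- stats::p.adjust(out$p, method = "BH")
  out$sig_05 <- !is.na(out$p) & out$p < 0.05
  out$sig_01 <- !is.na(out$p) & out$p < 0.01
  out[, c("codon", "r", "p", "p_bh", "n", "sig_05", "sig_01", "computable")]
}

#' Hierarchical clustering of an RSCU matrix
#'
#' Agglomerative clustering of genes (rows) and codons (columns) of an
#' RSCU matrix: average linkage on Euclidean distances, which is
#' deterministic given the matrix. Missing values (families absent from a
#' gene) are replaced by 0 for clustering and recorded in a mask. Each
#' cell is also banded into the three conventional RSCU categories:
#' `low` (< 1), `preferred` (1 to 1.6) and `over_represented` (> 1.6).
#'
#' @param rscu_matrix Numeric matrix, rows = genes, columns = codons.
#' @param linkage Linkage method for [stats::hclust()]; default
#'   `"average"`.
#' @return List of class `rscu_clustering`: `row_hclust`, `col_hclust`,
#'   `matrix` (reordered by both dendrograms), `category` (character
#'   matrix, same order), `na_mask` (logical matrix), `linkage`.
#' @export
cluster_rscu <- function(rscu_matrix, linkage = "average") {
  m <- as.matrix(rscu_matrix)
  if (nrow(m) < 2L || ncol(m) < 2L) {
    stop("need at least 2 rows and 2 columns to cluster")
  }
  na_mask <- !is.finite(m)
  m0 <- m
  m0[na_mask] <- 0
  row_hc <- stats::hclust(stats::dist(m0, method = "euclidean"),
                          method = linkage)
  col_hc <- stats::hclust(stats::dist(t(m0), method = "euclidean"),
                          method = linkage)
  ord <- m0[row_hc$order, col_hc$order, drop = FALSE]
  category <- matrix(
    cut(ord, breaks = c(-Inf, 1, 1.6, Inf),
        labels = c("low", "preferred", "over_represented"),
        right = TRUE),
    nrow = nrow(ord), dimnames = dimnames(ord)
  )
  structure(list(row_hclust = row_hc, col_hclust = col_hc,
                 matrix = ord, category = category,
                 na_mask = na_mask[row_hc$order, col_hc$order, drop = FALSE],
                 linkage = linkage),
            class = "rscu_clustering")
}

#' @export
print.rscu_clustering <- function(x, ...) {
  cat(sprintf("<rscu_clustering> %d genes x %d codons, %s linkage\n",
              nrow(x$matrix), ncol(x$matrix), x$linkage))
  cat("category counts:\n")
  print(table(x$category))
  invisible(x)
}
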