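#' Codon usage analysis of a set of coding sequences
#'
#' The package's main entry point: validates every input CDS, computes the
#' per-gene composition profile, RSCU table and scalar bias indices, and
#' assembles the cross-gene matrices used by the comparative analyses.
#' Invalid records are dropped (with reasons kept in the validation
#' report), mirroring the usual retrieval filter of perfect start/stop,
#' no ambiguous bases and length a multiple of three.
#'
#' @param x Path to a FASTA file, a named character vector of sequences,
#'   or a list of `cds` objects.
#' @param species Optional species labels (recycled over the inputs;
#'   defaults to the sequence ids).
#' @param include_stop Keep the terminal stop codon in composition
#'   counts? Default `TRUE`. RSCU/ENC/Fop/RCBS always exclude it.
#' @param enc_estimator Passed to [enc()].
#' @return Object of class `cub_analysis`: a list with
#'   \describe{
#'     \item{genes}{list of validated `cds` objects.}
#'     \item{validation}{data.frame report (id, status, reason).}
#'     \item{composition}{data.frame, one row per gene, the composition
#'       profile columns.}
#'     \item{indices}{data.frame of per-gene bias indices
#'       ([cub_indices()] rows).}
#'     \item{rscu_long}{stacked [rscu()] tables with an `id` column.}
#'     \item{rscu_matrix}{genes x 59 codons numeric matrix of RSCU
#'       values (`NA` for absent families).}
#'   }
#' @examples
#' genes <- lapply(1:4, function(i) generate_cds(200, seed = i,
#'                                               id = paste0("g", i)))
#' fit <- codon_usage(genes)
#' fit
#' summary(fit)
#' @export
codon_usage <- function(x, species = NULL, include_stop = TRUE,
                        enc_estimator = "sum_p2") {
  if (is.character(x) && length(x) == 1L && file.exists(x) &&
      is.null(names(x))) {
    x <- read_cds_fasta(x)
  }
  if (is.list(x) && all(vapply(x, inherits, logical(1L), "cds"))) {
    genes <- x
    validation <- data.frame(
      id = vapply(genes, `[[`, character(1L), "id"),
      status = "valid", reason = "", stringsAsFactors = FALSE)
  } else {
    vs <- validate_cds_set(x, species = species)
    genes <- vs$valid
    validation <- vs$report
  }
  if (length(genes) == 0L) {
    stop("no valid coding sequences in input")
  }
  ids <- vapply(genes, `[[`, character(1L), "id")

  comp <- do.call(rbind, lapply(genes, function(g) {
    as.data.frame(t(composition_profile(g, include_stop = include_stop)))
  }))
  comp <- cbind(id = ids,
                species = vapply(genes, `[[`, character(1L), "species"),
                comp, stringsAsFactors = FALSE)
  rownames(comp) <- NULL

  idx <- do.call(rbind, lapply(genes, cub_indices,
                               enc_estimator = enc_estimator))
  rownames(idx) <- NULL

  rscu_tabs <- lapply(genes, rscu)
  rscu_long <- do.call(rbind, Map(function(tab, id) {
    cbind(id = id, as.data.frame(tab), stringsAsFactors = FALSE)
  }, rscu_tabs, ids))
  rownames(rscu_long) <- NULL

  codons <- genetic_code()$degenerate_codons
  rscu_matrix <- t(vapply(rscu_tabs, function(tab) {
    stats::setNames(tab$rscu, tab$codon)[codons]
  }, numeric(length(codons))))
  rownames(rscu_matrix) <- ids

  structure(list(genes = genes, validation = validation,
                 composition = comp, indices = idx,
                 rscu_long = rscu_long, rscu_matrix = rscu_matrix,
                 include_stop = include_stop,
                 enc_estimator = enc_estimator),
            class = "cub_analysis")
}

#' @export
print.cub_analysis <- function(x, ...) {
  n_in <- nrow(x$validation)
  n_ok <- length(x$genes)
  cat(sprintf("Codon usage analysis: %d of %d sequences valid\n",
              n_ok, n_in))
  cat(sprintf("  mean length: %.0f bp\n",
              mean(x$indices$length_bp)))
  cat(sprintf("  ENC:  %s\n", fmt_range(x$indices$enc, 1)))
  cat(sprintf("  GC3s: %s\n", fmt_range(x$indices$gc3s, 3)))
  cat(sprintf("  RCBS: %s\n", fmt_range(x$indices$rcbs, 3)))
  tab <- table(x$indices$highest_rscu_codon)
  cat(sprintf("  highest-RSCU codon(s): %s\n",
              paste(sprintf("%s (%d)", names(tab), tab), collapse = ", ")))
  invisible(x)
}

fmt_range <- function(v, digits) {
  sprintf("mean %.*f, range %.*f-%.*f", digits, mean(v),
          digits, min(v), digits, max(v))
}

#' Summarise a codon usage analysis
#'
#' Cross-gene summary: mean/SD rows for the composition and index tables
#' (percent columns get proportion-scale SDs), the ENC-GC3s Pearson
#' correlation (>= 3 genes), and the over-represented codons.
#'
#' @param object A `cub_analysis` object.
#' @param ... Unused.
#' @return List of class `summary.cub_analysis`.
#' @method summary cub_analysis
#' @export
summary.cub_analysis <- function(object, ...) {
  pct_cols <- c("AT_pct", "GC_pct", "GC1", "GC2", "GC3", "AT3_pct", "GC12")
  comp_num <- object$composition[
    , setdiff(names(object$composition), c("id", "species")), drop = FALSE]
  idx_num <- object$indices[
    , c("rcbs", "enc", "gc3s", "fop", "gc_skew", "gc3_skew_gc",
        "gc3_skew_cg"), drop = FALSE]
  comp_sum <- if (nrow(comp_num) >= 2L) {
    summary_table(comp_num, proportion_sd_cols = pct_cols)
  } else {
    NULL
  }
  idx_sum <- if (nrow(idx_num) >= 2L) summary_table(idx_num) else NULL
  enc_gc3s <- if (nrow(idx_num) >= 3L &&
                  stats::sd(idx_num$enc) > 0 && stats::sd(idx_num$gc3s) > 0) {
    pearson(idx_num$enc, idx_num$gc3s)
  } else {
    NULL
  }
  over <- sort(unique(object$rscu_long$codon[
    object$rscu_long$over_represented]))
  structure(list(n_genes = length(object$genes),
                 composition_summary = comp_sum,
                 indices_summary = idx_sum,
                 enc_gc3s = enc_gc3s,
                 over_represented = over),
            class = "summary.cub_analysis")
}

#' @export
print.summary.cub_analysis <- function(x, ...) {
  cat(sprintf("Codon usage summary over %d genes\n", x$n_genes))
  if (!is.null(x$indices_summary)) {
    cat("\nBias indices (mean / sd):\n")
    print(round(x$indices_summary, 4))
  }
  if (!is.null(x$composition_summary)) {
    cat("\nComposition (mean / sd; percent columns: SD on proportions):\n")
    print(round(x$composition_summary, 4))
  }
  if (!is.null(x$enc_gc3s)) {
    cat(sprintf("\nPearson ENC ~ GC3s: r = %.3f (p = %.3g, n = %d)\n",
                x$enc_gc3s$r, x$enc_gc3s$p, x$enc_gc3s$n))
  }
  if (length(x$over_represented)) {
    cat("Over-represented codons (RSCU > 1.6 in >= 1 gene): ",
        paste(x$over_represented, collapse = " "), "\n", sep = "")
  }
  invisible(x)
}

#' Plot a codon usage analysis
#'
#' @param x A `cub_analysis` object.
#' @param type `"enc_gc3s"` (scatter of ENC against GC3s),
#'   `"rscu_heatmap"` (clustered RSCU heat map), or `"rcbs"` (bar plot of
#'   the per-gene RCBS distribution).
#' @param ... Passed on to the underlying base-graphics call.
#' @return Invisibly, `x`.
#' @method plot cub_analysis
#' @export
plot.cub_analysis <- function(x, type = c("enc_gc3s", "rscu_heatmap",
                                          "rcbs"), ...) {
  type <- match.arg(type)
  idx <- x$indices
  if (type == "enc_gc3s") {
    graphics::plot(idx$gc3s, idx$enc, xlab = "GC3s",
                   ylab = "ENC (effective number of codons)",
                   pch = 19, col = "firebrick", ...)
  } else if (type == "rcbs") {
    graphics::barplot(stats::setNames(idx$rcbs, idx$id), las = 2,
                      ylab = "RCBS", ...)
  } else {
    m <- x$rscu_matrix
    m[!is.finite(m)] <- 0
    stats::heatmap(t(m), hclustfun = function(d)
      stats::hclust(d, method = "average"),
      scale = "none", ...)
  }
  invisible(x)
}

#' Table-2-style RSCU report
#'
#' Long-format RSCU table over all genes of an analysis: per codon the
#' pooled count `N` and the RSCU value either averaged over genes
#' (`mode = "mean"`, the usual multi-species presentation) or recomputed
#' from the pooled counts (`mode = "pooled"`).
#'
#' @param object A `cub_analysis` object.
#' @param mode `"mean"` or `"pooled"`.
#' @return Data frame with `amino_acid`, `codon`, `n`, `rscu`.
#' @export
rscu_report <- function(object, mode = c("mean", "pooled")) {
  mode <- match.arg(mode)
  long <- object$rscu_long
  pooled_counts <- stats::aggregate(count ~ amino_acid + codon, long, sum)
  if (mode == "pooled") {
    counts <- stats::setNames(pooled_counts$count, pooled_counts$codon)
    rt <- rscu(counts)
    out <- rt[, c("amino_acid", "codon", "count", "rscu")]
  } else {
    mean_rscu <- stats::aggregate(rscu ~ amino_acid + codon, long, mean,
                                  na.action = stats::na.pass,
                                  na.rm = TRUE)
    out <- merge(pooled_counts, mean_rscu, by = c("amino_acid", "codon"))
  }
  names(out) <- c("amino_acid", "codon", "n", "rscu")
  out <- out[order(out$amino_acid, out$codon), ]
  rownames(out) <- NULL
  out
}
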