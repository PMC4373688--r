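#' Run the full codon-usage pipeline on a FASTA file
#'
#' One call from FASTA to the standard report files: a per-record
#' validation report, a composition table with mean/SD rows, long-format
#' RSCU, a per-gene bias-index table, the gene x codon RSCU matrix, the
#' per-codon GC3s correlation table, the RSCU clustering orders, and —
#' when an aligned input is supplied — the K2P/NJ tree with bootstrap
#' supports in Newick format. A JSON manifest records the configuration
#' and per-gene status. All outputs are deterministic given the input,
#' configuration and seed; every number is reproducible by calling the
#' corresponding function directly.
#'
#' @param input Path to a FASTA file of coding sequences (one CDS per
#'   record).
#' @param outdir Output directory (created if missing).
#' @param alignment Optional path to an aligned FASTA (equal-length rows)
#'   for the phylogenetic stage; if `NULL` the tree stage is skipped.
#' @param include_stop Keep stop codons in composition counts (default
#'   `TRUE`).
#' @param correlate `"rscu"` (default) or `"counts"`: per-codon variable
#'   correlated against GC3s.
#' @param gc3_variable `"gc3s"` (default) or `"gc3"`: compositional
#'   variable used for the codon correlations.
#' @param rscu_mode Passed to [rscu_report()].
#' @param linkage Clustering linkage (default `"average"`).
#' @param bootstrap Bootstrap replicate count for the tree stage
#'   (default 1000).
#' @param seed Integer seed (bootstrap resampling).
#' @param digits Rounding applied at serialisation only; `NULL` writes
#'   full precision.
#' @return Invisibly, a list with the analysis object, the file paths
#'   written, and the manifest.
#' @export
run_pipeline <- function(input, outdir, alignment = NULL,
                         include_stop = TRUE,
                         correlate = c("rscu", "counts"),
                         gc3_variable = c("gc3s", "gc3"),
                         rscu_mode = "mean", linkage = "average",
                         bootstrap = 1000L, seed = 1L, digits = 4L) {
  correlate <- match.arg(correlate)
  gc3_variable <- match.arg(gc3_variable)
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  paths <- list()
  notes <- character(0)

  seqs <- read_cds_fasta(input)
  fit <- codon_usage(seqs, include_stop = include_stop)

  paths$validation <- file.path(outdir, "validation.tsv")
  write_tsv(fit$validation, paths$validation)

  comp_cols <- c("id", "species", "A", "T", "G", "C", "A3", "T3", "G3",
                 "C3", "AT_pct", "GC_pct", "GC1", "GC2", "GC3", "AT3_pct",
                 "GC12", "GC3s", "at_skew", "gc_skew", "gc3_skew_gc",
                 "gc3_skew_cg")
  comp <- fit$composition[, comp_cols]
  if (nrow(comp) >= 2L) {
    s <- summary_table(comp[, -(1:2)],
                       proportion_sd_cols = c("AT_pct", "GC_pct", "GC1",
                                              "GC2", "GC3", "AT3_pct",
                                              "GC12"))
    extra <- cbind(id = c("mean", "sd"), species = "", s,
                   stringsAsFactors = FALSE)
    comp <- rbind(comp, extra)
  }
  paths$composition <- file.path(outdir, "composition.tsv")
  write_tsv(comp, paths$composition, digits = digits)

  paths$rscu <- file.path(outdir, "rscu.tsv")
  write_tsv(rscu_report(fit, mode = rscu_mode), paths$rscu, digits = digits)

  paths$indices <- file.path(outdir, "indices.tsv")
  write_tsv(fit$indices, paths$indices, digits = digits)

  paths$rscu_matrix <- file.path(outdir, "rscu_matrix.tsv")
  rm_df <- data.frame(id = rownames(fit$rscu_matrix),
                      as.data.frame(fit$rscu_matrix),
                      check.names = FALSE, stringsAsFactors = FALSE)
  write_tsv(rm_df, paths$rscu_matrix, digits = digits)

  if (length(fit$genes) >= 3L) {
    usage <- if (correlate == "rscu") {
      fit$rscu_matrix
    } else {
      t(vapply(fit$genes, function(g)
        count_codons(g, include_stop = FALSE)[
          genetic_code()$degenerate_codons],
        numeric(59L)))
    }
    gc3v <- if (gc3_variable == "gc3s") {
      fit$indices$gc3s
    } else {
      fit$composition$GC3 / 100
    }
    corr <- codon_gc3_correlation(usage, gc3v)
    paths$correlation <- file.path(outdir, "codon_gc3_correlation.tsv")
    write_tsv(corr, paths$correlation, digits = digits)

    cl <- cluster_rscu(ifelse(is.finite(fit$rscu_matrix),
                              fit$rscu_matrix, 0), linkage = linkage)
    paths$cluster <- file.path(outdir, "rscu_cluster_order.tsv")
    write_tsv(data.frame(
      type = c(rep("gene", nrow(cl$matrix)), rep("codon", ncol(cl$matrix))),
      label = c(rownames(cl$matrix), colnames(cl$matrix)),
      position = c(seq_len(nrow(cl$matrix)), seq_len(ncol(cl$matrix))),
      stringsAsFactors = FALSE), paths$cluster)
  } else {
    notes <- c(notes, "comparative stages skipped: fewer than 3 valid genes")
  }

  if (!is.null(alignment)) {
    aln <- read_cds_fasta(alignment)
    if (length(aln) >= 3L) {
      D <- k2p_matrix(aln)
      paths$distances <- file.path(outdir, "k2p_distances.tsv")
      write_tsv(data.frame(taxon = rownames(D), as.data.frame(D),
                           check.names = FALSE), paths$distances,
                digits = digits)
      if (length(aln) >= 4L && bootstrap >= 1L) {
        bs <- bootstrap_support(aln, replicates = bootstrap, seed = seed)
        tree <- bs$tree
      } else {
        tree <- nj_tree(D)
      }
      paths$tree <- file.path(outdir, "tree.nwk")
      write_newick(tree, paths$tree)
    } else {
      notes <- c(notes, "tree stage skipped: fewer than 3 aligned taxa")
    }
  } else {
    notes <- c(notes, "tree stage skipped: no alignment supplied")
  }

  manifest <- list(
    package = "codonbias",
    version = as.character(utils::packageVersion("codonbias")),
    input = normalizePath(input),
    config = list(include_stop = include_stop, correlate = correlate,
                  gc3_variable = gc3_variable, rscu_mode = rscu_mode,
                  linkage = linkage, bootstrap = bootstrap, seed = seed,
                  digits = digits),
    n_records = nrow(fit$validation),
    n_valid = length(fit$genes),
    validation = fit$validation,
    notes = notes,
    outputs = lapply(paths, basename)
  )
  paths$manifest <- file.path(outdir, "manifest.json")
  jsonlite::write_json(manifest, paths$manifest, auto_unbox = TRUE,
                       pretty = TRUE, digits = NA)
  invisible(list(analysis = fit, paths = paths, manifest = manifest))
}
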