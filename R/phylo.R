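# Alignments are named character vectors of equal-length strings over
# {A,C,G,T,-,N} (case-insensitive); helpers convert to a character matrix.

aln_to_matrix <- function(aln) {
  if (is.matrix(aln)) {
    m <- toupper(aln)
  } else {
    stopifnot(is.character(aln), length(aln) >= 1L)
    lens <- nchar(aln)
    if (length(unique(lens)) != 1L) {
      stop("alignment rows differ in length")
    }
    nm <- names(aln)
    if (is.null(nm)) nm <- sprintf("seq%d", seq_along(aln))
    m <- do.call(rbind, strsplit(toupper(aln), ""))
    rownames(m) <- nm
  }
  m
}

matrix_to_aln <- function(m) {
  stats::setNames(apply(m, 1L, paste, collapse = ""), rownames(m))
}

#' Remove alignment columns with gaps or ambiguous bases
#'
#' Complete deletion: every column containing a character outside
#' {A,C,G,T} in any row is removed for all rows, preserving column order.
#'
#' @param aln Named character vector of equal-length aligned sequences (or
#'   a character matrix of single bases).
#' @return Alignment in the same representation restricted to usable
#'   columns, with attribute `kept` (the retained column indices).
#' @examples
#' complete_deletion(c(a = "ATG-A", b = "ATGCA"))  # columns 1,2,3,5
#' @export
complete_deletion <- function(aln) {
  m <- aln_to_matrix(aln)
  usable <- apply(m, 2L, function(col) all(col %in% c("A", "C", "G", "T")))
  if (!any(usable)) {
    stop("no alignment columns survive complete deletion")
  }
  out <- m[, usable, drop = FALSE]
  if (is.matrix(aln)) {
    attr(out, "kept") <- which(usable)
    return(out)
  }
  res <- matrix_to_aln(out)
  attr(res, "kept") <- which(usable)
  res
}

#' Kimura 2-parameter distance
#'
#' Substitutions per site between two aligned sequences, correcting
#' separately for transitions and transversions: with `P` the observed
#' transition proportion and `Q` the transversion proportion,
#' `d = -1/2 * log(1 - 2P - Q) - 1/4 * log(1 - 2Q)`.
#'
#' @param s1,s2 Equal-length DNA strings over {A,C,G,T} (already past
#'   [complete_deletion()]).
#' @return Distance in substitutions/site. Errors with a saturation
#'   message if `1 - 2P - Q <= 0` or `1 - 2Q <= 0`.
#' @examples
#' k2p_distance(strrep("A", 10), strrep("A", 10))  # 0
#' @export
k2p_distance <- function(s1, s2) {
  a <- strsplit(toupper(s1), "")[[1L]]
  b <- strsplit(toupper(s2), "")[[1L]]
  if (length(a) != length(b)) stop("sequences differ in length")
  if (length(a) == 0L) stop("zero-length sequences")
  k2p_from_pq_counts(a, b)
}

k2p_from_pq_counts <- function(a, b) {
  purine <- c("A", "G")
  diff <- a != b
  same_class <- (a %in% purine) == (b %in% purine)
  P <- sum(diff & same_class) / length(a)
  Q <- sum(diff & !same_class) / length(a)
  k2p_from_pq(P, Q)
}

#' K2P distance from transition/transversion proportions
#'
#' @param P Observed transition proportion.
#' @param Q Observed transversion proportion.
#' @return `-log(1 - 2P - Q)/2 - log(1 - 2Q)/4`.
#' @examples
#' k2p_from_pq(0.1, 0.05)  # 0.17018
#' @export
k2p_from_pq <- function(P, Q) {
  w1 <- 1 - 2 * P - Q
  w2 <- 1 - 2 * Q
  if (w1 <= 0 || w2 <= 0) {
    stop("K2P distance saturated (P = ", signif(P, 4), ", Q = ",
         signif(Q, 4), "); distance undefined")
  }
  -0.5 * log(w1) - 0.25 * log(w2)
}

#' Pairwise K2P distance matrix for an alignment
#'
#' Applies [complete_deletion()] and then [k2p_distance()] to every pair.
#'
#' @param aln Named character vector of equal-length aligned sequences.
#' @return Symmetric numeric matrix with zero diagonal and the taxon
#'   labels as dimnames.
#' @export
k2p_matrix <- function(aln) {
  m <- aln_to_matrix(aln)
  m <- complete_deletion(m)
  n <- nrow(m)
  D <- matrix(0, n, n, dimnames = list(rownames(m), rownames(m)))
  if (n < 2L) return(D)
  for (i in seq_len(n - 1L)) {
    for (j in seq.int(i + 1L, n)) {
      d <- k2p_from_pq_counts(m[i, ], m[j, ])
      D[i, j] <- d
      D[j, i] <- d
    }
  }
  D
}

#' Neighbor-joining tree from a distance matrix
#'
#' Saitou-Nei neighbor joining (via [ape::nj()]) on a symmetric distance
#' matrix; the result is unrooted and exact on additive matrices.
#' Negative estimated branch lengths are clamped to zero and counted in
#' the `clamped_edges` attribute.
#'
#' @param D Symmetric numeric matrix (zero diagonal, finite entries) with
#'   taxon labels, or a `dist` object; at least 3 taxa.
#' @return An [ape::phylo] tree with attribute `clamped_edges`.
#' @export
nj_tree <- function(D) {
  if (inherits(D, "dist")) D <- as.matrix(D)
  if (!is.matrix(D) || nrow(D) != ncol(D)) {
    stop("D must be a square matrix or dist object")
  }
  if (nrow(D) < 3L) stop("need at least 3 taxa")
  if (any(!is.finite(D))) stop("distance matrix has non-finite entries")
  if (max(abs(D - t(D))) > 1e-8) stop("distance matrix is not symmetric")
  tree <- ape::nj(D)
  clamped <- sum(tree$edge.length < 0)
  tree$edge.length[tree$edge.length < 0] <- 0
  attr(tree, "clamped_edges") <- clamped
  tree
}

#' Bootstrap support for a neighbor-joining tree
#'
#' Resamples alignment columns with replacement; each replicate is run
#' through K2P distances and neighbor joining, and the support of each
#' internal branch of the full-data tree is the percentage of replicates
#' containing the same bipartition. Replicates whose distance matrix
#' saturates are skipped and counted (a warning is raised if more than 1%
#' are skipped). Reproducible under a fixed seed.
#'
#' @param aln Named character vector of equal-length aligned sequences
#'   (>= 4 taxa for internal branches to exist).
#' @param replicates Number of bootstrap replicates (default 1000).
#' @param seed Integer RNG seed.
#' @return List with `tree` (the full-data NJ tree, node labels set to
#'   rounded supports), `support` (numeric per internal node, percent;
#'   the root node is `NA`), `n_used`, `n_skipped`.
#' @export
bootstrap_support <- function(aln, replicates = 1000L, seed = 1L) {
  stopifnot(replicates >= 1L)
  m <- complete_deletion(aln_to_matrix(aln))
  ref <- nj_tree(k2p_matrix_from_clean(m))
  boot_trees <- vector("list", replicates)
  n_skipped <- 0L
  with_seed(seed, {
    for (r in seq_len(replicates)) {
      cols <- sample.int(ncol(m), ncol(m), replace = TRUE)
      t_r <- tryCatch(nj_tree(k2p_matrix_from_clean(m[, cols, drop = FALSE])),
                      error = function(e) NULL)
      if (is.null(t_r)) n_skipped <- n_skipped + 1L else boot_trees[[r]] <- t_r
    }
  })
  boot_trees <- boot_trees[!vapply(boot_trees, is.null, logical(1L))]
  n_used <- length(boot_trees)
  if (n_used == 0L) stop("all bootstrap replicates saturated")
  if (n_skipped > 0.01 * replicates) {
    warning(sprintf("%d of %d bootstrap replicates skipped (saturation)",
                    n_skipped, replicates))
  }
  counts <- ape::prop.clades(ref, boot_trees, rooted = FALSE)
  support <- 100 * counts / n_used
  support[1L] <- NA_real_  # root bipartition of an unrooted tree is trivial
  ref$node.label <- ifelse(is.na(support), "", as.character(round(support)))
  list(tree = ref, support = support, n_used = n_used, n_skipped = n_skipped)
}

# K2P matrix for an already clean base matrix (no complete_deletion rerun)
k2p_matrix_from_clean <- function(m) {
  n <- nrow(m)
  D <- matrix(0, n, n, dimnames = list(rownames(m), rownames(m)))
  for (i in seq_len(n - 1L)) {
    for (j in seq.int(i + 1L, n)) {
      d <- k2p_from_pq_counts(m[i, ], m[j, ])
      D[i, j] <- d
      D[j, i] <- d
    }
  }
  D
}

#' Write / read a tree in Newick format
#'
#' Thin wrappers over [ape::write.tree()] / [ape::read.tree()] so that
#' trees (including bootstrap node labels) round-trip through text.
#'
#' @param tree An [ape::phylo] object.
#' @param path Output file; if `NULL` the Newick string is returned.
#' @return `write_newick`: the Newick string (invisibly if written to a
#'   file). `read_newick`: an [ape::phylo] object.
#' @export
write_newick <- function(tree, path = NULL) {
  s <- ape::write.tree(tree)
  if (is.null(path)) return(s)
  writeLines(s, path)
  invisible(s)
}

#' @rdname write_newick
#' @param text Newick string (alternative to `path`).
#' @export
read_newick <- function(path = NULL, text = NULL) {
  if (!is.null(text)) ape::read.tree(text = text) else ape::read.tree(path)
}
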