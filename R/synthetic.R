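#' Generate a synthetic coding sequence with controlled codon usage
#'
#' Draws an amino-acid sequence (by default close to uniform over the 18
#' degenerate families, with Met and Trp appearing occasionally) and then
#' a synonymous codon for each amino acid from per-family probability
#' vectors. The result is a valid CDS: ATG start, sampled stop codon,
#' length a multiple of three, no ambiguous bases. Generation is a pure
#' function of its arguments, seed included.
#'
#' @param n_codons Total codon count including the start and stop codons
#'   (>= 3).
#' @param codon_probs Optional named numeric vector of relative weights
#'   over (a subset of) the 59 degenerate-family codons; weights are
#'   renormalised within each family. Unnamed codons get weight 0 when
#'   their family has any named member, else the family is uniform.
#'   Default: uniform within every family.
#' @param aa_weights Optional named numeric over one-letter amino acids;
#'   default weight 1 for each degenerate family and 0.1 each for M and W.
#' @param seed Integer RNG seed.
#' @param id,species Labels for the returned `cds`.
#' @return A validated `cds` object.
#' @examples
#' g <- generate_cds(100, seed = 42)
#' enc(g)
#' @export
generate_cds <- function(n_codons, codon_probs = NULL, aa_weights = NULL,
                         seed = 1L, id = "synthetic", species = id) {
  stopifnot(n_codons >= 3L)
  code <- genetic_code()
  fams <- code$degenerate_families
  if (is.null(aa_weights)) {
    aa_weights <- stats::setNames(rep(1, length(fams)), names(fams))
    aa_weights <- c(aa_weights, M = 0.1, W = 0.1)
  }
  aa_weights <- aa_weights[aa_weights > 0]
  fam_probs <- family_probs(codon_probs)
  body_len <- n_codons - 2L
  with_seed(seed, {
    aas <- sample(names(aa_weights), body_len, replace = TRUE,
                  prob = aa_weights)
    body <- vapply(aas, function(aa) {
      codons <- code$families[[aa]]
      if (length(codons) == 1L) return(codons)
      sample(codons, 1L, prob = fam_probs[[aa]])
    }, character(1L))
    stop_codon <- sample(code$stop_codons, 1L)
    seqs <- paste(c("ATG", body, stop_codon), collapse = "")
    validate_cds(seqs, id = id, species = species)
  })
}

# per-family normalised probability vectors from a flat weight vector
family_probs <- function(codon_probs) {
  code <- genetic_code()
  lapply(code$degenerate_families, function(codons) {
    if (is.null(codon_probs)) {
      return(rep(1 / length(codons), length(codons)))
    }
    w <- codon_probs[codons]
    w[is.na(w)] <- 0
    if (sum(w) == 0) {
      rep(1 / length(codons), length(codons))
    } else {
      as.numeric(w / sum(w))
    }
  })
}

#' Deterministic CDS at the ENC endpoints
#'
#' Builds a CDS whose body either uses exactly one synonymous codon per
#' degenerate family (`"single_codon"`, maximal bias, ENC = 20) or every
#' synonymous codon of every family equally often (`"equal_usage"`, no
#' bias, ENC = 61 under the sum-of-squares homozygosity estimator). The
#' chosen codon of each family under `"single_codon"` is its
#' alphabetically first.
#'
#' @param usage `"single_codon"` or `"equal_usage"`.
#' @param per_family Occurrences per (codon, family) unit; default 10.
#' @return A validated `cds` object.
#' @examples
#' as.numeric(enc(make_extreme_cds("single_codon")))  # exactly 20
#' @export
make_extreme_cds <- function(usage = c("single_codon", "equal_usage"),
                             per_family = 10L) {
  usage <- match.arg(usage)
  fams <- genetic_code()$degenerate_families
  body <- unlist(lapply(fams, function(codons) {
    picked <- if (usage == "single_codon") codons[1L] else codons
    rep(picked, each = per_family)
  }), use.names = FALSE)
  validate_cds(paste(c("ATG", body, "TAA"), collapse = ""),
               id = paste0("extreme_", usage))
}

#' Synthetic CDS series with controlled GC3 levels
#'
#' For each target level `g`, builds per-family codon weights that put
#' total probability `g` on the G/C-ending codons of every degenerate
#' family (split equally within the G/C and A/T subsets), so the expected
#' synonymous-third-position GC content equals `g`. Amino acids are drawn
#' uniformly from the 18 degenerate families (no Met/Trp), so GC3 and
#' GC3s coincide up to the stop codon.
#'
#' @param levels Numeric vector of target GC3 levels, each in (0, 1).
#' @param n_codons Codon count per gene (start/stop included).
#' @param seed Integer seed; gene `i` uses `seed + i`.
#' @return List of `cds` objects, one per level, ids recording the
#'   target.
#' @examples
#' series <- generate_gc3_series(c(0.3, 0.7), n_codons = 300, seed = 7)
#' sapply(series, function(g) composition_profile(g)[["GC3s"]])
#' @export
generate_gc3_series <- function(levels, n_codons = 500L, seed = 1L) {
  stopifnot(all(levels > 0 & levels < 1))
  fams <- genetic_code()$degenerate_families
  aa_w <- stats::setNames(rep(1, length(fams)), names(fams))
  lapply(seq_along(levels), function(i) {
    g <- levels[i]
    w <- unlist(lapply(fams, function(codons) {
      third <- substr(codons, 3L, 3L)
      gc_end <- third %in% c("G", "C")
      v <- numeric(length(codons))
      v[gc_end] <- g / sum(gc_end)
      v[!gc_end] <- (1 - g) / sum(!gc_end)
      stats::setNames(v, codons)
    }), use.names = TRUE)
    names(w) <- sub("^[A-Z]\\.", "", names(w))  # strip family prefix
    generate_cds(n_codons, codon_probs = w, aa_weights = aa_w,
                 seed = seed + i,
                 id = sprintf("gc3_%0.2f", g))
  })
}

#' Evolve an alignment under a two-parameter substitution model
#'
#' Simulates gap-free sequences along a given tree under the Kimura
#' two-parameter (K80) model: transitions occur at `kappa` times the rate
#' of each transversion, branch lengths are expected substitutions per
#' site, and each site evolves independently using the exact transition
#' probabilities of the model (no discrete mutation events), so long
#' branches are handled correctly. The root sequence is uniform over the
#' four bases.
#'
#' @param tree An [ape::phylo] tree with branch lengths, or a Newick
#'   string.
#' @param kappa Transition/transversion rate ratio (> 0); `kappa = 0.5`
#'   reduces to Jukes-Cantor (all substitution types equal).
#' @param length Number of sites (>= 1).
#' @param seed Integer RNG seed.
#' @return List with `alignment` (named character vector, one string per
#'   tip) and `tree` (the true tree, as phylo).
#' @examples
#' sim <- evolve_alignment("(A:0.1,B:0.1);", kappa = 2, length = 200, seed = 1)
#' nchar(sim$alignment[["A"]])
#' @export
evolve_alignment <- function(tree, kappa = 2, length = 1000L, seed = 1L) {
  stopifnot(kappa > 0, length >= 1L)
  if (is.character(tree)) tree <- ape::read.tree(text = tree)
  if (is.null(tree$edge.length)) stop("tree must have branch lengths")
  if (any(tree$edge.length < 0)) stop("negative branch lengths")
  tree <- ape::reorder.phylo(tree, "cladewise")
  ntip <- length(tree$tip.label)
  nnode <- tree$Nnode
  bases <- c("A", "C", "G", "T")
  seqs <- vector("list", ntip + nnode)
  root <- ntip + 1L
  with_seed(seed, {
    seqs[[root]] <- sample.int(4L, length, replace = TRUE)
    for (e in seq_len(nrow(tree$edge))) {
      parent <- tree$edge[e, 1L]
      child <- tree$edge[e, 2L]
      P <- k80_pmatrix(tree$edge.length[e], kappa)
      ps <- seqs[[parent]]
      cs <- integer(length)
      for (b in 1:4) {
        idx <- which(ps == b)
        if (length(idx)) {
          cs[idx] <- sample.int(4L, length(idx), replace = TRUE,
                                prob = P[b, ])
        }
      }
      seqs[[child]] <- cs
    }
  })
  aln <- vapply(seq_len(ntip), function(i) {
    paste(bases[seqs[[i]]], collapse = "")
  }, character(1L))
  names(aln) <- tree$tip.label
  list(alignment = aln, tree = tree)
}

# K80 transition probability matrix for branch length d (subs/site);
# base order A, C, G, T; transitions A<->G and C<->T.
k80_pmatrix <- function(d, kappa) {
  bt <- d / (kappa + 2)       # beta * t (each transversion type)
  at <- kappa * bt            # alpha * t (transition)
  e1 <- exp(-4 * bt)
  e2 <- exp(-2 * (at + bt))
  p_same <- 0.25 + 0.25 * e1 + 0.5 * e2
  p_ts <- 0.25 + 0.25 * e1 - 0.5 * e2
  p_tv <- 0.25 - 0.25 * e1
  P <- matrix(p_tv, 4L, 4L,
              dimnames = list(c("A", "C", "G", "T"), c("A", "C", "G", "T")))
  diag(P) <- p_same
  P["A", "G"] <- P["G", "A"] <- p_ts
  P["C", "T"] <- P["T", "C"] <- p_ts
  P
}
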