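test_that("complete deletion removes exactly the unusable columns", {
  aln <- c(a = "ATGCA", b = "ATGCA")
  expect_equal(as.character(complete_deletion(aln)), c("ATGCA", "ATGCA"))

  aln2 <- c(a = "ATG-A", b = "ATGCA", c = "ATGNA")
  out <- complete_deletion(aln2)
  expect_equal(as.character(out), c("ATGA", "ATGA", "ATGA"))
  expect_equal(attr(out, "kept"), c(1L, 2L, 3L, 5L))

  # constructed fixture: 10 of 50 columns gapped
  set.seed(4)
  base <- paste(sample(c("A", "C", "G", "T"), 50, TRUE), collapse = "")
  gapped <- strsplit(base, "")[[1]]
  gap_cols <- sample(50, 10)
  gapped[gap_cols] <- "-"
  out2 <- complete_deletion(c(x = base, y = paste(gapped, collapse = "")))
  expect_equal(unname(nchar(out2)), c(40L, 40L))

  expect_error(complete_deletion(c(a = "---", b = "AAA")), "no alignment")
})

test_that("K2P distance matches the closed form and its oracles", {
  expect_equal(k2p_distance("AAAA", "AAAA"), 0)
  expect_equal(k2p_from_pq(0.1, 0.05), 0.17018, tolerance = 1e-4)
  expect_equal(k2p_from_pq(0.1, 0.05),
               -0.5 * log(0.75) - 0.25 * log(0.9), tolerance = 1e-12)
  expect_error(k2p_from_pq(0.5, 0), "saturated")

  # sequence pair realising P = 0.1, Q = 0.05 over 100 sites
  s1 <- strrep("A", 100)
  s2 <- paste0(strrep("G", 10), strrep("C", 5), strrep("A", 85))
  expect_equal(k2p_distance(s1, s2), 0.1701812, tolerance = 1e-6)

  # equals Jukes-Cantor when transitions are 1/3 of all changes
  for (p in c(0.06, 0.15, 0.3)) {
    jc <- -0.75 * log(1 - 4 * p / 3)
    expect_equal(k2p_from_pq(p / 3, 2 * p / 3), jc, tolerance = 1e-12)
  }
})

test_that("K2P matrix agrees with an independent implementation", {
  sim <- evolve_alignment("((a:0.1,b:0.15):0.05,(c:0.2,d:0.1):0.05);",
                          kappa = 2, length = 2000, seed = 12)
  D <- k2p_matrix(sim$alignment)
  bin <- ape::as.DNAbin(lapply(strsplit(tolower(sim$alignment), ""),
                               identity))
  D_ape <- as.matrix(ape::dist.dna(bin, model = "K80"))
  expect_equal(D, D_ape[rownames(D), colnames(D)], tolerance = 1e-10)
  expect_true(isSymmetric(D))
  expect_true(all(diag(D) == 0))
})

test_that("neighbor joining is exact on additive matrices", {
  # 4-taxon tree ((A,B),(C,D)) with chosen branch lengths, by path sums
  bl <- c(A = 0.10, B = 0.07, C = 0.05, D = 0.12, internal = 0.04)
  D <- matrix(0, 4, 4, dimnames = list(LETTERS[1:4], LETTERS[1:4]))
  D["A", "B"] <- D["B", "A"] <- bl["A"] + bl["B"]
  D["C", "D"] <- D["D", "C"] <- bl["C"] + bl["D"]
  for (x in c("A", "B")) for (y in c("C", "D")) {
    D[x, y] <- D[y, x] <- bl[x] + bl[y] + bl["internal"]
  }
  tree <- nj_tree(D)
  expect_equal(attr(tree, "clamped_edges"), 0L)
  # topology: A,B form a cherry apart from C,D
  expect_true(ape::is.monophyletic(ape::root(tree, "C"), c("A", "B")))
  # branch lengths recovered: pairwise tree distances equal the input
  patristic <- ape::cophenetic.phylo(tree)[rownames(D), colnames(D)]
  expect_equal(patristic, D, tolerance = 1e-10)

  # random additive matrices from random trees
  for (i in 1:5) {
    set.seed(600 + i)
    tr <- ape::rtree(6, br = function(n) runif(n, 0.05, 0.3))
    tr <- ape::unroot(tr)
    D_i <- ape::cophenetic.phylo(tr)
    rec <- nj_tree(D_i)
    expect_equal(ape::dist.topo(ape::unroot(rec), tr), structure(0, names = "PH85"),
                 ignore_attr = TRUE)
    expect_equal(ape::cophenetic.phylo(rec)[rownames(D_i), colnames(D_i)],
                 D_i, tolerance = 1e-8)
  }

  # 3 taxa: closed-form three-point branch lengths
  D3 <- matrix(c(0, 0.3, 0.4,
                 0.3, 0, 0.5,
                 0.4, 0.5, 0), 3, 3,
               dimnames = list(c("x", "y", "z"), c("x", "y", "z")))
  t3 <- nj_tree(D3)
  el <- stats::setNames(t3$edge.length, t3$tip.label[t3$edge[, 2]])
  expect_equal(unname(el["x"]), (0.3 + 0.4 - 0.5) / 2)
  expect_equal(unname(el["y"]), (0.3 + 0.5 - 0.4) / 2)
  expect_equal(unname(el["z"]), (0.4 + 0.5 - 0.3) / 2)

  expect_error(nj_tree(matrix(c(0, 1, 2, 0), 2, 2)), "3 taxa")
  bad <- D3; bad[1, 2] <- 9
  expect_error(nj_tree(bad), "symmetric")
})

test_that("bootstrap support is deterministic and saturates on clean
           splits", {
  sim <- evolve_alignment(
    "((a:0.02,b:0.02):0.3,(c:0.02,d:0.02):0.3);",
    kappa = 2, length = 1500, seed = 19)
  bs1 <- bootstrap_support(sim$alignment, replicates = 50, seed = 7)
  bs2 <- bootstrap_support(sim$alignment, replicates = 50, seed = 7)
  expect_identical(bs1$support, bs2$support)
  expect_identical(write_newick(bs1$tree), write_newick(bs2$tree))
  # the a|b vs c|d split is unambiguous at this divergence
  expect_gte(max(bs1$support, na.rm = TRUE), 99)
  expect_equal(bs1$n_used + bs1$n_skipped, 50L)

  # replicates = 1: supports only 0 or 100
  bs3 <- bootstrap_support(sim$alignment, replicates = 1, seed = 3)
  expect_true(all(bs3$support[-1] %in% c(0, 100)))
})

test_that("newick output round-trips with branch lengths and labels", {
  s <- "(A:0.1,B:0.2,C:0.3);"
  tree <- read_newick(text = s)
  expect_equal(write_newick(tree), s)

  for (i in 1:5) {
    set.seed(700 + i)
    tr <- ape::rtree(7)
    tr$node.label <- as.character(sample(0:100, tr$Nnode))
    back <- read_newick(text = write_newick(tr))
    expect_equal(back$tip.label, tr$tip.label)
    expect_equal(back$node.label, tr$node.label)
    expect_equal(back$edge.length, tr$edge.length, tolerance = 1e-8)
  }
})
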