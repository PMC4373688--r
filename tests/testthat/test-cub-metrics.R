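test_that("RSCU matches the definition on equal, pooled and absent usage", {
  # equal counts in every family -> all RSCU exactly 1
  rt <- rscu(make_extreme_cds("equal_usage"))
  expect_true(all(abs(rt$rscu - 1) < 1e-12))

  # pooled Leu counts: RSCU(CTG) = 6 * 143 / 269
  leu <- c(TTA = 9, TTG = 31, CTA = 17, CTC = 39, CTG = 143, CTT = 30)
  rt2 <- rscu(leu)
  expect_equal(rt2$rscu[rt2$codon == "CTG"], 6 * 143 / 269,
               tolerance = 1e-12)
  expect_equal(round(rt2$rscu[rt2$codon == "CTG"], 2), 3.19)

  # an unused codon in a used family scores 0; absent families are NA
  ile <- c(ATC = 61, ATT = 11)  # ATA absent
  rt3 <- rscu(ile)
  expect_equal(rt3$rscu[rt3$codon == "ATA"], 0)
  expect_true(all(is.na(rt3$rscu[rt3$amino_acid == "Leu"])))
})

test_that("RSCU sums to the family degeneracy for every present family", {
  for (i in 1:8) {
    rt <- rscu(generate_cds(120, seed = 400 + i))
    sums <- as.numeric(tapply(rt$rscu, rt$amino_acid, sum))
    deg <- as.numeric(tapply(rt$degeneracy, rt$amino_acid, unique))
    present <- !is.na(sums)
    expect_equal(sums[present], deg[present], tolerance = 1e-9)
  }
})

test_that("ENC hits its analytic endpoints and component values", {
  expect_identical(as.numeric(enc(make_extreme_cds("single_codon"))), 20)
  expect_identical(as.numeric(enc(make_extreme_cds("equal_usage"))), 61)

  # a 2-fold family with counts (3, 1): F = 0.75^2 + 0.25^2 = 0.625
  counts <- c(TTT = 3, TTC = 1)
  e <- enc(c(counts, ATC = 1, GTA = 1, GTC = 1, CTA = 1))
  expect_equal(unname(attr(e, "F")["F2"]), 0.625)

  # Wright's corrected estimator differs at finite n but stays in range
  cds <- generate_cds(300, seed = 21)
  e1 <- as.numeric(enc(cds))
  e2 <- as.numeric(enc(cds, estimator = "wright"))
  expect_true(e2 >= 20 - 1e-9 && e2 <= 61 + 1e-9)
  expect_false(identical(e1, e2))
})

test_that("ENC is invariant to codon order and synonym relabeling, and
           decreases as usage concentrates", {
  cds <- generate_cds(200, seed = 31)
  counts <- count_codons(cds, include_stop = FALSE)
  body <- cds$codons[2:(length(cds$codons) - 1)]
  set.seed(1)
  shuffled <- paste(c("ATG", sample(body),
                      cds$codons[length(cds$codons)]), collapse = "")
  expect_equal(as.numeric(enc(validate_cds(shuffled))),
               as.numeric(enc(counts)))

  # relabel synonyms within Phe: swap TTT and TTC counts
  counts2 <- counts
  counts2[c("TTT", "TTC")] <- counts[c("TTC", "TTT")]
  expect_equal(as.numeric(enc(counts2)), as.numeric(enc(counts)))

  # concentrating a 2-fold family monotonically lowers ENC
  base <- count_codons(make_extreme_cds("equal_usage"),
                       include_stop = FALSE)
  encs <- sapply(seq(0.5, 1, by = 0.1), function(p) {
    cc <- base
    tot <- cc[["TTT"]] + cc[["TTC"]]
    cc[["TTT"]] <- p * tot
    cc[["TTC"]] <- (1 - p) * tot
    as.numeric(enc(cc))
  })
  expect_true(all(diff(encs) < 0))
})

test_that("F3 imputation applies when the Ile family is absent", {
  counts <- count_codons(make_extreme_cds("equal_usage"),
                         include_stop = FALSE)
  counts[c("ATA", "ATC", "ATT")] <- 0
  e <- enc(counts)
  expect_true(attr(e, "imputed_F3"))
  expect_equal(unname(attr(e, "F")["F3"]),
               mean(unname(attr(e, "F")[c("F2", "F4")])))
})

test_that("Fop follows its definition, tie-breaks and explicit sets", {
  expect_equal(as.numeric(fop(make_extreme_cds("single_codon"))), 1)

  # uniform usage in 2-fold families: ties go to one codon holding half
  two_fold <- c(TTT = 5, TTC = 5, CAA = 5, CAG = 5)
  expect_equal(as.numeric(fop(two_fold)), 0.5)

  # pooled reference counts under the per-gene definition
  rt <- tp53_reference("rscu")
  counts <- stats::setNames(rt$n, rt$codon)
  expect_equal(as.numeric(fop(counts)), 1517 / 2988, tolerance = 1e-12)

  # an explicit optimal set equals a naive count ratio
  cds <- generate_cds(250, seed = 41)
  counts_g <- count_codons(cds, include_stop = FALSE)
  opt <- c("CTG", "GCC", "TTC")
  syn <- genetic_code()$degenerate_codons
  naive <- sum(counts_g[opt]) / sum(counts_g[syn])
  expect_equal(as.numeric(fop(cds, optimal_set = opt)), naive)
})

test_that("RCBS matches a brute-force oracle and its null case", {
  # codon counts exactly at positional independence -> RCBS 0:
  # all 64 codons once with uniform positional frequencies
  counts_null <- stats::setNames(rep(1, 64), genetic_code()$codon_to_aa |>
                                   names())
  pos_uniform <- matrix(0.25, 3, 4,
                        dimnames = list(NULL, c("A", "C", "G", "T")))
  expect_equal(as.numeric(rcbs_from_counts(counts_null, pos_uniform)), 0,
               tolerance = 1e-12)
  expect_equal(as.numeric(rcbs("ATGAAAAAATAA")),
               unname(rcbs_oracle("ATGAAAAAATAA")))

  # frozen brute-force value for the 4-codon toy gene
  expect_equal(as.numeric(rcbs("ATGAAAAAATAA")), 0.8898816,
               tolerance = 1e-6)

  # oracle equivalence and order invariance on random genes
  for (i in 1:5) {
    cds <- generate_cds(80, seed = 500 + i)
    expect_equal(as.numeric(rcbs(cds)), unname(rcbs_oracle(cds$sequence)),
                 tolerance = 1e-12)
    body <- cds$codons[2:(length(cds$codons) - 1)]
    set.seed(i)
    shuf <- paste(c("ATG", sample(body), cds$codons[length(cds$codons)]),
                  collapse = "")
    expect_equal(as.numeric(rcbs(shuf)), as.numeric(rcbs(cds)),
                 tolerance = 1e-12)
  }
})

test_that("per-gene index summary picks the dominant codon", {
  # force CTG to dominate leucine and everything else
  probs <- stats::setNames(rep(1, 59), genetic_code()$degenerate_codons)
  probs["CTG"] <- 50
  aa_w <- stats::setNames(rep(1, 18), names(genetic_code()$degenerate_families))
  aa_w["L"] <- 10
  cds <- generate_cds(300, codon_probs = probs, aa_weights = aa_w, seed = 3)
  idx <- cub_indices(cds)
  expect_equal(idx$highest_rscu_codon, "CTG")
  expect_equal(idx$highest_rscu_aa, "Leu")
  expect_true(idx$fop >= 0 && idx$fop <= 1)
  expect_true(idx$enc >= 20 && idx$enc <= 61)
  expect_gt(idx$rcbs, -1)
})
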