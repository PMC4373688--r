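make_fixture_fasta <- function(n = 5, n_codons = 200) {
  genes <- lapply(seq_len(n), function(i) {
    generate_cds(n_codons, seed = 1100 + i, id = sprintf("g%02d", i))
  })
  write_temp_fasta(stats::setNames(
    lapply(genes, `[[`, "sequence"),
    vapply(genes, `[[`, character(1), "id")))
}

test_that("codon_usage assembles consistent per-gene and matrix views", {
  fa <- make_fixture_fasta(4)
  fit <- codon_usage(fa)
  expect_s3_class(fit, "cub_analysis")
  expect_equal(length(fit$genes), 4L)
  expect_equal(nrow(fit$indices), 4L)
  expect_equal(dim(fit$rscu_matrix), c(4L, 59L))

  # matrix agrees with the per-gene rscu() calls
  g1 <- fit$genes[[1]]
  rt <- rscu(g1)
  expect_equal(unname(fit$rscu_matrix[g1$id, rt$codon]), rt$rscu)
  # indices agree with direct computation
  expect_equal(fit$indices$enc[1], as.numeric(enc(g1)))
  expect_equal(fit$indices$rcbs[1], as.numeric(rcbs(g1)))

  # invalid records are dropped but reported
  seqs <- c(ok = g1$sequence, bad = "ATGAA")
  fit2 <- codon_usage(seqs)
  expect_equal(length(fit2$genes), 1L)
  expect_equal(fit2$validation$reason[fit2$validation$id == "bad"],
               "bad_length")
  expect_error(codon_usage(c(bad = "ATGAA")), "no valid")
})

test_that("summary and print methods run and report the key statistics", {
  fit <- codon_usage(make_fixture_fasta(5))
  expect_output(print(fit), "5 of 5 sequences valid")
  s <- summary(fit)
  expect_s3_class(s, "summary.cub_analysis")
  expect_equal(s$indices_summary$enc[1], mean(fit$indices$enc))
  expect_output(print(s), "Pearson ENC ~ GC3s")

  grDevices::pdf(NULL)
  on.exit(grDevices::dev.off())
  expect_invisible(plot(fit, type = "enc_gc3s"))
  expect_invisible(plot(fit, type = "rcbs"))
  plot(fit, type = "rscu_heatmap")
})

test_that("rscu_report pooled mode matches rscu() on summed counts", {
  fit <- codon_usage(make_fixture_fasta(3))
  pooled <- rscu_report(fit, mode = "pooled")
  total_counts <- colSums(t(vapply(fit$genes, function(g)
    count_codons(g, include_stop = FALSE)[genetic_code()$degenerate_codons],
    numeric(59))))
  rt <- rscu(total_counts)
  m <- merge(pooled, rt[, c("codon", "rscu")], by = "codon")
  expect_equal(m$rscu.x, m$rscu.y, tolerance = 1e-12)

  mean_mode <- rscu_report(fit, mode = "mean")
  ctg <- vapply(fit$genes, function(g) {
    t <- rscu(g); t$rscu[t$codon == "CTG"]
  }, numeric(1))
  expect_equal(mean_mode$rscu[mean_mode$codon == "CTG"],
               mean(ctg, na.rm = TRUE))
})

test_that("run_pipeline writes deterministic, reproducible outputs", {
  fa <- make_fixture_fasta(4, n_codons = 150)
  sim <- evolve_alignment("((a:0.05,b:0.05):0.1,(c:0.05,d:0.05):0.1);",
                          kappa = 2, length = 600, seed = 17)
  aln_fa <- write_temp_fasta(as.list(sim$alignment))

  out1 <- tempfile("run1_")
  out2 <- tempfile("run2_")
  r1 <- run_pipeline(fa, out1, alignment = aln_fa, bootstrap = 20,
                     seed = 99)
  r2 <- run_pipeline(fa, out2, alignment = aln_fa, bootstrap = 20,
                     seed = 99)

  expect_true(all(file.exists(unlist(r1$paths))))
  for (nm in setdiff(names(r1$paths), "manifest")) {
    expect_identical(readLines(r1$paths[[nm]]), readLines(r2$paths[[nm]]),
                     info = nm)
  }

  # every serialized number reproduces the owning operation
  idx <- utils::read.delim(r1$paths$indices)
  expect_equal(idx$enc, round(r1$analysis$indices$enc, 4))
  comp <- utils::read.delim(r1$paths$composition)
  expect_equal(comp$GC_pct[1:4], round(r1$analysis$composition$GC_pct, 4))

  # composition table carries mean/sd rows
  expect_equal(tail(comp$id, 2), c("mean", "sd"))
  expect_equal(tail(comp$GC_pct, 2)[1],
               round(mean(r1$analysis$composition$GC_pct), 4))

  # the tree file parses and carries the four taxa
  tr <- read_newick(r1$paths$tree)
  expect_setequal(tr$tip.label, c("a", "b", "c", "d"))

  # fewer than 3 genes: comparative stages skipped with a note
  fa1 <- make_fixture_fasta(1)
  r3 <- run_pipeline(fa1, tempfile("run3_"))
  expect_true(any(grepl("fewer than 3", r3$manifest$notes)))
  expect_null(r3$paths$correlation)
})
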