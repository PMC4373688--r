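# shared fixtures and independent oracles for the test suite

# write a small FASTA file in a tempdir, return the path
write_temp_fasta <- function(seqs, wrap = FALSE) {
  path <- tempfile(fileext = ".fasta")
  lines <- unlist(lapply(names(seqs), function(nm) {
    s <- seqs[[nm]]
    body <- if (wrap) {
      substring(s, seq(1, nchar(s), 60), pmin(seq(60, nchar(s) + 59, 60),
                                              nchar(s)))
    } else {
      s
    }
    c(paste0(">", nm), body)
  }))
  writeLines(lines, path)
  path
}

# brute-force RCBS oracle: enumerate codons of a stop-stripped CDS string
# and apply the definition term by term, independent of the package path
rcbs_oracle <- function(cds_string) {
  n <- nchar(cds_string)
  codons <- substring(cds_string, seq(1, n, 3), seq(3, n, 3))
  if (codons[length(codons)] %in% c("TAA", "TAG", "TGA")) {
    codons <- codons[-length(codons)]
  }
  ot <- length(codons)
  f <- lapply(1:3, function(p) {
    tab <- table(substr(codons, p, p))
    as.numeric(tab[c("A", "C", "G", "T")]) / ot -> v
    names(v) <- c("A", "C", "G", "T")
    v[is.na(v)] <- 0
    v
  })
  acc <- 0
  for (cd in unique(codons)) {
    oc <- sum(codons == cd)
    e <- ot * f[[1]][substr(cd, 1, 1)] * f[[2]][substr(cd, 2, 2)] *
      f[[3]][substr(cd, 3, 3)]
    w <- (oc - e) / e
    acc <- acc + oc * log(1 + w)
  }
  exp(acc / ot) - 1
}

# random valid CDS string (uniform codon usage), for property loops
random_cds_string <- function(n_codons, seed) {
  codonbias::generate_cds(n_codons, seed = seed)$sequence
}

# apply a single random corruption to a valid CDS string
corrupt_cds <- function(s, kind = c("bad_start", "bad_stop", "bad_length",
                                    "ambiguous_base")) {
  kind <- match.arg(kind)
  switch(kind,
    bad_start = paste0("CTG", substr(s, 4, nchar(s))),
    bad_stop = paste0(substr(s, 1, nchar(s) - 3), "AAA"),
    bad_length = substr(s, 1, nchar(s) - 1),
    ambiguous_base = {
      i <- max(4, nchar(s) %/% 2)
      paste0(substr(s, 1, i - 1), "N", substr(s, i + 1, nchar(s)))
    })
}
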