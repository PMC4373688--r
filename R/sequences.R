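#' Read candidate coding sequences from a FASTA file
#'
#' Reads a (possibly line-wrapped) multi-record FASTA file, uppercases the
#' sequences and maps U to T. No validation is performed beyond parsing; use
#' [validate_cds()] / [validate_cds_set()] to enforce the CDS invariants.
#'
#' @param path Path to a FASTA file.
#' @return A named character vector of sequences, one per record, in file
#'   order. Names are the first whitespace-delimited token of each header;
#'   the full headers are kept in the `"description"` attribute.
#' @examples
#' fa <- tempfile(fileext = ".fasta")
#' writeLines(c(">g1 toy", "ATGAAATAA", ">g2", "ATGTGCTGA"), fa)
#' read_cds_fasta(fa)
#' @export
read_cds_fasta <- function(path) {
  if (!file.exists(path)) {
    stop("cannot read FASTA file: ", path)
  }
  set <- Biostrings::readBStringSet(path)
  if (length(set) == 0L) {
    stop("empty FASTA input: ", path, " contains no records")
  }
  seqs <- toupper(as.character(set))
  seqs <- gsub("U", "T", seqs, fixed = TRUE)
  headers <- names(set)
  ids <- vapply(strsplit(headers, "[ \t]+"), `[[`, character(1L), 1L)
  names(seqs) <- ids
  attr(seqs, "description") <- headers
  seqs
}

#' Write coding sequences to FASTA
#'
#' @param seqs Named character vector of sequences, or a list of `cds`
#'   objects.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_cds_fasta <- function(seqs, path) {
  if (is.list(seqs)) {
    nm <- vapply(seqs, function(x) x$id, character(1L))
    seqs <- stats::setNames(vapply(seqs, function(x) x$sequence,
                                   character(1L)), nm)
  }
  set <- Biostrings::BStringSet(seqs)
  Biostrings::writeXStringSet(set, path, width = 70L)
  invisible(path)
}

#' Validate one coding sequence
#'
#' Enforces the CDS invariants: only A/C/G/T after normalisation, length a
#' multiple of three, ATG start codon, stop codon (TAA/TAG/TGA) at the end.
#' Lowercase letters and U are normalised; any other IUPAC ambiguity code is
#' rejected.
#'
#' @param sequence A single DNA string.
#' @param id Identifier carried on the returned object.
#' @param species Optional species label (defaults to `id`).
#' @return An object of class `cds`: a list with `id`, `species`,
#'   `sequence`, `codons` (character vector of in-frame triplets) and
#'   `length_bp`. On failure an error of class `cds_validation_error` is
#'   signalled whose `reason` field is one of `"ambiguous_base"`,
#'   `"bad_length"`, `"bad_start"`, `"bad_stop"`.
#' @examples
#' validate_cds("ATGAAATAA", id = "toy")
#' try(validate_cds("ATGANATAA", id = "bad"))
#' @export
validate_cds <- function(sequence, id = "cds", species = id) {
  stopifnot(is.character(sequence), length(sequence) == 1L)
  if (!nzchar(sequence)) {
    cds_invalid(id, "bad_length", "sequence is empty")
  }
  seq <- gsub("U", "T", toupper(sequence), fixed = TRUE)
  if (grepl("[^ACGT]", seq)) {
    cds_invalid(id, "ambiguous_base",
                "sequence contains characters outside {A,C,G,T}")
  }
  n <- nchar(seq)
  if (n %% 3L != 0L) {
    cds_invalid(id, "bad_length", sprintf(
      "length %d is not a multiple of 3", n))
  }
  codons <- substring(seq, seq.int(1L, n, 3L), seq.int(3L, n, 3L))
  if (codons[1L] != "ATG") {
    cds_invalid(id, "bad_start", "first codon is not ATG")
  }
  if (!(codons[length(codons)] %in% genetic_code()$stop_codons)) {
    cds_invalid(id, "bad_stop", "last codon is not a stop codon")
  }
  structure(
    list(id = id, species = species, sequence = seq,
         codons = codons, length_bp = n),
    class = "cds"
  )
}

cds_invalid <- function(id, reason, message) {
  cond <- structure(
    class = c("cds_validation_error", "error", "condition"),
    list(message = sprintf("invalid CDS '%s' [%s]: %s", id, reason, message),
         call = NULL, id = id, reason = reason)
  )
  stop(cond)
}

#' @export
print.cds <- function(x, ...) {
  cat(sprintf("<cds> %s (%s): %d bp, %d codons\n",
              x$id, x$species, x$length_bp, length(x$codons)))
  invisible(x)
}

#' Validate a set of sequences, keeping a per-record report
#'
#' @param seqs Named character vector (as from [read_cds_fasta()]).
#' @param species Optional character vector of species labels, recycled
#'   against `seqs`.
#' @return A list with `valid` (list of `cds` objects) and `report`
#'   (data.frame with columns `id`, `status`, `reason`).
#' @export
validate_cds_set <- function(seqs, species = NULL) {
  ids <- names(seqs)
  if (is.null(ids)) ids <- sprintf("seq%d", seq_along(seqs))
  if (is.null(species)) species <- ids
  species <- rep_len(species, length(seqs))
  valid <- list()
  status <- character(length(seqs))
  reason <- character(length(seqs))
  for (i in seq_along(seqs)) {
    res <- tryCatch(validate_cds(seqs[[i]], id = ids[i],
                                 species = species[i]),
                    cds_validation_error = function(e) e)
    if (inherits(res, "cds")) {
      valid[[length(valid) + 1L]] <- res
      status[i] <- "valid"
      reason[i] <- ""
    } else {
      status[i] <- "invalid"
      reason[i] <- res$reason
    }
  }
  list(valid = valid,
       report = data.frame(id = ids, status = status, reason = reason,
                           stringsAsFactors = FALSE))
}

#' Count in-frame codons
#'
#' Counts every non-overlapping triplet of a CDS in reading frame. With
#' `include_stop = FALSE` the terminal stop codon is excluded and the total
#' reduced by one; this is the convention used for RSCU/ENC/Fop/RCBS, while
#' composition tables keep the stop codon by default.
#'
#' @param x A `cds` object, or a single in-frame DNA string (length a
#'   multiple of 3).
#' @param include_stop Keep the terminal stop codon? Default `TRUE`.
#' @return Named integer vector over all 64 codons (alphabetical), with
#'   attribute `"total"` = number of codons counted.
#' @examples
#' count_codons(validate_cds("ATGAAATAA"))["TAA"]
#' attr(count_codons("ATGAAATAA", include_stop = FALSE), "total")  # 2
#' @export
count_codons <- function(x, include_stop = TRUE) {
  codons <- as_codons(x)
  if (!include_stop &&
      codons[length(codons)] %in% genetic_code()$stop_codons) {
    codons <- codons[-length(codons)]
  }
  counts <- integer(64L)
  names(counts) <- all_codons()
  tab <- table(codons)
  counts[names(tab)] <- as.integer(tab)
  attr(counts, "total") <- length(codons)
  counts
}

# accept a cds object or an in-frame DNA string
as_codons <- function(x) {
  if (inherits(x, "cds")) {
    return(x$codons)
  }
  stopifnot(is.character(x), length(x) == 1L)
  seq <- gsub("U", "T", toupper(x), fixed = TRUE)
  n <- nchar(seq)
  if (n == 0L || n %% 3L != 0L) {
    stop("sequence length must be a positive multiple of 3")
  }
  if (grepl("[^ACGT]", seq)) {
    stop("sequence contains characters outside {A,C,G,T}")
  }
  substring(seq, seq.int(1L, n, 3L), seq.int(3L, n, 3L))
}
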