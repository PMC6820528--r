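#' Parse a coding sequence into codons
#'
#' Normalizes a nucleotide string (uppercase, U to T), checks that it is a
#' clean open reading frame, and partitions it into codons. Internal stop
#' codons are tolerated but flagged with a warning, since a recoded variant
#' must never introduce one silently.
#'
#' @param sequence A single nucleotide string over A, C, G, T, U (case
#'   insensitive).
#' @param id Identifier for the sequence.
#' @return An object of class `coding_sequence`: a list with elements `id`,
#'   `nt` (normalized sequence) and `codons` (character vector of length-3
#'   strings).
#' @examples
#' cds <- parse_cds("auggctTAA", id = "demo")
#' cds$codons
#' @export
parse_cds <- function(sequence, id = "cds") {
  stopifnot(is.character(sequence), length(sequence) == 1L, nzchar(sequence))
  nt <- toupper(gsub("\\s", "", sequence))
  nt <- chartr("U", "T", nt)
  bad <- gsub("[ACGT]", "", nt)
  if (nzchar(bad)) {
    stop("invalid-alphabet: sequence '", id, "' contains non-ACGTU characters: ",
         paste(unique(strsplit(bad, "")[[1]]), collapse = ","), call. = FALSE)
  }
  n <- nchar(nt)
  if (n %% 3L != 0L) {
    stop("frame-error: sequence '", id, "' has length ", n,
         ", not divisible by 3", call. = FALSE)
  }
  codons <- substring(nt, seq(1L, n, by = 3L), seq(3L, n, by = 3L))
  internal_stop <- which(codons %in% STOP_CODONS)
  internal_stop <- internal_stop[internal_stop < length(codons)]
  if (length(internal_stop)) {
    warning("sequence '", id, "' contains internal stop codon(s) at codon position(s) ",
            paste(internal_stop, collapse = ","), " (1-based)", call. = FALSE)
  }
  structure(list(id = id, nt = nt, codons = codons),
            class = "coding_sequence")
}

#' @export
print.coding_sequence <- function(x, ...) {
  cat("<coding_sequence> ", x$id, ": ", nchar(x$nt), " nt / ",
      length(x$codons), " codons\n", sep = "")
  invisible(x)
}

#' Read coding sequences from a FASTA file
#'
#' @param path Path to a FASTA file of in-frame coding sequences.
#' @return A named list of [parse_cds()] objects, one per record.
#' @export
read_cds_fasta <- function(path) {
  recs <- Biostrings::readBStringSet(path)
  ids <- sub("\\s.*$", "", names(recs))
  out <- lapply(seq_along(recs), function(i) parse_cds(as.character(recs[[i]]), id = ids[i]))
  stats::setNames(out, ids)
}

#' Write coding sequences to a FASTA file
#'
#' @param cds_list A `coding_sequence` or list of them.
#' @param path Output path.
#' @export
write_cds_fasta <- function(cds_list, path) {
  if (inherits(cds_list, "coding_sequence")) cds_list <- list(cds_list)
  seqs <- Biostrings::DNAStringSet(vapply(cds_list, `[[`, "", "nt"))
  names(seqs) <- vapply(cds_list, `[[`, "", "id")
  Biostrings::writeXStringSet(seqs, path)
  invisible(path)
}

#' Translate a coding sequence
#'
#' @param cds A `coding_sequence`.
#' @return Single amino-acid string (stops as `*`).
#' @export
translate_cds <- function(cds) {
  stopifnot(inherits(cds, "coding_sequence"))
  paste(GENETIC_CODE_TBL[cds$codons], collapse = "")
}

#' GC composition of a coding sequence
#'
#' Overall GC percentage and GC percentage restricted to third codon
#' positions (GC3), the positions where synonymous recoding acts.
#'
#' @param cds A `coding_sequence`, or a plain nucleotide string (for which
#'   `gc3_pct` is `NA` unless the length is a multiple of 3).
#' @return A tibble with columns `gene_id`, `gc_pct`, `gc3_pct`.
#' @export
composition <- function(cds) {
  if (is.character(cds)) {
    nt0 <- chartr("U", "T", toupper(gsub("\\s", "", cds)))
    cds <- list(id = "sequence", nt = nt0)
  }
  nt <- strsplit(cds$nt, "")[[1]]
  gc <- 100 * sum(nt %in% c("G", "C")) / length(nt)
  gc3 <- if (length(nt) %% 3L == 0L) {
    third <- nt[seq(3L, length(nt), by = 3L)]
    100 * sum(third %in% c("G", "C")) / length(third)
  } else NA_real_
  tibble::tibble(gene_id = cds$id, gc_pct = gc, gc3_pct = gc3)
}

#' Divergence between two colinear synonymous variants
#'
#' Position-by-position comparison of two equal-length coding sequences,
#' reported as percent mismatched nucleotides, percent mismatched codons and
#' whether the encoded proteins are identical. No alignment is performed:
#' synonymous recodings are colinear by construction.
#'
#' @param a,b `coding_sequence` objects of equal nucleotide length.
#' @return A tibble with `nt_pct`, `codon_pct`, `aa_identical`.
#' @examples
#' sequence_divergence(parse_cds("ATGGCT"), parse_cds("ATGGCC"))
#' @export
sequence_divergence <- function(a, b) {
  stopifnot(inherits(a, "coding_sequence"), inherits(b, "coding_sequence"))
  if (nchar(a$nt) != nchar(b$nt)) {
    stop("not-comparable: sequences differ in length (", nchar(a$nt), " vs ",
         nchar(b$nt), " nt); divergence assumes colinear variants", call. = FALSE)
  }
  na <- strsplit(a$nt, "")[[1]]
  nb <- strsplit(b$nt, "")[[1]]
  nt_pct <- 100 * sum(na != nb) / length(na)
  codon_pct <- 100 * sum(a$codons != b$codons) / length(a$codons)
  tibble::tibble(
    nt_pct = nt_pct,
    codon_pct = codon_pct,
    aa_identical = identical(translate_cds(a), translate_cds(b))
  )
}
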