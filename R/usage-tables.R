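#' Construct a codon-usage table
#'
#' A codon-usage table holds one non-negative count (or frequency) per sense
#' codon, e.g. genomic usage or usage derived from a transcriptome. Missing
#' sense codons are an error; stop codons are optional and ignored by the
#' downstream statistics.
#'
#' @param x A data frame with columns `codon` and `count`, or a named numeric
#'   vector keyed by codon.
#' @param source Label recording where the usage statistics come from.
#' @return A tibble of class `codon_usage` with columns `codon`, `count` and
#'   attribute `source`.
#' @export
codon_usage_table <- function(x, source = "unknown") {
  if (is.numeric(x) && !is.null(names(x))) {
    x <- tibble::tibble(codon = names(x), count = unname(x))
  }
  stopifnot(is.data.frame(x), all(c("codon", "count") %in% names(x)))
  tbl <- tibble::as_tibble(x[, c("codon", "count")])
  tbl$codon <- chartr("U", "T", toupper(tbl$codon))
  if (anyDuplicated(tbl$codon)) stop("duplicate codons in usage table", call. = FALSE)
  missing_sense <- setdiff(SENSE_CODONS, tbl$codon)
  if (length(missing_sense)) {
    stop("usage table must cover all 61 sense codons; missing: ",
         paste(utils::head(missing_sense, 5), collapse = ","),
         if (length(missing_sense) > 5) " ...", call. = FALSE)
  }
  tbl <- tbl[tbl$codon %in% SENSE_CODONS, ]
  if (any(!is.finite(tbl$count)) || any(tbl$count < 0)) {
    stop("usage counts must be finite and >= 0", call. = FALSE)
  }
  fam <- GENETIC_CODE_TBL[tbl$codon]
  fam_sum <- tapply(tbl$count, fam, sum)
  if (any(fam_sum == 0)) {
    warning("amino-acid families with all-zero usage: ",
            paste(names(fam_sum)[fam_sum == 0], collapse = ","), call. = FALSE)
  }
  attr(tbl, "source") <- source
  class(tbl) <- c("codon_usage", class(tbl))
  tbl
}

#' Construct a codon-pair-usage table
#'
#' Holds non-negative counts for ordered sense-codon pairs. Pairs absent from
#' the input are taken as zero.
#'
#' @param x A data frame with columns `codon1`, `codon2`, `count`.
#' @param source Label for the origin of the counts.
#' @return A tibble of class `codon_pair_usage`.
#' @export
codon_pair_usage_table <- function(x, source = "unknown") {
  stopifnot(is.data.frame(x), all(c("codon1", "codon2", "count") %in% names(x)))
  tbl <- tibble::as_tibble(x[, c("codon1", "codon2", "count")])
  tbl$codon1 <- chartr("U", "T", toupper(tbl$codon1))
  tbl$codon2 <- chartr("U", "T", toupper(tbl$codon2))
  keep <- tbl$codon1 %in% SENSE_CODONS & tbl$codon2 %in% SENSE_CODONS
  if (!all(keep)) {
    stop("pair-usage table keyed by non-sense codons (stops or invalid codons)",
         call. = FALSE)
  }
  if (any(!is.finite(tbl$count)) || any(tbl$count < 0)) {
    stop("pair-usage counts must be finite and >= 0", call. = FALSE)
  }
  if (anyDuplicated(paste(tbl$codon1, tbl$codon2))) {
    stop("duplicate codon pairs in pair-usage table", call. = FALSE)
  }
  attr(tbl, "source") <- source
  class(tbl) <- c("codon_pair_usage", class(tbl))
  tbl
}

#' Read a codon-usage table from TSV
#'
#' Expects a header and columns `codon`, `count`.
#'
#' @param path TSV path.
#' @param source Optional label; defaults to the file name.
#' @export
read_usage_table <- function(path, source = basename(path)) {
  tbl <- utils::read.delim(path, stringsAsFactors = FALSE, check.names = FALSE)
  codon_usage_table(tbl, source = source)
}

#' Read a codon-pair-usage table from TSV
#'
#' Expects a header and columns `codon1`, `codon2`, `count`.
#'
#' @inheritParams read_usage_table
#' @export
read_pair_usage_table <- function(path, source = basename(path)) {
  tbl <- utils::read.delim(path, stringsAsFactors = FALSE, check.names = FALSE)
  codon_pair_usage_table(tbl, source = source)
}

#' Read a tRNA-abundance table from TSV
#'
#' Expects columns `codon` and `abundance` (relative tRNA level decoding each
#' codon). Returned as a named numeric vector usable with [annotate_track()].
#'
#' @param path TSV path.
#' @export
read_trna_table <- function(path) {
  tbl <- utils::read.delim(path, stringsAsFactors = FALSE, check.names = FALSE)
  stopifnot(all(c("codon", "abundance") %in% names(tbl)))
  codon <- chartr("U", "T", toupper(tbl$codon))
  stats::setNames(as.numeric(tbl$abundance), codon)
}

#' Write a codon-usage table to TSV
#' @param usage A `codon_usage` table.
#' @param path Output path.
#' @export
write_usage_table <- function(usage, path) {
  utils::write.table(as.data.frame(usage[, c("codon", "count")]), path,
                     sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
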