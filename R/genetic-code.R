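# Standard genetic code, keyed by DNA codon. Families are the synonymous
# codon sets per amino acid; stops are never part of an RSCU/CAI family.
GENETIC_CODE_TBL <- Biostrings::GENETIC_CODE

STOP_CODONS <- names(GENETIC_CODE_TBL)[GENETIC_CODE_TBL == "*"]
SENSE_CODONS <- names(GENETIC_CODE_TBL)[GENETIC_CODE_TBL != "*"]

# codons of the single-codon families (Met and Trp)
SINGLE_CODON_FAMILIES <- local({
  singles <- names(which(table(GENETIC_CODE_TBL[SENSE_CODONS]) == 1L))
  SENSE_CODONS[GENETIC_CODE_TBL[SENSE_CODONS] %in% singles]
})

#' Amino acid encoded by each sense codon
#'
#' @return A tibble with columns `codon` and `amino_acid` for the 61 sense
#'   codons of the standard genetic code.
#' @export
codon_families <- function() {
  tibble::tibble(codon = SENSE_CODONS,
                 amino_acid = unname(GENETIC_CODE_TBL[SENSE_CODONS]))
}
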