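#' Relative synonymous codon usage (RSCU)
#'
#' For codon c in synonymous family F, RSCU(c) = count(c) / mean count over
#' F. A value of 1 means no bias; single-codon families (ATG, TGG) are 1 by
#' definition. Families whose counts sum to zero yield `NA`.
#'
#' @param usage A [codon_usage_table()].
#' @return A tibble with columns `codon`, `amino_acid`, `rscu`.
#' @examples
#' u <- synthetic_usage_table(seed = 1)
#' compute_rscu(u)
#' @export
compute_rscu <- function(usage) {
  stopifnot(inherits(usage, "codon_usage"))
  fam <- codon_families()
  tbl <- dplyr::left_join(fam, tibble::as_tibble(usage), by = "codon")
  tbl <- dplyr::group_by(tbl, .data$amino_acid)
  tbl <- dplyr::mutate(
    tbl,
    rscu = if (dplyr::n() == 1L) 1
           else if (sum(.data$count) == 0) NA_real_
           else .data$count / mean(.data$count)
  )
  dplyr::ungroup(tbl)[, c("codon", "amino_acid", "rscu")]
}

#' Relative synonymous codon pair usage (RSCPU)
#'
#' The codon-pair analogue of RSCU: an ordered codon pair's count divided by
#' the mean count over all synonymous pairs encoding the same ordered
#' amino-acid pair. Pairs absent from the table count as zero; amino-acid
#' pair families with zero total yield `NA`.
#'
#' @param pair_usage A [codon_pair_usage_table()].
#' @return A tibble with `codon1`, `codon2`, `aa_pair`, `rscpu` covering all
#'   61 x 61 sense-codon pairs.
#' @export
compute_rscpu <- function(pair_usage) {
  stopifnot(inherits(pair_usage, "codon_pair_usage"))
  grid <- tidyr::expand_grid(codon1 = SENSE_CODONS, codon2 = SENSE_CODONS)
  grid <- dplyr::left_join(grid, tibble::as_tibble(pair_usage),
                           by = c("codon1", "codon2"))
  grid$count[is.na(grid$count)] <- 0
  grid$aa_pair <- paste0(GENETIC_CODE_TBL[grid$codon1], GENETIC_CODE_TBL[grid$codon2])
  grid <- dplyr::group_by(grid, .data$aa_pair)
  grid <- dplyr::mutate(
    grid,
    rscpu = if (sum(.data$count) == 0) NA_real_
            else .data$count / mean(.data$count)
  )
  dplyr::ungroup(grid)[, c("codon1", "codon2", "aa_pair", "rscpu")]
}

#' Codon adaptation index (CAI)
#'
#' Geometric mean, over a gene's codons, of each codon's relative
#' adaptiveness w(c) = count(c) / max count in its synonymous family. ATG,
#' TGG and stop codons are excluded from the mean (single-codon families
#' carry no information; stops are not decoded). Codons with zero usage
#' count receive w = `zero_w_num` / max-count rather than 0, so a single rare
#' codon cannot annihilate the geometric mean.
#'
#' @param cds A `coding_sequence`.
#' @param usage A [codon_usage_table()].
#' @param zero_w_num Numerator of the zero-count convention (default 0.5,
#'   i.e. half a count).
#' @return CAI as a single number in (0, 1].
#' @export
cai <- function(cds, usage, zero_w_num = 0.5) {
  stopifnot(inherits(cds, "coding_sequence"), inherits(usage, "codon_usage"))
  counts <- stats::setNames(usage$count, usage$codon)
  fam <- split(SENSE_CODONS, GENETIC_CODE_TBL[SENSE_CODONS])
  w <- unlist(lapply(fam, function(cods) {
    mx <- max(counts[cods])
    if (mx == 0) return(stats::setNames(rep(NA_real_, length(cods)), cods))
    wi <- counts[cods] / mx
    wi[wi == 0] <- zero_w_num / mx
    wi
  }))
  names(w) <- unlist(fam)
  keep <- setdiff(cds$codons, c(STOP_CODONS, SINGLE_CODON_FAMILIES))
  used <- cds$codons[cds$codons %in% keep]
  wv <- w[used]
  wv <- wv[!is.na(wv)]
  if (!length(wv)) {
    stop("undefined-CAI: no codons left after exclusions", call. = FALSE)
  }
  exp(mean(log(wv)))
}
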