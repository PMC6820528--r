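# Small deterministic fixtures built in code.

# usage table with hand-set Leu/Phe counts on top of a uniform background,
# so family statistics can be checked by hand counting
hand_usage <- function(leu = c(CTG = 3, CTA = 1, CTC = 0, CTT = 0, TTA = 0, TTG = 0),
                       phe = c(TTT = 10, TTC = 5)) {
  sense <- codon_families()$codon
  counts <- stats::setNames(rep(1, length(sense)), sense)
  counts[names(leu)] <- leu
  counts[names(phe)] <- phe
  codon_usage_table(counts, source = "hand")
}

uniform_usage <- function() {
  codon_usage_table(stats::setNames(rep(7, 61), codon_families()$codon),
                    source = "uniform")
}

uniform_pair_usage <- function(count = 2) {
  grid <- expand.grid(codon1 = codon_families()$codon,
                      codon2 = codon_families()$codon,
                      stringsAsFactors = FALSE)
  grid$count <- count
  codon_pair_usage_table(grid, source = "uniform")
}
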