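# Independent brute-force oracle for the built-in folding model: exhaustive
# enumeration of all pseudoknot-free structures, direct energy counting, and
# the Boltzmann-weighted pairing frequencies. Kept deliberately separate from
# the dynamic-programming implementation it checks.

oracle_can_pair <- function(a, b) {
  paste0(a, b) %in% c("AU", "UA", "GC", "CG", "GU", "UG")
}

# all structures of `seq` as lists of pairs c(i, j), 1-based
oracle_enumerate <- function(seq, min_loop = 3L) {
  s <- strsplit(chartr("Tt", "Uu", toupper(seq)), "")[[1]]
  rec <- function(i, j) {
    if (j - i < min_loop + 1L) return(list(list()))
    out <- rec(i, j - 1L)  # j unpaired
    for (k in i:(j - min_loop - 1L)) {
      if (!oracle_can_pair(s[k], s[j])) next
      left <- if (k > i) rec(i, k - 1L) else list(list())
      inner <- rec(k + 1L, j - 1L)
      for (L in left) for (I in inner) {
        out <- c(out, list(c(L, I, list(c(k, j)))))
      }
    }
    out
  }
  rec(1L, length(s))
}

oracle_energy <- function(pairs, pair_score = -1, stack_score = -1) {
  if (!length(pairs)) return(0)
  e <- length(pairs) * pair_score
  key <- vapply(pairs, function(p) paste(p, collapse = ","), "")
  for (p in pairs) {
    if (paste(p[1] + 1L, p[2] - 1L, sep = ",") %in% key) e <- e + stack_score
  }
  e
}

oracle_mfe <- function(seq, pair_score = -1, stack_score = -1, min_loop = 3L) {
  min(vapply(oracle_enumerate(seq, min_loop), oracle_energy, numeric(1),
             pair_score = pair_score, stack_score = stack_score))
}

oracle_pair_prob <- function(seq, pair_score = -1, stack_score = -1,
                             min_loop = 3L, beta = 1) {
  st <- oracle_enumerate(seq, min_loop)
  w <- exp(-beta * vapply(st, oracle_energy, numeric(1),
                          pair_score = pair_score, stack_score = stack_score))
  Z <- sum(w)
  p <- numeric(nchar(seq))
  for (si in seq_along(st)) {
    for (pr in st[[si]]) {
      p[pr[1]] <- p[pr[1]] + w[si] / Z
      p[pr[2]] <- p[pr[2]] + w[si] / Z
    }
  }
  p
}

random_rna <- function(n) paste(sample(c("A", "C", "G", "U"), n, replace = TRUE),
                                collapse = "")

# every sequence of length n over ACGU
all_rna_seqs <- function(n) {
  apply(do.call(expand.grid, rep(list(c("A", "C", "G", "U")), n)), 1, paste,
        collapse = "")
}
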