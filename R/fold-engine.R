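#' Configure a folding engine
#'
#' Two engines compute secondary structures and base-pairing probabilities:
#'
#' * `"builtin"` — a self-contained pseudoknot-free model scoring
#'   `pair_score` per canonical pair (AU, UA, GC, CG, GU, UG) and an extra
#'   `stack_score` per stacked pair, with hairpin loops of at least
#'   `min_loop` unpaired nucleotides. Energies are dimensionless score
#'   units. Probabilities come from the exact partition function of the same
#'   ensemble at inverse temperature `beta`. Deterministic, dependency-free,
#'   and verifiable against exhaustive enumeration at small lengths.
#' * `"external"` — an adapter around a thermodynamic folder implementing
#'   the RNAfold command-line contract (structure + free energy in kcal/mol,
#'   pairing probabilities from the ensemble). Use this when the physical
#'   free-energy scale matters.
#'
#' @param kind `"builtin"` or `"external"`.
#' @param min_loop Minimum hairpin loop length (nt), default 3.
#' @param pair_score,stack_score Built-in model scores, default -1 each.
#' @param beta Built-in inverse temperature (dimensionless), default 1.
#' @param temperature Folding temperature in Celsius for the external
#'   engine, default 37.
#' @param command External folder executable, default `RNAfold` on `PATH`.
#' @return A `fold_engine` object.
#' @export
fold_engine <- function(kind = c("builtin", "external"), min_loop = 3L,
                        pair_score = -1, stack_score = -1, beta = 1,
                        temperature = 37, command = "RNAfold") {
  kind <- match.arg(kind)
  structure(list(kind = kind, min_loop = as.integer(min_loop),
                 pair_score = pair_score, stack_score = stack_score,
                 beta = beta, temperature = temperature, command = command),
            class = "fold_engine")
}

as_rna <- function(seq) {
  if (inherits(seq, "coding_sequence")) seq <- seq$nt
  stopifnot(is.character(seq), length(seq) == 1L, nzchar(seq))
  chartr("Tt", "Uu", toupper(seq))
}

external_available <- function(engine) nzchar(Sys.which(engine$command))

run_rnafold <- function(engine, seqs, args = character()) {
  if (!external_available(engine)) {
    stop("engine-error: external folder '", engine$command,
         "' not found on PATH; install ViennaRNA or use fold_engine(\"builtin\")",
         call. = FALSE)
  }
  fa <- tempfile(fileext = ".fa")
  on.exit(unlink(fa), add = TRUE)
  writeLines(paste0(">", names(seqs), "\n", unname(seqs)), fa)
  out <- suppressWarnings(system2(
    engine$command, c("--noPS", paste0("-T", engine$temperature), args),
    stdin = fa, stdout = TRUE, stderr = FALSE))
  if (!is.null(attr(out, "status")) && attr(out, "status") != 0) {
    stop("engine-error: '", engine$command, "' exited with status ",
         attr(out, "status"), call. = FALSE)
  }
  out
}

parse_rnafold_mfe <- function(lines) {
  hit <- grep("^[.()]+\\s+\\(\\s*-?[0-9.]+\\s*\\)\\s*$", lines)
  if (!length(hit)) stop("engine-error: could not parse folder output", call. = FALSE)
  structs <- character(length(hit))
  energies <- numeric(length(hit))
  for (k in seq_along(hit)) {
    m <- regmatches(lines[hit[k]],
                    regexec("^([.()]+)\\s+\\(\\s*(-?[0-9.]+)\\s*\\)\\s*$",
                            lines[hit[k]]))[[1]]
    structs[k] <- m[2]
    energies[k] <- as.numeric(m[3])
  }
  stats::setNames(energies, structs)
}

#' Minimum-free-energy secondary structure
#'
#' Folds a sequence (T read as U) into its optimal pseudoknot-free secondary
#' structure under the selected engine.
#'
#' @param seq Nucleotide string or `coding_sequence`.
#' @param engine A [fold_engine()]; default built-in.
#' @return A `secondary_structure`: list with `dotbracket`, `energy` and
#'   `units` (`"score"` for the built-in engine, `"kcal/mol"` for the
#'   external one).
#' @examples
#' fold_mfe("GGGAAAACCC")
#' @export
fold_mfe <- function(seq, engine = fold_engine()) {
  rna <- as_rna(seq)
  if (engine$kind == "builtin") {
    res <- .fold_mfe_cpp(rna, engine$pair_score, engine$stack_score, engine$min_loop)
    out <- list(dotbracket = res$dotbracket, energy = res$energy, units = "score")
  } else {
    lines <- run_rnafold(engine, c(q = rna))
    parsed <- parse_rnafold_mfe(lines)
    out <- list(dotbracket = names(parsed)[1], energy = unname(parsed[1]),
                units = "kcal/mol")
  }
  structure(out, class = "secondary_structure")
}

#' @export
print.secondary_structure <- function(x, ...) {
  cat("<secondary_structure> energy ", format(x$energy), " ", x$units, "\n",
      x$dotbracket, "\n", sep = "")
  invisible(x)
}

#' Equilibrium base-pairing probabilities
#'
#' Probability that each nucleotide is paired in the Boltzmann ensemble of
#' pseudoknot-free structures: p(i) = sum over j of P(i pairs j).
#'
#' @inheritParams fold_mfe
#' @return A tibble with columns `position` (1-based) and `p_paired`.
#' @export
pair_probabilities <- function(seq, engine = fold_engine()) {
  rna <- as_rna(seq)
  n <- nchar(rna)
  if (engine$kind == "builtin") {
    p <- .pair_prob_cpp(rna, engine$pair_score, engine$stack_score,
                        engine$min_loop, engine$beta)
  } else {
    dir <- tempfile("fold")
    dir.create(dir)
    on.exit(unlink(dir, recursive = TRUE), add = TRUE)
    old <- setwd(dir); on.exit(setwd(old), add = TRUE)
    run_rnafold(engine, c(q = rna), args = "-p")
    dp <- list.files(dir, pattern = "_dp\\.ps$", full.names = TRUE)
    if (length(dp) != 1) stop("engine-error: no dot-plot output from external folder",
                              call. = FALSE)
    lines <- readLines(dp[1])
    ub <- grep("^[0-9]+ [0-9]+ [0-9.eE+-]+ ubox$", lines, value = TRUE)
    p <- numeric(n)
    if (length(ub)) {
      parts <- do.call(rbind, strsplit(ub, " "))
      i <- as.integer(parts[, 1]); j <- as.integer(parts[, 2])
      pij <- as.numeric(parts[, 3])^2  # dot plot stores sqrt(p)
      for (k in seq_along(i)) {
        p[i[k]] <- p[i[k]] + pij[k]
        p[j[k]] <- p[j[k]] + pij[k]
      }
    }
    p <- pmin(pmax(p, 0), 1)
  }
  tibble::tibble(position = seq_len(n), p_paired = as.numeric(p))
}

#' Windowed minimum-free-energy track
#'
#' For each codon of a CDS embedded in a transcript, folds the window of
#' `window_nt` nucleotides centered on the codon's middle nucleotide
#' (truncated at the transcript ends) and records the window's MFE. This is
#' the local-structure predictor usually named `MFE_151`.
#'
#' @param transcript Nucleotide string (transcript or ORF).
#' @param cds_start 0-based nt offset of the CDS within `transcript`
#'   (default 0: the transcript is the ORF).
#' @param n_codons Number of codons to annotate; default the full CDS from
#'   `cds_start` to the end of the transcript.
#' @param engine A [fold_engine()].
#' @param window_nt Window width in nt; must be odd (default 151, i.e. the
#'   middle nucleotide +/- 75).
#' @param gene_id Gene label for the resulting track.
#' @return A [feature_track()] with feature `"MFE_<window_nt>"`.
#' @export
windowed_mfe_track <- function(transcript, cds_start = 0L, n_codons = NULL,
                               engine = fold_engine(), window_nt = 151L,
                               gene_id = "gene") {
  rna <- as_rna(transcript)
  n <- nchar(rna)
  if (window_nt %% 2L == 0L) {
    stop("parameter-error: window_nt must be odd, got ", window_nt, call. = FALSE)
  }
  if (is.null(n_codons)) n_codons <- (n - cds_start) %/% 3L
  stopifnot(n_codons >= 1L, cds_start + 3L * n_codons <= n)
  h <- (window_nt - 1L) %/% 2L
  centers <- cds_start + 3L * seq_len(n_codons) - 2L + 1L  # 1-based middle nt
  lo <- pmax(1L, centers - h)
  hi <- pmin(n, centers + h)
  wins <- substring(rna, lo, hi)
  if (engine$kind == "builtin") {
    vals <- vapply(unique(wins), function(w) fold_mfe(w, engine)$energy, numeric(1))
  } else {
    uw <- unique(wins)
    lines <- run_rnafold(engine, stats::setNames(uw, paste0("w", seq_along(uw))))
    parsed <- parse_rnafold_mfe(lines)
    if (length(parsed) != length(uw)) {
      stop("engine-error: folder returned ", length(parsed), " structures for ",
           length(uw), " windows", call. = FALSE)
    }
    vals <- stats::setNames(unname(parsed), uw)
  }
  feature_track(unname(vals[wins]), feature = paste0("MFE_", window_nt),
                gene_id = gene_id)
}

#' Per-codon average pairing probability
#'
#' Averages the pairing probabilities of each codon's three nucleotides.
#'
#' @param p A [pair_probabilities()] tibble (or plain numeric vector of
#'   per-nucleotide probabilities).
#' @param cds_start 0-based nt offset of the CDS within the folded sequence.
#' @param n_codons Number of codons; default fills from `cds_start` onward.
#' @param gene_id Gene label.
#' @return A [feature_track()] with feature `"pair_prob"`.
#' @export
per_codon_pair_prob <- function(p, cds_start = 0L, n_codons = NULL,
                                gene_id = "gene") {
  if (is.data.frame(p)) p <- p$p_paired[order(p$position)]
  n <- length(p)
  if (is.null(n_codons)) n_codons <- (n - cds_start) %/% 3L
  if (cds_start < 0L || n_codons < 1L || cds_start + 3L * n_codons > n) {
    stop("coordinate-error: CDS range [", cds_start, ", ",
         cds_start + 3L * n_codons, ") does not fit the probability vector",
         call. = FALSE)
  }
  idx <- cds_start + seq_len(3L * n_codons)
  m <- matrix(p[idx], nrow = 3L)
  feature_track(colMeans(m), feature = "pair_prob", gene_id = gene_id)
}

#' Paired comparison of two pairing-probability profiles
#'
#' Wilcoxon signed-rank test over positions of two colinear variants' pairing
#' probabilities. Zero differences are dropped; for up to 25 informative
#' positions the exact null distribution is used (when untied), otherwise the
#' normal approximation with continuity and tie correction.
#'
#' @param a,b Equal-length numeric vectors or [pair_probabilities()] tibbles.
#' @return A tibble with `statistic` (V), `p_value`, `n_effective`,
#'   `degenerate`.
#' @export
compare_pair_prob <- function(a, b) {
  if (is.data.frame(a)) a <- a$p_paired[order(a$position)]
  if (is.data.frame(b)) b <- b$p_paired[order(b$position)]
  stopifnot(is.numeric(a), is.numeric(b))
  if (length(a) != length(b)) {
    stop("positionwise comparison requires equal lengths (", length(a), " vs ",
         length(b), ")", call. = FALSE)
  }
  d <- a - b
  d <- d[d != 0]
  n_eff <- length(d)
  if (n_eff == 0L) {
    return(tibble::tibble(statistic = NA_real_, p_value = 1, n_effective = 0L,
                          degenerate = TRUE))
  }
  exact <- n_eff <= 25L && !anyDuplicated(abs(d))
  wt <- suppressWarnings(stats::wilcox.test(d, mu = 0, paired = FALSE,
                                            exact = exact, correct = TRUE))
  tibble::tibble(statistic = unname(wt$statistic), p_value = wt$p.value,
                 n_effective = n_eff, degenerate = FALSE)
}
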