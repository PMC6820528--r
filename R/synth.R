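#' Synthetic biased codon-usage table
#'
#' Draws one random usage table with realistic within-family bias: family
#' member weights are Gamma draws raised to `bias`, so larger `bias` gives
#' more skewed synonymous preferences (bias 0 is uniform usage). `gc3_bias`
#' tilts the preference toward codons ending in G or C (values > 1) or in
#' A/T (values < 1), mirroring the empirical tendency of mammalian
#' "optimal" codons to be GC-ended — the lever that makes an optimized
#' recoding more GC-rich and more structured than its wild-type source.
#'
#' @param bias Skew exponent, default 2.
#' @param gc3_bias Multiplier on the weight of G/C-ending codons, default 1
#'   (no compositional tilt).
#' @param total Approximate total count per family member scale.
#' @param seed Integer seed.
#' @return A [codon_usage_table()] labelled `synthetic`.
#' @export
synthetic_usage_table <- function(bias = 2, gc3_bias = 1, total = 1000,
                                  seed = 1L) {
  fam <- codon_families()
  counts <- stats::setNames(numeric(nrow(fam)), fam$codon)
  withr::with_seed(seed, {
    for (cods in split(fam$codon, fam$amino_acid)) {
      w <- stats::rgamma(length(cods), shape = 1)^bias
      w <- w * ifelse(substr(cods, 3, 3) %in% c("G", "C"), gc3_bias, 1)
      counts[cods] <- pmax(1, round(total * w / sum(w)))
    }
  })
  codon_usage_table(counts, source = "synthetic")
}

#' Synthetic codon-pair-usage table
#'
#' Builds pair counts as the product of two independent draws from a usage
#' table (optionally perturbed), the simplest pair table whose RSCPU has the
#' product structure implied by independent codons.
#'
#' @param usage A [codon_usage_table()].
#' @param noise_sd Lognormal perturbation SD on each pair count (0 = exact
#'   independence).
#' @param seed Integer seed.
#' @return A [codon_pair_usage_table()].
#' @export
synthetic_pair_usage_table <- function(usage, noise_sd = 0, seed = 1L) {
  cu <- stats::setNames(usage$count, usage$codon)
  grid <- tidyr::expand_grid(codon1 = SENSE_CODONS, codon2 = SENSE_CODONS)
  cnt <- as.numeric(cu[grid$codon1]) * as.numeric(cu[grid$codon2]) / sum(cu)
  if (noise_sd > 0) {
    cnt <- withr::with_seed(seed, cnt * stats::rlnorm(length(cnt), 0, noise_sd))
  }
  codon_pair_usage_table(tibble::tibble(grid, count = cnt), source = "synthetic")
}

#' Sample a gene with codon usage drawn from a table
#'
#' For each amino acid of the protein, draws a synonymous codon with
#' probability proportional to its usage count — a "wild-type-like" gene
#' whose codon bias mirrors the table.
#'
#' @param usage A [codon_usage_table()].
#' @param protein Amino-acid string, or an integer length (a random protein
#'   starting with Met is drawn).
#' @param seed Integer seed.
#' @param id Identifier for the resulting sequence.
#' @return A `coding_sequence`.
#' @export
sample_gene <- function(usage, protein, seed = 1L, id = "synthetic_wt") {
  fam <- split(stats::setNames(usage$count, usage$codon),
               GENETIC_CODE_TBL[usage$codon])
  withr::with_seed(seed, {
    if (is.numeric(protein)) {
      aas <- c("M", sample(setdiff(names(fam), "M"), protein - 1, replace = TRUE))
    } else {
      aas <- strsplit(protein, "")[[1]]
    }
    codons <- vapply(aas, function(a) {
      cnts <- fam[[a]]
      if (is.null(cnts)) stop("generation-error: unknown amino acid '", a, "'",
                              call. = FALSE)
      if (sum(cnts) == 0) stop("generation-error: all-zero usage family for '",
                               a, "'", call. = FALSE)
      if (length(cnts) == 1L) names(cnts) else sample(names(cnts), 1L, prob = cnts)
    }, character(1))
  })
  parse_cds(paste(codons, collapse = ""), id = id)
}

#' Maximal codon optimization of a gene
#'
#' Replaces every codon by its synonymous family's maximum-usage codon — a
#' deterministic stand-in for commercial optimizers that captures their
#' defining property, enrichment of common codons. The protein is unchanged
#' and the result has CAI = 1 under the optimizing table.
#'
#' @param cds A `coding_sequence`.
#' @param usage The [codon_usage_table()] to optimize against.
#' @param id Identifier for the optimized sequence.
#' @return A `coding_sequence`.
#' @export
optimize_codons <- function(cds, usage, id = paste0(cds$id, "_opt")) {
  cu <- stats::setNames(usage$count, usage$codon)
  fam <- split(SENSE_CODONS, GENETIC_CODE_TBL[SENSE_CODONS])
  best <- vapply(fam, function(cods) {
    # deterministic: first max in codon-name order
    cods <- sort(cods)
    cods[which.max(cu[cods])]
  }, character(1))
  aa <- GENETIC_CODE_TBL[cds$codons]
  new_codons <- ifelse(aa == "*", cds$codons, best[aa])
  suppressWarnings(parse_cds(paste(new_codons, collapse = ""), id = id))
}

#' Ground truth of a coverage simulation
#'
#' @param beta Named coefficients of the log-scale mean model: `intercept`,
#'   `lag1`..`lag3`, plus one entry per feature track supplied to
#'   [simulate_profiles()].
#' @param sigma Residual SD on the log scale (> 0).
#' @param depth Expected fragments per codon (> 0).
#' @param region_shift Optional `list(start, end, multiplier)`: codons in
#'   \[start, end) (0-based) have their mean multiplied by `multiplier`,
#'   emulating a regionally slowed segment.
#' @param seed Integer seed.
#' @return A list of class `simulation_truth`.
#' @export
simulation_truth <- function(beta = c(intercept = 0, lag1 = 0.4),
                             sigma = 0.3, depth = 100, region_shift = NULL,
                             seed = 1L) {
  stopifnot(sigma > 0, depth > 0)
  if (!is.null(region_shift)) {
    stopifnot(all(c("start", "end", "multiplier") %in% names(region_shift)),
              region_shift$start >= 0, region_shift$end > region_shift$start)
  }
  structure(list(beta = beta, sigma = sigma, depth = depth,
                 region_shift = region_shift, seed = as.integer(seed)),
            class = "simulation_truth")
}

#' Simulate per-codon ribosome-footprint coverage with known truth
#'
#' Generates the data-generating process the downstream regression assumes:
#' a log-scale per-codon field z with downstream-lag dependence and feature
#' effects, and Poisson counts on its exponential. Per codon i (recursing
#' from the 3' end so the downstream lags are well defined),
#' `mu_i = intercept + sum_f beta_f feature_f(i) + sum_k lag_k z_(i+k)`
#' (+ log multiplier inside the shifted region), `z_i = mu_i + N(0, sigma)`,
#' and counts are `Poisson(depth * exp(z_i) / mean exp(z))`. Replicates draw
#' independent fields via seed offsets.
#'
#' @param n_codons Number of codons, or a `coding_sequence` (its length is
#'   used and its id labels the profiles).
#' @param truth A [simulation_truth()].
#' @param features Named list of per-codon numeric vectors (or
#'   [feature_track()]s) entering the mean model with coefficients
#'   `truth$beta[name]`.
#' @param replicates Number of replicates, default 3.
#' @param gene_id Label; defaults to the sequence id or `"synthetic"`.
#' @return A coverage tibble (`gene_id`, `replicate`, `codon_index`,
#'   `count`) with attributes `truth` and `z` (the latent log fields,
#'   codons x replicates).
#' @export
simulate_profiles <- function(n_codons, truth = simulation_truth(),
                              features = list(), replicates = 3L,
                              gene_id = NULL) {
  if (inherits(n_codons, "coding_sequence")) {
    if (is.null(gene_id)) gene_id <- n_codons$id
    n_codons <- length(n_codons$codons)
  }
  if (is.null(gene_id)) gene_id <- "synthetic"
  n <- as.integer(n_codons)
  feats <- lapply(features, function(f) if (is.data.frame(f)) track_values(f) else as.numeric(f))
  stopifnot(all(lengths(feats) == n))
  beta <- truth$beta
  b0 <- if ("intercept" %in% names(beta)) beta[["intercept"]] else 0
  lag_ks <- grep("^lag[0-9]+$", names(beta), value = TRUE)
  lag_order <- as.integer(sub("lag", "", lag_ks))
  feat_effect <- rep(0, n)
  for (nm in names(feats)) {
    if (!nm %in% names(beta)) next
    fv <- feats[[nm]]
    fv[is.na(fv)] <- mean(fv, na.rm = TRUE)
    feat_effect <- feat_effect + beta[[nm]] * fv
  }
  shift <- rep(0, n)
  if (!is.null(truth$region_shift)) {
    rs <- truth$region_shift
    stopifnot(rs$end <= n)
    shift[(rs$start + 1L):rs$end] <- log(rs$multiplier)
  }
  zmat <- matrix(NA_real_, nrow = n, ncol = replicates)
  out <- vector("list", replicates)
  for (r in seq_len(replicates)) {
    counts <- withr::with_seed(truth$seed + 1000L * (r - 1L), {
      eps <- stats::rnorm(n, 0, truth$sigma)
      z <- numeric(n)
      for (i in n:1) {
        lag_sum <- 0
        for (j in seq_along(lag_ks)) {
          k <- lag_order[j]
          if (i + k <= n) lag_sum <- lag_sum + beta[[lag_ks[j]]] * z[i + k]
        }
        z[i] <- b0 + feat_effect[i] + shift[i] + lag_sum + eps[i]
      }
      zmat[, r] <- z
      lam <- truth$depth * exp(z) / mean(exp(z))
      stats::rpois(n, lam)
    })
    out[[r]] <- tibble::tibble(gene_id = gene_id,
                               replicate = paste0("rep", r),
                               codon_index = seq_len(n) - 1L,
                               count = counts)
  }
  res <- dplyr::bind_rows(out)
  attr(res, "truth") <- truth
  attr(res, "z") <- zmat
  res
}

#' Build a transcript model with flanks for a simulated gene
#'
#' @param n_codons CDS length in codons.
#' @param id Transcript id.
#' @param utr5,utr3 Flank lengths in nt (the 5' flank must be at least the
#'   A-site offset so every codon is reachable by a fragment).
#' @export
synthetic_transcript_model <- function(n_codons, id = "synthetic",
                                       utr5 = 30L, utr3 = 60L) {
  transcript_model(id, length = utr5 + 3L * n_codons + utr3,
                   cds_start = utr5, cds_end = utr5 + 3L * n_codons)
}

#' Emit aligned fragments realizing a coverage profile
#'
#' The inverse of [codon_coverage()]: for every codon and every one of its
#' counts, emits one fragment whose A-site nucleotide (5' end + offset)
#' falls inside that codon, with lengths drawn uniformly from `lengths`.
#' A filter/coverage round trip recovers the profile exactly.
#'
#' @param profile A coverage tibble (`gene_id`, `replicate`, `codon_index`,
#'   `count`).
#' @param tm The [transcript_model()] the fragments live on.
#' @param lengths Fragment lengths to draw from (default the RPF keep set
#'   20-22, 27-29 nt).
#' @param offset_nt A-site offset, default 15.
#' @param seed Integer seed.
#' @param kind Fragment kind label, default `"RPF"`.
#' @return A fragments tibble.
#' @export
simulate_fragments <- function(profile, tm, lengths = c(20:22, 27:29),
                               offset_nt = 15L, seed = 1L, kind = "RPF") {
  stopifnot(nrow(tm) == 1L)
  n_codons <- (tm$cds_end - tm$cds_start) %/% 3L
  stopifnot(max(profile$codon_index) < n_codons)
  if (tm$cds_start < offset_nt - 2L) {
    stop("placement-error: transcript needs >= ", offset_nt - 2L,
         " nt of 5' flank for A-site offset ", offset_nt, call. = FALSE)
  }
  expanded <- profile[rep(seq_len(nrow(profile)), profile$count), ]
  if (!nrow(expanded)) {
    return(tibble::tibble(transcript_id = character(), start = integer(),
                          length = integer(), sample = character(),
                          kind = character()))
  }
  withr::with_seed(seed, {
    within_codon <- sample(0:2, nrow(expanded), replace = TRUE)
    a_nt <- tm$cds_start + 3L * expanded$codon_index + within_codon
    start <- a_nt - offset_nt
    # clamp the A-site position inside the codon when the 5' end would
    # protrude past the transcript start
    low <- pmax(start, 0L)
    a_nt <- a_nt + (low - start)
    bad <- a_nt > tm$cds_start + 3L * expanded$codon_index + 2L
    if (any(bad)) {
      stop("placement-error: 5' flank too short to place fragments in codon ",
           min(expanded$codon_index[bad]), call. = FALSE)
    }
    start <- a_nt - offset_nt
    len <- sample(rep(lengths, 2), nrow(expanded), replace = TRUE)
    # shrink to the transcript end where needed, staying in the length set
    max_len <- tm$length - start
    for (i in which(len > max_len)) {
      ok <- lengths[lengths <= max_len[i]]
      if (!length(ok)) stop("placement-error: 3' flank too short for any ",
                            "fragment length", call. = FALSE)
      len[i] <- sample(rep(ok, 2), 1L)
    }
  })
  tibble::tibble(transcript_id = tm$id, start = as.integer(start),
                 length = as.integer(len), sample = expanded$replicate,
                 kind = kind)
}

#' Plot per-codon coverage profiles
#'
#' @param profile A coverage tibble (optionally normalized).
#' @param value Column to plot (default `normalized` if present else
#'   `count`).
#' @return A ggplot object.
#' @export
plot_coverage_profile <- function(profile, value = NULL) {
  if (is.null(value)) value <- if ("normalized" %in% names(profile)) "normalized" else "count"
  ggplot2::ggplot(profile,
                  ggplot2::aes(x = .data$codon_index, y = .data[[value]],
                               colour = .data$replicate)) +
    ggplot2::geom_line(alpha = 0.8) +
    ggplot2::facet_wrap(~gene_id, ncol = 1, scales = "free_y") +
    ggplot2::labs(x = "codon (0-based)", y = value, colour = "replicate") +
    ggplot2::theme_minimal()
}
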