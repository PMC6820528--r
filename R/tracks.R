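#' Build a per-codon feature track
#'
#' A feature track is a long-format tibble aligned to a gene's codons:
#' one row per codon with columns `gene_id`, `codon_index` (0-based),
#' `feature` and `value`. `NA` marks positions where the feature is
#' undefined (masked), which is distinct from 0.
#'
#' @param values Numeric vector, one value per codon (`NA` = masked).
#' @param feature Feature name (e.g. `"RSCU_Genome"`, `"MFE_151"`).
#' @param gene_id Gene identifier.
#' @return A tibble of class `feature_track`.
#' @export
feature_track <- function(values, feature, gene_id) {
  stopifnot(is.numeric(values) || all(is.na(values)))
  out <- tibble::tibble(gene_id = gene_id,
                        codon_index = seq_along(values) - 1L,
                        feature = feature,
                        value = as.numeric(values))
  class(out) <- c("feature_track", class(out))
  out
}

track_values <- function(track) {
  stopifnot(is.data.frame(track), all(c("codon_index", "value") %in% names(track)))
  track$value[order(track$codon_index)]
}

#' Annotate a coding sequence with a codon- or pair-keyed feature
#'
#' Maps per-codon values onto a gene. For codon-keyed maps position i takes
#' the value of codon i; for pair-keyed maps position i takes the value of
#' the ordered pair (codon i, codon i+1) and the last codon is masked.
#' Codons (or pairs) absent from the map are masked `NA`, never 0.
#'
#' @param cds A `coding_sequence`.
#' @param values Either a named numeric vector keyed by codon, a data frame
#'   with a `codon` column plus one value column (e.g. [compute_rscu()]
#'   output), or a data frame with `codon1`/`codon2` plus one value column
#'   (e.g. [compute_rscpu()] output).
#' @param feature Name for the resulting track; defaults to the value
#'   column's name when `values` is a data frame.
#' @return A [feature_track()] tibble of length equal to the codon count.
#' @export
annotate_track <- function(cds, values, feature = NULL) {
  stopifnot(inherits(cds, "coding_sequence"))
  codons <- cds$codons
  if (is.numeric(values) && !is.null(names(values))) {
    map <- values
    names(map) <- chartr("U", "T", toupper(names(map)))
    v <- unname(map[codons])
    if (is.null(feature)) feature <- "feature"
  } else if (is.data.frame(values) && all(c("codon1", "codon2") %in% names(values))) {
    value_col <- setdiff(names(values), c("codon1", "codon2", "aa_pair", "count"))[1]
    if (is.null(feature)) feature <- value_col
    key <- paste(values$codon1, values$codon2)
    map <- stats::setNames(values[[value_col]], key)
    n <- length(codons)
    pair_key <- paste(codons[-n], codons[-1])
    v <- c(unname(map[pair_key]), NA_real_)
  } else if (is.data.frame(values) && "codon" %in% names(values)) {
    value_col <- setdiff(names(values), c("codon", "amino_acid", "count"))[1]
    if (is.null(feature)) feature <- value_col
    map <- stats::setNames(values[[value_col]], values$codon)
    v <- unname(map[codons])
  } else {
    stop("values must be a named vector or a codon-/pair-keyed data frame",
         call. = FALSE)
  }
  feature_track(v, feature = feature, gene_id = cds$id)
}

#' Centered sliding-window mean of a feature track
#'
#' Smooths a per-codon track with a centered window of odd width. Only full
#' windows produce values, so floor(w/2) positions at each end are masked;
#' masked inputs inside a window are excluded from its mean.
#'
#' @param track A [feature_track()] (single feature, single gene).
#' @param w Odd window width in codons, default 7.
#' @return A `feature_track` of the same length with smoothed values.
#' @export
sliding_window_mean <- function(track, w = 7L) {
  v <- track_values(track)
  n <- length(v)
  if (w %% 2L == 0L || w < 1L) {
    stop("parameter-error: window width must be odd and positive, got ", w,
         call. = FALSE)
  }
  if (w > n) {
    stop("parameter-error: window width ", w, " exceeds track length ", n,
         call. = FALSE)
  }
  h <- (w - 1L) %/% 2L
  out <- rep(NA_real_, n)
  for (i in seq.int(h + 1L, n - h)) {
    win <- v[(i - h):(i + h)]
    if (any(!is.na(win))) out[i] <- mean(win, na.rm = TRUE)
  }
  res <- track
  res$value <- out[order(order(track$codon_index))]
  res
}

#' Combine feature tracks into one long table
#'
#' @param ... `feature_track` tibbles (or lists of them).
#' @return A single long tibble (gene_id, codon_index, feature, value).
#' @export
bind_tracks <- function(...) {
  xs <- list(...)
  xs <- purrr::flatten(purrr::map(xs, function(x) if (is.data.frame(x)) list(x) else x))
  dplyr::bind_rows(xs)
}

#' Write feature tracks as long-format TSV
#'
#' @param tracks A long track tibble (see [bind_tracks()]).
#' @param path Output path.
#' @export
write_tracks_tsv <- function(tracks, path) {
  utils::write.table(
    as.data.frame(tracks[, c("gene_id", "codon_index", "feature", "value")]),
    path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read feature tracks from long-format TSV
#' @param path TSV with columns gene_id, codon_index, feature, value.
#' @export
read_tracks_tsv <- function(path) {
  tbl <- tibble::as_tibble(utils::read.delim(path, stringsAsFactors = FALSE))
  stopifnot(all(c("gene_id", "codon_index", "feature", "value") %in% names(tbl)))
  tbl
}

#' Plot feature tracks along a gene
#'
#' One line per gene, faceted by feature — the standard way to look at
#' smoothed RSCU/RSCPU or structure tracks for a wild-type/optimized pair.
#'
#' @param tracks Long track tibble.
#' @param smooth_window Optional odd window; if given, each gene x feature
#'   track is smoothed with [sliding_window_mean()] before plotting.
#' @return A ggplot object.
#' @export
plot_feature_tracks <- function(tracks, smooth_window = NULL) {
  if (!is.null(smooth_window)) {
    tracks <- dplyr::group_by(tracks, .data$gene_id, .data$feature)
    tracks <- dplyr::group_modify(tracks, function(d, key) {
      d2 <- d
      d2$value <- sliding_window_mean(d, w = smooth_window)$value
      d2
    })
    tracks <- dplyr::ungroup(tracks)
  }
  ggplot2::ggplot(tracks,
                  ggplot2::aes(x = .data$codon_index, y = .data$value,
                               colour = .data$gene_id)) +
    ggplot2::geom_line(na.rm = TRUE) +
    ggplot2::facet_wrap(~feature, scales = "free_y") +
    ggplot2::labs(x = "codon (0-based)", y = "value", colour = "gene") +
    ggplot2::theme_minimal()
}
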