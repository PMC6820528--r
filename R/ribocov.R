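#' Transcript models
#'
#' A transcript model records, in transcript coordinates, the transcript
#' length and the CDS bounds (0-based half-open, length divisible by 3).
#'
#' @param id Transcript/gene identifier.
#' @param length Transcript length in nt.
#' @param cds_start,cds_end 0-based half-open CDS bounds.
#' @return A one-row tibble of class `transcript_model`.
#' @export
transcript_model <- function(id, length, cds_start, cds_end) {
  stopifnot(cds_start >= 0, cds_start < cds_end, cds_end <= length,
            (cds_end - cds_start) %% 3 == 0)
  out <- tibble::tibble(id = id, length = as.integer(length),
                        cds_start = as.integer(cds_start),
                        cds_end = as.integer(cds_end))
  class(out) <- c("transcript_model", class(out))
  out
}

#' Read transcript models from TSV
#'
#' Columns: `id`, `length`, `cds_start`, `cds_end` (0-based half-open).
#'
#' @param path TSV path.
#' @return A tibble of validated transcript models.
#' @export
read_transcript_models <- function(path) {
  tbl <- utils::read.delim(path, stringsAsFactors = FALSE)
  stopifnot(all(c("id", "length", "cds_start", "cds_end") %in% names(tbl)))
  dplyr::bind_rows(purrr::pmap(tbl[, c("id", "length", "cds_start", "cds_end")],
                               transcript_model))
}

#' Read aligned fragments from TSV
#'
#' The primary fragment dialect is a 4-column TSV in transcript coordinates:
#' `transcript_id`, `start` (0-based 5' end), `length` (nt), `sample`. An
#' optional `kind` column (`RPF`/`mRNA`) is preserved.
#'
#' @param path TSV path.
#' @param kind Optional kind label applied to all rows if no `kind` column.
#' @return A fragments tibble.
#' @export
read_fragments <- function(path, kind = NULL) {
  tbl <- tibble::as_tibble(utils::read.delim(path, stringsAsFactors = FALSE))
  stopifnot(all(c("transcript_id", "start", "length", "sample") %in% names(tbl)))
  if (!"kind" %in% names(tbl) && !is.null(kind)) tbl$kind <- kind
  stopifnot(all(tbl$start >= 0), all(tbl$length > 0))
  tbl
}

#' Write aligned fragments to TSV
#' @param frags Fragments tibble.
#' @param path Output path.
#' @export
write_fragments <- function(frags, path) {
  cols <- intersect(c("transcript_id", "start", "length", "sample", "kind"),
                    names(frags))
  utils::write.table(as.data.frame(frags[, cols]), path, sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read aligned fragments from a SAM file
#'
#' Maps each mapped record's leftmost position to a 0-based transcript
#' start. Requires the Rsamtools package.
#'
#' @param path SAM file path.
#' @param sample Sample label for all records.
#' @param kind Fragment kind label, default `"RPF"`.
#' @return A fragments tibble.
#' @export
read_fragments_sam <- function(path, sample, kind = "RPF") {
  if (!requireNamespace("Rsamtools", quietly = TRUE)) {
    stop("read_fragments_sam requires the Rsamtools package", call. = FALSE)
  }
  bam <- Rsamtools::asBam(path, destination = tempfile(), overwrite = TRUE,
                          indexDestination = FALSE)
  on.exit(unlink(c(bam, paste0(bam, ".bai"))), add = TRUE)
  rec <- Rsamtools::scanBam(bam, param = Rsamtools::ScanBamParam(
    what = c("rname", "pos", "qwidth", "flag")))[[1]]
  keep <- !bitwAnd(rec$flag, 4L) & !is.na(rec$pos)
  tibble::tibble(transcript_id = as.character(rec$rname)[keep],
                 start = rec$pos[keep] - 1L,
                 length = rec$qwidth[keep],
                 sample = sample, kind = kind)
}

#' Filter fragments by length
#'
#' Ribosome-protected fragments retain the two footprint populations
#' (20-22 nt and 27-29 nt by default); total-mRNA fragments retain
#' everything of at least `min_length` (25 nt by default). Order is
#' preserved.
#'
#' @param frags Fragments tibble.
#' @param kind `"RPF"` or `"mRNA"` — selects the default rule.
#' @param keep_lengths Integer set of lengths to keep (RPF rule).
#' @param min_length Minimum length to keep (mRNA rule).
#' @return The filtered tibble.
#' @export
filter_fragments <- function(frags, kind = c("RPF", "mRNA"),
                             keep_lengths = NULL, min_length = NULL) {
  kind <- match.arg(kind)
  if (kind == "RPF") {
    if (is.null(keep_lengths)) keep_lengths <- c(20:22, 27:29)
    frags[frags$length %in% keep_lengths, ]
  } else {
    if (is.null(min_length)) min_length <- 25L
    frags[frags$length >= min_length, ]
  }
}

#' A-site codon of each fragment
#'
#' The decoded codon is located `offset_nt` downstream of a footprint's 5'
#' end. Fragments whose A-site nucleotide falls outside the CDS get `NA`.
#'
#' @param frags Fragments tibble.
#' @param tm A [transcript_model()] row for the fragments' transcript.
#' @param offset_nt A-site offset from the 5' end, default 15.
#' @return `frags` with added columns `a_site_nt` and `a_codon` (0-based
#'   codon index within the CDS).
#' @export
a_site_codon <- function(frags, tm, offset_nt = 15L) {
  stopifnot(nrow(tm) == 1L)
  a_nt <- frags$start + offset_nt
  in_cds <- a_nt >= tm$cds_start & a_nt < tm$cds_end
  frags$a_site_nt <- a_nt
  frags$a_codon <- ifelse(in_cds, (a_nt - tm$cds_start) %/% 3L, NA_integer_)
  frags
}

#' Per-codon A-site coverage
#'
#' Counts, per replicate, the fragments whose A-site lies in each CDS codon.
#' The result covers every codon (zeros included), independent of input
#' order.
#'
#' @param frags Pre-filtered fragments tibble for one transcript.
#' @param tm A [transcript_model()] row.
#' @param offset_nt A-site offset, default 15.
#' @return A coverage tibble: `gene_id`, `replicate`, `codon_index`, `count`.
#' @export
codon_coverage <- function(frags, tm, offset_nt = 15L) {
  stopifnot(nrow(tm) == 1L)
  n_codons <- (tm$cds_end - tm$cds_start) %/% 3L
  frags <- frags[frags$transcript_id == tm$id, , drop = FALSE]
  ann <- a_site_codon(frags, tm, offset_nt)
  ann <- ann[!is.na(ann$a_codon), , drop = FALSE]
  reps <- sort(unique(frags$sample))
  if (!length(reps)) reps <- character(0)
  grid <- tidyr::expand_grid(replicate = reps,
                             codon_index = seq_len(n_codons) - 1L)
  cnt <- dplyr::count(ann, replicate = .data$sample, codon_index = .data$a_codon,
                      name = "count")
  out <- dplyr::left_join(grid, cnt, by = c("replicate", "codon_index"))
  out$count[is.na(out$count)] <- 0L
  dplyr::mutate(out, gene_id = tm$id, .before = 1)
}

#' Normalize a coverage profile to mean 1
#'
#' Divides each replicate's per-codon counts by that replicate's mean count
#' over the CDS, the usual normalized-codon-coverage scale.
#'
#' @param profile A [codon_coverage()] tibble, or a plain numeric vector.
#' @return Same shape with a `normalized` column (or a numeric vector).
#' @export
normalize_profile <- function(profile) {
  if (is.numeric(profile)) {
    m <- mean(profile)
    if (m == 0) stop("normalization-error: all-zero profile", call. = FALSE)
    return(profile / m)
  }
  stopifnot(is.data.frame(profile), "count" %in% names(profile))
  out <- dplyr::group_by(profile, .data$gene_id, .data$replicate)
  out <- dplyr::mutate(out, normalized = {
    m <- mean(.data$count)
    if (m == 0) stop("normalization-error: all-zero profile for gene '",
                     .data$gene_id[1], "' replicate '", .data$replicate[1], "'",
                     call. = FALSE)
    .data$count / m
  })
  dplyr::ungroup(out)
}

#' Average per-codon profiles across replicates
#'
#' @param profiles Either a list of equal-length numeric vectors, or a
#'   coverage tibble with a value column.
#' @param value Column to average when `profiles` is a tibble (default
#'   `"normalized"` if present, else `"count"`).
#' @return Positionwise mean: a numeric vector, or a tibble
#'   `gene_id`/`codon_index`/`mean_value`.
#' @export
average_replicates <- function(profiles, value = NULL) {
  if (is.list(profiles) && !is.data.frame(profiles)) {
    lens <- lengths(profiles)
    if (length(unique(lens)) != 1L) {
      stop("shape-error: replicate profiles differ in length", call. = FALSE)
    }
    return(rowMeans(do.call(cbind, profiles)))
  }
  if (is.null(value)) value <- if ("normalized" %in% names(profiles)) "normalized" else "count"
  out <- dplyr::group_by(profiles, .data$gene_id, .data$codon_index)
  out <- dplyr::summarise(out, mean_value = mean(.data[[value]]), .groups = "drop")
  out
}

#' Reads per kilobase per million mapped reads
#'
#' @param read_count Reads mapped to the region.
#' @param region_len_nt Region length in nt (> 0).
#' @param total_mapped Total mapped reads in the library (> 0).
#' @return RPKM value(s); vectorized.
#' @export
rpkm <- function(read_count, region_len_nt, total_mapped) {
  if (any(region_len_nt <= 0) || any(total_mapped <= 0)) {
    stop("parameter-error: region length and total mapped reads must be > 0",
         call. = FALSE)
  }
  read_count / ((region_len_nt / 1000) * (total_mapped / 1e6))
}

#' Translation efficiency
#'
#' TE = footprint RPKM / total-mRNA RPKM for a gene.
#'
#' @param rpf_rpkm,mrna_rpkm RPKM values; vectorized.
#' @return TE ratio(s).
#' @export
translation_efficiency <- function(rpf_rpkm, mrna_rpkm) {
  if (any(mrna_rpkm == 0)) {
    stop("undefined-TE: mRNA RPKM of 0", call. = FALSE)
  }
  rpf_rpkm / mrna_rpkm
}

#' Quality-control report for a fragment library
#'
#' Summarizes a ribosome-profiling library the standard way: fragment length
#' histogram; fraction of A-sites in 5' UTR / CDS / 3' UTR; reading-frame
#' distribution of CDS A-sites; and, if per-replicate RPKM values are given,
#' pairwise Pearson correlations of log10 RPKM over genes with RPKM >= 10 in
#' both replicates.
#'
#' @param frags Fragments tibble (possibly many transcripts).
#' @param tms Transcript models tibble covering the fragments' transcripts.
#' @param rpkm_tbl Optional tibble `gene`, `replicate`, `rpkm`.
#' @param offset_nt A-site offset, default 15.
#' @param min_rpkm RPKM floor for the correlation gene set, default 10.
#' @return A list of class `qc_report` with elements `length_histogram`,
#'   `region_fractions`, `frame_fractions`, `replicate_correlations`.
#' @export
qc_report <- function(frags, tms, rpkm_tbl = NULL, offset_nt = 15L,
                      min_rpkm = 10) {
  length_histogram <- dplyr::count(frags, length = .data$length, name = "count")

  ann <- dplyr::left_join(frags,
                          tms[, c("id", "length", "cds_start", "cds_end")],
                          by = c(transcript_id = "id"),
                          suffix = c("", ".tm"))
  a_nt <- ann$start + offset_nt
  region <- dplyr::case_when(
    a_nt < ann$cds_start ~ "utr5",
    a_nt < ann$cds_end ~ "cds",
    TRUE ~ "utr3"
  )
  region_fractions <- tibble::tibble(region = c("utr5", "cds", "utr3")) |>
    dplyr::left_join(
      dplyr::count(tibble::tibble(region = region), .data$region, name = "n"),
      by = "region")
  region_fractions$n[is.na(region_fractions$n)] <- 0L
  region_fractions$fraction <- region_fractions$n / sum(region_fractions$n)

  in_cds <- region == "cds"
  frame <- (a_nt[in_cds] - ann$cds_start[in_cds]) %% 3L
  frame_fractions <- tibble::tibble(frame = 0:2) |>
    dplyr::left_join(dplyr::count(tibble::tibble(frame = frame), .data$frame,
                                  name = "n"), by = "frame")
  frame_fractions$n[is.na(frame_fractions$n)] <- 0L
  frame_fractions$fraction <- frame_fractions$n / sum(frame_fractions$n)

  replicate_correlations <- NULL
  if (!is.null(rpkm_tbl)) {
    wide <- tidyr::pivot_wider(rpkm_tbl, names_from = "replicate",
                               values_from = "rpkm")
    reps <- setdiff(names(wide), "gene")
    pairs <- utils::combn(reps, 2, simplify = FALSE)
    replicate_correlations <- dplyr::bind_rows(lapply(pairs, function(pr) {
      x <- wide[[pr[1]]]; y <- wide[[pr[2]]]
      keep <- !is.na(x) & !is.na(y) & x >= min_rpkm & y >= min_rpkm
      tibble::tibble(rep1 = pr[1], rep2 = pr[2], n_genes = sum(keep),
                     pearson_r = if (sum(keep) >= 3)
                       stats::cor(log10(x[keep]), log10(y[keep])) else NA_real_)
    }))
  }
  structure(list(length_histogram = length_histogram,
                 region_fractions = region_fractions,
                 frame_fractions = frame_fractions,
                 replicate_correlations = replicate_correlations),
            class = "qc_report")
}

#' @export
print.qc_report <- function(x, ...) {
  cat("<qc_report>\n")
  cat("  fragments:", sum(x$length_histogram$count), "| lengths",
      min(x$length_histogram$length), "-", max(x$length_histogram$length), "\n")
  rf <- x$region_fractions
  cat(sprintf("  regions: 5'UTR %.1f%% | CDS %.1f%% | 3'UTR %.1f%%\n",
              100 * rf$fraction[rf$region == "utr5"],
              100 * rf$fraction[rf$region == "cds"],
              100 * rf$fraction[rf$region == "utr3"]))
  ff <- x$frame_fractions
  cat(sprintf("  frames: %.1f%% / %.1f%% / %.1f%%\n", 100 * ff$fraction[1],
              100 * ff$fraction[2], 100 * ff$fraction[3]))
  if (!is.null(x$replicate_correlations)) {
    cat("  replicate log10-RPKM Pearson r:",
        paste(sprintf("%s-%s %.3f", x$replicate_correlations$rep1,
                      x$replicate_correlations$rep2,
                      x$replicate_correlations$pearson_r), collapse = ", "), "\n")
  }
  invisible(x)
}

#' Write a QC report as JSON
#' @param qc A [qc_report()].
#' @param path Output path.
#' @export
write_qc_json <- function(qc, path) {
  jsonlite::write_json(unclass(qc), path, dataframe = "columns", auto_unbox = TRUE,
                       digits = NA, null = "null")
  invisible(path)
}
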