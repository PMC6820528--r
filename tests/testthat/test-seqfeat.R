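test_that("parse_cds normalizes, partitions, and rejects bad input", {
  cds <- parse_cds("auggct", id = "x")
  expect_s3_class(cds, "coding_sequence")
  expect_equal(cds$nt, "ATGGCT")
  expect_equal(cds$codons, c("ATG", "GCT"))

  expect_error(parse_cds("ATGG"), "frame-error")
  expect_error(parse_cds("ATGNNT"), "invalid-alphabet")
  expect_warning(parse_cds("ATGTAAGCT"), "internal stop")
  # trailing stop is not flagged
  expect_silent(parse_cds("ATGTAA"))
})

test_that("FASTA round trip preserves sequences", {
  f <- tempfile(fileext = ".fa")
  a <- parse_cds("ATGGCTTAA", id = "g1")
  b <- parse_cds("ATGCCC", id = "g2")
  write_cds_fasta(list(a, b), f)
  back <- read_cds_fasta(f)
  expect_named(back, c("g1", "g2"))
  expect_equal(back$g1$nt, a$nt)
  expect_equal(back$g2$codons, b$codons)
})

test_that("RSCU matches hand counts and definition identities", {
  rscu <- compute_rscu(hand_usage())
  leu <- rscu[rscu$amino_acid == "L", ]
  # Leu counts {CTG:3, CTA:1, rest 0}: family mean 4/6
  expect_equal(leu$rscu[leu$codon == "CTG"], 4.5)
  expect_equal(leu$rscu[leu$codon == "CTA"], 1.5)
  expect_equal(sum(leu$rscu == 0), 4)
  # single-codon families are 1 regardless of count
  expect_equal(rscu$rscu[rscu$codon == "ATG"], 1)
  expect_equal(rscu$rscu[rscu$codon == "TGG"], 1)

  # uniform usage: RSCU = 1 everywhere
  expect_true(all(compute_rscu(uniform_usage())$rscu == 1))

  # family means are 1 whenever all counts are nonzero
  set.seed(5)
  cnts <- stats::setNames(sample(1:50, 61, replace = TRUE), codon_families()$codon)
  by_fam <- split(compute_rscu(codon_usage_table(cnts))$rscu,
                  codon_families()$amino_acid)
  expect_true(all(vapply(by_fam, function(v) abs(mean(v) - 1) < 1e-12, logical(1))))

  # all-zero family is missing, not zero
  cnts["TGT"] <- 0; cnts["TGC"] <- 0
  rz <- suppressWarnings(compute_rscu(codon_usage_table(cnts)))
  expect_true(all(is.na(rz$rscu[rz$amino_acid == "C"])))
})

test_that("RSCPU matches hand counts, uniform identity, and singleton family", {
  # Met(ATG)-Phe(TTT/TTC) has exactly two synonymous pairs
  pu <- codon_pair_usage_table(
    data.frame(codon1 = c("ATG", "ATG", "ATG"),
               codon2 = c("TTT", "TTC", "TGG"),
               count = c(3, 1, 4)))
  rscpu <- compute_rscpu(pu)
  get <- function(c1, c2) rscpu$rscpu[rscpu$codon1 == c1 & rscpu$codon2 == c2]
  expect_equal(get("ATG", "TTT"), 1.5)   # mean of {3,1} is 2
  expect_equal(get("ATG", "TTC"), 0.5)
  expect_equal(get("ATG", "TGG"), 1)     # Met-Trp: singleton pair family
  # untouched families are all-zero hence missing
  expect_true(is.na(get("AAA", "AAA")))

  expect_true(all(compute_rscpu(uniform_pair_usage())$rscpu == 1))
})

test_that("RSCPU of an independence-product table has product structure", {
  u <- synthetic_usage_table(seed = 3)
  pu <- synthetic_pair_usage_table(u, noise_sd = 0)
  rscpu <- compute_rscpu(pu)
  rscu <- compute_rscu(u)
  r <- stats::setNames(rscu$rscu, rscu$codon)
  expect_equal(rscpu$rscpu,
               unname(r[rscpu$codon1] * r[rscpu$codon2]),
               tolerance = 1e-12)
})

test_that("RSCPU from independently drawn codon pairs converges to the product", {
  u <- synthetic_usage_table(seed = 11)
  prob <- u$count / sum(u$count)
  set.seed(11)
  n <- 4e5
  c1 <- sample(u$codon, n, replace = TRUE, prob = prob)
  c2 <- sample(u$codon, n, replace = TRUE, prob = prob)
  tab <- as.data.frame(table(codon1 = c1, codon2 = c2), stringsAsFactors = FALSE)
  names(tab)[3] <- "count"
  est <- compute_rscpu(codon_pair_usage_table(tab))
  exact <- compute_rscpu(synthetic_pair_usage_table(u, noise_sd = 0))
  keep <- !is.na(est$rscpu) & !is.na(exact$rscpu) & exact$rscpu > 0.2
  # Monte-Carlo agreement on the well-populated pairs
  expect_lt(stats::median(abs(est$rscpu[keep] - exact$rscpu[keep])), 0.25)
  expect_gt(stats::cor(est$rscpu[keep], exact$rscpu[keep]), 0.95)
})

test_that("CAI follows the relative-adaptiveness definition", {
  u <- hand_usage()
  # all most-frequent codons: CAI = 1
  best <- parse_cds("CTGTTT", id = "best")  # CTG and TTT are family maxima
  expect_equal(cai(best, u), 1)
  # w(TTC) = 5/10: two-codon gene TTT TTC has CAI sqrt(0.5)
  expect_equal(cai(parse_cds("TTTTTC"), u), sqrt(0.5))
  # ATG/TGG/stops excluded: adding them does not change CAI
  expect_equal(cai(parse_cds("ATGTTTTTCTGGTAA"), u), sqrt(0.5))
  # CAI <= 1 with equality only at all-maximal usage
  set.seed(9)
  for (s in 1:5) {
    ur <- synthetic_usage_table(seed = s)
    g <- sample_gene(ur, 120, seed = s)
    expect_lte(cai(g, ur), 1)
  }
  # zero-count codons get the half-count convention, not w = 0
  u2 <- hand_usage()
  expect_gt(cai(parse_cds("CTT"), u2), 0)  # CTT has count 0 in the Leu family
  expect_equal(cai(parse_cds("CTT"), u2), 0.5 / 3 / 1)  # w = 0.5/max(3), one codon
})

test_that("composition reports GC and GC3", {
  expect_equal(composition("ATGC")$gc_pct, 50)
  expect_true(is.na(composition("ATGC")$gc3_pct))
  cmp <- composition(parse_cds("GCAGCG"))
  expect_equal(cmp$gc3_pct, 50)  # third positions A, G
  expect_equal(cmp$gc_pct, 100 * 5 / 6)
})

test_that("annotate_track maps codon- and pair-keyed values with masking", {
  cds <- parse_cds("ATGGCTGCT", id = "g")
  tr <- annotate_track(cds, c(ATG = 1, GCT = 2), feature = "f")
  expect_equal(nrow(tr), 3)
  expect_equal(tr$value, c(1, 2, 2))

  # pair-keyed map: last codon masked, absent pairs masked
  pu <- compute_rscpu(codon_pair_usage_table(
    data.frame(codon1 = "ATG", codon2 = "GCT", count = 2)))
  trp <- annotate_track(cds, pu)
  expect_equal(nrow(trp), 3)
  # Met-Ala family has 4 synonymous pairs, counts {2,0,0,0}: 2/0.5 = 4
  expect_equal(trp$value[1], 4)
  expect_true(is.na(trp$value[2]))     # Ala-Ala family has zero counts
  expect_true(is.na(trp$value[3]))     # no pair at the last codon

  # codon absent from map is masked, not zero
  tr2 <- annotate_track(cds, c(ATG = 1), feature = "f")
  expect_true(all(is.na(tr2$value[2:3])))
})

test_that("sliding_window_mean is a centered full-window average", {
  tr <- feature_track(1:9, "f", "g")
  sm <- sliding_window_mean(tr, w = 7)
  expect_equal(sm$value, c(NA, NA, NA, 4, 5, 6, NA, NA, NA))
  # constant track: every unmasked value equals the constant
  cm <- sliding_window_mean(feature_track(rep(2.5, 10), "f", "g"), w = 5)
  expect_true(all(cm$value[3:8] == 2.5))
  expect_equal(sum(is.na(cm$value)), 4)  # floor(w/2) masked per end
  # commutes with adding a constant
  set.seed(2)
  v <- rnorm(15)
  s1 <- sliding_window_mean(feature_track(v + 3, "f", "g"), w = 7)$value
  s2 <- sliding_window_mean(feature_track(v, "f", "g"), w = 7)$value + 3
  expect_equal(s1, s2)
  # masked inputs are excluded from the window mean
  v2 <- c(1, NA, 3)
  expect_equal(sliding_window_mean(feature_track(v2, "f", "g"), w = 3)$value[2], 2)

  expect_error(sliding_window_mean(tr, w = 4), "parameter-error")
  expect_error(sliding_window_mean(tr, w = 11), "parameter-error")
})

test_that("sequence_divergence counts mismatches and checks the protein", {
  a <- parse_cds("ATGGCT")
  expect_equal(sequence_divergence(a, a),
               tibble::tibble(nt_pct = 0, codon_pct = 0, aa_identical = TRUE))
  d <- sequence_divergence(parse_cds("ATGGCT"), parse_cds("ATGGCC"))
  expect_equal(d$nt_pct, 100 / 6, tolerance = 1e-12)
  expect_equal(d$codon_pct, 50)
  expect_true(d$aa_identical)
  # symmetric in its arguments
  d2 <- sequence_divergence(parse_cds("ATGGCC"), parse_cds("ATGGCT"))
  expect_equal(d[, 1:2], d2[, 1:2])
  # non-synonymous change is reported
  expect_false(sequence_divergence(parse_cds("ATGGCT"), parse_cds("ATGACT"))$aa_identical)
  expect_error(sequence_divergence(a, parse_cds("ATGGCTGCT")), "not-comparable")
})

test_that("usage and tRNA table readers enforce the TSV dialect", {
  u <- synthetic_usage_table(seed = 2)
  f <- tempfile(fileext = ".tsv")
  write_usage_table(u, f)
  back <- read_usage_table(f)
  expect_equal(back$count[match(u$codon, back$codon)], u$count)

  # missing codons rejected
  bad <- tempfile(fileext = ".tsv")
  utils::write.table(data.frame(codon = "ATG", count = 5), bad,
                     sep = "\t", row.names = FALSE, quote = FALSE)
  expect_error(read_usage_table(bad), "61 sense codons")

  trna <- tempfile(fileext = ".tsv")
  utils::write.table(data.frame(codon = c("AAA", "GCU"), abundance = c(1.5, 0.2)),
                     trna, sep = "\t", row.names = FALSE, quote = FALSE)
  tv <- read_trna_table(trna)
  expect_equal(tv[["GCT"]], 0.2)  # U normalized to T
})
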