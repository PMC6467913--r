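test_that("read ratio is exact and errors on empty loci", {
  reads <- make_reads(1:100, c(rep("reference", 90), rep("non_reference", 10)))
  rr <- compute_read_ratio(reads, "chr1", 0, 200)
  expect_equal(rr$read_ratio, 0.10)
  expect_equal(rr$n_ref, 90)
  rr2 <- compute_read_ratio(make_reads(1:50, "non_reference"), "chr1", 0, 100)
  expect_equal(rr2$read_ratio, 1.0)
  expect_error(compute_read_ratio(reads, "chr1", 5000, 6000),
               class = "svscribe_empty_locus")
})

test_that("segmentation finds planted segments and ignores background noise", {
  # uniform 2% noise: P(Bin(250, 0.02) > 37.5) ~ 0, so no window triggers
  withr::with_seed(1, {
    noise <- make_reads(sort(sample.int(1e7, 1e5)),
                        ifelse(runif(1e5) < 0.02, "non_reference", "reference"))
  })
  expect_equal(nrow(segment_composite(noise)), 0)

  # noise-free hom inversion spanning many windows: one candidate covering it
  withr::with_seed(2, pos <- sort(sample.int(1e6, 2e4)))
  orient <- ifelse(pos >= 4e5 & pos < 5e5, "non_reference", "reference")
  cand <- segment_composite(make_reads(pos, orient))
  expect_equal(nrow(cand), 1)
  expect_lte(cand$start, min(pos[pos >= 4e5]))
  expect_gte(cand$end, max(pos[pos < 5e5]))
  expect_equal(cand$read_ratio, 1.0)

  # two inversions separated by >> one window span of reference reads
  orient2 <- ifelse((pos >= 1e5 & pos < 2e5) | (pos >= 7e5 & pos < 8e5),
                    "non_reference", "reference")
  cand2 <- segment_composite(make_reads(pos, orient2))
  expect_equal(nrow(cand2), 2)
  # brute-force window-scan oracle: triggering windows split into two runs
  nonref <- orient2 == "non_reference"
  w <- 250
  frac <- vapply(seq_len(length(pos) - w + 1),
                 function(i) mean(nonref[i:(i + w - 1)]), numeric(1))
  trig <- which(frac > 0.15)
  expect_equal(sum(diff(trig) > w), 1)  # exactly one gap between runs
})

test_that("genotyper matches the likelihood oracle and its boundaries", {
  p <- segmentation_params()
  # below the 50-read minimum: untyped regardless of ratio
  g49 <- genotype_locus(tibble::tibble(n_ref = 0, n_nonref = 49), p)
  expect_equal(g49$genotype, "untyped")
  g <- genotype_locus(tibble::tibble(n_ref = 0, n_nonref = 100), p)
  expect_equal(g$genotype, "hom_inv")

  # spot-check oracle equivalence on a deterministic grid (full enumeration
  # over all totals <= 100 runs in the acceptance suite)
  cases <- expand.grid(n_ref = c(0, 1, 5, 20, 40, 60, 97),
                       n_nonref = c(0, 1, 3, 25, 50, 75, 100))
  got <- genotype_locus(tibble::as_tibble(cases), p)
  for (i in seq_len(nrow(cases))) {
    o <- oracle_genotype(cases$n_ref[i], cases$n_nonref[i])
    expect_equal(got$genotype[i], o$genotype,
                 info = sprintf("(%d, %d)", cases$n_ref[i], cases$n_nonref[i]))
    expect_equal(got$best_model[i], o$best)
  }

  # monotonicity: at fixed total, increasing non-reference count never moves
  # the genotype from hom_inv back toward hom_ref
  lv <- c(hom_ref = 1, het = 2, hom_inv = 3, untyped = NA)
  for (total in c(60, 100)) {
    gts <- genotype_locus(
      tibble::tibble(n_ref = total:0, n_nonref = 0:total), p)$genotype
    ranks <- lv[gts]
    ranks <- ranks[!is.na(ranks)]
    expect_true(all(diff(ranks) >= 0))
  }
})

test_that("haplotype ratios respect the phased-read minimum", {
  nr <- make_reads(1:10, "non_reference", "H1")
  r <- compute_haplotype_ratios(nr, "chr1", 0, 100)
  expect_equal(r$hap_ratio_nonref, 1.0)
  expect_true(is.na(r$hap_ratio_ref))
  # nine tagged reads: one short of the minimum
  r9 <- compute_haplotype_ratios(nr[1:9, ], "chr1", 0, 100)
  expect_true(is.na(r9$hap_ratio_nonref))
  mixed <- make_reads(1:24, "reference", rep(c("H1", "H2"), 12))
  expect_equal(compute_haplotype_ratios(mixed, "chr1", 0, 100)$hap_ratio_ref, 0.5)
})

test_that("classification signatures and phasing match their definitions", {
  cl <- classify_inversion(
    genotype = c("hom_inv", "het", "het", "het", "het", "untyped"),
    hap_ratio_ref = c(NA, 0.79, 0.21, 0.50, 0.50, 0.5),
    hap_ratio_nonref = c(0.49, 0.23, 0.80, 0.90, 0.10, 0.9))
  expect_equal(cl$cls, c("simple_hom", "simple_het", "simple_het", "complex",
                         "complex", "unclassified"))
  expect_equal(cl$phase, c(NA, "0/1", "1/0", NA, NA, NA))
  # undefined required ratio -> unclassified
  cl2 <- classify_inversion("het", NA_real_, 0.9)
  expect_equal(cl2$cls, "unclassified")
})

test_that("misorient flagging requires hom genotype in every individual", {
  base <- tibble::tibble(chrom = "chr1", start = 1000, end = 5000,
                         genotype = "hom_inv")
  nine_hom <- dplyr::bind_rows(lapply(1:9, function(i)
    dplyr::mutate(base, individual = sprintf("ind%d", i),
                  start = 1000 + i, end = 5000 + i)))
  fl <- flag_misorients(nine_hom)
  expect_true(all(fl$misorient))

  eight_one <- nine_hom
  eight_one$genotype[5] <- "het"
  expect_false(any(flag_misorients(eight_one)$misorient))

  disjoint <- dplyr::mutate(nine_hom,
                            start = start + (1:9) * 1e5,
                            end = end + (1:9) * 1e5)
  expect_false(any(flag_misorients(disjoint)$misorient))
  expect_error(flag_misorients(dplyr::mutate(base, individual = "only")),
               ">= 2 individuals")
})

test_that("planted simple and complex inversions are recovered at realistic depth", {
  gm <- tiny_genome(chrom_length = 5e6)
  truth <- plant_inversions(gm, 20, 1e4, 1e5, hom_fraction = 1 / 3,
                            complex_fraction = 0.3, seed = 21)
  reads <- simulate_strandseq_composite(gm, truth, read_density = 25,
                                        orientation_error = 0.02,
                                        haplotag_rate = 0.3, seed = 22)
  scan <- call_inversions(reads)
  calls <- tidy(scan)
  hits <- lapply(seq_len(nrow(truth)), function(i) {
    ro <- reciprocal_overlap(truth$start[i], truth$end[i],
                             calls$start, calls$end)
    which(pmin(ro$frac_a, ro$frac_b) > 0.5 & calls$chrom == truth$chrom[i])
  })
  matched <- lengths(hits) > 0
  simple <- truth$cls == "simple"
  cls_of <- vapply(hits, function(h)
    if (length(h) == 0) NA_character_ else calls$cls[h[1]], character(1))
  expect_gte(mean(cls_of[simple] %in% c("simple_hom", "simple_het")), 0.95)
  expect_gte(mean(cls_of[!simple] == "complex"), 0.90)
  # correct genotype for matched simple events
  eff <- vapply(hits, function(h) {
    if (length(h) == 0) return(NA_character_)
    if (calls$model_rejected[h[1]]) calls$best_model[h[1]] else calls$genotype[h[1]]
  }, character(1))
  want <- ifelse(truth$genotype == "hom", "hom_inv", "het")
  ok <- matched & eff == want
  expect_gte(mean(ok[simple]), 0.95)
})
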