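no_tr <- tibble::tibble(chrom = character(), start = double(), end = double())

test_that("haplotype merging genotypes by TR-aware reciprocal overlap", {
  h1 <- tibble::tibble(call_id = c("a1", "a2"), chrom = "chr1",
                       start = c(1000, 50000), end = c(1500, 50400),
                       type = "DEL", sv_len = c(500, 400))
  h2 <- tibble::tibble(call_id = "b1", chrom = "chr1", start = 1000,
                       end = 1500, type = "DEL", sv_len = 500)
  m <- merge_haplotypes(h1, h2, no_tr)
  expect_equal(m$calls$gt[m$calls$start == 1000], "1/1")
  expect_equal(m$calls$gt[m$calls$start == 50000], "1/0")
  expect_equal(nrow(m$set_aside_loci), 0)

  # RO 0.2 outside TR (threshold 0.10) -> homozygous; same pair inside a TR
  # (threshold 0.50) -> two heterozygous calls
  h1b <- tibble::tibble(call_id = "a1", chrom = "chr1", start = 0, end = 1000,
                        type = "DEL", sv_len = 1000)
  h2b <- tibble::tibble(call_id = "b1", chrom = "chr1", start = 800,
                        end = 1800, type = "DEL", sv_len = 1000)
  expect_equal(merge_haplotypes(h1b, h2b, no_tr)$calls$gt, "1/1")
  tr <- tibble::tibble(chrom = "chr1", start = 0, end = 2000)
  expect_setequal(merge_haplotypes(h1b, h2b, tr)$calls$gt, c("1/0", "0/1"))
})

test_that("saturated tandem-repeat loci are set aside", {
  tr <- tibble::tibble(chrom = "chr1", start = 10000, end = 20000)
  h1 <- tibble::tibble(call_id = sprintf("a%d", 1:6), chrom = "chr1",
                       start = 10000 + (0:5) * 1500,
                       end = 10000 + (0:5) * 1500 + 300,
                       type = "DEL", sv_len = 300)
  h2 <- tibble::tibble(call_id = "b1", chrom = "chr1", start = 10100,
                       end = 10400, type = "DEL", sv_len = 300)
  m <- merge_haplotypes(h1, h2, tr)
  expect_equal(nrow(m$set_aside_loci), 1)
  expect_equal(m$set_aside_loci$max_calls, 6)
  expect_equal(nrow(m$calls), 0)  # every call sat in the removed locus
  # five calls per haplotype at the locus stay in
  m5 <- merge_haplotypes(h1[1:5, ], h2, tr)
  expect_equal(nrow(m5$set_aside_loci), 0)
  expect_gt(nrow(m5$calls), 0)
})

test_that("haplotype merging is swap-symmetric and stable", {
  withr::with_seed(31, {
    h1 <- tibble::tibble(call_id = sprintf("a%d", 1:15), chrom = "chr1",
                         start = sort(sample.int(9e5, 15)) , type = "DEL") |>
      dplyr::mutate(end = start + sample(200:800, 15, TRUE),
                    sv_len = end - start)
    h2 <- tibble::tibble(call_id = sprintf("b%d", 1:15), chrom = "chr1",
                         start = sort(sample.int(9e5, 15)), type = "DEL") |>
      dplyr::mutate(end = start + sample(200:800, 15, TRUE),
                    sv_len = end - start)
  })
  m <- merge_haplotypes(h1, h2, no_tr)
  m_swap <- merge_haplotypes(h2, h1, no_tr)
  flip <- c("1/1" = "1/1", "1/0" = "0/1", "0/1" = "1/0")
  expect_equal(sort(unname(flip[m$calls$gt])), sort(m_swap$calls$gt))
  expect_equal(sum(m$calls$gt == "1/1"), sum(m_swap$calls$gt == "1/1"))
  # determinism / idempotence of the decision: re-running is identical
  expect_identical(m, merge_haplotypes(h1, h2, no_tr))
  # re-merging the homozygous representatives is again all homozygous
  hom <- m$calls[m$calls$gt == "1/1", ]
  if (nrow(hom) > 0) {
    again <- merge_haplotypes(
      dplyr::mutate(hom, call_id = h1_id), dplyr::mutate(hom, call_id = h2_id),
      no_tr)
    expect_true(all(again$calls$gt == "1/1"))
  }
})

test_that("PB unification applies its inclusion tiers in order", {
  ps <- tibble::tibble(call_id = c("p1", "p2", "p3"), chrom = "chr1",
                       start = c(1e4, 5e4, 9e4),
                       end = c(1e4 + 950, 5e4 + 500, 9e4 + 500),
                       type = "DEL", sv_len = c(950, 500, 500),
                       pbrc = c(2, 4, 1))
  ms <- tibble::tibble(call_id = c("m1", "m2"), chrom = "chr1",
                       start = c(5.4e4, 2e5), end = c(5.4e4 + 480, 2e5 + 300),
                       type = "DEL", sv_len = c(480, 300), pbrc = c(6, 6))
  bng <- tibble::tibble(chrom = "chr1", start = 1e4, end = 1e4 + 950,
                        type = "DEL", l_bn = 1000)
  u <- unify_pb(ps, ms, bng)
  # p1: PBRC 2 but f_BN = 0.05 -> tier (a)
  expect_equal(u$tier[u$call_id == "p1"], "bng_validated")
  # p2: PBRC 4 > 3 -> tier (b)
  expect_equal(u$tier[u$call_id == "p2"], "pbrc")
  # p3: PBRC 1, no BNG -> excluded
  expect_false("p3" %in% u$call_id)
  # m1 is 4 kb away from p2 -> excluded; m2 is > 10 kb from anything -> kept
  expect_false("m1" %in% u$call_id)
  expect_equal(u$tier[u$call_id == "m2"], "distance")
})

test_that("pan-SV integration partitions calls with PB > IL > BNG preference", {
  mk <- function(prefix, starts, len = 500) {
    tibble::tibble(call_id = sprintf("%s%d", prefix, seq_along(starts)),
                   chrom = "chr1", start = starts, end = starts + len,
                   type = "DEL", sv_len = len)
  }
  # loci: 1 = all three, 2 = PB+IL, 3 = IL+BNG, 4 = PB only, 5 = BNG only
  il <- mk("il", c(1e4, 5e4, 9e4))
  pb <- mk("pb", c(1e4 + 20, 5e4 + 20, 13e4))
  bng <- mk("bng", c(1e4 - 20, 9e4 + 20, 17e4))
  pan <- build_pan_sv(il, pb, bng)
  expect_equal(nrow(pan), 5)
  # partition: every input call appears exactly once
  members <- unlist(pan$members)
  expect_equal(sort(members),
               sort(c(paste0("IL:", il$call_id), paste0("PB:", pb$call_id),
                      paste0("BNG:", bng$call_id))))
  prov <- setNames(pan$provenance, pan$start)
  expect_equal(unname(prov[as.character(1e4 + 20)]), "PB,IL,BNG")
  expect_equal(pan$platform[pan$provenance == "PB,IL,BNG"], "PB")
  expect_equal(pan$platform[pan$provenance == "IL,BNG"], "IL")
  expect_equal(pan$platform[pan$provenance == "PB,IL"], "PB")
  expect_equal(pan$platform[pan$provenance == "BNG"], "BNG")
  s <- pan_sv_summary(pan)
  expect_equal(sum(s$n), 5)
  g <- glance(pan)
  expect_equal(g$n_records, 5)
})
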