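test_that("genome model honors density-zero, expectation and determinism", {
  gm <- generate_genome_model(1, 1e6, tr_density = 0, snv_spacing_mean = 1000,
                              seed = 7)
  expect_equal(nrow(gm$chroms), 1)
  expect_equal(nrow(gm$tandem_repeats), 0)
  # ~1000 SNVs expected at 1 kb spacing over 1 Mb
  expect_gt(nrow(gm$snvs), 800)
  expect_lt(nrow(gm$snvs), 1200)
  expect_true(all(diff(gm$snvs$pos) > 0))

  gm2a <- generate_genome_model(2, 1e6, 0.1, 1000, seed = 7)
  gm2b <- generate_genome_model(2, 1e6, 0.1, 1000, seed = 7)
  expect_identical(gm2a, gm2b)

  # Monte-Carlo band for merged coverage at tr_density 0.1
  gm3 <- generate_genome_model(1, 1e6, 0.1, 1000, seed = 7)
  cov <- sum(gm3$tandem_repeats$end - gm3$tandem_repeats$start) / 1e6
  expect_gt(cov, 0.05)
  expect_lt(cov, 0.15)

  expect_error(generate_genome_model(1, 1e4, 0, 1000, 1), "1e5")
  expect_error(generate_genome_model(1, 1e6, 0.6, 1000, 1), "tr_density")
})

test_that("planted inversions obey size law, disjointness and genotype mix", {
  gm <- tiny_genome(chrom_length = 1e6)
  one <- plant_inversions(gm, 1, 1e4, 1e4, hom_fraction = 1,
                          complex_fraction = 0, seed = 3)
  expect_equal(one$end - one$start, 1e4)
  expect_equal(one$genotype, "hom")
  expect_equal(one$cls, "simple")
  expect_equal(one$dup_copy_number, 0L)

  gm_big <- tiny_genome(n_chroms = 5, chrom_length = 1e7)
  many <- plant_inversions(gm_big, 100, 5e3, 5e5, hom_fraction = 0.33,
                           complex_fraction = 0.3, seed = 11)
  expect_equal(nrow(many), 100)
  by_chrom <- split(many, many$chrom)
  for (m in by_chrom) {
    m <- m[order(m$start), ]
    if (nrow(m) > 1) expect_true(all(m$start[-1] >= m$end[-nrow(m)]))
  }
  # complex events are heterozygous by construction; hom count among simple
  # follows Binomial(n_simple, 0.33): compare against its central 99% band
  expect_true(all(many$genotype[many$cls == "inverted_duplication"] != "hom"))
  simple <- many[many$cls == "simple", ]
  n_hom <- sum(simple$genotype == "hom")
  band <- qbinom(c(0.005, 0.995), nrow(simple), 0.33)
  expect_gte(n_hom, band[1])
  expect_lte(n_hom, band[2])

  expect_error(
    plant_inversions(tiny_genome(chrom_length = 2e5), 50, 5e4, 5e4, seed = 1),
    class = "svscribe_capacity_error")
})

test_that("composite simulation reproduces orientation signal and haplotags", {
  gm <- tiny_genome(chrom_length = 1e6)
  inv <- tibble::tibble(inv_id = "inv001", chrom = "chr1", start = 4e5,
                        end = 5e5, genotype = "hom", cls = "simple",
                        dup_copy_number = 0L)
  reads <- simulate_strandseq_composite(gm, inv, read_density = 20,
                                        orientation_error = 0,
                                        haplotag_rate = 1, seed = 5)
  inside <- reads[reads$pos >= 4e5 & reads$pos < 5e5, ]
  expect_true(all(inside$orientation == "non_reference"))
  outside <- reads[reads$pos < 4e5 | reads$pos >= 5e5, ]
  expect_true(all(outside$orientation == "reference"))

  # background non-reference fraction concentrates around the error rate
  none <- simulate_strandseq_composite(gm, inv[0, ], read_density = 100,
                                       orientation_error = 0.02, seed = 5)
  frac <- mean(none$orientation == "non_reference")
  expect_gt(frac, 0.015)
  expect_lt(frac, 0.025)

  # het_H1 carrier: all non-reference reads inside are H1-tagged at rate 1
  inv_h1 <- dplyr::mutate(inv, genotype = "het_H1")
  r2 <- simulate_strandseq_composite(gm, inv_h1, read_density = 20,
                                     orientation_error = 0, haplotag_rate = 1,
                                     seed = 5)
  ins <- r2[r2$pos >= 4e5 & r2$pos < 5e5, ]
  expect_true(all(ins$haplotag[ins$orientation == "non_reference"] == "H1"))
  expect_true(all(ins$haplotag[ins$orientation == "reference"] == "H2"))
})

test_that("caller simulation has exact noise-free limits and determinism", {
  gm <- tiny_genome(chrom_length = 1e6)
  truth <- plant_svs(gm, 20, 100, 2000, seed = 2)
  perfect <- caller_profile("perfect", sensitivity = 1, fp_rate = 0,
                            breakpoint_jitter_sd = 0,
                            detectable_types = c("DEL", "INS"))
  calls <- simulate_caller_callsets(truth, perfect, gm, seed = 9)
  expect_equal(nrow(calls), 20)
  m <- calls[order(calls$truth_id), ]
  t <- truth[order(truth$sv_id), ]
  expect_equal(m$start, t$start)
  expect_equal(m$end, t$end)

  blind <- caller_profile("blind", sensitivity = 0, fp_rate = 0)
  expect_equal(nrow(simulate_caller_callsets(truth, blind, gm, seed = 9)), 0)

  profs <- dplyr::bind_rows(caller_profile("a"), caller_profile("b"),
                            caller_profile("c"))
  expect_identical(simulate_caller_callsets(truth, profs, gm, seed = 4),
                   simulate_caller_callsets(truth, profs, gm, seed = 4))
})

test_that("validation evidence separates true from false calls", {
  gm <- tiny_genome(chrom_length = 1e6)
  truth <- plant_svs(gm, 40, 200, 1000, type_mix = c(DEL = 1, INS = 0),
                     hom_fraction = 1, seed = 2)
  prof <- caller_profile("p", sensitivity = 1, fp_rate = 20,
                         breakpoint_jitter_sd = 0,
                         detectable_types = "DEL")
  calls <- simulate_caller_callsets(truth, prof, gm, seed = 3)
  ev <- simulate_validation_evidence(calls, truth, support_mean_true = 20,
                                     support_mean_false = 1,
                                     bng_rel_error_sd = 0, base_depth = 40,
                                     bng_fraction = 1, seed = 6)
  is_true <- !is.na(calls$truth_id)
  # homozygous deletion coverage collapses
  expect_lt(max(ev$mean_depth[is_true]), 5)
  expect_gt(min(ev$mean_depth[!is_true]), 30)
  # optical-map length error 0 means exact length agreement (f_BN = 0)
  expect_equal(ev$L_BN[is_true], abs(calls$sv_len[is_true]))
  # Poisson(1) tail: false calls rarely reach support > 4
  expect_lt(mean(ev$alt_support[!is_true] > 4), 0.05)
})
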