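# End-to-end orchestration on synthetic data: simulate -> Strand-seq
# discovery -> inversion unification -> caller consensus/NCR -> long-read
# validation & merging -> pan-SV integration, with a reproducible manifest.

#' Build a pipeline configuration
#'
#' All thresholds default to the method's standard values; the simulation
#' block defines the synthetic study conditions. The configuration
#' round-trips losslessly through YAML/JSON serialisation.
#'
#' @param seed Master seed; every stage derives labeled sub-streams from it.
#' @param outdir Output directory.
#' @param ... Overrides for any default block entry (named lists are merged
#'   recursively at the top level).
#' @return A `pipeline_config` list.
#' @export
pipeline_config <- function(seed = 1, outdir = tempfile("svscribe_run_"),
                            ...) {
  cfg <- list(
    seed = seed,
    outdir = outdir,
    simulate = list(
      n_chroms = 2, chrom_length = 5e6, tr_density = 0.05,
      snv_spacing_mean = 1360,
      n_inversions = 12, inv_size_min = 2e4, inv_size_max = 3e5,
      hom_fraction = 1 / 3, complex_fraction = 0.3,
      n_svs = 80, sv_size_min = 100, sv_size_max = 5000,
      read_density = 25, orientation_error = 0.02, haplotag_rate = 0.3,
      support_mean_true = 20, support_mean_false = 1,
      bng_rel_error_sd = 0.05, base_depth = 40
    ),
    strandseq = list(window_reads = 250, window_step = 50,
                     nonref_trigger = 0.15, background = 0.02,
                     min_genotype_reads = 50, min_phased_reads = 10,
                     hap_lo = 0.25, hap_hi = 0.75, alpha = 0.01),
    integration = list(ro_min = 0.5, regenotype_min_reads = 25, tr_max = 0.9),
    consensus = list(ci_probs = c(0.1, 0.9), min_matches = 30,
                     default_ci = c(-500, 500), max_len = 1e6, max_k = 3),
    validation = list(min_support = 5, f_max = 0.1, max_min_cov = 30,
                      max_del_depth = 25, ro_non_tr = 0.1, ro_tr = 0.5,
                      max_cluster = 5, min_distance = 1e4, window = 250)
  )
  dots <- list(...)
  for (nm in names(dots)) {
    if (is.list(dots[[nm]]) && nm %in% names(cfg)) {
      cfg[[nm]] <- modifyList(cfg[[nm]], dots[[nm]])
    } else cfg[[nm]] <- dots[[nm]]
  }
  structure(cfg, class = "pipeline_config")
}

#' Run the full synthetic pipeline
#'
#' Executes every stage in dependency order on data simulated under the
#' configuration's seed, writes BED/VCF/TSV outputs plus a JSON run
#' manifest (config hash, per-stage record counts) to `config$outdir`, and
#' returns the results invisibly. Reruns with the same configuration are
#' bit-identical.
#'
#' @param config A [pipeline_config()].
#' @return (Invisibly) list with all stage results and the manifest.
#' @export
run_pipeline <- function(config = pipeline_config()) {
  stopifnot(inherits(config, "pipeline_config"))
  known <- c("seed", "outdir", "simulate", "strandseq", "integration",
             "consensus", "validation")
  unknown <- setdiff(names(config), known)
  if (length(unknown) > 0) {
    abort(sprintf("unknown config key(s): %s", paste(unknown, collapse = ", ")))
  }
  sim <- config$simulate
  seed <- config$seed
  dir.create(config$outdir, showWarnings = FALSE, recursive = TRUE)

  ## stage 1: simulation
  genome <- generate_genome_model(sim$n_chroms, sim$chrom_length,
                                  sim$tr_density, sim$snv_spacing_mean,
                                  seed = seed)
  inv_truth <- plant_inversions(genome, sim$n_inversions, sim$inv_size_min,
                                sim$inv_size_max, sim$hom_fraction,
                                sim$complex_fraction, seed = seed)
  sv_truth <- plant_svs(genome, sim$n_svs, sim$sv_size_min, sim$sv_size_max,
                        seed = seed)
  composite <- simulate_strandseq_composite(genome, inv_truth,
                                            sim$read_density,
                                            sim$orientation_error,
                                            sim$haplotag_rate, seed = seed)
  inv_platforms <- bind_rows(
    caller_profile("IL", 0.7, 0.3, 50, detectable_types = "INV"),
    caller_profile("PB", 0.8, 0.2, 20, detectable_types = "INV"),
    caller_profile("liWGS", 0.6, 0.3, 200, detectable_types = "INV"),
    caller_profile("BNG", 0.5, 0.1, 500, detectable_types = "INV"))
  inv_calls <- simulate_caller_callsets(inv_truth, inv_platforms, genome,
                                        seed = seed) |>
    rename(platform = "caller")
  sv_callers <- bind_rows(
    caller_profile("callerA", 0.85, 1.0, 30),
    caller_profile("callerB", 0.75, 0.6, 60),
    caller_profile("callerC", 0.65, 0.3, 15))
  sv_calls <- simulate_caller_callsets(sv_truth, sv_callers, genome,
                                       seed = seed + 1)
  evidence <- simulate_validation_evidence(sv_calls, sv_truth,
                                           sim$support_mean_true,
                                           sim$support_mean_false,
                                           sim$bng_rel_error_sd,
                                           sim$base_depth, seed = seed)

  ## stage 2: Strand-seq inversion discovery
  params <- do.call(segmentation_params, config$strandseq)
  scan <- call_inversions(composite, params)
  sts_calls <- scan$calls |>
    mutate(platform = "StS",
           genotype = if_else(.data$model_rejected, .data$best_model,
                              .data$genotype))

  ## stage 3: inversion integration
  all_inv <- bind_rows(
    select(inv_calls, "platform", "chrom", "start", "end", "genotype"),
    select(sts_calls, "platform", "chrom", "start", "end", "genotype"))
  itest <- intersection_test(all_inv, config$integration$ro_min)
  rtest <- regenotype_test(
    select(inv_calls, "platform", "chrom", "start", "end", "genotype"),
    composite, params, config$integration$regenotype_min_reads)
  support <- bind_rows(
    itest |> filter(.data$supported) |>
      transmute(.data$chrom, .data$start, .data$end, .data$platform,
                .data$genotype, support_source = "intersection"),
    rtest |> filter(.data$sts_status == "supported") |>
      transmute(.data$chrom, .data$start, .data$end, .data$platform,
                genotype = .data$sts_genotype, support_source = "sts_genotype"),
    sts_calls |> filter(.data$cls %in% c("simple_hom", "simple_het", "complex")) |>
      transmute(.data$chrom, .data$start, .data$end, platform = "StS",
                .data$genotype, cls = if_else(.data$cls == "complex",
                                              "complex", "simple"),
                support_source = "sts_phase"))
  unified_inv <- unify_inversions(support, genome, config$integration$ro_min,
                                  config$integration$tr_max)

  ## stage 4: caller consensus and combinations
  gold <- normalize_truth(sv_truth)
  cis <- suppressWarnings(estimate_breakpoint_ci(
    sv_calls, gold, probs = config$consensus$ci_probs,
    min_matches = config$consensus$min_matches,
    default_ci = config$consensus$default_ci))
  merged_cl <- ro_cluster(sv_calls, 0.5)
  consensus <- sv_calls |>
    mutate(._cl = merged_cl) |>
    group_by(.data$._cl) |>
    summarise(chrom = first(.data$chrom), start = min(.data$start),
              end = max(.data$end),
              n_callers = dplyr::n_distinct(.data$caller)) |>
    select(-"._cl")
  cyto <- bind_rows(
    centromere_track(genome),
    tibble(chrom = genome$chroms$chrom, start = 0,
           end = 1e4),
    tibble(chrom = genome$chroms$chrom,
           start = genome$chroms$length - 1e4, end = genome$chroms$length))
  qc <- qc_filter(consensus, cyto, config$consensus$max_len)
  combos <- evaluate_combinations(sv_calls,
                                  oracle = function(x) !is.na(x$truth_id),
                                  max_k = config$consensus$max_k)

  ## stage 5: long-read validation, haplotype merge, unification
  v <- config$validation
  ev <- left_join(sv_calls, evidence, by = "call_id")
  hap_of <- function(z) if_else(z == "hom", "both", if_else(z == "het_H1", "H1", "H2"))
  truth_hap <- setNames(hap_of(sv_truth$zygosity), sv_truth$sv_id)
  pb_pool <- ev |> filter(.data$caller == "callerA") |>
    mutate(pbrc = .data$alt_support)
  hap_lbl <- truth_hap[pb_pool$truth_id]
  hap_lbl[is.na(hap_lbl)] <- rep(c("H1", "H2"),
                                 length.out = sum(is.na(hap_lbl)))
  h1 <- pb_pool[hap_lbl %in% c("H1", "both"), ]
  h2 <- pb_pool[hap_lbl %in% c("H2", "both"), ]
  diploid <- merge_haplotypes(h1, h2, genome$tandem_repeats,
                              v$ro_non_tr, v$ro_tr, v$max_cluster)
  phased_sv <- pb_pool
  mspac <- ev |> filter(.data$caller == "callerB") |>
    mutate(pbrc = .data$alt_support)
  bng_ev <- ev |> filter(!is.na(.data$L_BN)) |>
    transmute(.data$chrom, .data$start, .data$end, .data$type, l_bn = .data$L_BN)
  pb_unified <- unify_pb(phased_sv, mspac, bng_ev, v$f_max,
                         min_distance = v$min_distance, window = v$window)
  il_set <- ev |> filter(.data$caller == "callerC")
  il_f <- il_concordance_filter(
    il_set, select(phased_sv, "chrom", "start", "end", "type", "sv_len"),
    mutate(select(mspac, "chrom", "start", "end", "type", "sv_len"),
           read_id = sprintf("r%d", seq_len(nrow(mspac)))),
    select(bng_ev, "chrom", "start", "end", "type", sv_len = "l_bn"),
    setNames(il_set$mean_depth, il_set$call_id),
    max_del_depth = v$max_del_depth)
  pan <- build_pan_sv(filter(il_f, .data$concordant),
                      pb_unified,
                      bng_ev |> mutate(call_id = sprintf("bng%04d", row_number()),
                                       sv_len = .data$l_bn))

  ## outputs + manifest
  out <- file.path(config$outdir, c(
    composite = "composite.tsv", inv_truth = "truth_inversions.bed",
    sv_truth = "truth_svs.bed", unified_inv = "unified_inversions.bed",
    unified_inv_vcf = "unified_inversions.vcf", qc = "consensus_qc.tsv",
    combos = "combinations.tsv", pb_vcf = "pb_unified.vcf",
    pan_vcf = "pan_sv.vcf", pan_summary = "pan_sv_summary.tsv",
    manifest = "manifest.json"))
  names(out) <- c("composite", "inv_truth", "sv_truth", "unified_inv",
                  "unified_inv_vcf", "qc", "combos", "pb_vcf", "pan_vcf",
                  "pan_summary", "manifest")
  write_composite_tsv(composite, out["composite"])
  write_sv_bed(mutate(inv_truth, type = "INV", sv_len = end - start),
               out["inv_truth"])
  write_sv_bed(sv_truth |> rename(call_id = "sv_id") |>
                 mutate(genotype = .data$zygosity), out["sv_truth"])
  write_sv_bed(unified_inv |>
                 transmute(chrom = .data$chrom, start = .data$invr_start,
                           end = .data$invr_end, type = "INV",
                           sv_len = .data$invr_end - .data$invr_start,
                           genotype = .data$consensus_genotype),
               out["unified_inv"])
  write_sv_vcf(unified_inv |>
                 transmute(chrom = .data$chrom, start = .data$invr_start,
                           end = .data$invr_end, type = "INV",
                           sv_len = .data$invr_end - .data$invr_start,
                           genotype = if_else(.data$consensus_genotype == "hom",
                                              "1/1", "0/1")),
               out["unified_inv_vcf"])
  utils::write.table(as.data.frame(qc), out["qc"], sep = "\t",
                     row.names = FALSE, quote = FALSE)
  utils::write.table(as.data.frame(combos), out["combos"], sep = "\t",
                     row.names = FALSE, quote = FALSE)
  write_sv_vcf(pb_unified, out["pb_vcf"])
  write_sv_vcf(select(as_tibble(pan), "call_id" = "record_id", "chrom",
                      "start", "end", "type", "sv_len"), out["pan_vcf"])
  utils::write.table(as.data.frame(pan_sv_summary(pan)), out["pan_summary"],
                     sep = "\t", row.names = FALSE, quote = FALSE)
  manifest <- list(
    config_hash = config_hash(config),
    seed = seed,
    counts = list(
      reads = nrow(composite), inversion_truth = nrow(inv_truth),
      sv_truth = nrow(sv_truth), strandseq_candidates = nrow(scan$calls),
      supported = nrow(support), unified_inversions = nrow(unified_inv),
      consensus_calls = nrow(qc), qc_pass = sum(qc$label == "PASS"),
      combinations = nrow(combos), pb_unified = nrow(pb_unified),
      il_concordant = sum(il_f$concordant), pan_sv_records = nrow(pan)
    )
  )
  jsonlite::write_json(manifest, out["manifest"], auto_unbox = TRUE,
                       pretty = TRUE, digits = NA)
  invisible(list(genome = genome, inv_truth = inv_truth, sv_truth = sv_truth,
                 composite = composite, scan = scan, support = support,
                 unified_inversions = unified_inv, breakpoint_cis = cis,
                 consensus_qc = qc, combinations = combos,
                 diploid = diploid, pb_unified = pb_unified,
                 il_filtered = il_f, pan_sv = pan, manifest = manifest,
                 paths = out))
}

# Stable hash of the configuration (md5 of its canonical serialization);
# the output directory is not part of the scientific configuration.
config_hash <- function(config) {
  cfg <- unclass(config)
  cfg$outdir <- NULL
  tmp <- tempfile()
  on.exit(unlink(tmp))
  writeLines(paste(deparse(cfg), collapse = "\n"), tmp)
  unname(tools::md5sum(tmp))
}
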