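# Strand-seq inversion discovery from composite files of oriented reads.
#
# Discovery scans read-ratio windows (250 reads, step 50), genotypes
# candidate loci against three exact binomial models (background b, 0.5,
# 1 - b), and classifies loci from strand-aware haplotype ratios.

#' Segmentation and genotyping parameters
#'
#' Houses every tunable of the Strand-seq stage with its standard default:
#' a 250-read sliding window, a >15% non-reference trigger, a 2% background
#' rate allowed in the homozygous states, a 50-read genotyping minimum, a
#' 10-phased-read minimum per strand, and the 0.25/0.75 haplotype-ratio
#' bounds separating "single haplotype" from "both haplotypes" on a strand.
#'
#' @param window_reads Sliding window size, in reads.
#' @param window_step Window step, in reads.
#' @param nonref_trigger Non-reference fraction above which a window
#'   triggers (strict).
#' @param background Background non-reference rate `b` allowed in the
#'   homozygous models.
#' @param min_genotype_reads Minimum reads at a locus to genotype it.
#' @param min_phased_reads Minimum haplotagged reads per strand for a
#'   haplotype ratio.
#' @param hap_lo,hap_hi Haplotype-ratio bounds: below `hap_lo` or above
#'   `hap_hi` means one haplotype on the strand, between them means both.
#' @param alpha Rejection level of the exact two-sided test against the
#'   best-fitting model.
#' @param boundary_score_cut Per-read score offset for changepoint boundary
#'   refinement: candidate boundaries maximize the sum of
#'   `is_nonref - boundary_score_cut` over the run, so reads in background
#'   regions (non-reference rate ~ `background`) score negative and reads
#'   inside an event (rate >= 1/3) score positive. Must lie strictly
#'   between `background` and 1/3.
#' @return A list of class `segmentation_params`.
#' @export
segmentation_params <- function(window_reads = 250, window_step = 50,
                                nonref_trigger = 0.15, background = 0.02,
                                min_genotype_reads = 50, min_phased_reads = 10,
                                hap_lo = 0.25, hap_hi = 0.75, alpha = 0.01,
                                boundary_score_cut = 0.25) {
  if (nonref_trigger <= 0 || nonref_trigger >= 1) abort("`nonref_trigger` in (0, 1).")
  if (hap_lo >= hap_hi) abort("`hap_lo` must be < `hap_hi`.")
  if (background < 0 || background >= 0.5) abort("`background` in [0, 0.5).")
  if (boundary_score_cut <= background || boundary_score_cut >= 1 / 3) {
    abort("`boundary_score_cut` must lie between `background` and 1/3.")
  }
  structure(
    list(window_reads = window_reads, window_step = window_step,
         nonref_trigger = nonref_trigger, background = background,
         min_genotype_reads = min_genotype_reads,
         min_phased_reads = min_phased_reads,
         hap_lo = hap_lo, hap_hi = hap_hi, alpha = alpha,
         boundary_score_cut = boundary_score_cut),
    class = "segmentation_params")
}

#' Read ratio of an interval
#'
#' Counts reference and non-reference oriented reads in a half-open interval
#' and returns the read ratio (non-reference / total), the proxy for
#' inversion dosage.
#'
#' @param reads Oriented-read tibble (`chrom`, `pos`, `orientation`).
#' @param chrom,start,end The interval.
#' @return One-row tibble: `chrom`, `start`, `end`, `n_ref`, `n_nonref`,
#'   `read_ratio`.
#' @export
compute_read_ratio <- function(reads, chrom, start, end) {
  if (end <= start) abort("empty interval.")
  sel <- reads$chrom == chrom & reads$pos >= start & reads$pos < end
  n_nonref <- sum(reads$orientation[sel] == "non_reference")
  n_ref <- sum(sel) - n_nonref
  if (n_ref + n_nonref == 0) {
    abort("no reads in interval; read ratio undefined.",
          class = "svscribe_empty_locus")
  }
  tibble(chrom = chrom, start = start, end = end, n_ref = n_ref,
         n_nonref = n_nonref, read_ratio = n_nonref / (n_ref + n_nonref))
}

#' Segment a composite file into candidate inversion loci
#'
#' Slides a `window_reads`-read window (step `window_step`) along each
#' chromosome and scores the non-reference fraction. Maximal runs of
#' overlapping triggering windows (fraction > `nonref_trigger`) merge into
#' one candidate. Because a triggering run extends up to a window span past
#' the underlying segmental change on each side, the candidate boundaries
#' are refined to the maximal-scoring contiguous stretch of reads in the run
#' (score `is_nonref - boundary_score_cut` per read, the classic
#' changepoint/maximum-subarray localisation of the orientation switch) and
#' then trimmed to its first and last non-reference read; read counts are
#' re-taken over the trimmed interval. Chromosomes with fewer than
#' `window_reads` reads yield no candidates.
#'
#' @param reads Oriented-read tibble sorted by (`chrom`, `pos`).
#' @param params A [segmentation_params()] object.
#' @return Candidate tibble: `chrom`, `start`, `end`, `n_ref`, `n_nonref`,
#'   `read_ratio`.
#' @export
segment_composite <- function(reads, params = segmentation_params()) {
  stopifnot(inherits(params, "segmentation_params"))
  w <- params$window_reads
  purrr::map(split(reads, reads$chrom), function(rc) {
    n <- nrow(rc)
    if (n < w) return(NULL)
    if (is.unsorted(rc$pos)) rc <- arrange(rc, .data$pos)
    nonref <- rc$orientation == "non_reference"
    cs <- c(0, cumsum(nonref))
    starts <- seq(1L, n - w + 1L, by = params$window_step)
    if (tail(starts, 1) != n - w + 1L) starts <- c(starts, n - w + 1L)
    frac <- (cs[starts + w] - cs[starts]) / w
    trig <- frac > params$nonref_trigger
    if (!any(trig)) return(NULL)
    # merge triggering windows whose read-index spans overlap or touch
    ts <- starts[trig]; te <- ts + w - 1L
    runs <- list(); cur <- c(ts[1], te[1])
    for (i in seq_along(ts)[-1]) {
      if (ts[i] <= cur[2] + 1L) cur[2] <- te[i]
      else { runs <- c(runs, list(cur)); cur <- c(ts[i], te[i]) }
    }
    runs <- c(runs, list(cur))
    purrr::map(runs, function(r) {
      idx <- seq(r[1], r[2])
      sub <- max_subarray(as.numeric(nonref[idx]) - params$boundary_score_cut)
      idx <- idx[seq(sub[1], sub[2])]
      nr_idx <- idx[nonref[idx]]
      if (length(nr_idx) == 0) return(NULL)
      lo <- rc$pos[min(nr_idx)]; hi <- rc$pos[max(nr_idx)] + 1
      compute_read_ratio(rc, rc$chrom[1], lo, hi)
    }) |> list_rbind()
  }) |>
    list_rbind() |>
    (\(x) if (is.null(x) || nrow(x) == 0) {
      tibble(chrom = character(), start = double(), end = double(),
             n_ref = integer(), n_nonref = integer(), read_ratio = double())
    } else arrange(x, .data$chrom, .data$start))()
}

#' Genotype loci from oriented read counts
#'
#' Compares observed (reference, non-reference) counts against three exact
#' binomial models of the non-reference proportion: homozygous reference
#' (`b`), heterozygous (0.5) and homozygous inverted (`1 - b`), where `b` is
#' the background rate allowed in the homozygous states. The genotype is the
#' model of maximal binomial likelihood; loci with fewer than
#' `min_genotype_reads` reads, or whose best model is rejected by an exact
#' two-sided test at level `alpha`, are `untyped`. The maximum-likelihood
#' model is always reported as `best_model` together with the per-model
#' p-values.
#'
#' @param loci Tibble with columns `n_ref` and `n_nonref` (or a single
#'   locus given as two counts via `n_ref`/`n_nonref` arguments).
#' @param params A [segmentation_params()].
#' @return `loci` with columns `genotype` (`hom_ref`/`het`/`hom_inv`/
#'   `untyped`), `best_model`, `p_hom_ref`, `p_het`, `p_hom_inv` appended.
#' @export
genotype_locus <- function(loci, params = segmentation_params()) {
  if (!is.data.frame(loci)) abort("`loci` must be a data frame.")
  stopifnot(all(c("n_ref", "n_nonref") %in% names(loci)))
  if (any(loci$n_ref < 0 | loci$n_nonref < 0)) abort("counts must be >= 0.")
  b <- params$background
  models <- c(hom_ref = b, het = 0.5, hom_inv = 1 - b)
  res <- purrr::pmap(list(loci$n_ref, loci$n_nonref), function(nr, nn) {
    n <- nr + nn
    lik <- dbinom(nn, n, models)
    best <- names(models)[which.max(lik)]
    pv <- if (n == 0) rep(NA_real_, 3) else
      vapply(models, function(p) binom.test(nn, n, p)$p.value, numeric(1))
    genotype <- if (n < params$min_genotype_reads) "untyped"
    else if (pv[[which(names(models) == best)]] < params$alpha) "untyped"
    else best
    tibble(genotype = genotype, best_model = best,
           p_hom_ref = pv[[1]], p_het = pv[[2]], p_hom_inv = pv[[3]])
  }) |> list_rbind()
  bind_cols(loci, res)
}

#' Strand-aware haplotype ratios at a locus
#'
#' Among haplotagged reads of each orientation separately, the fraction
#' assigned to H1. A strand's ratio is `NA` when it carries fewer than
#' `min_phased_reads` tagged reads.
#'
#' @param reads Oriented-read tibble with `haplotag`.
#' @param chrom,start,end The locus interval.
#' @param params A [segmentation_params()].
#' @return One-row tibble: `hap_ratio_ref`, `hap_ratio_nonref`,
#'   `n_phased_ref`, `n_phased_nonref`.
#' @export
compute_haplotype_ratios <- function(reads, chrom, start, end,
                                     params = segmentation_params()) {
  if (end <= start) abort("empty interval.")
  sel <- reads[reads$chrom == chrom & reads$pos >= start & reads$pos < end, ]
  one <- function(orient) {
    tags <- sel$haplotag[sel$orientation == orient & sel$haplotag != "untagged"]
    n <- length(tags)
    ratio <- if (n < params$min_phased_reads) NA_real_ else mean(tags == "H1")
    list(ratio = ratio, n = n)
  }
  r <- one("reference"); nr <- one("non_reference")
  tibble(hap_ratio_ref = r$ratio, hap_ratio_nonref = nr$ratio,
         n_phased_ref = r$n, n_phased_nonref = nr$n)
}

#' Classify genotyped inversions from haplotype ratios
#'
#' Applies the strand-aware phase signatures: a homozygous locus with both
#' haplotypes on the non-reference strand (ratio strictly between `hap_lo`
#' and `hap_hi`) is a simple homozygous inversion; a heterozygous locus with
#' opposite single haplotypes on the two strands (> `hap_hi` on one, <
#' `hap_lo` on the other) is a simple heterozygous inversion and is phased
#' by its non-reference strand (ratio > `hap_hi` marks the inversion on H1,
#' genotype string `"1/0"`; < `hap_lo` marks H2, `"0/1"`); a heterozygous
#' locus with a single haplotype on the non-reference strand but both on
#' the reference strand is a complex event (inverted duplication signature).
#' Loci matching no signature, or missing a required ratio, are
#' `unclassified`.
#'
#' @param genotype Character vector of genotypes
#'   (`hom_ref`/`het`/`hom_inv`/`untyped`).
#' @param hap_ratio_ref,hap_ratio_nonref Haplotype ratios per strand (`NA`
#'   when undefined).
#' @param params A [segmentation_params()].
#' @return Tibble with `cls` (`simple_hom`/`simple_het`/`complex`/
#'   `unclassified`) and `phase` (`"1/0"`, `"0/1"` or `NA`).
#' @export
classify_inversion <- function(genotype, hap_ratio_ref, hap_ratio_nonref,
                               params = segmentation_params()) {
  n <- length(genotype)
  lo <- params$hap_lo; hi <- params$hap_hi
  cls <- rep("unclassified", n)
  phase <- rep(NA_character_, n)
  nonref_mid <- !is.na(hap_ratio_nonref) &
    hap_ratio_nonref > lo & hap_ratio_nonref < hi
  nonref_single <- !is.na(hap_ratio_nonref) &
    (hap_ratio_nonref < lo | hap_ratio_nonref > hi)
  ref_mid <- !is.na(hap_ratio_ref) & hap_ratio_ref > lo & hap_ratio_ref < hi
  ref_single_hi <- !is.na(hap_ratio_ref) & hap_ratio_ref > hi
  ref_single_lo <- !is.na(hap_ratio_ref) & hap_ratio_ref < lo
  cls[genotype == "hom_inv" & nonref_mid] <- "simple_hom"
  het <- genotype == "het"
  sh <- het & ((ref_single_hi & !is.na(hap_ratio_nonref) & hap_ratio_nonref < lo) |
               (ref_single_lo & !is.na(hap_ratio_nonref) & hap_ratio_nonref > hi))
  cls[sh] <- "simple_het"
  phase[sh & hap_ratio_nonref > hi] <- "1/0"
  phase[sh & hap_ratio_nonref < lo] <- "0/1"
  cx <- het & !sh & nonref_single & ref_mid
  cls[cx] <- "complex"
  tibble(cls = cls, phase = phase)
}

#' Discover, genotype and classify inversions in one composite file
#'
#' Runs segmentation, genotyping and strand-aware classification, returning
#' a `strandseq_scan` object. Loci whose best binomial model is rejected at
#' level `alpha` but that meet the read minimum are still classified using
#' the maximum-likelihood model: such non-diploid read ratios are exactly
#' the signature of inverted duplications, which the phase signatures then
#' resolve (they are flagged `model_rejected = TRUE`).
#'
#' @param reads Oriented-read tibble (`chrom`, `pos`, `orientation`,
#'   `haplotag`), sorted by position within chromosome.
#' @param params A [segmentation_params()].
#' @return A `strandseq_scan`: list with `calls` (candidate loci with
#'   genotype, haplotype ratios, class, phase), `params`, `n_reads`.
#' @export
call_inversions <- function(reads, params = segmentation_params()) {
  cand <- segment_composite(reads, params)
  if (nrow(cand) == 0) {
    calls <- bind_cols(cand, tibble(genotype = character(),
                                    best_model = character(),
                                    p_hom_ref = double(), p_het = double(),
                                    p_hom_inv = double(),
                                    hap_ratio_ref = double(),
                                    hap_ratio_nonref = double(),
                                    n_phased_ref = integer(),
                                    n_phased_nonref = integer(),
                                    model_rejected = logical(),
                                    cls = character(), phase = character()))
    return(structure(list(calls = calls, params = params,
                          n_reads = nrow(reads)),
                     class = "strandseq_scan"))
  }
  gt <- genotype_locus(cand, params)
  hr <- purrr::pmap(list(gt$chrom, gt$start, gt$end), function(ch, s, e) {
    compute_haplotype_ratios(reads, ch, s, e, params)
  }) |> list_rbind()
  gt <- bind_cols(gt, hr)
  total <- gt$n_ref + gt$n_nonref
  gt$model_rejected <- gt$genotype == "untyped" & total >= params$min_genotype_reads
  effective_gt <- if_else(gt$model_rejected, gt$best_model, gt$genotype)
  cl <- classify_inversion(effective_gt, gt$hap_ratio_ref, gt$hap_ratio_nonref,
                           params)
  calls <- bind_cols(gt, cl)
  structure(list(calls = calls, params = params, n_reads = nrow(reads)),
            class = "strandseq_scan")
}

#' @export
print.strandseq_scan <- function(x, ...) {
  cat(sprintf("<strandseq_scan> %d candidate loci from %d reads\n",
              nrow(x$calls), x$n_reads))
  print(dplyr::count(x$calls, .data$cls))
  invisible(x)
}

#' Flag putative reference-assembly misorients across individuals
#'
#' A locus genotyped homozygous-inverted in *every* individual most likely
#' marks a region where the reference assembly itself is misoriented rather
#' than a real polymorphism. Loci are matched across individuals by
#' single-linkage 50% reciprocal-overlap clustering.
#'
#' @param calls Tibble of genotyped loci from two or more individuals, with
#'   columns `individual`, `chrom`, `start`, `end`, `genotype`.
#' @param ro_min Reciprocal-overlap threshold for cross-individual matching.
#' @return `calls` with a logical `misorient` column; flagged loci should be
#'   excluded downstream.
#' @export
flag_misorients <- function(calls, ro_min = 0.5) {
  n_ind <- dplyr::n_distinct(calls$individual)
  if (n_ind < 2) abort("misorient flagging needs >= 2 individuals.")
  calls$._cl <- ro_cluster(calls, ro_min)
  flagged <- calls |>
    group_by(.data$._cl) |>
    summarise(
      misorient = dplyr::n_distinct(.data$individual) == n_ind &&
        all(.data$genotype == "hom_inv")
    )
  calls |>
    left_join(flagged, by = "._cl") |>
    select(-"._cl")
}
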