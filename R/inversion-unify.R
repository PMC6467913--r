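# Cross-platform inversion unification: intersection test, composite-file
# re-genotyping, and merging into a non-redundant unified callset with
# outer (InvR) and inner consensus breakpoints.

#' Cross-platform intersection test
#'
#' A call is supported when a call from a *different* platform shows > 50%
#' reciprocal overlap with it — the "two independent technologies"
#' requirement. Same-platform overlaps never count.
#'
#' @param calls Tibble of platform inversion calls: `platform`, `chrom`,
#'   `start`, `end` and optionally `genotype`.
#' @param ro_min Reciprocal-overlap threshold (strict).
#' @return `calls` with `supported` (logical) and `partners` (list column of
#'   supporting platforms) appended.
#' @export
intersection_test <- function(calls, ro_min = 0.5) {
  if (dplyr::n_distinct(calls$platform) < 2) {
    abort("intersection test needs calls from >= 2 platforms.")
  }
  supported <- logical(nrow(calls))
  partners <- vector("list", nrow(calls))
  for (ch in unique(calls$chrom)) {
    idx <- which(calls$chrom == ch)
    ir <- as_iranges0(calls$start[idx], calls$end[idx])
    hits <- IRanges::findOverlaps(ir, ir)
    qi <- S4Vectors::queryHits(hits); si <- S4Vectors::subjectHits(hits)
    keep <- qi != si & calls$platform[idx][qi] != calls$platform[idx][si]
    qi <- qi[keep]; si <- si[keep]
    if (length(qi) == 0) next
    ro <- reciprocal_overlap(calls$start[idx][qi], calls$end[idx][qi],
                             calls$start[idx][si], calls$end[idx][si])
    pass <- pmin(ro$frac_a, ro$frac_b) > ro_min
    for (k in which(pass)) {
      i <- idx[qi[k]]
      supported[i] <- TRUE
      partners[[i]] <- union(partners[[i]], calls$platform[idx][si[k]])
    }
  }
  calls$supported <- supported
  calls$partners <- partners
  calls
}

#' Re-genotype platform calls in a Strand-seq composite file
#'
#' Tests whether orthogonal support for each predicted inversion is seen in
#' the composite file by genotyping the call's interval with the three-model
#' exact binomial genotyper. A call is `supported` when the composite
#' genotype is heterozygous or homozygous-inverted, `refuted` when
#' homozygous-reference (or the fit is rejected), and `ungenotyped` when
#' fewer than `min_reads` reads cover the locus.
#'
#' @param calls Platform-call tibble (`chrom`, `start`, `end`).
#' @param composite Oriented-read tibble.
#' @param params [segmentation_params()] supplying background and alpha.
#' @param min_reads Minimum composite reads to genotype, default 25.
#' @return `calls` with `sts_genotype` and `sts_status`
#'   (`supported`/`refuted`/`ungenotyped`) appended.
#' @export
regenotype_test <- function(calls, composite, params = segmentation_params(),
                            min_reads = 25) {
  p2 <- params
  p2$min_genotype_reads <- min_reads
  counts <- purrr::pmap(list(calls$chrom, calls$start, calls$end),
                        function(ch, s, e) {
    sel <- composite$chrom == ch & composite$pos >= s & composite$pos < e
    nn <- sum(composite$orientation[sel] == "non_reference")
    tibble(n_ref = sum(sel) - nn, n_nonref = nn)
  }) |> list_rbind()
  gt <- genotype_locus(counts, p2)
  calls$sts_genotype <- gt$genotype
  calls$sts_status <- dplyr::case_when(
    counts$n_ref + counts$n_nonref < min_reads ~ "ungenotyped",
    gt$genotype %in% c("het", "hom_inv") ~ "supported",
    TRUE ~ "refuted"
  )
  calls
}

#' Merge supported inversions into the unified callset
#'
#' Merges the three supported inversion lists (cross-platform intersection,
#' Strand-seq re-genotyping, Strand-seq phase-classified) into a
#' non-redundant set by single-linkage > 50% reciprocal-overlap chaining.
#' Per merged locus: the outer breakpoints (InvR) are the outermost start
#' and end over member predictions; with more than one prediction the inner
#' breakpoints are the consensus region covered by at least half of the
#' overlapping predictions, otherwise they equal the InvR. The consensus
#' genotype is the majority over contributing platforms (one vote each),
#' `ambiguous` when no majority exists. Pericentric events (InvR overlapping
#' the centromere annotation) and events with tandem-repeat fraction >
#' `tr_max` are removed. A locus is `complex` when any supporting Strand-seq
#' call is classified complex or carries a copy-number flag.
#'
#' @param support Tibble of supported calls with columns `chrom`, `start`,
#'   `end`, `platform`, `support_source` (one of `intersection`,
#'   `sts_genotype`, `sts_phase`), optional `genotype` (normalised to
#'   `het`/`hom`), optional `cls`, optional `cn_flag`.
#' @param genome A `genome_model` providing centromere and tandem-repeat
#'   tracks.
#' @param ro_min Reciprocal-overlap threshold for chaining.
#' @param tr_max Maximum tolerated tandem-repeat fraction.
#' @return Tibble of unified inversions: `chrom`, `invr_start`, `invr_end`,
#'   `inner_start`, `inner_end`, `platforms`, `support_sources`,
#'   `n_predictions`, `consensus_genotype`, `cls`.
#' @export
unify_inversions <- function(support, genome, ro_min = 0.5, tr_max = 0.9) {
  if (nrow(support) == 0) {
    return(tibble(chrom = character(), invr_start = double(),
                  invr_end = double(), inner_start = double(),
                  inner_end = double(), platforms = list(),
                  support_sources = list(), n_predictions = integer(),
                  consensus_genotype = character(), cls = character()))
  }
  if (!"genotype" %in% names(support)) support$genotype <- NA_character_
  if (!"cls" %in% names(support)) support$cls <- NA_character_
  if (!"cn_flag" %in% names(support)) support$cn_flag <- FALSE
  support$._cl <- ro_cluster(support, ro_min)
  uni <- support |>
    group_by(.data$._cl) |>
    summarise(
      chrom = first(.data$chrom),
      invr_start = min(.data$start), invr_end = max(.data$end),
      inner = list(consensus_inner(.data$start, .data$end)),
      platforms = list(sort(unique(.data$platform))),
      support_sources = list(sort(unique(.data$support_source))),
      n_predictions = n(),
      consensus_genotype = majority_genotype(.data$genotype, .data$platform),
      cls = if (any(.data$cls %in% "complex") || any(.data$cn_flag))
        "complex" else "simple"
    ) |>
    mutate(inner_start = map_dbl(.data$inner, 1),
           inner_end = map_dbl(.data$inner, 2)) |>
    select(-"inner", -"._cl")
  # removal filters: pericentric and tandem-repeat-dominated loci
  cen <- centromere_track(genome)
  iv <- tibble(chrom = uni$chrom, start = uni$invr_start, end = uni$invr_end)
  peri <- purrr::pmap_lgl(iv, function(chrom, start, end) {
    ci <- cen[cen$chrom == chrom, ]
    nrow(ci) > 0 && start < ci$end && end > ci$start
  })
  trf <- tandem_repeat_fraction(iv, genome$tandem_repeats)
  uni <- uni[!peri & trf <= tr_max, , drop = FALSE]
  uni |>
    select("chrom", "invr_start", "invr_end", "inner_start", "inner_end",
           "platforms", "support_sources", "n_predictions",
           "consensus_genotype", "cls") |>
    arrange(.data$chrom, .data$invr_start)
}

# Consensus region covered by at least half of k overlapping predictions;
# with a single prediction the inner breakpoints match the outer ones.
consensus_inner <- function(start, end) {
  k <- length(start)
  if (k == 1) return(c(start, end))
  bp <- sort(unique(c(start, end)))
  seg_cov <- vapply(seq_len(length(bp) - 1), function(i) {
    sum(start <= bp[i] & end >= bp[i + 1])
  }, numeric(1))
  need <- ceiling(k / 2)
  ok <- which(seg_cov >= need)
  if (length(ok) == 0) return(c(min(start), max(end)))
  c(bp[min(ok)], bp[max(ok) + 1])
}

# Majority genotype with one vote per platform; ties -> ambiguous.
majority_genotype <- function(genotype, platform) {
  votes <- tibble(genotype = genotype, platform = platform) |>
    filter(!is.na(.data$genotype)) |>
    mutate(genotype = if_else(.data$genotype %in% c("hom_inv", "1/1"), "hom",
                              if_else(.data$genotype %in% c("het", "0/1", "1/0", "0|1", "1|0"),
                                      "het", .data$genotype))) |>
    distinct(.data$platform, .data$genotype)
  if (nrow(votes) == 0) return("ambiguous")
  tab <- sort(table(votes$genotype), decreasing = TRUE)
  if (length(tab) > 1 && tab[1] == tab[2]) return("ambiguous")
  names(tab)[1]
}
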