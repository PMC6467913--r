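# Diploid merging of haplotype-resolved callsets and unification of the
# two long-read assembly callsets into one PB callset.

#' Merge haplotype-resolved callsets into diploid calls
#'
#' Tandem-repeat loci (track padded by `tr_pad` bp and merged) carrying six
#' or more SVs on either haplotype are set aside: their calls are removed
#' from both haplotypes and the locus recorded. Remaining calls are matched
#' across haplotypes by reciprocal overlap with a tandem-repeat-aware
#' threshold — a loose 0.10 outside tandem repeats (breakpoints of the same
#' SV assembled on separate haplotypes are consistent there) and 0.50
#' inside. Matched pairs become one homozygous call (genotype `1/1`,
#' H1 representation); unmatched calls stay heterozygous (`1/0` on H1,
#' `0/1` on H2).
#'
#' @param h1_calls,h2_calls Per-haplotype call tibbles: `call_id`, `chrom`,
#'   `start`, `end`, `type`, `sv_len`.
#' @param tr_track Tandem-repeat track tibble (`chrom`, `start`, `end`).
#' @param ro_non_tr,ro_tr Reciprocal-overlap thresholds outside/inside
#'   tandem repeats.
#' @param max_cluster Maximum SVs a tandem-repeat locus may carry per
#'   haplotype before it is set aside (6 or more are removed).
#' @param tr_pad Padding added to tandem-repeat annotations, bp.
#' @return List with `calls` (diploid tibble with `gt` and provenance
#'   columns `h1_id`/`h2_id`) and `set_aside_loci` (tibble of removed
#'   tandem-repeat loci with their call counts).
#' @export
merge_haplotypes <- function(h1_calls, h2_calls, tr_track,
                             ro_non_tr = 0.10, ro_tr = 0.50,
                             max_cluster = 5, tr_pad = 20) {
  tr <- merge_track(tr_track, pad = tr_pad)
  tr$locus_id <- seq_len(nrow(tr))
  assign_locus <- function(calls) {
    locus <- rep(NA_integer_, nrow(calls))
    for (ch in unique(calls$chrom)) {
      idx <- which(calls$chrom == ch)
      tri <- tr[tr$chrom == ch, ]
      if (nrow(tri) == 0) next
      hits <- IRanges::findOverlaps(as_iranges0(calls$start[idx], calls$end[idx]),
                                    as_iranges0(tri$start, tri$end),
                                    select = "first")
      locus[idx] <- tri$locus_id[hits]
    }
    locus
  }
  h1_calls$tr_locus <- assign_locus(h1_calls)
  h2_calls$tr_locus <- assign_locus(h2_calls)
  count_loci <- function(calls) {
    loc <- calls$tr_locus[!is.na(calls$tr_locus)]
    tab <- table(loc)
    tibble(tr_locus = as.integer(names(tab)), n = as.integer(tab))
  }
  per_locus <- bind_rows(count_loci(h1_calls), count_loci(h2_calls))
  bad <- if (nrow(per_locus) == 0) {
    tibble(tr_locus = integer(), max_n = integer())
  } else {
    per_locus |>
      group_by(.data$tr_locus) |>
      summarise(max_n = max(.data$n)) |>
      filter(.data$max_n > max_cluster)
  }
  set_aside <- tr |>
    filter(.data$locus_id %in% bad$tr_locus) |>
    left_join(bad, by = c(locus_id = "tr_locus"))
  h1 <- filter(h1_calls, is.na(.data$tr_locus) | !.data$tr_locus %in% bad$tr_locus)
  h2 <- filter(h2_calls, is.na(.data$tr_locus) | !.data$tr_locus %in% bad$tr_locus)
  # cross-haplotype matching, TR-aware threshold, greedy best-RO pairing
  pairs <- list()
  for (ch in unique(c(h1$chrom, h2$chrom))) {
    i1 <- which(h1$chrom == ch); i2 <- which(h2$chrom == ch)
    if (length(i1) == 0 || length(i2) == 0) next
    hits <- IRanges::findOverlaps(as_iranges0(h1$start[i1], h1$end[i1]),
                                  as_iranges0(h2$start[i2], h2$end[i2]))
    qi <- S4Vectors::queryHits(hits); si <- S4Vectors::subjectHits(hits)
    if (length(qi) == 0) next
    same_type <- h1$type[i1][qi] == h2$type[i2][si]
    ro <- reciprocal_overlap(h1$start[i1][qi], h1$end[i1][qi],
                             h2$start[i2][si], h2$end[i2][si])
    ro_min_pair <- pmin(ro$frac_a, ro$frac_b)
    in_tr <- !is.na(h1$tr_locus[i1][qi]) | !is.na(h2$tr_locus[i2][si])
    thr <- if_else(in_tr, ro_tr, ro_non_tr)
    keep <- same_type & ro_min_pair >= thr
    if (any(keep)) {
      pairs[[ch]] <- tibble(a = i1[qi[keep]], b = i2[si[keep]],
                            ro = ro_min_pair[keep])
    }
  }
  pairs <- list_rbind(pairs)
  matched_a <- integer(0); matched_b <- integer(0)
  if (!is.null(pairs) && nrow(pairs) > 0) {
    pairs <- arrange(pairs, dplyr::desc(.data$ro))
    for (k in seq_len(nrow(pairs))) {
      if (pairs$a[k] %in% matched_a || pairs$b[k] %in% matched_b) next
      matched_a <- c(matched_a, pairs$a[k])
      matched_b <- c(matched_b, pairs$b[k])
    }
  }
  hom <- if (length(matched_a) > 0) {
    tibble(chrom = h1$chrom[matched_a], start = h1$start[matched_a],
           end = h1$end[matched_a], type = h1$type[matched_a],
           sv_len = h1$sv_len[matched_a], gt = "1/1",
           h1_id = h1$call_id[matched_a], h2_id = h2$call_id[matched_b])
  } else NULL
  rest1 <- setdiff(seq_len(nrow(h1)), matched_a)
  rest2 <- setdiff(seq_len(nrow(h2)), matched_b)
  het1 <- if (length(rest1) > 0) {
    tibble(chrom = h1$chrom[rest1], start = h1$start[rest1],
           end = h1$end[rest1], type = h1$type[rest1],
           sv_len = h1$sv_len[rest1], gt = "1/0",
           h1_id = h1$call_id[rest1], h2_id = NA_character_)
  } else NULL
  het2 <- if (length(rest2) > 0) {
    tibble(chrom = h2$chrom[rest2], start = h2$start[rest2],
           end = h2$end[rest2], type = h2$type[rest2],
           sv_len = h2$sv_len[rest2], gt = "0/1",
           h1_id = NA_character_, h2_id = h2$call_id[rest2])
  } else NULL
  empty <- tibble(chrom = character(), start = double(), end = double(),
                  type = character(), sv_len = double(), gt = character(),
                  h1_id = character(), h2_id = character())
  list(
    calls = bind_rows(empty, hom, het1, het2) |>
      arrange(.data$chrom, .data$start),
    set_aside_loci = select(set_aside, "chrom", "start", "end",
                            locus_id = "locus_id", max_calls = "max_n")
  )
}

#' Unify two long-read assembly callsets into one PB callset
#'
#' Ordered inclusion across three tiers: (a) calls validated by optical-map
#' length concordance (`f_BN < f_max`), choosing between the two callsets by
#' minimal `f_BN` per optical-map event — included regardless of read
#' support; (b) remaining primary-callset (Phased-SV-style) calls with read
#' support `PBRC > 3`; (c) remaining secondary-callset (MS-PAC-style) calls
#' at least `min_distance` (10 kb) from any primary call. Calls are
#' deduplicated across tiers by the 250 bp boundary-window clustering, tier
#' precedence (a) > (b) > (c).
#'
#' @param phased_sv Primary callset tibble: `call_id`, `chrom`, `start`,
#'   `end`, `type`, `sv_len`, `pbrc`.
#' @param mspac Secondary callset tibble (same columns).
#' @param bng Optical-map events tibble: `chrom`, `start`, `end`, `type`,
#'   `l_bn`.
#' @param f_max Optical-map validation threshold.
#' @param min_pbrc Tier (b) support threshold; included when `pbrc > min_pbrc`.
#' @param min_distance Tier (c) distance from any primary call, bp.
#' @param window Deduplication boundary window, bp.
#' @return Unified callset with `source` (`phased_sv`/`mspac`) and `tier`
#'   (`bng_validated`/`pbrc`/`distance`) columns.
#' @export
unify_pb <- function(phased_sv, mspac, bng, f_max = 0.1, min_pbrc = 3,
                     min_distance = 1e4, window = 250) {
  phased_sv$source <- "phased_sv"; mspac$source <- "mspac"
  pool <- bind_rows(phased_sv, mspac)
  tier_a_ids <- character(0)
  for (k in seq_len(nrow(bng))) {
    ev <- bng[k, ]
    cand <- pool[pool$chrom == ev$chrom & pool$type == ev$type &
                   pool$start < ev$end + 1000 & pool$end > ev$start - 1000, ]
    m <- fbn_match(cand, ev$l_bn, f_max)
    if (nrow(m) == 1 && m$validated) {
      tier_a_ids <- union(tier_a_ids, cand$call_id[m$best])
    }
  }
  tier_a <- pool |> filter(.data$call_id %in% tier_a_ids) |>
    mutate(tier = "bng_validated")
  tier_b <- phased_sv |>
    filter(!.data$call_id %in% tier_a_ids, .data$pbrc > min_pbrc) |>
    mutate(tier = "pbrc")
  far_from_primary <- function(calls) {
    purrr::pmap_lgl(list(calls$chrom, calls$start, calls$end),
                    function(ch, s, e) {
      p <- phased_sv[phased_sv$chrom == ch, ]
      if (nrow(p) == 0) return(TRUE)
      all(pmax(p$start - e, s - p$end, 0) >= min_distance)
    })
  }
  mspac_rest <- filter(mspac, !.data$call_id %in% tier_a_ids)
  tier_c <- mspac_rest[far_from_primary(mspac_rest), , drop = FALSE]
  tier_c <- mutate(tier_c, tier = "distance")
  unified <- bind_rows(tier_a, tier_b, tier_c)
  if (nrow(unified) == 0) return(unified)
  # dedupe across tiers within 250 bp boundary windows
  tier_rank <- c(bng_validated = 1, pbrc = 2, distance = 3)
  unified <- cluster_svs_by_window(unified, window = window)
  unified |>
    group_by(.data$cluster, .data$type) |>
    arrange(tier_rank[.data$tier], .data$call_id, .by_group = TRUE) |>
    slice(1) |>
    ungroup() |>
    select(-"cluster") |>
    arrange(.data$chrom, .data$start)
}
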