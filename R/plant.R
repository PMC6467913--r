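# Truth-set planting: inversions for the Strand-seq stages, deletions and
# insertions for the validation/merging stages.

#' Plant ground-truth inversions into a genome model
#'
#' Places `n` non-overlapping inversions with log-uniform sizes. Simple
#' inversions are homozygous with probability `hom_fraction`, otherwise
#' heterozygous on a random haplotype. A `complex_fraction` of events are
#' inverted duplications: the carrier haplotype holds one inverted plus
#' `dup_copies` direct copies of the segment, which depresses the
#' non-reference read fraction at the locus to
#' `inverted / total` copies (1/3 for the default single extra copy, the
#' intermediate read ratios typical of inverted duplications). Inverted
#' duplications are heterozygous by construction: with both haplotypes
#' rearranged the locus would carry both haplotypes on the non-reference
#' strand and match no phase signature.
#'
#' Events are kept clear of centromeres and separated by at least `min_gap`
#' so that neighbouring events remain individually resolvable.
#'
#' @param genome A `genome_model`.
#' @param n Number of inversions (>= 1).
#' @param size_min,size_max Size law bounds, bp (log-uniform between them).
#' @param hom_fraction Probability that a *simple* inversion is homozygous.
#' @param complex_fraction Fraction of events that are inverted duplications.
#' @param seed Integer seed.
#' @param dup_copies Extra direct copies carried by an inverted duplication.
#' @param min_gap Minimum separation between planted events, bp.
#' @return Tibble with `inv_id`, `chrom`, `start`, `end`, `genotype`
#'   (`het_H1`/`het_H2`/`hom`), `cls` (`simple`/`inverted_duplication`) and
#'   `dup_copy_number` (0 for simple events).
#' @export
plant_inversions <- function(genome, n, size_min, size_max,
                             hom_fraction = 1 / 3, complex_fraction = 0,
                             seed = 1, dup_copies = 1, min_gap = 50000) {
  if (n < 1) abort("`n` must be >= 1.")
  if (size_min > size_max || size_min < 1) abort("invalid size law.")
  with_substream(seed, "plant_inversions", {
    sizes <- floor(10^runif(n, log10(size_min), log10(size_max)))
    cls <- if_else(runif(n) < complex_fraction, "inverted_duplication", "simple")
    genotype <- dplyr::case_when(
      cls == "inverted_duplication" ~ sample(c("het_H1", "het_H2"), n, TRUE),
      runif(n) < hom_fraction ~ "hom",
      TRUE ~ sample(c("het_H1", "het_H2"), n, TRUE)
    )
    placed <- place_intervals(genome, sizes, min_gap)
    tibble(
      inv_id = sprintf("inv%03d", seq_len(n)),
      chrom = placed$chrom, start = placed$start, end = placed$end,
      genotype = genotype, cls = cls,
      dup_copy_number = if_else(cls == "inverted_duplication",
                                as.integer(dup_copies), 0L)
    ) |> arrange(.data$chrom, .data$start)
  })
}

#' Plant ground-truth deletions and insertions
#'
#' Truth set for the validation and merging stages. Deletions span their
#' interval; insertions are point anchors with an `sv_len` payload.
#'
#' @inheritParams plant_inversions
#' @param type_mix Named probabilities for `DEL` and `INS`.
#' @param hom_fraction Probability an event is homozygous.
#' @return Tibble with `sv_id`, `chrom`, `start`, `end`, `type`, `sv_len`,
#'   `zygosity` (`het_H1`/`het_H2`/`hom`).
#' @export
plant_svs <- function(genome, n, size_min = 50, size_max = 5000,
                      type_mix = c(DEL = 0.5, INS = 0.5),
                      hom_fraction = 1 / 3, seed = 1, min_gap = 2000) {
  if (n < 1) abort("`n` must be >= 1.")
  with_substream(seed, "plant_svs", {
    sizes <- floor(10^runif(n, log10(size_min), log10(size_max)))
    type <- sample(names(type_mix), n, TRUE, prob = type_mix)
    zyg <- if_else(runif(n) < hom_fraction, "hom",
                   sample(c("het_H1", "het_H2"), n, TRUE))
    placed <- place_intervals(genome, sizes, min_gap)
    tibble(
      sv_id = sprintf("sv%04d", seq_len(n)),
      chrom = placed$chrom,
      start = placed$start,
      end = if_else(type == "DEL", placed$end, placed$start + 1),
      type = type, sv_len = sizes, zygosity = zyg
    ) |> arrange(.data$chrom, .data$start)
  })
}

# Rejection-sample non-overlapping placements away from centromeres.
place_intervals <- function(genome, sizes, min_gap) {
  n <- length(sizes)
  chrom <- character(n); start <- double(n)
  placed <- vector("list", length(genome$chroms$chrom))
  names(placed) <- genome$chroms$chrom
  cen <- centromere_track(genome)
  max_tries <- 200L
  for (i in order(sizes, decreasing = TRUE)) {
    ok <- FALSE
    for (try in seq_len(max_tries)) {
      ci <- sample.int(nrow(genome$chroms), 1,
                       prob = genome$chroms$length)
      ch <- genome$chroms$chrom[ci]
      L <- genome$chroms$length[ci]
      if (sizes[i] >= L) next
      s <- floor(runif(1, 0, L - sizes[i]))
      e <- s + sizes[i]
      cen_i <- cen[cen$chrom == ch, ]
      if (s < cen_i$end + min_gap && e > cen_i$start - min_gap) next
      prev <- placed[[ch]]
      clash <- any(vapply(prev, function(p) {
        s < p[2] + min_gap && e > p[1] - min_gap
      }, logical(1)))
      if (!clash) {
        placed[[ch]] <- c(prev, list(c(s, e)))
        chrom[i] <- ch; start[i] <- s
        ok <- TRUE
        break
      }
    }
    if (!ok) {
      abort(sprintf(
        "capacity error: could not place event of %d bp (placed %d of %d); enlarge the genome or reduce `n`/sizes.",
        sizes[i], sum(chrom != ""), n), class = "svscribe_capacity_error")
    }
  }
  tibble(chrom = chrom, start = start, end = start + sizes)
}
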