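#' Simulate a Strand-seq composite file
#'
#' Emits the merged, orientation-preserving pool of Strand-seq reads for one
#' individual. Reads are modelled as points (5' positions). Each haplotype
#' contributes half the read density; inside an inversion the carrier
#' haplotype's reads flip to the non-reference orientation, so a
#' heterozygous simple inversion reads ~0.5 non-reference and a homozygous
#' one ~1. Inside an inverted duplication the carrier haplotype carries
#' `1 + dup_copy_number` copies of the segment of which one is inverted:
#' read density rises proportionally and the non-reference fraction at the
#' locus falls to inverted/total copies (1/3 for one extra copy).
#' Orientation noise flips each read independently with probability
#' `orientation_error`; haplotags record the haplotype of origin with
#' probability `haplotag_rate` (the fraction of fragments that capture a
#' phased heterozygous SNV).
#'
#' @param genome A `genome_model`.
#' @param truth Tibble of planted inversions from [plant_inversions()] (may
#'   have zero rows).
#' @param read_density Total reads per kb across both haplotypes (> 0).
#' @param orientation_error Probability a read's orientation is flipped, in
#'   `[0, 0.5)`.
#' @param haplotag_rate Probability a read carries its haplotype tag.
#' @param seed Integer seed.
#' @return Tibble of oriented reads, sorted by (`chrom`, `pos`):
#'   `chrom`, `pos`, `orientation` (`reference`/`non_reference`),
#'   `haplotag` (`H1`/`H2`/`untagged`).
#' @export
simulate_strandseq_composite <- function(genome, truth, read_density = 25,
                                         orientation_error = 0.02,
                                         haplotag_rate = 0.3, seed = 1) {
  if (read_density <= 0) abort("`read_density` must be > 0.")
  if (orientation_error < 0 || orientation_error >= 0.5) {
    abort("`orientation_error` must lie in [0, 0.5).")
  }
  if (haplotag_rate < 0 || haplotag_rate > 1) abort("`haplotag_rate` in [0, 1].")
  with_substream(seed, "strandseq_composite", {
    reads <- purrr::map(seq_len(nrow(genome$chroms)), function(ci) {
      ch <- genome$chroms$chrom[ci]
      L <- genome$chroms$length[ci]
      per_hap <- purrr::map(c("H1", "H2"), function(hap) {
        n_base <- rpois(1, L * read_density / 2 / 1000)
        pos <- floor(runif(n_base, 0, L))
        df <- tibble(pos = pos, hap = hap, nonref = FALSE)
        tr_ch <- truth[truth$chrom == ch, , drop = FALSE]
        for (k in seq_len(nrow(tr_ch))) {
          ev <- tr_ch[k, ]
          carrier <- ev$genotype == "hom" ||
            (ev$genotype == "het_H1" && hap == "H1") ||
            (ev$genotype == "het_H2" && hap == "H2")
          if (!carrier) next
          inside <- df$pos >= ev$start & df$pos < ev$end
          if (ev$cls == "simple") {
            df$nonref[inside] <- TRUE
          } else {
            # inverted duplication: carrier haplotype has 1 inverted +
            # dup_copy_number direct copies; duplicate coverage, then each
            # carrier read is non-reference with prob 1 / (1 + copies).
            copies <- 1 + ev$dup_copy_number
            n_extra <- rpois(1, (ev$end - ev$start) * read_density / 2 / 1000 *
                               (copies - 1))
            extra <- tibble(pos = floor(runif(n_extra, ev$start, ev$end)),
                            hap = hap, nonref = FALSE)
            df <- bind_rows(df, extra)
            inside <- df$pos >= ev$start & df$pos < ev$end
            df$nonref[inside] <- runif(sum(inside)) < 1 / copies
          }
        }
        df
      }) |> list_rbind()
      per_hap$chrom <- ch
      per_hap
    }) |> list_rbind()
    flip <- runif(nrow(reads)) < orientation_error
    reads$nonref <- xor(reads$nonref, flip)
    tagged <- runif(nrow(reads)) < haplotag_rate
    reads |>
      transmute(
        chrom = .data$chrom,
        pos = .data$pos,
        orientation = if_else(.data$nonref, "non_reference", "reference"),
        haplotag = if_else(tagged, .data$hap, "untagged")
      ) |>
      arrange(.data$chrom, .data$pos)
  })
}
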