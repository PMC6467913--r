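#' Generate a synthetic genome model
#'
#' Builds the annotation context every downstream stage consumes: chromosome
#' sizes, a centromere interval per chromosome, tandem-repeat and
#' segmental-duplication tracks, and heterozygous SNV positions with H1/H2
#' alleles. All coordinates are 0-based half-open.
#'
#' The centromere occupies the central 5% of each chromosome. Tandem-repeat
#' intervals are placed uniformly with exponential lengths until their
#' expected (pre-merge) coverage reaches `tr_density`; merged coverage is
#' therefore slightly below `tr_density` (approximately
#' `1 - exp(-tr_density)` for short repeats). Heterozygous SNV spacing is
#' exponential with mean `snv_spacing_mean`, emulating the roughly 1-1.5 kb
#' spacing between phased heterozygous sites in a human genome.
#'
#' @param n_chroms Number of chromosomes.
#' @param chrom_length Length of every chromosome in bp (>= 1e5).
#' @param tr_density Target tandem-repeat coverage fraction, in `[0, 0.5)`.
#' @param snv_spacing_mean Mean distance between heterozygous SNVs, bp.
#' @param seed Integer seed; output is bit-identical for a fixed seed.
#' @param tr_length_mean Mean tandem-repeat interval length, bp.
#' @param segdup_density Coverage fraction for the segmental-duplication
#'   track.
#' @return An object of class `genome_model`: a list with tibbles `chroms`
#'   (`chrom`, `length`, `cen_start`, `cen_end`), `tandem_repeats`,
#'   `segdups` (`chrom`, `start`, `end`) and `snvs` (`chrom`, `pos`).
#' @examples
#' gm <- generate_genome_model(1, 1e6, tr_density = 0.1,
#'                             snv_spacing_mean = 1000, seed = 7)
#' @export
generate_genome_model <- function(n_chroms, chrom_length, tr_density = 0.05,
                                  snv_spacing_mean = 1360, seed = 1,
                                  tr_length_mean = 500,
                                  segdup_density = 0.01) {
  if (chrom_length < 1e5) abort("`chrom_length` must be >= 1e5 bp.")
  if (tr_density < 0 || tr_density >= 0.5) abort("`tr_density` must lie in [0, 0.5).")
  if (n_chroms < 1) abort("`n_chroms` must be >= 1.")
  if (snv_spacing_mean <= 0 || tr_length_mean <= 0) {
    abort("lengths and spacings must be positive.")
  }
  chroms <- tibble(
    chrom = sprintf("chr%d", seq_len(n_chroms)),
    length = as.double(chrom_length),
    cen_start = floor(chrom_length * 0.475),
    cen_end = ceiling(chrom_length * 0.525)
  )
  place_track <- function(density, len_mean, label) {
    with_substream(seed, label, {
      purrr::map(chroms$chrom, function(ch) {
        if (density <= 0) {
          return(tibble(chrom = character(), start = double(), end = double()))
        }
        n_iv <- ceiling(density * chrom_length / len_mean)
        len <- pmax(20, round(rexp(n_iv, 1 / len_mean)))
        start <- floor(runif(n_iv, 0, chrom_length - len))
        tibble(chrom = ch, start = start, end = pmin(start + len, chrom_length))
      }) |> list_rbind()
    }) |> merge_track()
  }
  tr <- place_track(tr_density, tr_length_mean, "tandem_repeats")
  sd_track <- place_track(segdup_density, 5 * tr_length_mean, "segdups")
  snvs <- with_substream(seed, "snvs", {
    purrr::map(chroms$chrom, function(ch) {
      gaps <- rexp(ceiling(1.3 * chrom_length / snv_spacing_mean) + 10,
                   1 / snv_spacing_mean)
      pos <- floor(cumsum(gaps))
      pos <- unique(pos[pos < chrom_length])
      tibble(chrom = ch, pos = pos)
    }) |> list_rbind()
  })
  structure(
    list(chroms = chroms, tandem_repeats = tr, segdups = sd_track, snvs = snvs),
    class = "genome_model"
  )
}

#' @export
print.genome_model <- function(x, ...) {
  cat(sprintf(
    "<genome_model> %d chromosome(s), %.3g bp each; %d tandem repeats; %d segdups; %d het SNVs\n",
    nrow(x$chroms), x$chroms$length[1], nrow(x$tandem_repeats),
    nrow(x$segdups), nrow(x$snvs)))
  invisible(x)
}

genome_size <- function(genome) sum(genome$chroms$length)

centromere_track <- function(genome) {
  tibble(chrom = genome$chroms$chrom,
         start = genome$chroms$cen_start,
         end = genome$chroms$cen_end)
}
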