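#' Describe a synthetic SV caller
#'
#' A caller profile fixes the error model of one simulated discovery
#' algorithm or platform: its sensitivity, false-positive rate, breakpoint
#' jitter and the SV types it can see.
#'
#' @param name Caller/platform name.
#' @param sensitivity Detection probability per true event, in `[0, 1]`.
#' @param fp_rate False positives per Mb of genome.
#' @param breakpoint_jitter_sd SD of the centred Gaussian breakpoint error, bp.
#' @param length_bias Multiplicative bias applied to reported lengths.
#' @param detectable_types Character vector, subset of DEL/INS/DUP/INV.
#' @return One-row tibble usable with [simulate_caller_callsets()].
#' @export
caller_profile <- function(name, sensitivity = 0.9, fp_rate = 0.5,
                           breakpoint_jitter_sd = 20, length_bias = 1,
                           detectable_types = c("DEL", "INS", "INV")) {
  if (sensitivity < 0 || sensitivity > 1) abort("`sensitivity` in [0, 1].")
  if (breakpoint_jitter_sd < 0) abort("`breakpoint_jitter_sd` must be >= 0.")
  tibble(name = name, sensitivity = sensitivity, fp_rate = fp_rate,
         breakpoint_jitter_sd = breakpoint_jitter_sd, length_bias = length_bias,
         detectable_types = list(detectable_types))
}

#' Simulate per-caller SV callsets from a truth set
#'
#' Each truth event is detected by caller `c` with probability
#' `sensitivity(c)`; detected breakpoints are perturbed by centred Gaussian
#' noise with the caller's jitter SD. False positives are added as a Poisson
#' draw of `fp_rate` per Mb, placed uniformly with log-uniform lengths.
#' Truth linkage (`truth_id`, `NA` for false positives) is retained for
#' scoring.
#'
#' @param truth Truth tibble from [plant_svs()] or [plant_inversions()].
#' @param profiles Tibble of [caller_profile()] rows.
#' @param genome A `genome_model` (for false-positive placement).
#' @param seed Integer seed.
#' @param fp_size_range Log-uniform length range for false positives, bp.
#' @return Tibble of calls: `caller`, `chrom`, `start`, `end`, `type`,
#'   `sv_len`, `genotype`, `truth_id`.
#' @export
simulate_caller_callsets <- function(truth, profiles, genome, seed = 1,
                                     fp_size_range = c(100, 10000)) {
  if (nrow(profiles) == 0) abort("`profiles` must be non-empty.")
  truth <- normalize_truth(truth)
  purrr::map(seq_len(nrow(profiles)), function(pi) {
    prof <- profiles[pi, ]
    with_substream(seed, paste0("caller_callset/", prof$name), {
      types_ok <- truth$type %in% prof$detectable_types[[1]]
      det <- types_ok & runif(nrow(truth)) < prof$sensitivity
      tp <- truth[det, , drop = FALSE]
      if (nrow(tp) > 0) {
        js <- round(rnorm(nrow(tp), 0, prof$breakpoint_jitter_sd))
        je <- round(rnorm(nrow(tp), 0, prof$breakpoint_jitter_sd))
        start <- pmax(0, tp$start + js)
        end <- pmax(start + 1, tp$end + je)
        tp_calls <- tibble(
          caller = prof$name, chrom = tp$chrom, start = start, end = end,
          type = tp$type,
          sv_len = round(tp$sv_len * prof$length_bias),
          genotype = if_else(tp$zygosity == "hom", "1/1",
                             if_else(tp$zygosity == "het_H1", "1|0", "0|1")),
          truth_id = tp$truth_id
        )
      } else {
        tp_calls <- tibble(caller = character(), chrom = character(),
                           start = double(), end = double(), type = character(),
                           sv_len = double(), genotype = character(),
                           truth_id = character())
      }
      n_fp <- rpois(1, prof$fp_rate * genome_size(genome) / 1e6)
      if (n_fp > 0) {
        ci <- sample.int(nrow(genome$chroms), n_fp, TRUE,
                         prob = genome$chroms$length)
        len <- floor(10^runif(n_fp, log10(fp_size_range[1]),
                              log10(fp_size_range[2])))
        start <- floor(runif(n_fp, 0, genome$chroms$length[ci] - len))
        fp_type <- purrr::map_chr(seq_len(n_fp), function(i)
          sample(prof$detectable_types[[1]], 1))
        fp_calls <- tibble(
          caller = prof$name, chrom = genome$chroms$chrom[ci],
          start = start,
          end = if_else(fp_type == "INS", start + 1, start + len),
          type = fp_type, sv_len = len,
          genotype = "0|1", truth_id = NA_character_
        )
      } else {
        fp_calls <- tp_calls[0, ]
      }
      bind_rows(tp_calls, fp_calls)
    })
  }) |>
    list_rbind() |>
    arrange(.data$caller, .data$chrom, .data$start) |>
    mutate(call_id = sprintf("c%05d", row_number()), .before = 1)
}

# Accept either an inversion truth (inv_id/genotype/cls) or an SV truth
# (sv_id/type/zygosity) and present a common schema.
normalize_truth <- function(truth) {
  if ("inv_id" %in% names(truth)) {
    tibble(truth_id = truth$inv_id, chrom = truth$chrom, start = truth$start,
           end = truth$end, type = "INV", sv_len = truth$end - truth$start,
           zygosity = truth$genotype)
  } else {
    tibble(truth_id = truth$sv_id, chrom = truth$chrom, start = truth$start,
           end = truth$end, type = truth$type, sv_len = truth$sv_len,
           zygosity = truth$zygosity)
  }
}
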