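#' Simulate validation evidence for a callset
#'
#' Produces the per-call evidence the validation calculus consumes:
#' alternate-allele supporting read counts (Poisson around
#' `support_mean_true` for calls linked to truth, `support_mean_false` for
#' false positives), an optical-map length `L_BN = L_PB * (1 + N(0, sd))`
#' for a configurable subset of calls, and a per-bp coverage profile over
#' the call interval plus flank in which homozygous deletions drop to ~0x
#' and heterozygous deletions to ~half the base depth.
#'
#' @param calls Callset tibble from [simulate_caller_callsets()] (columns
#'   `call_id`, `type`, `sv_len`, `truth_id`).
#' @param truth Truth tibble from [plant_svs()] (for zygosity lookup).
#' @param support_mean_true,support_mean_false Poisson means for the
#'   alternate-allele read support of true and false calls (>= 0).
#' @param bng_rel_error_sd Relative SD of the optical-map length error.
#' @param base_depth Diploid background sequencing depth, fold coverage.
#' @param bng_fraction Fraction of calls that receive an optical-map length.
#' @param flank Flank added to each side of the coverage profile, bp.
#' @param seed Integer seed.
#' @return Tibble with `call_id`, `alt_support`, `L_BN` (NA when absent),
#'   `mean_depth` (mean coverage over the call interval) and `depth_profile`
#'   (list column of per-bp coverage over interval + flanks).
#' @export
simulate_validation_evidence <- function(calls, truth,
                                         support_mean_true = 20,
                                         support_mean_false = 1,
                                         bng_rel_error_sd = 0.05,
                                         base_depth = 40,
                                         bng_fraction = 0.5,
                                         flank = 500, seed = 1) {
  if (support_mean_true < 0 || support_mean_false < 0) {
    abort("support means must be >= 0.")
  }
  zyg <- setNames(truth$zygosity, truth$sv_id)
  with_substream(seed, "validation_evidence", {
    is_true <- !is.na(calls$truth_id)
    alt <- rpois(nrow(calls),
                 if_else(is_true, support_mean_true, support_mean_false))
    has_bng <- runif(nrow(calls)) < bng_fraction
    l_bn <- if_else(
      has_bng,
      pmax(1, round(calls$sv_len * (1 + rnorm(nrow(calls), 0, bng_rel_error_sd)))),
      NA_real_
    )
    profiles <- purrr::map(seq_len(nrow(calls)), function(i) {
      span <- max(1, calls$end[i] - calls$start[i])
      n_bp <- span + 2 * flank
      lambda <- rep(base_depth, n_bp)
      if (is_true[i] && calls$type[i] == "DEL") {
        z <- zyg[[calls$truth_id[i]]] %||% "het_H1"
        inside <- seq(flank + 1, flank + span)
        lambda[inside] <- if (z == "hom") 0.5 else base_depth / 2
      }
      rpois(n_bp, lambda)
    })
    tibble(
      call_id = calls$call_id,
      alt_support = alt,
      L_BN = l_bn,
      mean_depth = purrr::map2_dbl(profiles, calls$end - calls$start,
                                   function(p, span) {
                                     span <- max(1, span)
                                     mean(p[seq(flank + 1, flank + span)])
                                   }),
      depth_profile = profiles
    )
  })
}
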