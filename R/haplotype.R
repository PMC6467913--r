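#' Assign a long read to a haplotype from SNV observations
#'
#' Scores each haplotype as the product, over heterozygous SNVs the read
#' covers, of `1 - q_i` when the read base matches that haplotype's allele
#' and `q_i` when it does not, where `q_i` is the base error probability.
#' Scores are computed in log10 space; the read is assigned to the
#' higher-scoring haplotype only when the phred-scaled score gap,
#' `10 * |log10(S_H1) - log10(S_H2)|`, exceeds `qv_threshold`. Reads
#' spanning no SNV are ambiguous.
#'
#' @param obs Tibble of per-SNV observations for one read: columns
#'   `matches_h1` (logical) and `q` (error probability in (0, 1)). Zero rows
#'   mean the read spans no SNV.
#' @param qv_threshold Phred-scaled score-gap threshold, default 10.
#' @return One of `"H1"`, `"H2"`, `"ambiguous"`.
#' @examples
#' assign_read_haplotype(tibble::tibble(matches_h1 = TRUE, q = 0.25))
#' @export
assign_read_haplotype <- function(obs, qv_threshold = 10) {
  if (nrow(obs) == 0) return("ambiguous")
  if (any(obs$q <= 0 | obs$q >= 1)) abort("`q` must lie in (0, 1).")
  log_h1 <- sum(log10(if_else(obs$matches_h1, 1 - obs$q, obs$q)))
  log_h2 <- sum(log10(if_else(obs$matches_h1, obs$q, 1 - obs$q)))
  gap <- 10 * abs(log_h1 - log_h2)
  if (gap <= qv_threshold) return("ambiguous")
  if (log_h1 > log_h2) "H1" else "H2"
}
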