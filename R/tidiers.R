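# broom-style accessors for result objects.

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' Tidy a Strand-seq scan
#'
#' @param x A `strandseq_scan` from [call_inversions()].
#' @param ... Unused.
#' @return The candidate-locus tibble (one row per locus with genotype,
#'   haplotype ratios, class and phase).
#' @export
tidy.strandseq_scan <- function(x, ...) as_tibble(x$calls)

#' One-row summary of a Strand-seq scan
#'
#' @param x A `strandseq_scan`.
#' @param ... Unused.
#' @return Tibble with read/candidate counts and per-class totals.
#' @export
glance.strandseq_scan <- function(x, ...) {
  tibble(
    n_reads = x$n_reads,
    n_candidates = nrow(x$calls),
    n_simple_hom = sum(x$calls$cls == "simple_hom"),
    n_simple_het = sum(x$calls$cls == "simple_het"),
    n_complex = sum(x$calls$cls == "complex"),
    n_unclassified = sum(x$calls$cls == "unclassified")
  )
}

#' Tidy a pan-SV callset
#'
#' @param x A `pan_sv` tibble.
#' @param ... Unused.
#' @return The records as a plain tibble.
#' @export
tidy.pan_sv <- function(x, ...) as_tibble(x)

#' One-row summary of a pan-SV callset
#'
#' @param x A `pan_sv` tibble.
#' @param ... Unused.
#' @return Tibble with record count and per-provenance-class counts.
#' @export
glance.pan_sv <- function(x, ...) {
  s <- pan_sv_summary(x)
  bind_cols(tibble(n_records = nrow(x)),
            tidyr::pivot_wider(s[, c("provenance", "n")],
                               names_from = "provenance", values_from = "n",
                               names_prefix = "n_"))
}
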