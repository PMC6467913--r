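#' Evaluate caller combinations by non-concordance rate
#'
#' Benchmarks callsets formed from combinations of up to `max_k` algorithms
#' under three conditions: the union of two callsets (`union2`), the union
#' of three (`union3`), and calls made by at least two of three algorithms
#' (`two_of_three`). Calls are merged across the combination's callers by
#' single-linkage 50% reciprocal overlap; a merged call is concordant when
#' any member call is. The non-concordance rate, NCR = 1 - concordant
#' fraction, is the proxy for the false discovery rate of the combination.
#'
#' @param calls Callset tibble: `caller`, `chrom`, `start`, `end`, plus
#'   either a logical `concordant` column or none if `oracle` is given.
#' @param oracle Optional function mapping a calls tibble to a logical
#'   concordance vector; overrides the `concordant` column.
#' @param max_k Largest combination size (2 or 3).
#' @param ro_min Reciprocal overlap for cross-caller merging.
#' @return A `combination_result` tibble: `combo` (callers, "+"-joined),
#'   `mode`, `n_calls`, `ncr`, sorted by (`ncr`, decreasing `n_calls`).
#' @export
evaluate_combinations <- function(calls, oracle = NULL, max_k = 3,
                                  ro_min = 0.5) {
  if (!is.null(oracle)) calls$concordant <- oracle(calls)
  stopifnot(is.logical(calls$concordant))
  callers <- sort(unique(calls$caller))
  combos <- list()
  if (max_k >= 2 && length(callers) >= 2) {
    combos <- c(combos, purrr::map(
      as.data.frame(combn(callers, 2)), function(cc) list(callers = cc, mode = "union2")))
  }
  if (max_k >= 3 && length(callers) >= 3) {
    trip <- as.data.frame(combn(callers, 3))
    combos <- c(combos,
                purrr::map(trip, function(cc) list(callers = cc, mode = "union3")),
                purrr::map(trip, function(cc) list(callers = cc, mode = "two_of_three")))
  }
  res <- purrr::map(combos, function(cb) {
    sub <- calls[calls$caller %in% cb$callers, , drop = FALSE]
    if (nrow(sub) == 0) {
      return(tibble(combo = paste(cb$callers, collapse = "+"),
                    mode = cb$mode, n_calls = 0L, ncr = NA_real_))
    }
    cl <- ro_cluster(sub, ro_min)
    merged <- tibble(cl = cl, caller = sub$caller, concordant = sub$concordant) |>
      group_by(.data$cl) |>
      summarise(n_callers = dplyr::n_distinct(.data$caller),
                concordant = any(.data$concordant))
    if (cb$mode == "two_of_three") {
      merged <- filter(merged, .data$n_callers >= 2)
    }
    tibble(combo = paste(cb$callers, collapse = "+"), mode = cb$mode,
           n_calls = nrow(merged),
           ncr = if (nrow(merged) == 0) NA_real_ else 1 - mean(merged$concordant))
  }) |> list_rbind()
  res <- arrange(res, .data$ncr, dplyr::desc(.data$n_calls))
  class(res) <- c("combination_result", class(res))
  res
}
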