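#' Concordance filter for short-read calls against long-read evidence
#'
#' An Illumina call is concordant when at least one of four conditions
#' holds: (1) the maximal length concordance with an assembly-level PB SV or
#' a BNG SV collected near the call is at least 0.5; (2) at least three
#' individual PB reads carry an SV with length concordance >= 0.7 to the
#' call; (3) the call is a deletion and the mean PB read depth over its
#' interval is below 25; (4) a pluggable raw-read predicate fires (default:
#' never — raw-read dotplot evidence is supplied externally). Targets for
#' (1) and (2) are collected within `flank` bp of the call's breakpoints;
#' BNG targets are matched on their position interval.
#'
#' @param il_calls Query call tibble: `call_id`, `chrom`, `start`, `end`,
#'   `type`, `sv_len`.
#' @param pb_assembly Assembly-level PB calls (`chrom`, `start`, `end`,
#'   `type`, `sv_len`).
#' @param pb_reads Read-level PB calls with a `read_id` column.
#' @param bng_calls BNG calls (`chrom`, `start`, `end`, `type`, `sv_len`).
#' @param mean_depth Named numeric: mean PB depth per `call_id` (or a
#'   numeric vector aligned with `il_calls`).
#' @param flank Breakpoint neighbourhood for target collection, bp.
#' @param min_concordance Condition (1) threshold.
#' @param read_min_concordance,read_min_count Condition (2) thresholds.
#' @param max_del_depth Condition (3) threshold.
#' @param dotplot_predicate Condition (4) function of one call row returning
#'   logical; default always `FALSE`.
#' @return `il_calls` with per-condition logicals `cond_concordance`,
#'   `cond_reads`, `cond_depth`, `cond_dotplot` and the disjunction
#'   `concordant`.
#' @export
il_concordance_filter <- function(il_calls, pb_assembly, pb_reads, bng_calls,
                                  mean_depth, flank = 1000,
                                  min_concordance = 0.5,
                                  read_min_concordance = 0.7,
                                  read_min_count = 3,
                                  max_del_depth = 25,
                                  dotplot_predicate = NULL) {
  depth_vec <- if (!is.null(names(mean_depth))) {
    unname(mean_depth[il_calls$call_id])
  } else rep_len(mean_depth, nrow(il_calls))
  near_targets <- function(targets, call) {
    targets[targets$chrom == call$chrom &
              targets$start < call$end + flank &
              targets$end > call$start - flank &
              targets$type == call$type, , drop = FALSE]
  }
  res <- purrr::map(seq_len(nrow(il_calls)), function(i) {
    call <- il_calls[i, ]
    tg <- bind_rows(near_targets(pb_assembly, call), near_targets(bng_calls, call))
    c1 <- nrow(tg) > 0 &&
      max(length_concordance(call$sv_len, tg$sv_len)) >= min_concordance
    rd <- near_targets(pb_reads, call)
    c2 <- if (nrow(rd) == 0) FALSE else {
      conc <- length_concordance(call$sv_len, rd$sv_len)
      dplyr::n_distinct(rd$read_id[conc >= read_min_concordance]) >= read_min_count
    }
    c3 <- call$type == "DEL" && !is.na(depth_vec[i]) && depth_vec[i] < max_del_depth
    c4 <- if (is.null(dotplot_predicate)) FALSE else isTRUE(dotplot_predicate(call))
    tibble(cond_concordance = c1, cond_reads = c2, cond_depth = c3,
           cond_dotplot = c4)
  }) |> list_rbind()
  bind_cols(il_calls, res) |>
    mutate(concordant = .data$cond_concordance | .data$cond_reads |
             .data$cond_depth | .data$cond_dotplot)
}
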