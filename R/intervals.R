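# Interval arithmetic on 0-based half-open coordinates. IRanges backs the
# overlap machinery; IRanges is 1-based closed, so [start, end) maps to
# IRanges(start + 1, end).

as_iranges0 <- function(start, end) {
  IRanges::IRanges(start = as.integer(start) + 1L, end = as.integer(end))
}

#' Reciprocal overlap of two interval sets
#'
#' For each pair of half-open intervals, the number of intersecting base
#' pairs divided by each interval's own length. A pair passes a reciprocal
#' overlap (RO) threshold `t` when *both* fractions exceed `t`.
#'
#' @param a_start,a_end,b_start,b_end Vectors of 0-based half-open interval
#'   bounds (recycled to common length).
#' @param a_chrom,b_chrom Optional chromosome identifiers; pairs on
#'   different chromosomes have overlap 0.
#' @return A tibble with columns `frac_a` and `frac_b`, each in `[0, 1]`.
#' @examples
#' reciprocal_overlap(0, 100, 50, 150)   # 0.5 / 0.5
#' @export
reciprocal_overlap <- function(a_start, a_end, b_start, b_end,
                               a_chrom = NULL, b_chrom = NULL) {
  n <- max(length(a_start), length(b_start))
  a_start <- rep_len(as.double(a_start), n); a_end <- rep_len(as.double(a_end), n)
  b_start <- rep_len(as.double(b_start), n); b_end <- rep_len(as.double(b_end), n)
  inter <- pmax(0, pmin(a_end, b_end) - pmax(a_start, b_start))
  if (!is.null(a_chrom) || !is.null(b_chrom)) {
    same <- rep_len(a_chrom, n) == rep_len(b_chrom, n)
    inter[!same] <- 0
  }
  tibble(frac_a = inter / (a_end - a_start), frac_b = inter / (b_end - b_start))
}

# Single-linkage clustering of intervals by reciprocal overlap > ro_min
# (strict). Returns an integer cluster id per row; rows on different
# chromosomes never cluster.
ro_cluster <- function(df, ro_min = 0.5) {
  stopifnot(all(c("chrom", "start", "end") %in% names(df)))
  if (nrow(df) == 0) return(integer(0))
  cl <- integer(nrow(df))
  nxt <- 0L
  for (ch in unique(df$chrom)) {
    idx <- which(df$chrom == ch)
    ir <- as_iranges0(df$start[idx], df$end[idx])
    hits <- IRanges::findOverlaps(ir, ir)
    qi <- S4Vectors::queryHits(hits); si <- S4Vectors::subjectHits(hits)
    ro <- reciprocal_overlap(df$start[idx][qi], df$end[idx][qi],
                             df$start[idx][si], df$end[idx][si])
    keep <- qi != si & pmin(ro$frac_a, ro$frac_b) > ro_min
    g <- igraph::graph_from_data_frame(
      data.frame(from = qi[keep], to = si[keep]),
      directed = FALSE,
      vertices = data.frame(name = seq_along(idx))
    )
    comp <- igraph::components(g)$membership
    cl[idx] <- nxt + comp[as.character(seq_along(idx))]
    nxt <- nxt + max(comp)
  }
  as.integer(cl)
}

#' Fraction of an interval covered by a track
#'
#' Computes, for each query interval, the fraction of its bases covered by a
#' (merged) annotation track such as tandem repeats or segmental
#' duplications.
#'
#' @param intervals Tibble with `chrom`, `start`, `end` (0-based half-open).
#' @param track Tibble with `chrom`, `start`, `end`; overlapping track
#'   entries are merged before counting.
#' @return Numeric vector of covered fractions in `[0, 1]`.
#' @export
tandem_repeat_fraction <- function(intervals, track) {
  if (nrow(intervals) == 0) return(numeric(0))
  out <- numeric(nrow(intervals))
  for (ch in unique(intervals$chrom)) {
    qi <- which(intervals$chrom == ch)
    tr <- track[track$chrom == ch, , drop = FALSE]
    if (nrow(tr) == 0) next
    tir <- IRanges::reduce(as_iranges0(tr$start, tr$end))
    qir <- as_iranges0(intervals$start[qi], intervals$end[qi])
    ov <- IRanges::findOverlaps(qir, tir)
    if (length(ov) == 0) next
    w <- IRanges::width(IRanges::pintersect(
      qir[S4Vectors::queryHits(ov)], tir[S4Vectors::subjectHits(ov)]))
    cov <- tapply(w, S4Vectors::queryHits(ov), sum)
    out[qi[as.integer(names(cov))]] <- as.numeric(cov)
  }
  out / (intervals$end - intervals$start)
}

# Merge a track into disjoint sorted intervals, optionally padded.
merge_track <- function(track, pad = 0) {
  if (nrow(track) == 0) return(track)
  track |>
    group_by(.data$chrom) |>
    dplyr::reframe({
      ir <- IRanges::reduce(as_iranges0(pmax(0, .data$start - pad), .data$end + pad))
      tibble(start = IRanges::start(ir) - 1L, end = IRanges::end(ir))
    }) |>
    arrange(.data$chrom, .data$start)
}
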