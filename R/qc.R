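# Quality-control labeling of merged short-read consensus calls and the
# length-concordance statistic used throughout the concordance filters.

#' Label merged consensus calls for quality control
#'
#' Applies the primary QC labels in order of precedence:
#' `telomere_centromere` for calls overlapping a telomere or centromere
#' band, `oversize` for calls longer than `max_len` (default 1 Mb),
#' `redundancy` for single-algorithm calls that reciprocally overlap a
#' merged call supported by multiple algorithms (such singletons are
#' assumed to be represented by the cluster), and `PASS` for the rest.
#' Labeled non-PASS calls are removed from downstream analysis but kept in
#' the returned table.
#'
#' @param calls Consensus-call tibble: `chrom`, `start`, `end`,
#'   `n_callers` (number of distinct supporting algorithms).
#' @param cytoband Tibble of telomere/centromere intervals: `chrom`,
#'   `start`, `end`.
#' @param max_len Maximum call length, bp.
#' @param ro_min Reciprocal overlap for the redundancy test.
#' @return `calls` with a `label` column.
#' @export
qc_filter <- function(calls, cytoband, max_len = 1e6, ro_min = 0.5) {
  n <- nrow(calls)
  label <- rep("PASS", n)
  if (nrow(cytoband) > 0 && n > 0) {
    for (ch in unique(calls$chrom)) {
      idx <- which(calls$chrom == ch)
      cb <- cytoband[cytoband$chrom == ch, ]
      if (nrow(cb) == 0) next
      hits <- IRanges::findOverlaps(as_iranges0(calls$start[idx], calls$end[idx]),
                                    as_iranges0(cb$start, cb$end))
      label[idx[unique(S4Vectors::queryHits(hits))]] <- "telomere_centromere"
    }
  }
  oversize <- calls$end - calls$start > max_len & label == "PASS"
  label[oversize] <- "oversize"
  single <- which(label == "PASS" & calls$n_callers == 1)
  multi <- which(label %in% c("PASS") & calls$n_callers > 1)
  if (length(single) > 0 && length(multi) > 0) {
    for (ch in unique(calls$chrom[single])) {
      si <- single[calls$chrom[single] == ch]
      mi <- multi[calls$chrom[multi] == ch]
      if (length(mi) == 0) next
      hits <- IRanges::findOverlaps(as_iranges0(calls$start[si], calls$end[si]),
                                    as_iranges0(calls$start[mi], calls$end[mi]))
      qi <- S4Vectors::queryHits(hits); sj <- S4Vectors::subjectHits(hits)
      ro <- reciprocal_overlap(calls$start[si][qi], calls$end[si][qi],
                               calls$start[mi][sj], calls$end[mi][sj])
      hit <- unique(qi[pmin(ro$frac_a, ro$frac_b) > ro_min])
      label[si[hit]] <- "redundancy"
    }
  }
  calls$label <- label
  calls
}

#' Length concordance between two SVs
#'
#' The ratio of the shorter to the longer of the two SV lengths, in
#' `(0, 1]`; computed on length magnitudes.
#'
#' @param len_query,len_target SV lengths (vectors recycled).
#' @return Numeric vector of concordances.
#' @examples
#' length_concordance(50, 100)  # 0.5
#' @export
length_concordance <- function(len_query, len_target) {
  lq <- abs(as.double(len_query)); lt <- abs(as.double(len_target))
  if (any(lq <= 0 | lt <= 0)) abort("lengths must be positive.")
  pmin(lq, lt) / pmax(lq, lt)
}
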