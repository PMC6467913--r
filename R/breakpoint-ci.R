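# Empirical breakpoint confidence intervals per caller and CI-overlap
# clustering into consensus breakpoints.

#' Estimate per-caller breakpoint confidence intervals
#'
#' Matches each caller's calls to a base-pair-resolved gold callset by
#' reciprocal overlap (> `ro_min` on both sides) and records the signed
#' offset between matched breakpoints on each side. The empirical 10th and
#' 90th percentiles of the offset distribution (linear interpolation
#' between order statistics) form the caller's per-side confidence
#' interval. Callers with fewer than `min_matches` matches on a side
#' receive `default_ci` with a warning.
#'
#' @param calls Caller calls tibble: `caller`, `chrom`, `start`, `end`.
#' @param gold Gold callset tibble: `chrom`, `start`, `end`.
#' @param ro_min Reciprocal-overlap match threshold.
#' @param probs The two percentile probabilities, default `c(0.1, 0.9)`.
#' @param min_matches Minimum matches for a stable estimate.
#' @param default_ci Fallback interval (offsets, bp) for sparse callers.
#' @return Tibble: `caller`, `side` (`left`/`right`), `lo`, `hi`,
#'   `n_matches`, `is_default`.
#' @export
estimate_breakpoint_ci <- function(calls, gold, ro_min = 0.5,
                                   probs = c(0.1, 0.9), min_matches = 30,
                                   default_ci = c(-500, 500)) {
  offsets <- purrr::map(split(calls, calls$caller), function(cc) {
    res <- list()
    for (ch in unique(cc$chrom)) {
      ci <- cc[cc$chrom == ch, ]
      gi <- gold[gold$chrom == ch, ]
      if (nrow(gi) == 0) next
      hits <- IRanges::findOverlaps(as_iranges0(ci$start, ci$end),
                                    as_iranges0(gi$start, gi$end))
      qi <- S4Vectors::queryHits(hits); si <- S4Vectors::subjectHits(hits)
      ro <- reciprocal_overlap(ci$start[qi], ci$end[qi],
                               gi$start[si], gi$end[si])
      keep <- pmin(ro$frac_a, ro$frac_b) > ro_min
      if (!any(keep)) next
      res[[ch]] <- tibble(left = ci$start[qi[keep]] - gi$start[si[keep]],
                          right = ci$end[qi[keep]] - gi$end[si[keep]])
    }
    list_rbind(res)
  })
  purrr::imap(offsets, function(off, caller) {
    purrr::map(c("left", "right"), function(side) {
      x <- if (is.null(off) || nrow(off) == 0) numeric(0) else off[[side]]
      if (length(x) < min_matches) {
        warn(sprintf("caller %s/%s: %d matches < %d; using default CI.",
                     caller, side, length(x), min_matches))
        tibble(caller = caller, side = side, lo = default_ci[1],
               hi = default_ci[2], n_matches = length(x), is_default = TRUE)
      } else {
        q <- unname(quantile(x, probs, type = 7))
        tibble(caller = caller, side = side, lo = q[1], hi = q[2],
               n_matches = length(x), is_default = FALSE)
      }
    }) |> list_rbind()
  }) |> list_rbind()
}

#' Cluster breakpoints by confidence-interval overlap
#'
#' Breakpoints (each annotated with its caller's CI, applied as
#' `[point + lo, point + hi]`) are chained into candidate groups wherever
#' CIs overlap (closed ends). Within a group, if all CIs share a common
#' intersection the minimized common CI is `[max(lo_i), min(hi_i)]` and the
#' group is one cluster. Otherwise a two-step fallback applies: the CIs are
#' stacked and the number of CIs covering each elementary segment between
#' sorted endpoints is counted; each local maximum (peak) of this coverage
#' step function together with the segment immediately to its right is
#' assigned as a sub-CI, and every breakpoint joins its nearest sub-CI to
#' form sub-clusters. The consensus breakpoint of every cluster is the
#' coordinate most frequently proposed, smallest coordinate on ties.
#'
#' @param bp Tibble of breakpoints: `caller`, `point` and either `lo`/`hi`
#'   absolute CI bounds or nothing (then joined from `cis`).
#' @param cis Optional per-caller offset CI tibble from
#'   [estimate_breakpoint_ci()]; requires a `side` column on `bp`.
#' @return `bp` with columns `cluster`, `consensus_lo`, `consensus_hi`,
#'   `consensus_bp` appended.
#' @export
cluster_by_ci <- function(bp, cis = NULL) {
  if (!is.null(cis)) {
    bp <- bp |>
      left_join(select(cis, "caller", "side", "lo", "hi"),
                by = c("caller", "side")) |>
      mutate(lo = .data$point + .data$lo, hi = .data$point + .data$hi)
  }
  stopifnot(all(c("point", "lo", "hi") %in% names(bp)))
  if (any(bp$lo > bp$point | bp$hi < bp$point)) {
    abort("each CI must contain its breakpoint.")
  }
  if (nrow(bp) == 0) {
    return(mutate(bp, cluster = integer(), consensus_lo = double(),
                  consensus_hi = double(), consensus_bp = double()))
  }
  ord <- order(bp$lo, bp$hi)
  group <- integer(nrow(bp))
  g <- 0L; run_hi <- -Inf
  for (i in ord) {
    if (bp$lo[i] > run_hi) { g <- g + 1L; run_hi <- bp$hi[i] }
    else run_hi <- max(run_hi, bp$hi[i])
    group[i] <- g
  }
  out <- vector("list", g)
  next_cl <- 0L
  for (gi in seq_len(g)) {
    idx <- which(group == gi)
    sub <- bp[idx, , drop = FALSE]
    if (max(sub$lo) <= min(sub$hi)) {
      assign_cl <- rep(1L, nrow(sub))
      cons <- tibble(cl = 1L, lo = max(sub$lo), hi = min(sub$hi))
    } else {
      e <- sort(unique(c(sub$lo, sub$hi)))
      cov <- vapply(seq_len(length(e) - 1), function(k) {
        sum(sub$lo <= e[k] & sub$hi >= e[k + 1])
      }, numeric(1))
      # peaks of the coverage step function (plateau-aware via run-length
      # encoding); sub-CI = peak segment(s) + the segment to their right
      r <- rle(cov)
      run_end <- cumsum(r$lengths)
      run_start <- run_end - r$lengths + 1
      is_peak <- vapply(seq_along(r$values), function(k) {
        left_ok <- k == 1 || r$values[k] > r$values[k - 1]
        right_ok <- k == length(r$values) || r$values[k] > r$values[k + 1]
        left_ok && right_ok
      }, logical(1))
      sub_ci <- purrr::map(which(is_peak), function(k) {
        c(e[run_start[k]], e[min(run_end[k] + 2, length(e))])
      })
      dmat <- vapply(sub_ci, function(ci) {
        pmax(0, pmax(ci[1] - sub$point, sub$point - ci[2]))
      }, numeric(nrow(sub)))
      dmat <- matrix(dmat, nrow = nrow(sub))
      assign_cl <- apply(dmat, 1, which.min)
      cons <- purrr::imap(sub_ci, function(ci, k) {
        m <- sub[assign_cl == k, , drop = FALSE]
        if (nrow(m) > 0 && max(m$lo) <= min(m$hi)) {
          tibble(cl = k, lo = max(m$lo), hi = min(m$hi))
        } else tibble(cl = k, lo = ci[1], hi = ci[2])
      }) |> list_rbind()
    }
    res <- tibble(row = idx, cluster = next_cl + assign_cl)
    res <- left_join(res, mutate(cons, cluster = next_cl + .data$cl),
                     by = "cluster")
    out[[gi]] <- res
    next_cl <- next_cl + max(assign_cl)
  }
  res <- list_rbind(out) |> arrange(.data$row)
  bp$cluster <- res$cluster
  bp$consensus_lo <- res$lo
  bp$consensus_hi <- res$hi
  bp |>
    group_by(.data$cluster) |>
    mutate(consensus_bp = consensus_breakpoint(.data$point)) |>
    ungroup()
}

#' Consensus breakpoint of a cluster
#'
#' The coordinate proposed most frequently by different algorithms; ties
#' are broken by the smallest coordinate.
#'
#' @param points Numeric vector of proposed breakpoint coordinates.
#' @return A single coordinate.
#' @export
consensus_breakpoint <- function(points) {
  if (length(points) == 0) abort("empty cluster.")
  tab <- table(points)
  as.numeric(names(tab)[tab == max(tab)][1])
}
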