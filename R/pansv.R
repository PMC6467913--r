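#' Integrate Illumina, PB and BNG callsets into a pan-SV callset
#'
#' Merges the three filtered callsets into one record per locus: calls are
#' clustered across platforms by single-linkage reciprocal overlap (>
#' `ro_min`, same type), each record's provenance is the set of platforms
#' present, and the representative call is the PB variant when available,
#' otherwise the IL variant (also when shared between BNG and IL), otherwise
#' the BNG variant. Every input call lands in exactly one record.
#'
#' @param il,pb,bng Filtered callset tibbles: `call_id`, `chrom`, `start`,
#'   `end`, `type`, `sv_len`.
#' @param ro_min Cross-platform reciprocal-overlap threshold.
#' @return A `pan_sv` tibble: `record_id`, representative `chrom`, `start`,
#'   `end`, `type`, `sv_len`, `provenance` (e.g. `"PB,IL"`), `platform`
#'   (representative platform), `members` (list of platform:call_id).
#' @export
build_pan_sv <- function(il, pb, bng, ro_min = 0.5) {
  pool <- bind_rows(
    mutate(il, platform = "IL"),
    mutate(pb, platform = "PB"),
    mutate(bng, platform = "BNG")
  )
  if (nrow(pool) == 0) {
    return(structure(tibble(record_id = character(), chrom = character(),
                            start = double(), end = double(),
                            type = character(), sv_len = double(),
                            provenance = character(), platform = character(),
                            members = list()),
                     class = c("pan_sv", "tbl_df", "tbl", "data.frame")))
  }
  cl <- integer(nrow(pool))
  nxt <- 0L
  for (tp in unique(pool$type)) {
    idx <- which(pool$type == tp)
    cl[idx] <- nxt + ro_cluster(pool[idx, , drop = FALSE], ro_min)
    nxt <- max(cl)
  }
  res <- purrr::map(split(pool, cl), function(g) {
    i <- order(match(g$platform, c("PB", "IL", "BNG")))[1]
    tibble(
      chrom = g$chrom[i], start = g$start[i], end = g$end[i],
      type = g$type[i], sv_len = g$sv_len[i], platform = g$platform[i],
      provenance = paste(intersect(c("PB", "IL", "BNG"), unique(g$platform)),
                         collapse = ","),
      members = list(paste(g$platform, g$call_id, sep = ":"))
    )
  }) |>
    list_rbind() |>
    arrange(.data$chrom, .data$start) |>
    mutate(record_id = sprintf("pansv%05d", row_number()), .before = 1)
  class(res) <- c("pan_sv", class(res))
  res
}

#' Summarise a pan-SV callset by provenance class
#'
#' Counts and mean representative lengths per provenance class, the
#' standard summary table of a three-way integration (the `"PB,IL,BNG"`
#' class corresponds to calls shared by all platforms).
#'
#' @param pan A `pan_sv` tibble from [build_pan_sv()].
#' @return Tibble: `provenance`, `n`, `mean_len`.
#' @export
pan_sv_summary <- function(pan) {
  pan |>
    as_tibble() |>
    group_by(.data$provenance) |>
    summarise(n = n(), mean_len = mean(abs(.data$sv_len))) |>
    arrange(dplyr::desc(.data$n))
}
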