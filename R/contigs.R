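#' Merge local assemblies into contigs via a DAG longest path
#'
#' Builds a directed acyclic graph with a vertex per local assembly and an
#' edge between two assemblies when their genomic regions are separated by
#' at most `max_gap` (100 kb) and their overlap alignment is at least
#' `min_overlap` (10 kb), the edge directed by genomic order. One contig is
#' emitted per weakly connected component: the path maximizing the total
#' genomic span (union of member intervals). The maximization is exact via
#' a Pareto dynamic program over (rightmost end reached, union length)
#' states, so overlapping tiles are not double-counted.
#'
#' @param assemblies Tibble of local assemblies: `id`, `chrom`, `start`,
#'   `end` (0-based half-open) from one haplotype plus the autozygous set.
#' @param max_gap Maximum genomic separation for an edge, bp.
#' @param min_overlap Minimum overlap alignment for an edge, bp.
#' @param overlaps Optional tibble (`from`, `to`, `overlap_bp`) of
#'   sequence-level overlap alignments between assemblies; when absent the
#'   genomic interval intersection is used.
#' @return Tibble of contigs: `contig_id`, `chrom`, `members` (list of ids
#'   in path order), `n_members`, `span_start`, `span_end`,
#'   `spanned_length`.
#' @export
merge_local_assemblies <- function(assemblies, max_gap = 1e5,
                                   min_overlap = 1e4, overlaps = NULL) {
  stopifnot(all(c("id", "chrom", "start", "end") %in% names(assemblies)))
  if (any(assemblies$end <= assemblies$start)) abort("assembly intervals must be non-empty.")
  asm <- arrange(assemblies, .data$chrom, .data$start, .data$end)
  n <- nrow(asm)
  if (n == 0) return(tibble(contig_id = character(), chrom = character(),
                            members = list(), n_members = integer(),
                            span_start = double(), span_end = double(),
                            spanned_length = double()))
  ov_lookup <- NULL
  if (!is.null(overlaps)) {
    ov_lookup <- setNames(overlaps$overlap_bp,
                          paste(overlaps$from, overlaps$to, sep = "\r"))
  }
  edge_from <- integer(0); edge_to <- integer(0)
  for (i in seq_len(n)) {
    j <- i + 1L
    while (j <= n && asm$chrom[j] == asm$chrom[i] &&
           asm$start[j] - asm$end[i] <= max_gap) {
      ov <- if (!is.null(ov_lookup)) {
        ov_lookup[[paste(asm$id[i], asm$id[j], sep = "\r")]] %||%
          ov_lookup[[paste(asm$id[j], asm$id[i], sep = "\r")]] %||% 0
      } else {
        max(0, min(asm$end[i], asm$end[j]) - max(asm$start[i], asm$start[j]))
      }
      if (ov >= min_overlap) {
        edge_from <- c(edge_from, i); edge_to <- c(edge_to, j)
      }
      j <- j + 1L
    }
  }
  g <- igraph::graph_from_data_frame(
    data.frame(from = edge_from, to = edge_to), directed = TRUE,
    vertices = data.frame(name = seq_len(n)))
  if (!igraph::is_dag(g)) abort("internal error: assembly graph is not a DAG.")
  comp <- igraph::components(g, mode = "weak")$membership[as.character(seq_len(n))]
  adj <- split(edge_to, edge_from)
  purrr::map(seq_len(max(comp)), function(ci) {
    nodes <- which(comp == ci)
    best <- longest_span_path(nodes, adj, asm$start, asm$end)
    tibble(contig_id = sprintf("contig%03d", ci),
           chrom = asm$chrom[nodes[1]],
           members = list(asm$id[best$path]),
           n_members = length(best$path),
           span_start = asm$start[best$path[1]],
           span_end = max(asm$end[best$path]),
           spanned_length = best$len)
  }) |>
    list_rbind() |>
    arrange(.data$chrom, .data$span_start)
}

# Exact longest-span path in a component: Pareto DP over states
# (path ending at v, rightmost end reached, union length). Vertices are in
# genomic order, so added span of v after a path with rightmost end E is
# max(0, end_v - max(start_v, E)).
longest_span_path <- function(nodes, adj, start, end) {
  states <- list()  # per node: list of (max_end, len, path)
  for (v in nodes) {
    states[[as.character(v)]] <- list(list(max_end = end[v],
                                           len = end[v] - start[v],
                                           path = v))
  }
  for (v in nodes) {  # nodes in genomic (topological) order
    for (st in states[[as.character(v)]]) {
      for (w in adj[[as.character(v)]] %||% integer(0)) {
        add <- max(0, end[w] - max(start[w], st$max_end))
        cand <- list(max_end = max(st$max_end, end[w]),
                     len = st$len + add, path = c(st$path, w))
        cur <- states[[as.character(w)]]
        dominated <- any(vapply(cur, function(s)
          s$max_end <= cand$max_end && s$len >= cand$len, logical(1)))
        if (!dominated) {
          cur <- c(purrr::keep(cur, function(s)
            !(cand$max_end <= s$max_end && cand$len >= s$len)), list(cand))
          states[[as.character(w)]] <- cur
        }
      }
    }
  }
  all_states <- unlist(lapply(nodes, function(v) states[[as.character(v)]]),
                       recursive = FALSE)
  lens <- vapply(all_states, function(s) s$len, numeric(1))
  best <- all_states[[which.max(lens)]]
  list(path = best$path, len = best$len)
}
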