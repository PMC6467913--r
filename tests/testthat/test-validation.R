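test_that("read haplotype scoring follows the phred-gap rule", {
  expect_equal(assign_read_haplotype(tibble::tibble(matches_h1 = logical(0),
                                                    q = numeric(0))),
               "ambiguous")
  # three matches at q = 0.01: gap = 30 * log10(99) >> 10
  expect_equal(assign_read_haplotype(
    tibble::tibble(matches_h1 = rep(TRUE, 3), q = rep(0.01, 3))), "H1")
  # one SNV at q = 0.25: gap = 10 * log10(3) ~ 4.77 < 10
  expect_equal(assign_read_haplotype(
    tibble::tibble(matches_h1 = TRUE, q = 0.25)), "ambiguous")
  expect_error(assign_read_haplotype(tibble::tibble(matches_h1 = TRUE, q = 1)),
               "q")
})

test_that("haplotype scoring matches a brute-force product oracle and is symmetric", {
  for (case in 1:40) {
    withr::with_seed(300 + case, {
      k <- sample(0:10, 1)
      obs <- tibble::tibble(matches_h1 = runif(k) < 0.5,
                            q = runif(k, 0.001, 0.4))
    })
    got <- assign_read_haplotype(obs)
    # direct product-space oracle
    s1 <- prod(ifelse(obs$matches_h1, 1 - obs$q, obs$q))
    s2 <- prod(ifelse(obs$matches_h1, obs$q, 1 - obs$q))
    want <- if (k == 0 || 10 * abs(log10(s1 / s2)) <= 10) "ambiguous"
    else if (s1 > s2) "H1" else "H2"
    expect_equal(got, want)
    # H1/H2 relabeling symmetry
    swapped <- assign_read_haplotype(
      dplyr::mutate(obs, matches_h1 = !matches_h1))
    expect_equal(swapped,
                 c(H1 = "H2", H2 = "H1", ambiguous = "ambiguous")[[got]])
  }
})

test_that("assembly merging follows the gap/overlap edge rules", {
  tiles <- tibble::tibble(id = c("a", "b", "c"), chrom = "chr1",
                          start = c(0, 4e4, 8e4), end = c(6e4, 1e5, 1.4e5))
  one <- merge_local_assemblies(tiles)
  expect_equal(nrow(one), 1)
  expect_equal(one$members[[1]], c("a", "b", "c"))
  expect_equal(one$spanned_length, 1.4e5)

  apart <- tibble::tibble(id = c("a", "b"), chrom = "chr1",
                          start = c(0, 2.6e5), end = c(6e4, 3.2e5))
  expect_equal(nrow(merge_local_assemblies(apart)), 2)

  # supplied sequence-level overlaps let gapped regions join (gap <= 100 kb)
  gapped <- tibble::tibble(id = c("a", "b"), chrom = "chr1",
                           start = c(0, 1.1e5), end = c(6e4, 1.7e5))
  ov <- tibble::tibble(from = "a", to = "b", overlap_bp = 1.5e4)
  joined <- merge_local_assemblies(gapped, overlaps = ov)
  expect_equal(nrow(joined), 1)
  expect_equal(joined$n_members, 2)
})

test_that("DAG longest path equals exhaustive enumeration on random inputs", {
  enum_paths <- function(adj, v) {
    succ <- adj[[as.character(v)]]
    if (is.null(succ) || length(succ) == 0) return(list(v))
    out <- list(v)
    for (w in succ) out <- c(out, lapply(enum_paths(adj, w), function(p) c(v, p)))
    out
  }
  for (case in 1:25) {
    withr::with_seed(400 + case, {
      n <- sample(3:10, 1)
      start <- sort(sample.int(3e5, n))
      len <- sample(2e4:6e4, n, replace = TRUE)
    })
    asm <- tibble::tibble(id = sprintf("n%02d", 1:n), chrom = "chr1",
                          start = start, end = start + len)
    got <- merge_local_assemblies(asm)
    # oracle: rebuild edges per the rules, enumerate all paths, maximize
    # interval-union length
    asm_o <- asm[order(asm$start, asm$end), ]
    adj <- list()
    for (i in seq_len(n)) for (j in seq_len(n)) {
      if (i == j || asm_o$start[j] < asm_o$start[i] ||
          (asm_o$start[j] == asm_o$start[i] && j < i)) next
      gap <- asm_o$start[j] - asm_o$end[i]
      ov <- max(0, min(asm_o$end[i], asm_o$end[j]) -
                  max(asm_o$start[i], asm_o$start[j]))
      if (gap <= 1e5 && ov >= 1e4) {
        adj[[as.character(i)]] <- c(adj[[as.character(i)]], j)
      }
    }
    # component membership via undirected reachability
    und <- matrix(FALSE, n, n)
    for (i in names(adj)) for (j in adj[[i]]) {
      und[as.integer(i), j] <- TRUE; und[j, as.integer(i)] <- TRUE
    }
    comp <- seq_len(n)
    repeat {
      changed <- FALSE
      for (i in seq_len(n)) for (j in seq_len(n)) {
        if (und[i, j] && comp[j] != comp[i]) {
          comp[c(i, j)] <- min(comp[i], comp[j]); changed <- TRUE
        }
      }
      if (!changed) break
    }
    best_by_comp <- vapply(unique(comp), function(cc) {
      nodes <- which(comp == cc)
      paths <- unlist(lapply(nodes, function(v) enum_paths(adj, v)),
                      recursive = FALSE)
      max(vapply(paths, function(p)
        union_length(asm_o$start[p], asm_o$end[p]), numeric(1)))
    }, numeric(1))
    expect_equal(sort(got$spanned_length), sort(unname(best_by_comp)),
                 info = paste("case", case))
  }
})

test_that("boundary-window clustering and evaluation intervals are exact", {
  close_dels <- tibble::tibble(chrom = "chr1", start = c(5000, 5600),
                               end = c(5500, 6100), type = "DEL")
  cl <- cluster_svs_by_window(close_dels)  # boundaries 100 bp apart
  expect_equal(dplyr::n_distinct(cl$cluster), 1)
  far_dels <- tibble::tibble(chrom = "chr1", start = c(5000, 5800),
                             end = c(5500, 6300), type = "DEL")
  expect_equal(dplyr::n_distinct(cluster_svs_by_window(far_dels)$cluster), 2)

  single <- cluster_svs_by_window(
    tibble::tibble(chrom = "chr1", start = 5000, end = 5500, type = "DEL"))
  iv <- cluster_intervals(single)
  expect_equal(c(iv$eval_start, iv$eval_end), c(4000, 6500))
  ins <- cluster_svs_by_window(
    tibble::tibble(chrom = "chr1", start = 5000, end = 5001, type = "INS"))
  expect_equal(cluster_intervals(ins)$eval_end, 6000)
})

test_that("validators sit on the stated side of their decision boundaries", {
  expect_false(pbrc_validate(4))
  expect_true(pbrc_validate(5))
  expect_false(pbrc_validate(0))
  expect_false(pbrc_validate(NA))

  m <- fbn_match(tibble::tibble(sv_len = c(950, 700)), 1000)
  expect_equal(m$best, 1L)
  expect_equal(m$f_bn, 0.05)
  expect_true(m$validated)
  expect_false(fbn_match(tibble::tibble(sv_len = 880), 1000)$validated)
  expect_equal(fbn_match(tibble::tibble(sv_len = 1000), 1000)$f_bn, 0)
  expect_false(fbn_match(tibble::tibble(sv_len = 900), 1000)$validated) # f = 0.1 exactly
  expect_equal(nrow(fbn_match(tibble::tibble(sv_len = numeric(0)), 1000)), 0)

  expect_true(depth_validate_deletion(rep(20, 100), 10))
  expect_false(depth_validate_deletion(rep(40, 100), 10))
  expect_false(depth_validate_deletion(rep(30, 100), 10))  # strict <
  dip <- c(rep(40, 45), rep(10, 10), rep(40, 45))
  expect_true(depth_validate_deletion(dip, 10))
  expect_error(depth_validate_deletion(rep(10, 5), 10), "shorter")
})

test_that("depth validation equals a brute-force sliding-window oracle", {
  for (case in 1:20) {
    withr::with_seed(500 + case, {
      prof <- rpois(200, sample(c(20, 35, 45), 1))
      w <- sample(5:50, 1)
    })
    means <- vapply(seq_len(length(prof) - w + 1),
                    function(i) mean(prof[i:(i + w - 1)]), numeric(1))
    expect_equal(depth_validate_deletion(prof, w), min(means) < 30)
  }
})

test_that("short-read concordance filter applies its four conditions", {
  il <- tibble::tibble(call_id = c("q1", "q2", "q3", "q4"),
                       chrom = "chr1",
                       start = c(1e4, 5e4, 9e4, 13e4),
                       end = c(1e4 + 500, 5e4 + 500, 9e4 + 500, 13e4 + 500),
                       type = "DEL", sv_len = 500)
  pb_asm <- tibble::tibble(chrom = "chr1", start = 1e4, end = 1e4 + 400,
                           type = "DEL", sv_len = 400)       # concordance 0.8
  pb_reads <- tibble::tibble(chrom = "chr1", start = rep(5e4, 3),
                             end = rep(5e4 + 375, 3), type = "DEL",
                             sv_len = 375,                   # concordance 0.75
                             read_id = c("r1", "r2", "r3"))
  bng <- tibble::tibble(chrom = character(), start = double(),
                        end = double(), type = character(), sv_len = double())
  depth <- c(q1 = 40, q2 = 40, q3 = 10, q4 = 40)
  res <- il_concordance_filter(il, pb_asm, pb_reads, bng, depth)
  expect_equal(res$concordant, c(TRUE, TRUE, TRUE, FALSE))
  expect_true(res$cond_concordance[1])
  expect_true(res$cond_reads[2])
  expect_true(res$cond_depth[3])
  expect_false(any(res$cond_dotplot))
  # two supporting reads are not enough for condition (2)
  res2 <- il_concordance_filter(il[2, ], pb_asm[0, ], pb_reads[1:2, ], bng,
                                c(q2 = 40))
  expect_false(res2$concordant)
})
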