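# Shared fixture builders: every fixture is constructed in code.

# Oriented reads with sensible defaults.
make_reads <- function(pos, orientation = "reference", haplotag = "untagged",
                       chrom = "chr1") {
  tibble::tibble(chrom = chrom, pos = pos,
                 orientation = rep_len(orientation, length(pos)),
                 haplotag = rep_len(haplotag, length(pos)))
}

# A small deterministic genome for interval tests.
tiny_genome <- function(n_chroms = 1, chrom_length = 1e6, tr_density = 0,
                        seed = 1) {
  generate_genome_model(n_chroms, chrom_length, tr_density = tr_density,
                        snv_spacing_mean = 1000, seed = seed)
}

# Independent two-sided exact binomial p-value by direct enumeration
# (sums the probabilities of all outcomes no more likely than the observed
# one); deliberately not binom.test().
enum_binom_p <- function(x, n, p) {
  d <- dbinom(0:n, n, p)
  sum(d[d <= d[x + 1] * (1 + 1e-7)])
}

# Independent three-model genotyping oracle.
oracle_genotype <- function(n_ref, n_nonref, b = 0.02, min_reads = 50,
                            alpha = 0.01) {
  n <- n_ref + n_nonref
  models <- c(hom_ref = b, het = 0.5, hom_inv = 1 - b)
  lik <- vapply(models, function(p) dbinom(n_nonref, n, p), numeric(1))
  best <- names(models)[which.max(lik)]
  if (n < min_reads) return(list(genotype = "untyped", best = best))
  p_best <- enum_binom_p(n_nonref, n, models[[best]])
  list(genotype = if (p_best < alpha) "untyped" else best, best = best)
}

# Union length of a set of intervals (independent of package internals).
union_length <- function(start, end) {
  o <- order(start)
  start <- start[o]; end <- end[o]
  tot <- 0; cur_s <- start[1]; cur_e <- end[1]
  for (i in seq_along(start)[-1]) {
    if (start[i] > cur_e) { tot <- tot + cur_e - cur_s; cur_s <- start[i]; cur_e <- end[i] }
    else cur_e <- max(cur_e, end[i])
  }
  tot + cur_e - cur_s
}
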