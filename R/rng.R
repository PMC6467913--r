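# Seeded sub-streams: every generator draws from its own stream derived from
# (seed, label) so the output of one module never depends on how many random
# numbers another module consumed.

# Deterministic 31-bit hash of a label string (polynomial rolling hash).
hash_label <- function(label) {
  m <- 2147483647  # 2^31 - 1
  h <- 0
  for (k in utf8ToInt(label)) h <- (h * 131 + k) %% m
  as.integer(h)
}

# Derive a 31-bit sub-seed from a user seed and a stream label.
substream_seed <- function(seed, label) {
  stopifnot(is.numeric(seed), length(seed) == 1, !is.na(seed))
  m <- 2147483647
  as.integer((abs(as.double(seed)) %% m * 48271 + hash_label(label)) %% m)
}

# Evaluate `expr` under the labeled sub-stream, restoring RNG state after.
with_substream <- function(seed, label, expr) {
  withr::with_seed(substream_seed(seed, label), expr)
}

# Maximal-sum contiguous subarray (Kadane); returns c(from, to) indices.
max_subarray <- function(x) {
  best <- -Inf; best_from <- 1L; best_to <- 1L
  cur <- 0; cur_from <- 1L
  for (i in seq_along(x)) {
    if (cur <= 0) { cur <- x[i]; cur_from <- i }
    else cur <- cur + x[i]
    if (cur > best) { best <- cur; best_from <- cur_from; best_to <- i }
  }
  c(best_from, best_to)
}
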