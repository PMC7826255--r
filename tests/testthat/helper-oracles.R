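# Independent oracles used across the suite. These stay deliberately naive
# (brute force, direct formulas) and never share code with the implementation
# paths they check.

# microhomology by exhaustive placement enumeration: count equal-length
# deletions yielding the identical edited string
brute_mh <- function(reference, del_start, del_end) {
  n <- nchar(reference)
  d <- del_end - del_start
  del_at <- function(s) paste0(substr(reference, 1, s),
                               substr(reference, s + d + 1, n))
  target <- del_at(del_start)
  placements <- sum(vapply(0:(n - d), function(s) del_at(s) == target,
                           logical(1)))
  placements - 1L
}

# Gini by double loop over all pairs
brute_gini <- function(x) {
  n <- length(x)
  tot <- 0
  for (i in seq_len(n)) for (j in seq_len(n)) tot <- tot + abs(x[i] - x[j])
  tot / (2 * n^2 * mean(x))
}

# Pearson r^2 via the direct covariance formula
brute_r2 <- function(x, y) {
  sxy <- sum((x - mean(x)) * (y - mean(y)))
  (sxy^2) / (sum((x - mean(x))^2) * sum((y - mean(y))^2))
}

# random DNA string
rand_dna <- function(n) paste(sample(c("A", "C", "G", "T"), n, replace = TRUE),
                              collapse = "")

# random non-overlapping indel op table within [lo, hi) of a reference
rand_ops <- function(ref_len, n_ops = sample(1:3, 1), lo = 10L,
                     hi = ref_len - 10L) {
  ops <- NULL
  tries <- 0
  while (is.null(ops) && tries < 50) {
    tries <- tries + 1
    kind <- sample(c("insertion", "deletion"), n_ops, replace = TRUE)
    start <- sort(sample(seq.int(lo, hi - 6L), n_ops))
    end <- start
    ins <- rep("", n_ops)
    for (i in seq_len(n_ops)) {
      if (kind[i] == "deletion") end[i] <- start[i] + sample(1:6, 1)
      else ins[i] <- rand_dna(sample(1:4, 1))
    }
    ops <- tryCatch(edit_ops(kind, start, end, ins), error = function(e) NULL)
  }
  ops
}

# a small deterministic test amplicon with known context:
# -4 base T, planted 3-nt microhomology collapsing a 7-nt deletion
fixture_amp <- function(seed = 42) {
  random_amplicon(seed = seed, minus4 = "T", planted_mh = list(c(3, 7)),
                  id = "fix")
}

# default per-test simulation scale (small; acceptance tests set their own)
small_config <- function(...) {
  args <- modifyList(list(depth = 4000L, timepoints = c(4, 8, 12, 24, 48),
                          editable_fraction = 0.4), list(...))
  do.call(sim_config, args)
}
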