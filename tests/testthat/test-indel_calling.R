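# alignment, op extraction, window filtering, aggregation

test_that("alignment of the reference to itself is gapless and op-free", {
  amp <- fixture_amp()
  al <- align_to_reference(amp$reference_sequence, amp)
  expect_true(al$ok)
  expect_identical(nrow(al$ops), 0L)
  expect_equal(al$identity, 1)
})

test_that("single indels round-trip through alignment", {
  amp <- fixture_amp()
  ops <- edit_ops("deletion", amp$cut_site - 3L, amp$cut_site)
  read <- apply_allele(amp, ops)
  al <- align_to_reference(read, amp)
  # same placement-equivalence class: applying the recovered ops rebuilds
  # the identical read
  expect_identical(apply_allele(amp, al$ops), read)
  expect_identical(sum(al$ops$ref_end - al$ops$ref_start), 3L)
})

test_that("a slidable gap is reported at its leftmost placement", {
  # deleting any G of the GGG run yields the same string; leftmost wins
  ref <- paste0(strrep("ACT", 40), "AAGGGTT", strrep("TCA", 40))
  g_start <- 120L + 2L   # 0-based index of the first G
  for (del in g_start + 0:2) {
    read <- apply_allele(ref, edit_ops("deletion", del, del + 1L))
    amp_like <- list(reference_sequence = ref)
    res <- editrace:::align_signatures_cpp(read, ref, 2, -4, -10, -1, 24L)
    expect_identical(as.character(res$signature),
                     paste0("D:", g_start, "-", g_start + 1L))
  }
  # same for insertions in a homopolymer
  read <- apply_allele(ref, edit_ops("insertion", g_start + 2L, g_start + 2L,
                                     "G"))
  res <- editrace:::align_signatures_cpp(read, ref, 2, -4, -10, -1, 24L)
  expect_identical(as.character(res$signature),
                   paste0("I:", g_start, ":G"))
})

test_that("multi-column gaps coalesce into single ops", {
  amp <- fixture_amp()
  read <- apply_allele(amp, edit_ops("insertion", amp$cut_site, amp$cut_site,
                                     "TA"))
  al <- align_to_reference(read, amp)
  expect_identical(nrow(al$ops), 1L)
  expect_identical(nchar(al$ops$ins_seq), 2L)
})

test_that("call_allele applies the cut-window artifact rule", {
  amp <- fixture_amp()
  cut <- amp$cut_site
  # 1-bp insertion at the cut: edited
  ca <- call_allele(edit_ops("insertion", cut, cut, "T"), amp)
  expect_true(ca$edited)
  # 1-bp deletion 80 nt away: artifact, unedited
  ca2 <- call_allele(edit_ops("deletion", cut - 81L, cut - 80L), amp)
  expect_false(ca2$edited)
  # 25-bp deletion starting 30 nt left of the cut and spanning it: edited
  ca3 <- call_allele(edit_ops("deletion", cut - 30L, cut - 5L), amp)
  expect_true(ca3$edited)
  # substitution-only reads are unedited
  ca4 <- call_allele(edit_ops("substitution", cut, cut + 1L, "A"), amp)
  expect_false(ca4$edited)
})

test_that("aggregation reproduces exact counts and applies filters", {
  amp <- fixture_amp()
  cut <- amp$cut_site
  x <- apply_allele(amp, edit_ops("insertion", cut, cut, "T"))
  y <- apply_allele(amp, edit_ops("deletion", cut - 4L, cut))
  reads <- c(rep(amp$reference_sequence, 60), rep(x, 30), rep(y, 10))
  st <- call_sample(reads, amp)
  expect_identical(st$total_reads, 100L)
  expect_equal(sort(st$alleles$frequency, decreasing = TRUE), c(0.3, 0.1))
  expect_equal(editing_efficiency(st), 0.4)
  expect_identical(st$n_unalignable + st$n_unedited + sum(st$alleles$count),
                   st$total_reads)
  # a singleton allele under min_count = 2 is dropped from the edited set
  z <- apply_allele(amp, edit_ops("deletion", cut - 2L, cut + 3L))
  st2 <- call_sample(c(reads, z), amp, min_count = 2L)
  expect_false(any(grepl(paste0(cut + 3L), st2$alleles$signature)))
  expect_equal(editing_efficiency(st2), 40 / 101)
  # all-unedited sample
  st3 <- call_sample(rep(amp$reference_sequence, 5), amp)
  expect_identical(nrow(st3$alleles), 0L)
  expect_equal(editing_efficiency(st3), 0)
  expect_error(call_sample(character(), amp), "zero reads")
})

test_that("round-trip: ops of error-free reads are recovered for random alleles", {
  set.seed(99)
  amp <- fixture_amp()
  n_bad <- 0L
  for (i in 1:1000) {
    ops <- rand_ops(nchar(amp$reference_sequence),
                    n_ops = sample(1:2, 1),
                    lo = amp$cut_site - 40L, hi = amp$cut_site + 40L)
    read <- apply_allele(amp, ops)
    al <- align_to_reference(read, amp)
    if (!al$ok || !identical(apply_allele(amp, al$ops), read)) n_bad <- n_bad + 1L
  }
  expect_identical(n_bad, 0L)
})

test_that("top_n_patterns ranks by frequency with deterministic ties", {
  st <- sample_table(c("I:10:T", "D:10-12", "D:20-25"), c(30, 10, 10), 100)
  tp <- top_n_patterns(st, 10)
  expect_identical(nrow(tp), 3L)
  expect_identical(tp$signature[1], "I:10:T")
  # tie between D:10-12 (span 2) and D:20-25 (span 5): shorter span first
  expect_identical(tp$signature[2], "D:10-12")
  expect_identical(nrow(top_n_patterns(st, 2)), 2L)
})
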