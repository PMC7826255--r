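# microhomology, +1 duplication detection, pathway rules, category bins

test_that("microhomology matches the worked examples", {
  mh <- microhomology("TTACGACGTT", 2, 5)       # delete "ACG"
  expect_identical(mh$length, 3L)
  expect_identical(mh$sequence, "ACG")
  expect_identical(mh$placements, 4L)
  # distinct flanks: no repeat
  expect_identical(microhomology("ACGTACGT", 3, 4)$length, 0L)
  # perfect tandem repeat: cap at 16
  rep20 <- strrep(paste(rep(c("A","C","G","T"), 5), collapse = ""), 2)
  mh2 <- microhomology(rep20, 0, 20)
  expect_identical(mh2$length, 16L)
  expect_gt(mh2$placements, 17L)
})

test_that("microhomology equals brute-force placement enumeration", {
  set.seed(7)
  for (i in 1:2000) {
    n <- sample(20:60, 1)
    ref <- paste(sample(c("A", "C", "G", "T"), n, replace = TRUE,
                        prob = c(0.3, 0.2, 0.2, 0.3)), collapse = "")
    s <- sample(0:(n - 2), 1)
    e <- s + sample(1:min(8, n - s - 1), 1)
    mh <- microhomology(ref, s, e, cap = 1000L)
    expect_identical(mh$length, brute_mh(ref, s, e),
                     label = paste(ref, s, e))
  }
})

test_that("+1 duplications of the -4 base are detected, with sliding", {
  amp <- fixture_amp()   # -4 base T
  cut <- amp$cut_site
  expect_identical(is_plus1_duplication(edit_ops("insertion", cut, cut, "T"),
                                        amp), "T")
  # a non-duplicating insertion is not flagged
  expect_true(is.na(is_plus1_duplication(
    edit_ops("insertion", cut, cut, "G"), amp)))
  # 2-nt insertions never qualify
  expect_true(is.na(is_plus1_duplication(
    edit_ops("insertion", cut, cut, "TT"), amp)))
  # the left-aligned placement of the duplication still includes the cut
  sig <- ops_to_signature(editrace:::.left_align(
    amp$reference_sequence, edit_ops("insertion", cut, cut, "T")))
  expect_identical(is_plus1_duplication(sig, amp), "T")
})

test_that("classification follows the ordered pathway rules", {
  amp <- fixture_amp()   # planted MH 3 with 7-nt separation
  cut <- amp$cut_site
  # MMEJ: planted deletion has MH 3
  cl <- classify_allele(edit_ops("deletion", cut - 7L, cut), amp)
  expect_identical(cl$repair_class, "MMEJ")
  expect_identical(cl$mh_length, 3L)
  # insertions are NHEJ
  expect_identical(classify_allele(edit_ops("insertion", cut, cut, "T"),
                                   amp)$repair_class, "NHEJ")
  # complex alleles are NHEJ
  cl2 <- classify_allele(edit_ops(c("deletion", "insertion"),
                                  c(cut - 10L, cut), c(cut - 8L, cut),
                                  c("", "A")), amp)
  expect_identical(cl2$repair_class, "NHEJ")
  expect_identical(cl2$subtype, "complex")
  # HDR requires the donor and exact insert at the cut
  donor <- donor_spec("GGATCCAA")
  hdr_ops <- edit_ops("insertion", cut, cut, "GGATCCAA")
  expect_identical(classify_allele(hdr_ops, amp, donor)$repair_class, "HDR")
  expect_identical(classify_allele(hdr_ops, amp)$repair_class, "NHEJ")
  # a different insert is not HDR
  expect_identical(classify_allele(edit_ops("insertion", cut, cut,
                                            "GGATCCAT"), amp,
                                   donor)$repair_class, "NHEJ")
})

test_that("the 1-nt G|G / C|C rule fires only in the right context", {
  base_for <- function(b) {
    amp <- NULL
    for (s in 1:50) {
      cand <- random_amplicon(seed = s * 17L, minus4 = b)
      right <- substr(cand$reference_sequence, cand$cut_site + 1L,
                      cand$cut_site + 1L)
      if (right == b) { amp <- cand; break }
    }
    amp
  }
  ampG <- base_for("G")   # G|G across the cut
  cl <- classify_allele(edit_ops("deletion", ampG$cut_site - 1L,
                                 ampG$cut_site), ampG)
  expect_identical(cl$repair_class, "MMEJ")
  expect_identical(cl$subtype, "-1 G|G")
  ampT <- base_for("T")   # T|T across the cut -> NHEJ catch-all
  clT <- classify_allele(edit_ops("deletion", ampT$cut_site - 1L,
                                  ampT$cut_site), ampT)
  expect_identical(clT$repair_class, "NHEJ")
})

test_that("classification is invariant across equivalent deletion placements", {
  set.seed(21)
  for (i in 1:200) {
    amp <- random_amplicon(seed = 1000L + i)
    cut <- amp$cut_site
    s <- cut - sample(2:10, 1)
    e <- s + sample(2:8, 1)
    mh <- microhomology(amp$reference_sequence, s, e)
    calls <- vapply(mh$range, function(s2) {
      classify_allele(edit_ops("deletion", s2, s2 + (e - s)),
                      amp)$repair_class
    }, character(1))
    expect_identical(length(unique(calls)), 1L)
  }
})

test_that("category schemes bin alleles as documented", {
  amp <- fixture_amp()
  cut <- amp$cut_site
  insT <- edit_ops("insertion", cut, cut, "T")
  expect_identical(categorize("NHEJ", insT, amp, "seven_group"), "+A/T")
  expect_identical(categorize("NHEJ", insT, amp, "eleven_cat"), "+T")
  expect_identical(categorize("NHEJ", insT, amp, "competition_bins"), "+1")
  del7 <- edit_ops("deletion", cut - 7L, cut)
  expect_identical(categorize("MMEJ", del7, amp, "seven_group"), "-6 to -9")
  expect_identical(categorize("MMEJ", del7, amp, "t50_bins"), "-6 to -9")
  del40 <- edit_ops("deletion", cut - 40L, cut)
  expect_identical(categorize("NHEJ", del40, amp, "eleven_cat"), "other")
  expect_true(is.na(categorize("NHEJ", del40, amp, "seven_group")))
  expect_identical(categorize("MMEJ", del40, amp, "t50_bins"), ">= -10")
  del12 <- edit_ops("deletion", cut - 12L, cut)
  expect_identical(categorize("MMEJ", del12, amp, "eleven_cat"), "-10 to -23")
  expect_identical(categorize("MMEJ", del12, amp, "competition_bins"),
                   "-10 to -30")
  expect_identical(categorize("HDR", edit_ops("insertion", cut, cut,
                                              "GGATCCAA"), amp,
                              "competition_bins"), "HDR")
  expect_error(categorize("NHEJ", insT, amp, "nonsense"))
})

test_that("classify_sample annotates every allele with exactly one class", {
  amp <- fixture_amp()
  cut <- amp$cut_site
  st <- sample_table(c(ops_to_signature(edit_ops("insertion", cut, cut, "T")),
                       ops_to_signature(edit_ops("deletion", cut - 7L, cut)),
                       ops_to_signature(edit_ops("deletion", cut - 1L, cut))),
                     c(50, 30, 5), 200)
  cs <- classify_sample(st, amp)
  expect_true(all(cs$alleles$repair_class %in% c("NHEJ", "MMEJ")))
  expect_false(any(cs$alleles$repair_class == "HDR"))  # no donor, no HDR
  expect_true(all(nzchar(cs$alleles$cat_competition_bins)))
})
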