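# Gini, relative frequencies, competition deltas, correlations, predictions

test_that("Gini closed forms hold", {
  expect_equal(gini_coefficient(rep(0.2, 5)), 0)
  expect_equal(gini_coefficient(c(1, 0, 0, 0, 0)), 0.8)
  expect_equal(gini_coefficient(c(0.5, 0.2, 0.15, 0.1, 0.05)), 0.4)
})

test_that("gini_top_n pads to n, refuses donor samples and empty samples", {
  st <- sample_table(c("I:10:T", "D:10-12"), c(30, 10), 100)
  # top-5 with zero padding: shares 0.3, 0.1, 0, 0, 0
  expect_equal(gini_top_n(st, 5), brute_gini(c(0.3, 0.1, 0, 0, 0)))
  stp <- sample_table("I:10:T", 30, 100, condition = "donor_present")
  expect_error(gini_top_n(stp), "donor")
  st0 <- sample_table(character(), integer(), 100)
  expect_error(gini_top_n(st0), "Gini")
})

test_that("gini_coefficient equals the brute-force double loop", {
  set.seed(31)
  for (i in 1:1000) {
    x <- runif(sample(3:8, 1))
    expect_equal(gini_coefficient(x), brute_gini(x), tolerance = 1e-12)
  }
})

test_that("relative frequencies are shares of edited events summing to 1", {
  st <- sample_table(c("I:10:T", "D:10-12"), c(30, 10), 100)
  rf <- relative_frequencies(st)
  expect_equal(rf$share, c(0.75, 0.25))
  expect_equal(sum(rf$share), 1, tolerance = 1e-12)
  expect_error(relative_frequencies(sample_table(character(), integer(),
                                                 100)), "no edited")
  set.seed(32)
  for (i in 1:50) {
    k <- sample(2:6, 1)
    st2 <- sample_table(paste0("D:", 10 + seq_len(k) * 3, "-",
                               12 + seq_len(k) * 3),
                        sample(1:50, k), 500)
    expect_equal(sum(relative_frequencies(st2)$share), 1, tolerance = 1e-12)
  }
})

test_that("competition deltas compare per-bin shares", {
  amp <- fixture_amp()
  cut <- amp$cut_site
  sigs <- c(ops_to_signature(edit_ops("insertion", cut, cut, "T")),
            ops_to_signature(edit_ops("deletion", cut - 7L, cut)))
  s0 <- classify_sample(sample_table(sigs, c(40, 40), 200), amp)
  s0b <- classify_sample(sample_table(sigs, c(40, 40), 200,
                                      condition = "donor_present"), amp)
  d_same <- competition_delta(s0, s0b)
  expect_true(all(abs(d_same$delta) < 1e-12))
  # share halves: delta -50%
  s1 <- classify_sample(sample_table(sigs, c(60, 20), 200,
                                     condition = "donor_present"), amp)
  d <- competition_delta(s0, s1)
  expect_equal(d$delta[d$bin == "-6 to -9"], -0.5)
  expect_equal(d$delta[d$bin == "+1"], 0.5)
  # mismatched amplicons are rejected
  s2 <- s1; s2$amplicon_id <- "other"
  expect_error(competition_delta(s0, s2), "same amplicon")
})

test_that("competition_test reports a paired t statistic across loci", {
  amp <- fixture_amp()
  cut <- amp$cut_site
  sigs <- c(ops_to_signature(edit_ops("insertion", cut, cut, "T")),
            ops_to_signature(edit_ops("deletion", cut - 7L, cut)))
  mk <- function(c1, c2, cond) classify_sample(
    sample_table(sigs, c(c1, c2), 200, condition = cond), amp)
  pairs <- list(
    list(absent = mk(40, 40, "donor_absent"),
         present = mk(50, 25, "donor_present")),
    list(absent = mk(45, 35, "donor_absent"),
         present = mk(52, 20, "donor_present")))
  ct <- competition_test(pairs)
  row <- ct[ct$bin == "-6 to -9", ]
  expect_identical(row$n, 2L)
  expect_lt(row$mean_delta, 0)
  expect_true(is.finite(row$t))
})

test_that("pearson_r2 matches the direct formula and edge rules", {
  expect_equal(pearson_r2(1:5, 1:5)$r2, 1)
  expect_equal(pearson_r2(1:5, 2 * (1:5) + 1)$r2, 1)  # affine invariance
  set.seed(33)
  for (i in 1:100) {
    x <- rnorm(sample(4:10, 1)); y <- rnorm(length(x))
    expect_equal(pearson_r2(x, y)$r2, brute_r2(x, y), tolerance = 1e-12)
  }
  expect_error(pearson_r2(c(1, 1, 1), c(1, 2, 3)), "constant")
  expect_error(pearson_r2(1:2, 1:2), "3 points")
})

test_that("external prediction tables are matched by signature", {
  amp <- fixture_amp()
  cut <- amp$cut_site
  sigs <- c(paste0("I:", cut, ":T"), paste0("I:", cut, ":G"),
            paste0("I:", cut, ":C"),
            paste0("D:", cut - 7, "-", cut), paste0("D:", cut - 3, "-", cut),
            paste0("D:", cut - 5, "-", cut + 1))
  canon <- vapply(sigs, function(s) ops_to_signature(
    editrace:::.left_align(amp$reference_sequence, signature_to_ops(s))),
    character(1))
  st <- classify_sample(sample_table(canon, c(40, 10, 6, 20, 14, 10), 200),
                        amp)
  shares <- relative_frequencies(st)
  pred <- data.frame(signature = shares$signature,
                     frequency = shares$share)
  res <- compare_external_predictions(st, pred)
  expect_equal(res$r2, c(1, 1), tolerance = 1e-12)
  # permuted predictions lose the correlation
  set.seed(34)
  pred2 <- pred; pred2$frequency <- rev(pred2$frequency)
  res2 <- compare_external_predictions(st, pred2)
  expect_lt(res2$r2[res2$class == "NHEJ_plus1"], 0.99)
  # a table without deletions errors on the MMEJ class only
  pred3 <- pred[grepl("^I", pred$signature), ]
  expect_error(compare_external_predictions(st, pred3), "MMEJ_dels")
  one <- compare_external_predictions(st, pred3, classes = "NHEJ_plus1")
  expect_equal(one$r2, 1, tolerance = 1e-12)
  expect_error(compare_external_predictions(
    st, data.frame(signature = "D:1-2", frequency = 1)), "no common")
})

test_that("prediction CSV dialects are rewritten into canonical signatures", {
  amp <- fixture_amp()
  cut <- amp$cut_site
  tf <- tempfile(fileext = ".csv")
  # generic dialect passes through
  write.csv(data.frame(signature = c("I:100:T", "D:90-95"),
                       frequency = c(0.6, 0.4)), tf, row.names = FALSE)
  gen <- read_prediction_csv(tf)
  expect_identical(gen$signature, c("I:100:T", "D:90-95"))
  # indelphi-like dialect: category/position/length relative to the cut
  write.csv(data.frame(category = c("ins", "del"), position = c(NA, -7),
                       length = c(1, 7), inserted = c("T", NA),
                       frequency = c(0.3, 0.2)), tf, row.names = FALSE)
  ind <- read_prediction_csv(tf, amp, dialect = "indelphi")
  expect_identical(nrow(ind), 2L)
  expect_identical(ind$signature[2], ops_to_signature(
    editrace:::.left_align(amp$reference_sequence,
                           edit_ops("deletion", cut - 7L, cut))))
  # forecast-like dialect: D<len>_L<start> and I<len>_<base>
  write.csv(data.frame(pattern = c(paste0("D7_L", cut - 7), "I1_T"),
                       frequency = c(0.2, 0.3)), tf, row.names = FALSE)
  fc <- read_prediction_csv(tf, amp, dialect = "forecast")
  expect_identical(fc$signature[1], ind$signature[2])
})
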