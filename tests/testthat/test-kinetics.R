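# time courses, eligibility, T50 estimation

test_that("normalize_to_final rescales to the 48 h value", {
  tc <- time_course(c(4, 48), c(0.1, 0.4))
  expect_equal(normalize_to_final(tc)$frequencies, c(0.25, 1))
  const <- time_course(c(4, 8, 48), rep(0.2, 3))
  expect_equal(normalize_to_final(const)$frequencies, rep(1, 3))
  zero <- time_course(c(4, 48), c(0.1, 0))
  expect_error(normalize_to_final(zero), "zero")
})

test_that("eligibility needs >1% absolute and >2% of final indels", {
  tc_small <- time_course(c(4, 8, 12, 24, 48), rep(0.005, 5))
  expect_false(check_eligibility(tc_small, 0.5))
  tc_minor <- time_course(c(4, 8, 12, 24, 48),
                          c(0.01, 0.02, 0.03, 0.04, 0.05))
  expect_false(check_eligibility(tc_minor, 5))     # share 0.01 of indels
  expect_true(check_eligibility(tc_minor, 0.5))    # share 0.10
})

test_that("noise-free saturation curves are recovered exactly", {
  tp <- c(4, 8, 12, 24, 48)
  grid <- expand.grid(T50 = c(2, 3.5, 6.2, 9, 14, 20, 28, 34, 40),
                      F_max = c(0.02, 0.1, 0.4, 0.8))
  grid <- grid[seq(1, nrow(grid), length.out = 20), ]
  for (k in seq_len(nrow(grid))) {
    T50 <- grid$T50[k]; F <- grid$F_max[k]
    y <- F * (1 - 2^(-tp / T50))
    ft <- fit_t50(time_course(tp, y))
    expect_identical(ft$method, "least_squares")
    expect_lt(abs(ft$T50 - T50), 1e-6)
    expect_lt(abs(ft$F_max - F), 1e-6)
  }
})

test_that("the interpolation fallback crosses 0.5 where expected", {
  # a saturating-then-flat curve the parametric model cannot represent
  tc <- time_course(c(4, 8, 12, 24, 48), c(0.25, 0.5, 0.75, 1, 1))
  ft <- fit_t50(tc)
  if (ft$method == "interpolation") {
    expect_equal(ft$T50, 8)
  } else {
    # if the parametric stage accepted the fit it must still place the
    # half-crossing of the normalized curve near 8 h
    expect_lt(abs(editrace:::.interp_t50(tc$times, tc$frequencies) - 8), 1e-9)
  }
  # ineligible patterns are not fitted
  ft2 <- fit_t50(tc, eligible = FALSE)
  expect_false(ft2$ok)
  expect_true(is.na(ft2$T50))
  # non-monotone curves without a crossing fail cleanly
  bad <- time_course(c(4, 8, 12, 24, 48), c(0.4, 0.2, 0.1, 0.05, 0))
  expect_error(normalize_to_final(bad))
})

test_that("T50 is invariant under scaling of the frequency axis", {
  tp <- c(4, 8, 12, 24, 48)
  y <- 0.6 * (1 - 2^(-tp / 11))
  f1 <- fit_t50(time_course(tp, y))
  f2 <- fit_t50(time_course(tp, y / 3))
  expect_lt(abs(f1$T50 - f2$T50), 1e-6)
})

test_that("summarize_t50 aggregates eligible fits per category", {
  fits <- data.frame(
    category = c("+T", "+T", "-3 to -5", "-3 to -5", "-3 to -5"),
    T50 = c(6, 8, 18, 20, 99),
    eligible = c(TRUE, TRUE, TRUE, TRUE, FALSE))
  sm <- summarize_t50(fits)
  expect_equal(sm$mean_T50[sm$category == "+T"], 7)
  expect_equal(sm$sd_T50[sm$category == "+T"], sqrt(2))
  expect_identical(sm$n[sm$category == "-3 to -5"], 2L)  # ineligible excluded
  single <- summarize_t50(data.frame(category = "x", T50 = 6.5,
                                     eligible = TRUE))
  expect_equal(single$sd_T50, 0)
  expect_identical(single$n, 1L)
  expect_warning(summarize_t50(data.frame(category = c("a", "b"),
                                          T50 = c(5, NA),
                                          eligible = c(TRUE, TRUE))),
                 "omitted")
})

test_that("build_time_courses assembles trajectories across timepoints", {
  amp <- fixture_amp()
  cut <- amp$cut_site
  sig <- ops_to_signature(edit_ops("insertion", cut, cut, "T"))
  samples <- lapply(c(4, 8, 12, 24, 48), function(tp)
    sample_table(sig, round(tp * 10), 10000, timepoint_h = tp))
  btc <- build_time_courses(samples)
  expect_identical(names(btc$time_courses), sig)
  expect_equal(btc$time_courses[[sig]]$frequencies,
               c(4, 8, 12, 24, 48) * 10 / 10000)
  expect_equal(btc$total_indels_final, 0.048)
})
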