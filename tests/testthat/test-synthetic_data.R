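# generator: amplicon constraints, race model vs analytic oracle, reads

test_that("random_amplicon satisfies requested constraints deterministically", {
  a1 <- random_amplicon(seed = 5, minus4 = "C")
  a2 <- random_amplicon(seed = 5, minus4 = "C")
  expect_identical(a1$reference_sequence, a2$reference_sequence)
  expect_identical(minus4_base(a1), "C")
  # planted microhomology is detected by the classifier machinery
  amp <- random_amplicon(seed = 8, planted_mh = list(c(3, 7), c(2, 5)))
  expect_identical(microhomology(amp$reference_sequence, amp$cut_site - 7L,
                                 amp$cut_site)$length, 3L)
  expect_identical(microhomology(amp$reference_sequence, amp$cut_site - 5L,
                                 amp$cut_site)$length, 2L)
  # impossible constraints error out after bounded retries
  expect_error(random_amplicon(seed = 1, planted_mh = list(c(5, 3))),
               "separation")
})

test_that("outcome models encode the documented target shares", {
  cfg <- sim_config(seed = 1, cell_profile = "T", editable_fraction = 0.4)
  amp <- random_amplicon(seed = 5, minus4 = "T")
  set.seed(1)
  model <- build_outcome_model(amp, config = cfg)
  dup <- model$outcomes$target_share[1L]
  expect_equal(dup, 0.27, tolerance = 1e-9)
  # calibration: analytic shares at 48 h equal the targets
  oc <- race_occupancy(model$outcomes$activation, model$outcomes$rate, 48)
  expect_equal(oc$p / sum(oc$p), model$outcomes$target_share,
               tolerance = 1e-6, ignore_attr = TRUE)
  # iPSC multiplies +1 insertion shares by 1.4
  cfgI <- sim_config(seed = 1, cell_profile = "iPSC",
                     editable_fraction = 0.4)
  set.seed(1)
  modelI <- build_outcome_model(amp, config = cfgI)
  expect_equal(modelI$outcomes$target_share[1L], 0.27 * 1.4,
               tolerance = 1e-9)
  # HDR outcome exists iff a donor is present
  expect_false(any(model$outcomes$repair_class == "HDR"))
  set.seed(1)
  modelD <- build_outcome_model(amp, donor = donor_spec("GGATCCGTTAACTAG"),
                                config = cfg)
  expect_identical(sum(modelD$outcomes$repair_class == "HDR"), 1L)
  # the NHEJ inhibitor knob scales NHEJ rates
  cfgM <- sim_config(seed = 1, cell_profile = "T", nhej_scale = 0.1,
                     editable_fraction = 0.4)
  set.seed(1)
  modelM <- build_outcome_model(amp, config = cfgM)
  nh <- model$outcomes$kinetic_class == "NHEJ"
  expect_equal(modelM$outcomes$rate[nh], 0.1 * model$outcomes$rate[nh],
               tolerance = 1e-9)
})

test_that("simulate_locus matches the analytic occupancy oracle", {
  cfg <- sim_config(seed = 2, depth = 40000L, editable_fraction = 0.5)
  amp <- random_amplicon(seed = 9, minus4 = "A")
  set.seed(2)
  model <- build_outcome_model(amp, config = cfg)
  sim <- simulate_locus(model, cfg, seed = 3)
  for (tp in c("8", "48")) {
    oc <- race_occupancy(model$outcomes$activation, model$outcomes$rate,
                         as.numeric(tp))
    expected <- oc$p * model$editable_fraction
    got <- sim$truth[[tp]]$true_freq
    # binomial noise at depth 40k: 4 sigma per outcome
    tol <- 4 * sqrt(pmax(expected * (1 - expected), 1e-9) / cfg$depth)
    expect_true(all(abs(got - expected) < tol + 2e-3))
  }
  # conservation at every timepoint
  for (tp in names(sim$truth))
    expect_equal(sum(sim$truth[[tp]]$true_freq) + sim$unedited[[tp]], 1)
  # determinism
  sim2 <- simulate_locus(model, cfg, seed = 3)
  expect_identical(sim, sim2)
  # depth 0 gives empty tables
  cfg0 <- sim_config(seed = 2, depth = 0L, editable_fraction = 0.5)
  sim0 <- simulate_locus(model, cfg0, seed = 3)
  expect_equal(unname(sim0$unedited), rep(1, 5))
})

test_that("early NHEJ dominance: +1 share of edits is higher at 4 h than 48 h", {
  cfg <- sim_config(seed = 4, depth = 30000L, editable_fraction = 0.5)
  amp <- random_amplicon(seed = 10, minus4 = "T")
  set.seed(4)
  model <- build_outcome_model(amp, config = cfg)
  sim <- simulate_locus(model, cfg, seed = 5)
  share_at <- function(tp) {
    d <- sim$truth[[tp]]
    d$true_freq[1L] / sum(d$true_freq)
  }
  expect_gt(share_at("4"), share_at("48"))
})

test_that("reads_from_frequencies is exact without error and binomial with", {
  cfg <- sim_config(seed = 6, depth = 10000L, timepoints = 48,
                    error_rate = 0, editable_fraction = 0.4)
  amp <- random_amplicon(seed = 11, minus4 = "G")
  freq <- data.frame(signature = c("I:120:G", "D:114-120"),
                     true_freq = c(0.3, 0.1))
  rd <- reads_from_frequencies(amp, freq, cfg, seed = 7)
  # error-free reads merge back to exact fragments
  m <- merge_pairs(rd$r1, rd$r2)
  expect_true(all(m$ok))
  frags <- paste0(cfg$barcode, vapply(c(freq$signature, ""), function(s)
    apply_allele(amp, s), character(1)))
  expect_true(all(m$seq %in% frags))
  expect_identical(sum(rd$truth$reads), 10000L)
  # sampled counts near binomial expectation (4 sigma)
  expect_lt(abs(rd$truth$reads[1L] - 3000), 4 * sqrt(10000 * 0.3 * 0.7))
  # same seed, byte-identical reads
  rd2 <- reads_from_frequencies(amp, freq, cfg, seed = 7)
  expect_identical(rd, rd2)
})

test_that("the packaged kinetics fixture behaves as documented", {
  fx <- fixture_bcl11a_fig3(seed = 12,
                            config = small_config(seed = 12))
  # +1 duplication is the top pattern at 48 h
  d48 <- fx$sim$truth[["48"]]
  expect_identical(d48$signature[which.max(d48$true_freq)],
                   fx$plus1_signature)
  # generating taus: +1 five hours, -4 MMEJ sixteen
  oo <- fx$model$outcomes
  expect_equal(oo$tau[oo$signature == fx$plus1_signature], 5)
  expect_equal(oo$tau[oo$signature == fx$mmej4_signature], 16)
  # estimated T50 ordering through the full pipeline, across seeds
  wins <- 0L
  for (s in 1:5) {
    fx2 <- fixture_bcl11a_fig3(seed = 100 + s,
                               config = small_config(seed = 100 + s,
                                                     depth = 6000L))
    res <- run_locus_pipeline(fx2$amplicon, fx2$model, fx2$config,
                              seed = 200 + s)
    kk <- kinetics_by_category(res$samples)
    t_plus1 <- kk$fits$T50[kk$fits$pattern == fx2$plus1_signature]
    t_mh <- kk$fits$T50[kk$fits$pattern == fx2$mmej4_signature]
    if (length(t_plus1) == 1 && length(t_mh) == 1 && !is.na(t_plus1) &&
        !is.na(t_mh) && t_plus1 < t_mh) wins <- wins + 1L
  }
  expect_gte(wins, 4L)
})

test_that("a no-donor model never yields HDR calls end to end", {
  cfg <- small_config(seed = 13, depth = 3000L)
  cfg$timepoints <- 48
  amp <- random_amplicon(seed = 13)
  set.seed(13)
  model <- build_outcome_model(amp, config = cfg)
  res <- run_locus_pipeline(amp, model, cfg, seed = 13)
  expect_false(any(res$samples[[1L]]$alleles$repair_class == "HDR"))
})
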