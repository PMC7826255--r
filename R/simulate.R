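# Synthetic-data generator: amplicons with controllable -4 base and planted
# microhomologies, a per-locus editing-outcome model, and a stochastic
# repair-race that produces time-resolved allele frequencies and paired-end
# reads. The race gives every editable cell a completion time per candidate
# outcome (class delay + exponential stage, propensity accelerating the
# exponential); the earliest outcome wins the cell. Defaults encode the
# published editing biases (+1 duplication shares by -4 base, cell-type
# multipliers) and repair-speed ordering (NHEJ fastest, then HDR, then MMEJ
# with longer deletions slowest).

# class kinetic constants: tau = observable class T50 target (hours, iPSC),
# rho = fraction of tau spent in the deterministic delay. The rho values are
# package constants chosen against the printed class T50s (see the methods
# vignette for why a race model cannot match all marginals exactly).
.KINETIC_RHO <- c(NHEJ = 0.20, MMEJ_short = 0.68, MMEJ_long = 0.78,
                  HDR = 0.80)
.NHEJ_INS_TAU <- c(T = 6.2, A = 7.8, C = 7.9, G = 6.6)
.CLASS_TAU <- c(NHEJ = 7.1, MMEJ_short = 18.4, MMEJ_long = 21.9, HDR = 15)
# +1 duplication target shares of edited events by -4 base (non-iPSC)
.DUP_SHARE <- c(T = 0.27, A = 0.10, C = 0.05, G = 0.03)

#' Simulation configuration
#'
#' @param seed integer seed; fully determines all generator output.
#' @param cell_profile `"iPSC"`, `"K562"`, `"U937"` or `"T"`. iPSC multiplies
#'   +1-insertion target shares by 1.4; K562 and U937 slow NHEJ T50 by 2.0x
#'   and 1.6x; T cells speed MMEJ T50 by 0.85x.
#' @param depth reads (and simulated cells) per timepoint.
#' @param timepoints sampling times in hours (default 4, 8, 12, 24, 48).
#' @param error_rate per-base substitution sequencing-error rate
#'   (default 0.002; no indel errors).
#' @param read_length paired-end read length (default 150).
#' @param hdr_propensity target HDR share of edited events at the final
#'   timepoint when a donor is present (default 0.40; see vignette).
#' @param nhej_scale,mmej_scale inhibitor knobs in (0, 1]: multiply the
#'   exponential-stage rates of the corresponding class (1 = no inhibitor).
#' @param editable_fraction per-locus fraction of editable cells; `NULL`
#'   draws one value per locus from Uniform(0.2, 0.6).
#' @param barcode inline sample barcode prepended to simulated fragments.
#' @param calib_time horizon (hours) at which outcome shares are calibrated
#'   (default 48, the assay endpoint).
#' @return a `sim_config` list.
#' @export
sim_config <- function(seed = 1L, cell_profile = c("iPSC", "K562", "U937",
                                                   "T"),
                       depth = 50000L, timepoints = c(4, 8, 12, 24, 48),
                       error_rate = 0.002, read_length = 150L,
                       hdr_propensity = 0.40, nhej_scale = 1, mmej_scale = 1,
                       editable_fraction = NULL, barcode = "ACGTGGCT",
                       calib_time = 48) {
  cell_profile <- match.arg(cell_profile)
  stopifnot(depth >= 0, all(timepoints > 0), error_rate >= 0,
            error_rate < 1, read_length > 0,
            hdr_propensity > 0, hdr_propensity < 0.95,
            nhej_scale > 0, nhej_scale <= 1, mmej_scale > 0, mmej_scale <= 1)
  structure(list(seed = as.integer(seed), cell_profile = cell_profile,
                 depth = as.integer(depth), timepoints = sort(timepoints),
                 error_rate = error_rate, read_length = as.integer(read_length),
                 hdr_propensity = hdr_propensity, nhej_scale = nhej_scale,
                 mmej_scale = mmej_scale,
                 editable_fraction = editable_fraction, barcode = barcode,
                 calib_time = calib_time),
            class = "sim_config")
}

#' Random amplicon with controllable cut-site context
#'
#' Generates a uniform-random reference with a valid protospacer+NGG placed
#' centrally, the requested -4 nucleotide, and optional planted
#' microhomology pairs straddling the cut (a repeat of `mh_len` bases whose
#' collapse deletes `separation` bases ending at the cut).
#'
#' @param seed integer seed (`NULL` = use current RNG state).
#' @param length reference length (default 240, >= 120).
#' @param minus4 requested -4 base or `NULL` for random.
#' @param planted_mh list of `c(mh_len, separation)` pairs; each plants a
#'   repeat so that deleting `[cut - separation, cut)` has exactly `mh_len`
#'   microhomology. Requires `separation >= max(mh_len, 2)`.
#' @param id amplicon id.
#' @param strand strand to annotate the protospacer on.
#' @param max_tries bounded retries before giving up on an impossible
#'   constraint combination.
#' @return an [amplicon()].
#' @export
random_amplicon <- function(seed = NULL, length = 240L, minus4 = NULL,
                            planted_mh = NULL, id = "sim_amp",
                            strand = "+", max_tries = 200L) {
  if (!is.null(seed)) set.seed(seed)
  length <- as.integer(length)
  if (length < 120L) stop("length must be >= 120")
  if (!is.null(minus4)) stopifnot(minus4 %in% .BASES)
  for (p in planted_mh) {
    if (p[2L] < max(p[1L], 2L) || p[2L] > 30L)
      stop("planted microhomology needs max(mh_len, 2) <= separation <= 30")
  }
  for (try in seq_len(max_tries)) {
    s <- sample(.BASES, length, replace = TRUE)
    cut0 <- length %/% 2L               # 0-based inter-base cut index
    pam_start <- cut0 + 3L
    s[pam_start + 2L] <- "G"; s[pam_start + 3L] <- "G"   # 1-based indices
    if (!is.null(minus4)) {
      s[cut0] <- minus4                  # 1-based: base left of the cut
      s[pam_start + 1L] <- minus4        # PAM N; copied into planted repeats
    }
    ok <- TRUE
    for (p in planted_mh) {
      L <- as.integer(p[1L]); sep <- as.integer(p[2L])
      src <- s[(cut0 + 1L):(cut0 + L)]            # right copy (exists already)
      s[(cut0 - sep + 1L):(cut0 - sep + L)] <- src  # left copy
    }
    if (!is.null(minus4) && s[cut0] != minus4) ok <- FALSE
    if (s[pam_start + 2L] != "G" || s[pam_start + 3L] != "G") ok <- FALSE
    ref <- paste(s, collapse = "")
    if (ok) for (p in planted_mh) {
      mh <- microhomology(ref, cut0 - p[2L], cut0)
      if (mh$length != p[1L]) { ok <- FALSE; break }
    }
    if (!ok) next
    amp <- tryCatch({
      if (strand == "+") amplicon(id, ref, pam_start)
      else amplicon(id, revcomp(ref),
                    length - (pam_start + 3L), strand = "-")
    }, error = function(e) NULL)
    if (is.null(amp)) next
    if (!is.null(minus4) && minus4_base(amp) != minus4) next
    return(amp)
  }
  stop("could not satisfy the amplicon constraints in ", max_tries, " tries")
}

#' Exact occupancy of the repair race
#'
#' For outcomes with activation times `activation` and exponential rates
#' `rate`, returns `P(outcome i wins and completes by t)` for each outcome
#' and the surviving (still-uncommitted) fraction. This closed form is the
#' calibration engine and serves as the independent oracle for the Monte
#' Carlo simulator.
#'
#' @param activation,rate parallel numeric vectors (class delay; exponential
#'   stage rate).
#' @param t observation time (hours).
#' @return list with `p` (per-outcome occupancy) and `surviving`.
#' @export
race_occupancy <- function(activation, rate, t) {
  stopifnot(length(activation) == length(rate), all(rate >= 0))
  K <- length(activation)
  p <- numeric(K); surv <- 1
  segs <- c(sort(unique(activation[activation < t])), t)
  if (length(segs) < 2L && all(activation >= t))
    return(list(p = p, surviving = 1))
  for (k in seq_len(length(segs) - 1L)) {
    lo <- segs[k]; hi <- segs[k + 1L]
    act <- which(activation <= lo + 1e-12)
    Lam <- sum(rate[act]); d <- hi - lo
    intS <- if (Lam <= 0) surv * d else surv * (1 - exp(-Lam * d)) / Lam
    p[act] <- p[act] + rate[act] * intS
    surv <- surv * exp(-Lam * d)
  }
  list(p = p, surviving = surv)
}

# solve outcome weights so that occupancy shares at calib_time match the
# target shares (multiplicative fixed point on the exact occupancy)
.calibrate_weights <- function(target, activation, mu, t, iter = 400L,
                               tol = 1e-10) {
  w <- target / sum(target)
  for (i in seq_len(iter)) {
    lam <- (w / mean(w)) / mu
    oc <- race_occupancy(activation, lam, t)
    q <- oc$p / sum(oc$p)
    if (max(abs(q - target / sum(target))) < tol) break
    w <- w * (target / sum(target) / q)^0.7
    w <- w / sum(w)
  }
  w
}

#' Build the per-locus editing-outcome model
#'
#' Enumerates candidate outcomes and calibrates their race propensities so
#' that the expected shares of edited events at `calib_time` equal the
#' documented targets:
#' \itemize{
#'   \item +1 duplication of the -4 base: share by base (T 0.27, A 0.10,
#'     C 0.05, G 0.03; iPSC multiplies +1 insertions by 1.4);
#'   \item a +1 non-duplication insertion and a -1 NHEJ deletion, 0.05 each;
#'   \item the 1-nt G|G / C|C microhomology deletion (0.04) when the cut
#'     context provides it;
#'   \item all MMEJ deletions (length 2-30 touching the cut, junction MH
#'     2-16) sharing the remaining mass proportionally to
#'     `mh_len * exp(-del_len / 15)`.
#' }
#' When a donor is present an HDR outcome is appended with its rate solved
#' so that HDR reaches `hdr_propensity` of edited events at `calib_time` at
#' the frozen indel rates (competition then emerges from the race rather
#' than from renormalisation). Inhibitor knobs scale class rates after
#' calibration.
#'
#' @param amp the [amplicon()].
#' @param donor optional [donor_spec()].
#' @param config a [sim_config()].
#' @param tau_overrides,share_overrides optional named vectors (by outcome
#'   signature) overriding class T50 or target share for specific outcomes
#'   (used by the packaged fixtures).
#' @return an `outcome_model`: list with `outcomes` data.frame (`signature`,
#'   `repair_class`, `kinetic_class`, `tau`, `activation`, `mu`, `rate`,
#'   `target_share`), `editable_fraction`, `donor`, `amplicon_id`.
#' @export
build_outcome_model <- function(amp, donor = NULL, config = sim_config(),
                                tau_overrides = NULL, share_overrides = NULL) {
  stopifnot(inherits(amp, "amplicon"), inherits(config, "sim_config"))
  ref <- amp$reference_sequence
  cut <- amp$cut_site
  m4 <- minus4_base(amp)
  ipsc <- config$cell_profile == "iPSC"
  ins_mult <- if (ipsc) 1.4 else 1.0

  canon <- function(ops) ops_to_signature(.left_align(ref, ops))
  sig_dup <- canon(edit_ops("insertion", cut, cut,
                            if (amp$strand == "+") m4 else .complement[[m4]]))
  nondup_base <- sample(setdiff(.BASES, m4), 1L)
  sig_nondup <- canon(edit_ops("insertion", cut, cut,
                               if (amp$strand == "+") nondup_base
                               else .complement[[nondup_base]]))
  sig_del1 <- canon(edit_ops("deletion", cut - 1L, cut))

  sig <- c(sig_dup, sig_nondup)
  tgt <- c(unname(.DUP_SHARE[m4]) * ins_mult, 0.05 * ins_mult)
  # -1 at the cut: G|G / C|C context makes it the 1-nt MMEJ outcome
  left <- substr(ref, cut, cut); right <- substr(ref, cut + 1L, cut + 1L)
  gg_context <- left == right && left %in% c("G", "C")
  sig <- c(sig, sig_del1)
  tgt <- c(tgt, if (gg_context) 0.04 else 0.05)

  # MMEJ candidates: deletions touching the cut, 2-30 nt, junction MH 2-16
  cand <- list()
  for (s0 in seq.int(max(0L, cut - 30L), cut)) {
    for (e0 in seq.int(max(cut, s0 + 2L), min(nchar(ref), s0 + 30L))) {
      mh <- microhomology(ref, s0, e0)
      if (mh$length >= 2L && mh$length <= 16L) {
        sg <- canon(edit_ops("deletion", s0, e0))
        cand[[sg]] <- c(mh = mh$length, d = e0 - s0)
      }
    }
  }
  cand <- cand[setdiff(names(cand), sig)]
  if (length(cand) > 0L) {
    kern <- vapply(cand, function(x) x[["mh"]] * exp(-x[["d"]] / 15),
                   numeric(1L))
    rem <- 1 - sum(tgt)
    if (rem > 0.01) {
      sig <- c(sig, names(cand))
      tgt <- c(tgt, rem * kern / sum(kern))
    }
  }
  tgt <- tgt / sum(tgt)
  names(tgt) <- sig
  if (!is.null(share_overrides)) {
    for (nm in names(share_overrides)) {
      if (!nm %in% sig) stop("share override for unknown outcome ", nm)
      tgt[nm] <- share_overrides[[nm]]
    }
    others <- setdiff(sig, names(share_overrides))
    tgt[others] <- tgt[others] / sum(tgt[others]) *
      max(1 - sum(tgt[names(share_overrides)]), 1e-6)
  }

  # classify outcomes and assign kinetic classes / taus
  rc <- character(length(sig)); kc <- character(length(sig))
  tau <- numeric(length(sig))
  for (i in seq_along(sig)) {
    cl <- classify_allele(sig[i], amp)
    rc[i] <- cl$repair_class
    o <- signature_to_ops(sig[i])
    if (o$kind[1L] == "insertion") {
      kc[i] <- "NHEJ"
      b <- if (amp$strand == "+") o$ins_seq[1L] else .complement[[o$ins_seq[1L]]]
      tau[i] <- if (nchar(o$ins_seq[1L]) == 1L) .NHEJ_INS_TAU[[b]]
                else .CLASS_TAU[["NHEJ"]]
    } else {
      d <- o$ref_end[1L] - o$ref_start[1L]
      if (rc[i] == "MMEJ") {
        kc[i] <- if (d <= 5L) "MMEJ_short" else "MMEJ_long"
      } else kc[i] <- "NHEJ"
      tau[i] <- .CLASS_TAU[[kc[i]]]
    }
  }
  # cell-profile kinetic multipliers
  nhej_mult <- switch(config$cell_profile, K562 = 2.0, U937 = 1.6, 1.0)
  mmej_mult <- switch(config$cell_profile, T = 0.85, 1.0)
  tau <- tau * ifelse(kc == "NHEJ", nhej_mult, mmej_mult)
  if (!is.null(tau_overrides)) {
    for (nm in names(tau_overrides)) {
      if (!nm %in% sig) stop("tau override for unknown outcome ", nm)
      tau[match(nm, sig)] <- tau_overrides[[nm]]
    }
  }
  rho <- .KINETIC_RHO[kc]
  activation <- rho * tau
  mu <- (1 - rho) * tau / log(2)

  w <- .calibrate_weights(tgt, activation, mu, config$calib_time)
  rate <- (w / mean(w)) / mu
  # inhibitor knobs scale class rates post-calibration
  rate <- rate * ifelse(kc == "NHEJ", config$nhej_scale, config$mmej_scale)

  out <- data.frame(signature = sig, repair_class = rc, kinetic_class = kc,
                    tau = tau, activation = activation, mu = mu, rate = rate,
                    target_share = as.numeric(tgt),
                    stringsAsFactors = FALSE)

  if (!is.null(donor)) {
    donor_edited_sequence(amp, donor)   # validates non-recognition
    sig_h <- canon(edit_ops("insertion", cut, cut, donor$insert_sequence))
    tau_h <- .CLASS_TAU[["HDR"]]
    if (!is.null(tau_overrides) && sig_h %in% names(tau_overrides))
      tau_h <- tau_overrides[[sig_h]]
    a_h <- .KINETIC_RHO[["HDR"]] * tau_h
    mu_h <- (1 - .KINETIC_RHO[["HDR"]]) * tau_h / log(2)
    hshare <- function(lamH) {
      oc <- race_occupancy(c(out$activation, a_h), c(out$rate, lamH),
                           config$calib_time)
      oc$p[length(oc$p)] / sum(oc$p)
    }
    hi <- 1
    while (hshare(hi) < config$hdr_propensity && hi < 1e4) hi <- hi * 2
    lam_h <- uniroot(function(x) hshare(x) - config$hdr_propensity,
                     c(1e-8, hi), tol = 1e-10)$root
    out <- rbind(out, data.frame(
      signature = sig_h, repair_class = "HDR", kinetic_class = "HDR",
      tau = tau_h, activation = a_h, mu = mu_h, rate = lam_h,
      target_share = config$hdr_propensity, stringsAsFactors = FALSE))
  }
  if (nrow(out) == 0L) stop("no candidate outcomes for this amplicon")
  E <- config$editable_fraction
  if (is.null(E)) E <- runif(1L, 0.2, 0.6)
  structure(list(amplicon_id = amp$id, outcomes = out,
                 editable_fraction = E, donor = donor,
                 cell_profile = config$cell_profile),
            class = "outcome_model")
}

#' @export
print.outcome_model <- function(x, ...) {
  cat("<outcome_model> ", x$amplicon_id, ": ", nrow(x$outcomes),
      " outcomes (", paste(unique(x$outcomes$kinetic_class), collapse = ", "),
      "), editable fraction ", sprintf("%.2f", x$editable_fraction),
      "\n", sep = "")
  invisible(x)
}

#' Model-implied allele frequencies at given times
#'
#' The exact (infinite-depth) per-outcome frequencies implied by the race:
#' `editable_fraction * P(outcome wins and completes by t)`.
#'
#' @param model an [build_outcome_model()] result.
#' @param times numeric vector of hours.
#' @return matrix `[outcome, time]` of absolute frequencies.
#' @export
model_implied_frequencies <- function(model, times) {
  out <- vapply(times, function(t) {
    race_occupancy(model$outcomes$activation, model$outcomes$rate, t)$p *
      model$editable_fraction
  }, numeric(nrow(model$outcomes)))
  out <- matrix(out, nrow = nrow(model$outcomes),
                dimnames = list(model$outcomes$signature, times))
  out
}

#' Monte Carlo simulation of one locus
#'
#' Simulates `depth` cells; each editable cell (probability
#' `editable_fraction`) draws a completion time per outcome (activation
#' delay + exponential with the outcome's rate) and commits to the earliest.
#' A cell observed at time t carries its winning allele iff the winner
#' completed by t. The same cohort is observed at every timepoint.
#'
#' @param model an `outcome_model`.
#' @param config a [sim_config()].
#' @param seed optional seed (`NULL` = current RNG state).
#' @return list with `truth` (per-timepoint data.frame: `signature`,
#'   `repair_class`, `kinetic_class`, `true_freq`), `unedited` (per-timepoint
#'   unedited fraction) and `timepoints`.
#' @export
simulate_locus <- function(model, config = sim_config(), seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  N <- config$depth
  K <- nrow(model$outcomes)
  tp <- config$timepoints
  if (N == 0L) {
    truth <- lapply(tp, function(t)
      data.frame(signature = character(), repair_class = character(),
                 kinetic_class = character(), true_freq = numeric()))
    names(truth) <- as.character(tp)
    return(list(truth = truth, unedited = setNames(rep(1, length(tp)),
                                                   as.character(tp)),
                timepoints = tp))
  }
  editable <- runif(N) < model$editable_fraction
  ne <- sum(editable)
  winner <- integer(N); wtime <- rep(Inf, N)
  if (ne > 0L && K > 0L) {
    tt <- matrix(rexp(ne * K, rate = 1), nrow = K) / model$outcomes$rate +
      model$outcomes$activation
    winner_e <- max.col(-t(tt), ties.method = "first")
    wtime_e <- tt[cbind(winner_e, seq_len(ne))]
    winner[editable] <- winner_e
    wtime[editable] <- wtime_e
  }
  truth <- lapply(tp, function(t) {
    done <- winner > 0L & wtime <= t
    cnt <- tabulate(winner[done], nbins = K)
    data.frame(signature = model$outcomes$signature,
               repair_class = model$outcomes$repair_class,
               kinetic_class = model$outcomes$kinetic_class,
               true_freq = cnt / N, stringsAsFactors = FALSE)
  })
  names(truth) <- as.character(tp)
  unedited <- vapply(truth, function(d) 1 - sum(d$true_freq), numeric(1L))
  list(truth = truth, unedited = unedited, timepoints = tp)
}

# sprinkle substitution errors over reads (vectorised over the erroneous
# subset; R RNG only)
.mutate_reads <- function(seqs, error_rate) {
  if (error_rate <= 0) return(seqs)
  L <- nchar(seqs)
  nerr <- rbinom(length(seqs), L, error_rate)
  idx <- which(nerr > 0L)
  for (i in idx) {
    pos <- sample.int(L[i], nerr[i])
    for (p in pos) {
      old <- substr(seqs[i], p, p)
      substr(seqs[i], p, p) <- sample(setdiff(.BASES, old), 1L)
    }
  }
  seqs
}

#' Generate paired-end reads from an allele frequency table
#'
#' Builds each allele's fragment (barcode + edited amplicon sequence),
#' samples `depth` reads from the table's frequencies (remainder unedited),
#' emits `read_length`-bp paired reads with per-base substitution errors at
#' the configured rate and constant phred quality, and returns the ground
#' truth alongside.
#'
#' @param amp the [amplicon()].
#' @param freq_table data.frame with `signature` and `true_freq` (one
#'   timepoint of [simulate_locus()] truth).
#' @param config a [sim_config()].
#' @param seed optional seed.
#' @return list with `r1`, `r2`, `q1`, `q2` (character vectors) and `truth`
#'   (the sampled read counts per allele).
#' @export
reads_from_frequencies <- function(amp, freq_table, config = sim_config(),
                                   seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  stopifnot(sum(freq_table$true_freq) <= 1 + 1e-9)
  N <- config$depth
  rl <- config$read_length
  frags <- vapply(freq_table$signature, function(sg)
    paste0(config$barcode, apply_allele(amp, sg)), character(1L))
  frag_un <- paste0(config$barcode, amp$reference_sequence)
  if (any(nchar(c(frags, frag_un)) < rl))
    stop("fragment shorter than the read length; increase the amplicon")
  probs <- c(freq_table$true_freq, 1 - sum(freq_table$true_freq))
  idx <- sample.int(length(probs), N, replace = TRUE, prob = probs)
  allf <- c(frags, frag_un)
  fr <- allf[idx]
  L <- nchar(fr)
  r1 <- substr(fr, 1L, rl)
  r2 <- revcomp(substr(fr, L - rl + 1L, L))
  r1 <- .mutate_reads(r1, config$error_rate)
  r2 <- .mutate_reads(r2, config$error_rate)
  q <- strrep("I", rl)
  truth <- data.frame(signature = c(freq_table$signature, ""),
                      reads = tabulate(idx, nbins = length(probs)),
                      stringsAsFactors = FALSE)
  list(r1 = r1, r2 = r2, q1 = rep(q, N), q2 = rep(q, N), truth = truth)
}

#' Simulate one locus and run the full pipeline on its reads
#'
#' Convenience driver used by the acceptance suite: simulates the race,
#' generates paired reads per timepoint, merges, demultiplexes, calls
#' alleles and classifies them.
#'
#' @param amp the [amplicon()].
#' @param model an `outcome_model` (built with the same donor).
#' @param config a [sim_config()].
#' @param seed integer seed driving the whole run.
#' @param min_count,min_freq caller filters (see [call_sample()]).
#' @return list with `samples` (classified `sample_table` per timepoint),
#'   `sim` (the [simulate_locus()] truth) and `model`.
#' @export
run_locus_pipeline <- function(amp, model, config = sim_config(), seed = 1L,
                               min_count = 2L, min_freq = 5e-4) {
  set.seed(seed)
  sim <- simulate_locus(model, config)
  bt <- barcode_table("s1", config$barcode)
  condition <- if (is.null(model$donor)) "donor_absent" else "donor_present"
  samples <- lapply(seq_along(config$timepoints), function(k) {
    tp <- config$timepoints[k]
    rd <- reads_from_frequencies(amp, sim$truth[[k]], config)
    key <- paste0(rd$r1, "\r", rd$r2)
    tab <- table(key)
    ukey <- names(tab)
    parts <- strsplit(ukey, "\r", fixed = TRUE)
    u1 <- vapply(parts, `[`, character(1L), 1L)
    u2 <- vapply(parts, `[`, character(1L), 2L)
    mg <- merge_pairs(u1, u2, strrep("I", nchar(u1)), strrep("I", nchar(u2)))
    okm <- mg$ok
    counts <- as.integer(tab)
    dm <- demultiplex(mg$seq[okm], bt)
    keep <- !is.na(dm$assignment)
    reads <- rep(substr(mg$seq[okm][keep],
                        nchar(config$barcode) + 1L,
                        nchar(mg$seq[okm][keep])),
                 counts[okm][keep])
    st <- call_sample(reads, amp, min_count = min_count, min_freq = min_freq,
                      condition = condition, timepoint_h = tp)
    st$n_unmerged <- sum(counts[!okm])
    st$n_unassigned <- sum(counts[okm][!keep])
    classify_sample(st, amp, donor = model$donor)
  })
  names(samples) <- as.character(config$timepoints)
  list(samples = samples, sim = sim, model = model)
}

#' Packaged single-locus kinetics fixture
#'
#' A worked-example locus emulating a time-course experiment in iPSCs where
#' a +1 duplication (+T NHEJ) and a strong 4-nt microhomology deletion (-4
#' MMEJ) dominate: the fixture's generating T50s are 5 h for the +1 allele
#' and 16 h for the -4 MMEJ allele, with target shares 0.35 and 0.25 of
#' edited events.
#'
#' @param seed integer seed.
#' @param config optional [sim_config()] override (profile forced to iPSC).
#' @return list with `amplicon`, `model`, `config`, and the
#'   [simulate_locus()] output under `sim`.
#' @export
fixture_bcl11a_fig3 <- function(seed = 1L, config = NULL) {
  if (is.null(config)) config <- sim_config(seed = seed)
  config$cell_profile <- "iPSC"
  set.seed(seed)
  amp <- random_amplicon(length = 240L, minus4 = "T",
                         planted_mh = list(c(4L, 4L)), id = "bcl11a_like")
  cut <- amp$cut_site
  sig_dup <- ops_to_signature(.left_align(amp$reference_sequence,
                                          edit_ops("insertion", cut, cut, "T")))
  sig_mh <- ops_to_signature(.left_align(amp$reference_sequence,
                                         edit_ops("deletion", cut - 4L, cut)))
  model <- build_outcome_model(
    amp, donor = NULL, config = config,
    tau_overrides = setNames(c(5, 16), c(sig_dup, sig_mh)),
    share_overrides = setNames(c(0.35, 0.25), c(sig_dup, sig_mh)))
  sim <- simulate_locus(model, config)
  list(amplicon = amp, model = model, config = config, sim = sim,
       plus1_signature = sig_dup, mmej4_signature = sig_mh)
}
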