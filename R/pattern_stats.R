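# Dispersion, competition and concordance statistics over classified allele
# tables. The Gini coefficient uses the plain relative-mean-absolute-
# difference definition on the top-n pattern percentages, zero-padded to n.

#' Gini coefficient of the top-n editing patterns
#'
#' `G = sum_ij |x_i - x_j| / (2 n^2 xbar)` over the top `n` pattern
#' frequencies of a donor-absent sample (padded with zeros when fewer than
#' `n` edited alleles exist). High values flag one or two predominant repair
#' events; the maximum for n patterns is `(n-1)/n`.
#'
#' @param sample a `sample_table` (donor-absent by definition of the
#'   statistic; classified HDR alleles trigger an error).
#' @param n number of top patterns (default 5).
#' @return Gini coefficient in \[0, (n-1)/n\].
#' @export
gini_top_n <- function(sample, n = 5L) {
  stopifnot(inherits(sample, "sample_table"))
  if (!is.null(sample$alleles$repair_class) &&
      any(sample$alleles$repair_class == "HDR"))
    stop("the pattern-dispersion Gini is defined on donor-absent samples")
  if (identical(sample$condition, "donor_present"))
    stop("the pattern-dispersion Gini is defined on donor-absent samples")
  top <- top_n_patterns(sample, n)
  if (nrow(top) == 0L) stop("no edited alleles: Gini undefined")
  x <- c(top$frequency, rep(0, n - nrow(top)))
  gini_coefficient(x)
}

#' @rdname gini_top_n
#' @param x numeric vector of non-negative shares.
#' @export
gini_coefficient <- function(x) {
  if (any(x < 0)) stop("negative shares")
  if (mean(x) == 0) stop("all-zero shares: Gini undefined")
  n <- length(x)
  sum(abs(outer(x, x, "-"))) / (2 * n^2 * mean(x))
}

#' Relative frequencies: per-allele share of edited events
#'
#' Divides each allele's frequency by the total edited frequency, so shares
#' sum to 1 over edited alleles.
#'
#' @param sample a `sample_table` with at least one edited allele.
#' @return the allele data.frame with an added `share` column.
#' @export
relative_frequencies <- function(sample) {
  stopifnot(inherits(sample, "sample_table"))
  eff <- editing_efficiency(sample)
  if (eff <= 0) stop("no edited alleles: relative frequencies undefined")
  al <- sample$alleles
  al$share <- al$frequency / eff
  al
}

#' Per-bin shares of edited events under a category scheme
#' @keywords internal
.bin_shares <- function(sample, scheme = "competition_bins") {
  al <- relative_frequencies(sample)
  catcol <- paste0("cat_", scheme)
  if (!catcol %in% names(al))
    stop("sample must be classified (classify_sample) first")
  agg <- tapply(al$share, al[[catcol]], sum)
  setNames(as.numeric(agg), names(agg))
}

#' Donor competition: per-bin relative change in pattern shares
#'
#' For a matched pair of samples from the same amplicon (donor absent vs
#' donor present) computes, per category bin, the relative change
#' `delta = (share_donor - share_no_donor) / share_no_donor` of the bin's
#' share of edited events. Bins absent from the donor-absent sample have an
#' undefined delta and are omitted. HDR reads count as edited events in the
#' donor-present denominator (so every indel bin's share already reflects
#' the donor competition), but the HDR bin itself has no baseline and is
#' not assigned a delta.
#'
#' @param sample_absent,sample_present classified `sample_table`s from the
#'   same amplicon.
#' @param scheme binning scheme (default `"competition_bins"`).
#' @return data.frame with `bin`, `share_no_donor`, `share_donor`, `delta`.
#' @export
competition_delta <- function(sample_absent, sample_present,
                              scheme = "competition_bins") {
  if (!identical(sample_absent$amplicon_id, sample_present$amplicon_id))
    stop("samples must come from the same amplicon")
  s0 <- .bin_shares(sample_absent, scheme)
  s1 <- .bin_shares(sample_present, scheme)
  bins <- names(s0)[names(s0) != "HDR" & s0 > 0]
  data.frame(bin = bins,
             share_no_donor = as.numeric(s0[bins]),
             share_donor = as.numeric(ifelse(is.na(s1[bins]), 0, s1[bins])),
             delta = as.numeric((ifelse(is.na(s1[bins]), 0, s1[bins]) -
                                   s0[bins]) / s0[bins]),
             row.names = NULL, stringsAsFactors = FALSE)
}

#' Paired t statistic for donor competition across loci
#'
#' For two or more matched locus pairs, runs a standard paired two-sided
#' t-test per bin on the shares (donor present vs absent).
#'
#' @param pairs list of lists with elements `absent` and `present`
#'   (classified `sample_table`s).
#' @param scheme binning scheme.
#' @return data.frame with `bin`, `mean_delta`, `t`, `df`, `p`, `n`.
#' @export
competition_test <- function(pairs, scheme = "competition_bins") {
  stopifnot(length(pairs) >= 2L)
  tabs <- lapply(pairs, function(p)
    competition_delta(p$absent, p$present, scheme))
  bins <- unique(unlist(lapply(tabs, function(d) d$bin)))
  rows <- lapply(bins, function(b) {
    d0 <- vapply(tabs, function(d) {
      i <- match(b, d$bin); if (is.na(i)) NA_real_ else d$share_no_donor[i]
    }, numeric(1L))
    d1 <- vapply(tabs, function(d) {
      i <- match(b, d$bin); if (is.na(i)) NA_real_ else d$share_donor[i]
    }, numeric(1L))
    keep <- !is.na(d0) & !is.na(d1)
    x <- d1[keep] - d0[keep]
    n <- length(x)
    if (n < 2L || sd(x) == 0) {
      tt <- NA_real_; p <- NA_real_
    } else {
      tt <- mean(x) / (sd(x) / sqrt(n))
      p <- 2 * pt(-abs(tt), df = n - 1L)
    }
    data.frame(bin = b, mean_delta = mean((d1[keep] - d0[keep]) / d0[keep]),
               t = tt, df = n - 1L, p = p, n = n,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

#' Pearson correlation, squared, with p-value
#'
#' @param xs,ys equal-length numeric vectors (n >= 3, both non-constant).
#' @return list with `r2` and two-sided `p` (t transform of r).
#' @export
pearson_r2 <- function(xs, ys) {
  stopifnot(length(xs) == length(ys))
  n <- length(xs)
  if (n < 3L) stop("need at least 3 points")
  if (sd(xs) == 0 || sd(ys) == 0) stop("constant vector: correlation undefined")
  r <- sum((xs - mean(xs)) * (ys - mean(ys))) /
    ((n - 1) * sd(xs) * sd(ys))
  r <- max(-1, min(1, r))
  tt <- r * sqrt((n - 2) / max(1 - r^2, .Machine$double.eps))
  list(r2 = r^2, p = 2 * pt(-abs(tt), df = n - 2L))
}

#' Concordance with external editing-outcome predictions
#'
#' Matches a predicted pattern-frequency table (two columns: `signature`,
#' `frequency`, in the generic import dialect) against observed shares and
#' reports a squared Pearson correlation per prediction class: `NHEJ_plus1`
#' (1-nt insertions) and `MMEJ_dels` (deletions of >= 2 nt).
#'
#' @param observed a classified `sample_table`.
#' @param predicted data.frame with columns `signature` and `frequency`
#'   (e.g. from [read_prediction_csv()]).
#' @param classes prediction classes to score.
#' @return data.frame with `class`, `r2`, `p`, `n_matched`,
#'   `unmatched_predicted_mass`.
#' @export
compare_external_predictions <- function(observed, predicted,
                                         classes = c("NHEJ_plus1",
                                                     "MMEJ_dels")) {
  al <- relative_frequencies(observed)
  if (!all(c("signature", "frequency") %in% names(predicted)))
    stop("predicted table needs columns: signature, frequency")
  common <- intersect(al$signature, predicted$signature)
  if (length(common) == 0L) stop("no common patterns between observed and ",
                                 "predicted tables")
  unmatched <- sum(predicted$frequency[!predicted$signature %in% common])
  kind_of <- function(sig) {
    o <- signature_to_ops(sig)
    if (nrow(o) == 1L && o$kind == "insertion" && nchar(o$ins_seq) == 1L)
      return("NHEJ_plus1")
    if (nrow(o) == 1L && o$kind == "deletion" && o$ref_end - o$ref_start >= 2L)
      return("MMEJ_dels")
    "other"
  }
  kinds <- vapply(common, kind_of, character(1L))
  rows <- lapply(classes, function(cl) {
    sigs <- common[kinds == cl]
    if (length(sigs) < 3L)
      stop("fewer than 3 matched patterns for class ", cl)
    obs <- al$share[match(sigs, al$signature)]
    prd <- predicted$frequency[match(sigs, predicted$signature)]
    pr <- pearson_r2(obs, prd)
    data.frame(class = cl, r2 = pr$r2, p = pr$p, n_matched = length(sigs),
               unmatched_predicted_mass = unmatched,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

#' Import a prediction CSV (inDelphi/FORECasT-style exports)
#'
#' The generic dialect is a two-column CSV `signature,frequency`. The
#' inDelphi-like dialect (`category,position,length,frequency` with
#' categories "ins"/"del") and the FORECasT-like dialect
#' (`pattern,frequency` with patterns such as `D7_L110` or `I1_T`) are
#' rewritten into signatures relative to the supplied amplicon.
#'
#' @param path CSV path.
#' @param amp the [amplicon()] the predictions refer to (needed for the
#'   dialects that encode positions relative to the cut site).
#' @param dialect `"generic"`, `"indelphi"` or `"forecast"`.
#' @return data.frame with `signature`, `frequency`.
#' @export
read_prediction_csv <- function(path, amp = NULL,
                                dialect = c("generic", "indelphi",
                                            "forecast")) {
  dialect <- match.arg(dialect)
  tab <- read.csv(path, stringsAsFactors = FALSE)
  if (dialect == "generic") {
    if (!all(c("signature", "frequency") %in% names(tab)))
      stop("generic prediction CSV needs columns signature, frequency")
    return(tab[, c("signature", "frequency")])
  }
  if (is.null(amp)) stop("amplicon required to rewrite ", dialect, " dialect")
  cut <- amp$cut_site
  if (dialect == "indelphi") {
    need <- c("category", "position", "length", "frequency")
    if (!all(need %in% names(tab)))
      stop("indelphi-style CSV needs columns: ", paste(need, collapse = ", "))
    sig <- vapply(seq_len(nrow(tab)), function(i) {
      if (tab$category[i] == "ins")
        paste0("I:", cut, ":", tab$inserted[i])
      else {
        s <- cut + tab$position[i]  # position: deletion start rel. to cut
        paste0("D:", s, "-", s + tab$length[i])
      }
    }, character(1L))
  } else {
    if (!all(c("pattern", "frequency") %in% names(tab)))
      stop("forecast-style CSV needs columns: pattern, frequency")
    sig <- vapply(tab$pattern, function(p) {
      if (grepl("^I", p)) {
        f <- strsplit(sub("^I", "", p), "_", fixed = TRUE)[[1L]]
        paste0("I:", cut, ":", f[2L])
      } else {
        f <- strsplit(sub("^D", "", p), "_L", fixed = TRUE)[[1L]]
        s <- as.integer(f[2L])
        paste0("D:", s, "-", s + as.integer(f[1L]))
      }
    }, character(1L))
  }
  # canonicalise via left alignment so signatures match the caller's
  sig <- vapply(sig, function(s) {
    o <- tryCatch(signature_to_ops(s), error = function(e) NULL)
    if (is.null(o)) return(NA_character_)
    ops_to_signature(.left_align(amp$reference_sequence, o))
  }, character(1L))
  out <- data.frame(signature = sig, frequency = tab$frequency,
                    stringsAsFactors = FALSE)
  out[!is.na(out$signature), , drop = FALSE]
}

# left-align an ops table against a reference (R-side mirror of the
# alignment kernel's normalisation; used when importing external tables)
.left_align <- function(reference, ops) {
  s <- strsplit(toupper(reference), "")[[1L]]
  for (i in seq_len(nrow(ops))) {
    lim <- if (i == 1L) 0L else ops$ref_end[i - 1L]
    if (ops$kind[i] == "deletion") {
      a <- ops$ref_start[i]; b <- ops$ref_end[i]
      while (a > lim && s[a] == s[b]) { a <- a - 1L; b <- b - 1L }
      ops$ref_start[i] <- a; ops$ref_end[i] <- b
    } else if (ops$kind[i] == "insertion") {
      p <- ops$ref_start[i]; t <- ops$ins_seq[i]; L <- nchar(t)
      while (p > lim && L > 0L && s[p] == substr(t, L, L)) {
        t <- paste0(substr(t, L, L), substr(t, 1L, L - 1L))
        p <- p - 1L
      }
      ops$ref_start[i] <- ops$ref_end[i] <- p
      ops$ins_seq[i] <- t
    }
  }
  ops
}
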