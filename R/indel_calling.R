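# Indel calling: global affine-gap alignment of merged reads against the
# amplicon reference, extraction of left-normalised edit operations, and
# aggregation into an allele table with artifact filters. Substitutions are
# never treated as edits: RNP editing produces indels, and near-cut
# substitutions are overwhelmingly sequencing/PCR error.

.default_align_opts <- function() {
  list(match = 2, mismatch = -4, gap_open = -10, gap_ext = -1,
       band_pad = 24L, min_identity = 0.6,
       min_len_frac = 0.4, max_len_frac = 1.6)
}

#' Align a read to the amplicon reference
#'
#' Global (Needleman-Wunsch/Gotoh) alignment with affine gap penalties
#' (defaults: match +2, mismatch -4, gap open -10, gap extend -1), computed
#' in a diagonal band wide enough for the indel sizes the assay produces.
#' Tie-breaking is deterministic and indels are reported left-aligned within
#' their repeat context.
#'
#' @param read merged read sequence.
#' @param amp the [amplicon()].
#' @param opts scoring options, see `.default_align_opts` defaults in the
#'   argument list of [call_sample()].
#' @return list with `ok`, `score`, `identity` (matches / alignment columns),
#'   `ops` (an [edit_ops()] table of indels; substitutions are counted in
#'   `n_mismatch` but not returned as ops).
#' @export
align_to_reference <- function(read, amp, opts = list()) {
  o <- modifyList(.default_align_opts(), opts)
  ref <- amp$reference_sequence
  rl <- nchar(read)
  if (rl < o$min_len_frac * nchar(ref) || rl > o$max_len_frac * nchar(ref))
    return(list(ok = FALSE, reason = "length"))
  band <- o$band_pad + abs(nchar(ref) - rl)
  res <- align_one_cpp(toupper(read), ref, o$match, o$mismatch, o$gap_open,
                       o$gap_ext, as.integer(band))
  if (!isTRUE(res$ok)) return(list(ok = FALSE, reason = "band"))
  identity <- res$n_match / res$n_cols
  ops <- extract_operations(res)
  list(ok = identity >= o$min_identity, reason = "identity", score = res$score,
       identity = identity, n_mismatch = res$n_mismatch, ops = ops)
}

#' Extract edit operations from an alignment
#'
#' Adjacent same-kind columns are coalesced into single ops and indels are
#' left-aligned within their homopolymer/repeat context (already done by the
#' alignment kernel). Substitution runs are recorded (with their replacement
#' bases, so `apply_allele()` round-trips the read exactly) but never count
#' as edits downstream.
#'
#' @param aln the raw alignment structure from the kernel.
#' @return an [edit_ops()] data frame.
#' @export
extract_operations <- function(aln) {
  if (length(aln$kind) == 0L) return(edit_ops())
  edit_ops(kind = c("insertion", "deletion", "substitution")[aln$kind],
           ref_start = aln$ref_start, ref_end = aln$ref_end,
           ins_seq = as.character(aln$ins_seq))
}

#' Decide whether a read is edited
#'
#' A read counts as edited iff at least one indel op overlaps the window
#' `[cut_site - window, cut_site + window]`; indels entirely outside the
#' window are discarded as PCR/sequencing artifacts, and substitution-only
#' reads are unedited.
#'
#' @param ops [edit_ops()] from [extract_operations()].
#' @param amp the [amplicon()].
#' @param window half-width of the cut-proximal window in nt (default 50;
#'   the assay's MMEJ deletions are < 50 nt).
#' @return list with `edited` (logical) and `ops` (the retained window ops).
#' @export
call_allele <- function(ops, amp, window = 50L) {
  ops <- ops[ops$kind != "substitution", , drop = FALSE]
  if (nrow(ops) == 0L) return(list(edited = FALSE, ops = edit_ops()))
  cut <- amp$cut_site
  lo <- cut - window; hi <- cut + window
  # an op overlaps the window if its span [ref_start, ref_end] (insertion:
  # point) intersects [lo, hi]
  keep <- ops$ref_end >= lo & ops$ref_start <= hi
  ops <- ops[keep, , drop = FALSE]
  list(edited = nrow(ops) > 0L, ops = ops)
}

#' Call every read of a sample and aggregate alleles
#'
#' Unique read sequences are aligned once (reads equal in length to the
#' reference and nearly identical to it take a Hamming shortcut and are
#' unedited by construction, since substitutions are not edits). Identical
#' indel-op lists are collapsed into alleles; alleles failing `min_count` or
#' `min_freq` are removed from the edited set (their reads stay in
#' `total_reads` but do not count as edited). Frequencies are
#' `count / total_reads`.
#'
#' @param seqs merged, demultiplexed read sequences (barcode trimmed).
#' @param amp the [amplicon()].
#' @param window cut-proximal window, see [call_allele()].
#' @param min_count,min_freq allele artifact filters (defaults 2 reads and
#'   0.05\%).
#' @param align_opts list of scoring overrides for [align_to_reference()].
#' @param amplicon_id,condition,timepoint_h sample metadata carried through.
#' @return a `sample_table`: list with `amplicon_id`, `condition`,
#'   `timepoint_h`, `total_reads`, `n_unalignable`, `n_unedited`, and
#'   `alleles` (data.frame: `signature`, `count`, `frequency`).
#' @export
call_sample <- function(seqs, amp, window = 50L, min_count = 2L,
                        min_freq = 5e-4, align_opts = list(),
                        condition = "donor_absent", timepoint_h = 48) {
  if (length(seqs) == 0L) stop("zero reads in sample")
  o <- modifyList(.default_align_opts(), align_opts)
  ref <- amp$reference_sequence
  tab <- table(seqs)
  useq <- names(tab)
  ucnt <- as.integer(tab)
  # Hamming shortcut: a same-length read with <= 3 mismatches is provably
  # optimally aligned without gaps under the default scoring (an ins+del
  # pair costs 22 and can recover at most 6 per realigned mismatch), hence
  # no indel ops -> unedited. Anything else goes through the full DP.
  hd <- hamming_to_ref_cpp(useq, ref)
  shortcut <- hd >= 0L & hd <= 3L
  sig <- character(length(useq))
  ok <- logical(length(useq))
  sig[shortcut] <- ""
  ok[shortcut] <- TRUE
  todo <- which(!shortcut)
  if (length(todo) > 0L) {
    res <- align_signatures_cpp(useq[todo], ref, o$match, o$mismatch,
                                o$gap_open, o$gap_ext, o$band_pad)
    rl <- nchar(useq[todo])
    lenok <- rl >= o$min_len_frac * nchar(ref) & rl <= o$max_len_frac * nchar(ref)
    ok[todo] <- res$ok & res$identity >= o$min_identity & lenok
    sig[todo] <- ifelse(ok[todo], as.character(res$signature), NA_character_)
  }
  # window filter on each unique signature
  usig <- unique(sig[ok & nzchar(sig)])
  win_sig <- vapply(usig, function(s) {
    cs <- call_allele(signature_to_ops(s), amp, window)
    if (cs$edited) ops_to_signature(cs$ops) else ""
  }, character(1L))
  map <- setNames(win_sig, usig)
  sig[ok & nzchar(sig)] <- unname(map[sig[ok & nzchar(sig)]])

  total <- sum(ucnt)
  n_unalign <- sum(ucnt[!ok])
  edited <- ok & nzchar(sig)
  n_unedited <- sum(ucnt[ok & !nzchar(sig)])
  al <- if (any(edited)) {
    agg <- tapply(ucnt[edited], sig[edited], sum)
    data.frame(signature = names(agg), count = as.integer(agg),
               stringsAsFactors = FALSE, row.names = NULL)
  } else data.frame(signature = character(), count = integer())
  al$frequency <- al$count / total
  pass <- al$count >= min_count & al$frequency >= min_freq
  n_unedited <- n_unedited + sum(al$count[!pass])  # filtered reads: not edited
  al <- al[pass, , drop = FALSE]
  al <- al[order(-al$count, al$signature), , drop = FALSE]
  rownames(al) <- NULL
  structure(list(amplicon_id = amp$id, condition = condition,
                 timepoint_h = timepoint_h, total_reads = total,
                 n_unalignable = n_unalign, n_unedited = n_unedited,
                 alleles = al),
            class = "sample_table")
}

#' Assemble a sample table from a pre-counted allele list
#'
#' Used by simulators and file import; applies the same filters as
#' [call_sample()].
#'
#' @param signatures,counts parallel allele description.
#' @param total_reads total sample reads (>= sum of counts).
#' @param amplicon_id,condition,timepoint_h metadata.
#' @param min_count,min_freq artifact filters (set to 0 to disable).
#' @return a `sample_table`.
#' @export
sample_table <- function(signatures, counts, total_reads,
                         amplicon_id = "amp", condition = "donor_absent",
                         timepoint_h = 48, min_count = 0L, min_freq = 0) {
  stopifnot(length(signatures) == length(counts), total_reads >= sum(counts))
  al <- data.frame(signature = as.character(signatures),
                   count = as.integer(counts), stringsAsFactors = FALSE)
  al <- al[nzchar(al$signature), , drop = FALSE]
  al$frequency <- al$count / total_reads
  keep <- al$count >= min_count & al$frequency >= min_freq
  al <- al[keep, , drop = FALSE]
  al <- al[order(-al$count, al$signature), , drop = FALSE]
  rownames(al) <- NULL
  structure(list(amplicon_id = amplicon_id, condition = condition,
                 timepoint_h = timepoint_h, total_reads = total_reads,
                 n_unalignable = 0L,
                 n_unedited = total_reads - sum(al$count),
                 alleles = al),
            class = "sample_table")
}

#' @export
print.sample_table <- function(x, ...) {
  cat("<sample_table> ", x$amplicon_id, " [", x$condition, ", t=",
      x$timepoint_h, "h]: ", x$total_reads, " reads, ",
      nrow(x$alleles), " alleles, efficiency ",
      sprintf("%.3f", editing_efficiency(x)), "\n", sep = "")
  invisible(x)
}

#' Editing efficiency of a sample
#'
#' The summed frequency of all edited alleles (HDR included when present).
#' @param sample a `sample_table`.
#' @return fraction in \[0, 1\].
#' @export
editing_efficiency <- function(sample) {
  stopifnot(inherits(sample, "sample_table"))
  sum(sample$alleles$frequency)
}

#' Top-n editing patterns
#'
#' Alleles ranked by frequency (descending); ties broken deterministically by
#' shorter total op span, then lexicographic signature.
#'
#' @param sample a `sample_table`.
#' @param n how many patterns (default 10; fewer if the sample has fewer).
#' @return the ranked allele data.frame.
#' @export
top_n_patterns <- function(sample, n = 10L) {
  stopifnot(inherits(sample, "sample_table"))
  al <- sample$alleles
  if (nrow(al) == 0L) return(al)
  span <- vapply(al$signature, function(s) {
    o <- signature_to_ops(s)
    sum(o$ref_end - o$ref_start) + sum(nchar(o$ins_seq))
  }, numeric(1L))
  ord <- order(-al$frequency, span, al$signature)
  out <- al[ord, , drop = FALSE][seq_len(min(n, nrow(al))), , drop = FALSE]
  rownames(out) <- NULL
  out
}
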