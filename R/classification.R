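# Repair-pathway classification. MMEJ is recognised by junction
# microhomology: a deletion whose boundaries carry repeated sequence can be
# placed at several equivalent positions, and the number of equivalent
# placements minus one is the microhomology length. Classification operates
# on the full placement-equivalence class, never on the (arbitrary)
# left-aligned placement the caller reports.

#' Microhomology of a deletion
#'
#' For the deletion of reference interval \[del_start, del_end) the
#' microhomology (MH) length is the number of distinct equal-length deletion
#' intervals producing the identical edited string, minus one, capped at
#' `cap`. It is computed by flank-identity extension: bases immediately left
#' of the deletion matching bases immediately left of `del_end` extend the
#' placement leftwards, and symmetrically to the right.
#'
#' @param reference DNA string.
#' @param del_start,del_end 0-based half-open deletion interval.
#' @param cap maximum reported MH length (default 16, the upper end of the
#'   2-16 nt junction homologies scored as MMEJ).
#' @return list with `length` (capped), `sequence` (the repeated junction
#'   sequence, uncapped flank run), `placements` (number of equivalent
#'   intervals, uncapped) and `range` (0-based start positions of all
#'   equivalent placements).
#' @export
microhomology <- function(reference, del_start, del_end, cap = 16L) {
  reference <- toupper(reference)
  n <- nchar(reference)
  del_start <- as.integer(del_start); del_end <- as.integer(del_end)
  if (del_start < 0L || del_end > n || del_start >= del_end)
    stop("invalid deletion interval")
  s <- strsplit(reference, "")[[1L]]
  # left extension: ref[s-1-i] == ref[e-1-i]
  L <- 0L
  while (del_start - 1L - L >= 0L &&
         s[del_start - L] == s[del_end - L]) L <- L + 1L
  # right extension: ref[s+i] == ref[e+i]
  R <- 0L
  while (del_end + R < n &&
         s[del_start + 1L + R] == s[del_end + 1L + R]) R <- R + 1L
  mh <- L + R
  seq <- if (mh > 0L)
    substr(reference, del_start - L + 1L, del_start - L + mh) else ""
  list(length = min(mh, as.integer(cap)), sequence = seq,
       placements = mh + 1L,
       range = seq.int(del_start - L, del_start + R))
}

#' Placement range of a 1-nt insertion
#'
#' An insertion of base `b` at inter-base position `p` is equivalent to
#' inserting at any position within the maximal run of `b` around `p`.
#' Returns all equivalent inter-base positions.
#' @keywords internal
.insertion_range <- function(reference, pos, base) {
  .ins_seq_range(reference, pos, base)
}

#' Detect a +1 duplication of the -4 nucleotide
#'
#' The signature NHEJ outcome of a staggered SpCas9 cut is a 1-nt insertion
#' duplicating the base immediately 5' of the cut (the -4 nucleotide before
#' the PAM). An allele qualifies when it consists of exactly one 1-nt
#' insertion whose placement range includes the cut site and whose base (in
#' protospacer orientation) equals [minus4_base()].
#'
#' @param ops [edit_ops()] (or signature) of the allele.
#' @param amp the [amplicon()].
#' @return the duplicated base (protospacer orientation) or `NA_character_`.
#' @export
is_plus1_duplication <- function(ops, amp) {
  if (is.character(ops) && !is.data.frame(ops)) ops <- signature_to_ops(ops)
  ops <- ops[ops$kind != "substitution", , drop = FALSE]
  if (nrow(ops) != 1L || ops$kind != "insertion" || nchar(ops$ins_seq) != 1L)
    return(NA_character_)
  rng <- .insertion_range(amp$reference_sequence, ops$ref_start, ops$ins_seq)
  if (!(amp$cut_site %in% rng)) return(NA_character_)
  base_ps <- if (amp$strand == "+") ops$ins_seq else .complement[[ops$ins_seq]]
  if (base_ps == minus4_base(amp)) base_ps else NA_character_
}

#' Classify an edited allele into a repair pathway
#'
#' Ordered rules:
#' \enumerate{
#'   \item HDR: the allele is a single insertion of exactly the donor insert
#'     whose placement range includes the cut site, with at least
#'     `flank_check` unedited reference bases on each side of the cut.
#'   \item MMEJ: a single deletion of length >= 2 whose junction
#'     microhomology is 2-16 nt.
#'   \item MMEJ (single-nucleotide rule): deletion of exactly one G (or C)
#'     where the two bases flanking the cut are G|G (or C|C) and the deleted
#'     base is one of them.
#'   \item NHEJ: every other edited allele (all other insertions, 1-nt A/T
#'     deletions, MH 0-1 deletions, complex multi-op alleles).
#' }
#'
#' 1-nt deletions in A|A or T|T context fall under the NHEJ catch-all; set
#' `drop_at_1nt = TRUE` in [classify_sample()] to exclude them from summaries
#' instead.
#'
#' @param ops [edit_ops()] or signature string of an edited allele.
#' @param amp the [amplicon()].
#' @param donor optional [donor_spec()].
#' @param flank_check exact-flank requirement for HDR calls (nt).
#' @return list with `repair_class` ("NHEJ", "MMEJ" or "HDR"), `subtype`
#'   (human-readable label), `mh_length` and `mh_sequence`.
#' @export
classify_allele <- function(ops, amp, donor = NULL, flank_check = 10L) {
  if (is.character(ops) && !is.data.frame(ops)) ops <- signature_to_ops(ops)
  ops <- ops[ops$kind != "substitution", , drop = FALSE]
  if (nrow(ops) == 0L) stop("classify_allele() requires an edited allele")
  ref <- amp$reference_sequence
  cut <- amp$cut_site

  # (1) HDR
  if (!is.null(donor)) {
    if (nrow(ops) == 1L && ops$kind == "insertion" &&
        ops$ins_seq == donor$insert_sequence) {
      rng <- .ins_seq_range(ref, ops$ref_start, ops$ins_seq)
      if (cut %in% rng &&
          ops$ref_start >= flank_check &&
          ops$ref_start + flank_check <= nchar(ref)) {
        return(list(repair_class = "HDR",
                    subtype = paste0("HDR +", nchar(donor$insert_sequence)),
                    mh_length = NA_integer_, mh_sequence = NA_character_))
      }
    }
  }

  if (nrow(ops) == 1L && ops$kind == "deletion") {
    dlen <- ops$ref_end - ops$ref_start
    mh <- microhomology(ref, ops$ref_start, ops$ref_end)
    # (2) MMEJ proper
    if (dlen >= 2L && mh$length >= 2L && mh$length <= 16L) {
      return(list(repair_class = "MMEJ",
                  subtype = sprintf("MH=%d del -%d", mh$length, dlen),
                  mh_length = mh$length, mh_sequence = mh$sequence))
    }
    # (3) single-nucleotide G|G / C|C rule: cut-adjacent repeated base
    if (dlen == 1L) {
      left <- substr(ref, cut, cut)          # base 5' of the cut
      right <- substr(ref, cut + 1L, cut + 1L)
      delbase <- substr(ref, ops$ref_start + 1L, ops$ref_start + 1L)
      if (left == right && left %in% c("G", "C") && delbase == left &&
          ops$ref_start %in% c(cut - 1L, cut)) {
        return(list(repair_class = "MMEJ",
                    subtype = sprintf("-1 %s|%s", left, right),
                    mh_length = 1L, mh_sequence = left))
      }
    }
  }

  # (4) NHEJ catch-all
  sub <- if (nrow(ops) == 1L && ops$kind == "insertion" &&
             nchar(ops$ins_seq) == 1L) {
    dup <- is_plus1_duplication(ops, amp)
    b <- if (amp$strand == "+") ops$ins_seq else .complement[[ops$ins_seq]]
    if (!is.na(dup)) paste0("+", b, " duplication") else paste0("+", b)
  } else if (nrow(ops) == 1L && ops$kind == "insertion") {
    paste0("+", nchar(ops$ins_seq))
  } else if (nrow(ops) == 1L && ops$kind == "deletion") {
    paste0("-", ops$ref_end - ops$ref_start)
  } else "complex"
  list(repair_class = "NHEJ", subtype = sub,
       mh_length = NA_integer_, mh_sequence = NA_character_)
}

# placement range of a multi-nt insertion (slid while the last inserted base
# matches the reference base to the left, rotating the insert)
.ins_seq_range <- function(reference, pos, seq) {
  s <- strsplit(toupper(reference), "")[[1L]]
  L <- nchar(seq)
  lo <- pos; t <- seq
  while (lo - 1L >= 0L && lo >= 1L && s[lo] == substr(t, L, L)) {
    t <- paste0(substr(t, L, L), substr(t, 1L, L - 1L))
    lo <- lo - 1L
  }
  hi <- pos; t <- seq
  while (hi + 1L <= length(s) && s[hi + 1L] == substr(t, 1L, 1L)) {
    t <- paste0(substr(t, 2L, L), substr(t, 1L, 1L))
    hi <- hi + 1L
  }
  seq.int(lo, hi)
}

#' Bin a classified allele into a reporting category
#'
#' Category schemes used by the summaries:
#' \describe{
#'   \item{seven_group}{+A/T, +C/G, -1, -2, -3 to -5, -6 to -9, -10 to -30.}
#'   \item{eleven_cat}{+A, +T, +G, +C, -1, -2, -3 to -5, -6 to -9,
#'     -10 to -23, -24 to -30, other.}
#'   \item{t50_bins}{insertions by base, -1, -2, then deletions merged into
#'     -3 to -5, -6 to -9 and >= -10.}
#'   \item{competition_bins}{+1, -1, -2 to -5, -6 to -9, -10 to -30, HDR.}
#' }
#' The net size of an allele is total inserted minus total deleted bases.
#' Alleles that fit no bin of a scheme return `"other"` (`NA` for
#' seven_group, which has no catch-all).
#'
#' @param repair_class the class from [classify_allele()].
#' @param ops [edit_ops()] or signature of the allele.
#' @param amp the [amplicon()] (for insertion base orientation).
#' @param scheme one of `"seven_group"`, `"eleven_cat"`, `"t50_bins"`,
#'   `"competition_bins"`.
#' @return a category label (character).
#' @export
categorize <- function(repair_class, ops, amp,
                       scheme = c("seven_group", "eleven_cat", "t50_bins",
                                  "competition_bins")) {
  scheme <- match.arg(scheme)
  if (is.character(ops) && !is.data.frame(ops)) ops <- signature_to_ops(ops)
  ops <- ops[ops$kind != "substitution", , drop = FALSE]
  if (repair_class == "HDR")
    return(if (scheme == "competition_bins") "HDR" else "other")
  ins_len <- sum(nchar(ops$ins_seq[ops$kind == "insertion"]))
  del_len <- sum((ops$ref_end - ops$ref_start)[ops$kind == "deletion"])
  net <- ins_len - del_len
  one_ins <- nrow(ops) == 1L && ops$kind == "insertion" &&
    nchar(ops$ins_seq) == 1L
  ins_base <- if (one_ins) {
    if (amp$strand == "+") ops$ins_seq else .complement[[ops$ins_seq]]
  } else NA_character_
  simple_del <- nrow(ops) == 1L && ops$kind == "deletion"
  d <- if (simple_del) del_len else NA_integer_

  if (scheme == "seven_group") {
    if (one_ins && ins_base %in% c("A", "T")) return("+A/T")
    if (one_ins && ins_base %in% c("C", "G")) return("+C/G")
    if (simple_del) {
      if (d == 1L) return("-1")
      if (d == 2L) return("-2")
      if (d <= 5L) return("-3 to -5")
      if (d <= 9L) return("-6 to -9")
      if (d <= 30L) return("-10 to -30")
    }
    return(NA_character_)
  }
  if (scheme == "eleven_cat") {
    if (one_ins) return(paste0("+", ins_base))
    if (simple_del) {
      if (d == 1L) return("-1")
      if (d == 2L) return("-2")
      if (d <= 5L) return("-3 to -5")
      if (d <= 9L) return("-6 to -9")
      if (d <= 23L) return("-10 to -23")
      if (d <= 30L) return("-24 to -30")
    }
    return("other")
  }
  if (scheme == "t50_bins") {
    if (one_ins) return(paste0("+", ins_base))
    if (simple_del) {
      if (d == 1L) return("-1")
      if (d == 2L) return("-2")
      if (d <= 5L) return("-3 to -5")
      if (d <= 9L) return("-6 to -9")
      return(">= -10")
    }
    return("other")
  }
  # competition_bins
  if (net == 1L && ins_len == 1L) return("+1")
  if (simple_del) {
    if (d == 1L) return("-1")
    if (d <= 5L) return("-2 to -5")
    if (d <= 9L) return("-6 to -9")
    if (d <= 30L) return("-10 to -30")
  }
  "other"
}

#' Classify and categorize every allele of a sample
#'
#' Adds `repair_class`, `subtype`, `mh_length` and one category column per
#' scheme to the allele table of a [call_sample()] result.
#'
#' @param sample a `sample_table`.
#' @param amp the [amplicon()].
#' @param donor optional [donor_spec()]; HDR is never called without it.
#' @param flank_check see [classify_allele()].
#' @param drop_at_1nt drop 1-nt deletions in A|A / T|T cut context from the
#'   edited set entirely (they are rare and were left unassigned in the
#'   scheme this package follows); default keeps them as NHEJ.
#' @return the sample with a classified allele table.
#' @export
classify_sample <- function(sample, amp, donor = NULL, flank_check = 10L,
                            drop_at_1nt = FALSE) {
  stopifnot(inherits(sample, "sample_table"))
  al <- sample$alleles
  n <- nrow(al)
  cls <- character(n); sub <- character(n)
  mhl <- integer(n); mhs <- character(n)
  for (i in seq_len(n)) {
    cc <- classify_allele(al$signature[i], amp, donor, flank_check)
    cls[i] <- cc$repair_class; sub[i] <- cc$subtype
    mhl[i] <- if (is.na(cc$mh_length)) NA_integer_ else cc$mh_length
    mhs[i] <- cc$mh_sequence
  }
  al$repair_class <- cls; al$subtype <- sub
  al$mh_length <- mhl; al$mh_sequence <- mhs
  for (scheme in c("seven_group", "eleven_cat", "t50_bins",
                   "competition_bins")) {
    al[[paste0("cat_", scheme)]] <-
      vapply(seq_len(n), function(i)
        categorize(cls[i], al$signature[i], amp, scheme), character(1L))
  }
  if (drop_at_1nt) {
    cut <- amp$cut_site; ref <- amp$reference_sequence
    left <- substr(ref, cut, cut); right <- substr(ref, cut + 1L, cut + 1L)
    if (left == right && left %in% c("A", "T")) {
      at1 <- vapply(al$signature, function(s) {
        o <- signature_to_ops(s)
        nrow(o) == 1L && o$kind == "deletion" && o$ref_end - o$ref_start == 1L &&
          o$ref_start %in% c(cut - 1L, cut)
      }, logical(1L))
      al <- al[!at1, , drop = FALSE]
    }
  }
  sample$alleles <- al
  sample
}
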