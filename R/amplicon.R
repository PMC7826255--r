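# Core domain model: amplicon geometry, edit operations, donor specification.
# Coordinates are 0-based, half-open throughout; cut_site is an inter-base
# index (the blunt SpCas9 cut 3 nt 5' of the PAM on the protospacer strand).

#' Construct an amplicon with guide and cut-site geometry
#'
#' An amplicon couples a reference sequence with the position of the SpCas9
#' protospacer and PAM. The protospacer may sit on either strand of the stored
#' reference; all editing events are reported in protospacer-strand
#' orientation downstream. `pam_start` is the 0-based index of the leftmost
#' reference base of the PAM triplet as laid on the reference. The blunt cut
#' is placed 3 nt 5' of the PAM on the protospacer strand, so
#' `cut_site = pam_start - 3` for strand `"+"` and `pam_start + 6` for strand
#' `"-"` (an inter-base index).
#'
#' @param id amplicon identifier.
#' @param reference uppercase DNA reference (A/C/G/T/N), length >= 120.
#' @param pam_start 0-based reference index of the PAM triplet.
#' @param strand `"+"` or `"-"`: the strand carrying the protospacer.
#' @param protospacer optional 20-nt protospacer; when supplied it is checked
#'   against the reference, otherwise it is read off the reference.
#' @return an object of class `"amplicon"` with fields `id`,
#'   `reference_sequence`, `protospacer`, `pam_start`, `strand`, `cut_site`.
#' @examples
#' amp <- random_amplicon(seed = 1, minus4 = "T")
#' amp$cut_site
#' minus4_base(amp)
#' @export
amplicon <- function(id, reference, pam_start, strand = c("+", "-"),
                     protospacer = NULL) {
  strand <- match.arg(strand)
  reference <- toupper(reference)
  len <- nchar(reference)
  if (len < 120L)
    stop("reference must be at least 120 nt (+-50 bp deletion window)")
  if (grepl("[^ACGTN]", reference))
    stop("reference contains non-ACGTN characters")
  pam_start <- as.integer(pam_start)
  if (strand == "+") {
    if (pam_start < 20L || pam_start + 3L > len)
      stop("PAM does not leave room for a 20-nt protospacer on '+' strand")
    pam <- substr(reference, pam_start + 1L, pam_start + 3L)
    if (substr(pam, 2L, 3L) != "GG")
      stop("no NGG PAM at pam_start on '+' strand (found ", pam, ")")
    ps <- substr(reference, pam_start - 19L, pam_start)
    cut_site <- pam_start - 3L
  } else {
    if (pam_start < 0L || pam_start + 23L > len)
      stop("PAM does not leave room for a 20-nt protospacer on '-' strand")
    pam_ref <- substr(reference, pam_start + 1L, pam_start + 3L)
    if (substr(pam_ref, 1L, 2L) != "CC")
      stop("no NGG PAM at pam_start on '-' strand (found CC-complement ",
           pam_ref, ")")
    ps <- revcomp(substr(reference, pam_start + 4L, pam_start + 23L))
    cut_site <- pam_start + 6L
  }
  if (!is.null(protospacer) && toupper(protospacer) != ps)
    stop("supplied protospacer does not match the reference at its ",
         "stated coordinates")
  if (cut_site <= 0L || cut_site >= len)
    stop("cut_site falls outside the reference")
  structure(
    list(id = as.character(id), reference_sequence = reference,
         protospacer = ps, pam_start = pam_start, strand = strand,
         cut_site = cut_site),
    class = "amplicon")
}

#' @export
print.amplicon <- function(x, ...) {
  cat("<amplicon> ", x$id, ": ", nchar(x$reference_sequence), " nt, strand ",
      x$strand, ", cut at ", x$cut_site, ", protospacer ", x$protospacer,
      "\n", sep = "")
  invisible(x)
}

#' The -4 nucleotide of an amplicon
#'
#' Returns the base immediately 5' of the cut site on the protospacer strand
#' (position 17 of the 20-nt protospacer). Its duplication is the signature
#' +1 NHEJ insertion.
#'
#' @param amp an [amplicon()].
#' @return single character, one of A/C/G/T.
#' @export
minus4_base <- function(amp) {
  stopifnot(inherits(amp, "amplicon"))
  k <- amp$cut_site
  b <- if (amp$strand == "+") {
    substr(amp$reference_sequence, k, k)            # base left of the cut
  } else {
    .complement[[substr(amp$reference_sequence, k + 1L, k + 1L)]]
  }
  if (b == "N") stop("reference is ambiguous (N) at the -4 position")
  b
}

# -- edit operations ---------------------------------------------------------

#' Create a table of edit operations
#'
#' Edit operations are stored as a data frame with columns `kind`
#' ("insertion", "deletion" or "substitution"), `ref_start`, `ref_end`
#' (0-based, half-open; equal for insertions) and `ins_seq` (inserted bases,
#' empty otherwise), sorted by `ref_start`.
#'
#' @param kind,ref_start,ref_end,ins_seq parallel vectors describing the ops.
#' @return a `data.frame` of validated, sorted operations.
#' @export
edit_ops <- function(kind = character(), ref_start = integer(),
                     ref_end = integer(), ins_seq = "") {
  ops <- data.frame(kind = as.character(kind),
                    ref_start = as.integer(ref_start),
                    ref_end = as.integer(ref_end),
                    ins_seq = toupper(rep_len(as.character(ins_seq),
                                              length(kind))),
                    stringsAsFactors = FALSE)
  if (nrow(ops) == 0L) return(ops)
  bad <- !ops$kind %in% c("insertion", "deletion", "substitution")
  if (any(bad)) stop("unknown op kind: ", ops$kind[bad][1L])
  if (any(ops$ref_start > ops$ref_end)) stop("ref_start > ref_end")
  ins <- ops$kind == "insertion"
  if (any(ins & (ops$ref_start != ops$ref_end | !nzchar(ops$ins_seq))))
    stop("insertions need ref_start == ref_end and non-empty ins_seq")
  if (any(ops$kind == "deletion" & nzchar(ops$ins_seq)))
    stop("deletions carry no inserted sequence")
  if (any(ops$kind == "deletion" & ops$ref_end <= ops$ref_start))
    stop("deletions need ref_end > ref_start")
  sub <- ops$kind == "substitution"
  if (any(sub & nchar(ops$ins_seq) != ops$ref_end - ops$ref_start))
    stop("substitutions need replacement bases matching the span length")
  ops <- ops[order(ops$ref_start, ops$ref_end), , drop = FALSE]
  if (nrow(ops) > 1L) {
    prev_end <- ops$ref_end[-nrow(ops)]
    nxt_start <- ops$ref_start[-1L]
    if (any(nxt_start < prev_end)) stop("edit operations overlap")
  }
  rownames(ops) <- NULL
  ops
}

#' Serialize / parse indel signatures
#'
#' A signature is the canonical string form of an indel op list, e.g.
#' `"D:110-117"` for deleting reference bases \[110,117) or `"I:120:TT"` for
#' inserting TT at inter-base position 120, multiple ops joined by `";"`.
#' The empty string denotes an unedited allele. Substitution ops are never
#' part of a signature.
#'
#' @param ops an [edit_ops()] data frame.
#' @return `ops_to_signature()`: a character scalar; `signature_to_ops()`:
#'   an [edit_ops()] data frame.
#' @export
ops_to_signature <- function(ops) {
  ops <- ops[ops$kind != "substitution", , drop = FALSE]
  if (nrow(ops) == 0L) return("")
  paste(ifelse(ops$kind == "deletion",
               paste0("D:", ops$ref_start, "-", ops$ref_end),
               paste0("I:", ops$ref_start, ":", ops$ins_seq)),
        collapse = ";")
}

#' @rdname ops_to_signature
#' @param sig a signature string.
#' @export
signature_to_ops <- function(sig) {
  if (is.na(sig) || !nzchar(sig)) return(edit_ops())
  parts <- strsplit(sig, ";", fixed = TRUE)[[1L]]
  kind <- character(length(parts)); s <- e <- integer(length(parts))
  ins <- character(length(parts))
  for (i in seq_along(parts)) {
    f <- strsplit(parts[i], ":", fixed = TRUE)[[1L]]
    if (f[1L] == "D") {
      kind[i] <- "deletion"
      se <- as.integer(strsplit(f[2L], "-", fixed = TRUE)[[1L]])
      s[i] <- se[1L]; e[i] <- se[2L]; ins[i] <- ""
    } else if (f[1L] == "I") {
      kind[i] <- "insertion"
      s[i] <- e[i] <- as.integer(f[2L]); ins[i] <- f[3L]
    } else stop("malformed signature: ", sig)
  }
  edit_ops(kind, s, e, ins)
}

#' Apply edit operations to a reference
#'
#' Reconstructs the edited sequence by applying all ops (left to right) to
#' the amplicon reference. This is the round-trip oracle for the indel
#' caller: calling an error-free read built by `apply_allele()` recovers the
#' same ops.
#'
#' @param amp an [amplicon()] or a plain reference string.
#' @param ops an [edit_ops()] data frame or a signature string.
#' @return the edited DNA string.
#' @export
apply_allele <- function(amp, ops) {
  ref <- if (inherits(amp, "amplicon")) amp$reference_sequence else toupper(amp)
  if (is.character(ops) && length(ops) == 1L && !is.data.frame(ops))
    ops <- signature_to_ops(ops)
  ops <- edit_ops(ops$kind, ops$ref_start, ops$ref_end, ops$ins_seq) # validate
  if (nrow(ops) > 0L && max(ops$ref_end) > nchar(ref))
    stop("edit operation extends beyond the reference")
  out <- character(0L)
  pos <- 0L  # 0-based consumed prefix
  for (i in seq_len(nrow(ops))) {
    out <- c(out, substr(ref, pos + 1L, ops$ref_start[i]))
    if (ops$kind[i] == "insertion") {
      out <- c(out, ops$ins_seq[i])
      pos <- ops$ref_start[i]
    } else if (ops$kind[i] == "deletion") {
      pos <- ops$ref_end[i]
    } else {  # substitution: replacement bases over the same span
      out <- c(out, ops$ins_seq[i])
      pos <- ops$ref_end[i]
    }
  }
  paste0(paste(out, collapse = ""), substr(ref, pos + 1L, nchar(ref)))
}

# -- HDR donor ---------------------------------------------------------------

#' Specify an HDR donor insert
#'
#' The donor carries a short insert (8 or 15 bp in the emulated experiments)
#' placed exactly at the Cas9 cut site, flanked by long homology arms. After
#' perfect HDR the protospacer+PAM is disrupted, so the edited locus is no
#' longer an RNP substrate.
#'
#' @param insert_sequence DNA string inserted at the cut site (non-empty).
#' @param homology_arm_length nominal arm length in nt (default 600;
#'   informational at desk scale).
#' @return an object of class `"donor_spec"`.
#' @export
donor_spec <- function(insert_sequence, homology_arm_length = 600L) {
  insert_sequence <- toupper(insert_sequence)
  if (!nzchar(insert_sequence))
    stop("empty donor insert: HDR alleles would be indistinguishable ",
         "from unedited reads")
  if (grepl("[^ACGT]", insert_sequence))
    stop("donor insert contains non-ACGT characters")
  structure(list(insert_sequence = insert_sequence,
                 insertion_point = NA_integer_,  # always the amplicon cut site
                 homology_arm_length = as.integer(homology_arm_length)),
            class = "donor_spec")
}

#' Donor-edited reference sequence
#'
#' Places the donor insert at the amplicon cut site and verifies that the
#' intact 23-nt protospacer+PAM no longer occurs in the edited sequence (on
#' either strand): a donor whose edges restore the target site is rejected.
#'
#' @param amp an [amplicon()].
#' @param donor a [donor_spec()].
#' @return the HDR-edited reference string.
#' @export
donor_edited_sequence <- function(amp, donor) {
  stopifnot(inherits(amp, "amplicon"), inherits(donor, "donor_spec"))
  ops <- edit_ops("insertion", amp$cut_site, amp$cut_site,
                  donor$insert_sequence)
  edited <- apply_allele(amp, ops)
  site <- if (amp$strand == "+") {
    paste0(amp$protospacer,
           substr(amp$reference_sequence, amp$pam_start + 1L,
                  amp$pam_start + 3L))
  } else {
    paste0(amp$protospacer,
           revcomp(substr(amp$reference_sequence, amp$pam_start + 1L,
                          amp$pam_start + 3L)))
  }
  if (grepl(site, edited, fixed = TRUE) ||
      grepl(site, revcomp(edited), fixed = TRUE))
    stop("donor insert recreates the intact protospacer+PAM; ",
         "the edited locus would remain an RNP substrate")
  edited
}
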