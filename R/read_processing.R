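# Paired-end merging and inline-barcode demultiplexing. Amplicons are short
# enough (<= ~500 bp) that the overlap search is exhaustive over offsets;
# unmerged pairs are dropped (the analysis operates on merged reads only).

#' Merge 150-bp paired-end reads into amplicon fragments
#'
#' Reverse-complements read 2 and slides it along read 1, scoring every
#' offset; an offset is acceptable when the overlap is at least `min_overlap`
#' bases and the mismatch fraction within the overlap is at most
#' `max_mismatch_frac`. Among acceptable offsets the one with the most
#' matching bases wins. Disagreeing overlap bases are resolved toward the
#' higher phred score and the merged quality is the per-base maximum.
#'
#' @param r1,r2 character vectors of read sequences (phred+33 companions in
#'   `q1`, `q2`). `r2` is given in sequencing orientation.
#' @param q1,q2 quality strings; default constant high quality.
#' @param min_overlap minimum acceptable overlap (default 10).
#' @param max_mismatch_frac maximum mismatch fraction in the overlap
#'   (default 0.1).
#' @return a data.frame with columns `seq`, `qual`, `ok`; failed merges have
#'   `ok = FALSE` and `NA` sequence (they are excluded downstream but
#'   counted).
#' @export
merge_pairs <- function(r1, r2, q1 = NULL, q2 = NULL, min_overlap = 10L,
                        max_mismatch_frac = 0.1) {
  stopifnot(length(r1) == length(r2))
  if (is.null(q1)) q1 <- strrep("I", nchar(r1))
  if (is.null(q2)) q2 <- strrep("I", nchar(r2))
  if (any(nchar(q1) != nchar(r1)) || any(nchar(q2) != nchar(r2)))
    stop("sequence and quality lengths differ")
  if (any(!nzchar(r1)) || any(!nzchar(r2))) stop("empty reads")
  res <- merge_pairs_cpp(toupper(r1), toupper(r2), q1, q2,
                         as.integer(min_overlap), max_mismatch_frac)
  data.frame(seq = as.character(res$seq), qual = as.character(res$qual),
             ok = res$ok, stringsAsFactors = FALSE)
}

#' Build a validated barcode table
#'
#' @param sample_id,barcode,amplicon_id parallel vectors describing the
#'   demultiplexing layout; barcodes must be of uniform length, unique, and
#'   pairwise Hamming distance strictly greater than `2 * max_mismatch` so
#'   that every read is at most `max_mismatch` from a unique barcode.
#' @param max_mismatch the mismatch tolerance the table must support.
#' @return a `barcode_table` data.frame.
#' @export
barcode_table <- function(sample_id, barcode, amplicon_id = sample_id,
                          max_mismatch = 1L) {
  barcode <- toupper(barcode)
  if (length(unique(nchar(barcode))) != 1L)
    stop("barcodes must have uniform length")
  if (anyDuplicated(barcode)) stop("duplicate barcodes")
  n <- length(barcode)
  for (i in seq_len(max(0L, n - 1L))) for (j in seq.int(i + 1L, n)) {
    d <- sum(strsplit(barcode[i], "")[[1L]] != strsplit(barcode[j], "")[[1L]])
    if (d <= 2L * max_mismatch)
      stop("barcodes ", sample_id[i], " and ", sample_id[j],
           " are within Hamming distance ", 2L * max_mismatch)
  }
  structure(data.frame(sample_id = as.character(sample_id), barcode = barcode,
                       amplicon_id = as.character(amplicon_id),
                       stringsAsFactors = FALSE),
            class = c("barcode_table", "data.frame"),
            max_mismatch = as.integer(max_mismatch))
}

#' Demultiplex merged reads by 5' inline barcode
#'
#' A read is assigned to the unique barcode within `max_mismatch` of its 5'
#' prefix; ties and non-matches go to the unassigned bin. The barcode prefix
#' is trimmed from assigned reads.
#'
#' @param seqs merged read sequences.
#' @param table a [barcode_table()].
#' @param quals optional parallel quality strings (trimmed alongside).
#' @param max_mismatch maximum allowed barcode mismatches (default 1).
#' @return list with `assignment` (sample id or `NA`), `bins` (named list of
#'   trimmed sequence vectors per sample), `unassigned` (untrimmed), and a
#'   `report` data.frame of counts (assigned + unassigned = input).
#' @export
demultiplex <- function(seqs, table, quals = NULL, max_mismatch = 1L) {
  stopifnot(inherits(table, "barcode_table"))
  if (max_mismatch > attr(table, "max_mismatch"))
    stop("barcode table was validated for max_mismatch = ",
         attr(table, "max_mismatch"))
  blen <- nchar(table$barcode[1L])
  idx <- demux_assign_cpp(seqs, table$barcode, as.integer(max_mismatch))
  assignment <- table$sample_id[ifelse(idx > 0L, idx, NA_integer_)]
  trimmed <- substr(seqs, blen + 1L, nchar(seqs))
  bins <- lapply(seq_len(nrow(table)), function(k) trimmed[idx == k])
  names(bins) <- table$sample_id
  qbins <- NULL
  if (!is.null(quals)) {
    qt <- substr(quals, blen + 1L, nchar(quals))
    qbins <- lapply(seq_len(nrow(table)), function(k) qt[idx == k])
    names(qbins) <- table$sample_id
  }
  report <- data.frame(
    sample_id = c(table$sample_id, "(unassigned)"),
    n = c(vapply(seq_len(nrow(table)), function(k) sum(idx == k), integer(1L)),
          sum(idx == 0L)))
  list(assignment = assignment, bins = bins, qual_bins = qbins,
       unassigned = seqs[idx == 0L], report = report)
}

# -- FASTQ / FASTA / sidecar IO ---------------------------------------------

#' Read and write FASTQ (phred+33)
#'
#' Thin wrappers around Biostrings for the plain-text FASTQ used by the
#' pipeline and simulator.
#'
#' @param path file path.
#' @return `read_fastq()`: data.frame with `id`, `seq`, `qual`.
#' @export
read_fastq <- function(path) {
  x <- Biostrings::readQualityScaledDNAStringSet(path)
  data.frame(id = names(x), seq = as.character(x),
             qual = as.character(Biostrings::quality(x)),
             stringsAsFactors = FALSE, row.names = NULL)
}

#' @rdname read_fastq
#' @param id,seq,qual read names, sequences, phred+33 quality strings.
#' @export
write_fastq <- function(path, id, seq, qual) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(paste0("@", id, "\n", seq, "\n+\n", qual), con)
  invisible(path)
}

#' Read amplicons from FASTA plus sidecar TSV
#'
#' The sidecar TSV has columns `id`, `protospacer`, `pam_start` (0-based) and
#' `strand`, one row per amplicon in the FASTA.
#'
#' @param fasta path to the reference FASTA.
#' @param sidecar path to the sidecar TSV.
#' @return named list of [amplicon()] objects.
#' @export
read_amplicons <- function(fasta, sidecar) {
  refs <- Biostrings::readDNAStringSet(fasta)
  tab <- read.delim(sidecar, stringsAsFactors = FALSE)
  need <- c("id", "protospacer", "pam_start", "strand")
  if (!all(need %in% names(tab)))
    stop("amplicon sidecar must have columns: ", paste(need, collapse = ", "))
  out <- lapply(seq_len(nrow(tab)), function(i) {
    id <- tab$id[i]
    if (!id %in% names(refs)) stop("no FASTA record for amplicon ", id)
    amplicon(id, as.character(refs[[id]]), tab$pam_start[i], tab$strand[i],
             protospacer = tab$protospacer[i])
  })
  names(out) <- tab$id
  out
}

#' Read donor specifications from TSV
#'
#' Columns: `amplicon_id`, `insert_sequence`, `arm_length`.
#' @param path TSV path.
#' @return named list of [donor_spec()] keyed by amplicon id.
#' @export
read_donors <- function(path) {
  tab <- read.delim(path, stringsAsFactors = FALSE)
  need <- c("amplicon_id", "insert_sequence", "arm_length")
  if (!all(need %in% names(tab)))
    stop("donor table must have columns: ", paste(need, collapse = ", "))
  out <- lapply(seq_len(nrow(tab)), function(i)
    donor_spec(tab$insert_sequence[i], tab$arm_length[i]))
  names(out) <- tab$amplicon_id
  out
}
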