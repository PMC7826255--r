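# Pipeline orchestration and the TSV inter-stage contract. Every stage is
# runnable standalone on the previous stage's outputs; tables are written
# with 6-significant-digit floats and carry the run's config hash in a
# comment header so any output is reproducible from the log alone.

.fmt_num <- function(x) formatC(x, digits = 6, format = "g")

.config_hash <- function(obj) {
  tf <- tempfile()
  on.exit(unlink(tf))
  writeLines(paste(deparse(obj), collapse = ""), tf)
  unname(tools::md5sum(tf))
}

#' Write / read a pipeline TSV with config-hash header
#'
#' @param df data.frame to write.
#' @param path file path.
#' @param config the configuration object hashed into the `# config=` header.
#' @return `write_stage_tsv()`: the path; `read_stage_tsv()`: the data.frame
#'   (header comment skipped).
#' @export
write_stage_tsv <- function(df, path, config = NULL) {
  num <- vapply(df, is.numeric, logical(1L))
  for (j in which(num)) {
    if (!is.integer(df[[j]])) df[[j]] <- .fmt_num(df[[j]])
  }
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(paste0("# editrace config=", .config_hash(config)), con)
  write.table(df, con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_stage_tsv
#' @export
read_stage_tsv <- function(path) {
  read.delim(path, comment.char = "#", stringsAsFactors = FALSE)
}

#' Flatten sample tables to the allele-table TSV layout
#'
#' Columns: `amplicon`, `condition`, `timepoint_h`, `total_reads`,
#' `signature`, `count`, `frequency`, plus any classification columns.
#'
#' @param samples list of `sample_table`s.
#' @return a data.frame in the inter-stage layout.
#' @export
samples_to_table <- function(samples) {
  if (inherits(samples, "sample_table")) samples <- list(samples)
  do.call(rbind, lapply(samples, function(s) {
    al <- s$alleles
    if (nrow(al) == 0L)
      al <- data.frame(signature = "", count = 0L, frequency = 0)
    cbind(data.frame(amplicon = s$amplicon_id, condition = s$condition,
                     timepoint_h = s$timepoint_h, total_reads = s$total_reads,
                     stringsAsFactors = FALSE),
          al)
  }))
}

#' Rebuild sample tables from the allele-table TSV layout
#'
#' @param tab data.frame as produced by [samples_to_table()] (or read back
#'   from TSV).
#' @return list of `sample_table`s, one per (amplicon, condition, timepoint).
#' @export
table_to_samples <- function(tab) {
  key <- paste(tab$amplicon, tab$condition, tab$timepoint_h, sep = "\r")
  lapply(split(tab, key), function(d) {
    d <- d[nzchar(d$signature) & !is.na(d$signature), , drop = FALSE]
    st <- sample_table(d$signature, d$count,
                       total_reads = d$total_reads[1L],
                       amplicon_id = d$amplicon[1L],
                       condition = d$condition[1L],
                       timepoint_h = d$timepoint_h[1L])
    extra <- setdiff(names(d), c("amplicon", "condition", "timepoint_h",
                                 "total_reads", "signature", "count",
                                 "frequency"))
    if (length(extra) > 0L) {
      i <- match(st$alleles$signature, d$signature)
      for (col in extra) st$alleles[[col]] <- d[[col]][i]
    }
    st
  })
}

#' Load a pipeline configuration
#'
#' Accepts a YAML or JSON file (by extension) or a ready-made list. Required
#' fields depend on the stages run; [run_pipeline()] validates them.
#'
#' @param x path or list.
#' @return the configuration list.
#' @export
load_config <- function(x) {
  if (is.list(x)) return(x)
  if (grepl("\\.ya?ml$", x)) {
    if (!requireNamespace("yaml", quietly = TRUE))
      stop("yaml package required for YAML configs; use JSON instead")
    return(yaml::read_yaml(x))
  }
  jsonlite::fromJSON(x, simplifyVector = TRUE)
}

#' Run the full analysis pipeline
#'
#' Executes merge, demultiplex, call, classify, kinetics and stats over
#' the samples described by the configuration and writes the report bundle
#' (allele tables, kinetics tables, stats JSON and a run log with seed and
#' parameter snapshot) into `config$out_dir`.
#'
#' Configuration fields: `amplicon_fasta`, `amplicon_sidecar`, `barcodes`
#' (TSV: sample_id, barcode, amplicon_id, condition, timepoint_h),
#' `donors` (optional TSV), `r1`, `r2` (FASTQ paths), `out_dir`, and
#' optional `params` (window, min_count, min_freq, seed).
#'
#' @param config list, or path to a YAML/JSON configuration.
#' @return invisibly, a list with the classified samples, kinetics and stats.
#' @export
run_pipeline <- function(config) {
  cfg <- load_config(config)
  need <- c("amplicon_fasta", "amplicon_sidecar", "barcodes", "r1", "r2",
            "out_dir")
  miss <- setdiff(need, names(cfg))
  if (length(miss) > 0L)
    stop("config error: missing field(s) ", paste(miss, collapse = ", "))
  for (f in c("amplicon_fasta", "amplicon_sidecar", "barcodes", "r1", "r2"))
    if (!file.exists(cfg[[f]]))
      stop("data error: input not found: ", cfg[[f]])
  params <- modifyList(list(window = 50L, min_count = 2L, min_freq = 5e-4,
                            seed = 1L, min_overlap = 10L,
                            max_mismatch_frac = 0.1, max_mismatch = 1L),
                       if (is.null(cfg$params)) list() else cfg$params)
  dir.create(cfg$out_dir, showWarnings = FALSE, recursive = TRUE)

  amps <- read_amplicons(cfg$amplicon_fasta, cfg$amplicon_sidecar)
  donors <- if (!is.null(cfg$donors)) read_donors(cfg$donors) else list()
  btab <- read.delim(cfg$barcodes, stringsAsFactors = FALSE)
  bt <- barcode_table(btab$sample_id, btab$barcode, btab$amplicon_id,
                      max_mismatch = params$max_mismatch)

  f1 <- read_fastq(cfg$r1); f2 <- read_fastq(cfg$r2)
  mg <- merge_pairs(f1$seq, f2$seq, f1$qual, f2$qual,
                    min_overlap = params$min_overlap,
                    max_mismatch_frac = params$max_mismatch_frac)
  dm <- demultiplex(mg$seq[mg$ok], bt, max_mismatch = params$max_mismatch)
  write_stage_tsv(dm$report, file.path(cfg$out_dir, "demux_report.tsv"), cfg)

  samples <- lapply(seq_len(nrow(btab)), function(k) {
    sid <- btab$sample_id[k]
    amp <- amps[[btab$amplicon_id[k]]]
    if (is.null(amp))
      stop("data error: barcode table references unknown amplicon ",
           btab$amplicon_id[k])
    reads <- dm$bins[[sid]]
    if (length(reads) == 0L) return(NULL)
    st <- call_sample(reads, amp, window = params$window,
                      min_count = params$min_count,
                      min_freq = params$min_freq,
                      condition = if (!is.null(btab$condition))
                        btab$condition[k] else "donor_absent",
                      timepoint_h = if (!is.null(btab$timepoint_h))
                        btab$timepoint_h[k] else 48)
    classify_sample(st, amp, donor = donors[[btab$amplicon_id[k]]])
  })
  names(samples) <- btab$sample_id
  samples <- samples[!vapply(samples, is.null, logical(1L))]
  write_stage_tsv(samples_to_table(samples),
                  file.path(cfg$out_dir, "alleles.tsv"), cfg)

  # kinetics per (amplicon, condition) group with >= 4 timepoints
  kin <- list()
  grp <- split(samples, vapply(samples, function(s)
    paste(s$amplicon_id, s$condition), character(1L)))
  for (g in names(grp)) {
    if (length(grp[[g]]) >= 4L) {
      kk <- kinetics_by_category(grp[[g]])
      kin[[g]] <- kk
      write_stage_tsv(kk$fits,
                      file.path(cfg$out_dir, paste0("kinetics_",
                                                    gsub("\\s+", "_", g),
                                                    ".tsv")), cfg)
    }
  }

  stats <- lapply(samples, function(s) {
    gini <- tryCatch(gini_top_n(s), error = function(e) NA_real_)
    list(sample = paste(s$amplicon_id, s$condition, s$timepoint_h),
         editing_efficiency = editing_efficiency(s), gini_top5 = gini)
  })
  jsonlite::write_json(
    list(params = params, config_hash = .config_hash(cfg), stats = stats),
    file.path(cfg$out_dir, "stats.json"), auto_unbox = TRUE, digits = NA,
    pretty = TRUE, force = TRUE)
  log <- c(paste("editrace", as.character(utils::packageVersion("editrace"))),
           paste("R", getRversion()),
           paste("seed", params$seed),
           paste("config_hash", .config_hash(cfg)),
           paste("params:", jsonlite::toJSON(params, auto_unbox = TRUE)))
  writeLines(log, file.path(cfg$out_dir, "run_log.txt"))
  invisible(list(samples = samples, kinetics = kin, stats = stats))
}
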