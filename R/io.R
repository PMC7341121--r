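# Format readers/writers. FASTA is delegated to Biostrings; FASTQ and SAM are
# read/written directly so parse errors can name the offending record and the
# SAM writer can emit the aligner's =/X CIGARs. Gzip is handled transparently
# for FASTA/FASTQ by file extension.

open_text <- function(path, mode) {
  if (grepl("\\.gz$", path)) gzfile(path, mode) else file(path, mode)
}

read_lines_norm <- function(path) {
  # readLines() silently accepts CR/LF; peek at raw bytes to warn about it
  con <- open_text(path, "rb")
  head <- readBin(con, "raw", n = 65536L)
  close(con)
  if (any(head == as.raw(0x0d))) {
    warning("CR/LF line endings normalized in ", path, call. = FALSE)
  }
  con <- open_text(path, "rb")
  on.exit(close(con))
  lines <- readLines(con, warn = FALSE)
  gsub("\r", "", lines, fixed = TRUE)
}

#' Read / write FASTA
#'
#' @param path File path (`.gz` transparently handled).
#' @return `read_fasta`: a named character vector of sequences.
#' @export
read_fasta <- function(path) {
  x <- Biostrings::readDNAStringSet(path)
  out <- as.character(x)
  names(out) <- sub("\\s.*$", "", names(x))
  out
}

#' @rdname read_fasta
#' @param seqs Named character vector of sequences.
#' @export
write_fasta <- function(seqs, path) {
  x <- Biostrings::DNAStringSet(seqs)
  Biostrings::writeXStringSet(x, path, compress = grepl("\\.gz$", path))
  invisible(path)
}

#' Read / write 4-line FASTQ
#'
#' A truncated final record raises a parse error naming the record index.
#'
#' @param path File path (`.gz` transparently handled).
#' @return `read_fastq`: data.frame with columns `id`, `seq`, `qual`.
#' @export
read_fastq <- function(path) {
  lines <- read_lines_norm(path)
  n <- length(lines)
  if (n %% 4L != 0L) {
    stop(sprintf("truncated FASTQ record %d in %s (%d trailing lines)",
                 n %/% 4L + 1L, path, n %% 4L), call. = FALSE)
  }
  if (n == 0L) {
    return(data.frame(id = character(), seq = character(),
                      qual = character()))
  }
  heads <- lines[seq(1L, n, 4L)]
  bad <- which(!startsWith(heads, "@"))
  if (length(bad)) {
    stop(sprintf("malformed FASTQ record %d: header does not start with '@'",
                 bad[1L]), call. = FALSE)
  }
  data.frame(id = sub("^@", "", sub("\\s.*$", "", heads)),
             seq = lines[seq(2L, n, 4L)],
             qual = lines[seq(4L, n, 4L)])
}

#' @rdname read_fastq
#' @param reads data.frame with columns `id`, `seq` and optionally `qual`
#'   (defaults to constant Q40, `"I"`).
#' @export
write_fastq <- function(reads, path) {
  qual <- reads$qual
  if (is.null(qual)) qual <- strrep("I", nchar(reads$seq))
  con <- open_text(path, "wb")
  on.exit(close(con))
  writeLines(as.vector(rbind(paste0("@", reads$id), reads$seq, "+", qual)),
             con)
  invisible(path)
}

#' Read / write tab-separated tables
#'
#' @param path File path.
#' @return `read_tsv`: a data.frame (strings kept as-is).
#' @export
read_tsv <- function(path) {
  utils::read.delim(path, stringsAsFactors = FALSE, check.names = FALSE)
}

#' @rdname read_tsv
#' @param x data.frame to write.
#' @export
write_tsv <- function(x, path) {
  utils::write.table(x, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Write alignments as SAM
#'
#' Emits a SAM 1.6 text file with an `@HD`/`@SQ` header. Aligned records get
#' MAPQ 60; unaligned reads are written with flag 4. CIGARs use `=`/`X`/`I`/`D`
#' operations. BAM is deliberately not supported (text-only artifact).
#'
#' @param aln An alignment set from [align_set()] (or a compatible
#'   data.frame with columns `qname`, `aligned`, `ref_start`, `cigar`,
#'   `score`, `seq`).
#' @param ref_name,ref_len Reference name and length for the `@SQ` line.
#' @param path Output path.
#' @export
write_sam <- function(aln, ref_name, ref_len, path) {
  rec <- if (inherits(aln, "alignment_set")) aln$records else aln
  con <- file(path, "wb")
  on.exit(close(con))
  writeLines(c("@HD\tVN:1.6\tSO:unsorted",
               sprintf("@SQ\tSN:%s\tLN:%d", ref_name, as.integer(ref_len)),
               "@PG\tID:crisprseq\tPN:crisprseq"), con)
  flag <- ifelse(rec$aligned, 0L, 4L)
  rname <- ifelse(rec$aligned, ref_name, "*")
  pos <- ifelse(rec$aligned, rec$ref_start + 1L, 0L)
  mapq <- ifelse(rec$aligned, 60L, 0L)
  cig <- ifelse(rec$aligned, rec$cigar, "*")
  seqs <- if (is.null(rec$seq)) rep("*", nrow(rec)) else rec$seq
  writeLines(paste(rec$qname, flag, rname, pos, mapq, cig, "*", 0L, 0L,
                   seqs, "*", paste0("AS:i:", rec$score), sep = "\t"), con)
  invisible(path)
}

#' Read a SAM text file written by this package
#'
#' @param path SAM path.
#' @return List with `records` data.frame (`qname`, `aligned`, `ref_start`,
#'   `cigar`, `score`, `seq`) and `ref` (`name`, `length`).
#' @export
read_sam <- function(path) {
  lines <- read_lines_norm(path)
  hdr <- lines[startsWith(lines, "@")]
  body <- lines[!startsWith(lines, "@")]
  sq <- hdr[startsWith(hdr, "@SQ")]
  if (length(sq) != 1L) stop("expected exactly one @SQ line", call. = FALSE)
  ref_name <- sub("^.*SN:([^\t]+).*$", "\\1", sq)
  ref_len <- as.integer(sub("^.*LN:([0-9]+).*$", "\\1", sq))
  if (!length(body)) {
    rec <- data.frame(qname = character(), aligned = logical(),
                      ref_start = integer(), cigar = character(),
                      score = integer(), seq = character())
  } else {
    f <- strsplit(body, "\t", fixed = TRUE)
    get <- function(i) vapply(f, `[[`, character(1), i)
    flag <- as.integer(get(2))
    score <- suppressWarnings(as.integer(sub("^AS:i:", "",
      vapply(f, function(x) {
        hit <- grep("^AS:i:", x, value = TRUE)
        if (length(hit)) hit[1L] else "AS:i:NA"
      }, character(1)))))
    rec <- data.frame(qname = get(1), aligned = !bitwAnd(flag, 4L),
                      ref_start = as.integer(get(4)) - 1L, cigar = get(6),
                      score = score, seq = get(10))
    bad <- rec$aligned & (rec$ref_start < 0L | rec$ref_start >= ref_len)
    if (any(bad)) stop("malformed SAM record: POS outside reference",
                       call. = FALSE)
  }
  list(records = rec, ref = list(name = ref_name, length = ref_len))
}

# --- flat key:value configuration ------------------------------------------

config_defaults <- function() {
  list(reference = "", primers = "", fwd_primer = "etr-1PCR1F",
       rev_primer = "etr-1PCR1R", edited_cell_fraction = 0.10,
       per_allele_edit_prob = 1.0, del_len_mean = 25, max_del_len = 160,
       left_extent_frac = 0.3, insertion_prob = 0, n_alleles = 2000,
       n_reads = 100000, read_len = 250, subst_error_rate = 0.001,
       alpha = 0.01, min_del_len = 1, seed = 1, out_dir = "crisprseq_out",
       log_level = "info")
}

#' Read / write a pipeline configuration
#'
#' Flat `key: value` text format. Unknown keys are rejected; omitted keys take
#' packaged defaults. Values round-trip losslessly through [write_config()].
#'
#' @param path Config file path.
#' @return `read_config`: a named list (a `pipeline_config`).
#' @export
read_config <- function(path) {
  lines <- read_lines_norm(path)
  lines <- lines[nzchar(trimws(lines)) & !startsWith(trimws(lines), "#")]
  kv <- regmatches(lines, regexec("^\\s*([A-Za-z_0-9]+)\\s*:\\s*(.*?)\\s*$",
                                  lines))
  bad <- which(lengths(kv) != 3L)
  if (length(bad)) stop("malformed config line: ", lines[bad[1L]],
                        call. = FALSE)
  defs <- config_defaults()
  cfg <- defs
  for (m in kv) {
    key <- m[2L]
    if (!key %in% names(defs)) stop("unknown config key: ", key,
                                    call. = FALSE)
    val <- m[3L]
    cfg[[key]] <- if (is.numeric(defs[[key]])) as.numeric(val) else val
  }
  structure(cfg, class = "pipeline_config")
}

#' @rdname read_config
#' @param cfg A `pipeline_config` (named list of known keys).
#' @export
write_config <- function(cfg, path) {
  defs <- config_defaults()
  unknown <- setdiff(names(cfg), names(defs))
  if (length(unknown)) stop("unknown config key: ", unknown[1L],
                            call. = FALSE)
  vals <- vapply(cfg, function(v) format(v, scientific = FALSE,
                                         trim = TRUE), character(1))
  writeLines(paste0(names(cfg), ": ", vals), path)
  invisible(path)
}

# --- logging ----------------------------------------------------------------

.log_levels <- c(debug = 1L, info = 2L, warn = 3L, error = 4L)

log_msg <- function(level, ..., min_level = getOption("crisprseq.log_level",
                                                      "info")) {
  if (.log_levels[[level]] >= .log_levels[[min_level]]) {
    message(sprintf("[crisprseq %s] %s", level, paste0(...)))
  }
  invisible(NULL)
}
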