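# Adapter trimming and semi-global affine-gap alignment of reads to the
# amplicon reference. The DP core lives in src/semiglobal.cpp; this file owns
# validation, indel left-normalization, CIGAR bookkeeping, and the set-level
# driver that deduplicates identical reads before aligning.

.OP_CHARS <- c("=", "X", "I", "D")

#' Alignment scoring scheme
#'
#' Affine gaps: a gap of length L scores `gap_open + (L - 1) * gap_extend`.
#' Defaults use BWA-MEM-like ratios. A read whose optimal score falls below
#' `min_score_frac * match * read_length` is reported unaligned.
#'
#' @param match Match reward (> 0).
#' @param mismatch Mismatch penalty (< 0).
#' @param gap_open First-gap-base penalty (<= gap_extend < 0).
#' @param gap_extend Per-extra-gap-base penalty (< 0).
#' @param min_score_frac Alignment acceptance threshold in (0, 1].
#' @return A `scoring_scheme`.
#' @export
scoring_scheme <- function(match = 1L, mismatch = -4L, gap_open = -6L,
                           gap_extend = -1L, min_score_frac = 0.6) {
  if (!(match > 0 && mismatch < 0)) {
    stop("require match > 0 > mismatch", call. = FALSE)
  }
  if (!(gap_open <= gap_extend && gap_extend < 0)) {
    stop("require gap_open <= gap_extend < 0", call. = FALSE)
  }
  if (!(min_score_frac > 0 && min_score_frac <= 1)) {
    stop("min_score_frac must lie in (0, 1]", call. = FALSE)
  }
  structure(list(match = as.integer(match), mismatch = as.integer(mismatch),
                 gap_open = as.integer(gap_open),
                 gap_extend = as.integer(gap_extend),
                 min_score_frac = min_score_frac),
            class = "scoring_scheme")
}

#' Trim 3' adapter read-through
#'
#' Removes the longest read suffix that exactly matches a prefix of the
#' adapter with at least `min_overlap` bases. Reads without a qualifying
#' match (or shorter than `min_overlap`) are returned unchanged.
#'
#' @param reads Character vector of read sequences.
#' @param adapter Adapter sequence appearing at the 3' end of read-through
#'   reads (for read-1 geometry this is
#'   `revcomp(rev_tail) + revcomp(i7) + revcomp(P7)`).
#' @param min_overlap Minimum exact overlap (>= 3).
#' @return Trimmed reads.
#' @export
trim_adapter <- function(reads, adapter, min_overlap = 3L) {
  min_overlap <- as.integer(min_overlap)
  if (min_overlap < 3L) stop("min_overlap must be >= 3", call. = FALSE)
  adapter <- dna_norm(adapter, "adapter")
  if (!length(reads)) return(reads)
  lens <- nchar(reads)
  best <- integer(length(reads))
  for (k in seq(min(nchar(adapter), max(lens)), min_overlap)) {
    todo <- best == 0L & lens >= k
    if (!any(todo)) next
    hit <- todo & substr(reads, lens - k + 1L, lens) ==
      substr(adapter, 1L, k)
    best[hit] <- k
  }
  ifelse(best > 0L, substr(reads, 1L, lens - best), reads)
}

# adapter string expected at the 3' end of read-1 for a design
design_read1_adapter <- function(design) {
  ix <- design$indices
  paste0(revcomp(design$rev$adapter_tail), revcomp(ix$i7_index),
         revcomp(ix$p7_const))
}

# shift I/D runs maximally 5' among equal-scoring placements; ops is a
# data.frame(op, len), read/ref are the aligned sequences, ref_start the
# 0-based alignment start. Returns list(ops, ref_start).
left_normalize <- function(ops, read, ref, ref_start) {
  op <- ops$op
  len <- ops$len
  repeat {
    moved <- FALSE
    k <- 2L
    while (k <= length(op)) {
      if (op[k] %in% c("I", "D") && op[k - 1L] %in% c("=", "X")) {
        # coordinates of this indel
        ri <- ref_start + c(0L, cumsum(ifelse(op %in% c("=", "X", "D"),
                                              len, 0L)))[k]
        qi <- c(0L, cumsum(ifelse(op %in% c("=", "X", "I"), len, 0L)))[k]
        L <- len[k]
        shift <- 0L
        max_shift <- len[k - 1L]
        if (op[k] == "D") {
          while (shift < max_shift &&
                 substr(ref, ri - shift, ri - shift) ==
                 substr(ref, ri + L - shift, ri + L - shift)) {
            shift <- shift + 1L
          }
        } else {
          while (shift < max_shift &&
                 substr(read, qi - shift, qi - shift) ==
                 substr(read, qi + L - shift, qi + L - shift)) {
            shift <- shift + 1L
          }
        }
        if (shift > 0L) {
          moved <- TRUE
          len[k - 1L] <- len[k - 1L] - shift
          if (k < length(op) && op[k + 1L] %in% c("=", "X")) {
            len[k + 1L] <- len[k + 1L] + shift
          } else {
            op <- append(op, "=", after = k)
            len <- append(len, shift, after = k)
          }
          if (len[k - 1L] == 0L) {
            op <- op[-(k - 1L)]
            len <- len[-(k - 1L)]
            k <- k - 1L
          }
        }
      }
      k <- k + 1L
    }
    if (!moved) break
  }
  # the shifted flank columns may flip between = and X; reclassify all
  # aligned columns, then merge adjacent equal ops
  out <- reclassify_ops(op, len, read, ref, ref_start)
  # a shift to the very front would create a leading D; the DP never starts
  # in D, but guard against a normalization artifact
  while (nrow(out$ops) && out$ops$op[1L] == "D") {
    out$ref_start <- out$ref_start + out$ops$len[1L]
    out$ops <- out$ops[-1L, , drop = FALSE]
  }
  out
}

# recompute =/X from sequences and merge adjacent runs of the same op
reclassify_ops <- function(op, len, read, ref, ref_start) {
  qi <- 0L
  ri <- ref_start
  oo <- character(0)
  ll <- integer(0)
  push <- function(o, l) {
    if (length(oo) && oo[length(oo)] == o) {
      ll[length(ll)] <<- ll[length(ll)] + l
    } else {
      oo[length(oo) + 1L] <<- o
      ll[length(ll) + 1L] <<- l
    }
  }
  for (k in seq_along(op)) {
    if (op[k] %in% c("=", "X")) {
      q <- strsplit(substr(read, qi + 1L, qi + len[k]), "")[[1L]]
      r <- strsplit(substr(ref, ri + 1L, ri + len[k]), "")[[1L]]
      eq <- q == r & q != "N"
      rl <- rle(eq)
      for (t in seq_along(rl$lengths)) {
        push(if (rl$values[t]) "=" else "X", rl$lengths[t])
      }
      qi <- qi + len[k]
      ri <- ri + len[k]
    } else if (op[k] == "I") {
      push("I", len[k])
      qi <- qi + len[k]
    } else {
      push("D", len[k])
      ri <- ri + len[k]
    }
  }
  list(ops = data.frame(op = oo, len = ll), ref_start = ref_start)
}

#' Semi-global alignment of one read to the amplicon reference
#'
#' Optimal affine-gap alignment in which the read is fully consumed and gaps
#' at the reference ends are free. Traceback ties are broken in the fixed
#' order diagonal > deletion > insertion, and indels are subsequently
#' left-normalized (shifted maximally 5' among equal-scoring placements), so
#' per-position deletion profiles are stable. The read is never silently
#' clipped: a poor alignment is returned whole with `aligned = FALSE`.
#'
#' @param read,ref Non-empty `ACGTN` sequences.
#' @param scheme A `scoring_scheme`.
#' @param read_id Optional identifier carried into the record.
#' @return An `alignment_record`: list with `read_id`, `ref_start`, `ops`
#'   (data.frame of `op` in `=XID` and `len`), `score`, `aligned`, `cigar`.
#' @export
semiglobal_align <- function(read, ref, scheme = scoring_scheme(),
                             read_id = "read") {
  read <- dna_norm(read, "read", allow_n = TRUE)
  ref <- dna_norm(ref, "ref", allow_n = TRUE)
  if (!nzchar(read) || !nzchar(ref)) {
    stop("read and ref must be non-empty", call. = FALSE)
  }
  raw <- .cpp_semiglobal(read, ref, scheme$match, scheme$mismatch,
                         scheme$gap_open, scheme$gap_extend)
  ops <- data.frame(op = .OP_CHARS[raw$ops + 1L], len = raw$lens)
  norm <- left_normalize(ops, read, ref, raw$ref_start)
  aligned <- raw$score >= scheme$min_score_frac * scheme$match * nchar(read)
  structure(list(read_id = read_id, ref_start = norm$ref_start,
                 ops = norm$ops, score = raw$score, aligned = aligned,
                 cigar = ops_to_cigar(norm$ops)),
            class = "alignment_record")
}

#' CIGAR helpers
#'
#' @param ops data.frame with columns `op`, `len`.
#' @return `ops_to_cigar`: a CIGAR string using `=`/`X`/`I`/`D`.
#' @export
ops_to_cigar <- function(ops) {
  paste0(paste0(ops$len, ops$op), collapse = "")
}

#' @rdname ops_to_cigar
#' @param cigar CIGAR string.
#' @export
cigar_to_ops <- function(cigar) {
  m <- gregexpr("[0-9]+[=XIDM]", cigar)[[1L]]
  toks <- regmatches(cigar, list(m))[[1L]]
  data.frame(op = substr(toks, nchar(toks), nchar(toks)),
             len = as.integer(substr(toks, 1L, nchar(toks) - 1L)))
}

# reconstruct the read from the reference and an ops walk (CIGAR consistency)
reconstruct_read <- function(ops, ref, ref_start, read = NULL) {
  ri <- ref_start
  out <- character(0)
  qi <- 0L
  for (k in seq_len(nrow(ops))) {
    o <- ops$op[k]
    l <- ops$len[k]
    if (o %in% c("=", "M")) {
      out <- c(out, substr0(ref, ri, ri + l))
      ri <- ri + l
      qi <- qi + l
    } else if (o == "X") {
      seg <- if (is.null(read)) strrep("N", l) else
        substr(read, qi + 1L, qi + l)
      out <- c(out, seg)
      ri <- ri + l
      qi <- qi + l
    } else if (o == "I") {
      seg <- if (is.null(read)) strrep("N", l) else
        substr(read, qi + 1L, qi + l)
      out <- c(out, seg)
      qi <- qi + l
    } else {
      ri <- ri + l
    }
  }
  paste0(out, collapse = "")
}

#' Align a read set to a single-sequence amplicon reference
#'
#' Trims 3' adapter read-through when the design is supplied, deduplicates
#' identical trimmed sequences, aligns each distinct sequence once with
#' [semiglobal_align()], and expands back to per-read records. Reads are not
#' reverse-complement searched by default (read-1 geometry is known); set
#' `both_strands = TRUE` to also try the reverse complement and keep the
#' better score.
#'
#' @param reads A `read_set`, a data.frame with `id`/`seq`, a named character
#'   vector, or a FASTQ path.
#' @param ref Reference: single-sequence named character vector, a
#'   `library_design` (its amplicon is used and its adapter is trimmed), or a
#'   FASTA path with exactly one sequence.
#' @param scheme A `scoring_scheme`.
#' @param both_strands Also try reverse-complemented reads.
#' @param trim Trim adapter read-through first (needs a `library_design`).
#' @return An `alignment_set`: list with `records` data.frame (`qname`,
#'   `aligned`, `ref_start`, `cigar`, `score`, `seq`), `summary`
#'   (`n_reads`, `n_aligned`, `n_unaligned`), `ref_name`, `ref_len`.
#' @export
align_set <- function(reads, ref, scheme = scoring_scheme(),
                      both_strands = FALSE, trim = TRUE) {
  design <- NULL
  if (inherits(ref, "library_design")) {
    design <- ref
    ref_seq <- design$amplicon$seq
    ref_name <- design$target$name
  } else if (is.character(ref) && length(ref) == 1L && file.exists(ref) &&
             grepl("\\.(fa|fasta|fa\\.gz|fasta\\.gz)$", ref)) {
    fa <- read_fasta(ref)
    if (length(fa) != 1L) {
      stop("amplicon mode needs a single-sequence reference (got ",
           length(fa), ")", call. = FALSE)
    }
    ref_seq <- unname(fa[1L])
    ref_name <- names(fa)[1L]
  } else {
    if (length(ref) != 1L) {
      stop("amplicon mode needs a single-sequence reference", call. = FALSE)
    }
    ref_seq <- unname(ref)
    ref_name <- if (!is.null(names(ref))) names(ref)[1L] else "amplicon"
  }
  if (inherits(reads, "read_set")) reads <- reads$reads
  if (is.character(reads) && length(reads) == 1L && file.exists(reads)) {
    reads <- read_fastq(reads)
  }
  if (is.character(reads)) {
    reads <- data.frame(id = if (is.null(names(reads)))
      sprintf("read%06d", seq_along(reads)) else names(reads),
      seq = unname(reads))
  }
  seqs <- toupper(reads$seq)
  if (trim && !is.null(design)) {
    seqs <- trim_adapter(seqs, design_read1_adapter(design))
  }
  if (nrow(reads) == 0L) {
    return(structure(list(
      records = data.frame(qname = character(), aligned = logical(),
                           ref_start = integer(), cigar = character(),
                           score = integer(), seq = character()),
      summary = list(n_reads = 0L, n_aligned = 0L, n_unaligned = 0L),
      ref_name = ref_name, ref_len = nchar(ref_seq)),
      class = "alignment_set"))
  }
  uniq <- unique(seqs)
  idx <- match(seqs, uniq)
  urec <- lapply(uniq, function(s) {
    rec <- semiglobal_align(s, ref_seq, scheme)
    if (both_strands) {
      rc <- semiglobal_align(revcomp(s), ref_seq, scheme)
      if (rc$score > rec$score) rec <- rc
    }
    rec
  })
  records <- data.frame(
    qname = reads$id,
    aligned = vapply(urec, `[[`, logical(1), "aligned")[idx],
    ref_start = vapply(urec, `[[`, integer(1), "ref_start")[idx],
    cigar = vapply(urec, `[[`, character(1), "cigar")[idx],
    score = vapply(urec, `[[`, integer(1), "score")[idx],
    seq = seqs)
  n_aligned <- sum(records$aligned)
  structure(list(records = records,
                 summary = list(n_reads = nrow(records),
                                n_aligned = n_aligned,
                                n_unaligned = nrow(records) - n_aligned),
                 ref_name = ref_name, ref_len = nchar(ref_seq)),
            class = "alignment_set")
}

#' @export
print.alignment_set <- function(x, ...) {
  cat(sprintf("Alignment set: %d reads vs %s (%d bp): %d aligned, %d unaligned\n",
              x$summary$n_reads, x$ref_name, x$ref_len,
              x$summary$n_aligned, x$summary$n_unaligned))
  invisible(x)
}
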