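# Per-position coverage and deletion ("absence rate") profiling, treated vs
# control comparison, and the read-level editing call. Only D operations
# count as missing bases: substitution errors and insertions never inflate
# the deletion signal.

# walk each distinct (ref_start, cigar) pair once; returns per-pair span and
# deletion intervals plus a weight (= number of reads with that alignment)
distinct_walks <- function(records) {
  rec <- records[records$aligned, , drop = FALSE]
  if (!nrow(rec)) {
    return(list(key = character(0), weight = integer(0), walks = list()))
  }
  key <- paste(rec$ref_start, rec$cigar, sep = "/")
  tab <- table(key)
  first <- rec[!duplicated(key), , drop = FALSE]
  fkey <- paste(first$ref_start, first$cigar, sep = "/")
  walks <- lapply(seq_len(nrow(first)), function(i) {
    ops <- cigar_to_ops(first$cigar[i])
    ri <- first$ref_start[i]
    dels <- list()
    for (k in seq_len(nrow(ops))) {
      if (ops$op[k] %in% c("=", "X", "M", "D")) {
        if (ops$op[k] == "D") {
          dels[[length(dels) + 1L]] <- c(ri, ri + ops$len[k])
        }
        ri <- ri + ops$len[k]
      }
    }
    list(start = first$ref_start[i], end = ri, dels = dels)
  })
  list(key = fkey, weight = as.integer(tab[fkey]), walks = walks)
}

#' Per-position deletion profile
#'
#' For every reference position, `coverage` counts aligned reads whose
#' reference span contains the position and `deletions` counts aligned reads
#' with a D operation covering it. Insertions do not contribute; unmapped
#' reads are ignored. `absence_rate` is `deletions / coverage` (0, flagged,
#' where coverage is 0).
#'
#' @param alignments An `alignment_set`, its `records` data.frame, or a SAM
#'   path written by [write_sam()].
#' @param ref_length Reference length; taken from the alignment set / SAM
#'   header when omitted.
#' @param sample Sample label stored in the profile.
#' @return A `deletion_profile`: data.frame with columns `position` (0-based),
#'   `coverage`, `deletions`, `absence_rate`, plus attributes `sample`,
#'   `mean_coverage`, `undefined_positions`.
#' @export
deletion_profile <- function(alignments, ref_length = NULL,
                             sample = "sample") {
  if (is.character(alignments) && length(alignments) == 1L) {
    sam <- read_sam(alignments)
    if (is.null(ref_length)) ref_length <- sam$ref$length
    records <- sam$records
  } else if (inherits(alignments, "alignment_set")) {
    if (is.null(ref_length)) ref_length <- alignments$ref_len
    records <- alignments$records
  } else {
    records <- alignments
  }
  if (is.null(ref_length)) stop("ref_length required", call. = FALSE)
  ref_length <- as.integer(ref_length)
  dw <- distinct_walks(records)
  cov_d <- integer(ref_length + 1L)
  del_d <- integer(ref_length + 1L)
  for (i in seq_along(dw$walks)) {
    w <- dw$walks[[i]]
    wt <- dw$weight[i]
    if (w$end > ref_length) {
      stop("malformed-record: alignment overruns the reference (end ",
           w$end, " > ", ref_length, ")", call. = FALSE)
    }
    cov_d[w$start + 1L] <- cov_d[w$start + 1L] + wt
    cov_d[w$end + 1L] <- cov_d[w$end + 1L] - wt
    for (dl in w$dels) {
      del_d[dl[1L] + 1L] <- del_d[dl[1L] + 1L] + wt
      del_d[dl[2L] + 1L] <- del_d[dl[2L] + 1L] - wt
    }
  }
  coverage <- cumsum(cov_d)[seq_len(ref_length)]
  deletions <- cumsum(del_d)[seq_len(ref_length)]
  undef <- coverage == 0L
  rate <- ifelse(undef, 0, deletions / pmax(coverage, 1L))
  out <- data.frame(position = seq_len(ref_length) - 1L, coverage = coverage,
                    deletions = deletions, absence_rate = rate)
  structure(out, class = c("deletion_profile", "data.frame"),
            sample = sample, mean_coverage = mean(coverage),
            undefined_positions = sum(undef))
}

#' Fraction of aligned reads carrying a deletion
#'
#' Fraction of aligned reads having at least one D operation of length >=
#' `min_del_len` intersecting the window. Reads that fail alignment are in
#' neither numerator nor denominator.
#'
#' @param alignments An `alignment_set` (or records data.frame / SAM path).
#' @param min_del_len Minimum deletion length counted.
#' @param window 0-based half-open reference interval `c(start, end)`, or
#'   `NULL` for the whole amplicon.
#' @return List with `fraction`, `n_deleted`, `n_aligned`.
#' @export
edited_read_fraction <- function(alignments, min_del_len = 1L,
                                 window = NULL) {
  records <- if (inherits(alignments, "alignment_set")) alignments$records
    else if (is.character(alignments)) read_sam(alignments)$records
    else alignments
  n_aligned <- sum(records$aligned)
  if (n_aligned == 0L) {
    stop("undefined-fraction: no aligned reads", call. = FALSE)
  }
  dw <- distinct_walks(records)
  hit <- vapply(dw$walks, function(w) {
    for (dl in w$dels) {
      if (dl[2L] - dl[1L] >= min_del_len &&
          (is.null(window) || (dl[1L] < window[2L] && dl[2L] > window[1L]))) {
        return(TRUE)
      }
    }
    FALSE
  }, logical(1))
  n_deleted <- sum(dw$weight[hit])
  list(fraction = n_deleted / n_aligned, n_deleted = n_deleted,
       n_aligned = n_aligned)
}

#' Compare treated and control deletion profiles
#'
#' Emits the per-position absence-rate difference (treated minus control) and
#' the peak position (argmax of the difference; ties resolved to the smallest
#' coordinate). A flat difference is flagged degenerate.
#'
#' @param treated,control `deletion_profile`s over the same reference length.
#' @return List with `table` (position, rates, difference), `peak_position`,
#'   `degenerate`.
#' @export
compare_profiles <- function(treated, control) {
  if (nrow(treated) != nrow(control)) {
    stop("profiles have different reference lengths", call. = FALSE)
  }
  diff <- treated$absence_rate - control$absence_rate
  tab <- data.frame(position = treated$position,
                    rate_treated = treated$absence_rate,
                    rate_control = control$absence_rate,
                    difference = diff)
  peak <- treated$position[which.max(diff)]
  list(table = tab, peak_position = peak,
       degenerate = max(diff) <= min(diff) + .Machine$double.eps)
}

#' Call whether cell-specific editing occurred
#'
#' Read-level two-sided Fisher exact test on the 2x2 table
#' (deleted, non-deleted) x (treated, control), using this package's
#' [fisher_exact_2x2()]. Editing is detected when p < alpha and the treated
#' deleted-read fraction exceeds the control's.
#'
#' @param treated,control `alignment_set`s (or SAM paths) for the treated and
#'   matched unedited control samples over the same amplicon.
#' @param alpha Significance level (default 0.01).
#' @param min_del_len Minimum deletion length counted.
#' @param window Optional 0-based half-open window around the cut site;
#'   `NULL` uses the whole amplicon.
#' @return An `edit_call`: list with the two fractions and counts, `p_value`,
#'   `detected`, `peak_position`, `window`.
#' @export
call_editing <- function(treated, control, alpha = 0.01, min_del_len = 1L,
                         window = NULL) {
  as_set <- function(x) {
    if (is.character(x)) {
      sam <- read_sam(x)
      structure(list(records = sam$records, ref_len = sam$ref$length,
                     ref_name = sam$ref$name,
                     summary = list(n_reads = nrow(sam$records),
                                    n_aligned = sum(sam$records$aligned))),
                class = "alignment_set")
    } else {
      x
    }
  }
  treated <- as_set(treated)
  control <- as_set(control)
  if (treated$ref_len != control$ref_len) {
    stop("treated and control were not aligned to the same amplicon",
         call. = FALSE)
  }
  ft <- edited_read_fraction(treated, min_del_len, window)
  fc <- edited_read_fraction(control, min_del_len, window)
  p <- as.numeric(fisher_exact_2x2(ft$n_deleted, ft$n_aligned - ft$n_deleted,
                                   fc$n_deleted, fc$n_aligned - fc$n_deleted))
  cmp <- compare_profiles(deletion_profile(treated, sample = "treated"),
                          deletion_profile(control, sample = "control"))
  structure(list(edited_read_fraction_treated = ft$fraction,
                 edited_read_fraction_control = fc$fraction,
                 counts_treated = c(deleted = ft$n_deleted,
                                    aligned = ft$n_aligned),
                 counts_control = c(deleted = fc$n_deleted,
                                    aligned = fc$n_aligned),
                 p_value = p,
                 detected = (p < alpha) && (ft$fraction > fc$fraction),
                 peak_position = cmp$peak_position,
                 peak_degenerate = cmp$degenerate,
                 window = if (is.null(window)) c(0L, treated$ref_len)
                   else as.integer(window),
                 alpha = alpha),
            class = "edit_call")
}

#' @export
print.edit_call <- function(x, ...) {
  cat(sprintf("Edit call: %s (p = %.3g, alpha = %g)\n",
              if (x$detected) "EDITING DETECTED" else "no editing detected",
              x$p_value, x$alpha))
  cat(sprintf("  treated deleted-read fraction: %.4f (%d / %d)\n",
              x$edited_read_fraction_treated, x$counts_treated["deleted"],
              x$counts_treated["aligned"]))
  cat(sprintf("  control deleted-read fraction: %.4f (%d / %d)\n",
              x$edited_read_fraction_control, x$counts_control["deleted"],
              x$counts_control["aligned"]))
  cat(sprintf("  peak difference at position %d%s\n", x$peak_position,
              if (x$peak_degenerate) " (degenerate: flat difference)" else ""))
  invisible(x)
}

#' Per-position binomial tests of treated vs control absence rates
#'
#' Exposed for exploration; the headline editing call is read-level, not
#' position-level (see [call_editing()]).
#'
#' @param treated,control `deletion_profile`s of equal length.
#' @return data.frame with `position`, counts, and a per-position exact
#'   binomial p-value (treated deletions against the control rate).
#' @export
position_binomial_tests <- function(treated, control) {
  if (nrow(treated) != nrow(control)) {
    stop("profiles have different reference lengths", call. = FALSE)
  }
  p0 <- pmin(pmax(control$absence_rate, 1e-12), 1 - 1e-12)
  pv <- vapply(seq_len(nrow(treated)), function(i) {
    if (treated$coverage[i] == 0L) return(NA_real_)
    stats::binom.test(treated$deletions[i], treated$coverage[i],
                      p = p0[i])$p.value
  }, numeric(1))
  data.frame(position = treated$position,
             deletions_treated = treated$deletions,
             coverage_treated = treated$coverage,
             deletions_control = control$deletions,
             coverage_control = control$coverage, p_value = pv)
}

#' Write / read a deletion profile TSV
#'
#' Machine-readable twin of the per-position deletion plots: columns
#' `position`, `coverage`, `deletions`, `absence_rate`.
#'
#' @param profile A `deletion_profile`.
#' @param path TSV path.
#' @export
write_profile <- function(profile, path) {
  write_tsv(as.data.frame(profile), path)
}

#' @rdname write_profile
#' @export
read_profile <- function(path) {
  out <- read_tsv(path)
  structure(out, class = c("deletion_profile", "data.frame"),
            sample = sub("\\.tsv$", "", basename(path)),
            mean_coverage = mean(out$coverage),
            undefined_positions = sum(out$coverage == 0))
}
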