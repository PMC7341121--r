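# Mosaic-population read simulation. Only a fraction of cells carry a
# Cas9-induced deletion anchored at the cut site; alleles whose deletion
# removes a primer binding site cannot be amplified and drop out of the
# library, which is the mechanism that makes observed deleted-read fractions
# underestimate the edited-cell fraction.

#' Edit model for a mosaic population
#'
#' Deletion lengths follow a geometric distribution (mean `del_len_mean`)
#' truncated at `max_del_len`; `floor(len * left_extent_frac)` deleted bases
#' are placed 5' of the cut site and the remainder 3', so every deletion
#' contains or abuts the cut. Defaults emulate continuous transgenic Cas9
#' exposure in body-wall muscle: 10% edited cells, full editing within them,
#' and deletions extending mostly 3' of the PAM-proximal cut.
#'
#' @param edited_cell_fraction Fraction of cells carrying the Cas9 transgene
#'   activity (default 0.10, the body-wall-muscle share of L1/L3 cells).
#' @param per_allele_edit_prob Editing efficiency within edited cells.
#' @param del_len_mean Mean deletion length (bp) before truncation.
#' @param max_del_len Maximum deletion length (bp).
#' @param left_extent_frac Share of deleted bases placed 5' of the cut.
#' @param insertion_prob Probability an edit is an insertion instead of a
#'   deletion (default 0; the deletion readout ignores inserted bases).
#' @return An `edit_model`.
#' @export
edit_model <- function(edited_cell_fraction = 0.10, per_allele_edit_prob = 1,
                       del_len_mean = 25, max_del_len = 160,
                       left_extent_frac = 0.3, insertion_prob = 0) {
  probs <- c(edited_cell_fraction, per_allele_edit_prob, left_extent_frac,
             insertion_prob)
  if (any(probs < 0 | probs > 1)) {
    stop("probabilities must lie in [0, 1]", call. = FALSE)
  }
  if (del_len_mean < 1 || max_del_len < 1) {
    stop("del_len_mean and max_del_len must be >= 1", call. = FALSE)
  }
  structure(list(edited_cell_fraction = edited_cell_fraction,
                 per_allele_edit_prob = per_allele_edit_prob,
                 del_len_mean = del_len_mean,
                 max_del_len = as.integer(max_del_len),
                 left_extent_frac = left_extent_frac,
                 insertion_prob = insertion_prob),
            class = "edit_model")
}

#' Read-simulation parameters
#'
#' @param n_reads Number of reads (default 100000, the stated per-sample
#'   minimum).
#' @param read_len Read length (default 250 nt single-end; the platform mode
#'   is not on record, this is a stand-in).
#' @param subst_error_rate Per-base substitution error probability.
#' @param seed RNG seed.
#' @return A `read_sim_params`.
#' @export
read_sim_params <- function(n_reads = 100000L, read_len = 250L,
                            subst_error_rate = 0.001, seed = 1L) {
  n_reads <- as.integer(n_reads)
  read_len <- as.integer(read_len)
  if (n_reads < 1L) stop("n_reads must be >= 1", call. = FALSE)
  if (read_len < 20L) stop("read_len must be >= 20", call. = FALSE)
  if (subst_error_rate < 0 || subst_error_rate > 1) {
    stop("subst_error_rate must lie in [0, 1]", call. = FALSE)
  }
  structure(list(n_reads = n_reads, read_len = read_len,
                 subst_error_rate = subst_error_rate,
                 seed = as.integer(seed)),
            class = "read_sim_params")
}

# geometric lengths (support 1, 2, ...) with mean m, truncated at max_len.
# Inverse-CDF sampling: one uniform per event, so with a fixed seed the drawn
# length is nondecreasing in max_len (dropout monotonicity holds exactly).
rgeom_trunc <- function(n, m, max_len) {
  if (n == 0L) return(integer(0))
  p <- 1 / m
  u <- stats::runif(n) * stats::pgeom(max_len - 1L, p)
  as.integer(stats::qgeom(u, p)) + 1L
}

#' Simulate a mosaic allele population
#'
#' Each allele is independently edited with probability
#' `edited_cell_fraction * per_allele_edit_prob`. An allele is amplifiable
#' unless its deletion interval intersects either primer binding site.
#'
#' @param design A `library_design`; its target must carry a cut site.
#' @param model An `edit_model`.
#' @param n_alleles Number of alleles to draw.
#' @param seed RNG seed (deterministic output for a fixed seed).
#' @return A `mosaic_population`: list with `alleles` truth data.frame
#'   (`allele_id`, `edited`, `del_start`, `del_len`, `ins_len`,
#'   `amplifiable`) and the `design`.
#' @export
simulate_population <- function(design, model, n_alleles, seed = 1L) {
  stopifnot(inherits(design, "library_design"), inherits(model, "edit_model"))
  cut <- design$target$cut_site
  if (is.null(cut)) stop("design target has no sgRNA/cut site", call. = FALSE)
  n_alleles <- as.integer(n_alleles)
  amp <- design$amplicon
  with_seed(seed, {
    edited <- stats::runif(n_alleles) <
      model$edited_cell_fraction * model$per_allele_edit_prob
    ne <- sum(edited)
    del_start <- rep(NA_integer_, n_alleles)
    del_len <- rep(NA_integer_, n_alleles)
    ins_len <- rep(NA_integer_, n_alleles)
    if (ne > 0L) {
      len <- rgeom_trunc(ne, model$del_len_mean, model$max_del_len)
      is_ins <- stats::runif(ne) < model$insertion_prob
      nleft <- as.integer(floor(len * model$left_extent_frac))
      s <- cut - nleft
      e <- s + len
      ref_len <- nchar(design$target$reference_seq)
      if (any(!is_ins & (s < 0L | e > ref_len))) {
        stop("edit model places deletions outside the reference ",
             "(bounds error); reduce max_del_len", call. = FALSE)
      }
      del_start[edited] <- ifelse(is_ins, NA_integer_, s)
      del_len[edited] <- ifelse(is_ins, NA_integer_, len)
      ins_len[edited] <- ifelse(is_ins, len, NA_integer_)
    }
    # dropout: deletion interval intersects a primer site interval
    hit <- function(s, e, site) !is.na(s) & (s < site[2L]) & (e > site[1L])
    de <- del_start + del_len
    amplifiable <- !(hit(del_start, de, amp$fwd_site) |
                       hit(del_start, de, amp$rev_site))
    alleles <- data.frame(allele_id = sprintf("allele%05d", seq_len(n_alleles)),
                          edited = edited, del_start = del_start,
                          del_len = del_len, ins_len = ins_len,
                          amplifiable = amplifiable)
    structure(list(alleles = alleles, design = design, model = model,
                   seed = as.integer(seed)),
              class = "mosaic_population")
  })
}

# amplicon sequence of one allele (deletion/insertion applied); random
# insert bases are drawn deterministically from the allele id hash
allele_amplicon <- function(pop, i) {
  d <- pop$design
  amp <- d$amplicon
  a <- pop$alleles[i, ]
  if (!a$edited) return(amp$seq)
  cut_in_amp <- d$target$cut_site - amp$start
  if (!is.na(a$del_len)) {
    s <- a$del_start - amp$start
    e <- s + a$del_len
    s2 <- max(s, 0L)
    e2 <- min(e, nchar(amp$seq))
    return(paste0(substr0(amp$seq, 0L, s2), substr0(amp$seq, e2,
                                                    nchar(amp$seq))))
  }
  ins <- paste(sample(c("A", "C", "G", "T"), a$ins_len, replace = TRUE),
               collapse = "")
  paste0(substr0(amp$seq, 0L, cut_in_amp), ins,
         substr0(amp$seq, cut_in_amp, nchar(amp$seq)))
}

#' Simulate sequencing reads from a mosaic population
#'
#' Reads are drawn uniformly from the amplifiable alleles only. Read-1
#' geometry: each read starts at the base immediately 3' of the forward
#' adapter tail and runs `read_len` bases, reading through into the reverse
#' adapter (and index/P7) when the library molecule is shorter. Substitution
#' errors are i.i.d. per base; qualities are constant Q40 (`"I"`), which the
#' downstream analysis never uses.
#'
#' @param pop A `mosaic_population` (or a list of `SimulatedAllele` rows plus
#'   design, as returned by [simulate_population()]).
#' @param params A `read_sim_params`.
#' @return A `read_set`: list with `reads` data.frame (`id`, `seq`, `qual`)
#'   and `truth` data.frame (`read_id`, `allele_id`, `del_start`, `del_len`,
#'   `amplifiable`).
#' @export
simulate_reads <- function(pop, params = read_sim_params()) {
  stopifnot(inherits(pop, "mosaic_population"),
            inherits(params, "read_sim_params"))
  ok <- which(pop$alleles$amplifiable)
  if (!length(ok)) {
    stop("empty-library: no amplifiable alleles (total amplification dropout)",
         call. = FALSE)
  }
  d <- pop$design
  ix <- d$indices
  tail3 <- paste0(revcomp(d$rev$adapter_tail), revcomp(ix$i7_index),
                  revcomp(ix$p7_const))
  with_seed(params$seed, {
    # read template per amplifiable allele (insert + 3' adapter read-through)
    templates <- vapply(ok, function(i) {
      mol <- paste0(allele_amplicon(pop, i), tail3)
      substr(mol, 1L, min(params$read_len, nchar(mol)))
    }, character(1))
    pick <- sample.int(length(ok), params$n_reads, replace = TRUE)
    seqs <- templates[pick]
    # i.i.d. substitution errors
    if (params$subst_error_rate > 0) {
      lens <- nchar(seqs)
      nerr <- stats::rbinom(length(seqs), lens, params$subst_error_rate)
      which_err <- which(nerr > 0L)
      for (i in which_err) {
        posn <- sample.int(lens[i], nerr[i])
        ch <- strsplit(seqs[i], "", fixed = TRUE)[[1L]]
        for (p in posn) {
          ch[p] <- sample(setdiff(c("A", "C", "G", "T"), ch[p]), 1L)
        }
        seqs[i] <- paste(ch, collapse = "")
      }
    }
    ids <- sprintf("read%06d", seq_len(params$n_reads))
    al <- pop$alleles[ok[pick], ]
    reads <- data.frame(id = ids, seq = seqs,
                        qual = strrep("I", nchar(seqs)))
    truth <- data.frame(read_id = ids, allele_id = al$allele_id,
                        del_start = al$del_start, del_len = al$del_len,
                        amplifiable = al$amplifiable)
    structure(list(reads = reads, truth = truth, params = params),
              class = "read_set")
  })
}

#' Write a simulated read set to FASTQ plus a truth-table TSV
#'
#' @param rs A `read_set`.
#' @param fastq_path Output FASTQ (`.gz` supported).
#' @param truth_path Optional truth TSV path.
#' @export
write_read_set <- function(rs, fastq_path, truth_path = NULL) {
  stopifnot(inherits(rs, "read_set"))
  write_fastq(rs$reads, fastq_path)
  if (!is.null(truth_path)) write_tsv(rs$truth, truth_path)
  invisible(fastq_path)
}
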