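# Two-step amplicon library design: gene-specific tailed primers (PCR1), then
# indexed Illumina adapter primers (PCR2), with in-silico PCR against a
# reference. Coordinates are 0-based, half-open.

# Default Illumina flow-cell constants. P5/P7 are the standard clustering
# sequences (29 and 24 nt); index defaults are 6-mers, matching the indices
# used for amplicon multiplexing (i7 "CAGATC" is the i7_i07 index). The i5
# default is an arbitrary 6-mer placeholder: the i5 primer descriptor in the
# source protocol is an opaque label, not a sequence.
ILLUMINA_P5 <- "AATGATACGGCGACCACCGAGATCTACAC"
ILLUMINA_P7 <- "CAAGCAGAAGACGGCATACGAGAT"
DEFAULT_I5 <- "GCCAAT"
DEFAULT_I7 <- "CAGATC"

#' Describe a genomic target for amplicon sequencing
#'
#' A target is a reference sequence plus the region to be amplified and,
#' optionally, the sgRNA/PAM annotation. The blunt SpCas9 cut site is derived
#' as 3 bp 5' of the PAM (plus-strand sgRNA).
#'
#' @param name Target name.
#' @param reference_seq Reference DNA (plus strand).
#' @param region_start,region_end 0-based half-open amplified region.
#' @param sgrna_seq 20-nt sgRNA protospacer sequence, or `NULL`.
#' @param pam_offset 0-based position of the first PAM base on
#'   `reference_seq`, or `NULL` when no sgRNA is given.
#' @return A `genomic_target` object with derived field `cut_site`.
#' @export
genomic_target <- function(name, reference_seq, region_start, region_end,
                           sgrna_seq = NULL, pam_offset = NULL) {
  reference_seq <- dna_norm(reference_seq, "reference_seq", allow_n = TRUE)
  n <- nchar(reference_seq)
  region_start <- as.integer(region_start)
  region_end <- as.integer(region_end)
  if (!(region_start >= 0L && region_start < region_end && region_end <= n)) {
    stop("require 0 <= region_start < region_end <= length(reference_seq)",
         call. = FALSE)
  }
  cut_site <- NULL
  if (!is.null(sgrna_seq)) {
    sgrna_seq <- dna_norm(sgrna_seq, "sgrna_seq")
    if (nchar(sgrna_seq) != 20L) stop("sgrna_seq must be 20 nt", call. = FALSE)
    if (is.null(pam_offset)) stop("pam_offset required with sgrna_seq",
                                  call. = FALSE)
    pam_offset <- as.integer(pam_offset)
    cut_site <- pam_offset - 3L
    if (cut_site < region_start || cut_site > region_end) {
      stop("cut site must fall inside the amplified region", call. = FALSE)
    }
  }
  structure(list(name = name, reference_seq = reference_seq,
                 region_start = region_start, region_end = region_end,
                 sgrna_seq = sgrna_seq, pam_offset = pam_offset,
                 cut_site = cut_site),
            class = "genomic_target")
}

#' Build a PCR1 tailed primer
#'
#' A PCR1 primer is an Illumina adapter tail (5') concatenated with a
#' gene-specific 3' part. The gene-specific part must be a non-empty `ACGT`
#' string; an empty adapter tail yields a degenerate (untailed) primer.
#'
#' @param adapter_tail 5' adapter tail.
#' @param gene_specific 3' gene-specific part.
#' @param name Optional primer name.
#' @return A `primer_spec` with derived `full_seq`.
#' @export
#' @examples
#' p <- build_pcr1_primer("CGACAGGTTCAGAGTTCTACAGTCCGACGATC",
#'                        "cccacggtcgcaatatccgattc")
#' nchar(p$full_seq)  # 55
build_pcr1_primer <- function(adapter_tail, gene_specific, name = "") {
  if (!nzchar(gene_specific)) {
    stop("gene_specific must be non-empty", call. = FALSE)
  }
  adapter_tail <- dna_norm(adapter_tail, "adapter_tail")
  gene_specific <- dna_norm(gene_specific, "gene_specific")
  structure(list(name = name, adapter_tail = adapter_tail,
                 gene_specific = gene_specific,
                 full_seq = paste0(adapter_tail, gene_specific)),
            class = "primer_spec")
}

#' PCR2 index primer constants
#'
#' @param p5_const,p7_const Flow-cell clustering constants.
#' @param i5_index,i7_index Sample indices; must have equal length.
#' @return An `index_primer_set`.
#' @export
index_primer_set <- function(p5_const = ILLUMINA_P5, i5_index = DEFAULT_I5,
                             p7_const = ILLUMINA_P7, i7_index = DEFAULT_I7) {
  p5_const <- dna_norm(p5_const, "p5_const")
  p7_const <- dna_norm(p7_const, "p7_const")
  i5_index <- dna_norm(i5_index, "i5_index")
  i7_index <- dna_norm(i7_index, "i7_index")
  if (nchar(i5_index) != nchar(i7_index)) {
    stop("i5 and i7 indices must have equal length within a set",
         call. = FALSE)
  }
  structure(list(p5_const = p5_const, i5_index = i5_index,
                 p7_const = p7_const, i7_index = i7_index),
            class = "index_primer_set")
}

#' In-silico PCR of a primer pair against a target
#'
#' Finds the unique exact occurrence of the forward gene-specific sequence on
#' the plus strand and of the reverse complement of the reverse gene-specific
#' sequence downstream of it, and returns the plus-strand amplicon including
#' both primer sites. No mismatches are tolerated; zero matches or more than
#' one valid pairing are errors (never a silent first-hit choice).
#'
#' @param target A `genomic_target`.
#' @param fwd,rev `primer_spec` objects (PCR1 primers).
#' @return List with `seq` (amplicon), `start`, `end` (0-based half-open on
#'   the reference), `fwd_site`, `rev_site` (length-2 integer intervals).
#' @export
in_silico_pcr <- function(target, fwd, rev) {
  stopifnot(inherits(target, "genomic_target"),
            inherits(fwd, "primer_spec"), inherits(rev, "primer_spec"))
  ref <- target$reference_seq
  find_all <- function(pat) {
    m <- gregexpr(pat, ref, fixed = TRUE)[[1L]]
    if (m[1L] == -1L) integer(0) else as.integer(m) - 1L
  }
  fstarts <- find_all(fwd$gene_specific)
  rstarts <- find_all(revcomp(rev$gene_specific))
  flen <- nchar(fwd$gene_specific)
  rlen <- nchar(rev$gene_specific)
  if (!length(fstarts) || !length(rstarts)) {
    stop("primer-not-found: no exact binding site for ",
         if (!length(fstarts)) "forward" else "reverse", " primer",
         call. = FALSE)
  }
  pairs <- expand.grid(f = fstarts, r = rstarts)
  pairs <- pairs[pairs$r >= pairs$f + flen, , drop = FALSE]
  if (nrow(pairs) == 0L) {
    stop("primer-not-found: no forward site upstream of a reverse site",
         call. = FALSE)
  }
  if (nrow(pairs) > 1L) {
    stop("ambiguous-priming: ", nrow(pairs),
         " valid forward/reverse pairings found", call. = FALSE)
  }
  start <- pairs$f[1L]
  end <- pairs$r[1L] + rlen
  list(seq = substr0(ref, start, end), start = start, end = end,
       fwd_site = c(start, start + flen), rev_site = c(end - rlen, end))
}

#' Assemble a full library design
#'
#' Runs in-silico PCR and records the derived PCR1/PCR2 molecule lengths.
#'
#' @param target A `genomic_target`.
#' @param fwd,rev PCR1 `primer_spec`s.
#' @param indices An `index_primer_set`.
#' @return A `library_design` with fields `amplicon`, `pcr1_len`, `pcr2_len`.
#' @export
library_design <- function(target, fwd, rev, indices = index_primer_set()) {
  amp <- in_silico_pcr(target, fwd, rev)
  pcr1_len <- nchar(amp$seq) + nchar(fwd$adapter_tail) + nchar(rev$adapter_tail)
  pcr2_len <- pcr1_len + nchar(indices$p5_const) + nchar(indices$i5_index) +
    nchar(indices$p7_const) + nchar(indices$i7_index)
  structure(list(target = target, fwd = fwd, rev = rev, indices = indices,
                 amplicon = amp, pcr1_len = pcr1_len, pcr2_len = pcr2_len),
            class = "library_design")
}

#' Predict the final (PCR2) library molecule
#'
#' The sequenced molecule is, 5' to 3' on the plus strand:
#' P5, i5 index, forward adapter tail, insert (amplicon, primer sites
#' included), reverse-complemented reverse adapter tail, reverse-complemented
#' i7 index, reverse-complemented P7.
#'
#' @param design A `library_design`.
#' @param insert Optional replacement insert sequence (e.g. an edited allele's
#'   amplicon); defaults to the design's reference amplicon.
#' @return List with `seq` and `length`.
#' @export
predict_library_molecule <- function(design, insert = NULL) {
  stopifnot(inherits(design, "library_design"))
  if (is.null(insert)) insert <- design$amplicon$seq
  ix <- design$indices
  seq <- paste0(ix$p5_const, ix$i5_index, design$fwd$adapter_tail, insert,
                revcomp(design$rev$adapter_tail), revcomp(ix$i7_index),
                revcomp(ix$p7_const))
  list(seq = seq, length = nchar(seq))
}

# PCR1-only molecule (tails + insert), used by tests and the simulator
pcr1_molecule <- function(design, insert = NULL) {
  if (is.null(insert)) insert <- design$amplicon$seq
  paste0(design$fwd$adapter_tail, insert, revcomp(design$rev$adapter_tail))
}

#' Read a PCR1 primer table
#'
#' TSV with columns `name`, `adapter_tail`, `gene_specific`. The packaged
#' fixture `table1_primers.tsv` holds the four published primer pairs for the
#' etr-1 exon 8 and mab-5 amplicons.
#'
#' @param path TSV path.
#' @return Named list of `primer_spec`s.
#' @export
read_primer_table <- function(path) {
  tab <- read_tsv(path)
  need <- c("name", "adapter_tail", "gene_specific")
  if (!all(need %in% names(tab))) {
    stop("primer table must have columns: ", paste(need, collapse = ", "),
         call. = FALSE)
  }
  out <- lapply(seq_len(nrow(tab)), function(i) {
    build_pcr1_primer(tab$adapter_tail[i], tab$gene_specific[i], tab$name[i])
  })
  names(out) <- tab$name
  out
}

# fixed synthetic filler so the demo locus is identical across sessions;
# generated once from a uniform base draw and frozen here
.SYNTH_FILLER <- paste0(
  "TCTGAACGGACTAAGGCTTCATCGAGTATCCGTTGAAACTCGGCTTAAGTCCGCTAGCTGTTAACGTCCT",
  "AGATCGGTATGCCAAGTTCCTAGGATACGCTTGGCATCAACGGTTTACCTGAGCGATATTCGAGGCTTAC",
  "CTAGCATTCGGAACGTATCCGGTTAGCATCGATTGCCAAGCTTATCGGACGTTAGCCTAACGGATTCGCA",
  "TGGCTAAGCGTTACCGGATATCGCTTAAGCCGATGCATTCGGTTAACGCCTAGATCGGCATATCGCTTGA",
  "ACCGGTTAGCGATATCCGGCTTAAGCGATACCGTTAGCATCGGCTATACGGTTAAGCGCTATCCGGATTA",
  "GCGTTAACCGGCTATAGCGATTACCGGTTAGCGCTATACGGATTAGCCGTTAACGGCTATAGCGGTTACC",
  "GATTAGCGCTAACCGGATATGCGTTAGCCGATTACGGCTAAGCGGATACCGTTAGCGCTTAACGGATAGC",
  "CGTTAGCGGCTATACCGATTAGCGGTTAACCGCTATAGCGATTACCGGCTTAGCGATATCGCGTTAACCG",
  "GATTAGCGCTATACCGGTTAGCGATACGGCTTAAGCGGTTACCGATATGCGCTAAGCCGATTAGCGGCTA",
  "ACCGGATTAGCGTTATACCGGCTAAGCGATTACGCGTTAGCCGGATATACGCTTAGCGGATTACCGCTAA")

#' Construct the bundled synthetic demo locus
#'
#' Builds a deterministic 1-kb synthetic reference that embeds the published
#' etr-1 exon 8 PCR1 primer binding sites delimiting a 170-bp amplicon. The
#' intervening sequence and the sgRNA are synthetic stand-ins (the real
#' protospacer is not available in machine-readable form); the sgRNA is placed
#' so the PAM lies 24 bp downstream of the forward primer's 3' end, putting
#' the cut site PAM-proximal near the 5' side of the amplicon.
#'
#' @param fwd,rev PCR1 `primer_spec`s (default: the packaged etr-1 pair).
#' @param region_len Amplicon length in bp.
#' @param flank Reference flank length on each side of the amplicon.
#' @return A `genomic_target` named `"etr-1_exon8_synthetic"`.
#' @export
synthetic_target <- function(fwd = NULL, rev = NULL, region_len = 170L,
                             flank = 415L) {
  if (is.null(fwd) || is.null(rev)) {
    primers <- read_primer_table(system.file("extdata", "table1_primers.tsv",
                                             package = "crisprseq"))
    if (is.null(fwd)) fwd <- primers[["etr-1PCR1F"]]
    if (is.null(rev)) rev <- primers[["etr-1PCR1R"]]
  }
  fgs <- fwd$gene_specific
  rgs <- revcomp(rev$gene_specific)
  mid_len <- region_len - nchar(fgs) - nchar(rgs)
  if (mid_len < 30L) stop("region too short for primers + sgRNA",
                          call. = FALSE)
  filler <- .SYNTH_FILLER
  # middle = 4 nt spacer + 20 nt sgRNA + TGG PAM + filler
  sgrna <- substr(filler, 301, 320)
  middle <- paste0(substr(filler, 1, 4), sgrna, "TGG",
                   substr(filler, 31, 30 + mid_len - 27))
  amplicon <- paste0(fgs, middle, rgs)
  ref <- paste0(substr(filler, 101, 100 + flank), amplicon,
                substr(filler, 151, 150 + flank))
  region_start <- flank
  pam_offset <- region_start + nchar(fgs) + 24L
  tg <- genomic_target("etr-1_exon8_synthetic", ref, region_start,
                       region_start + region_len, sgrna, pam_offset)
  # the synthetic filler must not create spurious priming sites
  stopifnot(length(gregexpr(fgs, ref, fixed = TRUE)[[1L]]) == 1L,
            length(gregexpr(rgs, ref, fixed = TRUE)[[1L]]) == 1L)
  tg
}

#' @export
print.library_design <- function(x, ...) {
  cat("Amplicon library design:", x$target$name, "\n")
  cat("  amplicon:", x$amplicon$start, "-", x$amplicon$end,
      sprintf("(%d bp)", nchar(x$amplicon$seq)), "\n")
  cat("  PCR1 molecule:", x$pcr1_len, "bp; PCR2 molecule:", x$pcr2_len,
      "bp\n")
  if (!is.null(x$target$cut_site)) {
    cat("  cut site at reference position", x$target$cut_site, "\n")
  }
  invisible(x)
}
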