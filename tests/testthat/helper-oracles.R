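# Independent oracles and shared fixtures for the test suite. The oracles are
# deliberately separate code paths from the package implementation: a plain
# quadratic-space R dynamic program for alignment scores, and a choose()-based
# full enumeration for the Fisher test.

# affine-gap semi-global score by direct DP over R matrices (scores only)
oracle_semiglobal_score <- function(read, ref, match = 1, mismatch = -4,
                                    gap_open = -6, gap_extend = -1) {
  q <- strsplit(read, "")[[1L]]
  r <- strsplit(ref, "")[[1L]]
  n <- length(q)
  m <- length(r)
  NEG <- -1e9
  M <- matrix(NEG, n + 1L, m + 1L)
  D <- matrix(NEG, n + 1L, m + 1L)
  I <- matrix(NEG, n + 1L, m + 1L)
  M[1L, ] <- 0
  for (i in 2L:(n + 1L)) I[i, 1L] <- gap_open + (i - 2L) * gap_extend
  for (i in 2L:(n + 1L)) {
    for (j in 2L:(m + 1L)) {
      s <- if (q[i - 1L] == r[j - 1L] && q[i - 1L] != "N") match else mismatch
      M[i, j] <- s + max(M[i - 1L, j - 1L], D[i - 1L, j - 1L],
                         I[i - 1L, j - 1L])
      D[i, j] <- max(M[i, j - 1L] + gap_open, D[i, j - 1L] + gap_extend,
                     I[i, j - 1L] + gap_open)
      I[i, j] <- max(M[i - 1L, j] + gap_open, D[i - 1L, j] + gap_open,
                     I[i - 1L, j] + gap_extend)
    }
  }
  max(M[n + 1L, ], I[n + 1L, ])
}

# two-sided Fisher by full enumeration of all tables with the same margins
oracle_fisher_enum <- function(a, b, c, d) {
  r1 <- a + b
  r2 <- c + d
  c1 <- a + c
  if (r1 == 0 || r2 == 0) return(1)
  xs <- max(0, c1 - r2):min(r1, c1)
  prob <- vapply(xs, function(x) {
    choose(r1, x) * choose(r2, c1 - x) / choose(r1 + r2, c1)
  }, numeric(1))
  obs <- prob[match(a, xs)]
  sum(prob[prob <= obs * (1 + 1e-7)])
}

substr0 <- crisprseq:::substr0

random_dna <- function(n) {
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}

# cached default design (bundled primers, synthetic locus)
default_design <- local({
  d <- NULL
  function() {
    if (is.null(d)) d <<- crisprseq:::library_design_default()
    d
  }
})

# minimal synthetic design with controllable geometry for small tests
tiny_design <- function(region_len = 80L, flank = 40L, pam_gap = 10L,
                        seed = 99L) {
  crisprseq:::with_seed(seed, {
    fwd <- build_pcr1_primer("ACGTACGTAC", random_dna(12L), "tinyF")
    rev <- build_pcr1_primer("TTGCATTGCA", random_dna(12L), "tinyR")
    repeat {
      mid <- random_dna(region_len - 24L - 27L)
      sg <- random_dna(20L)
      amp <- paste0(fwd$gene_specific, substr(random_dna(4L), 1, 4L), sg,
                    "TGG", mid, revcomp(rev$gene_specific))
      ref <- paste0(random_dna(flank), amp, random_dna(flank))
      if (length(gregexpr(fwd$gene_specific, ref, fixed = TRUE)[[1L]]) == 1L &&
          length(gregexpr(revcomp(rev$gene_specific), ref,
                          fixed = TRUE)[[1L]]) == 1L) {
        break
      }
    }
    tg <- genomic_target("tiny", ref, flank, flank + nchar(amp),
                         sg, flank + 12L + 4L + 20L)
    library_design(tg, fwd, rev)
  })
}

# build an alignment records data.frame directly (for profiling tests)
fake_records <- function(ref_start, cigar, n = 1L, aligned = TRUE,
                         prefix = "fk") {
  data.frame(qname = sprintf("%s%04d", prefix, seq_len(n)),
             aligned = aligned, ref_start = ref_start, cigar = cigar,
             score = 0L, seq = "N")
}
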