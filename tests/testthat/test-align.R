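test_that("trim_adapter removes 3' read-through and nothing else", {
  d <- default_design()
  adapter <- crisprseq:::design_read1_adapter(d)
  # read carrying 12 adapter bases
  expect_identical(trim_adapter(paste0("ACGTACGT", substr(adapter, 1, 12)),
                                adapter), "ACGTACGT")
  # no adapter bases -> unchanged
  expect_identical(trim_adapter("ACGTACGTACGT", adapter), "ACGTACGTACGT")
  # read shorter than min_overlap -> unchanged
  expect_identical(trim_adapter("AC", adapter), "AC")
  # full adapter read-through
  expect_identical(trim_adapter(paste0("GGGG", adapter), adapter), "GGGG")
  expect_error(trim_adapter("ACGT", adapter, min_overlap = 2L),
               "min_overlap")
  # vectorized
  expect_identical(
    trim_adapter(c(paste0("AAAA", substr(adapter, 1, 6)), "CCCC"), adapter),
    c("AAAA", "CCCC"))
})

test_that("identity read aligns as a single = run", {
  d <- default_design()
  ref <- d$amplicon$seq
  rec <- semiglobal_align(substr(ref, 41, 140), ref)
  expect_identical(rec$ref_start, 40L)
  expect_identical(rec$cigar, "100=")
  expect_identical(rec$score, 100L)
  expect_true(rec$aligned)
})

test_that("a clean deletion is recovered at its leftmost placement", {
  d <- default_design()
  ref <- d$amplicon$seq
  for (cut0 in c(30L, 60L, 100L, 140L)) {
    for (L in c(1L, 3L, 5L, 12L)) {
      read <- paste0(substr0(ref, 0L, cut0),
                     substring(ref, cut0 + L + 1L))
      rec <- semiglobal_align(read, ref)
      expect_identical(sum(rec$ops$len[rec$ops$op == "D"]), L)
      expect_identical(nrow(rec$ops[rec$ops$op == "D", ]), 1L)
      # oracle: leftmost equivalent placement by direct enumeration
      valid <- Filter(function(p) {
        paste0(substr0(ref, 0L, p), substring(ref, p + L + 1L)) == read
      }, 0:(nchar(ref) - L))
      d_at <- rec$ref_start +
        cumsum(c(0L, ifelse(rec$ops$op %in% c("=", "X", "D"),
                            rec$ops$len, 0L)))[which(rec$ops$op == "D")]
      expect_identical(d_at, min(unlist(valid)))
    }
  }
})

test_that("an unrelated read is flagged unaligned", {
  d <- default_design()
  set.seed(77)
  rec <- semiglobal_align(random_dna(50L), d$amplicon$seq)
  expect_false(rec$aligned)
  expect_lt(rec$score, 0.6 * 50)
})

test_that("scores match the independent DP oracle on random pairs", {
  set.seed(101)
  for (i in 1:40) {
    read <- random_dna(sample(20:90, 1))
    # mix of related and unrelated references
    ref <- if (i %% 2 == 0) {
      paste0(random_dna(15), read, random_dna(15))
    } else {
      random_dna(sample(60:120, 1))
    }
    rec <- semiglobal_align(read, ref)
    expect_identical(rec$score,
                     as.integer(oracle_semiglobal_score(read, ref)))
  }
})

test_that("CIGAR reconstruction reproduces the read byte-for-byte", {
  d <- default_design()
  ref <- d$amplicon$seq
  set.seed(55)
  for (i in 1:25) {
    # mutate a substring of the reference: substitutions and indels
    start <- sample(0:40, 1)
    read <- substr0(ref, start, start + sample(80:120, 1))
    ch <- strsplit(read, "")[[1]]
    for (k in sample(seq_along(ch), 3)) ch[k] <- sample(c("A", "C", "G", "T"), 1)
    if (i %% 3 == 0) ch <- ch[-sample(seq_along(ch), 4)]
    if (i %% 3 == 1) ch <- append(ch, "ACGG", sample(seq_along(ch), 1))
    read <- paste(ch, collapse = "")
    rec <- semiglobal_align(read, ref)
    expect_identical(
      crisprseq:::reconstruct_read(rec$ops, ref, rec$ref_start, read), read)
    # ops invariants: read fully consumed, D never first/last, runs merged
    expect_identical(sum(rec$ops$len[rec$ops$op %in% c("=", "X", "I")]),
                     nchar(read))
    expect_false(rec$ops$op[1] == "D")
    expect_false(rec$ops$op[nrow(rec$ops)] == "D")
    expect_true(all(rle(rec$ops$op)$lengths == 1L))
  }
})

test_that("left-normalization is idempotent", {
  d <- default_design()
  ref <- d$amplicon$seq
  set.seed(66)
  for (i in 1:15) {
    start <- sample(0:30, 1)
    read <- substr0(ref, start, start + 100L)
    ch <- strsplit(read, "")[[1]]
    ch <- ch[-(sample(20:80, 1) + 0:3)]
    read <- paste(ch, collapse = "")
    rec <- semiglobal_align(read, ref)
    again <- crisprseq:::left_normalize(rec$ops, read, ref, rec$ref_start)
    expect_identical(again$ops, rec$ops)
    expect_identical(again$ref_start, rec$ref_start)
  }
})

test_that("align_set handles perfect, truth-labelled and empty inputs", {
  d <- default_design()
  # 1,000 error-free unedited reads -> all aligned
  pop <- simulate_population(d, edit_model(0), 5L, seed = 8)
  rs <- simulate_reads(pop, read_sim_params(1000L, subst_error_rate = 0,
                                            seed = 9))
  aln <- align_set(rs, d)
  expect_identical(aln$summary$n_aligned, 1000L)
  expect_identical(aln$summary$n_unaligned, 0L)
  expect_true(all(aln$records$cigar == "170="))
  # truth-labelled mixture: every aligned truth-deleted read carries a D op
  pop2 <- simulate_population(
    d, edit_model(edited_cell_fraction = 0.3, del_len_mean = 8,
                  max_del_len = 20), 200L, seed = 10)
  rs2 <- simulate_reads(pop2, read_sim_params(2000L, subst_error_rate = 0,
                                              seed = 11))
  aln2 <- align_set(rs2, d)
  deleted <- !is.na(rs2$truth$del_len)
  rec2 <- aln2$records
  expect_true(all(grepl("D", rec2$cigar[deleted & rec2$aligned])))
  expect_false(any(grepl("D", rec2$cigar[!deleted & rec2$aligned])))
  # summary counts conserved
  expect_identical(aln2$summary$n_aligned + aln2$summary$n_unaligned,
                   nrow(rec2))
  # empty input
  empty <- tempfile(fileext = ".fastq")
  file.create(empty)
  aln3 <- align_set(empty, d)
  expect_identical(aln3$summary$n_reads, 0L)
  unlink(empty)
})

test_that("multi-sequence references and bad schemes are rejected", {
  fa <- tempfile(fileext = ".fa")
  write_fasta(c(a = "ACGTACGTACGT", b = "TTTTACGT"), fa)
  expect_error(align_set(c(x = "ACGT"), fa), "single-sequence")
  unlink(fa)
  expect_error(scoring_scheme(match = -1), "match")
  expect_error(scoring_scheme(gap_open = -1, gap_extend = -2), "gap_open")
  expect_error(semiglobal_align("AC-T", "ACGT"), "invalid alphabet")
})
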