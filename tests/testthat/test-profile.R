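test_that("a single synthetic record places deletions exactly", {
  rec <- fake_records(5L, "10=3D10=")
  prof <- deletion_profile(rec, ref_length = 40L)
  expect_identical(prof$deletions[prof$position %in% 15:17], rep(1L, 3))
  expect_identical(sum(prof$deletions), 3L)
  expect_identical(prof$coverage[prof$position %in% 5:27], rep(1L, 23))
  expect_identical(sum(prof$coverage), 23L)
  # insertions do not contribute; unmapped records are ignored
  rec2 <- rbind(fake_records(0L, "5=2I5="),
                fake_records(0L, "10=", aligned = FALSE, prefix = "un"))
  prof2 <- deletion_profile(rec2, ref_length = 20L)
  expect_identical(sum(prof2$deletions), 0L)
  expect_identical(sum(prof2$coverage), 10L)
  # overrun -> malformed-record error
  expect_error(deletion_profile(fake_records(5L, "10=3D10="),
                                ref_length = 20L), "malformed-record")
})

test_that("null sample profiles to zero deletions everywhere", {
  d <- default_design()
  pop <- simulate_population(d, edit_model(0), 5L, seed = 3)
  rs <- simulate_reads(pop, read_sim_params(500L, subst_error_rate = 0,
                                            seed = 4))
  prof <- deletion_profile(align_set(rs, d))
  expect_true(all(prof$deletions == 0L))
  expect_true(all(prof$coverage == 500L))
  expect_identical(attr(prof, "mean_coverage"), 500)
})

test_that("a 50% fixed deletion shows binomially at deleted positions only", {
  d <- default_design()
  ref <- d$amplicon$seq
  cut <- d$target$cut_site - d$amplicon$start
  edited <- paste0(substr0(ref, 0L, cut - 2L), substring(ref, cut + 4L))
  set.seed(17)
  n <- 1000L
  from_edited <- runif(n) < 0.5
  reads <- ifelse(from_edited, edited, ref)
  aln <- align_set(stats::setNames(reads, sprintf("r%04d", 1:n)), ref,
                   trim = FALSE)
  prof <- deletion_profile(aln)
  k <- sum(from_edited)
  sd3 <- 3 * sqrt(n * 0.25)
  expect_lt(abs(k - 500), sd3)
  del_pos <- prof$position[prof$deletions > 0]
  expect_identical(length(del_pos), 5L)
  expect_true(all(prof$deletions[prof$deletions > 0] == k))
  expect_true(all(diff(del_pos) == 1L))
})

test_that("edited_read_fraction equals the truth fraction at zero error", {
  d <- default_design()
  pop <- simulate_population(
    d, edit_model(edited_cell_fraction = 0.2, del_len_mean = 6,
                  max_del_len = 15), 500L, seed = 23)
  rs <- simulate_reads(pop, read_sim_params(5000L, subst_error_rate = 0,
                                            seed = 24))
  aln <- align_set(rs, d)
  expect_identical(aln$summary$n_aligned, 5000L)  # small deletions all align
  fr <- edited_read_fraction(aln)
  expect_identical(fr$fraction, mean(!is.na(rs$truth$del_len)))
  # threshold limit: min_del_len above every simulated deletion -> 0
  fr0 <- edited_read_fraction(aln, min_del_len = 50L)
  expect_identical(fr0$n_deleted, 0L)
  # windowed: a window not containing the cut region sees nothing
  fr_far <- edited_read_fraction(aln, window = c(150L, 170L))
  expect_identical(fr_far$n_deleted, 0L)
  expect_error(edited_read_fraction(fake_records(0L, "5=",
                                                 aligned = FALSE)),
               "undefined-fraction")
})

test_that("profile conservation: column sums equal per-read deleted bases", {
  d <- default_design()
  pop <- simulate_population(d, edit_model(edited_cell_fraction = 0.25),
                             400L, seed = 27)
  rs <- simulate_reads(pop, read_sim_params(3000L, seed = 28))
  aln <- align_set(rs, d)
  prof <- deletion_profile(aln)
  per_read <- vapply(seq_len(nrow(aln$records)), function(i) {
    if (!aln$records$aligned[i]) return(0L)
    ops <- cigar_to_ops(aln$records$cigar[i])
    sum(ops$len[ops$op == "D"])
  }, integer(1))
  expect_identical(sum(prof$deletions), sum(per_read))
})

test_that("compare_profiles difference table and peak behave", {
  d <- default_design()
  rec <- fake_records(0L, "20=5D20=", n = 10L)
  treated <- deletion_profile(rec, 60L, "t")
  control <- deletion_profile(fake_records(0L, "45=", n = 10L), 60L, "c")
  cmp <- compare_profiles(treated, control)
  expect_identical(cmp$peak_position, 20L)  # ties -> smallest coordinate
  expect_false(cmp$degenerate)
  expect_true(all(cmp$table$difference[21:25] == 1))
  # identical profiles -> degenerate flat difference
  cmp0 <- compare_profiles(treated, treated)
  expect_true(cmp0$degenerate)
  expect_true(all(cmp0$table$difference == 0))
  # control higher at one position -> negative difference there
  cmp_neg <- compare_profiles(control, treated)
  expect_true(all(cmp_neg$table$difference[21:25] == -1))
  expect_error(compare_profiles(treated, deletion_profile(rec, 61L)),
               "different reference lengths")
})

test_that("call_editing applies the Fisher detection contract", {
  mk <- function(n_del, n_tot, ref_len = 100L) {
    structure(list(records = rbind(
      fake_records(10L, "30=4D30=", n = n_del, prefix = "del"),
      fake_records(10L, "64=", n = n_tot - n_del, prefix = "wt")),
      ref_len = ref_len, ref_name = "amp",
      summary = list(n_reads = n_tot, n_aligned = n_tot)),
      class = "alignment_set")
  }
  # identical samples -> p = 1, not detected
  same <- call_editing(mk(5L, 1000L), mk(5L, 1000L))
  expect_equal(same$p_value, 1)
  expect_false(same$detected)
  # 3/1000 vs 2/1000 -> not detected at alpha 0.01
  weak <- call_editing(mk(3L, 1000L), mk(2L, 1000L))
  expect_false(weak$detected)
  expect_equal(weak$p_value, oracle_fisher_enum(3, 997, 2, 998),
               tolerance = 1e-12)
  # 4% vs 0.05% at n = 100,000 -> detected, matching the Fisher oracle
  strong <- call_editing(mk(4000L, 100000L), mk(50L, 100000L))
  expect_true(strong$detected)
  expect_lt(strong$p_value, 1e-100)
  expect_identical(strong$peak_position, 40L)
  # degenerate direction: control above treated is never "detected"
  rev <- call_editing(mk(2L, 1000L), mk(30L, 1000L))
  expect_false(rev$detected)
})

test_that("parameter recovery without dropout across cell fractions", {
  d <- default_design()
  for (f in c(0.01, 0.05, 0.10)) {
    pop <- simulate_population(
      d, edit_model(edited_cell_fraction = f, del_len_mean = 5,
                    max_del_len = 12), 4000L, seed = round(1000 * f))
    expect_true(all(pop$alleles$amplifiable))  # dropout disabled by geometry
    rs <- simulate_reads(pop, read_sim_params(20000L, subst_error_rate = 0,
                                              seed = round(1000 * f) + 1L))
    fr <- edited_read_fraction(align_set(rs, d))
    sd3 <- 3 * sqrt(f * (1 - f) / 4000)  # allele-sampling binomial SD
    expect_lt(abs(fr$fraction - f), sd3 + 3 * sqrt(f / 20000))
  }
})

test_that("position_binomial_tests flags the deleted window", {
  rec_t <- rbind(fake_records(0L, "20=5D20=", n = 40L, prefix = "a"),
                 fake_records(0L, "45=", n = 60L, prefix = "b"))
  rec_c <- fake_records(0L, "45=", n = 100L, prefix = "c")
  pt <- deletion_profile(rec_t, 45L)
  pc <- deletion_profile(rec_c, 45L)
  res <- position_binomial_tests(pt, pc)
  expect_true(all(res$p_value[21:25] < 1e-6))
  expect_true(all(res$p_value[1:20] > 0.99))
})

test_that("profiles round-trip through TSV", {
  prof <- deletion_profile(fake_records(2L, "5=2D5="), 20L, "s")
  path <- tempfile(fileext = ".tsv")
  write_profile(prof, path)
  back <- read_profile(path)
  expect_equal(as.data.frame(back), as.data.frame(prof),
               ignore_attr = TRUE)
  unlink(path)
})
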