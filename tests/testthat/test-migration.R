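test_that("fisher_exact_2x2 reproduces published and trivial values", {
  # printed exact p-values that verify from their printed tallies
  expect_identical(signif(as.numeric(fisher_exact_2x2(86, 14, 74, 26)), 2),
                   0.051)
  expect_identical(signif(as.numeric(fisher_exact_2x2(98, 2, 88, 12)), 2),
                   0.010)
  expect_identical(signif(as.numeric(fisher_exact_2x2(100, 1, 94, 6)), 2),
                   0.065)
  # no association
  expect_identical(as.numeric(fisher_exact_2x2(50, 50, 50, 50)), 1)
  # degenerate margins -> p = 1 with flag
  p0 <- fisher_exact_2x2(0, 0, 3, 4)
  expect_identical(as.numeric(p0), 1)
  expect_true(attr(p0, "degenerate"))
  expect_error(fisher_exact_2x2(-1, 2, 3, 4), "nonnegative")
})

test_that("fisher_exact_2x2 equals exhaustive enumeration on small margins", {
  set.seed(123)
  for (i in 1:60) {
    r1 <- sample(1:12, 1)
    r2 <- sample(1:12, 1)
    a <- sample(0:r1, 1)
    c <- sample(0:r2, 1)
    expect_equal(as.numeric(fisher_exact_2x2(a, r1 - a, c, r2 - c)),
                 oracle_fisher_enum(a, r1 - a, c, r2 - c),
                 tolerance = 1e-12)
  }
})

test_that("fisher_exact_2x2 is symmetric under table symmetries", {
  set.seed(321)
  for (i in 1:30) {
    x <- sample(0:40, 4, replace = TRUE)
    p <- as.numeric(fisher_exact_2x2(x[1], x[2], x[3], x[4]))
    expect_equal(as.numeric(fisher_exact_2x2(x[3], x[4], x[1], x[2])), p,
                 tolerance = 1e-12)  # row swap
    expect_equal(as.numeric(fisher_exact_2x2(x[2], x[1], x[4], x[3])), p,
                 tolerance = 1e-12)  # column swap
    expect_equal(as.numeric(fisher_exact_2x2(x[1], x[3], x[2], x[4])), p,
                 tolerance = 1e-12)  # transpose
  }
})

test_that("additive_expectation matches the formula and its identities", {
  expect_equal(additive_expectation(0.15, 0.09), 0.2265)
  expect_equal(additive_expectation(0, 0.37), 0.37)
  expect_equal(additive_expectation(1, 0.2), 1)
  grid <- expand.grid(p1 = seq(0, 1, 0.1), p2 = seq(0, 1, 0.1))
  expect_equal(additive_expectation(grid$p1, grid$p2),
               1 - (1 - grid$p1) * (1 - grid$p2), tolerance = 1e-12)
  expect_equal(additive_expectation(0.3, 0.7),
               additive_expectation(0.7, 0.3))
  expect_error(additive_expectation(1.1, 0.5), "\\[0, 1\\]")
})

test_that("defect_proportion scores the normal position", {
  wt <- position_tally("+/+", "AQR", c(100, 0, 0, 0, 0))
  expect_identical(defect_proportion(wt), 0)
  lq61 <- position_tally("etr-1(lq61)", "AQR", c(85, 12, 2, 0, 1))
  expect_equal(defect_proportion(lq61), 0.15)
  pqr <- position_tally("x", "PQR", c(0, 0, 0, 0, 88))
  expect_identical(defect_proportion(pqr), 0)  # normal position 5 for PQR
  expect_error(position_tally("x", "AQR", c(1, 2, 3)), "5 nonnegative")
})

test_that("compare_to_control reproduces the published comparisons", {
  ex945 <- position_tally("lqEx945", "AQR", c(86, 14, 0, 0, 0))
  noex945 <- position_tally("no Ex", "AQR", c(74, 24, 1, 1, 0))
  expect_identical(signif(compare_to_control(ex945, noex945), 2), 0.051)
  ex947 <- position_tally("lqEx947", "PQR", c(1, 0, 0, 0, 100))
  noex947 <- position_tally("no Ex", "PQR", c(1, 1, 0, 4, 94))
  expect_identical(signif(compare_to_control(ex947, noex947), 2), 0.065)
  expect_equal(compare_to_control(ex945, ex945), 1)
  expect_error(compare_to_control(ex945, noex947), "different neurons")
})

test_that("synergy_test reproduces the published interaction p-value", {
  lq61 <- position_tally("etr-1(lq61)", "AQR", c(85, 12, 2, 0, 1))
  cwn2 <- position_tally("cwn-2(ok895)", "AQR", c(91, 9, 0, 0, 0))
  dbl <- position_tally("etr-1; cwn-2", "AQR", c(56, 35, 7, 0, 2))
  res <- synergy_test(lq61, cwn2, dbl)
  expect_equal(res$p1, 0.15)
  expect_equal(res$p2, 0.09)
  expect_equal(res$pA, 0.2265)
  expect_identical(unname(res$expected_counts), c(77L, 23L))
  expect_identical(signif(res$p_value, 1), 0.003)
  # double exactly at the additive expectation -> p = 1
  s <- position_tally("s", "AQR", c(80, 20, 0, 0, 0))
  dbl_add <- position_tally("d", "AQR", c(64, 36, 0, 0, 0))
  expect_equal(synergy_test(s, s, dbl_add)$p_value, 1)
  # no defects anywhere -> pA = 0, p = 1
  clean <- position_tally("c", "AQR", c(50, 0, 0, 0, 0))
  res0 <- synergy_test(clean, clean, clean)
  expect_identical(res0$pA, 0)
  expect_equal(res0$p_value, 1)
})

test_that("reproduce_tables evaluates every footnoted comparison", {
  rep <- reproduce_tables()
  expect_identical(sum(rep$table == "table2"), 4L)
  expect_identical(sum(rep$table == "table3"), 14L)
  # the four muscle-expression lines contribute 8 comparisons
  muscle <- rep[rep$table == "table3" &
                  grepl("lqEx94[4-7]", rep$genotype), ]
  expect_identical(nrow(muscle), 8L)
  # printed exact values that verify, at printed precision
  expect_true(rep$pass[rep$genotype == "etr-1(lq61); lqEx945" &
                         rep$neuron == "AQR"])
  expect_true(rep$pass[rep$genotype == "etr-1(lq61); lqEx945" &
                         rep$neuron == "PQR"])
  expect_true(rep$pass[rep$genotype == "etr-1(lq61); lqEx947" &
                         rep$neuron == "PQR"])
  expect_true(rep$pass[rep$genotype == "etr-1(lq61); cwn-2(ok895)" &
                         rep$neuron == "AQR"])
  # every printed bound (< 0.01, < 0.001) is satisfied
  bounds <- rep[startsWith(trimws(rep$printed_p), "<"), ]
  expect_gt(nrow(bounds), 10L)
  expect_true(all(bounds$pass))
  # NS rows are NS
  ns <- rep[trimws(rep$printed_p) == "NS", ]
  expect_true(all(ns$computed_p >= 0.05))
  # the one printed value that does not reproduce from its printed tallies:
  # computed 0.0092 under both two-sided conventions, printed 0.023.
  # reproduce_tables reports the discrepancy rather than hiding it.
  odd <- rep[rep$genotype == "etr-1(lq61); lqEx946" & rep$neuron == "AQR", ]
  expect_false(odd$pass)
  expect_identical(signif(odd$computed_p, 2), 0.0092)
  expect_identical(signif(odd$doubling_p, 2), 0.0092)
})

test_that("reproduce_tables errors on a missing fixture row", {
  dir <- tempfile()
  dir.create(dir)
  src <- system.file("extdata", "table2.tsv", package = "crisprseq")
  tab <- read_tsv(src)
  tab$comparison_target[tab$row_id == "lqEx817_AQR"] <- "nonexistent_row"
  write_tsv(tab, file.path(dir, "table2.tsv"))
  expect_error(reproduce_tables(dir, tables = "table2"),
               "missing fixture row: nonexistent_row")
  # empty fixture -> empty report
  write_tsv(tab[0, ], file.path(dir, "table2.tsv"))
  expect_identical(nrow(reproduce_tables(dir, tables = "table2")), 0L)
  unlink(dir, recursive = TRUE)
})
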