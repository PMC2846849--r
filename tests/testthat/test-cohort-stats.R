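# Exact and asymptotic 2x2 tests, relative risks, carrier collapse,
# burden tables.

test_that("two-sided Fisher reproduces printed table rows", {
  # compared at the printed rounding
  expect_identical(round(fisher_exact_two_sided(two_by_two(4, 0, 31, 40)), 3),
                   0.043)
  expect_identical(round(fisher_exact_two_sided(two_by_two(0, 2, 35, 38)), 3),
                   0.495)
  expect_identical(fisher_exact_two_sided(two_by_two(0, 0, 35, 40)), 1)
  expect_identical(round(fisher_exact_two_sided(two_by_two(6, 2, 29, 38)), 3),
                   0.136)
})

test_that("Fisher enumeration equals the factorial-ratio oracle on random margins", {
  set.seed(91)
  for (i in 1:200) {
    n <- sample(4:30, 1)
    m <- sample(1:(n - 1), 1)      # cases
    r <- sample(0:n, 1)            # carriers
    support <- max(0, r - (n - m)):min(r, m)
    a <- support[sample.int(length(support), 1)]
    tab <- two_by_two(a, r - a, m - a, (n - m) - (r - a))
    expect_equal(fisher_exact_two_sided(tab),
                 oracle_fisher(tab$a, tab$b, tab$c, tab$d),
                 tolerance = 1e-12, info = paste(tab$a, tab$b, tab$c, tab$d))
  }
})

test_that("Fisher is symmetric under cohort relabelling", {
  set.seed(92)
  for (i in 1:50) {
    cells <- sample(0:12, 4, TRUE)
    t1 <- two_by_two(cells[1], cells[2], cells[3], cells[4])
    t2 <- two_by_two(cells[2], cells[1], cells[4], cells[3])
    expect_equal(fisher_exact_two_sided(t1), fisher_exact_two_sided(t2))
  }
})

test_that("hypergeometric point probabilities sum to one for tested margins", {
  for (margins in list(c(35L, 40L, 25L), c(10L, 10L, 7L), c(30L, 1L, 12L))) {
    m <- margins[1]; n <- margins[2]; r <- margins[3]
    support <- max(0L, r - n):min(r, m)
    expect_equal(sum(dhyper(support, m, n, r)), 1, tolerance = 1e-9)
  }
})

test_that("Pearson chi-square matches the closed form and its limits", {
  res <- pearson_chi2(two_by_two(18, 7, 17, 33))
  expect_equal(res$statistic, 9.67, tolerance = 0.001)
  expect_equal(res$p_value, 0.0019, tolerance = 0.02)
  # the printed ND2 row (0.005) matches chi-square, not Fisher
  expect_equal(pearson_chi2(two_by_two(10, 2, 25, 38))$p_value, 0.005,
               tolerance = 0.1)
  # a = b with equal cohort sizes: statistic 0, p 1
  res <- pearson_chi2(two_by_two(5, 5, 15, 15))
  expect_identical(res$statistic, 0)
  expect_identical(res$p_value, 1)
  expect_error(pearson_chi2(two_by_two(0, 0, 10, 10)), "margins")
  # large balanced tables: chi-square and Fisher agree within 10%
  tab <- two_by_two(40, 25, 60, 75)
  expect_equal(pearson_chi2(tab)$p_value, fisher_exact_two_sided(tab),
               tolerance = 0.1)
})

test_that("cohort relative risk reproduces printed RR and Katz CI", {
  rr <- cohort_rr(two_by_two(21, 4, 14, 36))
  expect_equal(rr$rr, 3.00, tolerance = 0.002)
  expect_equal(rr$ci_low, 1.86, tolerance = 0.005)
  expect_equal(rr$ci_high, 4.83, tolerance = 0.005)
  expect_equal(cohort_rr(two_by_two(1, 1, 34, 39))$rr, 1.07, tolerance = 0.005)
  # equal carrier rates: rr exactly 1
  expect_equal(cohort_rr(two_by_two(3, 3, 12, 12))$rr, 1)
  # the printed ND4L row matches the control-cohort orientation
  expect_equal(cohort_rr(two_by_two(0, 2, 35, 38), "control-cohort")$rr,
               1.92, tolerance = 0.005)
  # the printed CYB row matches the exposure (carrier-rate) orientation
  expect_equal(cohort_rr(two_by_two(4, 8, 31, 32), "exposure")$rr,
               0.57, tolerance = 0.01)
  expect_error(cohort_rr(two_by_two(0, 2, 35, 38)), "zero")
})

test_that("orientation duality and CI monotonicity hold", {
  set.seed(93)
  for (i in 1:30) {
    cells <- sample(1:20, 4, TRUE)
    t1 <- two_by_two(cells[1], cells[2], cells[3], cells[4])
    swapped <- two_by_two(cells[2], cells[1], cells[4], cells[3])
    expect_equal(cohort_rr(swapped, "case-cohort")$rr,
                 cohort_rr(t1, "control-cohort")$rr)
    rr95 <- cohort_rr(t1, conf_level = 0.95)
    rr99 <- cohort_rr(t1, conf_level = 0.99)
    expect_true(rr95$ci_low <= rr95$rr && rr95$rr <= rr95$ci_high)
    expect_true(rr99$ci_low <= rr95$ci_low && rr99$ci_high >= rr95$ci_high)
  }
})

test_that("carrier collapse counts each subject once per gene", {
  ann <- function(...) {
    g <- c(...)
    data.frame(gene = g, effect = rep("non-synonymous", length(g)))
  }
  cases <- c(rep(list(ann("G1")), 5), list(ann("G1", "G1")),  # double counts once
             rep(list(ann("G2")), 29))
  controls <- c(rep(list(ann("G1")), 2), rep(list(ann()), 38))
  tab <- carrier_table("G1", cases, controls)
  expect_identical(c(tab$a, tab$b, tab$c, tab$d), c(6L, 2L, 29L, 38L))
  expect_error(carrier_table("G1", list(), controls), "non-empty")
})

test_that("burden_table reproduces the printed per-gene statistics", {
  t4 <- load_fixture("table4_counts")
  b <- burden_from_counts(t4, 35, 40, policy = "fisher")
  p_of <- function(g) round(b$p_value[b$gene == g], 3)
  expect_identical(p_of("ND1"), 0.136)
  expect_identical(p_of("CYB"), 0.360)
  expect_identical(p_of("CO3"), 0.467)
  expect_identical(p_of("CO2"), 0.019)
  nd5 <- b[b$gene == "ND5", ]
  expect_equal(nd5$rr, 3.00, tolerance = 0.002)
  # all-zero gene: p 1, RR marked undefined
  nd4 <- b[b$gene == "ND4", ]
  expect_identical(nd4$p_value, 1)
  expect_true(is.na(nd4$rr))
})

test_that("burden_table on cohorts applies policy and pools Others", {
  ann <- function(g, eff) data.frame(gene = g, effect = eff)
  cases <- c(rep(list(ann("ND5", "non-synonymous")), 10),
             rep(list(ann("tRNA-Lys", "rna_gene")), 3),
             rep(list(ann("ND5", "synonymous")), 22))
  controls <- rep(list(ann("CYB", "synonymous")), 40)
  b <- burden_table(cases, controls, genes = "ND5", policy = "auto",
                    others_genes = "tRNA-Lys")
  nd5 <- b[b$gene == "ND5", ]
  expect_identical(c(nd5$a, nd5$b), c(10L, 0L))  # synonymous do not count
  oth <- b[b$gene == "Others", ]
  expect_identical(c(oth$a, oth$b), c(3L, 0L))
  expect_true(all(b$test_used %in% c("fisher", "chi2")))
})
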