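# Exact clinical association tests and the cohort tallies.

test_that("Fisher exact test reproduces the reference values", {
  # carriers-vs-tumor-history table from the candidate-gene analysis
  expect_equal(round(fisher_exact_2x2(6, 2, 11, 27), 2), 0.04)
  expect_equal(fisher_exact_2x2(1, 1, 1, 1), 1)
  expect_equal(fisher_exact_2x2(3, 0, 0, 3), 0.10)
  expect_equal(fisher_exact_2x2(0, 0, 5, 5), 1)  # zero margin convention
  expect_error(fisher_exact_2x2(-1, 0, 1, 1), "non-negative")
})

test_that("Fisher equals the enumeration oracle and fisher.test, and is
           invariant to simultaneous row/column swaps", {
  set.seed(21)
  for (i in 1:200) {
    cells <- as.integer(rmultinom(1, sample(1:40, 1), runif(4, 0.1, 1)))
    p <- fisher_exact_2x2(cells[1], cells[2], cells[3], cells[4])
    expect_equal(p, oracle_fisher(cells[1], cells[2], cells[3], cells[4]),
                 tolerance = 1e-12, info = paste(cells, collapse = ","))
    if (sum(cells[1:2]) > 0 && sum(cells[3:4]) > 0 &&
        sum(cells[c(1, 3)]) > 0 && sum(cells[c(2, 4)]) > 0) {
      expect_equal(p, fisher.test(matrix(cells, 2, byrow = TRUE))$p.value,
                   tolerance = 1e-7)
    }
    # swap rows and columns together
    expect_equal(fisher_exact_2x2(cells[4], cells[3], cells[2], cells[1]), p,
                 tolerance = 1e-12)
  }
})

test_that("Mann-Whitney exact path matches enumeration; approximation and
           degenerate cases behave", {
  expect_equal(mann_whitney_u(c(1, 2), c(3, 4))$p_value, 1 / 3)
  expect_equal(mann_whitney_u(5, 7)$p_value, 1)
  tied <- mann_whitney_u(c(1, 2), c(1, 2))
  expect_equal(tied$U, 2)                      # n1*n2/2: no evidence
  expect_equal(tied$p_value, 1)
  expect_error(mann_whitney_u(numeric(0), 1), "non-empty")
})

test_that("Mann-Whitney exact path equals the enumeration oracle for all
           tie-free partitions with combined n <= 10", {
  set.seed(31)
  for (n in 2:10) {
    vals <- sample(100, n)  # distinct values
    for (n1 in 1:(n - 1)) {
      for (rep in 1:3) {
        idx <- sample(n, n1)
        x <- vals[idx]; y <- vals[-idx]
        got <- mann_whitney_u(x, y)
        expect_equal(got$method, "exact enumeration")
        expect_equal(got$p_value, oracle_mwu(x, y), tolerance = 1e-12)
      }
    }
  }
  # large samples agree with the normal-approximation reference
  set.seed(32)
  x <- rnorm(30); y <- rnorm(35, 0.5)
  got <- mann_whitney_u(x, y)
  ref <- wilcox.test(x, y, exact = FALSE, correct = TRUE)
  expect_equal(got$p_value, ref$p.value, tolerance = 1e-10)
})

test_that("carrier tallies reproduce the clinical-cohort fixture", {
  clin <- read_clinical_table(pb_fixture("clinical_carriers.csv"))
  asgn <- data.frame(case_id = clin$case_id, gene = clin$gene)
  cs <- carrier_summary(clin, asgn, n_cohort = 125L)
  expect_equal(cs$n_carriers, 17L)
  expect_equal(round(100 * cs$carrier_rate, 1), 13.6)
  expect_equal(unname(cs$per_gene["MITF"]), 9L)
  expect_equal(cs$n_carriers_with_mc1r, 12L)
  expect_error(carrier_summary(clin, data.frame(case_id = "ghost",
                                                gene = "MITF")),
               "unknown case id")
  # multi-hit counting
  clin2 <- data.frame(case_id = c("a", "b"), sex = "F",
                      mc1r_variants = NA_character_)
  asgn2 <- data.frame(case_id = c("a", "a", "b"), gene = c("G1", "G2", "G1"))
  cs2 <- carrier_summary(clin2, asgn2)
  expect_equal(cs2$n_multi_hit, 1L)
  expect_equal(cs2$n_single_hit, 1L)
  cs0 <- carrier_summary(clin2, asgn2[0, ])
  expect_equal(cs0$n_carriers, 0L)
})

test_that("carrier-versus-history test builds the published 2x2 and p-value", {
  clin <- read_clinical_table(pb_fixture("wes_clinical_synthetic.csv"))
  asgn <- read.delim(pb_fixture("wes_assignments_synthetic.tsv"))
  out <- exclusivity_and_history_test(asgn, clin, c("CLTCL1", "SETD2"))
  expect_equal(unname(as.vector(t(out$table))), c(6, 2, 11, 27))
  expect_equal(round(out$p_value, 2), 0.04)
  # all cases carriers: zero margin, p = 1
  all_carriers <- data.frame(case_id = clin$case_id, gene = "CLTCL1")
  expect_equal(exclusivity_and_history_test(all_carriers, clin,
                                            "CLTCL1")$p_value, 1)
  expect_error(exclusivity_and_history_test(asgn, clin, character(0)),
               "non-empty")
})

test_that("age-at-onset comparison reports medians and reacts to shifts", {
  clin <- data.frame(case_id = sprintf("P%02d", 1:20), sex = "M",
                     age_first_melanoma = c(seq(40, 49), seq(55, 64)),
                     mc1r_variants = NA_character_)
  asgn <- data.frame(case_id = sprintf("P%02d", 1:10), gene = "MTOR")
  out <- age_onset_comparison(asgn, clin, "MTOR")
  expect_equal(out$median_carrier, 44.5)
  expect_equal(out$median_noncarrier, 59.5)
  expect_lt(out$p_value, 0.01)
  # smaller shift, larger p (monotone response to effect size)
  clin2 <- clin
  clin2$age_first_melanoma <- c(seq(40, 49), seq(42, 51))
  out2 <- age_onset_comparison(asgn, clin2, "MTOR")
  expect_gt(out2$p_value, out$p_value)
  # identical distributions: no evidence
  clin3 <- clin
  clin3$age_first_melanoma <- rep(seq(40, 49), 2)
  out3 <- age_onset_comparison(asgn, clin3, "MTOR")
  expect_equal(out3$U, 50)
  expect_equal(out3$p_value, 1)
  clin4 <- clin; clin4$age_first_melanoma <- NA_real_
  expect_error(age_onset_comparison(asgn, clin4, "MTOR"), "age")
})
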