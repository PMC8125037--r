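# The synonymous-proxy Poisson LRT, weighting, genomic control, BH and the
# end-to-end scan.

test_that("equal functional/synonymous ratios give a null statistic", {
  r <- proxecat_lrt(2, 4, 100, 200)
  expect_equal(r$statistic, 0)
  expect_equal(r$p_value, 1)
})

test_that("degenerate counts yield a missing result with a reason code", {
  r <- proxecat_lrt(5, 0, 50, 0)
  expect_true(is.na(r$statistic))
  expect_equal(r$reason, "no synonymous proxy")
  r0 <- proxecat_lrt(0, 0, 0, 0)
  expect_equal(r0$reason, "no alleles")
  expect_error(proxecat_lrt(-1, 1, 1, 1), "non-negative")
})

test_that("closed-form constrained MLE matches numerical maximization", {
  set.seed(3)
  for (i in 1:60) {
    cnt <- rpois(4, lambda = sample(c(2, 10, 60, 300), 4, replace = TRUE))
    if (cnt[2] + cnt[4] == 0) next
    got <- proxecat_lrt(cnt[1], cnt[2], cnt[3], cnt[4])$statistic
    want <- oracle_proxecat_stat(cnt[1], cnt[2], cnt[3], cnt[4])
    expect_equal(got, want, tolerance = 1e-8,
                 info = paste(cnt, collapse = ","))
  }
  # statistic is non-negative and zero only at exactly equal ratios
  set.seed(4)
  for (i in 1:200) {
    cnt <- rpois(4, 20) + c(1, 1, 1, 1)
    s <- proxecat_lrt(cnt[1], cnt[2], cnt[3], cnt[4])$statistic
    expect_gte(s, 0)
    if (cnt[1] * cnt[4] != cnt[2] * cnt[3]) expect_gt(s, 1e-12)
  }
})

test_that("weighted test reduces to the unweighted one for flat weights and
           is invariant to rescaling all weights", {
  counts <- data.frame(
    cohort = c("case", "case", "ctrl", "ctrl"),
    class = c("functional", "synonymous", "functional", "synonymous"),
    ac = c(4, 2, 100, 200), weight = 1)
  w1 <- proxecat_weighted(counts)
  flat <- proxecat_lrt(4, 2, 100, 200)
  expect_equal(w1$statistic, flat$statistic)
  expect_equal(w1$p_value, flat$p_value)
  counts2 <- counts; counts2$weight <- 2
  w2 <- proxecat_weighted(counts2)
  expect_equal(w2$statistic, w1$statistic)
  # heterogeneous weights still match the numerical oracle on the totals
  # (weights normalized to mean one within each cohort)
  counts3 <- counts; counts3$weight <- c(3, 1, 0.5, 2)
  w3 <- proxecat_weighted(counts3)
  wbar <- rep(c(mean(c(3, 1)), mean(c(0.5, 2))), each = 2)
  tot <- counts3$weight * counts3$ac / wbar
  expect_equal(w3$statistic,
               oracle_proxecat_stat(tot[1], tot[2], tot[3], tot[4]),
               tolerance = 1e-8)
  # a zero-weight variant contributes nothing
  counts4 <- rbind(counts3,
                   data.frame(cohort = "case", class = "functional",
                              ac = 50, weight = 0))
  expect_equal(proxecat_weighted(counts4)$statistic, w3$statistic)
})

test_that("Madsen-Browning weights grow as control frequency falls", {
  w <- madsen_browning_weights(c(0, 10, 1000), 4000)
  expect_true(all(diff(w) < 0))
})

test_that("genomic control clamps at one and rescales the tail", {
  null_med <- qchisq(0.5, 1)
  g1 <- genomic_control(c(null_med, null_med, null_med))
  expect_equal(g1$lambda, 1)
  stats <- c(4.0, 0.8, 0.2)
  g2 <- genomic_control(stats)
  expect_equal(g2$lambda, 0.8 / null_med)
  expect_equal(g2$p_gc, pchisq(stats / g2$lambda, 1, lower.tail = FALSE))
  g3 <- genomic_control(c(0.01, 0.02, 0.03))  # deflated set: clamped
  expect_equal(g3$lambda, 1)
  expect_error(genomic_control(numeric(0)), "statistic")
})

test_that("BH q-values follow the step-up definition", {
  expect_equal(bh_qvalues(0.03), 0.03)
  expect_equal(bh_qvalues(c(0.01, 0.02, 0.03, 0.04)), rep(0.04, 4))
  expect_equal(bh_qvalues(rep(1, 5)), rep(1, 5))
  expect_error(bh_qvalues(c(0, 0.5)), "\\(0, 1\\]")
  expect_error(bh_qvalues(c(0.2, 0.3), m = 1), "at least")
  # family larger than the supplied subset
  expect_equal(bh_qvalues(c(2e-5), m = 4446), 2e-5 * 4446)
})

test_that("BH agrees with an independent step-up and with p.adjust,
           and is permutation-invariant", {
  set.seed(9)
  for (i in 1:25) {
    p <- runif(sample(1:40, 1))^sample(1:3, 1)
    p[p == 0] <- 1e-12
    q <- bh_qvalues(p)
    expect_equal(q, oracle_bh(p), tolerance = 1e-12)
    expect_equal(q, p.adjust(p, method = "BH"), tolerance = 1e-12)
    perm <- sample(seq_along(p))
    expect_equal(bh_qvalues(p[perm]), q[perm])
    expect_true(all(diff(q[order(p)]) >= -1e-15))  # monotone in p
  }
})

test_that("gene aggregation sums rare deleterious functional and rare
           synonymous alleles with the right filters", {
  # candidate-gene-like toy: two deleterious missense case alleles plus a
  # below-threshold missense, a synonymous and a common variant
  v <- toy_variants(
    gene = "PIK3CD",
    consequence = c("missense", "missense", "missense", "synonymous",
                    "missense"),
    cadd = c(25, 35, 12, 3, 30),
    ac = c(1L, 1L, 1L, 2L, 1L),
    af_popmax = c(NA, 9e-6, NA, NA, 0.01))
  ctrl <- toy_controls("PIK3CD", fun_ac = 68L, syn_ac = 40L, n_ctrl = 19751L)
  agg <- aggregate_gene_counts(v, ctrl)
  expect_equal(agg$fun_case, 2)    # CADD >= 20 and rare only
  expect_equal(agg$syn_case, 2)    # no deleteriousness filter on synonymous
  expect_equal(agg$fun_ctrl, 68)
  expect_equal(agg$syn_ctrl, 40)
  # a homozygote contributes two alleles
  v2 <- toy_variants("G1", "missense", cadd = 30, ac = 2L)
  agg2 <- aggregate_gene_counts(v2, toy_controls("G1", 5L, 5L))
  expect_equal(agg2$fun_case, 2)
  # absent gene: all-zero counts, not an error
  agg3 <- aggregate_gene_counts(v2, toy_controls("G1", 5L, 5L),
                                genes = c("G1", "NOPE"))
  expect_equal(agg3$fun_case[agg3$gene == "NOPE"], 0)
})

test_that("the scan pipeline flags a strongly enriched gene and matches the
           per-gene weighted test", {
  genes <- sprintf("G%02d", 1:20)
  v <- do.call(rbind, lapply(seq_along(genes), function(i) {
    n_fun <- if (i == 1L) 12L else 2L
    toy_variants(genes[i], c(rep("missense", n_fun), "synonymous", "synonymous"),
                 cadd = 30, ac = 1L)
  }))
  v$pos <- seq_len(nrow(v)) * 10L
  class(v) <- c("variant_table", "data.frame")
  ctrl <- toy_controls(genes, fun_ac = rep(40L, 20), syn_ac = rep(40L, 20),
                       n_ctrl = 2000L)
  res <- run_enrichment_scan(v, ctrl)
  expect_s3_class(res, "enrichment_result")
  expect_equal(nrow(res), 20L)
  expect_equal(res$gene[1], "G01")
  expect_true(res$significant[1])
  expect_true(attr(res, "lambda") >= 1)
  # vectorized weighted totals equal the documented per-gene operation
  detail <- attr(aggregate_gene_counts(v, ctrl), "detail")
  for (g in c("G01", "G07")) {
    pg <- proxecat_weighted(detail[detail$gene == g, ])
    expect_equal(res$statistic[res$gene == g], pg$statistic,
                 tolerance = 1e-10)
  }
  # no qualifying case variant anywhere: empty result with a warning
  v0 <- toy_variants("G1", "missense", cadd = 5, ac = 1L)
  expect_warning(res0 <- run_enrichment_scan(v0, toy_controls("G1", 5L, 5L)),
                 "no testable")
  expect_equal(nrow(res0), 0L)
})

test_that("a processing artifact shifts the naive test but not the proxy", {
  # kappa = 2 doubles both control classes: proxy ratio unchanged
  r_clean <- proxecat_lrt(4, 4, 160, 160)
  r_kappa <- proxecat_lrt(4, 4, 320, 320)
  expect_equal(r_kappa$statistic, r_clean$statistic, tolerance = 1e-12)
  n_naive <- naive_functional_test(c(4, 4), c(160, 320), 46, 1000)
  expect_gt(n_naive$statistic[2], n_naive$statistic[1])
})
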