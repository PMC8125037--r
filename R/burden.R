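# Gene-level aggregation and the synonymous-proxy external-control enrichment
# test: a Poisson likelihood-ratio test of whether the functional/synonymous
# rare-allele ratio differs between cases and controls, followed by genomic
# control and Benjamini-Hochberg false-discovery control.

# x*log(mu) with the 0*log(0) == 0 convention
.xlogm <- function(x, mu) ifelse(x > 0, x * log(mu), 0)

#' Poisson likelihood-ratio test with a synonymous proxy
#'
#' Tests, per gene, the null that the ratio of functional to synonymous
#' rare-allele rates is equal in cases and controls. Counts are modeled as
#' independent Poisson; the unconstrained likelihood uses the observed counts
#' as rates, and the constrained maximum has the closed form
#' `r = (fun_case + fun_ctrl) / (syn_case + syn_ctrl)`,
#' `mu_case = (fun_case + syn_case) / (1 + r)`,
#' `mu_ctrl = (fun_ctrl + syn_ctrl) / (1 + r)`.
#' The statistic is `2 * (ll1 - ll0)`, referred to the upper tail of a
#' chi-square with one degree of freedom. Because the synonymous counts enter
#' both cohorts, any multiplicative processing artifact acting equally on both
#' control classes cancels from the tested ratio.
#'
#' @param fun_case,syn_case,fun_ctrl,syn_ctrl non-negative (possibly weighted)
#'   rare-allele counts; vectorized.
#' @param one_sided if `TRUE`, report the one-sided p-value for enrichment of
#'   the case functional/synonymous ratio (off by default).
#' @return data.frame with columns `statistic`, `p_value` and `reason`
#'   (`NA` statistic with reason `"no synonymous proxy"` or `"no alleles"`
#'   when the test is degenerate).
#' @export
proxecat_lrt <- function(fun_case, syn_case, fun_ctrl, syn_ctrl,
                         one_sided = FALSE) {
  if (any(c(fun_case, syn_case, fun_ctrl, syn_ctrl) < 0, na.rm = TRUE))
    stop("allele counts must be non-negative")
  n <- length(fun_case)
  stat <- rep(NA_real_, n); p <- rep(NA_real_, n)
  reason <- rep(NA_character_, n)
  total <- fun_case + syn_case + fun_ctrl + syn_ctrl
  syn_tot <- syn_case + syn_ctrl
  reason[total == 0] <- "no alleles"
  reason[total > 0 & syn_tot == 0] <- "no synonymous proxy"
  ok <- which(is.na(reason))
  if (length(ok)) {
    fc <- fun_case[ok]; sc <- syn_case[ok]
    fk <- fun_ctrl[ok]; sk <- syn_ctrl[ok]
    ll1 <- .xlogm(fc, fc) - fc + .xlogm(sc, sc) - sc +
      .xlogm(fk, fk) - fk + .xlogm(sk, sk) - sk
    r <- (fc + fk) / (sc + sk)
    mu_c <- (fc + sc) / (1 + r)
    mu_k <- (fk + sk) / (1 + r)
    ll0 <- .xlogm(fc, r * mu_c) - r * mu_c + .xlogm(sc, mu_c) - mu_c +
      .xlogm(fk, r * mu_k) - r * mu_k + .xlogm(sk, mu_k) - mu_k
    lam <- pmax(0, 2 * (ll1 - ll0))
    stat[ok] <- lam
    p2 <- stats::pchisq(lam, df = 1L, lower.tail = FALSE)
    if (one_sided) {
      enriched <- fc * sk > fk * sc  # case ratio strictly above control ratio
      p[ok] <- ifelse(enriched, p2 / 2, 1 - p2 / 2)
    } else {
      p[ok] <- p2
    }
  }
  data.frame(statistic = stat, p_value = p, reason = reason,
             stringsAsFactors = FALSE)
}

#' Madsen-Browning allele-frequency weights
#'
#' `1 / sqrt(p * (1 - p))` with `p = (ac + 1) / (an + 2)` estimated from the
#' control cohort (pseudo-count stabilized); rarer variants get larger weights.
#'
#' @param ac,an control allele counts and allele numbers.
#' @return numeric weights.
#' @export
madsen_browning_weights <- function(ac, an) {
  p <- (ac + 1) / (an + 2)
  1 / sqrt(p * (1 - p))
}

#' Weighted synonymous-proxy test
#'
#' Applies [proxecat_lrt()] to weighted allele totals
#' `sum(weight * allele count)`. Weights are normalized to mean one across the
#' contributing variants of each cohort within the gene before summing, so
#' that the statistic stays on the chi-square-1 scale and flat weights
#' reproduce the unweighted test exactly. Per-cohort normalization matters:
#' control-estimated frequencies make case-only variants systematically
#' "rarer" than control singletons (the pseudo-count), and an overall weight
#' scale difference between cohorts would inflate one side's effective counts
#' exactly like a processing artifact. The within-cohort functional-versus-
#' synonymous weight contrast — the point of the weighting — is preserved.
#'
#' @param counts data.frame with columns `ac` (allele count) and `weight`,
#'   plus `cohort` (`"case"`/`"ctrl"`) and `class`
#'   (`"functional"`/`"synonymous"`); one row per contributing variant. An
#'   optional `n_variants` column marks rows that summarize several singleton
#'   variants sharing a weight (default 1).
#' @param one_sided see [proxecat_lrt()].
#' @return one-row data.frame as [proxecat_lrt()], plus the weighted totals.
#' @export
proxecat_weighted <- function(counts, one_sided = FALSE) {
  stopifnot(all(c("ac", "weight", "cohort", "class") %in% names(counts)))
  if (any(counts$weight < 0)) stop("weights must be non-negative")
  if (!"n_variants" %in% names(counts)) counts$n_variants <- 1L
  counts <- counts[counts$ac > 0 & counts$weight > 0, , drop = FALSE]
  wbar_of <- function(cohort) {
    i <- counts$cohort == cohort
    if (!any(i)) return(1)
    sum(counts$weight[i] * counts$n_variants[i]) / sum(counts$n_variants[i])
  }
  wbar <- c(case = wbar_of("case"), ctrl = wbar_of("ctrl"))
  wtot <- function(cohort, cls) {
    i <- counts$cohort == cohort & counts$class == cls
    sum(counts$weight[i] * counts$ac[i]) / wbar[[cohort]]
  }
  fc <- wtot("case", "functional"); sc <- wtot("case", "synonymous")
  fk <- wtot("ctrl", "functional"); sk <- wtot("ctrl", "synonymous")
  out <- proxecat_lrt(fc, sc, fk, sk, one_sided = one_sided)
  cbind(out, data.frame(wfun_case = fc, wsyn_case = sc,
                        wfun_ctrl = fk, wsyn_ctrl = sk))
}

#' Genomic-control correction
#'
#' Estimates the inflation factor as the median observed statistic divided by
#' the chi-square-1 median (0.4549...), clamped at 1 so that deflated sets are
#' never made more significant, and rescales the statistics.
#'
#' @param statistics vector of chi-square-1-scale statistics (`NA` allowed).
#' @return list with `lambda`, `statistic_adj` and `p_gc`.
#' @export
genomic_control <- function(statistics) {
  if (length(statistics) == 0L || all(is.na(statistics)))
    stop("no finite statistics for genomic control")
  lambda <- max(1, stats::median(statistics, na.rm = TRUE) /
                  stats::qchisq(0.5, df = 1L))
  adj <- statistics / lambda
  list(lambda = lambda, statistic_adj = adj,
       p_gc = stats::pchisq(adj, df = 1L, lower.tail = FALSE))
}

#' Benjamini-Hochberg q-values
#'
#' Step-up false-discovery-rate values: `q_i` is the minimum over `j` with
#' `p_j >= p_i` of `p_j * m / rank_j`, capped at 1. `m` may exceed the length
#' of `p` when only a subset of the tested family is supplied.
#'
#' @param p p-values in `(0, 1]` (`NA` passed through).
#' @param m size of the test family; defaults to `length(p)` (excluding `NA`).
#' @return q-values, monotone non-decreasing in `p`.
#' @export
bh_qvalues <- function(p, m = NULL) {
  ok <- !is.na(p)
  if (any(p[ok] <= 0 | p[ok] > 1)) stop("p-values must lie in (0, 1]")
  n <- sum(ok)
  if (is.null(m)) m <- n
  if (m < n) stop("m must be at least the number of p-values")
  q <- rep(NA_real_, length(p))
  if (n) {
    idx <- which(ok)
    o <- order(p[idx])
    ps <- p[idx[o]]
    qs <- rev(cummin(rev(pmin(1, ps * m / seq_len(n)))))
    q[idx[o]] <- qs
  }
  q
}

# per-variant qualifying case counts: rare + class; deleterious filter applies
# to the functional stratum only (the synonymous proxy must reflect
# processing, not constraint)
.qualify_variants <- function(variants, ac, cfg) {
  cls <- classify_functional_class(variants$consequence, cfg)
  rare <- is_rare(variants, cfg)
  del <- is_deleterious(variants, cfg)
  keep_fun <- rare & cls == "functional" & del & ac > 0
  keep_syn <- rare & cls == "synonymous" & ac > 0
  list(class = cls, keep = keep_fun | keep_syn)
}

#' Aggregate rare-allele counts per gene
#'
#' Builds the per-gene functional/synonymous rare-allele counts entering the
#' enrichment test. The functional numerators sum rare *deleterious*
#' functional alleles; the synonymous proxies sum rare synonymous alleles with
#' no deleteriousness filter. Per-variant Madsen-Browning weights are computed
#' from control allele frequencies (variants absent from controls get
#' `ac = 0` at `an = 2 * n_controls`).
#'
#' @param variants case variant table; case allele counts are taken from
#'   `geno` when given, else from an `ac_case` column.
#' @param controls [control_summary] (per-variant or per-class shape; per-class
#'   counts are assumed already restricted to rare qualifying alleles).
#' @param geno optional [cohort_genotypes] aligned with `variants`.
#' @param cfg [filter_config].
#' @param genes genes to aggregate; default: all genes seen in cases (the
#'   case-ascertained testing universe) — set `mode = "union"` to include
#'   genes carried only by controls.
#' @param mode `"case"` (default) or `"union"`.
#' @return data.frame of class `gene_burden` with raw and weighted counts per
#'   gene, plus a `detail` attribute holding the per-variant contribution
#'   table used by the weighted test.
#' @export
aggregate_gene_counts <- function(variants, controls, geno = NULL,
                                  cfg = filter_config(), genes = NULL,
                                  mode = c("case", "union")) {
  mode <- match.arg(mode)
  n_ctrl <- attr(controls, "n_controls")
  shape <- attr(controls, "shape")

  ac_case <- if (!is.null(geno)) {
    as.integer(rowSums(geno$dosage, na.rm = TRUE))
  } else if ("ac_case" %in% names(variants)) {
    variants$ac_case
  } else stop("case allele counts require genotypes or an ac_case column")

  qual <- .qualify_variants(variants, ac_case, cfg)
  case_df <- data.frame(gene = variants$gene, class = qual$class,
                        ac = ac_case, key = variant_key(variants),
                        stringsAsFactors = FALSE)[qual$keep, , drop = FALSE]

  if (shape == "variant") {
    ccls <- classify_functional_class(controls$consequence, cfg)
    crare <- if ("af_popmax" %in% names(controls))
      is_rare(controls$af_popmax, cfg) else rep(TRUE, nrow(controls))
    cdel <- is_deleterious(controls, cfg)
    ckeep <- crare & controls$ac > 0 &
      ((ccls == "functional" & cdel) | ccls == "synonymous")
    ctrl_df <- data.frame(gene = controls$gene, class = ccls,
                          ac = controls$ac, an = controls$an,
                          key = variant_key(controls),
                          n_variants = 1L,
                          stringsAsFactors = FALSE)[ckeep, , drop = FALSE]
  } else {
    ctrl_df <- data.frame(gene = controls$gene, class = controls$class,
                          ac = controls$ac, an = controls$an,
                          key = NA_character_,
                          n_variants = controls$n_variants,
                          stringsAsFactors = FALSE)
    ctrl_df <- ctrl_df[ctrl_df$ac > 0, , drop = FALSE]
  }

  # control-estimated weight per case variant: look up matching control allele
  ctrl_an_default <- 2 * n_ctrl
  if (shape == "variant" && nrow(case_df)) {
    idx <- match(case_df$key, ctrl_df$key)
    ac0 <- ifelse(is.na(idx), 0, ctrl_df$ac[idx])
    an0 <- ifelse(is.na(idx), ctrl_an_default, ctrl_df$an[idx])
  } else {
    ac0 <- rep(0, nrow(case_df)); an0 <- rep(ctrl_an_default, nrow(case_df))
  }
  case_df$weight <- madsen_browning_weights(ac0, an0)
  case_df$cohort <- rep("case", nrow(case_df))
  case_df$n_variants <- rep(1L, nrow(case_df))

  # control variants weighted from their own frequencies; aggregated per-class
  # rows are expanded conceptually as ac singletons (each allele seen once)
  ctrl_df$weight <- if (nrow(ctrl_df)) {
    ifelse(rep(shape == "variant", nrow(ctrl_df)),
           madsen_browning_weights(ctrl_df$ac, ctrl_df$an),
           madsen_browning_weights(1, ctrl_df$an))
  } else numeric(0)
  ctrl_df$cohort <- rep("ctrl", nrow(ctrl_df))

  cols <- c("gene", "class", "ac", "weight", "cohort", "n_variants")
  detail <- rbind(case_df[, cols, drop = FALSE], ctrl_df[, cols, drop = FALSE])

  if (is.null(genes)) {
    genes <- if (mode == "case") sort(unique(case_df$gene))
             else sort(unique(detail$gene))
  }
  tab <- function(cohort, cls) {
    i <- detail$cohort == cohort & detail$class == cls
    v <- tapply(detail$ac[i], factor(detail$gene[i], levels = genes), sum)
    out <- as.numeric(v); out[is.na(out)] <- 0; out
  }
  res <- data.frame(gene = genes,
                    fun_case = tab("case", "functional"),
                    syn_case = tab("case", "synonymous"),
                    fun_ctrl = tab("ctrl", "functional"),
                    syn_ctrl = tab("ctrl", "synonymous"),
                    stringsAsFactors = FALSE)
  res$n_case <- rep(if (!is.null(geno)) length(geno$sample_ids) else NA_integer_,
                    nrow(res))
  res$n_ctrl <- rep(n_ctrl, nrow(res))
  attr(res, "detail") <- detail
  class(res) <- c("gene_burden", "data.frame")
  res
}

#' Run the full enrichment scan
#'
#' Pipeline: qualify variants (rarity, class, deleteriousness on the
#' functional stratum), aggregate per gene, apply the (optionally weighted)
#' synonymous-proxy likelihood-ratio test, correct the statistics by genomic
#' control, and compute Benjamini-Hochberg q-values over the tested genes.
#' Genes enter the test when they carry at least one qualifying rare allele in
#' the case cohort (`mode = "case"`, the default) or in either cohort
#' (`mode = "union"`).
#'
#' @param variants case variant table.
#' @param controls [control_summary].
#' @param geno optional [cohort_genotypes].
#' @param cfg [filter_config].
#' @param weighted use Madsen-Browning weighted totals (default) or raw counts.
#' @param q_threshold significance flag threshold on the q-value (default 0.2).
#' @param m family size for BH; default: number of genes with a computable test.
#' @param mode gene universe, see above.
#' @return data.frame of class `enrichment_result`, sorted by q then p, with
#'   attributes `lambda` (genomic-control factor) and `n_tested`.
#' @export
run_enrichment_scan <- function(variants, controls, geno = NULL,
                                cfg = filter_config(), weighted = TRUE,
                                q_threshold = 0.2, m = NULL,
                                mode = c("case", "union")) {
  mode <- match.arg(mode)
  agg <- aggregate_gene_counts(variants, controls, geno = geno, cfg = cfg,
                               mode = mode)
  if (nrow(agg) == 0L) {
    warning("no testable gene after filtering")
    out <- data.frame(gene = character(0), statistic = numeric(0),
                      p_raw = numeric(0), p_gc = numeric(0), q = numeric(0),
                      significant = logical(0))
    attr(out, "lambda") <- NA_real_; attr(out, "n_tested") <- 0L
    class(out) <- c("enrichment_result", "data.frame")
    return(out)
  }
  detail <- attr(agg, "detail")
  if (weighted) {
    # vectorized equivalent of per-gene proxecat_weighted(): normalize the
    # per-variant weights to mean 1 within each gene and cohort, then sum
    # weight * ac per cohort/class
    d <- detail[detail$ac > 0 & detail$weight > 0, , drop = FALSE]
    f <- factor(d$gene, levels = agg$gene)
    sum_by <- function(v, sel) {
      out <- tapply(v[sel], f[sel], sum)
      out <- as.numeric(out); out[is.na(out)] <- 0; out
    }
    wbar_of <- function(cohort) {
      i <- d$cohort == cohort
      wb <- sum_by(d$weight * d$n_variants, i) /
        pmax(1e-300, sum_by(d$n_variants, i))
      wb[wb == 0] <- 1
      wb
    }
    wbar_case <- wbar_of("case"); wbar_ctrl <- wbar_of("ctrl")
    s <- d$weight * d$ac
    wfc <- sum_by(s, d$cohort == "case" & d$class == "functional") / wbar_case
    wsc <- sum_by(s, d$cohort == "case" & d$class == "synonymous") / wbar_case
    wfk <- sum_by(s, d$cohort == "ctrl" & d$class == "functional") / wbar_ctrl
    wsk <- sum_by(s, d$cohort == "ctrl" & d$class == "synonymous") / wbar_ctrl
    tst <- proxecat_lrt(wfc, wsc, wfk, wsk)
  } else {
    tst <- proxecat_lrt(agg$fun_case, agg$syn_case, agg$fun_ctrl, agg$syn_ctrl)
  }
  res <- data.frame(gene = agg$gene,
                    fun_case = agg$fun_case, syn_case = agg$syn_case,
                    fun_ctrl = agg$fun_ctrl, syn_ctrl = agg$syn_ctrl,
                    statistic = tst$statistic, p_raw = tst$p_value,
                    reason = tst$reason, stringsAsFactors = FALSE)
  gc_res <- genomic_control(res$statistic)
  res$p_gc <- gc_res$p_gc
  n_tested <- sum(!is.na(res$p_gc))
  if (is.null(m)) m <- n_tested
  res$q <- bh_qvalues(res$p_gc, m = m)
  res$significant <- !is.na(res$q) & res$q <= q_threshold
  res <- res[order(res$q, res$p_gc, res$gene), , drop = FALSE]
  rownames(res) <- NULL
  attr(res, "lambda") <- gc_res$lambda
  attr(res, "n_tested") <- n_tested
  class(res) <- c("enrichment_result", "data.frame")
  res
}

#' Naive functional-only comparison
#'
#' Two-sided Poisson likelihood-ratio test of the case versus control
#' functional rare-allele *rates* (per sequenced allele), ignoring the
#' synonymous proxy. Used as the benchmark that the proxy test protects
#' against processing artifacts: a multiplicative artifact on control counts
#' shifts this test's null rejection rate but cancels from the proxy test.
#'
#' @param fun_case,fun_ctrl functional rare-allele counts (vectorized).
#' @param n_case,n_ctrl cohort sizes.
#' @return data.frame with `statistic` and `p_value`.
#' @export
naive_functional_test <- function(fun_case, fun_ctrl, n_case, n_ctrl) {
  t1 <- 2 * n_case; t2 <- 2 * n_ctrl
  r1 <- fun_case / t1; r2 <- fun_ctrl / t2
  r0 <- (fun_case + fun_ctrl) / (t1 + t2)
  ll1 <- .xlogm(fun_case, r1 * t1) - r1 * t1 + .xlogm(fun_ctrl, r2 * t2) - r2 * t2
  ll0 <- .xlogm(fun_case, r0 * t1) - r0 * t1 + .xlogm(fun_ctrl, r0 * t2) - r0 * t2
  lam <- pmax(0, 2 * (ll1 - ll0))
  data.frame(statistic = lam,
             p_value = stats::pchisq(lam, df = 1L, lower.tail = FALSE))
}
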