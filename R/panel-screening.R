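# Candidate-variant screening against external panels: reference panels
# carrying allele frequencies (FrEx-style) and tumor-series panels carrying
# per-series occurrence counts (TCGA-style).

.TCGA_SERIES <- c("SKCM", "KIRC", "KIRP")
.PANEL_SERIES <- c(.TCGA_SERIES, "other")

#' Screen candidate variants against a panel
#'
#' Exact matching on the normalized `(chrom, pos, ref, alt)` key; no fuzzy or
#' positional-window matching, since rare-variant identity must be
#' allele-precise.
#'
#' @param candidates variant table (or anything with the key columns).
#' @param panel [read_panel_table()]-style panel.
#' @return list of class `screening_report` with `matches` (one row per
#'   candidate-panel hit), `n_variants_matched`, `n_distinct_genes` and, when
#'   the panel carries series labels, per-series occurrence sums.
#' @export
screen_panel <- function(candidates, panel) {
  keys <- variant_key(candidates)
  hit <- panel$key %in% keys
  matches <- panel[hit, , drop = FALSE]
  matches$gene <- candidates$gene[match(matches$key, keys)]
  report <- list(
    matches = matches,
    n_variants_matched = length(unique(matches$key)),
    n_distinct_genes = length(unique(matches$gene)))
  if ("occurrences" %in% names(matches)) {
    report$per_series <- tapply(matches$occurrences, matches$series, sum)
  }
  structure(report, class = "screening_report")
}

#' @export
print.screening_report <- function(x, ...) {
  cat("screening report:", x$n_variants_matched, "variant(s) matched across",
      x$n_distinct_genes, "gene(s)\n")
  if (!is.null(x$per_series)) {
    cat("occurrences per series:\n"); print(x$per_series)
  }
  invisible(x)
}

#' Tally candidate-variant occurrences in tumor series
#'
#' Matches candidates against a tumor-series panel (columns `series` in
#' `{SKCM, KIRC, KIRP, other}` and `occurrences`) and sums occurrences for the
#' tumor series only: entries labeled `other` (e.g. familial cancer series)
#' are excluded from the tallies. Melanoma occurrences are the SKCM sum; renal
#' cell carcinoma occurrences are the KIRC + KIRP sum.
#'
#' @param candidates variant table.
#' @param panel series panel.
#' @return `screening_report` with `n_variants_matched` (distinct candidates
#'   seen in a tumor series), `total_occurrences`, `melanoma_occurrences`,
#'   `rcc_occurrences` and `per_series`.
#' @export
tally_tcga_occurrences <- function(candidates, panel) {
  if (!all(c("series", "occurrences") %in% names(panel)))
    stop("series panel needs 'series' and 'occurrences' columns")
  bad <- setdiff(unique(panel$series), .PANEL_SERIES)
  if (length(bad))
    stop("unknown series label(s): ", paste(bad, collapse = ", "))
  keys <- variant_key(candidates)
  m <- panel[panel$key %in% keys & panel$series %in% .TCGA_SERIES, ,
             drop = FALSE]
  m$gene <- candidates$gene[match(m$key, keys)]
  per_series <- vapply(.TCGA_SERIES, function(s)
    sum(m$occurrences[m$series == s]), numeric(1L))
  structure(list(
    matches = m,
    n_variants_matched = length(unique(m$key)),
    n_distinct_genes = length(unique(m$gene)),
    total_occurrences = sum(m$occurrences),
    melanoma_occurrences = per_series[["SKCM"]],
    rcc_occurrences = per_series[["KIRC"]] + per_series[["KIRP"]],
    per_series = per_series), class = "screening_report")
}

#' Series enrichment test
#'
#' One-sided Fisher exact test of whether carriers of the candidate variant
#' set are over-represented in series A relative to series B, on the 2x2
#' carriers table `rbind(c(k_a, n_a - k_a), c(k_b, n_b - k_b))`.
#'
#' @param carriers_a,n_a carrier count and cohort size of the series of
#'   interest.
#' @param carriers_b,n_b carrier count and cohort size of the comparison
#'   series.
#' @param alternative passed to [fisher_exact_2x2()]; default `"greater"`.
#' @return the p-value.
#' @export
series_enrichment_test <- function(carriers_a, n_a, carriers_b, n_b,
                                   alternative = "greater") {
  stopifnot(carriers_a <= n_a, carriers_b <= n_b)
  fisher_exact_2x2(carriers_a, n_a - carriers_a, carriers_b, n_b - carriers_b,
                   alternative = alternative)
}

#' Novel or very rare classification
#'
#' A candidate is reported as novel or very rare when it has no recorded
#' popmax allele frequency or a popmax frequency strictly below the threshold
#' (default 1e-4; a value of exactly 1e-4 is excluded).
#'
#' @param variants variant table or numeric popmax AF vector.
#' @param threshold frequency threshold.
#' @return logical vector.
#' @export
is_novel_or_very_rare <- function(variants, threshold = 1e-4) {
  af <- if (is.data.frame(variants)) variants$af_popmax else variants
  is.na(af) | af < threshold
}
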