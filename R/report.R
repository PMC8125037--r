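# End-to-end orchestration: the full filter -> test -> FDR scan with a
# reproducibility manifest, and the cohort report recomputing the clinical and
# screening tallies from the shipped fixture tables.

#' Path to a shipped fixture table
#'
#' The package ships small plain-text tables describing the reference
#' double-primary (melanoma + renal cell carcinoma) cohort: cohort
#' demographics, the clinical records of the carriers of pathogenic variants
#' in known predisposing genes, the gene-level burden counts of the candidate
#' genes, the candidate variant set, the reference-panel and tumor-series
#' lookups, and a synthetic exome-cohort clinical table (constructed to match
#' the published marginal tallies; per-case data are not public).
#'
#' @param name file name under `extdata`, or `NULL` to list all fixtures.
#' @return file path.
#' @export
pb_fixture <- function(name = NULL) {
  if (is.null(name))
    return(list.files(system.file("extdata", package = "proxburden")))
  path <- system.file("extdata", name, package = "proxburden")
  if (!nzchar(path)) stop("no fixture named '", name, "'")
  path
}

#' Run the enrichment scan end to end, with a manifest
#'
#' Thin orchestration over [run_enrichment_scan()]: reads inputs when given
#' as file paths, runs the scan, writes the per-gene results as
#' tab-separated text and a JSON run manifest (config, input digests, seed,
#' package version, genomic-control factor, variant counts at every filter
#' stage) sufficient to re-execute the run bit-identically.
#'
#' @param variants case variant table or path to one.
#' @param controls [control_summary] or path.
#' @param geno optional [cohort_genotypes].
#' @param cfg [filter_config].
#' @param out_dir output directory; created if needed. `NULL` skips writing.
#' @param seed integer recorded in the manifest (the scan itself is
#'   deterministic).
#' @param ... passed to [run_enrichment_scan()].
#' @return the `enrichment_result`, with the manifest in attribute
#'   `manifest`.
#' @export
run_scan <- function(variants, controls, geno = NULL, cfg = filter_config(),
                     out_dir = NULL, seed = NA_integer_, ...) {
  digests <- list()
  if (is.character(variants)) {
    digests$variants <- unname(tools::md5sum(variants))
    variants <- read_variant_table(variants)
  }
  if (is.character(controls)) {
    digests$controls <- unname(tools::md5sum(controls))
    controls <- read_control_summary(controls)
  }
  n_input <- nrow(variants)
  rare <- is_rare(variants, cfg)
  cls <- classify_functional_class(variants$consequence, cfg)
  del <- is_deleterious(variants, cfg)
  stage_counts <- list(
    input = n_input,
    rare = sum(rare),
    rare_functional = sum(rare & cls == "functional"),
    rare_functional_deleterious = sum(rare & cls == "functional" & del),
    rare_synonymous = sum(rare & cls == "synonymous"))
  res <- run_enrichment_scan(variants, controls, geno = geno, cfg = cfg, ...)
  manifest <- list(
    package = "proxburden",
    version = as.character(utils::packageVersion("proxburden")),
    seed = seed,
    rng = "Mersenne-Twister",
    config = unclass(cfg),
    input_digests = digests,
    lambda_gc = attr(res, "lambda"),
    n_tested = attr(res, "n_tested"),
    stage_counts = stage_counts)
  attr(res, "manifest") <- manifest
  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    out <- as.data.frame(res)
    utils::write.table(out, file.path(out_dir, "enrichment_results.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    jsonlite::write_json(manifest, file.path(out_dir, "run_manifest.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
  }
  res
}

#' Cohort report from the shipped fixture tables
#'
#' Recomputes, from the fixture tables, the summary quantities of the
#' reference cohort analysis: the clinical-testing carrier tallies (overall
#' carrier rate, MITF p.E318K rate, MC1R co-carriage among carriers), the
#' candidate-variant novelty fraction, the reference-panel and tumor-series
#' screening overlaps, and the carrier-versus-tumor-history Fisher test on
#' the synthetic exome-cohort table.
#'
#' @param extdata_dir directory holding the fixture tables; defaults to the
#'   package's own `extdata`.
#' @return nested list of class `cohort_report`.
#' @export
cohort_report <- function(extdata_dir = system.file("extdata",
                                                    package = "proxburden")) {
  fp <- function(name) file.path(extdata_dir, name)
  demo <- utils::read.csv(fp("cohort_demographics.csv"),
                          stringsAsFactors = FALSE)
  n_cohort <- as.integer(demo$value[demo$field == "n_patients"])
  clinical <- read_clinical_table(fp("clinical_carriers.csv"))
  assignments <- data.frame(case_id = clinical$case_id, gene = clinical$gene,
                            stringsAsFactors = FALSE)
  cs <- carrier_summary(clinical, assignments, n_cohort = n_cohort)

  candidates <- read_variant_table(fp("candidate_variants.tsv"))
  novel <- is_novel_or_very_rare(candidates)
  frex <- screen_panel(candidates, read_panel_table(fp("frex_panel.tsv")))
  tcga <- tally_tcga_occurrences(candidates,
                                 read_panel_table(fp("tcga_panel.tsv")))

  wes_clin <- read_clinical_table(fp("wes_clinical_synthetic.csv"))
  wes_asgn <- utils::read.delim(fp("wes_assignments_synthetic.tsv"),
                                stringsAsFactors = FALSE)
  wes_cs <- carrier_summary(wes_clin, wes_asgn)
  excl <- exclusivity_and_history_test(wes_asgn, wes_clin,
                                       c("CLTCL1", "SETD2"))
  burden <- utils::read.delim(fp("candidate_gene_burden.tsv"),
                              stringsAsFactors = FALSE)

  structure(list(
    clinical_cohort = list(
      n_cohort = cs$n_cohort,
      n_carriers = cs$n_carriers,
      carrier_rate_pct = 100 * cs$carrier_rate,
      mitf_carriers = unname(cs$per_gene["MITF"]),
      mitf_rate_pct = 100 * unname(cs$per_gene["MITF"]) / cs$n_cohort,
      mc1r_cocarriage_pct = 100 * cs$n_carriers_with_mc1r / cs$n_carriers),
    candidates = list(
      n_genes = nrow(burden),
      n_variants = nrow(candidates),
      n_novel_or_very_rare = sum(novel),
      novel_or_very_rare_pct = 100 * mean(novel)),
    frex = list(
      n_variants_matched = frex$n_variants_matched,
      n_distinct_genes = frex$n_distinct_genes),
    tcga = list(
      n_variants_matched = tcga$n_variants_matched,
      total_occurrences = tcga$total_occurrences,
      melanoma_occurrences = tcga$melanoma_occurrences,
      rcc_occurrences = tcga$rcc_occurrences),
    wes_cohort = list(
      n_cohort = wes_cs$n_cohort,
      n_carriers = wes_cs$n_carriers,
      exclusivity_table = excl$table,
      clinical_fisher_p = excl$p_value)
  ), class = "cohort_report")
}

#' @export
print.cohort_report <- function(x, ...) {
  cc <- x$clinical_cohort
  cat(sprintf("Clinical cohort: %d/%d carriers (%.1f%%); MITF p.E318K %d (%.1f%%); MC1R co-carriage %.0f%%\n",
              cc$n_carriers, cc$n_cohort, cc$carrier_rate_pct,
              cc$mitf_carriers, cc$mitf_rate_pct, cc$mc1r_cocarriage_pct))
  cat(sprintf("Candidates: %d variants in %d genes; %d (%.0f%%) novel or very rare\n",
              x$candidates$n_variants, x$candidates$n_genes,
              x$candidates$n_novel_or_very_rare,
              x$candidates$novel_or_very_rare_pct))
  cat(sprintf("Reference panel overlap: %d variant(s) across %d gene(s)\n",
              x$frex$n_variants_matched, x$frex$n_distinct_genes))
  cat(sprintf("Tumor series overlap: %d variant(s), %d occurrence(s) (%d melanoma, %d RCC)\n",
              x$tcga$n_variants_matched, x$tcga$total_occurrences,
              x$tcga$melanoma_occurrences, x$tcga$rcc_occurrences))
  cat(sprintf("Exome cohort: carrier/tumor-history Fisher p = %.3f\n",
              x$wes_cohort$clinical_fisher_p))
  invisible(x)
}

#' Write a cohort report
#'
#' Emits the report both as human-readable text and machine-readable JSON.
#'
#' @param report [cohort_report()] output.
#' @param out_dir output directory.
#' @return paths of the files written, invisibly.
#' @export
write_report <- function(report, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  txt <- file.path(out_dir, "cohort_report.txt")
  jsn <- file.path(out_dir, "cohort_report.json")
  sink(txt); print(report); sink()
  rep2 <- unclass(report)
  rep2$wes_cohort$exclusivity_table <-
    as.list(as.data.frame(report$wes_cohort$exclusivity_table))
  jsonlite::write_json(rep2, jsn, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(c(txt, jsn))
}
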