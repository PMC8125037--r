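# Per-variant quality control and the composite rarity/deleteriousness
# classification that defines the tested variant set.

#' Filter configuration
#'
#' Thresholds of the composite variant filter. Defaults follow common exome
#' call-set practice for a small case cohort tested against external controls:
#'
#' * `missingness_max` (0.10): positions with a missing-genotype fraction
#'   strictly above this are dropped.
#' * `het_aaf_min` (0.25): heterozygous calls with alternate allelic fraction
#'   strictly below this are set to missing.
#' * `hwe_alpha` (1e-6): exact Hardy-Weinberg test threshold.
#' * `rarity_af_max` (0.0025): a variant is rare iff its popmax allele
#'   frequency is at or below this (the MITF p.E318K hotspot frequency), or
#'   unobserved.
#' * `cadd_min` (20): CADD phred threshold for deleteriousness.
#' * `frameshift_mq_min` (50): minimum mapping quality for frameshift indels
#'   to qualify as deleterious.
#' * `clinvar_min_assertions` (2): minimum number of concordant pathogenic
#'   ClinVar assertions.
#' * `splice_functional` (TRUE): whether splice variants count as functional.
#'
#' @param missingness_max,het_aaf_min,hwe_alpha,rarity_af_max,cadd_min
#'   numeric thresholds, see above.
#' @param frameshift_mq_min,clinvar_min_assertions,splice_functional see above.
#' @return object of class `filter_config`.
#' @export
filter_config <- function(missingness_max = 0.10, het_aaf_min = 0.25,
                          hwe_alpha = 1e-6, rarity_af_max = 0.0025,
                          cadd_min = 20, frameshift_mq_min = 50,
                          clinvar_min_assertions = 2L,
                          splice_functional = TRUE) {
  stopifnot(missingness_max >= 0, missingness_max <= 1,
            het_aaf_min >= 0, het_aaf_min <= 1,
            hwe_alpha > 0, hwe_alpha <= 1,
            rarity_af_max > 0, rarity_af_max < 1,
            cadd_min >= 0, frameshift_mq_min >= 0,
            clinvar_min_assertions >= 1,
            is.logical(splice_functional))
  structure(list(missingness_max = missingness_max, het_aaf_min = het_aaf_min,
                 hwe_alpha = hwe_alpha, rarity_af_max = rarity_af_max,
                 cadd_min = cadd_min, frameshift_mq_min = frameshift_mq_min,
                 clinvar_min_assertions = as.integer(clinvar_min_assertions),
                 splice_functional = splice_functional),
            class = "filter_config")
}

#' Missingness filter
#'
#' Drops genomic positions whose missing-genotype fraction is strictly greater
#' than `cfg$missingness_max`.
#'
#' @param geno [cohort_genotypes].
#' @param cfg [filter_config].
#' @return character vector of retained variant keys.
#' @export
filter_missingness <- function(geno, cfg = filter_config()) {
  if (length(geno$sample_ids) < 1L || length(geno$variant_keys) < 1L)
    stop("empty genotype matrix")
  miss <- rowMeans(is.na(geno$dosage))
  geno$variant_keys[miss <= cfg$missingness_max]
}

#' Heterozygous allelic-fraction filter
#'
#' Sets to missing any heterozygous call whose alternate allelic fraction
#' `alt / (ref + alt)` is strictly below `cfg$het_aaf_min`. Homozygous calls
#' are untouched. Heterozygous calls with zero total depth are set missing
#' with a warning.
#'
#' @param geno [cohort_genotypes] with allelic depths.
#' @param cfg [filter_config].
#' @return the genotype container with low-support het calls masked.
#' @export
filter_het_aaf <- function(geno, cfg = filter_config()) {
  if (is.null(geno$ad_ref) || is.null(geno$ad_alt))
    stop("allelic depths required for the het allelic-fraction filter")
  het <- !is.na(geno$dosage) & geno$dosage == 1L
  tot <- geno$ad_ref + geno$ad_alt
  zero <- het & !is.na(tot) & tot == 0L
  if (any(zero)) {
    warning(sum(zero), " heterozygous call(s) with zero depth set to missing")
    geno$dosage[zero] <- NA_integer_
    het <- het & !zero
  }
  aaf <- geno$ad_alt / tot
  low <- het & !is.na(aaf) & aaf < cfg$het_aaf_min
  geno$dosage[low] <- NA_integer_
  geno
}

#' Exact Hardy-Weinberg equilibrium test
#'
#' Exact conditional test of Hardy-Weinberg genotype proportions: given the
#' allele counts, the p-value is the sum of probabilities of all heterozygote
#' counts whose conditional probability does not exceed that of the observed
#' configuration (two-sided by probability ordering).
#'
#' @param n_hom_ref,n_het,n_hom_alt genotype counts (vectorized).
#' @return p-value(s) in `(0, 1]`.
#' @export
hwe_exact_test <- function(n_hom_ref, n_het, n_hom_alt) {
  if (length(n_hom_ref) > 1L || length(n_het) > 1L || length(n_hom_alt) > 1L) {
    return(mapply(hwe_exact_test, n_hom_ref, n_het, n_hom_alt))
  }
  if (any(c(n_hom_ref, n_het, n_hom_alt) < 0)) stop("negative genotype counts")
  n <- n_hom_ref + n_het + n_hom_alt
  if (n < 1L) stop("at least one genotype required")
  n_alt <- 2L * n_hom_alt + n_het
  n_ref <- 2L * n_hom_ref + n_het
  if (n_alt == 0L || n_ref == 0L) return(1)
  hets <- seq.int(n_alt %% 2L, min(n_alt, n_ref), by = 2L)
  hom_alt <- (n_alt - hets) / 2L
  hom_ref <- n - hets - hom_alt
  logp <- lfactorial(n) - lfactorial(hom_ref) - lfactorial(hets) -
    lfactorial(hom_alt) + hets * log(2) +
    lfactorial(n_alt) + lfactorial(n_ref) - lfactorial(2L * n)
  p <- exp(logp - max(logp))
  p <- p / sum(p)
  p_obs <- p[match(n_het, hets)]
  sum(p[p <= p_obs * (1 + 1e-9)])
}

#' Rarity classification
#'
#' A variant is rare iff its popmax allele frequency is less than or equal to
#' `cfg$rarity_af_max`, or missing (a novel variant is rare).
#'
#' @param variants variant table (uses `af_popmax`), or a numeric vector of
#'   popmax allele frequencies.
#' @param cfg [filter_config].
#' @return logical vector.
#' @export
is_rare <- function(variants, cfg = filter_config()) {
  af <- if (is.data.frame(variants)) variants$af_popmax else variants
  is.na(af) | af <= cfg$rarity_af_max
}

# TRUE iff >= min_n assertions, all pathogenic/likely pathogenic, none else
.clinvar_qualifies <- function(clinvar, min_n) {
  vapply(clinvar, function(s) {
    if (is.na(s) || !nzchar(s)) return(FALSE)
    labs <- tolower(trimws(strsplit(s, "[;|]")[[1L]]))
    labs <- gsub("_", " ", labs)
    length(labs) >= min_n && all(labs %in% c("pathogenic", "likely pathogenic"))
  }, logical(1L), USE.NAMES = FALSE)
}

#' Deleteriousness classification
#'
#' A variant is designated deleterious — likely to impact the encoded protein —
#' iff any of: CADD phred at or above `cfg$cadd_min`; at least
#' `cfg$clinvar_min_assertions` ClinVar assertions, all of them Pathogenic or
#' Likely pathogenic with no conflicting assertion; or a frameshift indel with
#' mapping quality at or above `cfg$frameshift_mq_min`.
#'
#' @param variants variant table with columns `cadd_phred`, `clinvar`, `mq`,
#'   `consequence` (missing columns are treated as all-missing).
#' @param cfg [filter_config].
#' @return logical vector.
#' @export
is_deleterious <- function(variants, cfg = filter_config()) {
  n <- nrow(variants)
  cadd <- if ("cadd_phred" %in% names(variants)) variants$cadd_phred else rep(NA_real_, n)
  mq <- if ("mq" %in% names(variants)) variants$mq else rep(NA_real_, n)
  clinvar <- if ("clinvar" %in% names(variants)) variants$clinvar else rep(NA_character_, n)
  by_cadd <- !is.na(cadd) & cadd >= cfg$cadd_min
  by_clinvar <- .clinvar_qualifies(clinvar, cfg$clinvar_min_assertions)
  by_fs <- variants$consequence == "frameshift" & !is.na(mq) &
    mq >= cfg$frameshift_mq_min
  by_cadd | by_clinvar | by_fs
}

#' Functional class of a consequence
#'
#' Assigns the burden-test stratum: `synonymous` stays synonymous; missense,
#' stopgain, frameshift, inframe and (by default) splice variants are
#' `functional`; everything else is `other` and enters neither numerator.
#'
#' @param consequence normalized consequence labels.
#' @param cfg [filter_config] (controls whether splice counts as functional).
#' @return character vector over `{"functional", "synonymous", "other"}`.
#' @export
classify_functional_class <- function(consequence, cfg = filter_config()) {
  functional <- c("missense", "stopgain", "frameshift", "inframe",
                  if (cfg$splice_functional) "splice")
  out <- rep("other", length(consequence))
  out[consequence %in% functional] <- "functional"
  out[consequence == "synonymous"] <- "synonymous"
  out
}

#' Hardy-Weinberg filter over a cohort
#'
#' Applies [hwe_exact_test()] per variant to the case genotype matrix and
#' retains variants with p-value at or above `cfg$hwe_alpha`.
#'
#' @param geno [cohort_genotypes].
#' @param cfg [filter_config].
#' @return character vector of retained variant keys.
#' @export
filter_hwe <- function(geno, cfg = filter_config()) {
  d <- geno$dosage
  p <- vapply(seq_len(nrow(d)), function(i) {
    x <- d[i, ]
    x <- x[!is.na(x)]
    if (!length(x)) return(1)
    hwe_exact_test(sum(x == 0L), sum(x == 1L), sum(x == 2L))
  }, numeric(1L))
  geno$variant_keys[p >= cfg$hwe_alpha]
}
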