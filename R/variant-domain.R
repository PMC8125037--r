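# Domain containers and readers for annotated variant tables, cohort genotype
# matrices, external-control summaries, screening panels and clinical records.
# Variant tables are plain data.frames (class "variant_table") so that the
# usual subsetting/merging idiom applies; genotype matrices live in a light
# S3 container validated on construction.

#' Controlled consequence vocabulary
#'
#' Normalized consequence labels used throughout the package. Annotator-specific
#' terms (ANNOVAR, VEP, snpEff dialects) are mapped onto this vocabulary by
#' [normalize_consequence()].
#'
#' @format Character vector of the eight recognized labels.
#' @export
CONSEQUENCE_LEVELS <- c("missense", "synonymous", "stopgain", "frameshift",
                        "inframe", "splice", "intronic", "other")

# annotator term -> normalized label; keys are lower-case with collapsed space
.CONSEQUENCE_MAP <- c(
  "missense"                 = "missense",
  "nonsynonymous snv"        = "missense",
  "missense_variant"         = "missense",
  "synonymous"               = "synonymous",
  "synonymous snv"           = "synonymous",
  "synonymous_variant"       = "synonymous",
  "stopgain"                 = "stopgain",
  "stop_gained"              = "stopgain",
  "nonsense"                 = "stopgain",
  "frameshift"               = "frameshift",
  "frameshift deletion"      = "frameshift",
  "frameshift insertion"     = "frameshift",
  "frameshift substitution"  = "frameshift",
  "frameshift_variant"       = "frameshift",
  "inframe"                  = "inframe",
  "nonframeshift deletion"   = "inframe",
  "nonframeshift insertion"  = "inframe",
  "nonframeshift substitution" = "inframe",
  "inframe_deletion"         = "inframe",
  "inframe_insertion"        = "inframe",
  "splice"                   = "splice",
  "splicing"                 = "splice",
  "splice_donor_variant"     = "splice",
  "splice_acceptor_variant"  = "splice",
  "splice_region_variant"    = "splice",
  "intronic"                 = "intronic",
  "intron_variant"           = "intronic",
  "other"                    = "other"
)

#' Default outbred reference populations
#'
#' Population labels (gnomAD v2.1.1 exome outbred set) over which the popmax
#' allele frequency is taken. Bottlenecked populations (Ashkenazi, Finnish) and
#' the unassigned remainder are excluded, following the popmax convention.
#'
#' @export
OUTBRED_POPULATIONS <- c("afr", "amr", "eas", "nfe", "sas")

#' Normalize chromosome labels
#'
#' Strips a leading `"chr"` so that `"chr7"` and `"7"` compare equal; panel
#' matching and variant identity depend on this normalization.
#'
#' @param x character vector of chromosome labels.
#' @return character vector without the `"chr"` prefix.
#' @export
normalize_chrom <- function(x) sub("^chr", "", as.character(x))

#' Normalize consequence annotations to the controlled vocabulary
#'
#' @param x character vector of annotator consequence terms.
#' @return character vector over [CONSEQUENCE_LEVELS]. Unknown terms map to
#'   `"other"` with a warning.
#' @export
normalize_consequence <- function(x) {
  key <- gsub("\\s+", " ", trimws(tolower(as.character(x))))
  out <- unname(.CONSEQUENCE_MAP[key])
  unknown <- is.na(out) & !is.na(key)
  if (any(unknown)) {
    warning("unknown consequence term(s) mapped to 'other': ",
            paste(unique(key[unknown]), collapse = ", "))
    out[unknown] <- "other"
  }
  out[is.na(key)] <- "other"
  out
}

# Trim shared allele suffix then prefix (advancing pos). Left-alignment without
# a reference genome reduces to this trimming; enough to make identical variants
# written with padded alleles compare equal.
.trim_alleles <- function(pos, ref, alt) {
  pos <- as.integer(pos); ref <- as.character(ref); alt <- as.character(alt)
  for (i in seq_along(pos)) {
    r <- ref[i]; a <- alt[i]; p <- pos[i]
    while (nchar(r) > 1L && nchar(a) > 1L &&
           substr(r, nchar(r), nchar(r)) == substr(a, nchar(a), nchar(a))) {
      r <- substr(r, 1L, nchar(r) - 1L); a <- substr(a, 1L, nchar(a) - 1L)
    }
    while (nchar(r) > 1L && nchar(a) > 1L && substr(r, 1L, 1L) == substr(a, 1L, 1L)) {
      r <- substr(r, 2L, nchar(r)); a <- substr(a, 2L, nchar(a)); p <- p + 1L
    }
    ref[i] <- r; alt[i] <- a; pos[i] <- p
  }
  list(pos = pos, ref = ref, alt = alt)
}

#' Canonical variant identity key
#'
#' Builds `"chrom:pos:ref:alt"` keys after chromosome normalization and
#' trimming of shared allele prefixes/suffixes, so that the same allele written
#' in different padded forms receives the same key. Coordinates are 1-based.
#'
#' @param chrom,pos,ref,alt vectors, or a data.frame with those columns as the
#'   single first argument.
#' @return character vector of keys.
#' @export
variant_key <- function(chrom, pos = NULL, ref = NULL, alt = NULL) {
  if (is.data.frame(chrom)) {
    df <- chrom
    return(variant_key(df$chrom, df$pos, df$ref, df$alt))
  }
  tr <- .trim_alleles(pos, ref, alt)
  paste(normalize_chrom(chrom), tr$pos, toupper(tr$ref), toupper(tr$alt), sep = ":")
}

.MANDATORY_VARIANT_COLS <- c("chrom", "pos", "ref", "alt", "gene", "consequence")

#' Derive the popmax allele frequency
#'
#' Maximum allele frequency over the outbred reference populations present in
#' the table (`af_<pop>` columns). Rows with no recorded AF get `NA`, the
#' convention for novel variants.
#'
#' @param variants variant table with zero or more `af_<pop>` columns.
#' @param populations population labels considered; default [OUTBRED_POPULATIONS].
#' @return numeric vector of popmax AFs (`NA` where no population AF present).
#' @export
derive_af_popmax <- function(variants, populations = OUTBRED_POPULATIONS) {
  cols <- intersect(paste0("af_", populations), names(variants))
  if (length(cols) == 0L) return(rep(NA_real_, nrow(variants)))
  m <- as.matrix(variants[, cols, drop = FALSE])
  out <- suppressWarnings(apply(m, 1L, max, na.rm = TRUE))
  out[!is.finite(out)] <- NA_real_
  out
}

#' Validate a variant table
#'
#' Checks the invariants of the variant record type: positive positions,
#' non-empty distinct alleles, allele frequencies inside `[0, 1]`, CADD scores
#' non-negative.
#'
#' @param variants data.frame to validate.
#' @return the table, invisibly; errors describe the offending row.
#' @export
validate_variant_table <- function(variants) {
  missing_cols <- setdiff(.MANDATORY_VARIANT_COLS, names(variants))
  if (length(missing_cols))
    stop("variant table lacks mandatory column(s): ",
         paste(missing_cols, collapse = ", "))
  bad <- which(is.na(variants$pos) | variants$pos < 1L)
  if (length(bad)) stop("invalid position at row ", bad[1L])
  bad <- which(!nzchar(variants$ref) | !nzchar(variants$alt) |
               variants$ref == variants$alt)
  if (length(bad)) stop("invalid ref/alt alleles at row ", bad[1L])
  af_cols <- grep("^af_", names(variants), value = TRUE)
  for (col in af_cols) {
    v <- variants[[col]]
    bad <- which(!is.na(v) & (v < 0 | v > 1))
    if (length(bad))
      stop("allele frequency outside [0,1] in column '", col, "' at row ", bad[1L])
  }
  if ("cadd_phred" %in% names(variants)) {
    bad <- which(!is.na(variants$cadd_phred) & variants$cadd_phred < 0)
    if (length(bad)) stop("negative CADD score at row ", bad[1L])
  }
  invisible(variants)
}

#' Read an annotated variant table
#'
#' Reads the tab-separated variant dialect: header row with columns
#' `chrom, pos, ref, alt, gene, consequence` and optionally `cadd_phred`,
#' `clinvar` (semicolon-separated assertion labels), `mq`, `ac_case` and any
#' number of `af_<pop>` columns. Consequences are normalized, chromosome labels
#' stripped of `"chr"`, and `af_popmax` derived over the outbred populations.
#'
#' @param path file path.
#' @param populations populations for the popmax derivation.
#' @return data.frame of class `variant_table` with derived columns
#'   `af_popmax` and `is_indel`.
#' @export
read_variant_table <- function(path, populations = OUTBRED_POPULATIONS) {
  raw <- utils::read.delim(path, header = TRUE, sep = "\t",
                           colClasses = "character", check.names = FALSE,
                           na.strings = c("NA", "", "."))
  missing_cols <- setdiff(.MANDATORY_VARIANT_COLS, names(raw))
  if (length(missing_cols))
    stop("'", path, "' lacks mandatory column(s): ",
         paste(missing_cols, collapse = ", "))
  parse_num <- function(col, what) {
    v <- raw[[col]]
    out <- suppressWarnings(as.numeric(v))
    bad <- which(!is.na(v) & is.na(out))
    if (length(bad))
      stop("unparseable ", what, " in '", col, "' at line ", bad[1L] + 1L,
           " of ", path)
    out
  }
  out <- data.frame(
    chrom = normalize_chrom(raw$chrom),
    pos = as.integer(parse_num("pos", "position")),
    ref = toupper(raw$ref),
    alt = toupper(raw$alt),
    gene = raw$gene,
    consequence = normalize_consequence(raw$consequence),
    stringsAsFactors = FALSE
  )
  for (col in setdiff(names(raw), .MANDATORY_VARIANT_COLS)) {
    if (grepl("^af_", col) || col %in% c("cadd_phred", "mq")) {
      out[[col]] <- parse_num(col, "value")
    } else if (col %in% c("ac_case", "an_case")) {
      out[[col]] <- as.integer(parse_num(col, "count"))
    } else {
      out[[col]] <- raw[[col]]
    }
  }
  # a precomputed af_popmax column (annotators often emit one, covering
  # populations beyond those shipped as af_<pop> columns) takes precedence
  if (!"af_popmax" %in% names(out))
    out$af_popmax <- derive_af_popmax(out, populations)
  out$is_indel <- nchar(out$ref) != nchar(out$alt)
  validate_variant_table(out)
  class(out) <- c("variant_table", "data.frame")
  out
}

#' Write a variant table
#'
#' Writes the non-derived columns (everything but `af_popmax` and `is_indel`)
#' as tab-separated text readable by [read_variant_table()].
#'
#' @param variants variant table.
#' @param path output path.
#' @export
write_variant_table <- function(variants, path) {
  keep <- setdiff(names(variants), c("af_popmax", "is_indel"))
  utils::write.table(variants[, keep, drop = FALSE], path, sep = "\t",
                     quote = FALSE, row.names = FALSE, na = "")
  invisible(path)
}

#' Cohort genotype container
#'
#' Sample-by-variant alt-allele dosage matrix with optional allelic depths.
#' Rows are variants (named by [variant_key()] keys), columns are samples.
#'
#' @param variant_keys character vector of variant keys.
#' @param sample_ids character vector of sample identifiers.
#' @param dosage integer matrix (variants x samples) with entries 0/1/2 or `NA`.
#' @param ad_ref,ad_alt optional matrices of reference/alternate read depths.
#' @return object of class `cohort_genotypes`.
#' @export
cohort_genotypes <- function(variant_keys, sample_ids, dosage,
                             ad_ref = NULL, ad_alt = NULL) {
  dosage <- as.matrix(dosage)
  if (nrow(dosage) != length(variant_keys) || ncol(dosage) != length(sample_ids))
    stop("dosage matrix dimensions do not match variant/sample counts")
  vals <- dosage[!is.na(dosage)]
  if (length(vals) && !all(vals %in% 0:2))
    stop("dosage entries must be 0, 1, 2 or missing")
  for (m in list(ad_ref, ad_alt)) {
    if (!is.null(m)) {
      if (!all(dim(m) == dim(dosage)))
        stop("allelic depth matrix dimensions do not match the dosage matrix")
      if (any(m[!is.na(m)] < 0)) stop("read depths must be non-negative")
    }
  }
  rownames(dosage) <- variant_keys
  colnames(dosage) <- sample_ids
  structure(list(variant_keys = variant_keys, sample_ids = sample_ids,
                 dosage = dosage, ad_ref = ad_ref, ad_alt = ad_alt),
            class = "cohort_genotypes")
}

#' @export
print.cohort_genotypes <- function(x, ...) {
  cat("cohort_genotypes:", length(x$variant_keys), "variants x",
      length(x$sample_ids), "samples",
      if (!is.null(x$ad_alt)) "(with allelic depths)" else "", "\n")
  invisible(x)
}

# dosage of alt allele `allele_idx` for one GT string vector ("0/1", "1|2", ...)
.gt_dosage <- function(gt, allele_idx) {
  out <- rep(NA_integer_, length(gt))
  ok <- !is.na(gt) & !grepl("\\.", gt)
  parts <- strsplit(gt[ok], "[/|]")
  out[ok] <- vapply(parts, function(p) sum(p == as.character(allele_idx)), 0L)
  out
}

#' Read a cohort VCF
#'
#' Reads a VCF 4.x file (via \pkg{vcfR}), honoring the GT and, when present,
#' AD fields. Multi-allelic sites are decomposed into one record per alternate
#' allele; the dosage of each record counts that allele only.
#'
#' @param path VCF file path.
#' @return list with components `genotypes` ([cohort_genotypes]) and
#'   `variants` (minimal `variant_table`: key columns plus consequence
#'   `"other"` placeholders when the VCF carries no annotation).
#' @export
read_vcf_cohort <- function(path) {
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  fix <- as.data.frame(vcfR::getFIX(v), stringsAsFactors = FALSE)
  if (ncol(v@gt) < 2L) stop("VCF has no sample columns")
  if (!all(grepl("(^|:)GT(:|$)", v@gt[, "FORMAT"])))
    stop("VCF FORMAT lacks GT for some records")
  gt <- vcfR::extract.gt(v, element = "GT")
  ad <- tryCatch(vcfR::extract.gt(v, element = "AD"), error = function(e) NULL)
  samples <- colnames(gt)

  rows <- list(); keys <- character(0)
  dosage <- list(); ad_ref <- list(); ad_alt <- list()
  for (i in seq_len(nrow(fix))) {
    alts <- strsplit(fix$ALT[i], ",", fixed = TRUE)[[1L]]
    ad_i <- if (!is.null(ad)) strsplit(ad[i, ], ",", fixed = TRUE) else NULL
    for (j in seq_along(alts)) {
      rows[[length(rows) + 1L]] <- data.frame(
        chrom = normalize_chrom(fix$CHROM[i]), pos = as.integer(fix$POS[i]),
        ref = fix$REF[i], alt = alts[j],
        gene = NA_character_, consequence = "other",
        stringsAsFactors = FALSE)
      dosage[[length(dosage) + 1L]] <- .gt_dosage(gt[i, ], j)
      if (!is.null(ad_i)) {
        ad_ref[[length(ad_ref) + 1L]] <-
          suppressWarnings(as.integer(vapply(ad_i, function(x) x[1L], "")))
        ad_alt[[length(ad_alt) + 1L]] <-
          suppressWarnings(as.integer(vapply(ad_i, function(x)
            if (length(x) > j) x[j + 1L] else NA_character_, "")))
      }
    }
  }
  variants <- do.call(rbind, rows)
  keys <- variant_key(variants)
  geno <- cohort_genotypes(
    keys, samples, do.call(rbind, dosage),
    ad_ref = if (length(ad_ref)) do.call(rbind, ad_ref) else NULL,
    ad_alt = if (length(ad_alt)) do.call(rbind, ad_alt) else NULL)
  class(variants) <- c("variant_table", "data.frame")
  list(genotypes = geno, variants = variants)
}

#' Read an external-control summary table
#'
#' Two shapes are accepted. Per-variant: tab-separated with columns
#' `chrom, pos, ref, alt, gene, consequence, ac, an` (and optional `af_<pop>`
#' columns). Per-class: columns `gene, class, ac, an, n_variants` where `class`
#' is `"functional"` or `"synonymous"` and counts are already restricted to
#' rare qualifying alleles.
#'
#' @param path file path.
#' @param n_controls control cohort size; if missing, inferred as `max(an)/2`.
#' @return data.frame of class `control_summary` with attribute `n_controls`
#'   and attribute `shape` (`"variant"` or `"class"`).
#' @export
read_control_summary <- function(path, n_controls = NULL) {
  df <- utils::read.delim(path, header = TRUE, sep = "\t",
                          na.strings = c("NA", "", "."),
                          stringsAsFactors = FALSE)
  control_summary(df, n_controls = n_controls)
}

#' Construct a control summary from a data.frame
#'
#' @param df data.frame in either shape accepted by [read_control_summary()].
#' @param n_controls control cohort size.
#' @return `control_summary` object.
#' @export
control_summary <- function(df, n_controls = NULL) {
  if (all(c("chrom", "pos", "ref", "alt") %in% names(df))) {
    shape <- "variant"
    if (!all(c("gene", "ac", "an") %in% names(df)))
      stop("per-variant control summary needs columns gene, ac, an")
    if ("consequence" %in% names(df))
      df$consequence <- normalize_consequence(df$consequence)
  } else {
    shape <- "class"
    need <- c("gene", "class", "ac", "an")
    if (!all(need %in% names(df)))
      stop("per-class control summary needs columns ",
           paste(need, collapse = ", "))
    if (!all(df$class %in% c("functional", "synonymous")))
      stop("control class labels must be 'functional' or 'synonymous'")
    if (!"n_variants" %in% names(df)) df$n_variants <- df$ac
  }
  if (any(df$ac < 0) || any(df$ac > df$an))
    stop("control allele counts must satisfy 0 <= ac <= an")
  if (is.null(n_controls)) n_controls <- max(df$an, 0L) / 2
  structure(df, class = c("control_summary", "data.frame"),
            shape = shape, n_controls = n_controls)
}

#' Read a screening panel
#'
#' Tab-separated panel keyed by `chrom, pos, ref, alt`, carrying either an
#' allele-frequency column `af` (reference panels) or `series, occurrences`
#' columns (tumor-series panels).
#'
#' @param path file path.
#' @return data.frame of class `panel_table` with a `key` column.
#' @export
read_panel_table <- function(path) {
  df <- utils::read.delim(path, header = TRUE, sep = "\t",
                          na.strings = c("NA", "", "."),
                          stringsAsFactors = FALSE)
  need <- c("chrom", "pos", "ref", "alt")
  if (!all(need %in% names(df)))
    stop("'", path, "' lacks panel key column(s): ",
         paste(setdiff(need, names(df)), collapse = ", "))
  if ("af" %in% names(df) && any(!is.na(df$af) & (df$af < 0 | df$af > 1)))
    stop("panel AF outside [0,1]")
  if ("occurrences" %in% names(df) &&
      any(!is.na(df$occurrences) & df$occurrences < 0))
    stop("panel occurrence counts must be non-negative")
  df$key <- variant_key(df)
  structure(df, class = c("panel_table", "data.frame"))
}

#' Read a clinical record table
#'
#' Comma-separated clinical table with columns `case_id, sex,
#' age_first_melanoma, age_first_rcc, melanoma_histology, rcc_histology,
#' other_solid_tumors, family_history, mc1r_variants`. `mc1r_variants` is a
#' semicolon-separated list of `variant:class` entries with class in
#' `R` (moderate melanoma risk), `r` (low risk) or `other`; empty means no
#' variant (wild type).
#'
#' @param path file path.
#' @return data.frame of class `clinical_table`.
#' @export
read_clinical_table <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE,
                        na.strings = c("NA", ""))
  need <- c("case_id", "sex")
  if (!all(need %in% names(df)))
    stop("clinical table lacks column(s): ",
         paste(setdiff(need, names(df)), collapse = ", "))
  for (col in c("age_first_melanoma", "age_first_rcc")) {
    if (col %in% names(df)) {
      bad <- which(!is.na(df[[col]]) & df[[col]] <= 0)
      if (length(bad)) stop("non-positive age at row ", bad[1L])
    }
  }
  if (!"mc1r_variants" %in% names(df)) df$mc1r_variants <- NA_character_
  for (col in c("other_solid_tumors", "family_history")) {
    if (col %in% names(df)) df[[col]] <- as.logical(df[[col]])
  }
  cls <- unlist(lapply(mc1r_classes(df$mc1r_variants), identity))
  if (length(cls) && !all(cls %in% c("R", "r", "other")))
    stop("MC1R variant classes must be 'R', 'r' or 'other'")
  structure(df, class = c("clinical_table", "data.frame"))
}

#' Parse MC1R variant class lists
#'
#' @param x character vector of semicolon-separated `variant:class` entries.
#' @return list of character vectors of class labels (empty = wild type).
#' @export
mc1r_classes <- function(x) {
  lapply(x, function(s) {
    if (is.na(s) || !nzchar(s)) return(character(0))
    parts <- strsplit(s, ";", fixed = TRUE)[[1L]]
    vapply(parts, function(p) sub("^.*:", "", trimws(p)), "", USE.NAMES = FALSE)
  })
}
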