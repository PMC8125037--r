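# Readers, variant identity and derived annotations.

write_tsv <- function(df, path = tempfile(fileext = ".tsv")) {
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE,
                     na = ".")
  path
}

test_that("variant tables read with popmax derivation and strict validation", {
  path <- write_tsv(data.frame(
    chrom = c("chr1", "2", "3"), pos = c(100, 200, 300),
    ref = c("A", "C", "G"), alt = c("G", "T", "A"),
    gene = c("PIK3CD", "GENE2", "GENE3"),
    consequence = c("nonsynonymous SNV", "synonymous SNV", "missense"),
    cadd_phred = c(35, 1, 22),
    af_nfe = c(9e-6, NA, 0.5), af_afr = c(NA, NA, 0.1)))
  tab <- read_variant_table(path)
  expect_s3_class(tab, "variant_table")
  expect_equal(tab$chrom, c("1", "2", "3"))  # "chr" stripped
  expect_equal(tab$consequence, c("missense", "synonymous", "missense"))
  expect_equal(tab$af_popmax, c(9e-6, NA, 0.5))
  expect_false(tab$is_indel[1])

  # out-of-range AF rejected, missing mandatory column named in the error
  bad <- write_tsv(data.frame(chrom = "1", pos = 1, ref = "A", alt = "G",
                              gene = "X", consequence = "missense",
                              af_nfe = 1.5))
  expect_error(read_variant_table(bad), "af_nfe")
  nocol <- write_tsv(data.frame(chrom = "1", pos = 1, ref = "A", alt = "G",
                                gene = "X"))
  expect_error(read_variant_table(nocol), "consequence")
  badpos <- write_tsv(data.frame(chrom = "1", pos = "12x", ref = "A",
                                 alt = "G", gene = "X",
                                 consequence = "missense"))
  expect_error(read_variant_table(badpos), "line 2")
})

test_that("round trip preserves all non-derived fields", {
  path <- pb_fixture("candidate_variants.tsv")
  t1 <- read_variant_table(path)
  out <- tempfile(fileext = ".tsv")
  write_variant_table(t1, out)
  t2 <- read_variant_table(out)
  keep <- setdiff(names(t1), c("af_popmax", "is_indel"))
  expect_identical(t1[, keep], t2[, keep])
  # fixture-specific sanity: 41 candidate variants in 13 genes
  expect_equal(nrow(t1), 41L)
  expect_equal(length(unique(t1$gene)), 13L)
})

test_that("af_popmax equals the brute-force max over recorded populations", {
  set.seed(42)
  pops <- OUTBRED_POPULATIONS
  for (i in 1:50) {
    df <- data.frame(chrom = "1", pos = 1L, ref = "A", alt = "G",
                     gene = "X", consequence = "missense")
    present <- sample(c(TRUE, FALSE), length(pops), replace = TRUE)
    afs <- ifelse(present, runif(length(pops), 0, 0.01), NA_real_)
    for (j in seq_along(pops)) df[[paste0("af_", pops[j])]] <- afs[j]
    got <- derive_af_popmax(df)
    want <- if (any(present)) max(afs, na.rm = TRUE) else NA_real_
    expect_equal(got, want)
  }
})

test_that("variant keys normalize padding and chromosome labels", {
  expect_equal(variant_key("chr7", 100, "A", "G"), variant_key("7", 100, "A", "G"))
  # shared suffix then prefix trimmed, position advanced
  expect_equal(variant_key("1", 100, "ATG", "ACG"), "1:101:T:C")
  expect_equal(variant_key("1", 100, "TA", "TG"), "1:101:A:G")
  expect_equal(variant_key("1", 100, "CAG", "CG"), "1:100:CA:C")
})

test_that("VCF cohorts decompose multi-allelic sites and honor GT/AD", {
  vcf <- tempfile(fileext = ".vcf")
  writeLines(c(
    "##fileformat=VCFv4.2",
    '##FORMAT=<ID=GT,Number=1,Type=String,Description="Genotype">',
    '##FORMAT=<ID=AD,Number=R,Type=Integer,Description="Allelic depths">',
    "#CHROM\tPOS\tID\tREF\tALT\tQUAL\tFILTER\tINFO\tFORMAT\tS1\tS2",
    "1\t100\t.\tA\tG\t.\tPASS\t.\tGT:AD\t0/1:5,7\t0/0:12,0",
    "1\t200\t.\tC\tT\t.\tPASS\t.\tGT:AD\t./.:.\t1/1:0,20",
    "2\t300\t.\tG\tA,T\t.\tPASS\t.\tGT:AD\t1/2:2,5,6\t0/1:8,9,0"),
    vcf)
  res <- read_vcf_cohort(vcf)
  geno <- res$genotypes
  expect_equal(length(geno$sample_ids), 2L)
  # site 1: GT 0/1 and 0/0 -> dosages 1, 0
  expect_equal(unname(geno$dosage[1, ]), c(1L, 0L))
  # site 2: ./. -> missing
  expect_true(is.na(geno$dosage[2, 1]))
  expect_equal(geno$dosage[2, 2], 2L)
  # triallelic site decomposes into two keys sharing the position,
  # matching a manual decomposition of the GT strings
  expect_equal(nrow(res$variants), 4L)
  tri <- res$variants[res$variants$pos == 300, ]
  expect_equal(tri$alt, c("A", "T"))
  expect_equal(unname(geno$dosage[3, ]), c(1L, 1L))  # allele 1 of 1/2 and 0/1
  expect_equal(unname(geno$dosage[4, ]), c(1L, 0L))  # allele 2
  expect_equal(unname(geno$ad_alt[4, ]), c(6L, 0L))
})

test_that("invalid genotype containers are rejected", {
  expect_error(cohort_genotypes("k", c("a", "b"), matrix(0L, 2, 2)),
               "dimensions")
  expect_error(cohort_genotypes("k", "a", matrix(3L, 1, 1)), "dosage")
  expect_error(control_summary(data.frame(gene = "g", class = "functional",
                                          ac = 5, an = 4)), "ac <= an")
})
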