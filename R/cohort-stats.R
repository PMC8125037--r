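# Exact clinical association tests and cohort summary tallies.

#' Two-sided Fisher exact test for a 2x2 table
#'
#' Exact p-value by probability ordering: with both margins fixed, sums the
#' hypergeometric probabilities of every table whose probability does not
#' exceed that of the observed one. A zero margin gives p = 1 by convention.
#'
#' @param a,b,c,d cell counts (rows = exposure groups, columns = outcome); or
#'   a 2x2 matrix as the single first argument.
#' @param alternative `"two.sided"` (default), `"greater"` (upper-left cell
#'   enriched) or `"less"`.
#' @return the exact p-value.
#' @export
fisher_exact_2x2 <- function(a, b = NULL, c = NULL, d = NULL,
                             alternative = c("two.sided", "greater", "less")) {
  alternative <- match.arg(alternative)
  if (is.matrix(a)) { d <- a[2, 2]; c <- a[2, 1]; b <- a[1, 2]; a <- a[1, 1] }
  cells <- c(a, b, c, d)
  if (any(cells < 0) || any(cells != floor(cells)))
    stop("cell counts must be non-negative integers")
  if (sum(cells) < 1) stop("table total must be at least 1")
  r1 <- a + b; r2 <- c + d; c1 <- a + c; c2 <- b + d
  if (r1 == 0 || r2 == 0 || c1 == 0 || c2 == 0) return(1)
  support <- max(0, c1 - r2):min(r1, c1)
  probs <- stats::dhyper(support, r1, r2, c1)
  p_obs <- probs[match(a, support)]
  switch(alternative,
         two.sided = sum(probs[probs <= p_obs * (1 + 1e-7)]),
         greater = sum(probs[support >= a]),
         less = sum(probs[support <= a]))
}

#' Mann-Whitney U test
#'
#' Rank-sum comparison of two samples. U is computed with midranks for ties.
#' The p-value is exact — by enumeration of all rank assignments — when the
#' combined sample size is at most `exact_max_n` and there are no ties;
#' otherwise a normal approximation with tie correction and continuity
#' correction is used.
#'
#' @param x,y numeric vectors (both non-empty).
#' @param exact_max_n switch point between the exact and approximate paths
#'   (default 12).
#' @return list with `U` (for the `x` sample), `p_value` and `method`.
#' @export
mann_whitney_u <- function(x, y, exact_max_n = 12L) {
  if (length(x) == 0L || length(y) == 0L) stop("both groups must be non-empty")
  n1 <- length(x); n2 <- length(y); n <- n1 + n2
  r <- rank(c(x, y))
  u <- sum(r[seq_len(n1)]) - n1 * (n1 + 1) / 2
  ties <- anyDuplicated(c(x, y)) > 0L
  mu <- n1 * n2 / 2
  if (!ties && n <= exact_max_n) {
    dev_obs <- abs(u - mu)
    combos <- utils::combn(n, n1)
    us <- colSums(matrix(seq_len(n)[combos], nrow = n1)) - n1 * (n1 + 1) / 2
    p <- mean(abs(us - mu) >= dev_obs - 1e-9)
    method <- "exact enumeration"
  } else {
    tab <- table(c(x, y))
    tie_term <- sum(tab^3 - tab) / (n * (n - 1))
    sigma <- sqrt(n1 * n2 / 12 * ((n + 1) - tie_term))
    if (sigma == 0) return(list(U = u, p_value = 1, method = "degenerate"))
    z <- (abs(u - mu) - 0.5) / sigma  # continuity-corrected
    z <- max(0, z)
    p <- 2 * stats::pnorm(z, lower.tail = FALSE)
    p <- min(1, p)
    method <- "normal approximation"
  }
  list(U = u, p_value = p, method = method)
}

#' Carrier summary tallies
#'
#' Deterministic cohort tallies from clinical records plus per-case variant
#' assignments: carrier counts overall and per gene, co-carriage of MC1R
#' variants among carriers, and single- versus multi-hit carriers (by number
#' of assigned variants).
#'
#' @param clinical [read_clinical_table()]-style data.frame covering carriers
#'   (it may cover the whole cohort).
#' @param assignments data.frame with columns `case_id`, `gene` (one row per
#'   assigned variant); every `case_id` must appear in `clinical`.
#' @param n_cohort total cohort size (defaults to `nrow(clinical)`).
#' @return list of class `carrier_summary` with `n_cohort`, `n_carriers`,
#'   `carrier_rate`, `per_gene` counts, `n_carriers_with_mc1r`,
#'   `n_single_hit`, `n_multi_hit`.
#' @export
carrier_summary <- function(clinical, assignments, n_cohort = nrow(clinical)) {
  stopifnot(all(c("case_id", "gene") %in% names(assignments)))
  dangling <- setdiff(assignments$case_id, clinical$case_id)
  if (length(dangling))
    stop("assignment references unknown case id(s): ",
         paste(dangling, collapse = ", "))
  carriers <- unique(assignments$case_id)
  n_carriers <- length(carriers)
  if (n_carriers > n_cohort) stop("more carriers than cohort members")
  per_gene <- if (nrow(assignments)) {
    tab <- tapply(assignments$case_id, assignments$gene,
                  function(ids) length(unique(ids)))
    stats::setNames(as.integer(tab), names(tab))
  } else integer(0)
  mc1r <- mc1r_classes(clinical$mc1r_variants[
    match(carriers, clinical$case_id)])
  hits <- table(assignments$case_id)
  structure(list(
    n_cohort = n_cohort,
    n_carriers = n_carriers,
    carrier_rate = n_carriers / n_cohort,
    per_gene = per_gene,
    n_carriers_with_mc1r = sum(lengths(mc1r) > 0L),
    n_single_hit = sum(hits == 1L),
    n_multi_hit = sum(hits > 1L)
  ), class = "carrier_summary")
}

#' @export
print.carrier_summary <- function(x, ...) {
  cat(sprintf("carriers: %d / %d (%.1f%%); with MC1R variant: %d; single-hit: %d, multi-hit: %d\n",
              x$n_carriers, x$n_cohort, 100 * x$carrier_rate,
              x$n_carriers_with_mc1r, x$n_single_hit, x$n_multi_hit))
  invisible(x)
}

#' Carrier status versus personal history of other solid tumors
#'
#' Builds the 2x2 table of carriage of a gene set against the presence of at
#' least one solid tumor other than the index diagnoses
#' (`other_solid_tumors`), and applies the two-sided Fisher exact test.
#'
#' @param assignments per-case variant assignments (`case_id`, `gene`).
#' @param clinical clinical table covering all cases, with the logical column
#'   `other_solid_tumors`.
#' @param genes non-empty character vector of genes defining carriage.
#' @return list with `table` (2x2 matrix: rows carrier/non-carrier, columns
#'   other-tumor yes/no) and `p_value`.
#' @export
exclusivity_and_history_test <- function(assignments, clinical, genes) {
  if (length(genes) == 0L) stop("gene set must be non-empty")
  carriers <- unique(assignments$case_id[assignments$gene %in% genes])
  is_carrier <- clinical$case_id %in% carriers
  tumor <- clinical$other_solid_tumors %in% TRUE
  tab <- matrix(c(sum(is_carrier & tumor), sum(is_carrier & !tumor),
                  sum(!is_carrier & tumor), sum(!is_carrier & !tumor)),
                nrow = 2L, byrow = TRUE,
                dimnames = list(c("carrier", "non-carrier"),
                                c("other tumor", "none")))
  list(table = tab, p_value = fisher_exact_2x2(tab))
}

#' Age at onset by carrier status
#'
#' Compares the age at first diagnosis between carriers and non-carriers of a
#' gene set with the Mann-Whitney U test, and reports the group medians.
#'
#' @param assignments per-case variant assignments.
#' @param clinical clinical table with the age column.
#' @param genes gene set defining carriage.
#' @param age_col which age column to compare
#'   (default `"age_first_melanoma"`).
#' @return list with `median_carrier`, `median_noncarrier`, `U`, `p_value`,
#'   `n_carrier`, `n_noncarrier`.
#' @export
age_onset_comparison <- function(assignments, clinical, genes,
                                 age_col = "age_first_melanoma") {
  carriers <- unique(assignments$case_id[assignments$gene %in% genes])
  age <- clinical[[age_col]]
  is_carrier <- clinical$case_id %in% carriers
  x <- age[is_carrier & !is.na(age)]
  y <- age[!is_carrier & !is.na(age)]
  if (length(x) == 0L && length(y) == 0L) stop("no ages available")
  if (length(x) == 0L || length(y) == 0L)
    stop("one comparison group has no recorded ages")
  mw <- mann_whitney_u(x, y)
  list(median_carrier = stats::median(x), median_noncarrier = stats::median(y),
       U = mw$U, p_value = mw$p_value,
       n_carrier = length(x), n_noncarrier = length(y))
}
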