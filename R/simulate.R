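# Synthetic case/control cohort generator with the statistical structure the
# enrichment analysis assumes: per-gene Poisson rare-allele counts split into
# functional and synonymous classes, an optional gene-level enrichment
# multiplier acting on case functional counts, and a processing-artifact
# multiplier acting equally on both control classes.

#' Simulation configuration
#'
#' Generative parameters for synthetic cohorts. Defaults emulate a small
#' double-primary case series (46 exomes) tested against an external control
#' panel, with per-gene allele rates typical of long, variant-rich genes
#' (roughly 10 kb of coding sequence):
#'
#' * `lambda_fun`, `lambda_syn` (0.08 each): expected rare *qualifying*
#'   functional (post-deleteriousness-filter) and synonymous alleles per
#'   diploid genome per gene.
#' * `fraction_deleterious` (0.5): share of functional variants passing the
#'   CADD rule; the generator draws total functional alleles at
#'   `lambda_fun / fraction_deleterious` and marks each deleterious with this
#'   probability, so the post-filter rate stays `lambda_fun`.
#' * `n_enriched`, `rho`: number of genes whose case functional rate is
#'   multiplied by `rho >= 1` (the first `n_enriched` genes).
#' * `kappa` (1): processing-artifact multiplier applied to BOTH control
#'   classes — it cancels from the functional/synonymous ratio, which is the
#'   property the synonymous-proxy test exploits.
#' * clinical model: ages at first diagnosis are normal around 57.3
#'   (melanoma) and 58.8 (RCC) years with SD 12, shifted by
#'   `carrier_age_shift` for carriers of enriched genes; probability of
#'   another solid tumor differs by carrier status.
#'
#' @param seed integer RNG seed (Mersenne-Twister).
#' @param n_case,n_ctrl cohort sizes (defaults 46 and 2000; pass 19751 for a
#'   full-size external panel).
#' @param n_genes number of simulated genes.
#' @param lambda_fun,lambda_syn,fraction_deleterious see above.
#' @param n_enriched,rho,kappa see above.
#' @param age_mean_melanoma,age_mean_rcc,age_sd,carrier_age_shift years.
#' @param other_tumor_p_carrier,other_tumor_p_noncarrier probabilities.
#' @return object of class `simulation_config`.
#' @export
simulation_config <- function(seed = 1L, n_case = 46L, n_ctrl = 2000L,
                              n_genes = 500L,
                              lambda_fun = 0.08, lambda_syn = 0.08,
                              fraction_deleterious = 0.5,
                              n_enriched = 0L, rho = 1, kappa = 1,
                              age_mean_melanoma = 57.3, age_mean_rcc = 58.8,
                              age_sd = 12, carrier_age_shift = -7,
                              other_tumor_p_carrier = 0.5,
                              other_tumor_p_noncarrier = 0.25) {
  stopifnot(n_case >= 1, n_ctrl >= 1, n_genes >= 1,
            lambda_fun >= 0, lambda_syn >= 0,
            fraction_deleterious > 0, fraction_deleterious <= 1,
            n_enriched >= 0, n_enriched <= n_genes,
            rho >= 1, kappa > 0, age_sd > 0,
            other_tumor_p_carrier >= 0, other_tumor_p_carrier <= 1,
            other_tumor_p_noncarrier >= 0, other_tumor_p_noncarrier <= 1)
  structure(list(seed = as.integer(seed), n_case = as.integer(n_case),
                 n_ctrl = as.integer(n_ctrl), n_genes = as.integer(n_genes),
                 lambda_fun = lambda_fun, lambda_syn = lambda_syn,
                 fraction_deleterious = fraction_deleterious,
                 n_enriched = as.integer(n_enriched), rho = rho, kappa = kappa,
                 age_mean_melanoma = age_mean_melanoma,
                 age_mean_rcc = age_mean_rcc, age_sd = age_sd,
                 carrier_age_shift = carrier_age_shift,
                 other_tumor_p_carrier = other_tumor_p_carrier,
                 other_tumor_p_noncarrier = other_tumor_p_noncarrier),
            class = "simulation_config")
}

#' Simulate a case/control cohort
#'
#' Draws, per gene, independent Poisson allele counts — case functional at
#' rate `2 * n_case * lambda_fun / fraction_deleterious * rho_g`, case
#' synonymous at `2 * n_case * lambda_syn`, control functional (qualifying)
#' at `2 * n_ctrl * lambda_fun * kappa` and control synonymous at
#' `2 * n_ctrl * lambda_syn * kappa` — and materializes the case counts as
#' singleton variants (each allele a distinct novel variant carried by one
#' sample), annotated so that the deleteriousness filter passes each
#' functional variant with probability `fraction_deleterious`. Controls are
#' emitted as a per-gene, per-class summary of qualifying alleles. Clinical
#' records follow the configured carrier model. Fully reproducible from the
#' seed.
#'
#' @param cfg [simulation_config].
#' @return list with `variants` (case variant table), `genotypes`
#'   ([cohort_genotypes]), `controls` ([control_summary]), `clinical`
#'   (clinical table), `config`, and attribute `rng` naming the generator.
#' @export
simulate_cohort <- function(cfg = simulation_config()) {
  if (!inherits(cfg, "simulation_config")) stop("cfg must be a simulation_config")
  set.seed(cfg$seed, kind = "Mersenne-Twister")
  g <- cfg$n_genes
  genes <- sprintf("G%04d", seq_len(g))
  rho_g <- rep(1, g)
  if (cfg$n_enriched > 0L) rho_g[seq_len(cfg$n_enriched)] <- cfg$rho

  lam_fun_total <- cfg$lambda_fun / cfg$fraction_deleterious
  n_fun <- stats::rpois(g, 2 * cfg$n_case * lam_fun_total * rho_g)
  n_syn <- stats::rpois(g, 2 * cfg$n_case * cfg$lambda_syn)

  gene_of <- c(rep(genes, n_fun), rep(genes, n_syn))
  gidx <- c(rep(seq_len(g), n_fun), rep(seq_len(g), n_syn))
  is_fun <- c(rep(TRUE, sum(n_fun)), rep(FALSE, sum(n_syn)))
  nv <- length(gene_of)
  deleterious <- is_fun & stats::runif(nv) < cfg$fraction_deleterious
  cadd <- ifelse(deleterious, 20 + stats::runif(nv, 0, 15),
                 stats::runif(nv, 0, 19.5))
  variants <- data.frame(
    chrom = as.character((gidx - 1L) %% 22L + 1L),
    pos = gidx * 100000L + stats::ave(gidx, gidx, FUN = seq_along),
    ref = "A", alt = "G",
    gene = gene_of,
    consequence = ifelse(is_fun, "missense", "synonymous"),
    cadd_phred = round(cadd, 1),
    stringsAsFactors = FALSE)
  variants$af_popmax <- NA_real_
  variants$is_indel <- FALSE
  class(variants) <- c("variant_table", "data.frame")

  samples <- sprintf("S%03d", seq_len(cfg$n_case))
  dosage <- matrix(0L, nrow = nv, ncol = cfg$n_case)
  if (nv) dosage[cbind(seq_len(nv),
                       sample.int(cfg$n_case, nv, replace = TRUE))] <- 1L
  geno <- cohort_genotypes(variant_key(variants), samples, dosage)

  ctrl_fun <- stats::rpois(g, 2 * cfg$n_ctrl * cfg$lambda_fun * cfg$kappa)
  ctrl_syn <- stats::rpois(g, 2 * cfg$n_ctrl * cfg$lambda_syn * cfg$kappa)
  controls <- control_summary(data.frame(
    gene = rep(genes, 2L),
    class = rep(c("functional", "synonymous"), each = g),
    ac = c(ctrl_fun, ctrl_syn),
    an = 2L * cfg$n_ctrl,
    n_variants = c(ctrl_fun, ctrl_syn),
    stringsAsFactors = FALSE), n_controls = cfg$n_ctrl)

  enriched_vars <- deleterious & gidx <= cfg$n_enriched
  carrier <- if (any(enriched_vars)) {
    colSums(dosage[enriched_vars, , drop = FALSE]) > 0L
  } else rep(FALSE, cfg$n_case)
  shift <- ifelse(carrier, cfg$carrier_age_shift, 0)
  p_tumor <- ifelse(carrier, cfg$other_tumor_p_carrier,
                    cfg$other_tumor_p_noncarrier)
  mc1r_pool <- c("V60L:r", "V92M:r", "R151C:R", "R160W:R", "R163Q:r")
  clinical <- data.frame(
    case_id = samples,
    sex = sample(c("M", "F"), cfg$n_case, replace = TRUE, prob = c(0.64, 0.36)),
    age_first_melanoma = pmax(18, round(stats::rnorm(
      cfg$n_case, cfg$age_mean_melanoma + shift, cfg$age_sd))),
    age_first_rcc = pmax(18, round(stats::rnorm(
      cfg$n_case, cfg$age_mean_rcc + shift, cfg$age_sd))),
    melanoma_histology = sample(c("SSM", "NM", "LMM"), cfg$n_case,
                                replace = TRUE, prob = c(0.7, 0.2, 0.1)),
    rcc_histology = sample(c("ccRCC", "pRCC", "chRCC"), cfg$n_case,
                           replace = TRUE, prob = c(0.75, 0.15, 0.1)),
    other_solid_tumors = stats::runif(cfg$n_case) < p_tumor,
    family_history = stats::runif(cfg$n_case) < 0.1,
    mc1r_variants = ifelse(stats::runif(cfg$n_case) < 0.65,
                           sample(mc1r_pool, cfg$n_case, replace = TRUE),
                           NA_character_),
    stringsAsFactors = FALSE)
  class(clinical) <- c("clinical_table", "data.frame")

  structure(list(variants = variants, genotypes = geno, controls = controls,
                 clinical = clinical, config = cfg),
            rng = "Mersenne-Twister")
}

#' Null calibration experiment
#'
#' Runs the full enrichment scan on replicate null cohorts (no enriched gene)
#' and reports the empirical type-I error of the weighted synonymous-proxy
#' test and of the naive functional-only comparison at the requested alpha
#' levels. With a processing artifact (`kappa != 1`) the naive test loses
#' calibration while the proxy test does not.
#'
#' @param cfg [simulation_config] with `n_enriched = 0`.
#' @param n_reps number of replicate cohorts.
#' @param alpha significance levels.
#' @return data.frame with columns `alpha`, `proxy_rate`, `naive_rate`,
#'   `n_genes` (total genes tested across replicates).
#' @export
null_calibration_experiment <- function(cfg = simulation_config(),
                                        n_reps = 4L,
                                        alpha = c(0.05, 0.01)) {
  if (cfg$n_enriched != 0L) stop("null calibration requires n_enriched = 0")
  if (n_reps == 0L)
    return(data.frame(alpha = numeric(0), proxy_rate = numeric(0),
                      naive_rate = numeric(0), n_genes = integer(0)))
  p_proxy <- numeric(0); p_naive <- numeric(0)
  for (rep in seq_len(n_reps)) {
    cfg_r <- cfg; cfg_r$seed <- cfg$seed + rep - 1L
    sim <- simulate_cohort(cfg_r)
    res <- run_enrichment_scan(sim$variants, sim$controls,
                               geno = sim$genotypes)
    p_proxy <- c(p_proxy, res$p_raw[!is.na(res$p_raw)])
    nv <- naive_functional_test(res$fun_case, res$fun_ctrl,
                                cfg$n_case, cfg$n_ctrl)
    p_naive <- c(p_naive, nv$p_value)
  }
  data.frame(alpha = alpha,
             proxy_rate = vapply(alpha, function(a) mean(p_proxy < a), 0),
             naive_rate = vapply(alpha, function(a) mean(p_naive < a), 0),
             n_genes = length(p_proxy))
}

#' Power experiment over enrichment rate ratios
#'
#' For each rate ratio in the grid, simulates cohorts in which the first
#' `n_enriched` genes carry the ratio, runs the enrichment scan and reports
#' the fraction of enriched genes reaching the discovery threshold.
#'
#' @param cfg base [simulation_config]; if `cfg$n_enriched` is 0, 5% of the
#'   genes (at least 1) are designated enriched.
#' @param rho_grid rate ratios, all `>= 1`.
#' @param n_reps replicates per grid point.
#' @param q_threshold discovery threshold on the q-value (default 0.2).
#' @return data.frame with `rho` and `power`.
#' @export
power_experiment <- function(cfg = simulation_config(), rho_grid = c(1, 2, 5, 10),
                             n_reps = 2L, q_threshold = 0.2) {
  stopifnot(all(rho_grid >= 1))
  if (cfg$n_enriched == 0L) cfg$n_enriched <- max(1L, round(cfg$n_genes * 0.05))
  power <- vapply(rho_grid, function(rho) {
    hits <- 0L; tot <- 0L
    for (rep in seq_len(n_reps)) {
      cfg_r <- cfg
      cfg_r$rho <- rho
      cfg_r$seed <- cfg$seed + 1000L * rep + round(100 * rho)
      sim <- simulate_cohort(cfg_r)
      res <- run_enrichment_scan(sim$variants, sim$controls,
                                 geno = sim$genotypes,
                                 q_threshold = q_threshold)
      enriched <- sprintf("G%04d", seq_len(cfg$n_enriched))
      hits <- hits + sum(res$significant[res$gene %in% enriched])
      tot <- tot + length(enriched)
    }
    hits / tot
  }, numeric(1L))
  data.frame(rho = rho_grid, power = power)
}
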