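# Brute-force oracles and small fixture builders shared across the suite.
# Each oracle is written independently of the implementation it checks.

# Exact HWE by explicit enumeration of genotype configurations: weight of a
# configuration (nAA, nAa, naa) given fixed allele counts is the multinomial
# coefficient times 2^nAa, normalized over all compatible configurations.
oracle_hwe <- function(n_hom_ref, n_het, n_hom_alt) {
  n <- n_hom_ref + n_het + n_hom_alt
  n_alt <- 2 * n_hom_alt + n_het
  cfgs <- expand.grid(aa = 0:n, ab = 0:n)
  cfgs$bb <- n - cfgs$aa - cfgs$ab
  cfgs <- cfgs[cfgs$bb >= 0 & (cfgs$ab + 2 * cfgs$bb) == n_alt, ]
  if (nrow(cfgs) <= 1L) return(1)
  w <- exp(lgamma(n + 1) - lgamma(cfgs$aa + 1) - lgamma(cfgs$ab + 1) -
             lgamma(cfgs$bb + 1) + cfgs$ab * log(2))
  pr <- w / sum(w)
  p_obs <- pr[cfgs$ab == n_het]
  sum(pr[pr <= p_obs * (1 + 1e-9)])
}

# Two-sided Fisher by full table enumeration with fixed margins, table
# probability from binomial coefficients.
oracle_fisher <- function(a, b, c, d) {
  r1 <- a + b; r2 <- c + d; c1 <- a + c; n <- r1 + r2
  if (r1 == 0 || r2 == 0 || c1 == 0 || (b + d) == 0) return(1)
  as <- max(0, c1 - r2):min(r1, c1)
  pr <- choose(r1, as) * choose(r2, c1 - as) / choose(n, c1)
  p_obs <- pr[as == a]
  sum(pr[pr <= p_obs * (1 + 1e-7)])
}

# Exact two-sided Mann-Whitney by enumeration of all group assignments,
# with U recomputed by direct pair counting.
oracle_mwu <- function(x, y) {
  u_pairs <- function(x, y) sum(outer(x, y, ">") + 0.5 * outer(x, y, "=="))
  n1 <- length(x); n <- n1 + length(y)
  vals <- c(x, y)
  mu <- n1 * (n - n1) / 2
  dev_obs <- abs(u_pairs(x, y) - mu)
  combos <- utils::combn(n, n1)
  devs <- apply(combos, 2, function(idx)
    abs(u_pairs(vals[idx], vals[-idx]) - mu))
  mean(devs >= dev_obs - 1e-9)
}

# Numerical maximization of the constrained Poisson log-likelihood (common
# functional/synonymous ratio) over (log r, log mu_case, log mu_ctrl); the
# LRT statistic follows by subtraction from the saturated likelihood.
oracle_proxecat_stat <- function(fc, sc, fk, sk) {
  xl <- function(x, m) if (x > 0) x * log(m) else 0
  ll0 <- function(par) {
    r <- exp(par[1]); mc <- exp(par[2]); mk <- exp(par[3])
    -(xl(fc, r * mc) - r * mc + xl(sc, mc) - mc +
        xl(fk, r * mk) - r * mk + xl(sk, mk) - mk)
  }
  best <- Inf
  for (r0 in c(0.25, 1, 4)) {
    start <- log(c(r0, (fc + sc + 1) / 2, (fk + sk + 1) / 2))
    fit <- stats::optim(start, ll0, method = "Nelder-Mead",
                        control = list(reltol = 1e-15, maxit = 20000))
    fit <- stats::optim(fit$par, ll0, method = "BFGS",
                        control = list(reltol = 1e-15, maxit = 5000))
    # polish: small coordinate refinement around the optimum
    fit <- stats::optim(fit$par, ll0, method = "Nelder-Mead",
                        control = list(reltol = 1e-15, maxit = 20000))
    best <- min(best, fit$value)
  }
  ll1 <- xl(fc, fc) - fc + xl(sc, sc) - sc + xl(fk, fk) - fk + xl(sk, sk) - sk
  2 * (ll1 + best)
}

# Independent BH step-up: sort ascending, walk from the largest rank down.
oracle_bh <- function(p, m = length(p)) {
  n <- length(p)
  o <- order(p)
  q <- numeric(n)
  cur <- 1
  for (i in n:1) {
    cur <- min(cur, p[o[i]] * m / i)
    q[o[i]] <- cur
  }
  q
}

# Toy genotype container: n_var x n_sample dosage matrix with simple keys.
toy_geno <- function(dosage, ad_ref = NULL, ad_alt = NULL) {
  dosage <- as.matrix(dosage)
  cohort_genotypes(
    variant_keys = sprintf("1:%d:A:G", seq_len(nrow(dosage))),
    sample_ids = sprintf("S%02d", seq_len(ncol(dosage))),
    dosage = dosage, ad_ref = ad_ref, ad_alt = ad_alt)
}

# Minimal case variant table; ac supplies the per-variant case allele count.
toy_variants <- function(gene, consequence, cadd = NA_real_, ac = 1L,
                         af_popmax = NA_real_) {
  n <- max(length(gene), length(consequence))
  df <- data.frame(
    chrom = "1", pos = seq_len(n) * 100L, ref = "A", alt = "G",
    gene = rep_len(gene, n), consequence = rep_len(consequence, n),
    cadd_phred = rep_len(cadd, n), ac_case = rep_len(as.integer(ac), n),
    af_popmax = rep_len(af_popmax, n), stringsAsFactors = FALSE)
  class(df) <- c("variant_table", "data.frame")
  df
}

toy_controls <- function(gene, fun_ac, syn_ac, n_ctrl = 1000L) {
  control_summary(data.frame(
    gene = rep(gene, 2L),
    class = rep(c("functional", "synonymous"), each = length(gene)),
    ac = c(fun_ac, syn_ac), an = 2L * n_ctrl,
    n_variants = pmax(1L, c(fun_ac, syn_ac)),
    stringsAsFactors = FALSE), n_controls = n_ctrl)
}
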