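# Independent oracles: straight-line re-implementations used only to check
# the package's vectorized equation code and samplers. Kept deliberately
# naive (inverse-CDF sampling, scalar loops) so they share no code path with
# the implementation.

# Truncated-normal sampling by inverse CDF (implementation uses rejection).
oracle_rtruncnorm <- function(n, mean, sd, lo, hi) {
  u <- runif(n, pnorm(lo, mean, sd), pnorm(hi, mean, sd))
  qnorm(u, mean, sd)
}

oracle_e2 <- function(t, e20, peak1, peak2, mu1, mu2, s1, s2) {
  e20 + (peak1 - e20) * exp(-(t - mu1)^2 / (2 * s1^2)) +
    (peak2 - e20) * exp(-(t - mu2)^2 / (2 * s2^2))
}

oracle_lh <- function(t, lh0, peak, surge, s) {
  lh0 + (peak - lh0) * exp(-(t - surge)^2 / (2 * s^2))
}

oracle_fsh <- function(t, fsh0, a_early, a_periov, surge, e2val,
                       t_early = 2, s_early = 1.5, s_periov = 0.8,
                       theta = 100, beta = 0.01) {
  v <- fsh0 + a_early * exp(-(t - t_early)^2 / (2 * s_early^2)) +
    a_periov * exp(-(t - (surge - 1))^2 / (2 * s_periov^2)) -
    beta * max(e2val - theta, 0)
  max(v, 0)
}

# Brute-force per-subject feature aggregation (scalar loops, no tapply).
oracle_subject_features <- function(records) {
  hs <- c(e2 = "Estradiol_pg_mL", e1 = "Estrone_pg_mL", fsh = "FSH_mIU_mL",
          lh = "LH_mIU_mL", amh = "AMH_ng_mL", t = "Testosterone_ng_mL",
          gnrh = "GnRH_AU")
  out <- list()
  for (nm in names(hs)) {
    v <- records[[hs[[nm]]]]
    out[[paste0(nm, "_mean")]] <- sum(v) / length(v)
    out[[paste0(nm, "_sd")]] <- sqrt(sum((v - mean(v))^2) / (length(v) - 1))
    out[[paste0(nm, "_max")]] <- max(v)
  }
  out$lh_fsh_ratio <- out$lh_mean / out$fsh_mean
  out$e1_e2_ratio <- out$e1_mean / out$e2_mean
  for (ph in c("follicular", "peri-ovulatory", "luteal", "anovulatory")) {
    out[[paste0("prop_", sub("-", "_", ph))]] <-
      sum(records$phase == ph) / nrow(records)
  }
  lens <- c()
  for (ci in sort(unique(records$cycle_index)))
    lens <- c(lens, records$cycle_length_days[records$cycle_index == ci][1])
  out$cycle_length_mean <- mean(lens)
  out$cycle_length_sd <- if (length(lens) > 1) sd(lens) else 0
  out
}

# Small configurations used across test files.
tiny_config <- function(seed = 42, ...) {
  sim_config(n_eumenorrheic = 4, n_pcos = 2, cycles_per_subject = 2,
             master_seed = seed, ...)
}

noise_off <- list(noise = list(
  e2 = list(base = 0, kappa = 0), lh = list(base = 0, kappa = 0),
  fsh = list(base = 0), e1 = list(base = 0), e1_eum = list(base = 0),
  t = list(base = 0), gnrh = list(base = 0), amh = list(base = 0)))

# One deterministic EUM subject/cycle pair for equation point checks.
point_subject <- function() {
  data.frame(subject_id = "S1", phenotype = "EUM", e2_baseline = 20,
             e2_peak1 = 260, e2_peak2 = 125, lh_baseline = 7, lh_peak = 53,
             fsh_baseline = 7.8, gnrh_baseline = 1.0, a_periov = 0.22,
             t_baseline = 0.4, amh_trait = 2.9, sigma1 = 1.1, sigma2 = 2.0,
             sigma_lh = 0.75, sigma_gnrh = 1.0, alpha_early = 1.5,
             alpha_periov = 1.2, t_amplitude = 0.04, t_phase = 0,
             stringsAsFactors = FALSE)
}

point_cycle <- function(surge = 14.5, delta = 2, dlut = 6.5, L = 28) {
  data.frame(subject_id = "S1", phenotype = "EUM", cycle_index = 1,
             length = L, lh_surge_day = surge, delta = delta,
             mu1 = surge - delta, delta_luteal = dlut,
             mu2 = surge - delta + dlut, stringsAsFactors = FALSE)
}
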