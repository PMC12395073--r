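#' Sample a cycle length
#'
#' Cycle lengths are truncated-normal: eumenorrheic mean 28 sd 2 days on
#' \[24, 35\]; PCOS-like mean 35 sd 6 days on \[28, 60\] (oligomenorrhoea).
#' Truncation is by rejection, so the PCOS mean sits slightly above 35.
#'
#' @param phenotype `"EUM"` or `"PCOS"`.
#' @param params parameter list (see [default_params()]).
#' @param n number of draws.
#' @return numeric vector of lengths in days.
#' @export
sample_cycle_length <- function(phenotype, params = default_params(), n = 1) {
  spec <- switch(match.arg(phenotype, c("EUM", "PCOS")),
                 EUM = params$eum$cycle_length,
                 PCOS = params$pcos$cycle_length)
  draw_param(spec, n)
}

#' Sample one virtual subject
#'
#' Draws every trait-level parameter of a virtual individual from the
#' configured distributions, each truncated to its physiological range by
#' rejection. PCOS AMH carries the negative BMI association
#' `AMH = alpha + beta_bmi * (BMI - 25)`; `alpha` is re-drawn until AMH lands
#' in its range, leaving the BMI marginal untouched.
#'
#' Draws happen under the caller's RNG state; [build_cohort()] wraps each
#' subject in its own derived substream.
#'
#' @param phenotype `"EUM"` or `"PCOS"`.
#' @param subject_id identifier stored in the profile.
#' @param params parameter list.
#' @return one-row `data.frame` (subject profile); PCOS-only and EUM-only
#'   columns are `NA` for the other phenotype.
#' @export
sample_subject <- function(phenotype, subject_id, params = default_params()) {
  phenotype <- match.arg(phenotype, c("EUM", "PCOS"))
  p <- if (phenotype == "EUM") params$eum else params$pcos
  prof <- data.frame(subject_id = subject_id, phenotype = phenotype,
                     age = draw_param(p$age), bmi = draw_param(p$bmi),
                     stringsAsFactors = FALSE)
  if (phenotype == "EUM") {
    prof$amh_trait    <- draw_param(p$amh)
    prof$e2_baseline  <- draw_param(p$e2_baseline)
    prof$e2_peak1     <- draw_param(p$e2_peak1)
    prof$e2_peak2     <- draw_param(p$e2_peak2)
    prof$lh_baseline  <- draw_param(p$lh_baseline)
    prof$lh_peak      <- draw_param(p$lh_peak)
    prof$fsh_baseline <- draw_param(p$fsh_baseline)
    prof$gnrh_baseline <- draw_param(p$gnrh_baseline)
    prof$t_baseline   <- draw_param(p$t_baseline)
    prof$sigma1       <- draw_param(p$sigma1)
    prof$sigma2       <- draw_param(p$sigma2)
    prof$sigma_lh     <- draw_param(p$sigma_lh)
    prof$sigma_gnrh   <- draw_param(p$sigma_gnrh)
    prof$alpha_early  <- draw_param(p$alpha_early)
    prof$alpha_periov <- draw_param(p$alpha_periov)
    prof$a_periov     <- p$gnrh_periov_frac * prof$gnrh_baseline
    prof$e1_level <- prof$e2_level <- prof$lh_level <- NA_real_
    prof$fsh_level <- prof$gnrh_level <- NA_real_
  } else {
    prof$e1_level   <- draw_param(p$e1_level)
    prof$e2_level   <- draw_param(p$e2_level)
    prof$lh_level   <- draw_param(p$lh_level)
    prof$fsh_level  <- draw_param(p$fsh_level)
    prof$gnrh_level <- draw_param(p$gnrh_level)
    prof$t_baseline <- draw_param(p$t_baseline)
    rng <- p$amh_range
    amh <- NA_real_
    for (it in 1:1000) {
      amh <- draw_param(p$amh_alpha) + p$beta_bmi * (prof$bmi - 25)
      if (amh >= rng[1] && amh <= rng[2]) break
      amh <- NA_real_
    }
    if (is.na(amh))
      stop("PCOS AMH rejection failed; beta_bmi/alpha incompatible with range")
    prof$amh_trait <- amh
    prof$e2_baseline <- prof$e2_peak1 <- prof$e2_peak2 <- NA_real_
    prof$lh_baseline <- prof$lh_peak <- prof$fsh_baseline <- NA_real_
    prof$gnrh_baseline <- prof$sigma1 <- prof$sigma2 <- prof$sigma_lh <- NA_real_
    prof$sigma_gnrh <- prof$alpha_early <- prof$alpha_periov <- NA_real_
    prof$a_periov <- NA_real_
  }
  prof$t_amplitude <- draw_param(p$t_amplitude)
  prof$t_phase     <- draw_param(p$t_phase)
  prof
}

#' Sample per-cycle timing parameters
#'
#' For eumenorrheic subjects each cycle re-draws its length, places the LH
#' surge near mid-cycle (`L/2` plus Gaussian jitter), and derives the E2 peak
#' centers: the pre-ovulatory peak leads the surge by `Delta ~ U[1.5, 2.0]` d
#' (the 36-48 h estradiol->LH positive-feedback lag) and the luteal peak
#' follows it by `delta ~ U[5.5, 7.5]` d. Draws violating
#' `1 < mu1 < mu2 < L` are retried (bounded).
#'
#' PCOS cycles are anovulatory: only a length is drawn; surge/peak fields
#' are `NA`.
#'
#' @param subject one-row profile from [sample_subject()].
#' @param cycle_index 1-based cycle number.
#' @param params parameter list.
#' @return one-row `data.frame` of cycle parameters.
#' @export
sample_cycle_params <- function(subject, cycle_index,
                                params = default_params()) {
  phen <- subject$phenotype
  L <- sample_cycle_length(phen, params)
  if (phen == "PCOS") {
    return(data.frame(subject_id = subject$subject_id, phenotype = phen,
                      cycle_index = cycle_index, length = L,
                      lh_surge_day = NA_real_, delta = NA_real_,
                      mu1 = NA_real_, delta_luteal = NA_real_,
                      mu2 = NA_real_, stringsAsFactors = FALSE))
  }
  for (it in 1:1000) {
    surge <- L / 2 + stats::rnorm(1, 0, params$cycle$surge_jitter_sd)
    delta <- draw_param(params$cycle$delta)
    dlut  <- draw_param(params$cycle$delta_luteal)
    mu1 <- surge - delta
    mu2 <- mu1 + dlut
    if (mu1 > 1 && mu2 < L) {
      return(data.frame(subject_id = subject$subject_id, phenotype = phen,
                        cycle_index = cycle_index, length = L,
                        lh_surge_day = surge, delta = delta, mu1 = mu1,
                        delta_luteal = dlut, mu2 = mu2,
                        stringsAsFactors = FALSE))
    }
  }
  stop("could not place cycle events inside a length-", round(L, 1), " cycle")
}

#' Build a virtual cohort
#'
#' Samples all subject profiles and per-cycle parameters for a configuration.
#' Each subject's draws come from a substream derived from
#' `(master_seed, subject index)`, so a subject's parameters are reproducible
#' independent of cohort composition or order.
#'
#' @param config a [sim_config()] object.
#' @return object of class `cycle_cohort`: list with `subjects` and `cycles`
#'   data frames plus the config.
#' @examples
#' coh <- build_cohort(sim_config(n_eumenorrheic = 3, n_pcos = 1,
#'                                cycles_per_subject = 2, master_seed = 1))
#' nrow(coh$subjects); nrow(coh$cycles)
#' @export
build_cohort <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  phens <- c(rep("EUM", config$n_eumenorrheic), rep("PCOS", config$n_pcos))
  ids <- sprintf("S%04d", seq_along(phens))
  subs <- vector("list", length(phens))
  cycs <- vector("list", length(phens))
  for (j in seq_along(phens)) {
    subs[[j]] <- with_seed(mix_seed(config$master_seed, j, 1L), {
      prof <- sample_subject(phens[j], ids[j], config$params)
      cc <- lapply(seq_len(config$cycles_per_subject), function(ci)
        sample_cycle_params(prof, ci, config$params))
      list(prof = prof, cycles = do.call(rbind, cc))
    })
    cycs[[j]] <- subs[[j]]$cycles
    subs[[j]] <- subs[[j]]$prof
  }
  structure(list(subjects = do.call(rbind, subs),
                 cycles = do.call(rbind, cycs),
                 config = config),
            class = "cycle_cohort")
}

#' @export
print.cycle_cohort <- function(x, ...) {
  tab <- table(x$subjects$phenotype)
  cat(sprintf("Virtual cohort: %d subjects (%s), %d cycle records\n",
              nrow(x$subjects),
              paste(sprintf("%d %s", tab, names(tab)), collapse = ", "),
              nrow(x$cycles)))
  invisible(x)
}

#' @export
summary.cycle_cohort <- function(object, ...) {
  s <- object$subjects
  by_phen <- split(s, s$phenotype)
  out <- lapply(by_phen, function(d) c(
    n = nrow(d), age_mean = mean(d$age), bmi_mean = mean(d$bmi),
    amh_mean = mean(d$amh_trait)))
  res <- do.call(rbind, out)
  class(res) <- c("summary.cycle_cohort", class(res))
  res
}
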