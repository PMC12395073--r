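# Observation layer: time-dependent noise, clipping, phase labels, surge
# flags, and assembly of the long-format daily dataset.

#' Observation noise standard deviation at a given cycle time
#'
#' Estradiol and LH variance is amplified near their event centers in
#' eumenorrheic cycles:
#' `sd(t) = base * sqrt(1 + kappa * exp(-(t - center)^2 / (2 * 1.2^2)))`
#' with center `mu1` for E2 and the surge day for LH. All other hormones —
#' and every hormone in PCOS cycles, which have no event centers — use the
#' constant subject-level base sd. AMH is trait-like and carries no daily
#' noise.
#'
#' @param hormone one of `"e2"`, `"e1"`, `"lh"`, `"fsh"`, `"amh"`, `"t"`,
#'   `"gnrh"`.
#' @param t cycle time (days), vectorized.
#' @param subject,cycle profile and cycle rows (cycle supplies EUM centers).
#' @param noise noise parameter block from [default_params()].
#' @return sd in the hormone's units, same length as `t`.
#' @export
noise_sd <- function(hormone, t, subject, cycle,
                     noise = default_params()$noise) {
  eum <- identical(subject$phenotype, "EUM")
  w2 <- 2 * noise$amp_width^2
  if (eum && hormone == "e2") {
    noise$e2$base * sqrt(1 + noise$e2$kappa * exp(-(t - cycle$mu1)^2 / w2))
  } else if (eum && hormone == "lh") {
    noise$lh$base *
      sqrt(1 + noise$lh$kappa * exp(-(t - cycle$lh_surge_day)^2 / w2))
  } else {
    base <- switch(hormone,
      e2 = noise$e2$base, lh = noise$lh$base, fsh = noise$fsh$base,
      e1 = if (eum) noise$e1_eum$base else noise$e1$base,
      t = noise$t$base, gnrh = noise$gnrh$base, amh = noise$amh$base,
      stop("unknown hormone: ", hormone))
    rep(base, length(t))
  }
}

#' Turn a noise-free value into an observation
#'
#' Adds zero-mean Gaussian noise and clips to physiological bounds.
#' Observation-level truncation is clipping (not rejection): it preserves the
#' record count and the noise law's center; with default bounds it alters
#' well under 1% of observations.
#'
#' @param value_true noise-free value(s).
#' @param sd noise sd (scalar or vector matching `value_true`).
#' @param bounds length-2 numeric `c(lo, hi)`.
#' @return list with `value` (observed) and `clipped` (logical).
#' @export
observe <- function(value_true, sd, bounds) {
  if (bounds[1] > bounds[2]) stop("invalid bounds: lo > hi")
  raw <- value_true + stats::rnorm(length(value_true), 0, sd)
  val <- pmin(pmax(raw, bounds[1]), bounds[2])
  list(value = val, clipped = val != raw)
}

#' Label the cycle phase of a day
#'
#' Eumenorrheic days are peri-ovulatory within +/-1 day of the LH surge,
#' follicular before and luteal after. PCOS cycles have no surge; every day
#' is `"anovulatory"`.
#'
#' @param t cycle time (days), vectorized.
#' @param cycle cycle-parameter row.
#' @param halfwidth peri-ovulatory half-width in days (default 1).
#' @return character vector of phase labels.
#' @export
label_phase <- function(t, cycle, halfwidth = 1) {
  if (!identical(cycle$phenotype, "EUM") || is.na(cycle$lh_surge_day))
    return(rep("anovulatory", length(t)))
  s <- cycle$lh_surge_day
  ifelse(abs(t - s) <= halfwidth, "peri-ovulatory",
         ifelse(t < s, "follicular", "luteal"))
}

#' Flag LH-surge days
#'
#' A day is flagged when the observed LH reaches 30 mIU/mL within +/-0.5 day
#' of the cycle's surge center. PCOS cycles (no surge center) never flag.
#'
#' @param lh_observed observed LH (mIU/mL), vectorized.
#' @param t cycle time (days).
#' @param cycle cycle-parameter row.
#' @param lh_min,window threshold (mIU/mL) and half-window (days).
#' @return integer vector of 0/1 flags.
#' @export
surge_flag <- function(lh_observed, t, cycle, lh_min = 30, window = 0.5) {
  if (!identical(cycle$phenotype, "EUM") || is.na(cycle$lh_surge_day))
    return(integer(length(t)))
  as.integer(lh_observed >= lh_min & abs(t - cycle$lh_surge_day) <= window)
}

#' Simulate the observed daily records of one cycle
#'
#' Evaluates the phenotype's noise-free panel on the rescaled grid, adds
#' (time-dependent) noise, clips to physiological caps, and attaches phase
#' labels and the surge flag. Eumenorrheic estrone tracks estradiol at a 0.7
#' ratio (low, E2-derived), so the E1/E2 feature is defined for both
#' phenotypes.
#'
#' @param subject,cycle profile and cycle rows.
#' @param params full parameter list.
#' @param grid_points days per cycle grid.
#' @return data.frame of `grid_points` daily records (unit-suffixed hormone
#'   columns) with a `clipped` count attribute.
#' @export
simulate_cycle <- function(subject, cycle, params = default_params(),
                           grid_points = 28) {
  d <- seq_len(grid_points)
  t <- rescale_time(d, cycle$length, grid_points)
  if (identical(subject$phenotype, "EUM")) {
    e2t <- e2_eum(t, subject, cycle)
    panel <- data.frame(
      e2 = e2t, e1 = 0.7 * e2t, lh = lh_eum(t, subject, cycle),
      fsh = fsh_eum(t, subject, cycle, e2t, params$fsh),
      gnrh = gnrh_eum(t, subject, cycle))
  } else {
    panel <- pcos_levels(t, subject)
  }
  panel$t_horm <- testosterone(t, subject, cycle)
  panel$amh <- rep(amh(subject), grid_points)

  obs <- list(); nclip <- 0L
  for (h in c("e2", "e1", "lh", "fsh", "amh", "t", "gnrh")) {
    truth <- switch(h, t = panel$t_horm, panel[[h]])
    o <- observe(truth, noise_sd(h, t, subject, cycle, params$noise),
                 params$caps[[h]])
    obs[[h]] <- o$value
    nclip <- nclip + sum(o$clipped)
  }
  ph <- label_phase(t, cycle, params$phase$periov_halfwidth)
  fl <- surge_flag(obs$lh, t, cycle, params$phase$surge_lh_min,
                   params$phase$surge_window)
  out <- data.frame(
    subject_id = subject$subject_id, phenotype = subject$phenotype,
    cycle_index = cycle$cycle_index, cycle_length_days = cycle$length,
    day_index = d, cycle_time = t, phase = ph, lh_surge_flag = fl,
    Estradiol_pg_mL = obs$e2, Estrone_pg_mL = obs$e1,
    FSH_mIU_mL = obs$fsh, LH_mIU_mL = obs$lh, AMH_ng_mL = obs$amh,
    Testosterone_ng_mL = obs$t, GnRH_AU = obs$gnrh,
    stringsAsFactors = FALSE)
  attr(out, "n_clipped") <- nclip
  out
}

#' Simulate a full cohort dataset
#'
#' Builds (or reuses) the cohort, then simulates every cycle of every
#' subject. Observation noise for each subject comes from its own derived
#' substream, so the dataset is reproducible independent of cohort order.
#'
#' @param config a [sim_config()]; ignored if `cohort` is supplied.
#' @param cohort optionally a prebuilt [build_cohort()] result.
#' @return object of class `cycle_dataset`: list with the long-format `daily`
#'   data.frame, the cohort's `subjects` and `cycles` tables, the `config`,
#'   and run summary stats (`clip_rate`, `surge_rate`).
#' @examples
#' ds <- simulate_cohort(sim_config(n_eumenorrheic = 2, n_pcos = 1,
#'                                  cycles_per_subject = 1, master_seed = 7))
#' nrow(ds$daily)  # 3 * 28
#' @export
simulate_cohort <- function(config, cohort = NULL) {
  if (is.null(cohort)) cohort <- build_cohort(config) else config <- cohort$config
  gp <- config$grid_points_per_cycle
  ids <- cohort$subjects$subject_id
  chunks <- vector("list", nrow(cohort$cycles))
  nclip <- 0L; k <- 0L
  for (j in seq_along(ids)) {
    subject <- cohort$subjects[j, ]
    cyc <- cohort$cycles[cohort$cycles$subject_id == ids[j], ]
    chunk <- with_seed(mix_seed(config$master_seed, j, 2L), {
      lapply(seq_len(nrow(cyc)), function(ci)
        simulate_cycle(subject, cyc[ci, ], config$params, gp))
    })
    for (cc in chunk) {
      k <- k + 1L
      nclip <- nclip + attr(cc, "n_clipped")
      chunks[[k]] <- cc
    }
  }
  daily <- do.call(rbind, chunks)
  rownames(daily) <- NULL
  eumc <- daily[daily$phenotype == "EUM", ]
  surge_rate <- if (nrow(eumc)) {
    per_cycle <- tapply(eumc$lh_surge_flag,
                        interaction(eumc$subject_id, eumc$cycle_index,
                                    drop = TRUE), max)
    mean(per_cycle == 1)
  } else NA_real_
  structure(list(daily = daily, subjects = cohort$subjects,
                 cycles = cohort$cycles, config = config,
                 clip_rate = nclip / (nrow(daily) * 7),
                 surge_rate = surge_rate),
            class = "cycle_dataset")
}

#' @export
print.cycle_dataset <- function(x, ...) {
  cat(sprintf("Simulated hormone dataset: %d daily records (%d subjects x %d cycles x %d days)\n",
              nrow(x$daily), nrow(x$subjects), x$config$cycles_per_subject,
              x$config$grid_points_per_cycle))
  cat(sprintf("  clip rate: %.3f%%  |  EUM cycles with surge flag: %.1f%%\n",
              100 * x$clip_rate, 100 * x$surge_rate))
  invisible(x)
}

#' @export
summary.cycle_dataset <- function(object, ...) {
  d <- object$daily
  horm <- c("Estradiol_pg_mL", "Estrone_pg_mL", "FSH_mIU_mL", "LH_mIU_mL",
            "AMH_ng_mL", "Testosterone_ng_mL", "GnRH_AU")
  res <- lapply(split(d[horm], d$phenotype), function(g)
    round(vapply(g, mean, numeric(1)), 3))
  res
}

#' Mean +/- SD daily trajectory panel
#'
#' Plots, for each hormone, the across-cycle mean trajectory on the day grid
#' with a +/-1 SD band, one curve per phenotype.
#'
#' @param x a `cycle_dataset`.
#' @param hormones columns to plot.
#' @param ... unused.
#' @export
plot.cycle_dataset <- function(x, hormones = c("Estradiol_pg_mL", "LH_mIU_mL",
                                               "FSH_mIU_mL", "GnRH_AU"), ...) {
  d <- x$daily
  op <- graphics::par(mfrow = c(ceiling(length(hormones) / 2), 2),
                      mar = c(4, 4, 2, 1))
  on.exit(graphics::par(op))
  cols <- c(EUM = "steelblue", PCOS = "darkorange")
  for (h in hormones) {
    agg_m <- tapply(d[[h]], list(d$day_index, d$phenotype), mean)
    agg_s <- tapply(d[[h]], list(d$day_index, d$phenotype), stats::sd)
    days <- as.numeric(rownames(agg_m))
    graphics::matplot(days, agg_m, type = "l", lty = 1, lwd = 2,
                      col = cols[colnames(agg_m)], xlab = "grid day",
                      ylab = h, main = h,
                      ylim = range(agg_m - agg_s, agg_m + agg_s, na.rm = TRUE))
    for (p in colnames(agg_m)) {
      ok <- !is.na(agg_s[, p])
      graphics::polygon(c(days[ok], rev(days[ok])),
                        c((agg_m[, p] + agg_s[, p])[ok],
                          rev((agg_m[, p] - agg_s[, p])[ok])),
                        col = grDevices::adjustcolor(cols[p], 0.2), border = NA)
    }
  }
  invisible(x)
}

# Required column set of the daily CSV schema.
daily_schema <- function() c(
  "subject_id", "phenotype", "cycle_index", "cycle_length_days", "day_index",
  "cycle_time", "phase", "lh_surge_flag", "Estradiol_pg_mL", "Estrone_pg_mL",
  "FSH_mIU_mL", "LH_mIU_mL", "AMH_ng_mL", "Testosterone_ng_mL", "GnRH_AU")

#' Write / read the daily dataset as CSV
#'
#' Plain comma-separated UTF-8 with a header of unit-suffixed column names,
#' "." decimal, no row-name column. Numeric values are written with 6
#' significant digits and round-trip at that precision. `read_dataset()`
#' validates the schema and names any missing column.
#'
#' @param dataset a `cycle_dataset` (or a conforming daily data.frame).
#' @param path CSV file path.
#' @return `write_dataset()`: the path, invisibly. `read_dataset()`: the
#'   daily records data.frame.
#' @export
write_dataset <- function(dataset, path) {
  d <- if (inherits(dataset, "cycle_dataset")) dataset$daily else dataset
  num <- vapply(d, is.numeric, logical(1))
  d[num] <- lapply(d[num], signif, digits = 6)
  utils::write.csv(d, path, row.names = FALSE, quote = FALSE,
                   fileEncoding = "UTF-8")
  invisible(path)
}

#' @rdname write_dataset
#' @export
read_dataset <- function(path) {
  d <- utils::read.csv(path, stringsAsFactors = FALSE, fileEncoding = "UTF-8")
  missing <- setdiff(daily_schema(), names(d))
  if (length(missing))
    stop("dataset schema violation; missing column(s): ",
         paste(missing, collapse = ", "))
  d[daily_schema()]
}
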