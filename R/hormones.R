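# Noise-free hormone trajectory equations. All take continuous cycle time t
# (days in [1, L]) and are vectorized over t. Subject/cycle arguments are
# one-row data frames (or lists) carrying the named parameters.

#' Map a grid day index to continuous cycle time
#'
#' Observations live on a fixed grid of `grid_points` days per cycle, affinely
#' rescaled to the cycle's length:
#' `t = 1 + (d - 1) / (grid_points - 1) * (L - 1)`, so `t(1) = 1` and
#' `t(grid_points) = L`.
#'
#' @param day_index integer day on the grid, in `[1, grid_points]`.
#' @param cycle_length cycle length L in days (>= 1).
#' @param grid_points grid size (default 28, denominator 27).
#' @return continuous cycle time in days.
#' @export
rescale_time <- function(day_index, cycle_length, grid_points = 28) {
  if (any(day_index < 1 | day_index > grid_points))
    stop("day_index outside [1, ", grid_points, "]")
  if (any(cycle_length < 1)) stop("cycle_length must be >= 1")
  1 + (day_index - 1) / (grid_points - 1) * (cycle_length - 1)
}

#' Eumenorrheic estradiol: biphasic two-Gaussian model (pg/mL)
#'
#' Baseline plus a narrow pre-ovulatory surge centered at `mu1` (amplitude
#' `peak1 - baseline`) and a broader luteal rise at `mu2 = mu1 + delta_luteal`
#' (amplitude `peak2 - baseline`).
#'
#' @param t cycle time (days), vectorized.
#' @param subject,cycle profile and cycle-parameter rows.
#' @return noise-free E2 in pg/mL.
#' @export
e2_eum <- function(t, subject, cycle) {
  a1 <- subject$e2_peak1 - subject$e2_baseline
  a2 <- subject$e2_peak2 - subject$e2_baseline
  subject$e2_baseline +
    a1 * exp(-(t - cycle$mu1)^2 / (2 * subject$sigma1^2)) +
    a2 * exp(-(t - cycle$mu2)^2 / (2 * subject$sigma2^2))
}

#' Eumenorrheic LH: single sharp surge Gaussian (mIU/mL)
#'
#' The surge center trails the pre-ovulatory E2 peak by 36-48 h (positive
#' feedback); width 0.6-0.9 d gives the brief (<1 d) surge.
#'
#' @inheritParams e2_eum
#' @export
lh_eum <- function(t, subject, cycle) {
  subject$lh_baseline + (subject$lh_peak - subject$lh_baseline) *
    exp(-(t - cycle$lh_surge_day)^2 / (2 * subject$sigma_lh^2))
}

#' Eumenorrheic FSH: biphasic bumps with estradiol negative feedback (mIU/mL)
#'
#' Baseline plus an early-follicular bump (center day 2) and a peri-ovulatory
#' bump (one day before the LH surge), minus linear suppression when
#' noise-free E2 exceeds `theta_e2` (100 pg/mL). Floored at 0.
#'
#' @inheritParams e2_eum
#' @param e2_true_value noise-free E2 at the same `t` (feedback acts on true
#'   physiology, not the noisy observation).
#' @param fsh_const feedback constants (`t_early`, `sigma_early`,
#'   `sigma_periov`, `theta_e2`, `beta_e2`); see [default_params()].
#' @export
fsh_eum <- function(t, subject, cycle, e2_true_value,
                    fsh_const = default_params()$fsh) {
  v <- subject$fsh_baseline +
    subject$alpha_early *
      exp(-(t - fsh_const$t_early)^2 / (2 * fsh_const$sigma_early^2)) +
    subject$alpha_periov *
      exp(-(t - (cycle$lh_surge_day - 1))^2 / (2 * fsh_const$sigma_periov^2)) -
    fsh_const$beta_e2 * pmax(e2_true_value - fsh_const$theta_e2, 0)
  pmax(v, 0)
}

#' Eumenorrheic GnRH daily area: baseline with peri-ovulatory bump (AU)
#'
#' Daily pulsatile drive summarized as an area near 1 AU, increased around
#' one day before the LH surge (amplitude 22% of baseline by default).
#'
#' @inheritParams e2_eum
#' @export
gnrh_eum <- function(t, subject, cycle) {
  subject$gnrh_baseline + subject$a_periov *
    exp(-(t - (cycle$lh_surge_day - 1))^2 / (2 * subject$sigma_gnrh^2))
}

#' Testosterone: low-amplitude sinusoid around a baseline (ng/mL)
#'
#' `T0 + A_T * sin(2*pi*t/L + phase)`; both phenotypes use this form, PCOS
#' with its elevated baseline (hyperandrogenism).
#'
#' @inheritParams e2_eum
#' @export
testosterone <- function(t, subject, cycle) {
  subject$t_baseline +
    subject$t_amplitude * sin(2 * pi * t / cycle$length + subject$t_phase)
}

#' AMH: trait-like, constant within subject (ng/mL)
#'
#' Ovarian-reserve marker; identical on every day of every cycle. For PCOS
#' subjects the trait already includes the negative BMI association applied
#' at sampling time.
#'
#' @param subject profile row.
#' @export
amh <- function(subject) subject$amh_trait

#' PCOS noise-free hormone panel: flat, non-cyclic levels
#'
#' Chronic anovulation: estrone, estradiol, LH, FSH and GnRH sit at the
#' subject's elevated/suppressed levels with no time dependence (no E2 surge,
#' LH constrained below 30 mIU/mL, GnRH tone above 1.3 AU).
#'
#' @param t cycle time (days), vectorized (values are constant in `t`).
#' @param subject PCOS profile row.
#' @return data.frame with columns `e1`, `e2`, `lh`, `fsh`, `gnrh`.
#' @export
pcos_levels <- function(t, subject) {
  if (!identical(subject$phenotype, "PCOS"))
    stop("pcos_levels() requires a PCOS subject")
  n <- length(t)
  data.frame(e1 = rep(subject$e1_level, n), e2 = rep(subject$e2_level, n),
             lh = rep(subject$lh_level, n), fsh = rep(subject$fsh_level, n),
             gnrh = rep(subject$gnrh_level, n))
}

#' Minute-resolution GnRH pulse train, integrated to a daily area (AU)
#'
#' Optional high-resolution variant of the GnRH model: Gaussian pulses with
#' 60-90 min interpulse intervals on a 1-min grid over 24 h, numerically
#' integrated (trapezoid) and divided by a calibration normalizer so the
#' baseline daily area is ~1 AU.
#'
#' @param pulse_amplitude mean pulse amplitude (AU).
#' @param pulse_width pulse sd omega in minutes.
#' @param interpulse_range interpulse interval range in minutes.
#' @param normalizer daily-area divisor calibrating baseline to ~1 AU;
#'   default = expected number of pulses x single-pulse area at defaults.
#' @param n_pulses fixed pulse count (overrides interval sampling); `0` gives
#'   an empty train and area 0.
#' @param pulse_times explicit pulse centers in minutes (developer entry
#'   point for testing; overrides both sampling modes).
#' @return list with `area` (AU), `n_pulses`, `pulse_times` (min).
#' @export
gnrh_pulse_train_daily_area <- function(pulse_amplitude = 1,
                                        pulse_width = 10,
                                        interpulse_range = c(60, 90),
                                        normalizer = NULL,
                                        n_pulses = NULL,
                                        pulse_times = NULL) {
  day_min <- 24 * 60
  if (is.null(normalizer)) {
    # expected pulses/day at the default 60-90 min spacing, unit amplitude
    normalizer <- day_min / mean(c(60, 90)) * 1 * 10 * sqrt(2 * pi)
  }
  times <- numeric(0)
  if (!is.null(pulse_times)) {
    times <- pulse_times
  } else if (is.null(n_pulses)) {
    tk <- stats::runif(1, 0, interpulse_range[2])
    while (tk < day_min) {
      times <- c(times, tk)
      tk <- tk + stats::runif(1, interpulse_range[1], interpulse_range[2])
    }
  } else if (n_pulses > 0) {
    times <- seq(0, by = interpulse_range[1], length.out = n_pulses)
  }
  if (!length(times))
    return(list(area = 0, n_pulses = 0L, pulse_times = numeric(0)))
  grid <- seq(0, day_min, by = 1)
  y <- rowSums(vapply(times, function(tk)
    pulse_amplitude * exp(-(grid - tk)^2 / (2 * pulse_width^2)),
    numeric(length(grid))))
  area <- sum((y[-1] + y[-length(y)]) / 2)   # trapezoid, 1-min steps
  list(area = area / normalizer, n_pulses = length(times), pulse_times = times)
}
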