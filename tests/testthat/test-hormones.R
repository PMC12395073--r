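test_that("cycle-time rescaling maps the grid affinely onto [1, L]", {
  expect_equal(rescale_time(1, 35), 1)
  expect_equal(rescale_time(28, 35), 35)
  expect_equal(rescale_time(14, 28), 14)   # 1 + 13/27 * 27
  expect_equal(rescale_time(1:28, 28), 1:28)
  expect_error(rescale_time(0, 28), "day_index")
  expect_error(rescale_time(29, 28), "day_index")
})

test_that("estradiol two-Gaussian model hits its peaks and baseline", {
  s <- point_subject(); cy <- point_cycle()   # mu1 = 12.5, mu2 = 19
  # at the luteal center the pre-ovulatory bump has fully decayed
  expect_equal(e2_eum(19, s, cy),
               oracle_e2(19, 20, 260, 125, 12.5, 19, 1.1, 2.0))
  expect_equal(e2_eum(19, s, cy), 125, tolerance = 1e-4)
  # at mu1 the luteal bump contributes a visible shoulder, not the oracle's 260
  expect_equal(e2_eum(12.5, s, cy),
               oracle_e2(12.5, 20, 260, 125, 12.5, 19, 1.1, 2.0))
  # far field (>= 5 sigma from both centers) decays to baseline
  expect_equal(e2_eum(1, s, cy), 20, tolerance = 1e-3)
})

test_that("LH surge model is exact at the center and decays to baseline", {
  s <- point_subject(); cy <- point_cycle(surge = 14.5)
  expect_equal(lh_eum(14.5, s, cy), 53)
  expect_equal(lh_eum(14.5 + 0.75, s, cy), 7 + 46 * exp(-0.5))
  expect_equal(lh_eum(14.5 + 0.75, s, cy), 34.9, tolerance = 1e-3)
  expect_equal(lh_eum(14.5 + 5 * 0.75, s, cy), 7, tolerance = 1e-4)
})

test_that("FSH combines bumps with thresholded estradiol suppression", {
  s <- point_subject(); cy <- point_cycle(surge = 20)
  # no suppression at or below the 100 pg/mL threshold
  expect_equal(fsh_eum(10, s, cy, 100), fsh_eum(10, s, cy, 50))
  # early bump center, surge far away
  expect_equal(fsh_eum(2, s, cy, 30), 7.8 + 1.5, tolerance = 1e-3)
  # peri-ovulatory bump with strong E2: 7.8 + 1.2 - 0.01*160 = 7.4
  expect_equal(fsh_eum(19, s, cy, 260), 7.4, tolerance = 1e-3)
  # suppression never pushes FSH below zero
  huge <- fsh_eum(19, s, cy, 1e5)
  expect_equal(huge, 0)
  # suppression only lowers FSH relative to the beta = 0 curve
  const0 <- default_params()$fsh; const0$beta_e2 <- 0
  t <- seq(1, 28, by = 0.5)
  e2t <- e2_eum(t, s, point_cycle(surge = 20))
  expect_true(all(fsh_eum(t, s, cy, e2t) <=
                  fsh_eum(t, s, cy, e2t, const0) + 1e-12))
})

test_that("GnRH daily-area bump peaks one day before the surge", {
  s <- point_subject(); cy <- point_cycle(surge = 14.5)
  expect_equal(gnrh_eum(13.5, s, cy), 1.0 + 0.22)
  expect_equal(gnrh_eum(1, s, cy), 1.0, tolerance = 1e-4)
  # 22% peak-day relative rise over baseline
  expect_equal((gnrh_eum(13.5, s, cy) - 1) / 1, 0.22)
})

test_that("testosterone sinusoid oscillates around its baseline", {
  s <- point_subject(); cy <- point_cycle(L = 28)
  expect_equal(testosterone(7, s, cy), 0.44)   # t = L/4, phase 0
  s0 <- s; s0$t_amplitude <- 0
  expect_equal(testosterone(1:28, s0, cy), rep(0.4, 28))
  # continuous mean over one full period is the baseline
  tt <- seq(0, 28, length.out = 20001)[-1]
  expect_equal(mean(testosterone(tt, s, cy)), 0.4, tolerance = 1e-4)
})

test_that("AMH is a constant subject trait", {
  s <- point_subject()
  expect_equal(amh(s), 2.9)
  expect_equal(amh(s), amh(s))
})

test_that("PCOS noise-free panel is flat and within its constraints", {
  p <- with_seed(21, sample_subject("PCOS", "p", default_params()))
  a <- pcos_levels(c(1, 10, 25), p)
  expect_equal(a[1, ], a[2, ], ignore_attr = TRUE)
  expect_equal(a[1, ], a[3, ], ignore_attr = TRUE)
  expect_lt(a$lh[1], 30)
  expect_gt(a$gnrh[1], 1.3)
  expect_error(pcos_levels(1, point_subject()), "PCOS")
})

test_that("closed forms agree with straight-line oracles on random draws", {
  set.seed(31)
  for (i in 1:1000) {
    e20 <- runif(1, 10, 30); p1 <- runif(1, 200, 320); p2 <- runif(1, 100, 150)
    mu1 <- runif(1, 10, 16); dl <- runif(1, 5.5, 7.5)
    s1 <- runif(1, 0.9, 1.3); s2 <- runif(1, 1.5, 2.5)
    lh0 <- runif(1, 2, 12); lhp <- runif(1, 35, 80); slh <- runif(1, 0.6, 0.9)
    t <- runif(1, 1, 28)
    subj <- point_subject()
    subj$e2_baseline <- e20; subj$e2_peak1 <- p1; subj$e2_peak2 <- p2
    subj$sigma1 <- s1; subj$sigma2 <- s2
    subj$lh_baseline <- lh0; subj$lh_peak <- lhp; subj$sigma_lh <- slh
    cy <- point_cycle(surge = mu1 + 1.75, delta = 1.75, dlut = dl)
    expect_equal(e2_eum(t, subj, cy),
                 oracle_e2(t, e20, p1, p2, mu1, mu1 + dl, s1, s2))
    expect_equal(lh_eum(t, subj, cy),
                 oracle_lh(t, lh0, lhp, mu1 + 1.75, slh))
    e2v <- oracle_e2(t, e20, p1, p2, mu1, mu1 + dl, s1, s2)
    expect_equal(fsh_eum(t, subj, cy, e2v),
                 oracle_fsh(t, 7.8, 1.5, 1.2, mu1 + 1.75, e2v))
  }
})

test_that("grid maximum understates the LH peak unless the surge sits on a grid point", {
  s <- point_subject()
  # surge exactly on the day-14 grid point of a 28-day cycle
  cy_on <- point_cycle(surge = 14, L = 28)
  on_grid <- max(lh_eum(rescale_time(1:28, 28), s, cy_on))
  expect_equal(on_grid, s$lh_peak)
  cy_off <- point_cycle(surge = 14.5, L = 28)
  off_grid <- max(lh_eum(rescale_time(1:28, 28), s, cy_off))
  expect_lt(off_grid, s$lh_peak)
})

test_that("pulse-train daily area matches Gaussian quadrature and pulse counting", {
  empty <- gnrh_pulse_train_daily_area(n_pulses = 0)
  expect_equal(empty$area, 0)
  expect_equal(empty$n_pulses, 0L)
  # fixed 60-min interpulse interval over 24 h yields 24 pulses
  set.seed(41)
  fixed <- gnrh_pulse_train_daily_area(interpulse_range = c(60, 60))
  expect_equal(fixed$n_pulses, 24L)
  # single mid-day pulse: numerical area equals alpha * omega * sqrt(2*pi)
  one <- gnrh_pulse_train_daily_area(pulse_amplitude = 2, pulse_width = 8,
                                     normalizer = 1, pulse_times = 720)
  expect_equal(one$area, 2 * 8 * sqrt(2 * pi), tolerance = 1e-6)
  # stochastic train at defaults is calibrated to ~1 AU/day
  set.seed(42)
  areas <- replicate(50, gnrh_pulse_train_daily_area()$area)
  expect_equal(mean(areas), 1, tolerance = 0.05)
})
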