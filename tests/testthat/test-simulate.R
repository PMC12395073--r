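test_that("noise sd is amplified only near the E2/LH event centers", {
  s <- point_subject(); cy <- point_cycle(surge = 14.5)  # mu1 = 12.5
  noise <- default_params()$noise
  expect_equal(noise_sd("e2", 12.5, s, cy, noise),
               noise$e2$base * sqrt(1 + noise$e2$kappa))
  expect_equal(noise_sd("lh", 14.5, s, cy, noise),
               noise$lh$base * sqrt(1 + noise$lh$kappa))
  expect_equal(noise_sd("e2", 1, s, cy, noise), noise$e2$base,
               tolerance = 1e-6)
  expect_equal(noise_sd("fsh", c(2, 13, 25), s, cy, noise),
               rep(noise$fsh$base, 3))
  expect_true(all(noise_sd("e2", seq(1, 28, 0.25), s, cy, noise) >=
                  noise$e2$base))
  # PCOS cycles have no centers: constant sd for every hormone
  p <- with_seed(2, sample_subject("PCOS", "p", default_params()))
  pcy <- data.frame(phenotype = "PCOS", lh_surge_day = NA_real_)
  expect_equal(noise_sd("e2", c(3, 14), p, pcy, noise),
               rep(noise$e2$base, 2))
})

test_that("observe() follows the stated normal law and clips at bounds", {
  expect_equal(observe(5, 0, c(0, 10))$value, 5)
  low <- observe(-3, 0, c(0, 10))
  expect_equal(low$value, 0)
  expect_true(low$clipped)
  expect_error(observe(1, 1, c(5, 2)), "bounds")
  set.seed(13)
  o <- observe(rep(50, 10000), 1, c(0, 100))
  expect_equal(mean(o$value), 50, tolerance = 0.05)
  expect_equal(sd(o$value), 1, tolerance = 0.05)
})

test_that("phase labels partition the cycle around the LH surge", {
  cy <- point_cycle(surge = 14)
  expect_equal(label_phase(14, cy), "peri-ovulatory")
  expect_equal(label_phase(13, cy), "peri-ovulatory")
  expect_equal(label_phase(2, cy), "follicular")
  expect_equal(label_phase(20, cy), "luteal")
  pcy <- data.frame(phenotype = "PCOS", lh_surge_day = NA_real_)
  expect_equal(label_phase(c(1, 15, 27), pcy), rep("anovulatory", 3))
  # every grid day receives exactly one of the three EUM phases
  ph <- label_phase(rescale_time(1:28, 29), cy)
  expect_true(all(ph %in% c("follicular", "peri-ovulatory", "luteal")))
  expect_equal(length(ph), 28)
})

test_that("surge flag requires both the LH threshold and the time window", {
  cy <- point_cycle(surge = 14)
  expect_equal(surge_flag(52, 14, cy), 1L)
  expect_equal(surge_flag(52, 16, cy), 0L)
  expect_equal(surge_flag(29.9, 14, cy), 0L)
  pcy <- data.frame(phenotype = "PCOS", lh_surge_day = NA_real_)
  expect_equal(surge_flag(c(52, 52), c(1, 14), pcy), c(0L, 0L))
})

test_that("simulate_cycle produces the full grid and is transparent without noise", {
  cfg <- sim_config(n_eumenorrheic = 1, n_pcos = 1, cycles_per_subject = 1,
                    master_seed = 5, overrides = noise_off)
  coh <- build_cohort(cfg)
  eum_s <- coh$subjects[1, ]; eum_c <- coh$cycles[1, ]
  rec <- simulate_cycle(eum_s, eum_c, cfg$params)
  expect_equal(nrow(rec), 28)
  expect_equal(rec$cycle_time[1], 1)
  expect_equal(rec$cycle_time[28], eum_c$length)
  tt <- rescale_time(1:28, eum_c$length)
  expect_equal(rec$LH_mIU_mL, lh_eum(tt, eum_s, eum_c))
  e2t <- e2_eum(tt, eum_s, eum_c)
  expect_equal(rec$Estradiol_pg_mL, e2t)
  expect_equal(rec$Estrone_pg_mL, 0.7 * e2t)
  expect_equal(rec$FSH_mIU_mL,
               fsh_eum(tt, eum_s, eum_c, e2t, cfg$params$fsh))
  expect_equal(rec$GnRH_AU, gnrh_eum(tt, eum_s, eum_c))
  expect_equal(rec$AMH_ng_mL, rep(eum_s$amh_trait, 28))
  # noise-free PCOS cycles are flat in everything but testosterone
  pc_s <- coh$subjects[2, ]; pc_c <- coh$cycles[2, ]
  prec <- simulate_cycle(pc_s, pc_c, cfg$params)
  for (col in c("Estradiol_pg_mL", "Estrone_pg_mL", "LH_mIU_mL",
                "FSH_mIU_mL", "AMH_ng_mL", "GnRH_AU"))
    expect_equal(length(unique(prec[[col]])), 1)
  expect_gt(length(unique(prec$Testosterone_ng_mL)), 1)
  expect_true(all(prec$phase == "anovulatory"))
  expect_true(all(prec$lh_surge_flag == 0))
})

test_that("cohort simulation conserves record counts and is deterministic", {
  cfg <- sim_config(n_eumenorrheic = 2, n_pcos = 1, cycles_per_subject = 1,
                    master_seed = 77)
  ds <- simulate_cohort(cfg)
  expect_equal(nrow(ds$daily), 3 * 28)
  expect_identical(ds$daily, simulate_cohort(cfg)$daily)
  # arbitrary config arithmetic
  cfg2 <- tiny_config(seed = 7)
  expect_equal(nrow(simulate_cohort(cfg2)$daily), 6 * 2 * 28)
  # every (subject, cycle) block has exactly grid_points records and a
  # complete one-phase-per-day labeling
  d <- simulate_cohort(cfg2)$daily
  cnt <- table(d$subject_id, d$cycle_index)
  expect_true(all(cnt == 28))
  eum <- d[d$phenotype == "EUM", ]
  expect_true(all(eum$phase %in% c("follicular", "peri-ovulatory", "luteal")))
})

test_that("surge detection is near-universal in EUM cycles and absent in PCOS", {
  ds <- simulate_cohort(sim_config(n_eumenorrheic = 150, n_pcos = 30,
                                   cycles_per_subject = 2, master_seed = 19))
  d <- ds$daily
  eum <- d[d$phenotype == "EUM", ]
  per_cycle <- tapply(eum$lh_surge_flag,
                      paste(eum$subject_id, eum$cycle_index), max)
  expect_gte(mean(per_cycle == 1), 0.95)
  pcos <- d[d$phenotype == "PCOS", ]
  expect_equal(sum(pcos$lh_surge_flag), 0)
  # observation clipping is rare at default parameters
  expect_lt(ds$clip_rate, 0.01)
  # all observations non-negative and within caps
  expect_true(all(d$Estradiol_pg_mL >= 0 & d$Estradiol_pg_mL <= 600))
  expect_true(all(d$LH_mIU_mL >= 0 & d$LH_mIU_mL <= 100))
})

test_that("dataset CSV round-trips with the unit-suffixed schema", {
  ds <- simulate_cohort(tiny_config(seed = 23))
  path <- tempfile(fileext = ".csv")
  write_dataset(ds, path)
  header <- strsplit(readLines(path, n = 1), ",")[[1]]
  expect_true(all(c("Estradiol_pg_mL", "FSH_mIU_mL", "GnRH_AU") %in% header))
  back <- read_dataset(path)
  expect_equal(nrow(back), nrow(ds$daily))
  expect_equal(names(back), names(ds$daily))
  expect_equal(back$Estradiol_pg_mL, ds$daily$Estradiol_pg_mL,
               tolerance = 1e-5)
  # a renamed column is a named schema error
  bad <- ds$daily
  names(bad)[names(bad) == "FSH_mIU_mL"] <- "FSH"
  path2 <- tempfile(fileext = ".csv")
  utils::write.csv(bad, path2, row.names = FALSE)
  expect_error(read_dataset(path2), "FSH_mIU_mL")
})
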