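test_that("config validation rejects out-of-range parameters", {
  expect_error(screen_config(outlier_rate = 1.5), "outlier_rate")
  expect_error(screen_config(divergence_fraction = -0.1),
               "divergence_fraction")
  expect_error(screen_config(n_variants = 2,
                             editing_fraction = c(KO001 = 1.2, KO002 = 1)),
               "editing fractions")
  expect_error(screen_config(n_variants = 3, effect_map = c(A = 1, B = 1)),
               "one effect per KO")
  expect_error(simulate_cell_sample(tiny_config(), "NOPE", "exposed"),
               "unknown variant")
})

test_that("zero dose makes exposed and sham samples draws from the same law", {
  cfg <- tiny_config(pulses = 0, cells_per_sample = 2000, outlier_rate = 0)
  ex <- simulate_cell_sample(cfg, "KO001", "exposed")
  sh <- simulate_cell_sample(cfg, "KO001", "sham")
  # same log-normal law: means and SDs agree within sampling error
  se <- sqrt(var(ex$yp) / 2000 + var(sh$yp) / 2000)
  expect_lt(abs(mean(ex$yp) - mean(sh$yp)), 4 * se)
  expect_gt(ks.test(ex$yp, sh$yp)$p.value, 0.001)
})

test_that("mean uptake grows linearly through the origin up to the limit", {
  doses <- c(10, 20, 30, 40, 50)
  dmeans <- vapply(doses, function(p) {
    cfg <- tiny_config(pulses = p, cells_per_sample = 2000,
                       outlier_rate = 0, sample_cv = 0, seed = 7L + p)
    mean(simulate_cell_sample(cfg, "KO001", "exposed")$yp) -
      mean(simulate_cell_sample(cfg, "KO001", "sham")$yp)
  }, numeric(1))
  fit <- lm(dmeans ~ doses)
  cfg0 <- tiny_config()
  # slope recovered within 2 SE; intercept consistent with zero
  expect_lt(abs(coef(fit)[2] - cfg0$slope_per_pulse),
            2 * summary(fit)$coefficients[2, 2] + 0.05)
  expect_lt(abs(coef(fit)[1]), 3 * summary(fit)$coefficients[1, 2] + 1)
})

test_that("KO effect multiplies the expected uptake increment", {
  cfg <- tiny_config(cells_per_sample = 10000, outlier_rate = 0,
                     sample_cv = 0,
                     effect_map = c(KO001 = 1.4, KO002 = 1, KO003 = 1,
                                    KO004 = 1, KO005 = 1, KO006 = 1),
                     n_variants = 6)
  dko <- mean(simulate_cell_sample(cfg, "KO001", "exposed")$yp) -
    mean(simulate_cell_sample(cfg, "KO001", "sham")$yp)
  expected <- expected_delta_f(cfg, "KO001")
  expect_equal(expected, 1.4 * expected_delta_f(cfg, "SCR01"))
  # Monte-Carlo mean against the closed form, 3-sigma band
  se <- cfg$slope_per_pulse * cfg$pulses * 1.4 * cfg$uptake_cv / sqrt(10000) +
    2 * cfg$sham_mean * cfg$sham_cv / sqrt(10000)
  expect_lt(abs(dko - expected), 4 * se)
})

test_that("mosaicism dilutes the effect toward the unedited response", {
  cfg <- tiny_config(cells_per_sample = 10000, outlier_rate = 0,
                     sample_cv = 0, n_variants = 2,
                     effect_map = c(KO001 = 1.4, KO002 = 1.4),
                     editing_fraction = c(KO001 = 0.5, KO002 = 1))
  # expected multiplier 0.5*1.4 + 0.5 = 1.2
  expect_equal(expected_delta_f(cfg, "KO001"),
               1.2 * cfg$slope_per_pulse * cfg$pulses)
  d <- mean(simulate_cell_sample(cfg, "KO001", "exposed")$yp) -
    mean(simulate_cell_sample(cfg, "KO001", "sham")$yp)
  expect_lt(abs(d - expected_delta_f(cfg, "KO001")) /
              expected_delta_f(cfg, "KO001"), 0.05)
})

test_that("screen generation counts samples and is reproducible", {
  cfg <- screen_config(n_variants = 20, plate_size = 20, n_scr_per_plate = 3,
                       n_experiments = 3, cells_per_sample = 50, seed = 5L)
  scr <- simulate_screen(cfg)
  n_samples <- 2 * (20 + 3) * 3
  expect_equal(nrow(scr$cells), n_samples * 50)
  expect_equal(nrow(unique(scr$cells[, c("experiment", "variant",
                                         "condition")])), n_samples)
  expect_setequal(scr$truth$variants$variant, sprintf("KO%03d", 1:20))
  scr2 <- simulate_screen(cfg)
  expect_identical(scr$cells, scr2$cells)
  expect_identical(scr$truth, scr2$truth)
})

test_that("variants are partitioned into plates with SCR controls on each", {
  cfg <- screen_config(n_variants = 30, plate_size = 15, n_scr_per_plate = 2,
                       n_experiments = 2, cells_per_sample = 20, seed = 9L)
  scr <- simulate_screen(cfg)
  per_plate <- table(unique(scr$cells[, c("plate", "variant")])$plate)
  expect_equal(unname(per_plate), rep(15 + 2, 2), ignore_attr = TRUE)
  expect_true(all(c("SCR01", "SCR02") %in%
                    scr$cells$variant[scr$cells$plate == "2"]))
})

test_that("replication attenuation scales editing fractions as specified", {
  cfg <- tiny_config(n_variants = 2, effect_map = c(KO001 = 1.4, KO002 = 1),
                     editing_fraction = c(KO001 = 0.8, KO002 = 0.8))
  r0 <- simulate_replication(cfg, 0)
  expect_equal(r0$truth$variants$editing_fraction, c(0.8, 0.8))
  r1 <- simulate_replication(cfg, 1)
  expect_equal(r1$truth$variants$editing_fraction, c(0, 0))
  # at full attenuation KOs behave as SCR: expected delta equals SCR's
  expect_equal(expected_delta_f(r1$config, "KO001"),
               expected_delta_f(r1$config, "SCR01"))
  # at 0.5 the excess over 100% halves: 0.8*1.4+0.2 = 1.32 -> 0.4*1.4+0.6 = 1.16
  r5 <- simulate_replication(cfg, 0.5)
  expect_equal(expected_delta_f(r5$config, "KO001") /
                 expected_delta_f(r5$config, "SCR01"), 1.16)
  expect_error(simulate_replication(cfg, 1.2), "attenuation")
})

test_that("median-based uptake resists dead-cell outliers, mean-based does not", {
  base <- tiny_config(cells_per_sample = 2000, outlier_rate = 0,
                      sample_cv = 0, seed = 33L)
  spiked <- tiny_config(cells_per_sample = 2000, outlier_rate = 0.02,
                        sample_cv = 0, seed = 33L)
  d0 <- compute_delta_f(simulate_cell_sample(base, "KO001", "exposed") |>
                          rbind(simulate_cell_sample(base, "KO001", "sham")))
  d2 <- compute_delta_f(simulate_cell_sample(spiked, "KO001", "exposed") |>
                          rbind(simulate_cell_sample(spiked, "KO001", "sham")))
  shift <- function(d, m) abs(d2$value[d2$metric == m] -
                                d0$value[d0$metric == m])
  # median shifts by a small fraction of the effect; the mean can move by
  # tens of a.u. when ~2% of cells sit at the outlier level
  expect_lt(shift(d0, "median"), 6)
  expect_gt(shift(d0, "mean"), shift(d0, "median"))
})

test_that("above the linear limit a broad component degrades the peak", {
  lin <- tiny_config(pulses = 50, cells_per_sample = 4000, outlier_rate = 0,
                     sample_cv = 0)
  div <- tiny_config(pulses = 75, cells_per_sample = 4000, outlier_rate = 0,
                     sample_cv = 0)
  yl <- simulate_cell_sample(lin, "KO001", "exposed")$yp
  yd <- simulate_cell_sample(div, "KO001", "exposed")$yp
  # dispersion grows much faster than the dose ratio once divergence starts
  expect_gt(sd(yd) / sd(yl), 75 / 50 * 1.5)
  expect_gt(mean(yd) / mean(yl), 75 / 50) # mean lifts above the line too
})
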