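test_that("compute_fbioa is the released/total ratio with guarded inputs", {
  expect_equal(compute_fbioa(0, 10000), 0)
  expect_equal(compute_fbioa(10000, 10000), 1)
  # the W300/phenanthrene measurement: 75.41 ng of 10000 ng -> 0.7541%
  expect_equal(compute_fbioa(75.41, 10000), 0.007541)

  expect_error(compute_fbioa(10, 0), "total_mass")
  expect_error(compute_fbioa(10, -5), "total_mass")
  expect_error(compute_fbioa(101, 100), "inconsistent")
  expect_error(compute_fbioa(-1, 100), "released_mass")
})

test_that("desorption series enforce monotone bounded cumulative release", {
  s <- desorption_series("Phe", "gamble", "W300", 10000,
                         time_h = c(2, 8, 24),
                         cum_released_ng = c(50, 120, 134))
  expect_s3_class(s, "desorption_series")

  expect_error(
    desorption_series("Phe", "gamble", "W300", 10000,
                      c(2, 8, 24), c(50, 40, 134)),
    "decreases")
  expect_error(
    desorption_series("Phe", "gamble", "W300", 100,
                      c(2, 8), c(50, 120)),
    "outside")
  expect_error(
    desorption_series("Phe", "gamble", "W300", 100,
                      numeric(), numeric()),
    "at least one timepoint")
})

test_that("fbioa_from_series takes the total extent of desorption", {
  s <- desorption_series("Phe", "gamble", "W300", 10000,
                         c(2, 8, 24), c(50, 120, 134))
  m <- fbioa_from_series(s)
  expect_s3_class(m, "bioaccessibility_measurement")
  expect_equal(m$f_bioa, 0.0134)
  expect_equal(m$matrix, "W300")

  # single zero-release timepoint
  z <- desorption_series("Pyr", "alf", "CN", 10000, 24, 0)
  expect_equal(fbioa_from_series(z)$f_bioa, 0)

  # one-point series agrees with the direct ratio
  one <- desorption_series("Phe", "gamble", "W300", 10000, 24, 75.41)
  expect_identical(fbioa_from_series(one)$f_bioa,
                   compute_fbioa(75.41, 10000))

  # appending timepoints below the running maximum leaves F_bioa fixed
  flat <- desorption_series("Phe", "gamble", "W300", 10000,
                            c(2, 8, 24, 48), c(50, 134, 134, 134))
  expect_equal(fbioa_from_series(flat)$f_bioa, 0.0134)
})

test_that("synthetic generator plateau feeds straight through the reduction", {
  cfg <- desorption_config(plateau_fraction = 0.196, noise_sigma = 0,
                           seed = 7)
  s <- generate_desorption(cfg, total_mass = 10000)
  expect_equal(fbioa_from_series(s)$f_bioa, 0.196, tolerance = 1e-4)
})

test_that("loading efficiency flags sub-threshold recoveries", {
  expect_silent(e1 <- loading_efficiency(1000, 1000))
  expect_equal(e1, 1)
  expect_warning(e2 <- loading_efficiency(1000, 850), "QC threshold")
  expect_equal(e2, 0.85)
  expect_silent(loading_efficiency(1000, 850, threshold = 0.8))
  expect_error(loading_efficiency(0, 10), "applied_mass")
})

test_that("Kd follows the standard ratio definition in L/kg", {
  expect_equal(compute_kd(100, 100), 1000)
  expect_equal(compute_kd(0, 50), 0)
  expect_error(compute_kd(10, 0), "aqueous_conc")

  # mass balance: 10000 ng total, 9990 ng on 1 g solid, 10 ng in 0.04 L
  sorbed <- 9990 / 1       # ng/g
  aqueous <- 10 / 0.04     # ng/L
  expect_equal(compute_kd(sorbed, aqueous), 9990 / 250 * 1000)
  expect_equal(compute_kd(sorbed, aqueous), 39960)
})

test_that("desorption and bioaccessibility CSVs round-trip", {
  s1 <- desorption_series("Phe", "gamble", "W300", 10000,
                          c(2, 8, 24), c(50, 120, 134))
  s2 <- desorption_series("Pyr", "alf", "CN", 5000,
                          c(2, 8, 24), c(10, 30, 41))
  path <- withr::local_tempfile(fileext = ".csv")
  write_desorption_csv(list(s1, s2), path)
  back <- read_desorption_csv(path)
  expect_length(back, 2)
  got <- back[[which(vapply(back, function(s) s$analyte, "") == "Phe")]]
  expect_equal(got$points, s1$points)
  expect_equal(got$total_ng, s1$total_ng)

  fpath <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("analyte,fluid,matrix,fbioa_percent",
               "Phe,gamble,W300,0.7541",
               "Nap,self,PM2.5,"), fpath)
  fb <- read_fbioa_csv(fpath)
  expect_equal(fb$f_bioa, c(0.007541, NA_real_))
})

test_that("F_bioa plateau is recovered from noisy synthetic series", {
  # 200 seeded series, plateaus across the biochar-to-PM2.5 range,
  # 2% multiplicative increment noise
  n <- 200
  set.seed(20260929)
  plateaus <- runif(n, 0.003, 0.45)
  seeds <- sample.int(1e6, n)
  rel_err <- vapply(seq_len(n), function(i) {
    cfg <- desorption_config(plateau_fraction = plateaus[i],
                             noise_sigma = 0.02, seed = seeds[i])
    m <- fbioa_from_series(generate_desorption(cfg, total_mass = 10000))
    abs(m$f_bioa - plateaus[i]) / plateaus[i]
  }, numeric(1))
  expect_gte(mean(rel_err < 0.05), 0.95)
})
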