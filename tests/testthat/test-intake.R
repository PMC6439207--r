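tox <- toxicity_parameters()

test_that("ADI derives from CR, IPF and TEF", {
  # maximum ADI (TEF = 0.001) prints as 0.26 ng/kg/day
  expect_equal(round_half_up(compute_adi(tox, 0.001), 2), 0.26)
  expect_equal(compute_adi(tox, 0.001), 1e-6 / (3.9e-3 * 0.001))
  # BaP (TEF = 1) prints as 0.0003
  expect_equal(round_half_up(compute_adi(tox, 1), 4), 0.0003)
  expect_error(compute_adi(tox, 0), "tef")
  expect_error(compute_adi(tox, -1), "tef")
})

test_that("matrix-route DI reproduces the biochar scenario numbers", {
  scen <- biochar_scenario()
  # W300/phenanthrene bioaccessible DI at 10 ug/g
  expect_lt(abs(compute_di_matrix(10000, 0.007541, scen) - 0.1056),
            tol_printed(4))
  # total-concentration DI at 10/50/100 ug/g loadings
  expect_equal(compute_di_matrix(c(1e4, 5e4, 1e5), 1, scen),
               c(14, 70, 140))
  expect_equal(compute_di_matrix(12345, 0, scen), 0)
  expect_error(compute_di_matrix(1e4, 1, exposure_scenario()),
               "c_particle")
  expect_error(compute_di_matrix(1e4, 1.2, scen), "f_bioa")
})

test_that("ambient-route DI reproduces the PM2.5 phenanthrene row", {
  scen <- exposure_scenario()
  expect_lt(abs(compute_di_ambient(2.30, 0.2128, scen) - 0.1224),
            tol_printed(4))
  expect_equal(compute_di_ambient(2.30, 1, scen), 0.5750)
  expect_equal(compute_di_ambient(0, 0.5, scen), 0)
})

test_that("risk classification is strict with an acceptable boundary", {
  adi_max <- compute_adi(tox, 0.001)
  expect_true(classify_intake(0.5750, adi_max))
  expect_false(classify_intake(0.1072, adi_max))
  expect_false(classify_intake(adi_max, adi_max))
  expect_true(classify_intake(adi_max, adi_max, boundary_risky = TRUE))
  expect_error(classify_intake(1, 0), "adi")
})

test_that("DI ratio is the reciprocal bioaccessible fraction", {
  expect_equal(signif(di_ratio(0.0213), 3), 47.0, tolerance = 0.003)
  expect_equal(signif(di_ratio(0.1958), 3), 5.11)
  expect_equal(di_ratio(1), 1)
  expect_error(di_ratio(0), "f_bioa")
  expect_error(di_ratio(1.5), "f_bioa")
})

test_that("DI is linear in every factor and reciprocal in body weight", {
  set.seed(101)
  for (i in 1:50) {
    q <- runif(1, 1, 1e5); f <- runif(1); tr <- runif(1, 0.01, 1)
    cp <- runif(1, 1e-5, 1e-2); v <- runif(1, 1, 40); bw <- runif(1, 30, 120)
    scen <- exposure_scenario(tr = tr, v_resp = v, bw = bw,
                              c_particle = cp)
    base <- compute_di_matrix(q, f, scen)
    expect_equal(compute_di_matrix(2 * q, f, scen), 2 * base)
    expect_equal(compute_di_matrix(q, f, exposure_scenario(
      tr = tr, v_resp = 2 * v, bw = bw, c_particle = cp)), 2 * base)
    expect_equal(compute_di_matrix(q, f, exposure_scenario(
      tr = tr, v_resp = v, bw = 2 * bw, c_particle = cp)), base / 2)
    # bioaccessible DI is F_bioa times the total-concentration DI
    expect_equal(base, f * compute_di_matrix(q, 1, scen))
  }
})

test_that("CR round-trips through the ADI definition", {
  set.seed(202)
  for (i in 1:50) {
    tx <- toxicity_parameters(cr = runif(1, 1e-6, 1e-4),
                              ipf_bap = runif(1, 1e-4, 1e-2),
                              ur = runif(1, 1e-6, 1e-3))
    tef <- runif(1, 1e-3, 1)
    expect_equal(compute_adi(tx, tef) * tx$ipf_bap * tef, tx$cr)
  }
})

test_that("DI agrees with an independent factor-by-factor oracle", {
  # oracle: accumulate the product one factor at a time in a shuffled
  # order, dividing by BW last
  oracle_di <- function(q, f, scen) {
    factors <- c(q = q, f = f, tr = scen$tr, cp = scen$c_particle,
                 v = scen$v_resp)
    acc <- 1
    for (x in sample(factors)) acc <- acc * x
    acc / scen$bw
  }
  set.seed(303)
  for (i in 1:1000) {
    q <- runif(1, 0, 1e5); f <- runif(1)
    scen <- exposure_scenario(tr = runif(1, 0.01, 1),
                              v_resp = runif(1, 1, 40),
                              bw = runif(1, 30, 120),
                              c_particle = runif(1, 0, 1e-2))
    expect_equal(compute_di_matrix(q, f, scen), oracle_di(q, f, scen),
                 tolerance = 1e-12)
  }
})

test_that("intake assessment of the PM2.5 profile matches the printed table", {
  pm <- load_fixture("pm25")
  res <- assess_intake_table(pm, mode = "both", route = "ambient")
  bio <- res[res$mode == "bioaccessible", ]
  tot <- res[res$mode == "total", ]

  # DI columns, cell by cell, at printed precision (4 decimals)
  expect_lt(max(abs(bio$di_ng_kg_day[!is.na(bio$di_ng_kg_day)] -
                      pm$di_bioaccessible_printed[!is.na(pm$fbioa_percent)])),
            tol_printed(4))
  expect_lt(max(abs(tot$di_ng_kg_day - pm$di_total_printed)),
            tol_printed(4))
  # ADI column recomputed from TEF
  expect_lt(max(abs(round_half_up(bio$adi_ng_kg_day, 4) -
                      pm$adi_printed_ng_kg_day)), tol_printed(4))

  # risk flags row-for-row
  expect_equal(bio$risky %in% TRUE, pm$risk_intake_bioaccessible == "Risky")
  expect_equal(tot$risky, pm$risk_intake_total == "Risky")

  # Nap: missing F_bioa is reported, never a silent zero
  nap <- bio[bio$analyte == "Nap", ]
  expect_true(is.na(nap$di_ng_kg_day))
  expect_true(is.na(nap$risky))
  expect_match(nap$note, "not assessed")

  # the 8 analytes risky regardless of bioaccessibility
  expect_setequal(bio$analyte[bio$risky %in% TRUE],
                  c("FA", "BaA", "Chr", "BbF+BkF", "BaP", "Ind", "DBahA",
                    "BghiP"))
  # Phe and Pyr flip from risky to acceptable with bioaccessibility
  expect_true(all(tot$risky[tot$analyte %in% c("Phe", "Pyr")]))
  expect_false(any(bio$risky[bio$analyte %in% c("Phe", "Pyr")]))

  # bioaccessible-mode risky implies total-mode risky (F_bioa <= 1)
  expect_true(all(tot$risky[bio$risky %in% TRUE]))
})

test_that("intake assessment handles empty input and unknown analytes", {
  empty <- data.frame(analyte = character(), c_ng_m3 = numeric(),
                      fbioa_percent = numeric())
  expect_equal(nrow(assess_intake_table(empty)), 0)
  bad <- data.frame(analyte = "Xyz", c_ng_m3 = 1, fbioa_percent = 10)
  expect_error(assess_intake_table(bad), "unknown analyte")
})
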