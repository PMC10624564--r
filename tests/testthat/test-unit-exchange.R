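test_that("closed-form alveolar fraction matches the bisection oracle", {
  grid <- expand.grid(
    lambda = c(0.005, 0.05, 0.47, 2, 15),
    ratio = c(0.01, 0.1, 0.8, 10, 100),  # VI/Q
    Fv = c(0, 0.1, 0.4, 0.7)
  )
  Q <- 5
  for (i in seq_len(nrow(grid))) {
    g <- grid[i, ]
    FA <- alveolar_fraction_constant_inflow(g$lambda, Q, g$ratio * Q, g$Fv)
    FA_oracle <- oracle_fa_bisect(g$lambda, Q, g$ratio * Q, g$Fv)
    expect_lt(abs(FA - FA_oracle), 1e-10,
              label = sprintf("|FA - oracle| at lambda=%g ratio=%g Fv=%g",
                              g$lambda, g$ratio, g$Fv))
    # physical bound and mass balance closure
    expect_gte(FA, 0)
    expect_lte(FA, g$Fv)
    VA <- expired_ventilation(g$ratio * Q, FA)
    expect_lt(abs(VA * FA - g$lambda * Q * (g$Fv - FA)), 1e-9)
  }
})

test_that("reference unit: N2O at Fv 0.7 in the standard lung unit", {
  # frozen from the bisection oracle
  FA <- alveolar_fraction_constant_inflow(0.47, Q = 5, VI = 4, Fv = 0.7)
  expect_equal(FA, oracle_fa_bisect(0.47, 5, 4, 0.7), tolerance = 1e-12)
  expect_equal(FA, 0.2200, tolerance = 1e-3)
  VA <- expired_ventilation(4, FA)
  expect_equal(VA, 5.128, tolerance = 1e-3)
  expect_equal(VA * FA, 1.128, tolerance = 1e-3)
})

test_that("alveolar fraction is monotone in venous fraction and solubility", {
  Fv <- seq(0, 0.7, by = 0.05)
  FA <- alveolar_fraction_constant_inflow(0.47, 5, 4, Fv)
  expect_true(all(diff(FA) > 0))

  lam <- 10^seq(-2.5, 1.5, by = 0.1)
  FA <- alveolar_fraction_constant_inflow(lam, 5, 4, 0.7)
  expect_true(all(diff(FA) > 0))
  # an infinitely soluble gas equilibrates alveolar gas to venous blood
  expect_equal(alveolar_fraction_constant_inflow(1e8, 5, 4, 0.7), 0.7,
               tolerance = 1e-6)
  # no venous gas, no alveolar gas
  expect_equal(alveolar_fraction_constant_inflow(0.47, 5, 4, 0), 0)
})

test_that("unit solvers reject nonphysical inputs", {
  expect_error(alveolar_fraction_constant_inflow(0, 5, 4, 0.5), "lambda")
  expect_error(alveolar_fraction_constant_inflow(0.47, -5, 4, 0.5), "Q and VI")
  expect_error(alveolar_fraction_constant_inflow(0.47, 5, 4, 1), "Fv")
  expect_error(expired_ventilation(4, 1), "FA")
  expect_error(sg_outflow(0.59, 5, 5, -0.1), "Fv")
  expect_error(sg_outflow(-1, 5, 5, 0.01), "lambda")
})

test_that("second-gas outflow follows the trace-gas transfer law", {
  expect_equal(expired_ventilation(4, 0), 4)
  expect_equal(expired_ventilation(4, 0.5), 8)

  # nothing to eliminate
  expect_equal(sg_outflow(0.59, 5.128, 5, 0), 0)
  # hand evaluation at sevoflurane solubility
  expect_equal(sg_outflow(0.59, 5.128, 5, 0.01),
               0.59 * 5.128 * 0.01 / (0.59 + 5.128 / 5))
  expect_equal(sg_outflow(0.59, 5.128, 5, 0.01), 0.018727, tolerance = 1e-4)
  # cannot eliminate more than arrives in blood, and eliminated fraction of
  # incoming tends to 1 as solubility tends to 0
  lam <- 10^seq(-6, 1, by = 0.5)
  flux <- sg_outflow(lam, 5, 5, 0.01)
  expect_true(all(flux <= lam * 5 * 0.01 + 1e-15))
  frac <- flux / (lam * 5 * 0.01)
  expect_true(all(diff(frac) < 0))
  expect_equal(frac[1], 1, tolerance = 1e-5)
})

test_that("constant-outflow variant is the same law at fixed expired flow", {
  expect_equal(sg_outflow_constant_outflow(0.59, 5.128, 5, 0.01),
               sg_outflow(0.59, 5.128, 5, 0.01))
  # hand evaluation: insoluble tracer at held outflow 4 L/min
  expect_equal(sg_outflow_constant_outflow(0.0076, 4, 5, 0.01),
               0.0076 * 4 * 0.01 / (0.0076 + 0.8))
  expect_equal(sg_outflow_constant_outflow(0.0076, 4, 5, 0.01),
               3.764e-4, tolerance = 1e-3)
})
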