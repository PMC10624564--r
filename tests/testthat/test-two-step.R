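test_that("venous N2O calibration matches the homogeneous closed form", {
  lung <- build_lung(0)
  Fv <- calibrate_venous_n2o(lung, target_elimination = 0.5)
  expect_equal(Fv, oracle_fv_homogeneous(0.5), tolerance = 1e-8)
  expect_equal(Fv, 0.3239, tolerance = 1e-3)
  # mismatch impairs N2O output, so more venous N2O is needed
  Fv2 <- calibrate_venous_n2o(build_lung(2), target_elimination = 0.5)
  expect_gt(Fv2, Fv)
  expect_lt(Fv2, 0.7)

  expect_equal(calibrate_venous_n2o(lung, target_elimination = 0), 0)
})

test_that("calibration recovers the elimination target across sigma", {
  for (sigma in c(0, 0.5, 1, 1.5, 2)) {
    lung <- build_lung(sigma)
    Fv <- calibrate_venous_n2o(lung, target_elimination = 0.5)
    res <- run_two_step(lung, Fv_n2o = Fv)
    expect_equal(sum(res$n2o$efflux), 0.5, tolerance = 1e-8)
  }
})

test_that("an unreachable target reports the achievable maximum, not a clamp", {
  lung <- build_lung(0)
  err <- tryCatch(
    calibrate_venous_n2o(lung, target_elimination = 2),
    sgewash_capped_target = function(e) e
  )
  expect_s3_class(err, "sgewash_capped_target")
  expect_lt(err$achievable, 2)
  expect_gt(err$achievable, 0)
  # the achievable maximum is the whole-lung output at the cap
  FA <- alveolar_fraction_constant_inflow(0.47, 5, 4, 0.7)
  expect_equal(err$achievable, 4 / (1 - FA) * FA, tolerance = 1e-12)
})

test_that("Step 1 reduces to the single-unit eliminated fraction", {
  lung <- build_lung(0)
  gases <- default_second_gases()
  s1 <- run_step1(lung, gases, Fv_sg = 0.01)
  incoming <- gases$lambda * 5 * 0.01
  frac <- as.numeric(s1[1, ]) / incoming
  expect_equal(frac, 0.8 / (gases$lambda + 0.8), tolerance = 1e-12)
  # insoluble gases are eliminated almost completely at constant volume
  expect_gt(frac[1], 0.99)
  # mismatch depresses constant-volume elimination of insoluble gases
  lung2 <- build_lung(2)
  s1_mm <- run_step1(lung2, gases, Fv_sg = 0.01)
  expect_lt(sum(s1_mm[, "sulfur hexafluoride"]), sum(s1[, "sulfur hexafluoride"]))
})

test_that("the two-step decomposition is exact and conservative", {
  lung <- build_lung(2)
  res <- run_two_step(lung, target_elimination = 0.5)
  gases <- res$gases

  # Step 1 + Step 2 equals the classical one-step flux at the expanded VA
  for (j in seq_len(nrow(gases))) {
    one_step <- sg_outflow(gases$lambda[j], res$n2o$VA, lung$Q, res$Fv_sg)
    two_step <- res$step1[, j] + res$step2[, j]
    expect_equal(two_step, one_step, tolerance = 1e-12)
  }
  # conservation of incoming gas across the decomposition
  closure <- res$step1 + res$step2 + res$retained - res$incoming
  expect_lt(max(abs(closure)), 1e-9)
  expect_equal(colSums(res$incoming),
               stats::setNames(gases$lambda * 5 * res$Fv_sg, gases$name),
               tolerance = 1e-12)
  # elimination always expands gas volume, so Step 2 is never negative
  expect_true(all(res$n2o$VA >= lung$VI))
  expect_true(all(res$step2 > -1e-15))
})

test_that("no N2O washout means no Step 2; constant outflow means no SGE", {
  lung <- build_lung(2)
  res0 <- run_two_step(lung, Fv_n2o = 0)
  expect_equal(res0$n2o$VA, lung$VI)
  expect_equal(max(abs(res0$step2)), 0)

  res_co <- run_two_step(lung, target_elimination = 0.5,
                         pattern = "constant_outflow")
  expect_equal(max(abs(res_co$step2)), 0)
  expect_equal(res_co$n2o$VA, lung$VI)
  # N2O is still being eliminated in this mode, just without volume change
  expect_gt(sum(res_co$n2o$efflux), 0)
})

test_that("whole-lung fractions at sigma 0 equal single-unit closed forms", {
  res <- run_two_step(build_lung(0), target_elimination = 0.5)
  lam <- res$gases$lambda
  expect_equal(res$summary$frac_step1, 0.8 / (lam + 0.8), tolerance = 1e-12)
  FA <- alveolar_fraction_constant_inflow(0.47, 5, 4, res$Fv_n2o)
  rA <- (4 / (1 - FA)) / 5
  expect_equal(res$summary$net_frac, rA / (lam + rA), tolerance = 1e-12)
})

test_that("reported fractions are invariant to the venous second-gas level", {
  lung <- build_lung(1.5)
  a <- run_two_step(lung, Fv_sg = 0.005, target_elimination = 0.5)
  b <- run_two_step(lung, Fv_sg = 0.02, target_elimination = 0.5)
  cols <- c("frac_step1", "frac_step2_of_incoming",
            "frac_step2_of_step2_input", "net_frac")
  for (cl in cols) {
    expect_equal(a$summary[[cl]], b$summary[[cl]], tolerance = 1e-12)
  }
})

test_that("distribution profiles conserve and normalize", {
  res <- run_two_step(build_lung(2), target_elimination = 0.5)
  dx <- (res$lung$x[2] - res$lung$x[1]) / log(10)
  for (gas in c("sulfur hexafluoride", "sevoflurane", "diethyl ether")) {
    prof <- distribution_profile(res, gas)
    expect_equal(sum(prof$incoming_density) * dx, 1, tolerance = 1e-12)
    expect_equal(prof$step1_eliminated_density + prof$step1_retained_density,
                 prof$incoming_density, tolerance = 1e-12)
    expect_equal(prof$step1_retained_density,
                 prof$step2_extra_density + prof$step2_retained_density,
                 tolerance = 1e-12)
    expect_equal(sum(prof$n2o_efflux_density) * dx, 0.5, tolerance = 1e-8)
  }
  expect_error(distribution_profile(res, "argon"), "unknown gas")
  expect_error(
    distribution_profile(run_two_step(build_lung(0)), "sevoflurane"),
    "distributed lung"
  )
})

test_that("whole-lung fluxes are stable under grid refinement", {
  gases <- default_second_gases()
  for (sigma in c(1, 2)) {
    a <- run_two_step(build_lung(sigma, N = 1001), gases,
                      target_elimination = 0.5)
    b <- run_two_step(build_lung(sigma, N = 2001), gases,
                      target_elimination = 0.5)
    for (cl in c("step1_total", "step2_total", "net_frac")) {
      rel <- abs(a$summary[[cl]] - b$summary[[cl]]) / abs(b$summary[[cl]])
      expect_lt(max(rel), 1e-3)
    }
    expect_equal(a$Fv_n2o, b$Fv_n2o, tolerance = 1e-3)
  }
})
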