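test_that("allometric flows follow the 0.74 power law", {
  expect_equal(allometric_flows(1, 15, 15)$QC, 15)
  expect_equal(allometric_flows(0.25, 15, 15)$QC, 15 * 0.25^0.74,
               tolerance = 1e-12)
  # hand arithmetic: 15 * exp(0.74 * log(0.25)) = 5.3773,
  #                  15 * exp(0.74 * log(70))   = 347.91
  expect_equal(allometric_flows(0.25)$QC, 5.3773, tolerance = 1e-4)
  expect_equal(allometric_flows(70)$QC, 347.91, tolerance = 1e-4)
  expect_error(allometric_flows(0), "positive")
  expect_error(allometric_flows(-1), "positive")
})

test_that("QC and QP increase strictly with body weight", {
  bw <- c(0.02, 0.25, 2, 20, 70, 200)
  qc <- vapply(bw, function(b) allometric_flows(b)$QC, 0)
  qp <- vapply(bw, function(b) allometric_flows(b)$QP, 0)
  expect_true(all(diff(qc) > 0))
  expect_true(all(diff(qp) > 0))
})

test_that("default adult physiology satisfies its invariants", {
  for (sp in c("rat", "human")) {
    ph <- physiology_at_age(sp)
    expect_equal(ph$body_weight, if (sp == "rat") 0.25 else 70)
    expect_true(all(ph$volume_fraction > 0))
    expect_equal(sum(ph$volume_fraction), ph$perfused_total,
                 tolerance = 1e-12)
    expect_equal(sum(ph$flow_fraction), 1, tolerance = 1e-9)
    expect_true(ph$QC > 0 && ph$QP > 0)
    # absolute volumes scale linearly with BW, fractions unchanged
    ph2 <- physiology_at_age(sp, body_weight = 2 * ph$body_weight)
    expect_equal(ph2$volume_fraction, ph$volume_fraction)
    expect_equal(ph2$volumes, 2 * ph$volumes)
  }
  expect_error(physiology_at_age("dog"), "rat")
})

test_that("growth model evaluates polynomials and refuses out-of-range ages", {
  gm <- growth_model(list(body_weight = c(3.5, 0)), age_range = c(0, 80))
  expect_equal(evaluate_growth(gm, "body_weight", 0), 3.5)
  gm2 <- growth_model(list(body_weight = c(3.5, 1.2, 0.01)),
                      age_range = c(0, 20))
  expect_equal(evaluate_growth(gm2, "body_weight", 10),
               3.5 + 1.2 * 10 + 0.01 * 100)
  expect_error(evaluate_growth(gm2, "body_weight", 25), "outside valid range")
  expect_error(evaluate_growth(gm2, "height", 5), "unknown quantity")
  # physiology picks body weight from the growth model
  ph <- physiology_at_age("human", age = 0, growth = gm)
  expect_equal(ph$body_weight, 3.5)
})

test_that("dietary ppm conversion is dimensional arithmetic", {
  expect_equal(diet_ppm_to_dose(0, 1, 1), 0)
  # 5 ppm at 10 g food per 100 g bw (0.25 kg rat eats 25 g/day)
  expect_equal(diet_ppm_to_dose(5, 0.025, 0.25), 0.5)
  expect_equal(diet_ppm_to_dose(1, 0.01, 1), 0.01)
  expect_error(diet_ppm_to_dose(5, 0.025, 0), "positive")
  expect_error(diet_ppm_to_dose(-1, 0.025, 0.25), "non-negative")
})

test_that("physiology round-trips through config unchanged", {
  path <- withr::local_tempfile(fileext = ".yaml")
  ph <- physiology_at_age("rat", body_weight = 0.31)
  write_physiology(ph, path)
  ph2 <- read_physiology(path)
  expect_identical(ph2$body_weight, ph$body_weight)
  expect_identical(ph2$volumes, ph$volumes)
  expect_identical(ph2$flows, ph$flows)
})
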