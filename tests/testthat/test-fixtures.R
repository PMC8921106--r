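test_that("noise-free fixtures reproduce simulator output exactly", {
  fx <- generate_timecourse_fixture("oral_40mgkg_182d", sigma_rel = 0,
                                    seed = 1)
  pred <- cdpbpk:::.predict_observations(fx$observations, fx$sim)
  expect_identical(fx$observations$value, pred)
})

test_that("the 40 mg/kg design carries the classical matrices and schedule", {
  fx <- generate_timecourse_fixture("oral_40mgkg_182d", sigma_rel = 0.1,
                                    seed = 2)
  obs <- fx$observations
  expect_setequal(unique(obs$matrix),
                  c("blood", "liver", "adipose", "faeces_cum", "urine_cum"))
  expect_equal(sort(obs$time_days[obs$matrix == "urine_cum"]), 1:7)
  expect_true(all(obs$time_days[obs$matrix == "blood"] <= 182))
})

test_that("fixtures are deterministic per seed and respond to the seed", {
  a <- generate_timecourse_fixture("iv_1mgkg", sigma_rel = 0.15, seed = 9)
  b <- generate_timecourse_fixture("iv_1mgkg", sigma_rel = 0.15, seed = 9)
  c <- generate_timecourse_fixture("iv_1mgkg", sigma_rel = 0.15, seed = 10)
  expect_identical(a$observations, b$observations)
  expect_false(identical(a$observations$value, c$observations$value))
  expect_error(generate_timecourse_fixture("no_such_design"), "unknown design")
})

test_that("multiplicative noise has the requested relative spread", {
  pred <- rep(10, 1000)
  noisy <- cdpbpk:::.with_seed(3, cdpbpk:::.apply_rel_noise(pred, 0.15))
  rel_sd <- sd(noisy / pred)
  expect_equal(rel_sd, 0.15, tolerance = 0.1)
  expect_equal(mean(noisy / pred), 1, tolerance = 0.02)
})

test_that("population survey reproduces the 166/337/168 quartile split", {
  sv <- generate_population_survey(n = 671, seed = 5)
  med <- survey_group_medians(sv)
  expect_equal(med$n, c(166L, 337L, 168L))
  expect_equal(sum(med$n), 671L)
  # group labels are consistent with the concentration ordering
  expect_lte(max(sv$concentration[sv$group == "Gr1"]),
             min(sv$concentration[sv$group == "Gr2"]))
  expect_lte(max(sv$concentration[sv$group == "Gr2"]),
             min(sv$concentration[sv$group == "Gr3"]))
})

test_that("survey group medians approximate the FWI quartile medians", {
  sv <- generate_population_survey(n = 671, seed = 1)
  med <- survey_group_medians(sv)
  expect_equal(med$median[med$group == "Gr1"], 0.06 / sqrt(2),
               tolerance = 0.25)
  expect_equal(med$median[med$group == "Gr2"], 0.42, tolerance = 0.25)
  expect_equal(med$median[med$group == "Gr3"], 1.48, tolerance = 0.25)
})

test_that("LOD censoring behaves and is monotone in the detection limit", {
  sv0 <- generate_population_survey(n = 200, lod = 0, seed = 8)
  expect_false(any(sv0$below_lod))
  frac <- vapply(c(0.02, 0.06, 0.2, 0.6), function(l) {
    mean(generate_population_survey(n = 400, lod = l, seed = 8)$below_lod)
  }, 0)
  expect_true(all(diff(frac) >= 0))
  expect_error(generate_population_survey(n = 2), "n must be")
})

test_that("LOD imputation substitutes LOD/sqrt(2) exactly", {
  expect_identical(impute_lod(0.10, FALSE, 0.06), 0.10)
  expect_equal(impute_lod(NA, TRUE, 0.06), 0.06 / sqrt(2))
  for (lod in c(0.01, 0.06, 1, 37)) {
    expect_equal(impute_lod(NA, TRUE, lod), lod / sqrt(2))
  }
  expect_error(impute_lod(1, TRUE, -0.1), "> 0")
})

test_that("observation sets round-trip through the calibration CSV schema", {
  fx <- generate_timecourse_fixture("dietary_3d", sigma_rel = 0.1, seed = 6)
  path <- withr::local_tempfile(fileext = ".csv")
  write_observations_csv(fx$observations, path)
  back <- read_observations_csv(path)
  expect_equal(back$value, fx$observations$value)
  expect_equal(back$matrix, fx$observations$matrix)
})

test_that("parameter configs round-trip bit-identically", {
  p <- rat_params()
  for (ext in c(".yaml", ".json")) {
    path <- withr::local_tempfile(fileext = ext)
    write_params(p, path)
    expect_identical(read_params(path), p)
  }
})
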