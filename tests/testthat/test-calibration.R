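make_obs <- function(value, below_lod = FALSE, lod = NA_real_) {
  observation_set(data.frame(
    subject = 1L, time_days = seq_along(value), matrix = "blood",
    value = value, below_lod = below_lod, lod = lod))
}

test_that("relative-error log-likelihood matches hand arithmetic", {
  # zero residual: only the normalisation terms remain
  obs <- make_obs(c(2, 5, 9))
  sg <- 0.3
  expect_equal(relative_error_loglik(obs, c(2, 5, 9), sg),
               -sum(log(sg * c(2, 5, 9) * sqrt(2 * pi))))
  # two points, obs = (1, 2), pred = (1, 1), sigma = 1
  expect_equal(relative_error_loglik(make_obs(c(1, 2)), c(1, 1), 1),
               -2 * log(sqrt(2 * pi)) - 0.5)
})

test_that("the likelihood penalises growing relative residuals", {
  obs <- make_obs(c(1, 2, 3))
  base <- relative_error_loglik(obs, c(1, 2, 3), 0.2)
  worse <- relative_error_loglik(obs, c(1, 2, 3 * 1.3), 0.2)
  worst <- relative_error_loglik(obs, c(1, 2, 3 * 1.6), 0.2)
  expect_gt(base, worse)
  expect_gt(worse, worst)
  # for fixed predictions the likelihood is maximal at obs == pred (only
  # the quadratic term involves the observation)
  for (eps in c(-0.01, 0.01)) {
    expect_lt(relative_error_loglik(make_obs(c(1, 2 * (1 + eps), 3)),
                                    c(1, 2, 3), 0.2), base)
  }
  # over predictions the proportional-error normalisation shifts the
  # optimum to pred = obs/(1 + sigma^2) + O(sigma^4)
  sg <- 0.2
  shifted <- relative_error_loglik(obs, c(1, 2, 3) / (1 + sg^2), sg)
  expect_gt(shifted, base)
})

test_that("below-LOD records contribute the left-censored mass", {
  obs <- make_obs(c(NA), below_lod = TRUE, lod = 0.06)
  pred <- 0.05
  expect_equal(relative_error_loglik(obs, pred, 0.4),
               pnorm(0.06, 0.05, 0.4 * 0.05, log.p = TRUE))
  expect_error(relative_error_loglik(make_obs(1), -1, 0.3), "non-positive")
  expect_error(relative_error_loglik(make_obs(1), 1, 0), "sigma")
})

test_that("fit with no free parameters returns the start unchanged", {
  fx <- generate_timecourse_fixture("dietary_3d", sigma_rel = 0.1, seed = 4)
  ds <- list(list(observations = fx$observations, scenario = fx$scenario))
  f <- fit_cd(list(), ds, rat_params())
  expect_identical(f$params, rat_params())
  expect_true(is.finite(f$logLik))
  # duplicated dataset doubles the likelihood exactly
  f2 <- fit_cd(list(), c(ds, ds), rat_params())
  expect_equal(f2$logLik, 2 * f$logLik, tolerance = 1e-12)
})

test_that("identifiable parameters are recovered from seeded fixtures", {
  truth <- rat_params()
  for (seed in c(11, 12)) {
    fx <- generate_timecourse_fixture("oral_40mgkg_182d", params = truth,
                                      sigma_rel = 0.1, seed = seed)
    ds <- list(list(observations = fx$observations, scenario = fx$scenario))
    start <- rat_params(CL_bile = truth$CL_bile * 1.6,
                        P_adipose = truth$P_adipose / 1.5)
    f <- fit_cd(list(CL_bile = c(1e-4, 0.1), P_adipose = c(20, 800)),
                ds, start, control = list(iter.max = 40, rel.tol = 1e-7))
    expect_lt(abs(f$estimates["CL_bile"] - truth$CL_bile) / truth$CL_bile,
              0.15)
    expect_lt(abs(f$estimates["P_adipose"] - truth$P_adipose) /
                truth$P_adipose, 0.15)
  }
})

test_that("fit guards bounds and unknown names", {
  fx <- generate_timecourse_fixture("dietary_3d", sigma_rel = 0, seed = 1)
  ds <- list(list(observations = fx$observations, scenario = fx$scenario))
  expect_error(fit_cd(list(no_param = c(0, 1)), ds, rat_params()),
               "unknown free parameter")
  expect_error(fit_cd(list(CL_bile = c(1, 2)), ds, rat_params()),
               "bounds")
})

test_that("human scale calibration meets its anchors and is idempotent", {
  p1 <- calibrate_human_scale(human_params())
  expect_equal(attr(p1, "achieved_dose"), 0.007, tolerance = 1e-3)
  expect_equal(attr(p1, "achieved_half_life"), 131, tolerance = 0.02)
  p2 <- calibrate_human_scale(p1)
  expect_equal(p2$CL_bile / p1$CL_bile, 1, tolerance = 1e-3)
  expect_equal(p2$P_adipose / p1$P_adipose, 1, tolerance = 1e-3)
  expect_error(calibrate_human_scale(rat_params()), "human")
})

test_that("concordance reproduces classical rank correlations", {
  expect_equal(concordance(1:5, 1:5)$rho, 1)
  expect_equal(concordance(1:5, 5:1)$rho, -1)
  r <- concordance(c(1, 2, 3, 4), c(1, 3, 2, 4))
  expect_equal(r$rho, 0.8)
  expect_true(r$approximate)
  # cross-check rho and p against the reference implementation
  set.seed(42)
  x <- rnorm(25); y <- x + rnorm(25)
  ref <- suppressWarnings(cor.test(x, y, method = "spearman"))
  r2 <- concordance(x, y)
  expect_equal(r2$rho, unname(ref$estimate), tolerance = 1e-12)
  expect_equal(r2$p_value, ref$p.value, tolerance = 0.05)
  expect_error(concordance(1:4, 1:5), "equal length")
  expect_error(concordance(1:2, 1:2), "at least 3")
})

test_that("simulated and noisily observed profiles rank-concord strongly", {
  fx <- generate_timecourse_fixture("oral_40mgkg_182d", sigma_rel = 0.15,
                                    seed = 7)
  blood <- fx$observations$matrix == "blood"
  pred <- cdpbpk:::.predict_observations(fx$observations[blood, ], fx$sim)
  r <- concordance(fx$observations$value[blood], pred)
  expect_gt(r$rho, 0.9)
  expect_lt(r$p_value, 0.001)
})
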