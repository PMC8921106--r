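test_that("scenario constructors set the expected switches and events", {
  s <- single_oral(mg_per_kg(40), species = "rat")
  expect_equal(nrow(s$events), 1L)
  expect_true(s$switches["oral_gavage"])
  expect_false(any(s$switches[c("intravenous", "dietary")]))

  z <- single_oral(0)
  expect_equal(nrow(z$events), 0L)
  expect_false(any(z$switches))

  iv <- iv_bolus(mg_per_kg(1), species = "rat")
  expect_true(iv$switches["intravenous"])

  expect_error(single_oral(-1), ">= 0")
  expect_error(iv_bolus(-1), ">= 0")
  expect_error(repeated_daily_oral(0.1, 10, 10), "> start")
  expect_error(
    exposure_scenario("human",
                      events = data.frame(time = 0, route = "dermal",
                                          dose = 1)),
    "unvalidated")
})

test_that("scenario construction is deterministic and serialisation round-trips", {
  a <- repeated_daily_oral(0.19, 0, days(1000))
  b <- repeated_daily_oral(0.19, 0, days(1000))
  expect_identical(a, b)

  path <- withr::local_tempfile(fileext = ".yaml")
  s <- exposure_scenario("rat",
                         events = data.frame(time = c(0, 24),
                                             route = "oral_gavage",
                                             dose = c(125.5, 40000)),
                         rates = data.frame(start = 48, stop = days(90),
                                            rate = 125))
  write_scenario(s, path)
  expect_identical(read_scenario(path), s)
  pj <- withr::local_tempfile(fileext = ".json")
  write_scenario(s, pj)
  expect_equal(read_scenario(pj), s)
})

test_that("administered-dose bookkeeping is exact", {
  s <- exposure_scenario("rat",
                         events = data.frame(time = c(0, 48),
                                             route = "oral_gavage",
                                             dose = c(100, 50)),
                         rates = data.frame(start = 0, stop = 240, rate = 24))
  bw <- 0.25
  # at t = 120 h: both boluses + 120 h of 24 ug/kg/day = 120 ug/kg
  expect_equal(administered_dose(s, 120, bw), (100 + 50 + 120) * bw)
  expect_equal(administered_dose(s, 1e6, bw), (150 + 240) * bw)
  # and the simulator's ledger agrees
  sim <- simulate_cd(s, rat_params(), rat_phys, duration = days(20))
  i <- which(sim$times == 240)
  expect_equal(unname(sim$states[i, "administered"]),
               administered_dose(s, 240, bw), tolerance = 1e-9)
})

test_that("IV delivers at least as much CD to blood as the same oral dose", {
  dose <- mg_per_kg(1)
  siv <- simulate_cd(iv_bolus(dose, species = "rat"), rat_params(), rat_phys,
                     duration = days(28))
  sor <- simulate_cd(single_oral(dose, species = "rat"), rat_params(),
                     rat_phys, duration = days(28))
  auc <- function(s) {
    x <- s$conc$time_days; y <- s$conc$blood_total
    sum(diff(x) * (head(y, -1) + tail(y, -1)) / 2)
  }
  expect_gt(auc(siv), auc(sor))
})
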