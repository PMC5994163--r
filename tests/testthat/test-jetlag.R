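# scenario runs are expensive-ish, share them across expectations
scenario_cache <- new.env()
get_run <- function(name) {
  if (is.null(scenario_cache[[name]]))
    scenario_cache[[name]] <- run_scenario(name, horizon = 120)
  scenario_cache[[name]]
}

test_that("period and peak detection work on constructed signals", {
  tt <- seq(0, 120, by = 0.1)
  sine <- data.frame(time = tt, P_X = 1 + cos(2 * pi * (tt - 3) / 24))
  # sinusoid of period 24 peaking at clock time 3
  expect_equal(compute_period(sine, "X"), 24, tolerance = 0.1 / 24)
  expect_equal(peak_time(sine, "X"), 3, tolerance = 0.1)
  flat <- data.frame(time = tt, P_X = rep(1, length(tt)))
  expect_true(is.na(compute_period(flat, "X")))
  expect_true(is.na(peak_time(flat, "X")))
  expect_error(compute_period(sine, "Q"), "no place")
})

test_that("persistence index is min/max over the windows", {
  tt <- seq(0, 100, by = 0.5)
  const <- data.frame(time = tt, P_X = rep(0.7, length(tt)))
  expect_identical(persistence_index(const, "X"), 1)
  dip <- data.frame(time = tt, P_X = ifelse(tt > 34 & tt < 36, 0, 0.8))
  expect_identical(persistence_index(dip, "X"), 0)
  expect_error(persistence_index(const, "X", windows = list(c(300, 310))),
               "empty window")
})

test_that("the normal scenario reproduces the clock phenotype", {
  res <- get_run("normal")
  m <- res$metrics
  get <- function(e, col) m[m$entity == e, col]
  expect_equal(get("Bmal", "period"), 24, tolerance = 0.02)
  expect_equal(get("PC", "period"), 24, tolerance = 0.02)
  expect_equal(get("Rev", "period"), 24, tolerance = 0.02)
  expect_equal(get("Bmal", "peak_clock_time"), 6, tolerance = 0.5)
  expect_equal(get("PC", "peak_clock_time"), 18, tolerance = 0.5)
  expect_equal(get("Rev", "peak_clock_time"), 8, tolerance = 0.5)
  # phase ordering within one cycle: BMAL1 before REV before PER-CRY
  expect_true(get("Bmal", "peak_clock_time") < get("Rev", "peak_clock_time"))
  expect_true(get("Rev", "peak_clock_time") < get("PC", "peak_clock_time"))
  # MYC and p53 express in opposition
  expect_lt(res$myc_p53_antiphase, 0)
})

test_that("severity ordering holds across the three presets", {
  rep <- compare_scenarios(get_run("normal"), get_run("mild"),
                           get_run("chronic"))
  expect_true(rep$verdicts$p53_suppression)
  expect_true(rep$verdicts$myc_persistence)
  expect_true(rep$verdicts$clock_amplitude_damping)
  # identical runs show no ordering
  same <- compare_scenarios(get_run("normal"), get_run("normal"),
                            get_run("normal"))
  expect_false(same$verdicts$p53_suppression)
  expect_false(same$verdicts$myc_persistence)
  expect_false(same$verdicts$clock_amplitude_damping)
})

test_that("p53 suppression is monotone along the severity sweep", {
  runs <- lapply(c(0, 0.5, 1), function(a)
    run_scenario(severity_rates(a), horizon = 120))
  rep <- compare_scenarios(runs[[1]], runs[[2]], runs[[3]])
  expect_true(rep$verdicts$p53_suppression)
})

test_that("comparison refuses mismatched runs", {
  short <- run_scenario("mild", horizon = 96)
  expect_error(compare_scenarios(get_run("normal"), short, get_run("chronic")),
               "identical horizon")
})
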