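test_that("target checking evaluates comparators and flags missing metrics", {
  targets <- list(
    list(id = "a", metric = "x", value = 1.0, cmp = "le", tol = 0.2),
    list(id = "b", metric = "y", value = 0.5, cmp = "le_abs", tol = 0.5),
    list(id = "c", metric = "z", value = 2.0, cmp = "eq", tol = 0.1),
    list(id = "d", metric = "missing", value = 1, cmp = "le", tol = 0))
  tf <- tempfile(fileext = ".json")
  jsonlite::write_json(targets, tf, auto_unbox = TRUE)
  report <- list(x = 1.1, y = 0.9, z = 2.05)
  out <- checkTargets(report, tf)
  expect_identical(out$status, c("pass", "fail", "pass", "indeterminate"))
  expect_identical(out$id, c("a", "b", "c", "d"))
  allPass <- checkTargets(list(x = 0.5, y = 0.4, z = 2, missing = 0.5), tf)
  expect_true(all(allPass$status == "pass"))
})

test_that("the experiment runner is reproducible and cache-aware", {
  outDir <- tempfile()
  cfg <- list(seed = 3, gridSpacing = c(1.5, 1.5, 1.5),
              population = list(n = 2, magnitudeRange = c(1.5, 3)))
  m1 <- runExperiment(cfg, outDir)
  expect_identical(m1$steps$population$status, "ok")
  expect_true(file.exists(file.path(outDir, "population_cases.csv")))
  expect_true(file.exists(file.path(outDir, "summary.json")))
  tab1 <- read.csv(file.path(outDir, "population_cases.csv"))
  # rerun with unchanged config: every step cache-hits, outputs unchanged
  m2 <- runExperiment(cfg, outDir)
  expect_true(isTRUE(m2$steps$population$cached))
  expect_identical(read.csv(file.path(outDir, "population_cases.csv")), tab1)
  # corrupting an output forces recomputation with identical results
  writeLines("corrupted", file.path(outDir, "population_cases.csv"))
  m3 <- runExperiment(cfg, outDir)
  expect_false(isTRUE(m3$steps$population$cached))
  expect_equal(read.csv(file.path(outDir, "population_cases.csv")), tab1)
})

test_that("population aggregates are recomputable from the per-case rows", {
  pop <- populationStudy()
  expect_identical(nrow(pop$cases), 10L)
  expect_equal(pop$pooled$arMedianOfCases, median(pop$cases$ar_median))
  expect_equal(pop$pooled$dinMedianOfCases, median(pop$cases$din_median))
  expect_true(all(pop$cases$din_p99 >= pop$cases$din_p95))
  expect_true(all(pop$cases$gtMaxDin > 0))
  # locations and modes stratified as configured
  expect_setequal(unique(pop$cases$location),
                  c("ascending", "descending", "arch"))
  # error correlates positively with deformation magnitude, as expected
  expect_gt(pop$pooled$corMagnitudeDiN, 0)
})
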