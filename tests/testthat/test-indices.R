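test_that("unit conversion uses the glucose molar mass", {
  expect_equal(mgdl_to_mmoll(0), 0)
  expect_equal(mgdl_to_mmoll(180.16), 10)
  expect_equal(mgdl_to_mmoll(140), 7.771, tolerance = 0.001 / 7.771)
  expect_error(mgdl_to_mmoll(-1), "non-negative")
})

test_that("glucose series validation catches malformed input", {
  expect_error(glucose_series(0, 100), "at least 2")
  expect_error(glucose_series(c(0, 0), c(100, 110)), "duplicated")
  expect_error(glucose_series(c(0, 4), c(100, -5)), "non-positive")
  expect_error(glucose_series(c(0, 30), c(100, 110)), "24 h")
  s <- glucose_series(c(4, 0), c(110, 100))  # sorted defensively
  expect_equal(s$values_mgdl, c(100, 110))
})

test_that("MBG and LAGE match their closed forms", {
  s <- glucose_series(seq(0, 20, 4), c(120, 130, 140, 150, 160, 170))
  expect_equal(compute_mbg(s), 145)
  expect_equal(compute_lage(s), 50)
  const <- glucose_series(seq(0, 20, 4), rep(140, 6))
  expect_equal(compute_mbg(const), 140)
  expect_equal(compute_lage(const), 0)
  set.seed(41)
  for (i in 1:20) {
    s <- random_series()
    expect_equal(compute_mbg(s), mean(s$values_mgdl))
    expect_equal(compute_lage(s), max(s$values_mgdl) - min(s$values_mgdl))
  }
})

test_that("MAG and GLI match hand formulas and loop oracles", {
  # values chosen as whole mmol/L: 5, 7, 6 mmol/L at t = 0, 4, 8
  s <- glucose_series(c(0, 4, 8), c(5, 7, 6) * 18.016)
  expect_equal(compute_mag(s), (2 + 1) / 8)
  expect_equal(compute_gli(s), 4 / 4 + 1 / 4)
  const <- glucose_series(seq(0, 20, 4), rep(140, 6))
  expect_equal(compute_mag(const), 0)
  expect_equal(compute_gli(const), 0)
  set.seed(42)
  for (i in 1:50) {
    s <- random_series(n = sample(3:8, 1))
    expect_equal(compute_mag(s), oracle_mag(s$values_mgdl, s$times))
    expect_equal(compute_gli(s), oracle_gli(s$values_mgdl, s$times))
  }
})

test_that("MAGE handles the canonical cases", {
  # perfect 4-mmol sawtooth: every adjacent excursion is 4 > SD ~ 2.19
  saw <- glucose_series(seq(0, 20, 4), c(5, 9, 5, 9, 5, 9) * 18.016)
  expect_equal(compute_mage(saw), 4)
  mono <- glucose_series(seq(0, 20, 4), seq(100, 200, by = 20))
  expect_equal(compute_mage(mono), 0)
  const <- glucose_series(seq(0, 20, 4), rep(140, 6))
  expect_equal(compute_mage(const), 0)
  expect_error(compute_mage(glucose_series(c(0, 4), c(100, 140))),
               "insufficient readings")
})

test_that("MAGE agrees with the brute-force extremum oracle", {
  set.seed(43)
  for (i in 1:1000) {
    n <- sample(3:8, 1)
    v <- runif(n, 60, 300)
    if (runif(1) < 0.3) v[sample(n, 2)] <- v[1]  # induce plateaus
    s <- glucose_series(seq(0, by = 3, length.out = n), v)
    expect_equal(compute_mage(s), oracle_mage(s$values_mgdl))
  }
})

test_that("index invariants: MAGE <= LAGE, translation and order invariance", {
  set.seed(44)
  for (i in 1:500) {
    s <- random_series(n = sample(4:8, 1))
    expect_lte(compute_mage(s), mgdl_to_mmoll(compute_lage(s)) + 1e-12)
    shift <- glucose_series(s$times, s$values_mgdl + 50)
    expect_equal(compute_mag(shift), compute_mag(s))
    expect_equal(compute_gli(shift), compute_gli(s))
    expect_equal(compute_lage(shift), compute_lage(s))
    expect_equal(compute_mage(shift), compute_mage(s))
    expect_equal(compute_mbg(shift), compute_mbg(s) + 50)
    o <- sample(length(s$times))
    scr <- glucose_series(s$times[o], s$values_mgdl[o])
    expect_equal(compute_mag(scr), compute_mag(s))
    expect_equal(compute_mage(scr), compute_mage(s))
  }
})

test_that("stratification applies the clinical boundaries and strict cutoffs", {
  idx <- data.frame(patient_id = 1:3, n_obs = 6, complete = TRUE,
                    baseline_mgdl = c(139.9, 140, 200),
                    mbg_mgdl = c(139.9, 140, 200),
                    mag_mmol_l_h = c(0.77, 0.7701, 0.5),
                    mage_mmol_l = c(2.58, 2.59, 1),
                    gli_mmol2_h = c(2.6, 2.61, 1),
                    lage_mgdl = c(79.2, 79.3, 10))
  st <- stratify_indices(idx, "paper")
  expect_equal(as.character(st$mbg_stratum), c("no", "mild", "severe"))
  expect_equal(as.character(st$baseline_stratum), c("no", "mild", "severe"))
  expect_equal(st$mag_high, c(FALSE, TRUE, FALSE))
  expect_equal(st$mage_high, c(FALSE, TRUE, FALSE))
  expect_equal(st$gli_high, c(FALSE, TRUE, FALSE))
  expect_equal(st$lage_high, c(FALSE, TRUE, FALSE))
})

test_that("median threshold mode recomputes cutpoints from the cohort", {
  set.seed(45)
  Y <- matrix(runif(60 * 6, 80, 280), 60)
  idx <- compute_indices(glucose_long(Y))
  st <- stratify_indices(idx, "median")
  th <- attr(st, "thresholds")
  expect_equal(th$mag, median(idx$mag_mmol_l_h))
  # half the cohort (up to ties at the median) flagged high
  expect_equal(sum(st$mag_high), 30)
  expect_error(stratify_indices(idx, list(mag = 1)), "missing threshold")
})

test_that("compute_indices emits one validated row per patient", {
  Y <- rbind(c(120, 130, 140, 150, 160, 170), rep(140, 6))
  idx <- compute_indices(glucose_long(Y))
  expect_equal(nrow(idx), 2)
  expect_equal(idx$baseline_mgdl, c(120, 140))
  expect_equal(idx$mbg_mgdl, c(145, 140))
  expect_true(all(idx$complete))
})
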