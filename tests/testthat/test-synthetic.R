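test_that("full retention leaves every organ at its equilibrium activity", {
  m <- redistribution_model(c(blood = 0, spleen = 0))
  bio <- c(blood = 17.9, spleen = 86, kidney = 4.7)
  masses <- c(blood = 1.5, spleen = 0.1, kidney = 0.4)
  tr <- simulate_redistribution(bio, m, masses)
  expect_equal(tr$A0_true, tr$A_eq_true)
  expect_equal(attr(tr, "urine_pool"), 0)
})

test_that("blood-only release reproduces the releasing-organ ratio", {
  m <- redistribution_model(c(blood = 0.94))
  tr <- simulate_redistribution(c(blood = 17.9, spleen = 86, kidney = 4.7),
                                m, c(blood = 1.5, spleen = 0.1,
                                     kidney = 0.4))
  blood <- tr[tr$organ == "blood", ]
  expect_equal(blood$A0_true / blood$A_eq_true, 0.06, tolerance = 1e-12)
  kidney <- tr[tr$organ == "kidney", ]
  expect_gt(kidney$A0_true, kidney$A_eq_true)   # kidney accumulates
})

test_that("redistribution conserves mass-weighted activity for random models", {
  set.seed(19)
  for (i in 1:20) {
    organs <- c("blood", "spleen", "kidney", "tumour")
    bio <- setNames(runif(4, 0.5, 200), organs)
    masses <- setNames(runif(4, 0.05, 2), organs)
    f <- runif(2); f <- c(f, 1 - sum(f))
    while (any(f < 0)) { f <- runif(2); f <- c(f, 1 - sum(f)) }
    m <- redistribution_model(setNames(runif(4), organs),
                              kidney_uptake_fraction = f[1],
                              urine_fraction = f[2], other_fraction = f[3])
    tr <- simulate_redistribution(bio, m, masses)
    total_before <- sum(bio * masses)
    total_after <- sum(tr$A0_true * tr$mass_g) + attr(tr, "urine_pool") +
      attr(tr, "other_pool")
    expect_equal(total_after, total_before, tolerance = 1e-12)
  }
})

test_that("redistribution model validates its fractions", {
  expect_error(redistribution_model(c(blood = 1.2)), "0, 1")
  expect_error(redistribution_model(c(blood = 0.5),
                                    kidney_uptake_fraction = 0.5,
                                    urine_fraction = 0.5,
                                    other_fraction = 0.5), "sum to 1")
  m <- redistribution_model(c(blood = 0.5))
  expect_error(simulate_redistribution(c(blood = 10), m, c(blood = 1)),
               "kidney")
})

test_that("counting series are exact in noise-free mode, Poisson otherwise", {
  s <- simulate_counting_series(86, 58)
  expect_equal(s$value, ingrowth_activity(86, 58, LAM_BI, s$t_min))
  # fit round-trip on the generated series
  fit <- fit_ingrowth(s, lambda2 = LAM_BI)
  expect_equal(unname(coef(fit)), c(86, 58), tolerance = 1e-9)
  # fixed seed -> identical draws
  a <- simulate_counting_series(86, 58, counts_per_unit = 100, seed = 4)
  b <- simulate_counting_series(86, 58, counts_per_unit = 100, seed = 4)
  expect_identical(a, b)
  c2 <- simulate_counting_series(86, 58, counts_per_unit = 100, seed = 5)
  expect_false(identical(a, c2))
  expect_error(simulate_counting_series(1, 1, schedule = numeric(0)),
               "empty")
})

test_that("cohorts with zero between-animal variation are identical animals", {
  co <- simulate_cohort(3, list(DTPA = dtpa_group_spec(cv = 0)),
                        counts_per_unit = Inf, seed = 1)
  tr <- co$truth
  for (org in unique(tr$organ))
    expect_equal(length(unique(tr$A0_true[tr$organ == org])), 1L)
  # single-animal bundles are valid
  co1 <- simulate_cohort(1, list(DTPA = dtpa_group_spec()), seed = 2)
  expect_equal(length(unique(co1$series$animal_id)), 1L)
  expect_true(all(c("series", "organs", "standards", "truth") %in%
                    names(co1)))
})

test_that("cohort CSV bundle round-trips through disk", {
  outdir <- file.path(tempdir(), "cohort_bundle")
  co <- simulate_cohort(2, list(DTPA = dtpa_group_spec(cv = 0)),
                        counts_per_unit = Inf, seed = 3, outdir = outdir)
  expect_true(all(file.exists(file.path(outdir,
                                        c("series.csv", "organs.csv",
                                          "standards.csv", "truth.json")))))
  back <- read.csv(file.path(outdir, "series.csv"))
  expect_equal(nrow(back), nrow(co$series))
  tj <- jsonlite::read_json(file.path(outdir, "truth.json"),
                            simplifyVector = TRUE)
  expect_equal(tj$A0_true, co$truth$A0_true, tolerance = 1e-12)
})

test_that("pipeline recovers the cohort group ratio within sampling error", {
  co <- simulate_cohort(5, list(DTPA = dtpa_group_spec()),
                        counts_per_unit = 2000, seed = 6)
  res <- run_retention_pipeline(list(series = co$series))
  blood <- res$ratios[res$ratios$organ == "blood", ]
  expect_lt(abs(blood$mean - 0.06), 3 * max(blood$sd, 0.005))
})

test_that("arrested tumours never reach the humane endpoint", {
  co <- simulate_tumour_cohort(8, "treated", treatment_effect = 0, seed = 9)
  expect_true(all(co$survival$event == 0))
  expect_true(all(co$survival$time_days == 115))
})

test_that("untreated doubling times centre on the configured mean", {
  set.seed(14)
  co <- simulate_tumour_cohort(200, "ctrl", doubling_days = 18,
                               regress_prob = 0)
  dd <- vapply(split(co$tracks, co$tracks$animal_id), function(d)
    doubling_event(d[order(d$day), ]), numeric(1))
  dd <- dd[!is.na(dd)]
  expect_gt(length(dd), 150)
  expect_lt(abs(mean(dd) - 18), 2 * sd(dd))
})

test_that("strong treatment effects are detectable by log-rank", {
  set.seed(25)
  hits <- replicate(60, {
    ctrl <- simulate_tumour_cohort(8, "ctrl", regress_prob = 0.25)
    trt <- simulate_tumour_cohort(8, "trt", treatment_effect = 0.05,
                                  regress_prob = 0.25)
    suppressWarnings(logrank_pair(ctrl$survival$time_days,
                                  ctrl$survival$event,
                                  trt$survival$time_days,
                                  trt$survival$event)$p_value) < 0.05
  })
  expect_gte(mean(hits), 0.8)
})
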