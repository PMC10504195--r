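# jecs_presets() re-runs the calibration solver; build once per test file.
presets <- jecs_presets()

test_that("preset truth surfaces reproduce the published table cells", {
  ref <- jecs_reference_values()
  hc <- c("h05", "h10", "h25", "h50", "h75", "h90", "h95")
  kn <- qnorm(c(0.05, 0.10, 0.25, 0.50, 0.75, 0.90, 0.95))
  for (nm in names(presets)) {
    s <- presets[[nm]]
    blk <- ref[ref$sex == s$sex & ref$outcome == s$outcome, ]
    for (k in seq_along(kn)) {
      fit <- truth_centile(s, blk$bp_percentile / 100, kn[k])
      expect_true(max(abs(fit - blk[[hc[k]]])) <= 0.5,
                  label = paste(nm, hc[k], "round trip within 0.5 mmHg"))
    }
  }
  # published medians at the 50th height percentile
  expect_equal(presets[["jecs-boys-sbp"]]$M_fn(0), 91)
  expect_equal(presets[["jecs-girls-sbp"]]$M_fn(0), 90)
  expect_equal(presets[["jecs-boys-dbp"]]$M_fn(0), 52)
  expect_equal(presets[["jecs-girls-dbp"]]$M_fn(0), 52)
})

test_that("truth surfaces are flat beyond the outer knots and positive", {
  s <- presets[["jecs-boys-sbp"]]
  expect_equal(s$M_fn(-3), s$M_fn(-1.6449))
  expect_equal(s$S_fn(3), s$S_fn(1.6449))
  zz <- seq(-3, 3, by = 0.05)
  expect_true(all(s$M_fn(zz) > 0))
  expect_true(all(s$S_fn(zz) > 0))
})

test_that("generation is deterministic and respects the sex split", {
  cfg <- sim_config(n_children = 500, seed = 123,
                    missing_second_rate = 0.05, crying_rate = 0.1,
                    unstable_rate = 0.05)
  a <- generate_cohort(cfg)
  b <- generate_cohort(cfg)
  expect_identical(a, b)
  pa <- withr::local_tempfile(fileext = ".csv")
  pb <- withr::local_tempfile(fileext = ".csv")
  write_cohort(a, pa); write_cohort(b, pb)
  expect_identical(readLines(pa), readLines(pb))

  cfg2 <- sim_config(n_children = 3361, pct_boys = 0.497, seed = 5)
  coh <- generate_cohort(cfg2)
  expect_true(sum(coh$sex == "boy") %in% c(1670, 1671))
})

test_that("a noise-free cohort has identical triplets that all pass", {
  cfg <- sim_config(n_children = 300, seed = 9,
                    within_child_noise_sd = 0)
  coh <- generate_cohort(cfg)
  expect_true(all(coh$sbp1 == coh$sbp2 & coh$sbp2 == coh$sbp3))
  out <- select_cohort(coh)
  expect_true(all(out$sbp_status == "accepted"))
  expect_true(all(out$dbp_status == "accepted"))
  expect_true(all(out$sbp_selected > out$dbp_selected))
})

test_that("non-outlier heights stay within 5 SD of the bundled standard", {
  cfg <- sim_config(n_children = 2000, seed = 31,
                    height_outlier_rate = 0.01)
  coh <- generate_cohort(cfg)
  z <- height_zscore(coh$height_cm, coh$sex, coh$age_months,
                     cfg$standard)$zht
  plain <- coh$planted_category != "height_outlier"
  # heights are rounded to 0.1 cm on output; allow that wobble
  expect_true(all(abs(z[plain]) <= 5 + 0.1 / (84 * 0.0345)))
  expect_true(all(abs(z[!plain]) > 5))
})

test_that("generated BP matches truth centiles near a knot", {
  cfg <- sim_config(n_children = 1e5, seed = 77, pct_boys = 1,
                    within_child_noise_sd = 0, reading_step = 0)
  coh <- generate_cohort(cfg)
  z <- height_zscore(coh$height_cm, coh$sex, coh$age_months,
                     cfg$standard)$zht
  near <- abs(z) < 0.05
  s <- presets[["jecs-boys-sbp"]]
  for (p in c(0.1, 0.5, 0.9)) {
    emp <- quantile(coh$sbp1[near], p)
    expect_lt(abs(emp - truth_centile(s, p, 0)), 1.0)
  }
})

test_that("configuration validation catches bad rates", {
  expect_error(sim_config(crying_rate = 0.7, unstable_rate = 0.5),
               "sum")
  expect_error(sim_config(pct_boys = 1.4), "pct_boys")
  expect_error(sim_config(n_children = 0), "n_children")
})

test_that("cohort CSV round-trips with empty strings for missing", {
  cfg <- sim_config(n_children = 120, seed = 4,
                    missing_second_rate = 0.2, dbp_zero_rate = 0.1)
  coh <- generate_cohort(cfg)
  path <- withr::local_tempfile(fileext = ".csv")
  write_cohort(coh, path)
  raw <- readLines(path)
  expect_false(any(grepl("NA", raw, fixed = TRUE)))
  back <- read_cohort(path)
  expect_equal(back$sbp2, coh$sbp2)
  expect_identical(back$chronic_disease, coh$chronic_disease)
})
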