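mk_clean_record <- function(id = "X1", sex = "boy", age = 26,
                            height = 84, sbp = c(100, 92, 94),
                            dbp = c(60, 56, 58)) {
  data.frame(child_id = id, sex = sex, age_months = age,
             height_cm = height, weight_kg = 11.5, season = "spring",
             gestational_weeks = 39, birth_weight_g = 3000,
             chronic_disease = FALSE, posture = "sitting",
             condition_flag = "stable",
             sbp1 = sbp[1], sbp2 = sbp[2], sbp3 = sbp[3],
             dbp1 = dbp[1], dbp2 = dbp[2], dbp3 = dbp[3],
             stringsAsFactors = FALSE)
}

std <- synthetic_growth_standard()

test_that("exclusion order: chronic disease precedes everything", {
  rec <- mk_clean_record()
  rec$chronic_disease <- TRUE
  rec$condition_flag <- "crying"   # would otherwise hit box (2)+(3)
  out <- apply_exclusions(rec, std)
  expect_equal(out$flow$sbp[["excluded_chronic"]], 1)
  expect_equal(out$flow$dbp[["excluded_chronic"]], 1)
  expect_equal(nrow(out$sbp_set), 0)
})

test_that("a 23-month-old otherwise-clean child is excluded as underage", {
  rec <- mk_clean_record(age = 23)
  out <- apply_exclusions(rec, std)
  expect_equal(out$flow$sbp[["excluded_underage"]], 1)
  expect_equal(out$flow$dbp[["excluded_underage"]], 1)
})

test_that("channel asymmetry: a DBP-only failure keeps the SBP analysis", {
  rec <- mk_clean_record(dbp = c(60, 0, 58))
  out <- apply_exclusions(rec, std)
  expect_equal(nrow(out$sbp_set), 1)
  expect_equal(nrow(out$dbp_set), 0)
  expect_equal(out$flow$dbp[["excluded_missing_or_condition"]], 1)
  expect_equal(out$reasons$dbp[["dbp_zero"]], 1)
})

test_that("every child lands in exactly one bucket per channel", {
  cfg <- sim_config(n_children = 1500, seed = 21,
                    missing_second_rate = jecs_rates()[["missing_second"]],
                    unstable_rate = jecs_rates()[["unstable"]],
                    crying_rate = jecs_rates()[["crying"]],
                    chronic_rate = jecs_rates()[["chronic"]],
                    dbp_zero_rate = jecs_rates()[["dbp_zero"]],
                    underage_rate = jecs_rates()[["underage"]],
                    height_outlier_rate = jecs_rates()[["height_outlier"]])
  coh <- generate_cohort(cfg)
  out <- apply_exclusions(coh, cfg$standard)
  for (ch in c("sbp", "dbp")) {
    f <- out$flow[[ch]]
    expect_equal(f[["total_in"]], sum(f[names(f) != "total_in"]))
    expect_equal(f[["total_in"]], nrow(coh))
  }
})

test_that("flow counts equal the generator's planted counts under zero noise", {
  rates <- jecs_rates()
  cfg <- sim_config(n_children = 2500, seed = 33,
                    within_child_noise_sd = 0,
                    missing_second_rate = rates[["missing_second"]],
                    unstable_rate = rates[["unstable"]],
                    crying_rate = rates[["crying"]],
                    chronic_rate = rates[["chronic"]],
                    dbp_zero_rate = rates[["dbp_zero"]],
                    underage_rate = rates[["underage"]],
                    height_outlier_rate = rates[["height_outlier"]])
  coh <- generate_cohort(cfg)
  out <- apply_exclusions(coh, cfg$standard)
  planted <- planted_flow(coh)
  expect_identical(unname(out$flow$sbp), unname(planted$sbp))
  expect_identical(unname(out$flow$dbp), unname(planted$dbp))
})

test_that("the analyzed set is exactly the violation-free children", {
  # exclusion bookkeeping depends on bucket order, membership must not:
  # a child is analyzed iff it has no violating feature at all
  rates <- jecs_rates()
  cfg <- sim_config(n_children = 1200, seed = 55,
                    missing_second_rate = rates[["missing_second"]],
                    unstable_rate = rates[["unstable"]],
                    crying_rate = rates[["crying"]],
                    chronic_rate = rates[["chronic"]],
                    dbp_zero_rate = rates[["dbp_zero"]],
                    underage_rate = rates[["underage"]],
                    height_outlier_rate = rates[["height_outlier"]])
  coh <- select_cohort(generate_cohort(cfg))
  out <- apply_exclusions(coh, cfg$standard)
  z <- height_zscore(coh$height_cm, coh$sex, coh$age_months,
                     cfg$standard)$zht
  clean_sbp <- !coh$chronic_disease &
    coh$condition_flag == "stable" &
    coh$sbp_status == "accepted" &
    abs(z) <= 5 & coh$age_months >= 24
  expect_setequal(out$sbp_set$child_id, coh$child_id[clean_sbp])
  clean_dbp <- !coh$chronic_disease &
    coh$condition_flag == "stable" &
    coh$dbp_status == "accepted" &
    abs(z) <= 5 & coh$age_months >= 24
  expect_setequal(out$dbp_set$child_id, coh$child_id[clean_dbp])
})

test_that("cohort summaries reproduce hand arithmetic", {
  a <- mk_clean_record("A", sbp = c(90, 90, 90), dbp = c(50, 50, 50))
  b <- mk_clean_record("B", sex = "girl", sbp = c(92, 92, 92),
                       dbp = c(52, 52, 52))
  out <- apply_exclusions(rbind(a, b), std)
  s <- cohort_summary(out$sbp_set, out$dbp_set)
  expect_equal(s$n, 2)
  expect_equal(s$sbp_mean, 91.0)
  expect_equal(s$sbp_sd, round(sd(c(90, 92)), 1))  # sample SD, 1.414 -> 1.4
  expect_equal(s$pct_boys, 50.0)

  boys <- apply_exclusions(rbind(a, mk_clean_record("C")), std)
  sb <- cohort_summary(boys$sbp_set, boys$dbp_set)
  expect_equal(sb$pct_boys, 100.0)

  empty <- cohort_summary(out$sbp_set[0, ], out$dbp_set[0, ])
  expect_true(attr(empty, "empty"))
})

test_that("mean selected BP matches a quadrature oracle over the truth", {
  cfg <- sim_config(n_children = 1e4, seed = 13, pct_boys = 1)
  coh <- generate_cohort(cfg)
  out <- apply_exclusions(coh, cfg$standard)
  s <- jecs_presets()[["jecs-boys-sbp"]]
  # E[BP | z] by Gauss-Legendre quadrature on the probability scale,
  # averaged over the analyzed children's Zht values
  gl_p <- (seq_len(2000) - 0.5) / 2000
  gl_p <- gl_p[abs(qnorm(gl_p)) <= 3.9]   # match the generator's clip
  cond_mean <- vapply(out$sbp_set$zht, function(z) {
    mean(truth_centile(s, gl_p, z))
  }, numeric(1))
  expect_lt(abs(mean(out$sbp_set$bp) - mean(cond_mean)), 0.5)
})
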