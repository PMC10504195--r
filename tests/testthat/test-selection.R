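test_that("the stated selection examples hold", {
  r <- select_bp_value(c(100, 92, 94))
  expect_equal(r$value, 93.0); expect_equal(r$pair_used, "2,3")

  r <- select_bp_value(c(100, NA, 98))
  expect_equal(r$value, 99.0); expect_equal(r$pair_used, "1,3")

  r <- select_bp_value(c(100, 94, 88))
  expect_equal(r$status, "rejected_unstable")

  # a difference of exactly 5 mmHg disqualifies a pair: (2,3) fails here
  # and the first pair steps in
  r <- select_bp_value(c(100, 100, 105))
  expect_equal(r$pair_used, "1,2"); expect_equal(r$value, 100)
  # ... and rejects outright when every consecutive pair sits at 5 mmHg
  expect_equal(select_bp_value(c(90, 95, 100))$status,
               "rejected_unstable")
  expect_equal(select_bp_value(c(NA, NA, 100))$status, "rejected_missing")
  expect_error(select_bp_value(c(0, 90, 90)), "positive")
  expect_error(select_bp_value(c(90, 90)), "3 slots")
})

test_that("selection properties: shift invariance, equal readings, pair preference", {
  set.seed(42)
  for (i in 1:200) {
    r <- sample(70:120, 3, replace = TRUE)
    a <- select_bp_value(r)
    b <- select_bp_value(r + 17)
    expect_equal(a$status, b$status)
    if (a$status == "accepted") {
      expect_equal(b$value - a$value, 17)
      expect_equal(a$pair_used, b$pair_used)
    }
  }
  # equal readings are always accepted at the common value
  for (v in c(60, 95, 140)) {
    r <- select_bp_value(c(v, v, v))
    expect_equal(r$value, v); expect_equal(r$pair_used, "2,3")
  }
  # when both consecutive pairs qualify, (2,3) wins
  r <- select_bp_value(c(90, 92, 94))
  expect_equal(r$pair_used, "2,3"); expect_equal(r$value, 93)
})

test_that("selection matches the brute-force oracle on a bounded grid", {
  vals <- seq(80, 96, by = 2)
  full <- as.matrix(expand.grid(vals, vals, vals))
  m <- rbind(full,
             cbind(NA, full[, 1:2]),
             cbind(full[, 1], NA, full[, 2]),
             cbind(full[, 1:2], NA))
  got <- bpcentile:::select_channel(m)
  want <- oracle_select_matrix(m)
  expect_identical(got$status, want$status)
  expect_identical(got$pair_used, want$pair_used)
  expect_identical(got$value, want$value)
  # the scalar entry point agrees with the vectorized core
  idx <- sample(nrow(m), 300)
  for (i in idx) {
    s <- select_bp_value(m[i, ])
    expect_identical(s$status, got$status[i])
    expect_identical(s$value, got$value[i])
  }
})

test_that("record-level rules: condition flags and the zero diastolic", {
  r <- select_record(c(100, 92, 94), c(60, 0, 58))
  expect_equal(r$sbp$value, 93.0)
  expect_equal(r$dbp$status, "rejected_dbp_zero")

  # crying rejects both channels regardless of readings
  r <- select_record(c(100, 92, 94), c(60, 58, 58),
                     condition_flag = "crying")
  expect_equal(r$sbp$status, "rejected_unstable")
  expect_equal(r$dbp$status, "rejected_unstable")

  # an accepted non-zero pair stands even with a zero elsewhere
  r <- select_record(c(100, 92, 94), c(62, 60, 0))
  expect_equal(r$dbp$value, 61)
  expect_equal(r$dbp$pair_used, "1,2")

  # a zero inside the adopted pair window rejects
  r <- select_record(c(100, 92, 94), c(60, 2, 0))
  expect_equal(r$dbp$status, "rejected_dbp_zero")

  expect_error(select_record(c(100, 92, 94), c(60, 58, 58),
                             condition_flag = "bored"), "condition")
  expect_error(select_record(c(50, 92, 94), c(60, 58, 58)), "exceed")
})

test_that("cohort-level selection agrees with record-level selection", {
  set.seed(7)
  n <- 400
  mk <- function() {
    m <- matrix(sample(c(40:120, NA), 3 * n, replace = TRUE), n, 3)
    m
  }
  smat <- mk() + 40  # keep SBP above DBP
  dmat <- mk()
  dmat[sample(n, 30), 2] <- 0
  cond <- sample(c("stable", "crying"), n, replace = TRUE,
                 prob = c(0.9, 0.1))
  cohort <- data.frame(sbp1 = smat[, 1], sbp2 = smat[, 2],
                       sbp3 = smat[, 3], dbp1 = dmat[, 1],
                       dbp2 = dmat[, 2], dbp3 = dmat[, 3],
                       condition_flag = cond)
  out <- select_cohort(cohort)
  for (i in sample(n, 120)) {
    # record-level path (validates SBP > DBP; relax rows violating it)
    dr <- dmat[i, ]
    sr <- smat[i, ]
    keep <- !(!is.na(sr) & !is.na(dr) & dr > 0 & sr <= dr)
    if (!all(keep)) next
    r <- select_record(sr, dr, cond[i])
    expect_identical(out$sbp_status[i], r$sbp$status)
    expect_identical(out$dbp_status[i], r$dbp$status)
    if (r$sbp$status == "accepted" && cond[i] == "stable") {
      expect_identical(out$sbp_selected[i], r$sbp$value)
    }
  }
})
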