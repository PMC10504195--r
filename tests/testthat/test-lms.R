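sim_const_bccg <- function(n, L, M, S, seed) {
  set.seed(seed)
  z <- rnorm(n)
  p <- pnorm(pmin(pmax(rnorm(n), -3.9), 3.9))
  data.frame(zht = z, bp = bccg_centile(p, L, M, S))
}

test_that("constant-parameter truth is recovered across the Zht range", {
  dat <- sim_const_bccg(5000, 1, 90, 0.09, seed = 101)
  fit <- fit_lms(dat, sex = "boy", outcome = "SBP")
  zz <- seq(-2, 2, by = 0.1)
  par <- bpcentile:::lms_params(fit, zz, allow_extrapolation = TRUE)
  expect_lt(max(abs(par$M - 90)), 0.5)
  expect_lt(max(abs(par$S - 0.09)), 0.01)
  # BIC of the selected model is minimal over the searched grid
  expect_equal(fit$bic, min(fit$bic_table$bic, na.rm = TRUE))
  # and the selected smoothness sits at (or next to) the grid minimum
  expect_lte(sum(fit$edf), 1 + 2 + 1 + 2)
})

test_that("a singleton edf grid is returned as-is", {
  dat <- sim_const_bccg(800, 1, 90, 0.09, seed = 7)
  grid <- data.frame(L = 1, M = 3, S = 2)
  fit <- fit_lms(dat, edf_grid = grid)
  expect_equal(unname(fit$edf), c(1, 3, 2))
})

test_that("fitting validates its input", {
  dat <- sim_const_bccg(30, 1, 90, 0.09, seed = 1)
  expect_error(fit_lms(dat), "at least 50")
  dat2 <- sim_const_bccg(200, 1, 90, 0.09, seed = 1)
  dat2$bp[1] <- -3
  expect_error(fit_lms(dat2), "positive")
  expect_error(fit_lms(dat2[0, ], edf_grid = data.frame()), "at least")
  expect_error(fit_lms(sim_const_bccg(200, 1, 90, 0.09, 2),
                       edf_grid = data.frame(x = 1)), "edf_grid")
})

test_that("z-residuals are standard normal under the truth model", {
  dat <- sim_const_bccg(5000, 0.5, 90, 0.09, seed = 202)
  fit <- fit_lms(dat)
  r <- z_residuals(fit)
  expect_equal(r$n_excluded, 0)
  expect_gt(mean(r$z), -0.05); expect_lt(mean(r$z), 0.05)
  expect_gt(sd(r$z), 0.95); expect_lt(sd(r$z), 1.05)
  # a single observation on the median curve has residual exactly 0
  m0 <- bpcentile:::lms_params(fit, 0)$M
  expect_equal(z_residuals(fit, data.frame(zht = 0, bp = m0))$z, 0,
               tolerance = 1e-12)
})

test_that("residuals pass a KS normality screen in most replicates", {
  crit <- 1.358 / sqrt(2000)  # 5% asymptotic critical value
  pass <- 0
  for (seed in 1:12) {
    dat <- sim_const_bccg(2000, 1, 90, 0.09, seed = 300 + seed)
    fit <- fit_lms(dat, edf_grid = data.frame(L = 1, M = 2, S = 1))
    ks <- suppressWarnings(ks.test(z_residuals(fit)$z, "pnorm"))
    pass <- pass + (ks$statistic < crit)
  }
  expect_gte(pass, 10)
})

test_that("fitted centiles do not cross and refuse silent extrapolation", {
  dat <- sim_const_bccg(3000, 0.5, 90, 0.09, seed = 77)
  fit <- fit_lms(dat)
  zz <- seq(max(-2.5, fit$zrange[1]), min(2.5, fit$zrange[2]),
            length.out = 81)
  prev <- -Inf
  for (p in c(0.05, 0.25, 0.5, 0.75, 0.9, 0.95, 0.99)) {
    cur <- lms_centile(fit, zz, rep(p, length(zz)))
    expect_true(all(cur > prev))
    prev <- cur
  }
  expect_error(lms_centile(fit, fit$zrange[2] + 1, 0.5), "extrapolation")
  expect_silent(lms_centile(fit, fit$zrange[2] + 1, 0.5,
                            allow_extrapolation = TRUE))
})

test_that("non-convergence surfaces as an informative error", {
  dat <- sim_const_bccg(500, 1, 90, 0.09, seed = 5)
  expect_error(fit_lms(dat, edf_grid = data.frame(L = 1, M = 2, S = 1),
                       max_iter = 1, tol = 1e-14),
               "failed for every edf triple")
})

test_that("a model rebuilt from its export evaluates identically", {
  dat <- sim_const_bccg(1200, 1, 90, 0.09, seed = 9)
  fit <- fit_lms(dat, edf_grid = data.frame(L = 1, M = 3, S = 2),
                 sex = "girl", outcome = "DBP")
  base <- withr::local_tempfile()
  write_lms_model(fit, base)
  back <- read_lms_model(base)
  kn <- qnorm(c(0.05, 0.25, 0.5, 0.75, 0.95))
  expect_identical(lms_centile(fit, kn, rep(0.9, 5)),
                   lms_centile(back, kn, rep(0.9, 5)))
  expect_identical(back$edf, fit$edf)
})
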