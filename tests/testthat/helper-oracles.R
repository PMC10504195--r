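# Independent oracles used by the test suite. These deliberately avoid the
# package's own code paths.

# Brute-force triplicate selection oracle: walks an explicit table of
# candidate pairs in preference order and checks eligibility naively.
oracle_select <- function(r) {
  stopifnot(length(r) == 3)
  candidates <- list(
    list(i = 2, j = 3, needs_missing2 = FALSE),
    list(i = 1, j = 2, needs_missing2 = FALSE),
    list(i = 1, j = 3, needs_missing2 = TRUE)
  )
  for (cand in candidates) {
    a <- r[cand$i]; b <- r[cand$j]
    if (cand$needs_missing2 && !is.na(r[2])) next
    if (is.na(a) || is.na(b)) next
    if (abs(a - b) < 5) {
      return(list(value = (a + b) / 2, status = "accepted",
                  pair_used = paste(cand$i, cand$j, sep = ",")))
    }
  }
  if (sum(is.na(r)) >= 2) {
    return(list(value = NA_real_, status = "rejected_missing",
                pair_used = NA_character_))
  }
  list(value = NA_real_, status = "rejected_unstable",
       pair_used = NA_character_)
}

# Vectorized form of the oracle over a matrix of triplets, built on the
# scalar oracle (kept dumb on purpose).
oracle_select_matrix <- function(m) {
  out <- apply(m, 1, oracle_select)
  data.frame(value = vapply(out, `[[`, numeric(1), "value"),
             status = vapply(out, `[[`, character(1), "status"),
             pair_used = vapply(out, `[[`, character(1), "pair_used"),
             stringsAsFactors = FALSE)
}

# Grid-search calibration oracle: with M pinned, scan L on a fine grid,
# solve S exactly from the first non-median quantile, score the fit on the
# remaining quantiles.
oracle_calibrate_grid <- function(probs, quantiles, l_grid = seq(-3, 3,
                                                                 by = 1e-3)) {
  M <- quantiles[probs == 0.5]
  zq <- qnorm(probs)
  free <- probs != 0.5
  zf <- zq[free]; qf <- quantiles[free]
  best <- NULL
  for (l in l_grid) {
    if (abs(l) < 1e-8) next
    s <- ((qf[1] / M)^l - 1) / (l * zf[1])
    if (!is.finite(s) || s <= 0) next
    arg <- 1 + l * s * zf
    if (any(arg <= 0)) next
    fit <- M * arg^(1 / l)
    err <- sqrt(mean((fit - qf)^2))
    if (is.null(best) || err < best$err) best <- list(L = l, S = s,
                                                      err = err)
  }
  best
}

# Normal-equations polynomial oracle.
oracle_poly_beta <- function(z, y) {
  X <- cbind(1, z, z^2, z^3, z^4)
  solve(t(X) %*% X, t(X) %*% y)[, 1]
}

# Build a constant-parameter bccg_lms object directly (no fitting).
make_constant_lms <- function(L, M, S, zrange = c(-3, 3), sex = "boy",
                              outcome = "SBP") {
  hknots <- qnorm(c(0.05, 0.10, 0.25, 0.50, 0.75, 0.90, 0.95))
  grid_z <- sort(unique(c(seq(zrange[1], zrange[2], length.out = 201),
                          hknots)))
  structure(list(sex = sex, outcome = outcome,
                 grid = data.frame(zht = grid_z, L = L, M = M, S = S),
                 edf = c(L = 1, M = 1, S = 1), bic = NA_real_,
                 loglik = NA_real_, n_fit = 0L, zrange = zrange,
                 iterations = 0L, converged = TRUE, bic_table = NULL,
                 failures = character(0), data = NULL),
            class = "bccg_lms")
}

# Build a bp_poly object directly from coefficients.
make_poly <- function(beta, resid_sd, sex = "boy", outcome = "SBP") {
  structure(list(sex = sex, outcome = outcome, beta = beta,
                 coef_names = c("(Intercept)", "zht", "I(zht^2)",
                                "I(zht^3)", "I(zht^4)"),
                 pooled_sex = FALSE, resid_sd = resid_sd, n_fit = 0L,
                 r_squared = NA_real_, lm_fit = NULL),
            class = "bp_poly")
}

# Truth surfaces paired per sex for a full-cohort simulation.
preset_truth_pair <- function(presets, sex) {
  stats::setNames(list(presets[[sprintf("jecs-%ss-sbp", sex)]],
                       presets[[sprintf("jecs-%ss-dbp", sex)]]),
                  paste0(sex, c("_SBP", "_DBP")))
}
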