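#' Truth surface: generating L/M/S curves over the height Z-score
#'
#' A truth surface is the generating counterpart of a fitted LMS model: three
#' curves mapping the height Z-score (Zht) to the Box-Cox power L, median M
#' (mmHg) and coefficient of variation S of the BP distribution at that
#' height. Between knots the curves are interpolated with a monotone cubic
#' (Fritsch-Carlson) spline; beyond the outermost knots they are held flat,
#' since published tables give no information outside the tabulated height
#' range.
#'
#' @param sex "boy" or "girl".
#' @param outcome "SBP" or "DBP".
#' @param knots numeric vector of Zht knot locations (increasing).
#' @param L,M,S parameter values at the knots (\code{M > 0}, \code{S > 0}).
#' @return object of class \code{truth_surface} with callable components
#'   \code{L_fn}, \code{M_fn}, \code{S_fn}.
#' @export
truth_surface <- function(sex, outcome, knots, L, M, S) {
  stopifnot(length(knots) >= 2, !is.unsorted(knots, strictly = TRUE),
            length(L) == length(knots), length(M) == length(knots),
            length(S) == length(knots))
  if (any(M <= 0) || any(S <= 0)) {
    stop("truth surface requires M > 0 and S > 0 at every knot",
         call. = FALSE)
  }
  rng <- range(knots)
  mk_fn <- function(v) {
    if (length(unique(v)) == 1L) {
      val <- v[1]
      function(z) rep(val, length(z))
    } else {
      f <- stats::splinefun(knots, v, method = "monoH.FC")
      function(z) f(pmin(pmax(z, rng[1]), rng[2]))
    }
  }
  structure(list(sex = sex, outcome = outcome, knots = knots,
                 L = L, M = M, S = S,
                 L_fn = mk_fn(L), M_fn = mk_fn(M), S_fn = mk_fn(S)),
            class = "truth_surface")
}

#' @export
print.truth_surface <- function(x, ...) {
  cat("Truth surface:", x$sex, x$outcome, "\n")
  cat("  Zht knots:", paste(round(x$knots, 4), collapse = " "), "\n")
  cat("  M at knots:", paste(round(x$M, 2), collapse = " "), "mmHg\n")
  cat("  S range:", paste(round(range(x$S), 4), collapse = " - "),
      " L range:", paste(round(range(x$L), 2), collapse = " - "), "\n")
  invisible(x)
}

#' Evaluate a truth-surface centile
#'
#' @param surface a [truth_surface()].
#' @param p BP probability in (0, 1).
#' @param zht height Z-score(s).
#' @return BP centile values in mmHg.
#' @export
truth_centile <- function(surface, p, zht) {
  stopifnot(inherits(surface, "truth_surface"))
  bccg_centile(p, surface$L_fn(zht), surface$M_fn(zht), surface$S_fn(zht))
}

#' Published 2-year-old reference values (JECS auscultatory study)
#'
#' The published sex-stratified reference grid for 2-year-old Japanese
#' children measured by auscultation: integer BP values at BP percentiles
#' {50, 90, 95, 99} and height percentiles {5, 10, 25, 50, 75, 90, 95}.
#' Used to calibrate the synthetic-data truth surfaces.
#'
#' @return data frame with columns \code{sex}, \code{outcome},
#'   \code{bp_percentile}, \code{h05} ... \code{h95}.
#' @export
jecs_reference_values <- function() {
  path <- system.file("extdata", "jecs_reference_2y.csv",
                      package = "bpcentile", mustWork = TRUE)
  utils::read.csv(path, stringsAsFactors = FALSE)
}

#' Calibrated truth-surface presets
#'
#' Builds the four truth surfaces ("jecs-boys-sbp", "jecs-girls-sbp",
#' "jecs-boys-dbp", "jecs-girls-dbp") by quantile-matching: at each of the
#' seven tabulated height percentiles, [calibrate_bccg_from_quantiles()]
#' inverts the published column of four BP centiles into a BCCG
#' \code{(L, M, S)} knot (M pinned to the printed median; L and S by least
#' squares constrained to reproduce every printed cell within its rounding
#' half-width). Knots sit at the normal quantiles of the height
#' percentiles.
#'
#' @return named list of [truth_surface()] objects.
#' @export
jecs_presets <- function() {
  ref <- jecs_reference_values()
  hp <- c(0.05, 0.10, 0.25, 0.50, 0.75, 0.90, 0.95)
  hcols <- c("h05", "h10", "h25", "h50", "h75", "h90", "h95")
  knots <- stats::qnorm(hp)
  out <- list()
  for (sx in c("boy", "girl")) {
    for (oc in c("SBP", "DBP")) {
      block <- ref[ref$sex == sx & ref$outcome == oc, ]
      probs <- block$bp_percentile / 100
      L <- M <- S <- numeric(length(knots))
      for (k in seq_along(knots)) {
        q <- block[[hcols[k]]]
        cal <- tryCatch(
          calibrate_bccg_from_quantiles(probs, q),
          error = function(e) {
            stop("preset calibration failed at knot Zht = ",
                 round(knots[k], 4), " (", sx, " ", oc, "): ",
                 conditionMessage(e), call. = FALSE)
          })
        L[k] <- cal$L; M[k] <- cal$M; S[k] <- cal$S
      }
      name <- sprintf("jecs-%ss-%s", sx, tolower(oc))
      out[[name]] <- truth_surface(sx, oc, knots, L, M, S)
    }
  }
  out
}

#' Simulation configuration
#'
#' Bundles every knob of the synthetic-cohort generator. All nuisance rates
#' are probabilities of mutually exclusive planted categories (their sum
#' must not exceed 1); the remainder of the cohort is "clean". Defaults
#' describe a pure-sampling cohort (all nuisance rates zero) matching the
#' published cohort's anthropometry: height 84.0 (SD 2.9) cm, 49.7% boys,
#' ages 24-30 months.
#'
#' @param n_children number of children to simulate.
#' @param pct_boys proportion of boys; the boy count is
#'   \code{round(n_children * pct_boys)}.
#' @param seed integer seed; fixed seed gives bit-identical output.
#' @param truth named list of [truth_surface()] objects keyed
#'   \code{"<sex>_<OUTCOME>"} (e.g. \code{"boy_SBP"}), or the string
#'   \code{"jecs"} to use [jecs_presets()].
#' @param standard a \code{growth_standard}; default the bundled synthetic
#'   stand-in.
#' @param height_mean_cm,height_sd_cm generating height distribution.
#' @param age_months_range integer range of ages at measurement.
#' @param missing_second_rate rate of a missed second reading (recoverable
#'   via the first/third fallback).
#' @param unstable_rate rate of planted unstable triplets (consecutive
#'   differences forced to at least 5 mmHg).
#' @param crying_rate rate of unstable measurement conditions (crying,
#'   sleeping, fever).
#' @param chronic_rate rate of chronic disease.
#' @param dbp_zero_rate rate of an unreadable diastolic (a 0 mmHg reading
#'   placed so the diastolic channel is rejected).
#' @param underage_rate rate of children under 24 months.
#' @param height_outlier_rate rate of deliberate height outliers
#'   (placed beyond 5 SD of the standard).
#' @param within_child_noise_sd SD (mmHg) of independent within-child
#'   reading noise. A free parameter of the generator: the source study
#'   does not report within-child reading variance.
#' @param reading_step readings are rounded to this step (mmHg);
#'   auscultatory convention reads to the nearest 2 mmHg.
#' @param sbp_dbp_rho Gaussian-copula correlation between a child's true
#'   SBP and DBP.
#' @return object of class \code{sim_config}.
#' @export
sim_config <- function(n_children = 3361,
                       pct_boys = 0.497,
                       seed = 1L,
                       truth = "jecs",
                       standard = synthetic_growth_standard(),
                       height_mean_cm = 84.0,
                       height_sd_cm = 2.9,
                       age_months_range = c(24L, 30L),
                       missing_second_rate = 0,
                       unstable_rate = 0,
                       crying_rate = 0,
                       chronic_rate = 0,
                       dbp_zero_rate = 0,
                       underage_rate = 0,
                       height_outlier_rate = 0,
                       within_child_noise_sd = 2,
                       reading_step = 2,
                       sbp_dbp_rho = 0.5) {
  rates <- c(missing_second = missing_second_rate,
             unstable = unstable_rate, crying = crying_rate,
             chronic = chronic_rate, dbp_zero = dbp_zero_rate,
             underage = underage_rate, height_outlier = height_outlier_rate)
  if (any(rates < 0) || any(rates > 1) || sum(rates) > 1) {
    stop("nuisance rates must lie in [0,1] and sum to at most 1",
         call. = FALSE)
  }
  if (n_children < 1) stop("n_children must be >= 1", call. = FALSE)
  if (pct_boys < 0 || pct_boys > 1) {
    stop("pct_boys must lie in [0, 1]", call. = FALSE)
  }
  if (within_child_noise_sd < 0 || reading_step < 0) {
    stop("noise SD and reading step must be non-negative", call. = FALSE)
  }
  structure(list(n_children = as.integer(n_children), pct_boys = pct_boys,
                 seed = as.integer(seed), truth = truth,
                 standard = standard,
                 height_mean_cm = height_mean_cm,
                 height_sd_cm = height_sd_cm,
                 age_months_range = as.integer(age_months_range),
                 rates = rates,
                 within_child_noise_sd = within_child_noise_sd,
                 reading_step = reading_step,
                 sbp_dbp_rho = sbp_dbp_rho),
            class = "sim_config")
}

#' Fig-1-style nuisance rates
#'
#' A documented rate set whose magnitudes emulate the published participant
#' flowchart (chronic disease rare; missing/condition problems the largest
#' category; unstable triplets next; a moderate underage fraction). Used by
#' flow-accounting demonstrations and tests; the pure-sampling defaults of
#' [sim_config()] leave them at zero.
#'
#' @return named numeric vector of rates.
#' @export
jecs_rates <- function() {
  c(missing_second = 0.03, unstable = 0.07, crying = 0.12,
    chronic = 0.006, dbp_zero = 0.03, underage = 0.05,
    height_outlier = 0.002)
}

resolve_truth <- function(truth) {
  if (identical(truth, "jecs")) {
    p <- jecs_presets()
    list(boy_SBP = p[["jecs-boys-sbp"]], girl_SBP = p[["jecs-girls-sbp"]],
         boy_DBP = p[["jecs-boys-dbp"]], girl_DBP = p[["jecs-girls-dbp"]])
  } else {
    stopifnot(is.list(truth), all(vapply(truth, inherits, logical(1),
                                         "truth_surface")))
    truth
  }
}

round_to_step <- function(x, step) {
  if (step <= 0) return(x)
  floor(x / step + 0.5) * step
}

#' Generate a synthetic cohort
#'
#' Simulates one child per row: sex, age, height (normal, truncated to 5 SD
#' of the growth standard), covariates, and a triplicate of (SBP, DBP)
#' readings. True BP is drawn from the truth surface's BCCG distribution at
#' the child's height Z-score (SBP and DBP coupled by a Gaussian copula);
#' each reading adds independent Gaussian noise and is rounded to the
#' configured step. Nuisance categories (chronic disease, unstable
#' condition, planted unstable triplets, a 0 mmHg diastolic, missing second
#' reading, underage, height outliers) are planted at the configured rates,
#' mutually exclusively, and recorded in \code{planted_category} so that
#' downstream flow accounting can be checked against the generator's
#' bookkeeping.
#'
#' @param config a [sim_config()].
#' @return data frame; one row per child. Readings columns are
#'   \code{sbp1..sbp3}, \code{dbp1..dbp3} with \code{NA} for a missed
#'   reading.
#' @export
generate_cohort <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  truth <- resolve_truth(config$truth)
  n <- config$n_children
  set.seed(config$seed)

  n_boys <- round(n * config$pct_boys)
  sex <- c(rep("boy", n_boys), rep("girl", n - n_boys))
  sex <- sample(sex)  # shuffle so ids are not sex-ordered

  cats <- c(names(config$rates), "clean")
  probs <- c(config$rates, clean = 1 - sum(config$rates))
  planted <- sample(cats, n, replace = TRUE, prob = probs)

  age_lo <- config$age_months_range[1]; age_hi <- config$age_months_range[2]
  age <- sample(age_lo:age_hi, n, replace = TRUE)
  age[planted == "underage"] <- sample(20:23, sum(planted == "underage"),
                                       replace = TRUE)

  height <- stats::rnorm(n, config$height_mean_cm, config$height_sd_cm)
  # truncate to +/- 5 SD of the standard by resampling
  repeat {
    z <- height_zscore(height, sex, age, config$standard)$zht
    bad <- abs(z) > 5
    if (!any(bad)) break
    height[bad] <- stats::rnorm(sum(bad), config$height_mean_cm,
                                config$height_sd_cm)
  }
  out_idx <- planted == "height_outlier"
  if (any(out_idx)) {
    sgn <- sample(c(-1, 1), sum(out_idx), replace = TRUE)
    height[out_idx] <- height_centile(stats::pnorm(sgn * 5.5),
                                      sex[out_idx], age[out_idx],
                                      config$standard)
  }
  zht <- height_zscore(height, sex, age, config$standard)$zht

  # true BP via Gaussian copula over the sex-specific truth surfaces
  rho <- config$sbp_dbp_rho
  z1 <- stats::rnorm(n); z2 <- rho * z1 + sqrt(1 - rho^2) * stats::rnorm(n)
  # BCCG support requires 1 + L*S*z > 0; draws this extreme are vanishingly
  # rare at cohort scale and are clipped
  z1 <- pmin(pmax(z1, -3.9), 3.9); z2 <- pmin(pmax(z2, -3.9), 3.9)
  sbp_true <- dbp_true <- numeric(n)
  for (sx in c("boy", "girl")) {
    i <- sex == sx
    if (!any(i)) next
    ts <- truth[[paste0(sx, "_SBP")]]; td <- truth[[paste0(sx, "_DBP")]]
    if (is.null(ts) || is.null(td)) {
      stop("truth surfaces must cover both outcomes for sex '", sx, "'",
           call. = FALSE)
    }
    draw <- function(zc, surf) {
      l <- surf$L_fn(zht[i]); m <- surf$M_fn(zht[i]); s <- surf$S_fn(zht[i])
      lim <- 0.999 / pmax(abs(l) * s, 1e-8)  # BCCG support: |L*S*z| < 1
      bccg_centile(stats::pnorm(pmin(pmax(zc, -lim), lim)), l, m, s)
    }
    sbp_true[i] <- draw(z1[i], ts)
    dbp_true[i] <- draw(z2[i], td)
  }

  noise <- config$within_child_noise_sd
  step <- config$reading_step
  smat <- matrix(stats::rnorm(3 * n, 0, noise), n, 3) + sbp_true
  dmat <- matrix(stats::rnorm(3 * n, 0, noise), n, 3) + dbp_true
  smat <- round_to_step(smat, step); dmat <- round_to_step(dmat, step)
  dmat <- pmax(dmat, 2)
  dmat <- pmin(dmat, smat - 2)  # physical constraint SBP > DBP

  # planted unstable triplets: consecutive differences forced to >= 5
  un <- planted == "unstable"
  if (any(un)) {
    smat[un, ] <- round_to_step(sbp_true[un], step) +
      matrix(c(-8, 0, 8), sum(un), 3, byrow = TRUE)
    dmat[un, ] <- round_to_step(dbp_true[un], step) +
      matrix(c(-8, 0, 8), sum(un), 3, byrow = TRUE)
  }
  ms <- planted == "missing_second"
  smat[ms, 2] <- NA; dmat[ms, 2] <- NA
  dz <- planted == "dbp_zero"
  dmat[dz, 2] <- 0  # zero second reading: no pair can avoid implication

  condition_flag <- rep("stable", n)
  cr <- planted == "crying"
  condition_flag[cr] <- sample(c("crying", "sleeping", "fever"),
                               sum(cr), replace = TRUE)
  posture <- sample(c("sitting", "supine"), n, replace = TRUE,
                    prob = c(0.997, 0.003))

  cohort <- data.frame(
    child_id = sprintf("C%05d", seq_len(n)),
    sex = sex,
    age_months = age,
    height_cm = round(height, 1),
    weight_kg = round(pmax(stats::rnorm(n, 11.5, 1.2), 5), 1),
    season = sample(c("spring", "summer", "autumn", "winter"), n,
                    replace = TRUE, prob = c(0.27, 0.27, 0.27, 0.19)),
    gestational_weeks = pmin(pmax(round(stats::rnorm(n, 39, 1.5)), 28), 42),
    birth_weight_g = round(pmax(stats::rnorm(n, 3000, 400), 800)),
    chronic_disease = planted == "chronic",
    posture = posture,
    condition_flag = condition_flag,
    sbp1 = smat[, 1], sbp2 = smat[, 2], sbp3 = smat[, 3],
    dbp1 = dmat[, 1], dbp2 = dmat[, 2], dbp3 = dmat[, 3],
    planted_category = planted,
    stringsAsFactors = FALSE
  )
  cohort
}

#' Expected flow accounting implied by the generator's bookkeeping
#'
#' Maps each planted nuisance category to the exclusion bucket it forces,
#' per BP channel. Exact only for cohorts generated with zero reading noise
#' (noise can additionally trip the unstable-BP rule on otherwise clean
#' children).
#'
#' @param cohort a generated cohort carrying \code{planted_category}.
#' @return list with \code{sbp} and \code{dbp} named count vectors.
#' @export
planted_flow <- function(cohort) {
  stopifnot("planted_category" %in% names(cohort))
  pc <- cohort$planted_category
  buckets <- function(channel) {
    b <- c(total_in = length(pc),
           excluded_chronic = sum(pc == "chronic"),
           excluded_missing_or_condition =
             sum(pc == "crying") +
             if (channel == "dbp") sum(pc == "dbp_zero") else 0L,
           excluded_unstable_bp = sum(pc == "unstable"),
           excluded_covariates_or_height_outlier =
             sum(pc == "height_outlier"),
           excluded_underage = sum(pc == "underage"))
    b["analyzed"] <- b["total_in"] - sum(b[-1])
    b
  }
  list(sbp = buckets("sbp"), dbp = buckets("dbp"))
}

#' Write / read a cohort CSV
#'
#' Readings and covariates are written as plain CSV with empty strings for
#' missing values; [read_cohort()] restores the schema.
#'
#' @param cohort cohort data frame.
#' @param path file path.
#' @return \code{path} (write) or the cohort data frame (read).
#' @export
write_cohort <- function(cohort, path) {
  utils::write.csv(cohort, path, row.names = FALSE, na = "")
  invisible(path)
}

#' @rdname write_cohort
#' @export
read_cohort <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE,
                        na.strings = c("", "NA"))
  df$chronic_disease <- as.logical(df$chronic_disease)
  df
}
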