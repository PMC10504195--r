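#' Default equivalent-degrees-of-freedom grid
#'
#' The smoothness search space for [fit_lms()]: edf 1 is a constant curve,
#' 2 is linear, larger values are smoothing splines of that effective
#' dimension. The default follows common LMS practice for a single-age
#' reference: the median gets the most flexibility, the coefficient of
#' variation less, and the Box-Cox power is constant or linear.
#'
#' @return data frame with columns \code{L}, \code{M}, \code{S}.
#' @export
default_edf_grid <- function() {
  expand.grid(L = c(1, 2), M = c(2, 3, 4, 5), S = c(1, 2, 3))
}

# Weighted smoother at fixed equivalent degrees of freedom.
# Returns a list(fitted, predict) where predict evaluates the smooth at
# arbitrary x. edf <= 1: weighted constant; edf == 2: weighted linear;
# otherwise cubic smoothing spline with df = edf.
wsmooth <- function(x, t, w, edf) {
  if (edf <= 1) {
    mu <- stats::weighted.mean(t, w)
    list(fitted = rep(mu, length(x)),
         predict = function(z) rep(mu, length(z)))
  } else if (edf == 2) {
    fit <- stats::lm.wfit(cbind(1, x), t, w)
    b <- fit$coefficients
    list(fitted = b[1] + b[2] * x,
         predict = function(z) b[1] + b[2] * z)
  } else {
    fit <- stats::smooth.spline(x, t, w = w, df = edf, cv = FALSE,
                                keep.data = FALSE)
    list(fitted = stats::predict(fit, x)$y,
         predict = function(z) stats::predict(fit, z)$y)
  }
}

bccg_loglik <- function(y, l, m, s) {
  w <- bccg_zscore(y, l, m, s)
  sum((l - 1) * log(y) - l * log(m) - log(s) - 0.5 * w^2 -
        0.5 * log(2 * pi))
}

# One penalized-likelihood backfit at a fixed edf triple.
# Outer iteration: Fisher-scoring update of each curve in turn (log link
# for M and S, identity for L), each smoothed at its edf; step-halving on
# a likelihood decrease. Expected-information weights follow Cole & Green:
# i_logM = (1 + 2 L^2 S^2)/S^2, i_logS = 2, i_L = 7 S^2 / 4.
lms_backfit <- function(z, y, edf, init = NULL, max_iter = 200,
                        tol = 1e-6) {
  n <- length(y)
  if (is.null(init)) {
    m0 <- wsmooth(z, y, rep(1, n), max(edf[["M"]], 2))$fitted
    m0 <- pmax(m0, min(y) / 2)
    s0 <- rep(stats::sd(y) / mean(y), n)
    l0 <- rep(1, n)
  } else {
    l0 <- init$l; m0 <- init$m; s0 <- init$s
  }
  l <- l0; m <- m0; s <- s0
  sm_l <- sm_m <- sm_s <- NULL
  ll_old <- bccg_loglik(y, l, m, s)
  converged <- FALSE
  iter <- 0
  for (iter in seq_len(max_iter)) {
    l_prev <- l; m_prev <- m; s_prev <- s
    sm_l_prev <- sm_l; sm_m_prev <- sm_m; sm_s_prev <- sm_s

    # M update (log link)
    w <- bccg_zscore(y, l, m, s)
    u <- -l + w * (1 + l * s * w) / s
    W <- 1 / s^2 + 2 * l^2
    sm_m <- wsmooth(z, log(m) + u / W, W, edf[["M"]])
    m_new <- exp(sm_m$fitted)

    # S update (log link)
    w <- bccg_zscore(y, l, m_new, s)
    u <- w^2 - 1
    sm_s <- wsmooth(z, log(s) + u / 2, rep(2, n), edf[["S"]])
    s_new <- exp(sm_s$fitted)
    s_new <- pmin(pmax(s_new, 1e-4), 2)

    # L update (identity link)
    w <- bccg_zscore(y, l, m_new, s_new)
    x <- log(y / m_new)
    dwdl <- ifelse(abs(l) > 1e-5,
                   x * (1 + l * s_new * w) / (l * s_new) - w / l,
                   x^2 / (2 * s_new))
    u <- x - w * dwdl
    W <- pmax(7 * s_new^2 / 4, 1e-4)
    sm_l <- wsmooth(z, l + u / W, W, edf[["L"]])
    l_new <- pmin(pmax(sm_l$fitted, -5), 5)

    ll_new <- tryCatch(bccg_loglik(y, l_new, m_new, s_new),
                       error = function(e) -Inf)
    # step-halving toward the previous iterate on a likelihood decrease
    alpha <- 1
    while (ll_new < ll_old - 1e-10 && alpha > 1 / 64) {
      alpha <- alpha / 2
      l_new <- l_prev + alpha * (pmin(pmax(sm_l$fitted, -5), 5) - l_prev)
      m_new <- exp(log(m_prev) + alpha * (sm_m$fitted - log(m_prev)))
      s_new <- exp(log(s_prev) + alpha * (log(pmin(pmax(exp(sm_s$fitted),
                   1e-4), 2)) - log(s_prev)))
      ll_new <- tryCatch(bccg_loglik(y, l_new, m_new, s_new),
                         error = function(e) -Inf)
    }
    if (!is.finite(ll_new) || ll_new < ll_old - 1e-10) {
      # no improving step: keep the previous iterate and stop
      l <- l_prev; m <- m_prev; s <- s_prev
      sm_l <- sm_l_prev; sm_m <- sm_m_prev; sm_s <- sm_s_prev
      converged <- TRUE
      break
    }
    l <- l_new; m <- m_new; s <- s_new
    if (abs(ll_new - ll_old) / (abs(ll_new) + 1) < tol) {
      ll_old <- ll_new
      converged <- TRUE
      break
    }
    ll_old <- ll_new
  }
  # prediction closures; sm_* may be NULL when no update step ever ran
  pred_or_const <- function(sm, vals, log_scale = FALSE) {
    if (is.null(sm)) {
      v <- if (log_scale) log(mean(vals)) else mean(vals)
      function(zz) {
        out <- rep(v, length(zz))
        if (log_scale) exp(out) else out
      }
    } else if (log_scale) {
      function(zz) exp(sm$predict(zz))
    } else {
      function(zz) sm$predict(zz)
    }
  }
  list(l = l, m = m, s = s,
       loglik = ll_old, iter = iter, converged = converged,
       L_fn = function(zz) pmin(pmax(pred_or_const(sm_l, l)(zz), -5), 5),
       M_fn = pred_or_const(sm_m, m, log_scale = TRUE),
       S_fn = function(zz) pmin(pmax(pred_or_const(sm_s, s,
                                log_scale = TRUE)(zz), 1e-4), 2))
}

#' Fit an LMS (BCCG) centile model over the height Z-score
#'
#' Fits smooth L (Box-Cox power), M (median) and S (coefficient of
#' variation) curves of blood pressure over the height Z-score by
#' penalized maximum likelihood, in the Cole-Green backfitting scheme:
#' each curve is updated by a Fisher-scoring step and smoothed at a fixed
#' equivalent degrees of freedom (edf) with a cubic smoothing spline. Every
#' edf triple in \code{edf_grid} is fitted (warm-started from the previous
#' triple) and the model minimizing
#' \code{BIC = -2 loglik + log(n) * (edf_L + edf_M + edf_S)} is returned.
#'
#' @param data data frame with columns \code{zht} and \code{bp} (mmHg,
#'   positive) for a single sex and outcome.
#' @param edf_grid data frame of edf triples with columns \code{L},
#'   \code{M}, \code{S}; see [default_edf_grid()].
#' @param sex,outcome labels stored on the fit.
#' @param n_min minimum number of observations (default 50).
#' @param max_iter,tol backfitting iteration cap and relative
#'   log-likelihood convergence tolerance.
#' @return object of class \code{bccg_lms}: fitted curve values on a dense
#'   Zht grid (\code{grid}), the selected \code{edf}, \code{bic},
#'   \code{loglik}, \code{n_fit}, the fitted range \code{zrange}, and the
#'   BIC of every grid point (\code{bic_table}).
#' @export
fit_lms <- function(data, edf_grid = default_edf_grid(),
                    sex = NA_character_, outcome = NA_character_,
                    n_min = 50, max_iter = 200, tol = 1e-6) {
  stopifnot(all(c("zht", "bp") %in% names(data)))
  data <- data[is.finite(data$zht) & is.finite(data$bp), ]
  z <- data$zht; y <- data$bp
  if (length(y) < n_min) {
    stop("need at least ", n_min, " observations to fit an LMS model",
         call. = FALSE)
  }
  if (any(y <= 0)) stop("BP values must be positive", call. = FALSE)
  edf_grid <- as.data.frame(edf_grid)
  if (!nrow(edf_grid) || !all(c("L", "M", "S") %in% names(edf_grid))) {
    stop("edf_grid must be a non-empty data frame with columns L, M, S",
         call. = FALSE)
  }
  max_df <- length(unique(z))
  if (any(edf_grid$M > max_df) || any(edf_grid$S > max_df)) {
    stop("edf exceeds the number of distinct Zht values", call. = FALSE)
  }

  n <- length(y)
  fits <- vector("list", nrow(edf_grid))
  bics <- rep(NA_real_, nrow(edf_grid))
  init <- NULL
  failures <- character(0)
  for (i in seq_len(nrow(edf_grid))) {
    edf <- c(L = edf_grid$L[i], M = edf_grid$M[i], S = edf_grid$S[i])
    fit <- tryCatch(
      lms_backfit(z, y, edf, init = init, max_iter = max_iter, tol = tol),
      error = function(e) e)
    if (inherits(fit, "error")) {
      failures <- c(failures, sprintf("edf (%g,%g,%g): %s", edf[1],
                                      edf[2], edf[3],
                                      conditionMessage(fit)))
      next
    }
    if (!fit$converged) {
      failures <- c(failures,
                    sprintf("edf (%g,%g,%g): no convergence in %d iters (last loglik %.3f)",
                            edf[1], edf[2], edf[3], fit$iter, fit$loglik))
      next
    }
    fits[[i]] <- fit
    bics[i] <- -2 * fit$loglik + log(n) * sum(edf)
    init <- list(l = fit$l, m = fit$m, s = fit$s)
  }
  if (all(is.na(bics))) {
    stop("LMS fitting failed for every edf triple:\n  ",
         paste(failures, collapse = "\n  "), call. = FALSE)
  }
  best <- which.min(bics)
  fit <- fits[[best]]
  edf <- c(L = edf_grid$L[best], M = edf_grid$M[best],
           S = edf_grid$S[best])

  zrange <- range(z)
  hknots <- stats::qnorm(c(0.05, 0.10, 0.25, 0.50, 0.75, 0.90, 0.95))
  grid_z <- sort(unique(c(seq(zrange[1], zrange[2], length.out = 201),
                          hknots[hknots >= zrange[1] &
                                 hknots <= zrange[2]])))
  grid <- data.frame(zht = grid_z,
                     L = fit$L_fn(grid_z),
                     M = fit$M_fn(grid_z),
                     S = fit$S_fn(grid_z))

  bic_table <- cbind(edf_grid, bic = bics)
  structure(list(sex = sex, outcome = outcome,
                 grid = grid, edf = edf,
                 bic = bics[best], loglik = fit$loglik,
                 n_fit = n, zrange = zrange,
                 iterations = fit$iter, converged = fit$converged,
                 bic_table = bic_table, failures = failures,
                 data = data.frame(zht = z, bp = y)),
            class = "bccg_lms")
}

# Evaluate the fitted curves at arbitrary Zht by linear interpolation of
# the dense fitted grid (grid spacing ~0.03 SD; interpolation error is
# negligible against sampling error).
lms_params <- function(model, zht, allow_extrapolation = FALSE) {
  stopifnot(inherits(model, "bccg_lms"))
  out_of_range <- zht < model$zrange[1] | zht > model$zrange[2]
  if (any(out_of_range) && !allow_extrapolation) {
    stop("Zht outside the fitted range [",
         round(model$zrange[1], 3), ", ", round(model$zrange[2], 3),
         "]; set allow_extrapolation = TRUE to extend the curves flat",
         call. = FALSE)
  }
  zz <- pmin(pmax(zht, model$zrange[1]), model$zrange[2])
  g <- model$grid
  list(L = stats::approx(g$zht, g$L, xout = zz)$y,
       M = stats::approx(g$zht, g$M, xout = zz)$y,
       S = stats::approx(g$zht, g$S, xout = zz)$y)
}

#' Centile from a fitted LMS model
#'
#' @param model a \code{bccg_lms} fit.
#' @param zht height Z-score(s); must lie in the fitted range unless
#'   \code{allow_extrapolation} (flat extension) is set.
#' @param p BP probability in (0, 1).
#' @param allow_extrapolation logical.
#' @return BP centiles in mmHg.
#' @export
lms_centile <- function(model, zht, p, allow_extrapolation = FALSE) {
  par <- lms_params(model, zht, allow_extrapolation)
  n <- max(length(zht), length(p))
  bccg_centile(rep_len(p, n), rep_len(par$L, n), rep_len(par$M, n),
               rep_len(par$S, n))
}

#' Z-score residuals of a fitted LMS model
#'
#' Transforms each observation through the fitted curves at its own Zht;
#' under a correct model the residuals are standard normal. Observations
#' outside the fitted Zht range are excluded and counted.
#'
#' @param model a \code{bccg_lms} fit.
#' @param data optional data frame (\code{zht}, \code{bp}); defaults to the
#'   training data stored on the model.
#' @return list with \code{z} (residuals) and \code{n_excluded}.
#' @export
z_residuals <- function(model, data = NULL) {
  stopifnot(inherits(model, "bccg_lms"))
  if (is.null(data)) data <- model$data
  inside <- data$zht >= model$zrange[1] & data$zht <= model$zrange[2]
  par <- lms_params(model, data$zht[inside])
  list(z = bccg_zscore(data$bp[inside], par$L, par$M, par$S),
       n_excluded = sum(!inside))
}

#' @export
residuals.bccg_lms <- function(object, ...) {
  z_residuals(object)$z
}

#' @export
predict.bccg_lms <- function(object, zht, p = 0.5,
                             allow_extrapolation = FALSE, ...) {
  lms_centile(object, zht, p, allow_extrapolation)
}

#' @export
coef.bccg_lms <- function(object, ...) {
  object$grid
}

#' @export
print.bccg_lms <- function(x, ...) {
  cat("LMS (BCCG) centile model", if (!is.na(x$sex))
    paste0("(", x$sex, " ", x$outcome, ")"), "\n")
  cat("  n =", x$n_fit, " Zht range [",
      paste(round(x$zrange, 2), collapse = ", "), "]\n")
  cat("  selected edf (L, M, S):", paste(x$edf, collapse = ", "),
      " BIC:", round(x$bic, 1), "\n")
  p <- lms_params(x, 0, allow_extrapolation = TRUE)
  cat("  at Zht = 0: L =", round(p$L, 3), " M =", round(p$M, 2),
      " S =", round(p$S, 4), "\n")
  invisible(x)
}

#' @export
summary.bccg_lms <- function(object, ...) {
  r <- z_residuals(object)$z
  structure(list(model = object,
                 resid_mean = mean(r), resid_sd = stats::sd(r),
                 bic_table = object$bic_table),
            class = "summary.bccg_lms")
}

#' @export
print.summary.bccg_lms <- function(x, ...) {
  print(x$model)
  cat("  z-residuals: mean", round(x$resid_mean, 4), " SD",
      round(x$resid_sd, 4), "\n")
  cat("  BIC over the edf grid:\n")
  print(x$bic_table, row.names = FALSE)
  invisible(x)
}

#' @export
plot.bccg_lms <- function(x, p = c(0.05, 0.5, 0.95), ...) {
  graphics::plot(x$data$zht, x$data$bp, pch = 16, cex = 0.3,
                 col = "grey60", xlab = "Height Z-score",
                 ylab = paste(x$outcome, "(mmHg)"),
                 main = paste("LMS centiles", x$sex, x$outcome), ...)
  zz <- x$grid$zht
  for (pp in p) {
    graphics::lines(zz, lms_centile(x, zz, pp), lwd = 2)
  }
  invisible(x)
}

#' @export
simulate.bccg_lms <- function(object, nsim = 1, seed = NULL, zht = NULL,
                              ...) {
  if (!is.null(seed)) set.seed(seed)
  if (is.null(zht)) zht <- object$data$zht
  par <- lms_params(object, zht)
  replicate(nsim,
            bccg_centile(stats::runif(length(zht),
                                      stats::pnorm(-3.9),
                                      stats::pnorm(3.9)),
                         par$L, par$M, par$S),
            simplify = nsim > 1)
}

#' Export / import a fitted LMS model
#'
#' Writes the fitted curve grid as a full-precision CSV (the role of a
#' published coefficient table) plus a JSON sidecar with edf, BIC and
#' convergence metadata. A model rebuilt from the export evaluates
#' identically.
#'
#' @param model a \code{bccg_lms} fit.
#' @param path base path; \code{<path>.csv} and \code{<path>.json} are
#'   written.
#' @return \code{path} invisibly (write); a \code{bccg_lms} (read).
#' @export
write_lms_model <- function(model, path) {
  stopifnot(inherits(model, "bccg_lms"))
  write_full_precision_csv(model$grid, paste0(path, ".csv"))
  meta <- list(sex = model$sex, outcome = model$outcome,
               edf = as.list(model$edf), bic = model$bic,
               loglik = model$loglik, n_fit = model$n_fit,
               zrange = model$zrange, iterations = model$iterations,
               converged = model$converged)
  jsonlite::write_json(meta, paste0(path, ".json"), auto_unbox = TRUE,
                       digits = NA)
  invisible(path)
}

#' @rdname write_lms_model
#' @export
read_lms_model <- function(path) {
  grid <- utils::read.csv(paste0(path, ".csv"))
  meta <- jsonlite::read_json(paste0(path, ".json"),
                              simplifyVector = TRUE)
  edf <- unlist(meta$edf)
  edf <- stats::setNames(as.numeric(edf), names(edf))
  structure(list(sex = meta$sex, outcome = meta$outcome, grid = grid,
                 edf = edf, bic = meta$bic,
                 loglik = meta$loglik, n_fit = meta$n_fit,
                 zrange = range(grid$zht), iterations = meta$iterations,
                 converged = meta$converged, bic_table = NULL,
                 failures = character(0), data = NULL),
            class = "bccg_lms")
}
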