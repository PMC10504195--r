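#' Box-Cox-Cole-Green (BCCG) z-score
#'
#' Transforms a positive measurement to its standard-normal equivalent under
#' the three-parameter BCCG distribution used by the LMS method: \code{L} is
#' the Box-Cox power (skewness), \code{M} the median, and \code{S} the
#' coefficient of variation.
#'
#' For \code{L != 0}, \code{z = ((y/M)^L - 1) / (L * S)}; in the limit
#' \code{L -> 0}, \code{z = log(y/M) / S}. Inputs are recycled to a common
#' length.
#'
#' @param y positive measurement (e.g. blood pressure in mmHg).
#' @param L Box-Cox power (dimensionless).
#' @param M median, same units as \code{y}; must be positive.
#' @param S coefficient of variation; must be positive.
#' @return numeric vector of z-scores.
#' @seealso [bccg_centile()] for the inverse.
#' @examples
#' bccg_zscore(98.1, L = 1, M = 90, S = 0.09)  # exactly 1
#' @export
bccg_zscore <- function(y, L, M, S) {
  n <- max(length(y), length(L), length(M), length(S))
  y <- rep_len(y, n); L <- rep_len(L, n)
  M <- rep_len(M, n); S <- rep_len(S, n)
  if (any(!is.finite(y)) || any(y <= 0)) {
    stop("bccg_zscore: 'y' must be positive and finite", call. = FALSE)
  }
  if (any(M <= 0) || any(S <= 0)) {
    stop("bccg_zscore: 'M' and 'S' must be positive", call. = FALSE)
  }
  z <- numeric(n)
  zero <- abs(L) < 1e-8
  if (any(zero)) z[zero] <- log(y[zero] / M[zero]) / S[zero]
  if (any(!zero)) {
    i <- !zero
    z[i] <- ((y[i] / M[i])^L[i] - 1) / (L[i] * S[i])
  }
  z
}

#' BCCG centile (quantile) function
#'
#' Returns the value below which a proportion \code{p} of a BCCG population
#' falls. This is the closed form behind every cell of an LMS reference
#' table: \code{M * (1 + L*S*qnorm(p))^(1/L)} for \code{L != 0} and
#' \code{M * exp(S * qnorm(p))} for \code{L = 0}.
#'
#' @param p probability in (0, 1).
#' @inheritParams bccg_zscore
#' @return numeric vector of quantiles, same units as \code{M}.
#' @examples
#' bccg_centile(0.5, L = -1, M = 91, S = 0.09)   # median property: 91
#' bccg_centile(0.8413, L = 1, M = 90, S = 0.09) # normal case: 98.1
#' @export
bccg_centile <- function(p, L, M, S) {
  n <- max(length(p), length(L), length(M), length(S))
  p <- rep_len(p, n); L <- rep_len(L, n)
  M <- rep_len(M, n); S <- rep_len(S, n)
  if (any(p <= 0) || any(p >= 1)) {
    stop("bccg_centile: 'p' must lie strictly in (0, 1)", call. = FALSE)
  }
  if (any(M <= 0) || any(S <= 0)) {
    stop("bccg_centile: 'M' and 'S' must be positive", call. = FALSE)
  }
  z <- stats::qnorm(p)
  out <- numeric(n)
  zero <- abs(L) < 1e-8
  if (any(zero)) out[zero] <- M[zero] * exp(S[zero] * z[zero])
  if (any(!zero)) {
    i <- !zero
    arg <- 1 + L[i] * S[i] * z[i]
    if (any(arg <= 0)) {
      stop("bccg_centile: requested centile outside the support ",
           "(1 + L*S*z <= 0)", call. = FALSE)
    }
    out[i] <- M[i] * arg^(1 / L[i])
  }
  out
}

#' Calibrate BCCG parameters from published quantiles
#'
#' Recovers \code{(L, M, S)} from a set of printed centiles, e.g. one height
#' column of a published reference table. The median centile, when supplied,
#' pins \code{M} analytically (the 50th centile of a BCCG distribution is its
#' median); the remaining quantiles determine \code{(L, S)} by least squares.
#' With exactly two non-median quantiles the fit is exact to solver
#' tolerance; with more it is a least-squares compromise.
#'
#' @param probs probabilities in (0, 1); at least 3 distinct values.
#' @param quantiles strictly increasing quantiles matching \code{probs}.
#' @param L if non-\code{NULL}, fix the Box-Cox power at this value and fit
#'   only the free parameters.
#' @param tol maximum acceptable root-mean-square quantile mismatch (same
#'   units as \code{quantiles}) for an exactly-determined system.
#' @param bound for overdetermined fits, the maximum allowed absolute
#'   mismatch at any quantile (default 0.5, the rounding half-width of a
#'   table printed in integers: the generating model must reproduce every
#'   printed cell to within rounding). Set \code{Inf} for plain least
#'   squares.
#' @return list with components \code{L}, \code{M}, \code{S},
#'   \code{residuals} (fitted minus supplied quantiles) and \code{rms}.
#' @examples
#' calibrate_bccg_from_quantiles(c(0.5, 0.9, 0.95, 0.99), c(91, 102, 106, 112))
#' @export
calibrate_bccg_from_quantiles <- function(probs, quantiles, L = NULL,
                                          tol = 0.01, bound = 0.5) {
  probs <- as.numeric(probs); quantiles <- as.numeric(quantiles)
  if (length(probs) != length(quantiles)) {
    stop("probs and quantiles must have the same length", call. = FALSE)
  }
  if (length(unique(probs)) < 2 ||
      (is.null(L) && length(unique(probs)) < 3)) {
    stop("need at least 3 distinct probabilities (2 when L is fixed)",
         call. = FALSE)
  }
  if (any(probs <= 0) || any(probs >= 1)) {
    stop("probs must lie strictly in (0, 1)", call. = FALSE)
  }
  ord <- order(probs)
  probs <- probs[ord]; quantiles <- quantiles[ord]
  if (any(diff(quantiles) <= 0)) {
    stop("quantiles must be strictly increasing in probability",
         call. = FALSE)
  }

  has_median <- any(abs(probs - 0.5) < 1e-12)
  if (has_median) {
    M <- quantiles[which.min(abs(probs - 0.5))]
  } else {
    # fall back: interpolate the median on the normal-quantile scale
    M <- stats::approx(stats::qnorm(probs), quantiles, xout = 0,
                       rule = 2)$y
  }
  zq <- stats::qnorm(probs)
  free <- abs(probs - 0.5) >= 1e-12

  n_free_par <- if (is.null(L)) 2L else 1L
  overdet <- sum(free) > n_free_par
  obj <- function(par) {
    l <- if (is.null(L)) par[1] else L
    s <- exp(par[length(par)])
    arg <- 1 + l * s * zq[free]
    if (any(arg <= 0) || abs(l) > 5) return(1e10)
    fit <- if (abs(l) < 1e-8) M * exp(s * zq[free]) else M * arg^(1 / l)
    r <- fit - quantiles[free]
    ssq <- sum(r^2)
    if (overdet && is.finite(bound)) {
      # soft bound slightly inside the limit so the solution respects it
      ssq <- ssq + 1e6 * sum(pmax(abs(r) - (bound - 1e-4), 0)^2)
    }
    ssq
  }

  s0 <- {
    iq <- which.max(abs(zq))
    abs((quantiles[iq] / M - 1) / zq[iq])
  }
  if (!is.finite(s0) || s0 <= 0) s0 <- 0.1
  # The (L, S) objective can carry several near-equivalent local minima
  # when the quantiles are integers rounded from a smooth model. Multi-
  # start, then break near-ties toward the normal case (smallest |L - 1|)
  # so that calibrations of neighbouring table columns land on the same
  # branch and knot sequences stay smooth.
  starts <- if (is.null(L)) {
    lapply(c(-2, -1, 0, 0.5, 1, 1.5, 2), function(l0) c(l0, log(s0)))
  } else {
    list(log(s0))
  }
  sols <- lapply(starts, function(par0) {
    fit <- stats::optim(par0, obj, method = "Nelder-Mead",
                        control = list(maxit = 5000, reltol = 1e-14,
                                       warn.1d.NelderMead = FALSE))
    stats::optim(fit$par, obj, method = "Nelder-Mead",
                 control = list(maxit = 5000, reltol = 1e-14,
                                warn.1d.NelderMead = FALSE))
  })
  vals <- vapply(sols, function(f) f$value, numeric(1))
  best_val <- min(vals)
  near <- which(vals <= best_val + max(0.02, 0.05 * best_val))
  Ls <- vapply(sols, function(f) if (is.null(L)) f$par[1] else L,
               numeric(1))
  pick <- near[which.min(abs(Ls[near] - 1))]
  fit <- sols[[pick]]
  Lhat <- if (is.null(L)) fit$par[1] else L
  Shat <- exp(fit$par[length(fit$par)])
  if (abs(Lhat) >= 5) {
    stop("calibration failed: no solution with |L| < 5", call. = FALSE)
  }
  fitted <- bccg_centile(probs, Lhat, M, Shat)
  resid <- fitted - quantiles
  rms <- sqrt(mean(resid[free]^2))
  # an exactly-determined system (2 free params, <= 2 free quantiles)
  # must be reproduced to tolerance; overdetermined fits may not
  if (!overdet && rms > tol) {
    stop(sprintf("calibration failed to reproduce quantiles (rms %.4f)",
                 rms), call. = FALSE)
  }
  list(L = Lhat, M = M, S = Shat, residuals = resid, rms = rms)
}
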