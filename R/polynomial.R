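#' Quartic polynomial BP model over the height Z-score
#'
#' The comparison model used alongside the LMS fit: an ordinary
#' least-squares regression of BP on the height Z-score and its powers up
#' to the fourth, fitted separately per sex and outcome, with percentiles
#' constructed from the normal residual model
#' \code{mean(zht) + qnorm(p) * resid_sd}. This follows the established
#' US reference-table methodology with the age terms dropped (a single-age
#' cohort).
#'
#' @param data data frame with columns \code{zht} and \code{bp}.
#' @param sex,outcome labels stored on the fit.
#' @param pooled_sex if \code{TRUE}, \code{data} may contain both sexes and
#'   a sex indicator is included as a covariate (the stratified fit is the
#'   default; the pooled variant exists because a pooled read of the
#'   methodology is also defensible).
#' @return object of class \code{bp_poly} with components \code{beta}
#'   (b0..b4), \code{resid_sd} (n - p denominator), \code{n_fit},
#'   \code{r_squared}.
#' @export
fit_bp_polynomial <- function(data, sex = NA_character_,
                              outcome = NA_character_,
                              pooled_sex = FALSE) {
  stopifnot(all(c("zht", "bp") %in% names(data)))
  data <- data[is.finite(data$zht) & is.finite(data$bp), ]
  if (nrow(data) <= 10) {
    stop("need more than 10 observations to fit the quartic model",
         call. = FALSE)
  }
  if (pooled_sex) {
    stopifnot("sex" %in% names(data))
    fit <- stats::lm(bp ~ zht + I(zht^2) + I(zht^3) + I(zht^4) +
                       I(sex == "boy"), data = data)
  } else {
    fit <- stats::lm(bp ~ zht + I(zht^2) + I(zht^3) + I(zht^4),
                     data = data)
  }
  if (any(is.na(stats::coef(fit)))) {
    stop("singular design: Zht powers are rank deficient", call. = FALSE)
  }
  s <- summary(fit)
  structure(list(sex = sex, outcome = outcome,
                 beta = unname(stats::coef(fit)),
                 coef_names = names(stats::coef(fit)),
                 pooled_sex = pooled_sex,
                 resid_sd = s$sigma,
                 n_fit = nrow(data),
                 r_squared = s$r.squared,
                 lm_fit = fit),
            class = "bp_poly")
}

#' @export
print.bp_poly <- function(x, ...) {
  cat("Quartic polynomial BP model", if (!is.na(x$sex)) paste0("(", x$sex,
      " ", x$outcome, ")"), "\n")
  cat("  beta:", paste(signif(x$beta, 6), collapse = ", "), "\n")
  cat("  residual SD:", round(x$resid_sd, 3), "mmHg on", x$n_fit,
      "children; R^2 =", round(x$r_squared, 4), "\n")
  invisible(x)
}

#' @export
coef.bp_poly <- function(object, ...) {
  stats::setNames(object$beta, object$coef_names)
}

#' @export
predict.bp_poly <- function(object, zht, ...) {
  b <- object$beta[1:5]
  b[1] + b[2] * zht + b[3] * zht^2 + b[4] * zht^3 + b[5] * zht^4
}

#' @export
residuals.bp_poly <- function(object, ...) {
  stats::residuals(object$lm_fit)
}

#' BP percentile from the polynomial model
#'
#' @param model a [fit_bp_polynomial()] fit.
#' @param zht height Z-score(s).
#' @param p BP probability in (0, 1).
#' @return predicted mean at \code{zht} plus \code{qnorm(p)} residual SDs.
#' @export
polynomial_centile <- function(model, zht, p) {
  stopifnot(inherits(model, "bp_poly"))
  if (any(p <= 0) || any(p >= 1)) {
    stop("'p' must lie strictly in (0, 1)", call. = FALSE)
  }
  predict(model, zht) + stats::qnorm(p) * model$resid_sd
}

#' Export / import polynomial coefficients
#'
#' The coefficient CSV mirrors the published supplementary coefficient
#' tables: one row per sex and outcome with b0..b4 and the residual SD.
#'
#' @param models list of \code{bp_poly} fits.
#' @param path file path.
#' @return \code{path} invisibly (write); list of models (read).
#' @export
write_poly_coefficients <- function(models, path) {
  rows <- do.call(rbind, lapply(models, function(m) {
    data.frame(sex = m$sex, outcome = m$outcome,
               b0 = m$beta[1], b1 = m$beta[2], b2 = m$beta[3],
               b3 = m$beta[4], b4 = m$beta[5],
               resid_sd = m$resid_sd, n_fit = m$n_fit,
               r_squared = m$r_squared, stringsAsFactors = FALSE)
  }))
  write_full_precision_csv(rows, path)
  invisible(path)
}

#' @rdname write_poly_coefficients
#' @export
read_poly_coefficients <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  lapply(seq_len(nrow(df)), function(i) {
    r <- df[i, ]
    structure(list(sex = r$sex, outcome = r$outcome,
                   beta = as.numeric(r[paste0("b", 0:4)]),
                   coef_names = c("(Intercept)", "zht", "I(zht^2)",
                                  "I(zht^3)", "I(zht^4)"),
                   pooled_sex = FALSE,
                   resid_sd = r$resid_sd, n_fit = r$n_fit,
                   r_squared = r$r_squared, lm_fit = NULL),
              class = "bp_poly")
  })
}
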