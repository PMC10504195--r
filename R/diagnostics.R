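#' Normal Q-Q coordinates for z-score residuals
#'
#' Pairs the sorted residuals with standard normal quantiles at plotting
#' positions \code{(i - 0.5)/n}; the testable data behind a normal Q-Q
#' diagnostic plot.
#'
#' @param z numeric residual vector (length >= 2).
#' @return data frame with \code{theoretical} and \code{sample} columns.
#' @export
qq_coordinates <- function(z) {
  z <- z[is.finite(z)]
  n <- length(z)
  if (n < 2) stop("need at least 2 residuals", call. = FALSE)
  if (stats::sd(z) == 0) {
    warning("constant residual vector: Q-Q sample side is degenerate",
            call. = FALSE)
  }
  data.frame(theoretical = stats::qnorm((seq_len(n) - 0.5) / n),
             sample = sort(z))
}

#' Observed-vs-fitted curve data over Zht bins
#'
#' Bins the data into equal-count Zht bins, computes empirical BP
#' quantiles per bin, and evaluates the model centiles at bin midpoints
#' (median Zht of the bin). Bins with fewer than \code{min_bin} points are
#' merged with a neighbor. The output is tidy data for external plotting.
#'
#' @param model a \code{bccg_lms} or \code{bp_poly} fit.
#' @param data data frame with \code{zht}, \code{bp}.
#' @param bp_ps BP probabilities to trace.
#' @param bins number of equal-count bins (default 10).
#' @param min_bin minimum points per bin before merging (default 20).
#' @return data frame with columns \code{bin}, \code{zht_mid}, \code{n},
#'   \code{p}, \code{observed}, \code{fitted}.
#' @export
fitcurve_data <- function(model, data, bp_ps = c(0.05, 0.5, 0.95),
                          bins = 10, min_bin = 20) {
  stopifnot(all(c("zht", "bp") %in% names(data)), nrow(data) > 0)
  data <- data[order(data$zht), ]
  n <- nrow(data)
  bins <- max(1, min(bins, floor(n / max(min_bin, 1))))
  idx <- ceiling(seq_len(n) / (n / bins))
  idx[idx > bins] <- bins
  # merge undersized bins with their left neighbor
  repeat {
    cnt <- table(idx)
    small <- names(cnt)[cnt < min_bin]
    if (!length(small) || length(unique(idx)) == 1) break
    b <- as.integer(small[1])
    idx[idx == b] <- if (b > min(idx)) b - 1L else min(idx[idx != b])
  }
  ids <- sort(unique(idx))
  out <- do.call(rbind, lapply(seq_along(ids), function(k) {
    sel <- idx == ids[k]
    zmid <- stats::median(data$zht[sel])
    fitted <- if (inherits(model, "bccg_lms")) {
      lms_centile(model, rep(zmid, length(bp_ps)), bp_ps,
                  allow_extrapolation = TRUE)
    } else {
      polynomial_centile(model, zmid, bp_ps)
    }
    data.frame(bin = k, zht_mid = zmid, n = sum(sel), p = bp_ps,
               observed = as.numeric(stats::quantile(data$bp[sel], bp_ps,
                                                     type = 7)),
               fitted = fitted)
  }))
  rownames(out) <- NULL
  out
}

#' Residual-density coordinates
#'
#' Kernel density of the z-score residuals with the standard normal
#' density alongside, for the residual-density diagnostic.
#'
#' @param z residual vector.
#' @return data frame with \code{x}, \code{density}, \code{normal}.
#' @export
residual_density <- function(z) {
  z <- z[is.finite(z)]
  if (length(z) < 2) stop("need at least 2 residuals", call. = FALSE)
  d <- stats::density(z)
  data.frame(x = d$x, density = d$y, normal = stats::dnorm(d$x))
}
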