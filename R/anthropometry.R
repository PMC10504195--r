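#' Construct a growth standard for height Z-scoring
#'
#' A growth standard is an LMS lookup table: one row per sex and age in
#' months giving the Box-Cox power \code{L}, median height \code{M} (cm) and
#' coefficient of variation \code{S}. A mean/SD-parameterized standard is the
#' \code{L = 1} special case with \code{S = SD/mean}.
#'
#' @param df data frame with columns \code{sex} ("boy"/"girl"),
#'   \code{age_months}, \code{L}, \code{M}, \code{S}.
#' @return object of class \code{growth_standard}.
#' @export
growth_standard <- function(df) {
  need <- c("sex", "age_months", "L", "M", "S")
  miss <- setdiff(need, names(df))
  if (length(miss)) {
    stop("growth standard is missing columns: ",
         paste(miss, collapse = ", "), call. = FALSE)
  }
  df <- as.data.frame(df)[need]
  df$sex <- as.character(df$sex)
  if (!all(df$sex %in% c("boy", "girl"))) {
    stop("growth standard 'sex' must be 'boy' or 'girl'", call. = FALSE)
  }
  if (any(!is.finite(df$M)) || any(df$M <= 0) ||
      any(!is.finite(df$S)) || any(df$S <= 0)) {
    stop("growth standard requires M > 0 and S > 0", call. = FALSE)
  }
  if (anyDuplicated(df[c("sex", "age_months")])) {
    stop("duplicate (sex, age_months) rows in growth standard",
         call. = FALSE)
  }
  df <- df[order(df$sex, df$age_months), ]
  rownames(df) <- NULL
  class(df) <- c("growth_standard", "data.frame")
  df
}

#' Read / write a growth standard CSV
#'
#' The on-disk schema is a plain CSV with header
#' \code{sex,age_months,L,M,S}; it is validated strictly on read.
#'
#' @param path file path.
#' @return [read_growth_standard()] returns a \code{growth_standard};
#'   [write_growth_standard()] returns \code{path} invisibly.
#' @export
read_growth_standard <- function(path) {
  growth_standard(utils::read.csv(path, stringsAsFactors = FALSE))
}

#' @rdname read_growth_standard
#' @param standard a \code{growth_standard}.
#' @export
write_growth_standard <- function(standard, path) {
  stopifnot(inherits(standard, "growth_standard"))
  utils::write.csv(as.data.frame(standard), path, row.names = FALSE,
                   quote = FALSE)
  invisible(path)
}

#' Bundled synthetic growth standard
#'
#' A self-contained stand-in standard for toddlers aged 18-42 months. It is
#' NOT a national growth reference: the median track is anchored at 84.0 cm
#' around 27 months with a gentle age slope, S matches a 2.9 cm SD at the
#' anchor, and L = 1 (mean/SD parameterization). It exists so that the
#' pipeline, which accepts any user-supplied standard, runs end to end
#' without restricted reference data.
#'
#' @param sexes which sexes to tabulate.
#' @return a \code{growth_standard}.
#' @export
synthetic_growth_standard <- function(sexes = c("boy", "girl")) {
  ages <- 18:42
  rows <- do.call(rbind, lapply(sexes, function(sx) {
    off <- if (sx == "boy") 0.3 else -0.3
    M <- 84.0 + off + 0.2 * (ages - 27)
    data.frame(sex = sx, age_months = ages, L = 1,
               M = M, S = round(2.9 / 84.0, 5))
  }))
  growth_standard(rows)
}

#' Height Z-score against a growth standard
#'
#' Standardizes height with the LMS transform using the standard's
#' \code{(L, M, S)} at the child's sex and age. Ages between tabulated rows
#' are handled by linear interpolation of L, M and S; ages outside the
#' standard's coverage are an error. Heights more than 5 SD from the
#' standard are flagged as outliers (the exclusion rule applied before
#' model fitting).
#'
#' @param height_cm height in cm (> 0); vectorized.
#' @param sex "boy" or "girl"; recycled.
#' @param age_months age in (possibly fractional) months; recycled.
#' @param standard a \code{growth_standard}.
#' @return data frame with columns \code{zht} and \code{outlier}
#'   (\code{|zht| > 5}).
#' @export
height_zscore <- function(height_cm, sex, age_months, standard) {
  stopifnot(inherits(standard, "growth_standard"))
  n <- max(length(height_cm), length(sex), length(age_months))
  height_cm <- rep_len(height_cm, n)
  sex <- rep_len(as.character(sex), n)
  age_months <- rep_len(age_months, n)
  if (any(!is.finite(height_cm)) || any(height_cm <= 0)) {
    stop("height must be positive and finite", call. = FALSE)
  }
  zht <- numeric(n)
  for (sx in unique(sex)) {
    rows <- standard[standard$sex == sx, ]
    if (!nrow(rows)) stop("sex '", sx, "' not in growth standard",
                          call. = FALSE)
    idx <- sex == sx
    a <- age_months[idx]
    if (any(a < min(rows$age_months)) || any(a > max(rows$age_months))) {
      stop("age outside growth-standard coverage [",
           min(rows$age_months), ", ", max(rows$age_months), "] months",
           call. = FALSE)
    }
    L <- stats::approx(rows$age_months, rows$L, xout = a)$y
    M <- stats::approx(rows$age_months, rows$M, xout = a)$y
    S <- stats::approx(rows$age_months, rows$S, xout = a)$y
    zht[idx] <- bccg_zscore(height_cm[idx], L, M, S)
  }
  data.frame(zht = zht, outlier = abs(zht) > 5)
}

#' Height centile from a growth standard
#'
#' Inverse of [height_zscore()] at a given probability; used to place
#' synthetic children at prescribed height percentiles.
#'
#' @inheritParams height_zscore
#' @param p probability in (0, 1); recycled.
#' @return heights in cm.
#' @export
height_centile <- function(p, sex, age_months, standard) {
  stopifnot(inherits(standard, "growth_standard"))
  n <- max(length(p), length(sex), length(age_months))
  p <- rep_len(p, n)
  sex <- rep_len(as.character(sex), n)
  age_months <- rep_len(age_months, n)
  out <- numeric(n)
  for (sx in unique(sex)) {
    rows <- standard[standard$sex == sx, ]
    idx <- sex == sx
    a <- age_months[idx]
    L <- stats::approx(rows$age_months, rows$L, xout = a)$y
    M <- stats::approx(rows$age_months, rows$M, xout = a)$y
    S <- stats::approx(rows$age_months, rows$S, xout = a)$y
    out[idx] <- bccg_centile(p[idx], L, M, S)
  }
  out
}

#' Height Z-score at a height percentile
#'
#' Reference tables are indexed by height percentile; under Z-scoring the
#' p-th height percentile corresponds to the standard normal quantile of p.
#'
#' @param p probability in (0, 1).
#' @return standard normal quantile(s).
#' @examples
#' zht_from_height_percentile(c(0.05, 0.5, 0.95))
#' @export
zht_from_height_percentile <- function(p) {
  if (any(p <= 0) || any(p >= 1)) {
    stop("height percentile must lie strictly in (0, 1)", call. = FALSE)
  }
  stats::qnorm(p)
}
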