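#' Build a height-percentile by BP-percentile reference table
#'
#' Evaluates a fitted centile model (LMS or polynomial) at the height
#' Z-scores corresponding to the requested height percentiles and at each
#' requested BP percentile, then rounds half-up to integer mmHg. The
#' published layout uses height percentiles {5, 10, 25, 50, 75, 90, 95}
#' and BP percentiles {50, 90, 95, 99}. Monotonicity down each height
#' column is validated on the unrounded values.
#'
#' @param model a \code{bccg_lms} or \code{bp_poly} fit.
#' @param height_ps height percentiles as probabilities in (0, 1).
#' @param bp_ps BP percentiles as probabilities in (0, 1).
#' @param allow_extrapolation passed to the LMS centile evaluator.
#' @return object of class \code{reference_table}: a list with the integer
#'   \code{grid} (rows = BP percentiles, columns = height percentiles),
#'   the \code{unrounded} grid, percentile vectors, and model metadata.
#' @export
build_reference_table <- function(model,
                                  height_ps = c(0.05, 0.10, 0.25, 0.50,
                                                0.75, 0.90, 0.95),
                                  bp_ps = c(0.50, 0.90, 0.95, 0.99),
                                  allow_extrapolation = FALSE) {
  if (any(height_ps <= 0) || any(height_ps >= 1) ||
      any(bp_ps <= 0) || any(bp_ps >= 1)) {
    stop("percentiles must lie strictly in (0, 1)", call. = FALSE)
  }
  height_ps <- sort(height_ps); bp_ps <- sort(bp_ps)
  zh <- zht_from_height_percentile(height_ps)
  model_kind <- if (inherits(model, "bccg_lms")) "lms"
    else if (inherits(model, "bp_poly")) "polynomial"
    else stop("model must be a bccg_lms or bp_poly fit", call. = FALSE)

  cell <- function(z, p) {
    if (model_kind == "lms") {
      tryCatch(lms_centile(model, z, p, allow_extrapolation),
               error = function(e) {
                 stop("cell (height p=", 100 * height_ps[match(z, zh)],
                      ", bp p=", 100 * p, "): ", conditionMessage(e),
                      call. = FALSE)
               })
    } else {
      polynomial_centile(model, z, p)
    }
  }
  unrounded <- matrix(NA_real_, length(bp_ps), length(height_ps),
                      dimnames = list(paste0("p", 100 * bp_ps),
                                      sprintf("h%02d",
                                              round(100 * height_ps))))
  for (i in seq_along(bp_ps)) {
    for (j in seq_along(height_ps)) {
      unrounded[i, j] <- cell(zh[j], bp_ps[i])
    }
  }
  if (any(apply(unrounded, 2, function(col) any(diff(col) <= 0)))) {
    stop("centile crossing: unrounded cells are not strictly increasing ",
         "in BP percentile", call. = FALSE)
  }
  grid <- round_half_up(unrounded)
  structure(list(sex = model$sex, outcome = model$outcome,
                 model_kind = model_kind,
                 height_ps = height_ps, bp_ps = bp_ps,
                 grid = grid, unrounded = unrounded),
            class = "reference_table")
}

#' @export
print.reference_table <- function(x, ...) {
  cat("Reference table:", x$sex, x$outcome, paste0("(", x$model_kind, ")"),
      "\n")
  cat("  rows: BP percentiles; columns: height percentiles\n")
  print(x$grid)
  invisible(x)
}

#' Look up one reference-table cell
#'
#' @param table a \code{reference_table}.
#' @param height_p,bp_p percentiles as probabilities.
#' @return integer mmHg value.
#' @export
table_cell <- function(table, height_p, bp_p) {
  stopifnot(inherits(table, "reference_table"))
  j <- which(abs(table$height_ps - height_p) < 1e-9)
  i <- which(abs(table$bp_ps - bp_p) < 1e-9)
  if (!length(i) || !length(j)) {
    stop("requested percentile not in the table grid", call. = FALSE)
  }
  table$grid[i, j]
}

#' Compare two reference tables cell by cell
#'
#' @param a,b \code{reference_table}s on identical percentile grids.
#' @return list with the \code{difference} matrix (a - b),
#'   \code{max_abs} and \code{mean_abs}.
#' @export
compare_tables <- function(a, b) {
  stopifnot(inherits(a, "reference_table"), inherits(b, "reference_table"))
  if (!isTRUE(all.equal(a$height_ps, b$height_ps)) ||
      !isTRUE(all.equal(a$bp_ps, b$bp_ps))) {
    stop("tables are on different percentile grids", call. = FALSE)
  }
  d <- a$grid - b$grid
  list(difference = d, max_abs = max(abs(d)), mean_abs = mean(abs(d)))
}

#' Export a reference table as CSV
#'
#' Writes the wide layout (one row per BP percentile, height-percentile
#' columns \code{h05..h95}) and, optionally alongside it, a long tidy
#' layout.
#'
#' @param table a \code{reference_table}.
#' @param path CSV path for the wide layout.
#' @param long_path optional CSV path for the long layout.
#' @return \code{path} invisibly.
#' @export
write_reference_table <- function(table, path, long_path = NULL) {
  stopifnot(inherits(table, "reference_table"))
  wide <- data.frame(sex = table$sex, outcome = table$outcome,
                     model = table$model_kind,
                     bp_percentile = 100 * table$bp_ps,
                     stringsAsFactors = FALSE)
  wide <- cbind(wide, as.data.frame(table$grid))
  utils::write.csv(wide, path, row.names = FALSE, quote = FALSE)
  if (!is.null(long_path)) {
    long <- expand.grid(bp_percentile = 100 * table$bp_ps,
                        height_percentile = 100 * table$height_ps)
    long$sex <- table$sex; long$outcome <- table$outcome
    long$model <- table$model_kind
    long$value <- as.vector(table$grid)
    utils::write.csv(long[c("sex", "outcome", "model", "height_percentile",
                            "bp_percentile", "value")],
                     long_path, row.names = FALSE, quote = FALSE)
  }
  invisible(path)
}
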