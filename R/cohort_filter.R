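#' Apply the six-criterion exclusion cascade with flow accounting
#'
#' Applies, per BP channel and in order, the staged exclusions used to
#' assemble the analysis sets: (1) chronic disease; (2)+(3) two or more
#' missing BP readings, a 0 mmHg diastolic, or an unstable measurement
#' condition (grouped as one flowchart box, sub-reasons logged); (4)
#' unstable BP values (consecutive readings differing by 5 mmHg or more);
#' (5) missing covariates or height more than 5 SD from the growth
#' standard; (6) age under 24 months. Each child lands in exactly one
#' bucket per channel (the first applicable); survivors carry their
#' selected BP value and height Z-score.
#'
#' @param cohort cohort data frame (schema of [generate_cohort()]; the
#'   selection columns are added here if absent).
#' @param standard a \code{growth_standard} for height Z-scoring.
#' @return list with \code{sbp_set} and \code{dbp_set} (data frames of
#'   analyzed children with \code{bp} and \code{zht} columns),
#'   \code{flow} (a \code{flow_accounting} object) and \code{reasons}
#'   (per-channel sub-reason counts within the grouped box).
#' @export
apply_exclusions <- function(cohort, standard) {
  if (!"sbp_status" %in% names(cohort)) cohort <- select_cohort(cohort)
  n <- nrow(cohort)

  covar_cols <- c("sex", "age_months", "height_cm", "weight_kg", "season")
  covar_missing <- rowSums(is.na(cohort[covar_cols]) |
                             cohort[covar_cols] == "") > 0

  zht <- rep(NA_real_, n)
  can_z <- !is.na(cohort$height_cm) & !is.na(cohort$age_months)
  if (any(can_z)) {
    # ages outside the standard's coverage count as unresolvable covariates
    zres <- tryCatch(
      height_zscore(cohort$height_cm[can_z], cohort$sex[can_z],
                    cohort$age_months[can_z], standard),
      error = function(e) NULL)
    if (is.null(zres)) {
      ok <- rep(FALSE, sum(can_z))
      zr <- rep(NA_real_, sum(can_z))
      idx <- which(can_z)
      for (j in seq_along(idx)) {
        r <- tryCatch(height_zscore(cohort$height_cm[idx[j]],
                                    cohort$sex[idx[j]],
                                    cohort$age_months[idx[j]], standard),
                      error = function(e) NULL)
        if (!is.null(r)) { ok[j] <- TRUE; zr[j] <- r$zht }
      }
      zht[idx[ok]] <- zr[ok]
      covar_missing[idx[!ok]] <- TRUE
    } else {
      zht[can_z] <- zres$zht
    }
  }
  height_outlier <- !is.na(zht) & abs(zht) > 5

  channel_buckets <- function(status) {
    bucket <- rep("analyzed", n)
    cond <- cohort$condition_flag != "stable"
    missing_box <- status %in% c("rejected_missing", "rejected_dbp_zero") |
      cond
    unstable_box <- status == "rejected_unstable" & !cond
    # first-applicable ordering
    bucket[cohort$age_months < 24 | is.na(cohort$age_months)] <-
      "excluded_underage"
    bucket[covar_missing | height_outlier] <-
      "excluded_covariates_or_height_outlier"
    bucket[unstable_box] <- "excluded_unstable_bp"
    bucket[missing_box] <- "excluded_missing_or_condition"
    bucket[cohort$chronic_disease %in% TRUE] <- "excluded_chronic"
    bucket
  }
  sbp_bucket <- channel_buckets(cohort$sbp_status)
  dbp_bucket <- channel_buckets(cohort$dbp_status)

  count_buckets <- function(bucket) {
    lv <- c("excluded_chronic", "excluded_missing_or_condition",
            "excluded_unstable_bp", "excluded_covariates_or_height_outlier",
            "excluded_underage", "analyzed")
    cnt <- vapply(lv, function(b) sum(bucket == b), integer(1))
    c(total_in = n, cnt)
  }
  flow <- structure(list(sbp = count_buckets(sbp_bucket),
                         dbp = count_buckets(dbp_bucket)),
                    class = "flow_accounting")

  reason_counts <- function(status) {
    cond <- cohort$condition_flag != "stable"
    c(unstable_condition = sum(cond),
      missing_readings = sum(status == "rejected_missing" & !cond),
      dbp_zero = sum(status == "rejected_dbp_zero" & !cond))
  }

  mk_set <- function(bucket, value_col) {
    keep <- bucket == "analyzed"
    out <- cohort[keep, c("child_id", "sex", "age_months", "height_cm",
                          "weight_kg", "season")]
    out$bp <- cohort[[value_col]][keep]
    out$zht <- zht[keep]
    rownames(out) <- NULL
    out
  }
  list(sbp_set = mk_set(sbp_bucket, "sbp_selected"),
       dbp_set = mk_set(dbp_bucket, "dbp_selected"),
       flow = flow,
       reasons = list(sbp = reason_counts(cohort$sbp_status),
                      dbp = reason_counts(cohort$dbp_status)),
       buckets = data.frame(child_id = cohort$child_id,
                            sbp_bucket = sbp_bucket,
                            dbp_bucket = dbp_bucket,
                            stringsAsFactors = FALSE))
}

#' @export
print.flow_accounting <- function(x, ...) {
  cat(format_flow(x), sep = "\n")
  invisible(x)
}

#' Render flow accounting as a text flowchart
#'
#' @param flow a \code{flow_accounting} object.
#' @return character vector of lines.
#' @export
format_flow <- function(flow) {
  lab <- c(total_in = "Assessed",
           excluded_chronic = "(1) chronic disease",
           excluded_missing_or_condition =
             "(2)+(3) missing BP / DBP 0 mmHg / unstable condition",
           excluded_unstable_bp = "(4) unstable BP (>= 5 mmHg)",
           excluded_covariates_or_height_outlier =
             "(5) missing covariates / height outlier",
           excluded_underage = "(6) under 24 months",
           analyzed = "Analyzed")
  out <- character(0)
  for (ch in c("sbp", "dbp")) {
    out <- c(out, paste0(toupper(ch), " channel"))
    for (nm in names(lab)) {
      out <- c(out, sprintf("  %-55s %6d", lab[[nm]], flow[[ch]][[nm]]))
    }
  }
  out
}

#' Descriptive summary of the analyzed cohort
#'
#' Computes the background table of the analyzed children: n, number and
#' percentage of boys, mean (sample SD) of height, weight and the selected
#' BP values, with per-channel availability. The base population is the
#' union of children analyzed in either channel. If a \code{region} column
#' is present the summary is additionally stratified.
#'
#' @param sbp_set,dbp_set analyzed sets from [apply_exclusions()].
#' @return data frame of class \code{cohort_summary}; one row per stratum
#'   plus a "Total" row.
#' @export
cohort_summary <- function(sbp_set, dbp_set) {
  both <- unique(rbind(sbp_set[c("child_id", "sex", "age_months",
                                 "height_cm", "weight_kg", "season")],
                       dbp_set[c("child_id", "sex", "age_months",
                                 "height_cm", "weight_kg", "season")]))
  if (!nrow(both)) {
    out <- data.frame(stratum = character(0))
    class(out) <- c("cohort_summary", "data.frame")
    attr(out, "empty") <- TRUE
    return(out)
  }
  one <- function(ids, label) {
    u <- both[both$child_id %in% ids, ]
    s <- sbp_set[sbp_set$child_id %in% ids, ]
    d <- dbp_set[dbp_set$child_id %in% ids, ]
    data.frame(
      stratum = label,
      n = nrow(u),
      n_boys = sum(u$sex == "boy"),
      pct_boys = round(100 * mean(u$sex == "boy"), 1),
      height_mean = round(mean(u$height_cm), 1),
      height_sd = round(stats::sd(u$height_cm), 1),
      weight_mean = round(mean(u$weight_kg), 1),
      weight_sd = round(stats::sd(u$weight_kg), 1),
      sbp_n = nrow(s),
      sbp_pct = round(100 * nrow(s) / nrow(u), 1),
      sbp_mean = round(mean(s$bp), 1),
      sbp_sd = round(stats::sd(s$bp), 1),
      dbp_n = nrow(d),
      dbp_pct = round(100 * nrow(d) / nrow(u), 1),
      dbp_mean = round(mean(d$bp), 1),
      dbp_sd = round(stats::sd(d$bp), 1),
      stringsAsFactors = FALSE
    )
  }
  out <- one(both$child_id, "Total")
  class(out) <- c("cohort_summary", "data.frame")
  attr(out, "empty") <- FALSE
  out
}
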