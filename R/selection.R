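#' Select a blood-pressure value from a triplicate of readings
#'
#' Implements the triplicate selection rule used in standardized pediatric
#' BP measurement: the adopted value is the average of two consecutive
#' readings that differ by less than 5 mmHg, preferring the second/third
#' pair; when the second reading is missing, the first/third pair stands in
#' provided it meets the same < 5 mmHg criterion. The cascade is:
#'
#' 1. readings 2 and 3 present and |r2 - r3| < 5  ->  mean(r2, r3), pair (2,3)
#' 2. readings 1 and 2 present and |r1 - r2| < 5  ->  mean(r1, r2), pair (1,2)
#' 3. reading 2 missing, 1 and 3 present, |r1 - r3| < 5 -> mean(r1, r3), pair (1,3)
#' 4. fewer than two readings present              ->  rejected_missing
#' 5. otherwise (differences all >= 5 mmHg)        ->  rejected_unstable
#'
#' A difference of exactly 5 mmHg rejects ("unstable BP" is defined as a
#' difference of >= 5 mmHg between consecutive readings). The rule is
#' applied separately to the systolic and diastolic channels.
#'
#' @param readings numeric vector of length 3; \code{NA} marks a missed
#'   reading. Present readings must be positive.
#' @return list with \code{value} (mean of the used pair, or \code{NA}),
#'   \code{status} (\code{"accepted"}, \code{"rejected_unstable"} or
#'   \code{"rejected_missing"}) and \code{pair_used} (\code{"2,3"},
#'   \code{"1,2"}, \code{"1,3"} or \code{NA}).
#' @examples
#' select_bp_value(c(100, 92, 94))   # accepted 93, pair (2,3)
#' select_bp_value(c(100, NA, 98))   # accepted 99, pair (1,3)
#' select_bp_value(c(100, 94, 88))   # rejected_unstable
#' @export
select_bp_value <- function(readings) {
  if (length(readings) != 3) {
    stop("a measurement triplet has exactly 3 slots", call. = FALSE)
  }
  readings <- as.numeric(readings)
  if (any(!is.na(readings) & readings <= 0)) {
    stop("readings must be positive (use NA for a missed reading)",
         call. = FALSE)
  }
  r1 <- readings[1]; r2 <- readings[2]; r3 <- readings[3]
  res <- function(value, status, pair) {
    list(value = value, status = status, pair_used = pair)
  }
  if (!is.na(r2) && !is.na(r3) && abs(r2 - r3) < 5) {
    return(res((r2 + r3) / 2, "accepted", "2,3"))
  }
  if (!is.na(r1) && !is.na(r2) && abs(r1 - r2) < 5) {
    return(res((r1 + r2) / 2, "accepted", "1,2"))
  }
  if (is.na(r2) && !is.na(r1) && !is.na(r3) && abs(r1 - r3) < 5) {
    return(res((r1 + r3) / 2, "accepted", "1,3"))
  }
  if (sum(is.na(readings)) >= 2) {
    return(res(NA_real_, "rejected_missing", NA_character_))
  }
  res(NA_real_, "rejected_unstable", NA_character_)
}

# DBP channel: a 0 mmHg diastolic marks an unreadable Korotkoff phase V.
# Zeros take part in pair selection as ordinary numbers; the channel is
# rejected as dbp_zero when the adopted pair contains a zero, or when no
# pair is adopted and a zero is among the readings (the zero is implicated
# in the failure). An accepted pair of non-zero readings stands even if the
# remaining reading is 0.
select_dbp_channel <- function(dbp) {
  dbp_rule <- dbp
  dbp_rule[!is.na(dbp_rule) & dbp_rule == 0] <- 1e-9  # keep positive for validation
  d <- select_bp_value(dbp_rule)
  zero <- !is.na(dbp) & dbp == 0
  implicated <- if (d$status == "accepted") {
    idx <- as.integer(strsplit(d$pair_used, ",")[[1]])
    any(zero[idx])
  } else {
    any(zero)
  }
  if (implicated) {
    d <- list(value = NA_real_, status = "rejected_dbp_zero",
              pair_used = NA_character_)
  }
  d
}

# Vectorized core of the selection cascade over matrices of readings
# (rows = children, 3 columns). Used by select_cohort for speed; must agree
# with select_bp_value on every row.
select_channel <- function(m) {
  stopifnot(is.matrix(m), ncol(m) == 3)
  r1 <- m[, 1]; r2 <- m[, 2]; r3 <- m[, 3]
  value <- rep(NA_real_, nrow(m))
  status <- rep("rejected_unstable", nrow(m))
  pair <- rep(NA_character_, nrow(m))

  p23 <- !is.na(r2) & !is.na(r3) & abs(r2 - r3) < 5
  p12 <- !p23 & !is.na(r1) & !is.na(r2) & abs(r1 - r2) < 5
  p13 <- !p23 & !p12 & is.na(r2) & !is.na(r1) & !is.na(r3) &
    abs(r1 - r3) < 5
  value[p23] <- (r2[p23] + r3[p23]) / 2
  value[p12] <- (r1[p12] + r2[p12]) / 2
  value[p13] <- (r1[p13] + r3[p13]) / 2
  status[p23 | p12 | p13] <- "accepted"
  pair[p23] <- "2,3"; pair[p12] <- "1,2"; pair[p13] <- "1,3"
  nmiss <- rowSums(is.na(m))
  mm <- status != "accepted" & nmiss >= 2
  status[mm] <- "rejected_missing"
  data.frame(value = value, status = status, pair_used = pair,
             stringsAsFactors = FALSE)
}

#' Apply the selection rule to both channels of a measurement triplet
#'
#' Runs [select_bp_value()] on the systolic and diastolic channels of one
#' child's triplicate, then applies the triplet-level exclusions: a
#' measurement condition other than "stable" (crying, sleeping, fever,
#' unstable posture) rejects both channels, and a diastolic reading of
#' 0 mmHg in the adopted pair rejects the diastolic channel
#' (\code{rejected_dbp_zero}). A child may therefore contribute to the
#' systolic analysis but not the diastolic one, or vice versa.
#'
#' @param sbp,dbp numeric vectors of length 3 (NA = missing).
#' @param condition_flag one of \code{"stable"}, \code{"crying"},
#'   \code{"sleeping"}, \code{"fever"}, \code{"unstable_posture"}.
#' @return list with components \code{sbp} and \code{dbp}, each as returned
#'   by [select_bp_value()].
#' @export
select_record <- function(sbp, dbp, condition_flag = "stable") {
  cond_levels <- c("stable", "crying", "sleeping", "fever",
                   "unstable_posture")
  if (!condition_flag %in% cond_levels) {
    stop("unknown condition flag: ", condition_flag, call. = FALSE)
  }
  ok <- !is.na(sbp) & !is.na(dbp) & dbp > 0
  if (any(ok & sbp <= dbp)) {
    stop("systolic reading must exceed diastolic reading", call. = FALSE)
  }
  rej <- function() list(value = NA_real_, status = "rejected_unstable",
                         pair_used = NA_character_)
  if (condition_flag != "stable") {
    return(list(sbp = rej(), dbp = rej()))
  }
  s <- select_bp_value(sbp)
  d <- select_dbp_channel(dbp)
  list(sbp = s, dbp = d)
}

#' Apply BP value selection to a whole cohort
#'
#' Adds \code{sbp_selected}, \code{sbp_status}, \code{sbp_pair},
#' \code{dbp_selected}, \code{dbp_status}, \code{dbp_pair} columns to a
#' cohort data frame holding \code{sbp1..sbp3}, \code{dbp1..dbp3} and
#' \code{condition_flag}.
#'
#' @param cohort cohort data frame (see [generate_cohort()] for the schema).
#' @return the cohort with selection columns appended.
#' @export
select_cohort <- function(cohort) {
  need <- c(paste0("sbp", 1:3), paste0("dbp", 1:3), "condition_flag")
  miss <- setdiff(need, names(cohort))
  if (length(miss)) stop("cohort is missing columns: ",
                         paste(miss, collapse = ", "), call. = FALSE)
  smat <- as.matrix(cohort[paste0("sbp", 1:3)])
  dmat <- as.matrix(cohort[paste0("dbp", 1:3)])
  dzero <- !is.na(dmat) & dmat == 0
  dmat_rule <- dmat
  dmat_rule[dzero] <- 1e-9

  s <- select_channel(smat)
  d <- select_channel(dmat_rule)
  pair_idx <- list("2,3" = c(2L, 3L), "1,2" = c(1L, 2L), "1,3" = c(1L, 3L))
  implicated <- vapply(seq_len(nrow(dmat)), function(i) {
    if (d$status[i] == "accepted") {
      any(dzero[i, pair_idx[[d$pair_used[i]]]])
    } else {
      any(dzero[i, ])
    }
  }, logical(1))
  d$status[implicated] <- "rejected_dbp_zero"
  d$value[implicated] <- NA_real_
  d$pair_used[implicated] <- NA_character_

  unstable_cond <- cohort$condition_flag != "stable"
  s$value[unstable_cond] <- NA_real_
  d$value[unstable_cond] <- NA_real_
  s$pair_used[unstable_cond] <- NA_character_
  d$pair_used[unstable_cond] <- NA_character_
  s$status[unstable_cond] <- "rejected_unstable"
  d$status[unstable_cond] <- "rejected_unstable"

  cohort$sbp_selected <- s$value
  cohort$sbp_status <- s$status
  cohort$sbp_pair <- s$pair_used
  cohort$dbp_selected <- d$value
  cohort$dbp_status <- d$status
  cohort$dbp_pair <- d$pair_used
  cohort
}
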