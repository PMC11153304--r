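#' Filter monitor wear days by validity rules
#'
#' Applies the wear-protocol validity rules to one participant's day-level
#' records: the first measured day is always dropped (it coincides with the
#' clinic visit and is not a typical day); the final day is dropped when it
#' contains 14 h or less of recorded information; remaining days are kept
#' only when waking time is at least 14 h (840 min).
#'
#' @param days data.frame with columns `day_index` (1 = first measured day,
#'   unique, ordered), `recorded_hours`, `waking_minutes`, and the behaviour
#'   columns used downstream.
#' @return The retained rows, in original order.
#' @seealso [average_daily_composition()]
#' @export
filter_valid_days <- function(days) {
  stopifnot(is.data.frame(days), nrow(days) >= 1)
  idx <- days$day_index
  if (anyDuplicated(idx) || is.unsorted(idx)) {
    stop("day_index values must be unique and ordered")
  }
  keep <- idx != 1
  last <- idx == max(idx)
  keep[last & days$recorded_hours <= 14] <- FALSE
  keep <- keep & days$waking_minutes >= 840
  out <- days[keep, , drop = FALSE]
  if (nrow(out) == 0) {
    stop(participant_invalid_error("no valid wear days after exclusions"))
  }
  out
}

participant_invalid_error <- function(msg) {
  structure(class = c("participant_invalid", "error", "condition"),
            list(message = msg, call = sys.call(-1)))
}

#' Split stepping time into LPA and MVPA by cadence
#'
#' Stepping epochs are classified by cadence: light physical activity below
#' 100 steps/min, moderate-to-vigorous at or above 100 steps/min. Total
#' stepping time is conserved exactly.
#'
#' @param epochs data.frame (or 2-column matrix) with columns `duration_min`
#'   and `cadence` (steps/min); may have zero rows.
#' @return Named numeric vector `c(lpa = ..., mvpa = ...)` in minutes.
#' @examples
#' cadence_split(data.frame(duration_min = c(30, 20), cadence = c(80, 110)))
#' @export
cadence_split <- function(epochs) {
  if (is.null(epochs) || NROW(epochs) == 0) return(c(lpa = 0, mvpa = 0))
  epochs <- as.data.frame(epochs)
  d <- epochs$duration_min
  cad <- epochs$cadence
  if (any(d < 0)) stop("negative epoch duration")
  if (any(cad < 0)) stop("negative cadence")
  c(lpa = sum(d[cad < 100]), mvpa = sum(d[cad >= 100]))
}

#' Average valid wear days into a daily composition
#'
#' Behaviour minutes are averaged arithmetically over valid days; sleeping
#' time is 24 h minus the average waking time. Waking time can exceed the
#' sum of classified behaviours (monitors leave a small unclassified
#' remainder); by default the residual is distributed proportionally over
#' the four waking behaviours so that waking time is exactly partitioned,
#' keeping the 24 h identity without inventing a sixth part.
#'
#' @param valid_days data.frame of retained days with columns
#'   `waking_minutes`, `sitting_minutes`, `standing_minutes`, `lpa_minutes`,
#'   `mvpa_minutes`.
#' @param residual How to treat waking minutes not classified into a
#'   behaviour: `"proportional"` (default) rescales the four waking
#'   behaviours to sum to mean waking time; `"error"` fails if the
#'   discrepancy exceeds 1 min.
#' @return Named composition vector (minutes/day) summing to 1440.
#' @export
average_daily_composition <- function(valid_days,
                                      residual = c("proportional", "error")) {
  residual <- match.arg(residual)
  stopifnot(is.data.frame(valid_days), nrow(valid_days) >= 1)
  waking <- mean(valid_days$waking_minutes)
  parts <- c(sitting = mean(valid_days$sitting_minutes),
             standing = mean(valid_days$standing_minutes),
             lpa = mean(valid_days$lpa_minutes),
             mvpa = mean(valid_days$mvpa_minutes))
  if (any(parts <= 0)) {
    stop(participant_invalid_error(paste0(
      "behaviour averaging to zero: ",
      paste(names(parts)[parts <= 0], collapse = ", "))))
  }
  gap <- waking - sum(parts)
  if (residual == "error" && abs(gap) > 1) {
    stop("waking time and classified behaviours differ by ", round(gap, 2),
         " min (residual = \"error\")")
  }
  parts <- parts * (waking / sum(parts))
  sleeping <- DAY_MINUTES - waking
  if (sleeping <= 0) {
    stop(participant_invalid_error("average waking time is 24 h or more"))
  }
  close_composition(c(parts, sleeping = sleeping))
}

#' Attach cadence-classified stepping minutes to a day table
#'
#' Joins a long-format epoch table (one row per stepping epoch) onto the
#' day table, classifying each epoch with [cadence_split()] and adding
#' `lpa_minutes` and `mvpa_minutes` columns (zero for days with no epochs).
#'
#' @param days data.frame with `participant_id` and `day_index`.
#' @param epochs data.frame with `participant_id`, `day_index`,
#'   `duration_min`, `cadence`.
#' @return `days` with `lpa_minutes` and `mvpa_minutes` appended.
#' @export
attach_stepping <- function(days, epochs) {
  if (any(epochs$duration_min < 0)) stop("negative epoch duration")
  if (any(epochs$cadence < 0)) stop("negative cadence")
  key_d <- paste(days$participant_id, days$day_index)
  key_e <- paste(epochs$participant_id, epochs$day_index)
  lpa <- rowsum(epochs$duration_min * (epochs$cadence < 100), key_e)
  mvpa <- rowsum(epochs$duration_min * (epochs$cadence >= 100), key_e)
  m <- match(key_d, rownames(lpa))
  days$lpa_minutes <- ifelse(is.na(m), 0, lpa[m, 1])
  days$mvpa_minutes <- ifelse(is.na(m), 0, mvpa[m, 1])
  days
}

#' Aggregate a day-level table into participant compositions
#'
#' Runs [filter_valid_days()] and [average_daily_composition()] per
#' participant. Participants with no valid days or a zero behaviour are
#' excluded, with the reason recorded.
#'
#' @param day_table data.frame with `participant_id` plus the day-level
#'   columns of [filter_valid_days()] / [average_daily_composition()].
#' @param residual Passed to [average_daily_composition()].
#' @return List with `compositions` (data.frame: participant_id, five
#'   behaviour columns, n_valid_days) and `exclusions` (data.frame:
#'   participant_id, reason).
#' @export
aggregate_participants <- function(day_table, residual = "proportional") {
  stopifnot(is.data.frame(day_table), "participant_id" %in% names(day_table))
  ids <- unique(day_table$participant_id)
  by_id <- split(day_table, factor(day_table$participant_id, levels = ids))
  rows <- vector("list", length(ids))
  excl <- list()
  for (i in seq_along(ids)) {
    pdays <- by_id[[i]]
    res <- tryCatch({
      valid <- filter_valid_days(pdays)
      comp <- average_daily_composition(valid, residual = residual)
      data.frame(participant_id = ids[i], t(comp), n_valid_days = nrow(valid))
    }, participant_invalid = function(e) {
      excl[[length(excl) + 1]] <<- data.frame(participant_id = ids[i],
                                              reason = conditionMessage(e))
      NULL
    })
    rows[[i]] <- res
  }
  comp <- do.call(rbind, Filter(Negate(is.null), rows))
  if (is.null(comp)) {
    comp <- data.frame(participant_id = character(),
                       sitting = numeric(), standing = numeric(),
                       lpa = numeric(), mvpa = numeric(),
                       sleeping = numeric(), n_valid_days = integer())
  }
  list(compositions = comp,
       exclusions = if (length(excl)) do.call(rbind, excl) else
         data.frame(participant_id = character(), reason = character()))
}
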