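#' Intensity cut points for 60-s count epochs
#'
#' Counts-per-minute thresholds separating the four intensity bands. The
#' defaults are the study-specific GT3X+ vector-magnitude cut points:
#' SB 0--99, LPA 100--3686, MPA 3687--5246, VPA >= 5247 count/min.
#'
#' @param sb_max upper bound (inclusive) of the sedentary band, count/min.
#' @param lpa_max upper bound (inclusive) of the light band, count/min.
#' @param mpa_max upper bound (inclusive) of the moderate band, count/min.
#' @return An object of class `cut_points`.
#' @examples
#' cut_points()
#' @export
cut_points <- function(sb_max = 99, lpa_max = 3686, mpa_max = 5246) {
  stopifnot(is.numeric(sb_max), is.numeric(lpa_max), is.numeric(mpa_max))
  if (!(sb_max >= 0 && sb_max < lpa_max && lpa_max < mpa_max)) {
    stop("cut points must satisfy 0 <= sb_max < lpa_max < mpa_max", call. = FALSE)
  }
  structure(
    list(sb_max = sb_max, lpa_max = lpa_max, mpa_max = mpa_max),
    class = "cut_points"
  )
}

#' @export
print.cut_points <- function(x, ...) {
  cat("Intensity cut points (count/min):\n")
  cat(sprintf("  SB  : 0-%g\n", x$sb_max))
  cat(sprintf("  LPA : %g-%g\n", x$sb_max + 1, x$lpa_max))
  cat(sprintf("  MPA : %g-%g\n", x$lpa_max + 1, x$mpa_max))
  cat(sprintf("  VPA : >=%g\n", x$mpa_max + 1))
  invisible(x)
}

#' Vector magnitude of tri-axial counts
#'
#' Euclidean norm of the three per-epoch axis counts (frontal, sagittal,
#' vertical), the quantity the cut points are defined on.
#'
#' @param axis1,axis2,axis3 non-negative activity counts per 60-s epoch;
#'   vectors are recycled to a common length by the usual rules.
#' @return `sqrt(axis1^2 + axis2^2 + axis3^2)`.
#' @examples
#' vector_magnitude(3, 4, 0)  # 5
#' @export
vector_magnitude <- function(axis1, axis2, axis3) {
  if (anyNA(axis1) || anyNA(axis2) || anyNA(axis3)) {
    stop("axis counts must not contain NA", call. = FALSE)
  }
  if (any(axis1 < 0) || any(axis2 < 0) || any(axis3 < 0)) {
    stop("axis counts must be non-negative", call. = FALSE)
  }
  sqrt(axis1^2 + axis2^2 + axis3^2)
}

#' Classify epoch vector magnitudes into intensity bands
#'
#' Assigns each vector-magnitude value to exactly one of SB, LPA, MPA, VPA.
#' The printed cut points are integer ranges (e.g. SB is 0--99, LPA starts
#' at 100), so fractional magnitudes between two bands are floored to the
#' lower band: any vm in (99, 100) is SB.
#'
#' @param vm non-negative vector magnitude, count/min.
#' @param cut_points a [cut_points()] object.
#' @return factor with levels `SB`, `LPA`, `MPA`, `VPA`.
#' @examples
#' classify_intensity(c(0, 99, 100, 3686, 3687, 5246, 5247))
#' @export
classify_intensity <- function(vm, cut_points = isotempo::cut_points()) {
  stopifnot(inherits(cut_points, "cut_points"))
  if (anyNA(vm)) stop("vm must not contain NA", call. = FALSE)
  if (any(vm < 0)) stop("vm must be non-negative", call. = FALSE)
  cut(floor(vm),
      breaks = c(-Inf, cut_points$sb_max, cut_points$lpa_max,
                 cut_points$mpa_max, Inf),
      labels = ACTIVITIES)
}

#' Summarize epoch streams into daily activity minutes
#'
#' Converts an epoch-level count table into per-participant-day minutes of
#' SB/LPA/MPA/VPA (one 60-s epoch contributes one minute to its band) and
#' per-participant mean daily minutes over valid days. Participants with
#' fewer valid days than `min_valid_days` are excluded from the means and
#' reported separately.
#'
#' @param epochs data.frame with columns `id`, `timestamp` (POSIXct or
#'   ISO-8601 string), `axis1`, `axis2`, `axis3`. Epochs must be strictly
#'   increasing in time within a participant, at 60-s spacing within a day.
#' @param cut_points a [cut_points()] object.
#' @param min_valid_days minimum number of valid days a participant needs
#'   to enter the per-participant means. Default 6 (>= 3 days/week over a
#'   2-week minimum protocol).
#' @param min_wear_minutes minimum epochs for a day to count as valid
#'   (default 1, i.e. any recorded day).
#' @param zero_run_nonwear optional integer: if set, runs of at least this
#'   many consecutive zero-magnitude epochs within a day are treated as
#'   non-wear and dropped before tallying. Off (`NULL`) by default: the
#'   intended protocol is supervised wear.
#' @return list with components `days` (participant_id, date, sb, lpa, mpa,
#'   vpa, tpa, n_valid_epochs), `participant_means` (mean daily minutes per
#'   band plus tpa and n_valid_days, valid participants only) and
#'   `excluded` (participant ids failing `min_valid_days`).
#' @examples
#' ep <- data.frame(
#'   id = "p1",
#'   timestamp = as.POSIXct("2021-07-01 09:00:00", tz = "UTC") + 60 * (0:9),
#'   axis1 = c(rep(0, 5), rep(4000, 5)), axis2 = 0, axis3 = 0
#' )
#' summarize_days(ep, min_valid_days = 1)$days
#' @export
summarize_days <- function(epochs, cut_points = isotempo::cut_points(),
                           min_valid_days = 6, min_wear_minutes = 1,
                           zero_run_nonwear = NULL) {
  stopifnot(min_valid_days >= 1, min_wear_minutes >= 1)
  required <- c("id", "timestamp", "axis1", "axis2", "axis3")
  missing_cols <- setdiff(required, names(epochs))
  if (length(missing_cols)) {
    stop("epochs is missing columns: ", paste(missing_cols, collapse = ", "),
         call. = FALSE)
  }
  if (nrow(epochs) == 0) {
    warning("empty epoch table; returning empty summaries", call. = FALSE)
    empty_days <- data.frame(
      participant_id = character(), date = as.Date(character()),
      sb = integer(), lpa = integer(), mpa = integer(), vpa = integer(),
      tpa = integer(), n_valid_epochs = integer()
    )
    return(list(days = empty_days,
                participant_means = empty_days[, c(1, 3:7)],
                excluded = character()))
  }

  ts <- epochs$timestamp
  if (!inherits(ts, "POSIXct")) ts <- as.POSIXct(ts, tz = "UTC")
  if (anyNA(ts)) stop("unparseable timestamps in epochs", call. = FALSE)
  if (anyDuplicated(paste(epochs$id, format(ts, "%Y-%m-%d %H:%M:%S")))) {
    stop("duplicate (participant, timestamp) epochs", call. = FALSE)
  }
  ord <- order(epochs$id, ts)
  epochs <- epochs[ord, ]
  ts <- ts[ord]
  # strictly increasing at multiples of 60 s within each participant
  same <- epochs$id[-1] == epochs$id[-nrow(epochs)]
  gaps <- as.numeric(diff(ts), units = "secs")[same]
  if (length(gaps) && (any(gaps <= 0) || any(gaps %% 60 != 0))) {
    stop("epochs must be strictly increasing at 60-s spacing per participant",
         call. = FALSE)
  }

  vm <- vector_magnitude(epochs$axis1, epochs$axis2, epochs$axis3)
  band <- classify_intensity(vm, cut_points)
  date <- as.Date(ts, tz = "UTC")
  # "\x1f" (unit separator) keeps ids containing "." or "-" unambiguous
  key <- factor(paste(epochs$id, format(date), sep = "\x1f"))

  keep <- rep(TRUE, length(vm))
  if (!is.null(zero_run_nonwear)) {
    stopifnot(zero_run_nonwear >= 1)
    for (k in levels(key)) {
      idx <- which(key == k)
      r <- rle(vm[idx] == 0)
      drop_run <- r$values & r$lengths >= zero_run_nonwear
      keep[idx] <- !rep(drop_run, r$lengths)
    }
  }

  tab <- table(key[keep], band[keep])
  counts <- as.data.frame.matrix(tab)
  split_key <- do.call(rbind, strsplit(rownames(counts), "\x1f", fixed = TRUE))
  days <- data.frame(
    participant_id = split_key[, 1],
    date = as.Date(split_key[, 2]),
    sb = counts$SB, lpa = counts$LPA, mpa = counts$MPA, vpa = counts$VPA,
    stringsAsFactors = FALSE
  )
  days$tpa <- days$sb + days$lpa + days$mpa + days$vpa
  days$n_valid_epochs <- days$tpa
  days <- days[order(days$participant_id, days$date), ]
  rownames(days) <- NULL

  valid <- days[days$n_valid_epochs >= min_wear_minutes, ]
  n_days <- table(valid$participant_id)
  ok_ids <- names(n_days)[n_days >= min_valid_days]
  excluded <- setdiff(unique(days$participant_id), ok_ids)

  vd <- valid[valid$participant_id %in% ok_ids, ]
  if (nrow(vd)) {
    means <- aggregate(vd[, c(ACTIVITY_COLS, "tpa")],
                       by = list(participant_id = vd$participant_id), mean)
    means$n_valid_days <- as.integer(n_days[means$participant_id])
  } else {
    means <- days[0, c("participant_id", ACTIVITY_COLS, "tpa")]
    means$n_valid_days <- integer()
  }
  list(days = days, participant_means = means, excluded = excluded)
}

#' Read an ActiGraph-style epoch CSV
#'
#' Expects the header `id,timestamp,axis1,axis2,axis3` with ISO-8601
#' timestamps at 60-s spacing.
#'
#' @param path file path.
#' @return data.frame suitable for [summarize_days()].
#' @export
read_epoch_csv <- function(path) {
  df <- read.csv(path, stringsAsFactors = FALSE)
  df$timestamp <- as.POSIXct(df$timestamp, tz = "UTC",
                             tryFormats = c("%Y-%m-%dT%H:%M:%S",
                                            "%Y-%m-%d %H:%M:%S"))
  df
}
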