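#' Build the daily engagement matrix from an event log
#'
#' Converts a long event table into an n x 182 binary matrix whose entry
#' (i, d) is 1 if participant i logged in at least once on day d, where day
#' 0 is the participant's randomization (anchor) date. Events outside the
#' half-open window \[0, 182) are ignored. Participants with no in-window
#' log-in at all are excluded from the matrix (mirroring an
#' analyzed-if-ever-logged-in cohort rule) and reported via the
#' `"excluded"` attribute and a message.
#'
#' @param events Data frame with column `participant_id` and either
#'   `day_index` (integer day offsets) or `timestamp` (parseable as dates,
#'   in which case `anchors` is required).
#' @param participant_ids Character vector of all cohort participants; every
#'   event's participant must be among them.
#' @param anchors Named vector of anchor dates (names = participant ids),
#'   required when `events` carries timestamps.
#' @param n_days Window length in days; default 182.
#' @return Binary integer matrix with row names = retained participant ids,
#'   columns `d0..d181`, and attribute `excluded` (ids with zero in-window
#'   log-ins).
#' @export
binarize_events <- function(events, participant_ids, anchors = NULL,
                            n_days = 182L) {
  stopifnot(is.data.frame(events), "participant_id" %in% names(events))
  participant_ids <- as.character(participant_ids)
  ev_ids <- as.character(events$participant_id)
  unknown <- setdiff(unique(ev_ids), participant_ids)
  if (length(unknown)) {
    stop("events reference unknown participants: ",
         paste(utils::head(unknown, 5), collapse = ", "))
  }
  if ("day_index" %in% names(events)) {
    day <- as.integer(events$day_index)
  } else if ("timestamp" %in% names(events)) {
    if (is.null(anchors)) stop("'anchors' required when events have timestamps")
    ts <- as.Date(as.character(events$timestamp), optional = TRUE)
    if (anyNA(ts)) {
      stop("unparseable timestamp in events row(s): ",
           paste(utils::head(which(is.na(ts)), 5), collapse = ", "))
    }
    day <- as.integer(ts - as.Date(anchors[ev_ids]))
  } else {
    stop("events must have a 'day_index' or 'timestamp' column")
  }
  keep <- !is.na(day) & day >= 0L & day < n_days
  mat <- matrix(0L, length(participant_ids), n_days,
                dimnames = list(participant_ids, paste0("d", seq_len(n_days) - 1L)))
  if (any(keep)) {
    mat[cbind(match(ev_ids[keep], participant_ids), day[keep] + 1L)] <- 1L
  }
  active <- rowSums(mat) > 0
  excluded <- participant_ids[!active]
  if (length(excluded)) {
    message(length(excluded), " participant(s) with zero in-window log-ins excluded")
  }
  out <- mat[active, , drop = FALSE]
  attr(out, "excluded") <- excluded
  out
}

#' Presmooth daily log-in indicators with a trailing moving average
#'
#' Each day's value becomes the mean of the indicator over that day and the
#' `window - 1` preceding days; at the start of the series the window
#' shrinks (day t averages days `max(0, t - window + 1) .. t`) rather than
#' zero-padding, so early values are unbiased means of the available days.
#'
#' @param mat Binary matrix from [binarize_events()] or a cohort's `logins`.
#' @param window Trailing window length in days (>= 1); default 7. With
#'   `window = 1` the input is returned unchanged.
#' @return Numeric matrix of the same shape with values in \[0, 1\] and
#'   attribute `window`.
#' @export
presmooth <- function(mat, window = 7L) {
  if (!is.matrix(mat)) stop("'mat' must be a matrix")
  if (window < 1) stop("'window' must be >= 1")
  window <- as.integer(window)
  p <- ncol(mat)
  cs <- t(apply(mat, 1, cumsum))
  if (p == 1) cs <- matrix(cs, ncol = 1) # apply drops dims for single column
  lagged <- if (window < p) {
    cbind(matrix(0, nrow(mat), window), cs[, seq_len(p - window), drop = FALSE])
  } else {
    matrix(0, nrow(mat), p)
  }
  denom <- pmin(seq_len(p), window)
  out <- sweep(cs - lagged, 2, denom, "/")
  dimnames(out) <- dimnames(mat)
  attr(out, "window") <- window
  out
}

#' Per-group mean weekly log-in days
#'
#' For each group, the mean over its members of the number of log-in days
#' in each of the 26 weeks (days `7w .. 7w+6`), on the 0-7 days/week scale
#' used for trajectory-group plots.
#'
#' @param mat Daily binary matrix (n x 182).
#' @param labels Group assignment of length `nrow(mat)` (any atomic type).
#' @return Numeric matrix, one row per group (sorted unique label), columns
#'   `week1..week26`, values in \[0, 7\].
#' @export
weekly_login_summary <- function(mat, labels) {
  if (!is.matrix(mat) || ncol(mat) %% 7 != 0) {
    stop("'mat' must be a matrix with a multiple of 7 columns")
  }
  if (length(labels) != nrow(mat)) {
    stop("'labels' length (", length(labels), ") does not match matrix rows (",
         nrow(mat), ")")
  }
  n_weeks <- ncol(mat) / 7
  weekly <- vapply(seq_len(n_weeks), function(w) {
    rowSums(mat[, (7 * (w - 1) + 1):(7 * w), drop = FALSE])
  }, numeric(nrow(mat)))
  if (nrow(mat) == 1) weekly <- matrix(weekly, nrow = 1)
  agg <- rowsum(weekly, group = labels)
  agg <- agg / as.vector(table(labels)[rownames(agg)])
  colnames(agg) <- paste0("week", seq_len(n_weeks))
  agg
}

#' Read a cohort back from its CSV files
#'
#' Counterpart of [write_cohort()]: reads `participants.csv` and
#' `events.csv` from `dir` and rebuilds the daily matrix with
#' [binarize_events()].
#'
#' @param dir Directory containing the two CSVs.
#' @return List with `participants` and the binary `logins` matrix (rows for
#'   all participants in the table, including any with zero log-ins).
#' @export
read_cohort_csv <- function(dir) {
  participants <- utils::read.csv(file.path(dir, "participants.csv"),
                                  stringsAsFactors = FALSE)
  events <- utils::read.csv(file.path(dir, "events.csv"),
                            stringsAsFactors = FALSE)
  ids <- participants$participant_id
  mat <- matrix(0L, length(ids), 182L,
                dimnames = list(ids, paste0("d", 0:181)))
  keep <- events$day_index >= 0 & events$day_index < 182
  mat[cbind(match(events$participant_id[keep], ids),
            events$day_index[keep] + 1L)] <- 1L
  list(participants = participants, logins = mat)
}
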