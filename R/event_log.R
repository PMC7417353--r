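#' Behavioural event logs
#'
#' An event log is a validated data frame of dyadic behavioural events with
#' columns `actor`, `recipient`, `behavior` (`"groom"` or `"headbutt"`),
#' `timestamp` (POSIXct) and `session`, plus a `study_start` attribute (the
#' Monday of observation week 1) from which calendar weeks are derived.
#'
#' @param df Data frame with the columns above.
#' @param study_start Date of the first observation day.
#' @return The validated data frame with class `event_log`.
#' @export
event_log <- function(df, study_start) {
  need <- c("actor", "recipient", "behavior", "timestamp", "session")
  miss <- setdiff(need, names(df))
  if (length(miss)) stop("event log missing columns: ",
                         paste(miss, collapse = ", "))
  df$actor <- as.character(df$actor)
  df$recipient <- as.character(df$recipient)
  errs <- validate_events(df)
  if (length(errs)) stop("invalid event log:\n  ",
                         paste(errs, collapse = "\n  "))
  df$timestamp <- as.POSIXct(df$timestamp, tz = "UTC")
  attr(df, "study_start") <- as.Date(study_start)
  class(df) <- c("event_log", "data.frame")
  df
}

#' @export
`[.event_log` <- function(x, ...) {
  out <- NextMethod()
  if (is.data.frame(out)) {
    attr(out, "study_start") <- attr(x, "study_start")
    class(out) <- class(x)
  }
  out
}

#' @export
print.event_log <- function(x, ...) {
  cat(sprintf("<event_log> %d events (%d groom, %d headbutt), study start %s\n",
              nrow(x), sum(x$behavior == "groom"),
              sum(x$behavior == "headbutt"),
              format(attr(x, "study_start"))))
  if (nrow(x)) print(head(as.data.frame(x), 5))
  invisible(x)
}

validate_events <- function(df) {
  errs <- character()
  bad <- which(df$actor == df$recipient)
  if (length(bad))
    errs <- c(errs, paste0("row ", bad, ": actor equals recipient"))
  bad <- which(!(df$behavior %in% c("groom", "headbutt")))
  if (length(bad))
    errs <- c(errs, paste0("row ", bad, ": unknown behavior '",
                           df$behavior[bad], "'"))
  ts <- vapply(as.character(df$timestamp), function(t)
    tryCatch(as.numeric(as.POSIXct(t, tz = "UTC")),
             error = function(e) NA_real_,
             warning = function(w) NA_real_), 0, USE.NAMES = FALSE)
  bad <- which(is.na(ts))
  if (length(bad))
    errs <- c(errs, paste0("row ", bad, ": unparseable timestamp"))
  errs
}

#' Read an event log from delimited text
#'
#' Expects a header `actor,recipient,behavior,timestamp,session`. Rows that
#' violate the invariants (self-interaction, unknown behaviour, unparseable
#' timestamp) are reported with their line numbers and the read fails.
#'
#' @param source Path to a CSV file, or a data frame.
#' @param study_start Date of the first observation day (week-1 Monday).
#' @return An [event_log()].
#' @export
read_event_log <- function(source, study_start) {
  df <- if (is.data.frame(source)) source else
    read.csv(source, stringsAsFactors = FALSE)
  event_log(df, study_start)
}

#' @rdname read_event_log
#' @param log An [event_log()].
#' @param path Output CSV path.
#' @export
write_event_log <- function(log, path) {
  out <- as.data.frame(log)
  out$timestamp <- format(out$timestamp, "%Y-%m-%d %H:%M:%S", tz = "UTC")
  write.csv(out, path, row.names = FALSE)
  invisible(path)
}

#' Observation week of each event
#'
#' @param log An [event_log()].
#' @return Integer vector: 1 for events in the first 7 days from
#'   `study_start`, and so on.
#' @export
event_week <- function(log) {
  start <- attr(log, "study_start")
  as.integer(floor(as.numeric(as.Date(log$timestamp) - start) / 7)) + 1L
}

#' Merge split grooming bouts
#'
#' Applies the bout rule: consecutive licking episodes by the same actor
#' directed at the same recipient are one grooming event unless the pause
#' between them exceeds `gap_seconds` or the actor performed another
#' behaviour in between, in which case they are separate events.
#'
#' @param obs Data frame of raw continuous licking/headbutt episodes with
#'   columns `actor`, `recipient`, `behavior`, `start`, `stop` (POSIXct or
#'   parseable), `session`.
#' @param gap_seconds Maximum pause within one bout (seconds).
#' @param study_start Date of the first observation day.
#' @return An [event_log()] with one row per merged event; the event
#'   timestamp is the start of its first episode.
#' @export
merge_split_bouts <- function(obs, gap_seconds = 20, study_start) {
  obs$start <- as.POSIXct(obs$start, tz = "UTC")
  obs$stop <- as.POSIXct(obs$stop, tz = "UTC")
  if (any(obs$stop < obs$start)) stop("episode with stop before start")
  obs <- obs[order(obs$actor, obs$start), , drop = FALSE]
  keep <- rep(TRUE, nrow(obs))
  for (a in unique(obs$actor)) {
    idx <- which(obs$actor == a)
    if (length(idx) < 2) next
    o <- obs[idx, ]
    if (any(o$start[-1] < o$stop[-nrow(o)]))
      stop("overlapping episodes for actor ", a)
    for (r in seq(2, length(idx))) {
      same_dyad <- o$recipient[r] == o$recipient[r - 1] &&
        o$behavior[r] == "groom" && o$behavior[r - 1] == "groom"
      gap <- as.numeric(difftime(o$start[r], o$stop[r - 1], units = "secs"))
      if (same_dyad && gap <= gap_seconds) {
        keep[idx[r]] <- FALSE
        # extend the merged bout so a following episode compares against it
        obs$stop[idx[r - 1]] <- max(obs$stop[idx[r - 1]], obs$stop[idx[r]])
        o$stop[r] <- obs$stop[idx[r - 1]]
        o$start[r] <- o$start[r - 1]
        obs$start[idx[r]] <- o$start[r]
        o$recipient[r] <- o$recipient[r - 1]
      }
    }
  }
  merged <- obs[keep, , drop = FALSE]
  event_log(data.frame(actor = merged$actor, recipient = merged$recipient,
                       behavior = merged$behavior, timestamp = merged$start,
                       session = merged$session, stringsAsFactors = FALSE),
            study_start)
}
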