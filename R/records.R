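# Longitudinal patient-record store. Flat and file-backed (JSON lines, one
# terminal-session summary per line) so the baseline comparison the app
# performs automatically is reproducible without a database.

#' Create an empty record store
#'
#' @return An object of class `ddst_record_store`.
#' @export
record_store <- function() {
  structure(list(patients = list()), class = "ddst_record_store")
}

#' Summarize a terminal session for storage
#'
#' Keeps what the baseline comparison needs: the outcome combination and the
#' per-item values of the objective cognitive items.
#'
#' @param session A terminal `ddst_session`.
#' @return A `ddst_session_summary`.
#' @export
summarize_session <- function(session) {
  if (!session$terminal) stop("session is not terminal", call. = FALSE)
  cog <- cognitive_items(session$bank)
  iv <- session$value[cog]
  names(iv) <- as.character(cog)
  structure(list(
    patient_id = session$patient_id,
    nurse_id = session$nurse_id,
    timestamp = as.numeric(session$ended),
    combo = session$outcome$combo,
    delirium = session$outcome$delirium,
    label = session$outcome$label,
    item_values = iv
  ), class = "ddst_session_summary")
}

#' Append a terminal session to a record store
#'
#' Idempotent on the (patient, timestamp) key: re-appending an identical key
#' leaves the store unchanged. Sessions are kept strictly time-ordered per
#' patient.
#'
#' @param store A `ddst_record_store`.
#' @param session A terminal `ddst_session` or a `ddst_session_summary`.
#' @return The updated store.
#' @export
append_session <- function(store, session) {
  stopifnot(inherits(store, "ddst_record_store"))
  s <- if (inherits(session, "ddst_session_summary")) session else
    summarize_session(session)
  pid <- s$patient_id
  cur <- store$patients[[pid]] %||% list()
  if (any(vapply(cur, `[[`, numeric(1), "timestamp") == s$timestamp))
    return(store)
  cur[[length(cur) + 1L]] <- s
  ord <- order(vapply(cur, `[[`, numeric(1), "timestamp"))
  store$patients[[pid]] <- cur[ord]
  store
}

#' Most recent session strictly before a time point
#'
#' This is the "previous evaluation results" lookup behind the auto-derived
#' baseline-comparison item.
#'
#' @param store A `ddst_record_store`.
#' @param patient_id Patient identifier.
#' @param time Cutoff (`POSIXct` or numeric epoch seconds); only sessions
#'   strictly earlier qualify.
#' @return A `ddst_session_summary`, or `NULL` when the patient is unknown or
#'   has no prior session.
#' @export
latest_before <- function(store, patient_id, time) {
  stopifnot(inherits(store, "ddst_record_store"))
  cur <- store$patients[[as.character(patient_id)]]
  if (is.null(cur)) return(NULL)
  ts <- vapply(cur, `[[`, numeric(1), "timestamp")
  ok <- which(ts < as.numeric(time))
  if (!length(ok)) return(NULL)
  cur[[max(ok)]]
}

#' Earliest stored session (the admission baseline)
#'
#' @param store A `ddst_record_store`.
#' @param patient_id Patient identifier.
#' @return A `ddst_session_summary` or `NULL`.
#' @export
baseline_session <- function(store, patient_id) {
  cur <- store$patients[[as.character(patient_id)]]
  if (is.null(cur) || !length(cur)) return(NULL)
  cur[[1L]]
}

#' All stored sessions for a patient, time-ordered
#'
#' @param store A `ddst_record_store`.
#' @param patient_id Patient identifier.
#' @return List of `ddst_session_summary` (possibly empty).
#' @export
patient_history <- function(store, patient_id) {
  store$patients[[as.character(patient_id)]] %||% list()
}

#' Save a record store as JSON lines
#'
#' One summary per line; [read_record_store()] round-trips to an identical
#' store.
#'
#' @param store A `ddst_record_store`.
#' @param path Output file.
#' @return `path`, invisibly.
#' @export
write_record_store <- function(store, path) {
  stopifnot(inherits(store, "ddst_record_store"))
  lines <- unlist(lapply(store$patients, function(sessions)
    vapply(sessions, function(s)
      jsonlite::toJSON(list(
        patient_id = s$patient_id, nurse_id = s$nurse_id,
        timestamp = s$timestamp, combo = as.list(s$combo),
        delirium = s$delirium, label = s$label,
        item_values = as.list(s$item_values)),
        auto_unbox = TRUE, digits = NA),
      character(1))), use.names = FALSE)
  writeLines(lines %||% character(0), path)
  invisible(path)
}

#' Load a record store from JSON lines
#'
#' @param path File written by [write_record_store()].
#' @return A `ddst_record_store`.
#' @export
read_record_store <- function(path) {
  if (!file.exists(path)) stop("record file not found: ", path, call. = FALSE)
  store <- record_store()
  for (line in readLines(path)) {
    if (!nzchar(line)) next
    x <- jsonlite::fromJSON(line, simplifyVector = FALSE)
    bad <- !all(c("patient_id", "timestamp", "combo", "item_values") %in%
                  names(x)) || length(x$combo) != 4L
    if (bad) stop("history integrity error: malformed record line",
                  call. = FALSE)
    s <- structure(list(
      patient_id = x$patient_id,
      nurse_id = x$nurse_id %||% NA_character_,
      timestamp = as.numeric(x$timestamp),
      combo = stats::setNames(vapply(x$combo, isTRUE, logical(1))[FEATURES],
                              FEATURES),
      delirium = isTRUE(x$delirium),
      label = x$label %||% NA_character_,
      item_values = stats::setNames(
        vapply(x$item_values,
               function(v) if (is.null(v)) NA_character_ else as.character(v),
               character(1)),
        names(x$item_values))
    ), class = "ddst_session_summary")
    store <- append_session(store, s)
  }
  store
}

#' @export
print.ddst_record_store <- function(x, ...) {
  n <- sum(lengths(x$patients))
  cat("<ddst_record_store>", length(x$patients), "patients,", n, "sessions\n")
  invisible(x)
}

#' @export
print.ddst_session_summary <- function(x, ...) {
  cat("<ddst_session_summary>", x$patient_id, "@",
      format(as.POSIXct(x$timestamp, origin = "1970-01-01"), "%Y-%m-%d %H:%M:%S"),
      "\n  ", x$label, "\n")
  invisible(x)
}
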