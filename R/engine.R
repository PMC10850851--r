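# Assessment engine: adaptive sequencing with automatic logic jumps, CAM
# feature scoring, auto-derivation of the baseline-comparison item, and
# classification into one of the 16 feature-combination outcome categories.

#' The CAM diagnostic rule
#'
#' Delirium is diagnosed when feature 1 (acute onset / fluctuating course)
#' and feature 2 (inattention) are both present, together with feature 3
#' (disorganized thinking) or feature 4 (altered level of consciousness).
#'
#' @param present Logical vector of length 4 (`F1..F4`), or a character
#'   vector of `"present"`/`"absent"`.
#' @return `TRUE` if the combination meets the diagnostic rule.
#' @export
#' @examples
#' cam_rule(c(TRUE, TRUE, FALSE, TRUE))   # TRUE
#' cam_rule(c(FALSE, TRUE, TRUE, TRUE))   # FALSE: F1 is required
cam_rule <- function(present) {
  p <- as_present(present)
  p[1] && p[2] && (p[3] || p[4])
}

as_present <- function(x) {
  if (is.character(x)) {
    stopifnot(all(x %in% c("present", "absent")))
    x <- x == "present"
  }
  stopifnot(is.logical(x), length(x) == 4L, !anyNA(x))
  x
}

#' Classify a complete feature combination
#'
#' @param present Logical (or `"present"`/`"absent"`) vector over `F1..F4`.
#' @return A list of class `ddst_outcome` with elements `combo` (named
#'   logical), `delirium` (logical) and `label` (stable display string).
#' @export
#' @examples
#' classify_outcome(c(TRUE, TRUE, TRUE, FALSE))$delirium
classify_outcome <- function(present) {
  p <- as_present(present)
  names(p) <- FEATURES
  delirium <- cam_rule(p)
  label <- paste0(paste0(FEATURES, ifelse(p, "+", "-"), collapse = " "),
                  " | ", if (delirium) "delirium-positive" else "delirium-negative")
  structure(list(combo = p, delirium = delirium, label = label),
            class = "ddst_outcome")
}

#' @export
print.ddst_outcome <- function(x, ...) {
  cat("<ddst_outcome>", x$label, "\n")
  invisible(x)
}

#' Enumerate the 16 outcome categories
#'
#' Evaluates the diagnostic rule on all 2^4 present/absent assignments of the
#' four CAM features. Exactly 3 categories are delirium-positive and 13
#' delirium-negative, one result interface per category.
#'
#' @return A 16-row data.frame with columns `F1..F4` (logical), `delirium`
#'   and `label`.
#' @export
#' @examples
#' out <- enumerate_outcomes()
#' table(out$delirium)   # 13 FALSE, 3 TRUE
enumerate_outcomes <- function() {
  grid <- expand.grid(F4 = c(FALSE, TRUE), F3 = c(FALSE, TRUE),
                      F2 = c(FALSE, TRUE), F1 = c(FALSE, TRUE))
  grid <- grid[, FEATURES]
  cats <- lapply(seq_len(nrow(grid)), function(i)
    classify_outcome(unlist(grid[i, ])))
  grid$delirium <- vapply(cats, `[[`, logical(1), "delirium")
  grid$label <- vapply(cats, `[[`, character(1), "label")
  grid[order(-grid$F1, -grid$F2, -grid$F3, -grid$F4), , drop = FALSE] ->
    grid
  rownames(grid) <- NULL
  grid
}

#' Start an assessment session
#'
#' Initializes an adaptive session over the displayed items in page order.
#' The acute-change-from-baseline item (item 22) is never asked: it is
#' pre-derived from the patient's record and injected as an `auto` response,
#' then kept up to date as responses accrue (see [derive_item22()]).
#'
#' @param bank A `ddst_item_bank`.
#' @param patient_id,nurse_id Identifiers (strings).
#' @param modality `"paper"` or `"dst"`. The engine is identical for both;
#'   modality is carried as metadata (reminders/cue display and human-error
#'   behaviour are properties of the administration, not of the scoring).
#' @param mode `"full"` administers every displayed item not made redundant
#'   by a within-feature jump; `"fast"` additionally stops as soon as the
#'   diagnostic outcome is decidable.
#' @param history Optional baseline source: a `ddst_record_store`, a single
#'   session summary (as returned by [latest_before()]), or `NULL`.
#' @param time Session start time (`POSIXct`); defaults to `Sys.time()`.
#' @return An object of class `ddst_session`.
#' @export
start_session <- function(bank, patient_id, nurse_id,
                          modality = c("dst", "paper"),
                          mode = c("fast", "full"),
                          history = NULL, time = Sys.time()) {
  validate_item_bank(bank)
  modality <- match.arg(modality)
  mode <- match.arg(mode)
  baseline <- resolve_baseline(history, patient_id, time)
  s <- structure(list(
    bank = bank,
    patient_id = as.character(patient_id),
    nurse_id = as.character(nurse_id),
    modality = modality,
    mode = mode,
    baseline = baseline,
    no_baseline = is.null(baseline),
    order = page_order(bank),
    status = rep("pending", 22L),   # pending / entered / skipped / auto
    value = rep(NA_character_, 22L),
    log = list(),
    terminal = FALSE,
    outcome = NULL,
    started = time,
    ended = NULL
  ), class = "ddst_session")
  auto_id <- bank$index$auto_id
  s$status[auto_id] <- "auto"
  s$value[auto_id] <- derive_item22(baseline, s)$value
  s$log[[1L]] <- list(item_id = auto_id, value = s$value[auto_id],
                      source = "auto", timestamp = time)
  maybe_finalize(s)
}

resolve_baseline <- function(history, patient_id, time) {
  if (is.null(history)) return(NULL)
  if (inherits(history, "ddst_record_store"))
    return(latest_before(history, patient_id, time))
  if (inherits(history, "ddst_session_summary")) return(history)
  stop("history must be NULL, a ddst_record_store or a session summary",
       call. = FALSE)
}

#' Current CAM feature states of a session
#'
#' A feature is `"present"` once any of its evidence items is positive,
#' `"absent"` once all of its evidence items have been administered (or
#' auto-derived) with none positive, and `"undetermined"` otherwise.
#'
#' @param session A `ddst_session`.
#' @return Named character vector over `F1..F4`.
#' @export
feature_states <- function(session) {
  emap <- session$bank$index$feature_items
  out <- character(4L)
  for (i in 1:4) {
    ids <- emap[[i]]
    v <- session$value[ids]
    st <- session$status[ids]
    out[i] <- if (any(!is.na(v) & v == "positive")) "present"
      else if (!any(st == "pending" | st == "skipped")) "absent"
      else "undetermined"
  }
  names(out) <- FEATURES
  out
}

#' Next administrable item
#'
#' Returns the id of the next item in page order, applying the automatic
#' logic jumps: items belonging to a feature already scored present are
#' skipped (their answer cannot change the feature), and in `fast` mode the
#' session terminates as soon as the diagnostic outcome is decidable --
#' i.e. when classifying only the currently-present features agrees with
#' classifying every present-or-undetermined feature as present.
#'
#' @param session A non-terminal `ddst_session`.
#' @return An item id, or `NA_integer_` when the session should terminate.
#' @export
next_item <- function(session) {
  if (session$terminal) stop("session is already terminal", call. = FALSE)
  next_item_internal(session, feature_states(session))
}

next_item_internal <- function(session, states) {
  if (session$mode == "fast") {
    lower <- states == "present"
    upper <- states != "absent"
    dx_lower <- lower[1L] && lower[2L] && (lower[3L] || lower[4L])
    dx_upper <- upper[1L] && upper[2L] && (upper[3L] || upper[4L])
    if (dx_lower == dx_upper) return(NA_integer_)
  }
  pending <- session$order[session$status[session$order] == "pending"]
  if (!length(pending)) return(NA_integer_)
  pending[1L]
}

#' Submit a response and advance the session
#'
#' Records the operator's judgment for the item the engine asked for,
#' rescores the CAM features, applies within-feature jumps, refreshes the
#' auto-derived baseline-comparison item, and finalizes the session (setting
#' its outcome) when stepping reaches the terminal state.
#'
#' @param session A non-terminal `ddst_session`.
#' @param item_id Must equal `next_item(session)`.
#' @param value `"normal"` or `"positive"` (positive = error on a cognitive
#'   test, endorsed symptom, or observed sign).
#' @param time Response timestamp; defaults to `Sys.time()`.
#' @return The updated session.
#' @export
submit_response <- function(session, item_id, value, time = Sys.time()) {
  if (session$terminal) stop("session is already terminal", call. = FALSE)
  stopifnot(length(item_id) == 1L, length(value) == 1L)
  item_id <- as.integer(item_id)
  if (!value %in% c("normal", "positive"))
    stop("value must be 'normal' or 'positive'", call. = FALSE)
  if (!item_id %in% 1:22 || session$status[item_id] != "pending")
    stop("duplicate or unknown item: ", item_id, call. = FALSE)
  expected <- next_item(session)
  if (is.na(expected) || item_id != expected)
    stop("out-of-order submission: expected item ", expected,
         ", got ", item_id, call. = FALSE)
  session$status[item_id] <- "entered"
  session$value[item_id] <- value
  session$log[[length(session$log) + 1L]] <-
    list(item_id = item_id, value = value, source = "entered",
         timestamp = time)
  session <- rescore(session)
  maybe_finalize(session, time)
}

# Recompute derived state after a response: within-feature jumps plus the
# auto item. A new deficit can flip item 22 to positive, which can in turn
# make F1 present and trigger further jumps, hence the fixed point loop
# (presence is monotone, so it converges in <= 2 passes).
rescore <- function(session) {
  idx <- session$bank$index
  repeat {
    states <- feature_states(session)
    newly_skippable <- FEATURES[idx$item_feature[session$order]] %in%
      FEATURES[states == "present"] &
      session$status[session$order] == "pending"
    if (any(newly_skippable)) {
      ids <- session$order[newly_skippable]
      session$status[ids] <- "skipped"
      for (id in ids)
        session$log[[length(session$log) + 1L]] <-
          list(item_id = id, value = NA_character_, source = "skipped",
               timestamp = NULL)
    }
    auto_id <- idx$auto_id
    new22 <- derive_item22(session$baseline, session)$value
    changed <- !identical(new22, session$value[auto_id])
    session$value[auto_id] <- new22
    if (!changed && !any(newly_skippable)) break
  }
  session
}

maybe_finalize <- function(session, time = session$started) {
  states <- feature_states(session)
  if (!is.na(next_item_internal(session, states))) return(session)
  leftover <- session$order[session$status[session$order] == "pending"]
  if (length(leftover)) {
    session$status[leftover] <- "skipped"
    for (id in leftover)
      session$log[[length(session$log) + 1L]] <-
        list(item_id = id, value = NA_character_, source = "skipped",
             timestamp = NULL)
  }
  # Features left undetermined (possible only under early stopping) map to
  # absent for labeling; the decidability bound guarantees the delirium
  # classification is unaffected.
  session$features <- states
  session$outcome <- classify_outcome(states == "present")
  session$terminal <- TRUE
  session$ended <- time
  session
}

#' Derive the acute-change-from-baseline item (item 22)
#'
#' The record-comparison item is never displayed: the system retrieves the
#' most recent prior assessment and scores the item automatically. It is
#' positive iff a prior session exists and the current evidence shows a NEW
#' deficit relative to it: a feature absent at baseline now has positive
#' evidence, or an objective cognitive item answered correctly at baseline is
#' now failed. With no prior session it is normal (flagged "no baseline").
#'
#' @param baseline A session summary ([latest_before()]) or `NULL`.
#' @param session The current (possibly partial) `ddst_session`.
#' @return A list with `item_id`, `value`, `source = "auto"`.
#' @export
derive_item22 <- function(baseline, session) {
  idx <- session$bank$index
  auto_id <- idx$auto_id
  res <- list(item_id = auto_id, value = "normal", source = "auto")
  if (is.null(baseline)) return(res)
  if (!inherits(baseline, "ddst_session_summary"))
    stop("history integrity error: baseline is not a session summary",
         call. = FALSE)
  # current evidence, excluding the auto item itself
  displayed <- setdiff(1:22, auto_id)
  pos_items <- displayed[!is.na(session$value[displayed]) &
                           session$value[displayed] == "positive"]
  current_present <- 1:4 %in% idx$item_feature[pos_items]
  new_feature <- any(current_present & !baseline$combo)
  cog <- intersect(cognitive_items(session$bank), pos_items)
  base_vals <- baseline$item_values[as.character(cog)]
  new_cog_deficit <- length(cog) > 0 &&
    any(is.na(base_vals) | base_vals == "normal")
  if (new_feature || new_cog_deficit) res$value <- "positive"
  res
}

#' Session administration metrics
#'
#' @param session A terminal `ddst_session`.
#' @return List with `items_administered`, `items_skipped`, `items_auto` and
#'   `duration` (minutes). The three counts always sum to 22.
#' @export
session_metrics <- function(session) {
  if (!session$terminal) stop("session is not terminal", call. = FALSE)
  dur <- if (is.null(session$ended)) NA_real_ else
    as.numeric(difftime(session$ended, session$started, units = "mins"))
  list(items_administered = sum(session$status == "entered"),
       items_skipped = sum(session$status == "skipped"),
       items_auto = sum(session$status == "auto"),
       duration = dur)
}

#' Drive a session to completion from a fixed answer vector
#'
#' Feeds the engine the latent answer for whichever item it asks for until
#' the session terminates. This is the bridge between the simulator (which
#' draws complete latent response vectors) and the adaptive engine (which
#' administers only a subset of them).
#'
#' @param session A freshly started `ddst_session`.
#' @param answers Character vector (`"normal"`/`"positive"`) indexed by item
#'   id, covering at least the displayed items 1..21; or a logical vector
#'   (`TRUE` = positive).
#' @return The terminal session.
#' @export
run_session <- function(session, answers) {
  if (is.logical(answers)) answers <- ifelse(answers, "positive", "normal")
  while (!session$terminal) {
    id <- next_item(session)
    if (is.na(id)) break
    session <- submit_response(session, id, answers[id],
                               time = session$started)
  }
  session
}

#' Ordered administration trace of a session
#'
#' @param session A `ddst_session`.
#' @return data.frame with one row per response event (entered, skipped or
#'   auto) in administration order.
#' @export
session_trace <- function(session) {
  data.frame(
    item_id = vapply(session$log, `[[`, integer(1), "item_id"),
    value = vapply(session$log, function(e) e$value %||% NA_character_,
                   character(1)),
    source = vapply(session$log, `[[`, character(1), "source"),
    stringsAsFactors = FALSE)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' @export
print.ddst_session <- function(x, ...) {
  cat("<ddst_session>", x$patient_id, "by", x$nurse_id,
      sprintf("[%s/%s]", x$modality, x$mode), "\n")
  if (x$terminal) {
    m <- session_metrics(x)
    cat("  terminal:", x$outcome$label, "\n")
    cat(sprintf("  administered %d, skipped %d, auto %d\n",
                m$items_administered, m$items_skipped, m$items_auto))
  } else {
    cat("  in progress; next item:", next_item(x), "\n")
  }
  invisible(x)
}
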