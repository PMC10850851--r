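# The four CAM diagnostic features. Order is canonical throughout the package:
# combos, outcome labels and evidence maps all index features in this order.
FEATURES <- c("F1", "F2", "F3", "F4")

FEATURE_LABELS <- c(
  F1 = "acute onset / fluctuating course",
  F2 = "inattention",
  F3 = "disorganized thinking",
  F4 = "altered level of consciousness"
)

#' CAM feature identifiers
#'
#' The Confusion Assessment Method rests on four features: F1 acute onset or
#' fluctuating course, F2 inattention, F3 disorganized thinking, F4 altered
#' level of consciousness. The diagnostic rule is
#' `F1 & F2 & (F3 | F4)`.
#'
#' @return Named character vector of length 4 (id -> human-readable label).
#' @export
#' @examples
#' cam_features()
cam_features <- function() FEATURE_LABELS

#' Construct the built-in 22-item instrument
#'
#' The default bank is a structural reconstruction of a 22-item, three-block
#' CAM operationalization: items 1-3 orientation tests (F3, reminders on 1
#' and 2), items 4-7 attention tests (F2, reminder on 5), items 8-10
#' patient-reported symptom probes (F1), items 11-13 observed altered
#' consciousness (F4), 14-17 observed disorganized thinking (F3), 18-20
#' observed inattention (F2) -- all of 11-20 carry interpretation cues --
#' item 21 observed fluctuation (F1) and item 22 the acute-change-from-baseline
#' comparison (F1), which is never displayed: it is derived automatically from
#' the patient's stored record. Items 1-21 are laid out on 8 pages.
#'
#' The wording shipped here is deliberately generic placeholder text; the
#' licensed instrument wording can be dropped in through a config file with
#' the same structure (see [load_item_bank()]).
#'
#' @return An object of class `ddst_item_bank`.
#' @export
#' @examples
#' bank <- default_item_bank()
#' bank
default_item_bank <- function() {
  it <- function(id, text, block, feature, page, reminder = NA_character_,
                 cue = NA_character_, auto = FALSE) {
    data.frame(id = id, text = text, block = block, feature = feature,
               page = page, reminder = reminder, cue = cue,
               auto_derived = auto, stringsAsFactors = FALSE)
  }
  items <- rbind(
    it(1L, "Orientation: what year is it?", "inquiry", "F3", 1L,
       reminder = "Correct response: the current year"),
    it(2L, "Orientation: what day of the week is it?", "inquiry", "F3", 1L,
       reminder = "Correct response: the current day of the week"),
    it(3L, "Orientation: what type of place is this?", "inquiry", "F3", 1L),
    it(4L, "Attention: repeat the digits 7-5-1 backward", "inquiry", "F2", 2L),
    it(5L, "Attention: repeat the digits 8-2-4-3 backward", "inquiry", "F2", 2L,
       reminder = "Correct response: 3-4-2-8"),
    it(6L, "Attention: name the days of the week backward", "inquiry", "F2", 3L),
    it(7L, "Attention: name the months of the year backward", "inquiry", "F2", 3L),
    it(8L, "Symptom probe: have you felt confused during the past day?",
       "inquiry", "F1", 4L),
    it(9L, "Symptom probe: did you think you were not in the hospital?",
       "inquiry", "F1", 4L),
    it(10L, "Symptom probe: did you see things that were not really there?",
       "inquiry", "F1", 4L),
    it(11L, "Observation: patient is sleepy or stuporous during assessment",
       "observation", "F4", 5L,
       cue = "Rate positive if the patient dozes off or is hard to arouse"),
    it(12L, "Observation: patient is hypervigilant", "observation", "F4", 5L,
       cue = "Rate positive for an inappropriately heightened startle/alertness"),
    it(13L, "Observation: level of consciousness is other than alert",
       "observation", "F4", 5L,
       cue = "Any state other than calm wakefulness counts as positive"),
    it(14L, "Observation: flow of ideas is unclear or illogical",
       "observation", "F3", 6L,
       cue = "Rambling, irrelevant or incoherent answers are positive"),
    it(15L, "Observation: conversation is rambling or off-target",
       "observation", "F3", 6L,
       cue = "Positive when the patient cannot keep to the question asked"),
    it(16L, "Observation: speech is unusually sparse or sparse-then-pressured",
       "observation", "F3", 6L,
       cue = "Marked poverty or pressure of speech is positive"),
    it(17L, "Observation: answers are internally inconsistent",
       "observation", "F3", 6L,
       cue = "Self-contradictory statements within the interview are positive"),
    it(18L, "Observation: patient has trouble keeping track of the questions",
       "observation", "F2", 7L,
       cue = "Needing repeated re-orienting to the task is positive"),
    it(19L, "Observation: patient is easily distracted by surroundings",
       "observation", "F2", 7L,
       cue = "Attention captured by irrelevant stimuli is positive"),
    it(20L, "Observation: patient's attention waxes and wanes",
       "observation", "F2", 7L,
       cue = "Fluctuating engagement with the interview is positive"),
    it(21L, "Selective: evidence of fluctuation during this assessment",
       "selective", "F1", 8L),
    it(22L, "Selective: acute change from the patient's baseline record",
       "selective", "F1", NA_integer_, auto = TRUE)
  )
  pages <- lapply(split(items$id[!items$auto_derived],
                        items$page[!items$auto_derived]),
                  as.integer)
  names(pages) <- NULL
  new_item_bank(items = items, pages = pages, version = "default-1.0")
}

new_item_bank <- function(items, pages, version) {
  bank <- structure(list(items = items, pages = pages, version = version),
                    class = "ddst_item_bank")
  validate_item_bank(bank)
  bank$index <- bank_index(bank)
  bank
}

# Precomputed lookups for the engine hot path; items are addressed by id
# (ids cover 1..22 after validation, so plain integer indexing is safe).
bank_index <- function(bank) {
  items <- bank$items[order(bank$items$id), ]
  feature_items <- lapply(FEATURES, function(f) items$id[items$feature == f])
  names(feature_items) <- FEATURES
  list(
    feature_items = feature_items,
    item_feature = match(items$feature, FEATURES),  # id -> feature index
    order = unlist(bank$pages, use.names = FALSE),
    auto_id = items$id[items$auto_derived],
    cognitive = items$id[items$block == "inquiry" &
                           items$feature %in% c("F2", "F3")]
  )
}

#' Validate an item bank
#'
#' Checks every structural invariant of the instrument: 22 uniquely numbered
#' items, reminders on items 1, 2 and 5, cues on items 11-20, item 22 the only
#' auto-derived item and absent from every page, 8 pages partitioning items
#' 1-21, and at least one evidence item per CAM feature.
#'
#' @param bank An object of class `ddst_item_bank`.
#' @return The bank, invisibly unchanged, or an error naming the first failing
#'   invariant.
#' @export
validate_item_bank <- function(bank) {
  stopifnot(inherits(bank, "ddst_item_bank"))
  items <- bank$items
  fail <- function(msg) stop("invalid item bank: ", msg, call. = FALSE)

  if (anyDuplicated(items$id)) fail("duplicate item ids")
  missing_ids <- setdiff(1:22, items$id)
  if (length(missing_ids))
    fail(paste("missing item", paste(missing_ids, collapse = ", ")))
  if (nrow(items) != 22L) fail("item ids must cover exactly 1..22")
  if (!all(items$block %in% c("inquiry", "observation", "selective")))
    fail("unknown block")
  if (!all(items$feature %in% FEATURES)) fail("unknown feature id")
  need_rem <- items$id %in% c(1L, 2L, 5L)
  if (any(is.na(items$reminder[need_rem]) | !nzchar(items$reminder[need_rem])))
    fail("items 1, 2 and 5 must carry a non-empty reminder")
  need_cue <- items$id %in% 11:20
  if (any(is.na(items$cue[need_cue]) | !nzchar(items$cue[need_cue])))
    fail("items 11 through 20 must carry a non-empty cue")
  if (!identical(items$id[items$auto_derived], 22L))
    fail("item 22, and only item 22, must be auto_derived")

  pages <- bank$pages
  if (length(pages) != 8L) fail("exactly 8 evaluation pages are required")
  paged <- unlist(pages, use.names = FALSE)
  if (anyDuplicated(paged)) fail("an item appears on more than one page")
  if (22L %in% paged) fail("item 22 must never appear on a page")
  if (!setequal(paged, 1:21)) fail("pages must cover items 1..21 exactly")
  for (f in FEATURES)
    if (!any(items$feature == f)) fail(paste("feature", f, "has no evidence item"))
  invisible(bank)
}

#' Load an instrument definition from a config file
#'
#' The config is a YAML or JSON document with top-level keys `version`,
#' `items` (a list of records with fields `id`, `text`, `block`, `feature`,
#' `page`, and optional `reminder`, `cue`, `auto_derived`) and `pages` (an
#' ordered list of integer item-id vectors). All item-bank invariants are
#' checked; with `path` omitted the built-in default bank is returned.
#'
#' @param path Path to a `.yaml`/`.yml`/`.json` config, or `NULL` for the
#'   default bank.
#' @return A validated `ddst_item_bank`.
#' @export
#' @examples
#' bank <- load_item_bank()          # built-in default
#' f <- tempfile(fileext = ".json")
#' write_item_bank(bank, f)
#' identical(load_item_bank(f)$items, bank$items)
load_item_bank <- function(path = NULL) {
  if (is.null(path)) return(default_item_bank())
  if (!file.exists(path)) stop("item bank config not found: ", path, call. = FALSE)
  raw <- if (grepl("\\.json$", path, ignore.case = TRUE)) {
    jsonlite::read_json(path, simplifyVector = FALSE)
  } else {
    yaml::read_yaml(path)
  }
  if (!all(c("version", "items", "pages") %in% names(raw)))
    stop("invalid item bank: config must have keys version, items, pages",
         call. = FALSE)
  field <- function(x, k, default) {
    v <- x[[k]]
    if (is.null(v)) default else v
  }
  items <- do.call(rbind, lapply(raw$items, function(x) {
    if (is.null(x$id) || is.null(x$text) || is.null(x$block) ||
        is.null(x$feature))
      stop("invalid item bank: every item needs id, text, block, feature",
           call. = FALSE)
    data.frame(
      id = as.integer(x$id), text = as.character(x$text),
      block = as.character(x$block), feature = as.character(x$feature),
      page = as.integer(field(x, "page", NA_integer_)),
      reminder = as.character(field(x, "reminder", NA_character_)),
      cue = as.character(field(x, "cue", NA_character_)),
      auto_derived = isTRUE(field(x, "auto_derived", FALSE)),
      stringsAsFactors = FALSE)
  }))
  pages <- lapply(raw$pages, function(p) as.integer(unlist(p)))
  new_item_bank(items = items, pages = pages,
                version = as.character(raw$version))
}

#' Serialize an item bank to a config file
#'
#' Writes the documented YAML/JSON schema; `load_item_bank()` on the result
#' round-trips to an identical bank.
#'
#' @param bank A `ddst_item_bank`.
#' @param path Output path; format chosen by extension (`.json` vs YAML).
#' @return `path`, invisibly.
#' @export
write_item_bank <- function(bank, path) {
  validate_item_bank(bank)
  drop_na <- function(x) x[!vapply(x, function(v) is.na(v) || (is.logical(v) && !v),
                                   logical(1))]
  items <- lapply(seq_len(nrow(bank$items)), function(i) {
    r <- bank$items[i, ]
    drop_na(list(id = r$id, text = r$text, block = r$block,
                 feature = r$feature, page = r$page, reminder = r$reminder,
                 cue = r$cue, auto_derived = r$auto_derived))
  })
  doc <- list(version = bank$version, items = items, pages = bank$pages)
  if (grepl("\\.json$", path, ignore.case = TRUE)) {
    jsonlite::write_json(doc, path, auto_unbox = TRUE, pretty = TRUE)
  } else {
    yaml::write_yaml(doc, path)
  }
  invisible(path)
}

#' Map CAM features to their evidence items
#'
#' @param bank A validated `ddst_item_bank`.
#' @return Named list `F1..F4`, each an integer vector of item ids; the four
#'   vectors partition the 22 items.
#' @export
#' @examples
#' feature_evidence_map(default_item_bank())$F1   # 8 9 10 21 22
feature_evidence_map <- function(bank) {
  validate_item_bank(bank)
  m <- lapply(FEATURES, function(f) bank$items$id[bank$items$feature == f])
  names(m) <- FEATURES
  m
}

# Items whose positive value means an error on an objective cognitive test;
# these drive the item-by-item branch of the baseline comparison (item 22).
cognitive_items <- function(bank) {
  if (!is.null(bank$index)) return(bank$index$cognitive)
  sort(bank$items$id[bank$items$block == "inquiry" &
                       bank$items$feature %in% c("F2", "F3")])
}

# Displayed items in administration (page) order.
page_order <- function(bank) {
  if (!is.null(bank$index)) return(bank$index$order)
  unlist(bank$pages, use.names = FALSE)
}

#' @export
print.ddst_item_bank <- function(x, ...) {
  cat("<ddst_item_bank> version", x$version, "\n")
  cat(sprintf("  %d items (%d displayed on %d pages, %d auto-derived)\n",
              nrow(x$items), sum(!x$items$auto_derived), length(x$pages),
              sum(x$items$auto_derived)))
  tab <- table(factor(x$items$feature, levels = FEATURES))
  cat("  evidence items per feature:",
      paste(sprintf("%s=%d", names(tab), tab), collapse = ", "), "\n")
  invisible(x)
}
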