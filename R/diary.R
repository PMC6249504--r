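#' Default purchase-location taxonomy
#'
#' Where a food was sourced, tagged on every diary entry so the
#' contribution of foods prepared outside the home can be analysed. The
#' published categories (cafes, bars, restaurants, fast-food outlets,
#' takeout shops, other food outlets) are extended with `home` and kept as
#' configuration.
#'
#' @return Character vector of location codes.
#' @export
location_taxonomy <- function() {
  c("home", "fast_food_chain", "cafe", "restaurant", "takeout", "bar", "other")
}

#' Logging day of a timestamp
#'
#' The diary day does not roll over at midnight but at 3 a.m. local time,
#' so late-night eating occasions attach to the evening they belong to and
#' participants cannot retrospectively edit a day once it has closed.
#' Times at or after 03:00 map to their own calendar date; times before
#' 03:00 map to the previous date.
#'
#' @param timestamp `POSIXct` vector (participant-local clock).
#' @return `Date` vector of logging days.
#' @export
#' @examples
#' logging_day(as.POSIXct("2018-01-02 02:59:00", tz = "UTC"))  # 2018-01-01
#' logging_day(as.POSIXct("2018-01-02 03:00:00", tz = "UTC"))  # 2018-01-02
logging_day <- function(timestamp) {
  stopifnot(inherits(timestamp, "POSIXt"))
  lt <- as.POSIXlt(timestamp)
  as.Date(lt) - (lt$hour < 3)
}

#' Create an empty diary store
#'
#' The diary is an append-only event log: every accepted entry is kept
#' verbatim with its server receipt time, and nothing is ever rewritten.
#'
#' @return A `diary_store`.
#' @export
diary_store <- function() {
  structure(list(entries = tibble(
    participant_id = character(0),
    timestamp = as.POSIXct(character(0), tz = "UTC"),
    food_ref = character(0),
    is_manual = logical(0),
    amount = numeric(0),
    unit = character(0),
    location = character(0),
    meal_slot = character(0),
    received_at = as.POSIXct(character(0), tz = "UTC"),
    logging_day = as.Date(character(0))
  )), class = "diary_store")
}

#' @export
print.diary_store <- function(x, ...) {
  cat(sprintf("<diary_store> %d entries, %d participant(s), %d manual\n",
              nrow(x$entries), length(unique(x$entries$participant_id)),
              sum(x$entries$is_manual)))
  invisible(x)
}

#' Construct a diary entry
#'
#' One logged consumption event. The amount is a count of the chosen unit
#' (e.g. `amount = 1`, `unit = "600 mL bottle"`), which is what prevents
#' the classic 600 x 600 mL double-entry error. Foods missing from the
#' database are entered as free text with `is_manual = TRUE`, flagging them
#' for researcher follow-up.
#'
#' @param participant_id Participant identifier.
#' @param timestamp `POSIXct` consumption time (local clock).
#' @param food_ref Food ID, or free text when `is_manual`.
#' @param amount Positive number of units consumed.
#' @param unit One of the food's portion labels, or `"g"`/`"mL"`.
#' @param location One of [location_taxonomy()] (or `taxonomy`).
#' @param is_manual Whether `food_ref` is free text rather than a food ID.
#' @param meal_slot Optional meal label (`"breakfast"`, ...).
#' @param taxonomy Permitted location codes.
#' @return One-row entry tibble.
#' @export
diary_entry <- function(participant_id, timestamp, food_ref, amount, unit,
                        location, is_manual = FALSE, meal_slot = NA_character_,
                        taxonomy = location_taxonomy()) {
  stopifnot(inherits(timestamp, "POSIXt"))
  if (!is.numeric(amount) || length(amount) != 1 || is.na(amount) || amount <= 0) {
    abort("amount must be a single positive number")
  }
  if (!location %in% taxonomy) {
    abort(sprintf("location '%s' not in the configured taxonomy (%s)",
                  location, paste(taxonomy, collapse = ", ")))
  }
  tibble(
    participant_id = participant_id,
    timestamp = as.POSIXct(timestamp),
    food_ref = food_ref,
    is_manual = isTRUE(is_manual),
    amount = amount,
    unit = unit,
    location = location,
    meal_slot = meal_slot
  )
}

#' Append an entry to the diary
#'
#' Entries are accepted only for the current logging day: once the 3 a.m.
#' boundary has passed, the previous day is closed and an entry timestamped
#' inside it is rejected (the error condition carries both logging days).
#' Accepted entries are appended with the receipt time; previously accepted
#' entries are never modified.
#'
#' @param store A [diary_store()].
#' @param entry A [diary_entry()].
#' @param now Current `POSIXct` time (receipt time).
#' @return The updated store.
#' @export
add_entry <- function(store, entry, now) {
  stopifnot(inherits(store, "diary_store"), inherits(now, "POSIXt"))
  entry_day <- logging_day(entry$timestamp)
  current_day <- logging_day(now)
  if (entry_day < current_day) {
    abort(
      sprintf("retrospective entry rejected: entry logging day %s precedes current logging day %s",
              format(entry_day), format(current_day)),
      class = "eatkit_retrospective_entry",
      entry_day = entry_day, current_day = current_day
    )
  }
  entry$received_at <- as.POSIXct(now)
  entry$logging_day <- entry_day
  store$entries <- bind_rows(store$entries, entry)
  store
}

#' Recently used foods
#'
#' The history list shown before a participant types a query: their
#' distinct recently logged foods, most recent first, deduplicated by food
#' reference (an entry re-logging a food moves it to the front).
#'
#' @param store A [diary_store()].
#' @param participant_id Participant to list history for.
#' @param n Maximum list length (>= 1).
#' @return Character vector of food references, length <= `n`.
#' @export
diary_history <- function(store, participant_id, n = 10L) {
  if (!is_count(n) || n < 1) abort("n must be >= 1")
  e <- store$entries[store$entries$participant_id == participant_id, ]
  refs <- rev(e$food_ref[order(e$timestamp)])
  utils::head(unique(refs), n)
}

#' Manual entries awaiting researcher review
#'
#' Foods a participant could not find and typed in manually are flagged to
#' the research team for follow-up; this returns exactly those entries, in
#' time order.
#'
#' @param store A [diary_store()].
#' @return Tibble of manual entries.
#' @export
manual_review_queue <- function(store) {
  q <- store$entries[store$entries$is_manual, ]
  q[order(q$timestamp), ]
}

#' Write / read the diary event log
#'
#' The store persists as JSON-lines, one accepted event per line in accept
#' order, matching the append-only contract.
#'
#' @param store A [diary_store()].
#' @param path File path.
#' @return `write_diary_log()`: `path` invisibly; `read_diary_log()`: the
#'   reconstructed store.
#' @export
write_diary_log <- function(store, path) {
  e <- store$entries
  lines <- vapply(seq_len(nrow(e)), function(i) {
    row <- as.list(e[i, ])
    row$timestamp <- format(row$timestamp, "%Y-%m-%dT%H:%M:%S", tz = "UTC")
    row$received_at <- format(row$received_at, "%Y-%m-%dT%H:%M:%S", tz = "UTC")
    row$logging_day <- format(row$logging_day)
    jsonlite::toJSON(row, auto_unbox = TRUE, na = "null")
  }, character(1))
  writeLines(lines, path)
  invisible(path)
}

#' @rdname write_diary_log
#' @export
read_diary_log <- function(path) {
  store <- diary_store()
  lines <- readLines(path)
  if (!length(lines)) return(store)
  rows <- lapply(lines, function(l) {
    row <- jsonlite::fromJSON(l)
    row$timestamp <- as.POSIXct(row$timestamp, format = "%Y-%m-%dT%H:%M:%S", tz = "UTC")
    row$received_at <- as.POSIXct(row$received_at, format = "%Y-%m-%dT%H:%M:%S", tz = "UTC")
    row$logging_day <- as.Date(row$logging_day)
    row$meal_slot <- row$meal_slot %||% NA_character_
    as_tibble(row)
  })
  store$entries <- bind_rows(rows)
  store
}

#' Score a System Usability Scale response
#'
#' Standard SUS arithmetic over the ten five-point items: odd-numbered
#' (positively worded) items contribute `score - 1`, even-numbered
#' (negatively worded) items contribute `5 - score`, and the sum is scaled
#' by 2.5 onto 0 (very difficult to use) to 100 (very easy to use).
#'
#' @param response Numeric vector of 10 integer item scores in 1..5.
#' @return SUS score in \[0, 100\].
#' @export
#' @examples
#' sus_score(rep(3, 10))          # 50
#' sus_score(rep(c(5, 1), 5))     # 100
sus_score <- function(response) {
  if (length(response) != 10 || anyNA(response) ||
      any(response < 1 | response > 5 | response != floor(response))) {
    abort("a SUS response is 10 integer item scores, each in 1..5")
  }
  odd <- response[c(1, 3, 5, 7, 9)]
  even <- response[c(2, 4, 6, 8, 10)]
  (sum(odd - 1) + sum(5 - even)) * 2.5
}

#' Summarise SUS responses
#'
#' Mean (reported rounded to the nearest integer, the questionnaire's usual
#' reporting convention), range, and how many respondents scored above the
#' average-usability threshold (68 by convention, configurable).
#'
#' @param responses List of 10-item response vectors, or a matrix/data
#'   frame with one response per row.
#' @param threshold Score above which usability counts as above average.
#' @return Tibble with `n`, `mean_score` (rounded), `mean_raw`, `min`,
#'   `max`, `n_above_threshold`, `threshold`.
#' @export
sus_summary <- function(responses, threshold = 68) {
  if (is.matrix(responses) || is.data.frame(responses)) {
    responses <- lapply(seq_len(nrow(responses)), function(i) as.numeric(responses[i, ]))
  }
  if (!length(responses)) abort("usage error: at least one SUS response is required")
  scores <- vapply(responses, sus_score, numeric(1))
  tibble(
    n = length(scores),
    mean_score = round(mean(scores)),
    mean_raw = mean(scores),
    min = min(scores),
    max = max(scores),
    n_above_threshold = sum(scores > threshold),
    threshold = threshold
  )
}
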