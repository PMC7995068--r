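# Deck and schedule serialisation ------------------------------------------
#
# Canonical deck format is JSON with a nested activity list per profile; a
# flat CSV dialect (one row per activity) is also accepted.  Round-trips are
# field-for-field identities, asserted in the tests.

#' Write a deck to JSON or flat CSV
#'
#' @param deck an `ed_deck`.
#' @param path output path; format chosen by extension (`.json` or `.csv`).
#' @return `path`, invisibly.
#' @export
write_deck <- function(deck, path) {
  validate_deck(deck)
  if (grepl("\\.json$", path, ignore.case = TRUE)) {
    recs <- lapply(seq_len(nrow(deck$profiles)), function(i) {
      p <- deck$profiles[i, ]
      a <- deck$activities[deck$activities$profile_id == p$profile_id, ,
                           drop = FALSE]
      list(
        profile_id = p$profile_id,
        urgent = p$urgent,
        priority_class = p$priority_class,
        sbar_note = p$sbar_note,
        activities = lapply(seq_len(nrow(a)), function(j) list(
          activity_id = a$activity_id[j],
          planned_rounds = a$planned_rounds[j],
          required_doctors = a$required_doctors[j],
          required_nurses = a$required_nurses[j]
        ))
      )
    })
    jsonlite::write_json(recs, path, auto_unbox = TRUE, pretty = TRUE)
  } else if (grepl("\\.csv$", path, ignore.case = TRUE)) {
    flat <- merge(deck$activities,
                  deck$profiles[, c("profile_id", "urgent", "priority_class")],
                  by = "profile_id", sort = FALSE)
    flat <- flat[, c("profile_id", "urgent", "priority_class", "activity_id",
                     "planned_rounds", "required_doctors", "required_nurses")]
    utils::write.csv(flat, path, row.names = FALSE)
  } else {
    ed_stop("unsupported deck format (use .json or .csv): ", path)
  }
  invisible(path)
}

#' Read a deck from JSON or flat CSV
#'
#' Invariants (unique ids, non-empty plans) are re-validated on read, so a
#' malformed file fails loudly with the offending record named.
#'
#' @param path input path written by [write_deck()] (or hand-authored).
#' @return An `ed_deck`.
#' @export
read_deck <- function(path) {
  if (!file.exists(path)) ed_stop("deck file not found: ", path)
  if (file.size(path) == 0L) ed_stop("deck file is empty: ", path)
  if (grepl("\\.json$", path, ignore.case = TRUE)) {
    recs <- jsonlite::read_json(path, simplifyVector = FALSE)
    if (length(recs) == 0L) ed_stop("deck file holds no profiles: ", path)
    prof <- do.call(rbind, lapply(recs, function(r) {
      for (f in c("profile_id", "urgent", "priority_class", "activities")) {
        if (is.null(r[[f]])) {
          ed_stop("deck record missing field `", f, "` (profile ",
                  r$profile_id %||% "<unknown>", ")")
        }
      }
      data.frame(profile_id = r$profile_id, urgent = isTRUE(r$urgent),
                 priority_class = as.integer(r$priority_class),
                 sbar_note = r$sbar_note %||% "",
                 stringsAsFactors = FALSE)
    }))
    acts <- do.call(rbind, lapply(recs, function(r) {
      if (length(r$activities) == 0L) {
        ed_stop("profile ", r$profile_id, " has an empty activity plan")
      }
      do.call(rbind, lapply(r$activities, function(a) data.frame(
        profile_id = r$profile_id,
        activity_id = a$activity_id,
        planned_rounds = as.integer(a$planned_rounds),
        required_doctors = as.integer(a$required_doctors),
        required_nurses = as.integer(a$required_nurses),
        stringsAsFactors = FALSE
      )))
    }))
    validate_deck(structure(list(profiles = prof, activities = acts),
                            class = "ed_deck"))
  } else if (grepl("\\.csv$", path, ignore.case = TRUE)) {
    flat <- utils::read.csv(path, stringsAsFactors = FALSE)
    need <- c("profile_id", "urgent", "priority_class", "activity_id",
              "planned_rounds", "required_doctors", "required_nurses")
    if (!all(need %in% names(flat))) {
      ed_stop("flat deck CSV missing columns: ",
              paste(setdiff(need, names(flat)), collapse = ", "))
    }
    if (nrow(flat) == 0L) ed_stop("deck file holds no profiles: ", path)
    first <- !duplicated(flat$profile_id)
    prof <- data.frame(
      profile_id = flat$profile_id[first],
      urgent = as.logical(flat$urgent[first]),
      priority_class = as.integer(flat$priority_class[first]),
      sbar_note = "",
      stringsAsFactors = FALSE
    )
    acts <- flat[, c("profile_id", "activity_id", "planned_rounds",
                     "required_doctors", "required_nurses")]
    validate_deck(structure(list(profiles = prof, activities = acts),
                            class = "ed_deck"))
  } else {
    ed_stop("unsupported deck format (use .json or .csv): ", path)
  }
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Write / read an arrival schedule (CSV columns round, profile_id)
#'
#' @param schedule an `ed_schedule` data.frame.
#' @param path CSV path.
#' @return `path` / the schedule.
#' @export
write_arrivals <- function(schedule, path) {
  validate_schedule(schedule)
  utils::write.csv(as.data.frame(schedule)[, c("round", "profile_id")],
                   path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_arrivals
#' @export
read_arrivals <- function(path) {
  if (!file.exists(path)) ed_stop("schedule file not found: ", path)
  df <- utils::read.csv(path, stringsAsFactors = FALSE,
                        colClasses = c(round = "integer",
                                       profile_id = "character"))
  validate_schedule(df)
  structure(df, class = c("ed_schedule", "data.frame"))
}
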