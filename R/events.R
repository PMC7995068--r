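# Telemetry event log --------------------------------------------------------
#
# One GameEvent per row.  The log is the single source of truth for scoring
# and behavior coding, so it must be self-describing: the red-module identity
# and schema version travel with it (JSONL header record on disk, attributes
# in memory).

EVENT_TYPES <- c(
  "round_start", "arrival", "triage_refer_out", "triage_admit", "triage_wait",
  "assign_module", "allocate_staff", "edit_profile", "broadcast_invite",
  "activity_tick", "activity_complete", "discharge", "scoring_update",
  "rule_enforcement"
)

INDICATORS <- c("PT", "AE", "RM", "PR")

event_log_columns <- function() {
  data.frame(
    seq = integer(), round = integer(), actor_role = character(),
    event_type = character(), profile_id = character(),
    module_id = character(), indicator = character(), delta = numeric(),
    planned_rounds = integer(), actual_rounds = integer(), note = character(),
    stringsAsFactors = FALSE
  )
}

new_event_log <- function(events, red_module) {
  df <- if (length(events)) {
    do.call(rbind, events)
  } else {
    event_log_columns()
  }
  df$seq <- seq_len(nrow(df))
  rownames(df) <- NULL
  structure(df, red_module = red_module, schema = "edgame-events-1",
            class = c("ed_event_log", "data.frame"))
}

validate_event_log <- function(log) {
  if (!inherits(log, "ed_event_log")) ed_stop("not an ed_event_log")
  bad <- setdiff(unique(log$event_type), EVENT_TYPES)
  if (length(bad)) {
    lines <- which(log$event_type %in% bad)
    ed_stop("unknown event_type ", paste(bad, collapse = ", "),
            " at record(s) ", paste(utils::head(lines, 5), collapse = ", "))
  }
  if (nrow(log) > 1 && is.unsorted(log$round)) {
    ed_stop("event rounds are not monotone non-decreasing")
  }
  su <- log[log$event_type == "scoring_update", ]
  if (nrow(su) && !all(su$indicator %in% INDICATORS)) {
    ed_stop("scoring_update events must carry exactly one indicator in ",
            paste(INDICATORS, collapse = "/"))
  }
  invisible(log)
}

#' Write an event log as JSON Lines
#'
#' First line is a schema header (`schema`, `red_module`); every following
#' line is one event object with `NA` fields omitted.  Serialisation is
#' canonical, so identical logs produce byte-identical files.
#'
#' @param log an `ed_event_log` from [run_session()].
#' @param path output `.jsonl` path.
#' @return `path`, invisibly.
#' @export
write_event_log <- function(log, path) {
  validate_event_log(log)
  con <- file(path, open = "wb")  # binary: fixed "\n", no CRLF surprises
  on.exit(close(con))
  header <- jsonlite::toJSON(
    list(schema = attr(log, "schema"), red_module = attr(log, "red_module")),
    auto_unbox = TRUE)
  writeLines(header, con, sep = "\n")
  for (i in seq_len(nrow(log))) {
    row <- as.list(log[i, ])
    row <- row[!vapply(row, function(v) is.na(v), logical(1))]
    writeLines(jsonlite::toJSON(row, auto_unbox = TRUE, digits = NA),
               con, sep = "\n")
  }
  invisible(path)
}

#' Read a JSON Lines event log
#'
#' @param path `.jsonl` path written by [write_event_log()].
#' @return An `ed_event_log`.
#' @export
read_event_log <- function(path) {
  if (!file.exists(path)) ed_stop("event log not found: ", path)
  lines <- readLines(path)
  if (!length(lines)) ed_stop("event log is empty: ", path)
  header <- tryCatch(jsonlite::fromJSON(lines[1]),
                     error = function(e) ed_stop("malformed header line 1: ",
                                                 conditionMessage(e)))
  if (is.null(header$schema) || header$schema != "edgame-events-1") {
    ed_stop("unsupported event-log schema: ",
            header$schema %||% "<missing>")
  }
  tmpl <- event_log_columns()
  events <- vector("list", length(lines) - 1L)
  for (i in seq_along(events)) {
    rec <- tryCatch(jsonlite::fromJSON(lines[i + 1L]),
                    error = function(e) ed_stop("malformed event at line ",
                                                i + 1L, ": ",
                                                conditionMessage(e)))
    row <- tmpl[0, ]
    row[1, ] <- NA
    for (f in names(rec)) {
      if (f %in% names(tmpl)) row[[f]] <- rec[[f]]
    }
    events[[i]] <- row
  }
  log <- new_event_log(events, red_module = header$red_module)
  validate_event_log(log)
  log
}

#' @export
print.ed_event_log <- function(x, ...) {
  cat(sprintf("<ed_event_log> %d events over %d rounds (red module: %s)\n",
              nrow(x), if (nrow(x)) max(x$round) else 0L,
              attr(x, "red_module")))
  tab <- table(x$event_type)
  if (length(tab)) print(tab)
  invisible(x)
}
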