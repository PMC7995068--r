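# Participatory behavior coding ---------------------------------------------
#
# Transcribes telemetry into per-player behavior sequences.  Behavior codes:
#   MR  managing resources (staff allocation / coordination)
#   EP  editing profiles (titles, tags, classifications)
#   IC  inviting cooperation (sharing with the team)
#   FT  finishing tasks (confirmed decision results)
# Stimulus codes: a scoring announcement is coded as RA (receiving update)
# followed by the indicator itself (PT / AE / RM / PR), modelling the point
# system informing the player as the start of a behavior chain.

BEHAVIOR_CODES <- c("MR", "EP", "IC", "FT")
STIMULUS_CODES <- c("RA", "PT", "AE", "RM", "PR")

#' Default event-to-code map
#'
#' Events not listed are explicitly uncoded (round markers, arrivals, waits,
#' ticks, rule enforcement).  Triage admit/refer decisions are coded FT: they
#' are confirmed decision results of the triage role.
#'
#' @return Named character vector, event_type -> behavior code.
#' @export
default_coding_map <- function() {
  c(allocate_staff = "MR",
    edit_profile = "EP",
    broadcast_invite = "IC",
    activity_complete = "FT",
    discharge = "FT",
    triage_admit = "FT",
    triage_refer_out = "FT")
}

#' Code an event log into per-player behavior sequences
#'
#' @param log an `ed_event_log` (or `.jsonl` path).
#' @param map event_type -> code map, see [default_coding_map()].
#' @param include_stimuli if TRUE (default) scoring updates enter the stream
#'   as an RA element followed by the indicator code; if FALSE the sequences
#'   hold behavior codes only.
#' @return A named list of `ed_coded_sequence` data.frames (player_id,
#'   ordinal, round, code), one per player role seen in the log, in stable
#'   role order.
#' @export
code_events <- function(log, map = default_coding_map(),
                        include_stimuli = TRUE) {
  if (is.character(log)) log <- read_event_log(log)
  validate_event_log(log)
  unknown <- setdiff(names(map), EVENT_TYPES)
  if (length(unknown)) {
    ed_stop("coding map names unknown event types: ",
            paste(unknown, collapse = ", "))
  }
  roles <- unique(log$actor_role)
  roles <- roles[order(roles != "triage", roles)]  # triage first, then modules
  out <- lapply(roles, function(role) {
    sub <- log[log$actor_role == role, , drop = FALSE]
    codes <- character(0)
    rounds <- integer(0)
    for (i in seq_len(nrow(sub))) {
      et <- sub$event_type[i]
      if (et == "scoring_update") {
        if (include_stimuli) {
          codes <- c(codes, "RA", sub$indicator[i])
          rounds <- c(rounds, sub$round[i], sub$round[i])
        }
      } else if (!is.na(map[et])) {
        codes <- c(codes, unname(map[et]))
        rounds <- c(rounds, sub$round[i])
      }
    }
    structure(
      data.frame(player_id = rep(role, length(codes)),
                 ordinal = seq_along(codes), round = rounds, code = codes,
                 stringsAsFactors = FALSE),
      class = c("ed_coded_sequence", "data.frame")
    )
  })
  stats::setNames(out, roles)
}

#' Write coded sequences as long CSV (player_id, ordinal, round, code)
#'
#' @param sequences list of coded sequences from [code_events()].
#' @param path CSV path.
#' @return `path` / named list of sequences.
#' @export
write_sequences <- function(sequences, path) {
  df <- do.call(rbind, lapply(sequences, as.data.frame))
  rownames(df) <- NULL
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_sequences
#' @export
read_sequences <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("player_id", "ordinal", "round", "code")
  if (!all(need %in% names(df))) {
    ed_stop("sequence CSV missing columns: ",
            paste(setdiff(need, names(df)), collapse = ", "))
  }
  split_df <- split(df, df$player_id)
  lapply(split_df, function(s) {
    s <- s[order(s$ordinal), need]
    rownames(s) <- NULL
    structure(s, class = c("ed_coded_sequence", "data.frame"))
  })
}

#' Learning-engagement attributes of one player
#'
#' The engagement proxies: per-behavior counts (tasks addressed: resource
#' allocations, profile edits, cooperation invites; tasks finished), a
#' time-on-task proxy (rounds with at least one behavior, converted to
#' minutes), and logistical performance (the role's total tokens for the
#' session).
#'
#' @param sequence an `ed_coded_sequence` for one player.
#' @param ledger the session `ed_ledger` (same session as the sequence).
#' @param minutes_per_round simulated minutes per round.
#' @return One-row data.frame: player_id, n_MR, n_EP, n_IC, n_FT,
#'   time_on_task, performance.
#' @export
engagement_attributes <- function(sequence, ledger, minutes_per_round = 30L) {
  stopifnot(inherits(sequence, "ed_coded_sequence"))
  player <- unique(sequence$player_id)
  if (length(player) > 1L) {
    ed_stop("sequence mixes players: ", paste(player, collapse = ", "))
  }
  beh <- sequence[sequence$code %in% BEHAVIOR_CODES, , drop = FALSE]
  counts <- vapply(BEHAVIOR_CODES, function(cd) sum(beh$code == cd),
                   integer(1))
  perf <- if (length(player) == 1L) {
    tot <- ledger_totals(ledger)[[player]]
    if (is.null(tot)) 0 else tot
  } else 0
  data.frame(
    player_id = if (length(player)) player else NA_character_,
    n_MR = counts[["MR"]], n_EP = counts[["EP"]], n_IC = counts[["IC"]],
    n_FT = counts[["FT"]],
    time_on_task = length(unique(beh$round)) * minutes_per_round,
    performance = perf,
    stringsAsFactors = FALSE
  )
}
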