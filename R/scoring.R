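# Token scoring --------------------------------------------------------------
#
# Pure functions of the event log.  apply_scoring() recomputes every delta
# from the rules plus the causal event; deltas stored on scoring_update
# telemetry are never trusted.  Conditions that exist only as state snapshots
# (a required staff member absent, zero free doctors at round end) enter the
# log as scoring_update events whose *occurrence* is causal; their deltas are
# still recomputed here.

#' Production-throughput deltas for one discharge
#'
#' A discharge credits the discharging module its throughput reward and the
#' triage role a quarter share of that reward.  With default rules: red
#' discharge gives the red role +16 and triage +4; a normal discharge gives
#' the module +4 and triage +1.
#'
#' @param module_role actor id of the discharging module.
#' @param is_red whether that module is the red (urgent) module.
#' @param rules an [scoring_rules()] object.
#' @return data.frame of ledger deltas (role, indicator, delta).
#' @export
score_throughput <- function(module_role, is_red, rules = scoring_rules()) {
  reward <- unname(rules$throughput_reward[if (is_red) "red" else "normal"])
  share <- reward * rules$triage_share
  # integer share under default rules; a fractional share rounds half away
  # from zero so the triage role is never short-changed by banker's rounding
  share <- sign(share) * floor(abs(share) + 0.5)
  data.frame(
    role = c(module_role, "triage"),
    indicator = "PT",
    delta = c(reward, share),
    stringsAsFactors = FALSE
  )
}

#' Triage rejection penalty
#'
#' Referring patients out of the ED costs the triage role tokens: -1 per two
#' rejections (cumulative over the session, floor rule).
#'
#' @param rejection_count non-negative total referrals out.
#' @param rules an [scoring_rules()] object.
#' @return A single (negative or zero) token delta.
#' @export
score_rejections <- function(rejection_count, rules = scoring_rules()) {
  assert_scalar_number(rejection_count, "rejection_count", lower = 0,
                       integer = TRUE)
  rules$rejection_penalty * (rejection_count %/% rules$rejection_unit)
}

#' Activity-execution delay penalty
#'
#' Compares the realised duration of an activity with its plan.  The delay
#' fraction `(actual - planned) / planned` selects a penalty bucket: the
#' largest threshold not exceeding the delay.  Delays under the first
#' threshold (25%) cost nothing; delays beyond 100% cap at the last bucket.
#' Triage has no activity plan, hence no penalty.  Early completion is a
#' validation error: the mechanic penalises delay only.
#'
#' @param planned_rounds,actual_rounds plan and realisation, in rounds.
#' @param role_class `"red"`, `"normal"` or `"triage"`.
#' @param rules an [scoring_rules()] object.
#' @return A token delta (0 or negative).
#' @export
score_activity_execution <- function(planned_rounds, actual_rounds,
                                     role_class = c("normal", "red", "triage"),
                                     rules = scoring_rules()) {
  role_class <- match.arg(role_class)
  assert_scalar_number(planned_rounds, "planned_rounds", lower = 1,
                       integer = TRUE)
  assert_scalar_number(actual_rounds, "actual_rounds", lower = 1,
                       integer = TRUE)
  if (actual_rounds < planned_rounds) {
    ed_stop("actual_rounds < planned_rounds: early completion carries no bonus")
  }
  if (role_class == "triage") return(0)
  delay <- (actual_rounds - planned_rounds) / planned_rounds
  bucket <- findInterval(delay + 1e-12, rules$ae_thresholds)
  bucket <- min(bucket, length(rules$ae_thresholds))
  if (bucket == 0L) 0 else rules$ae_penalty[[role_class]][bucket]
}

#' Resource-management penalty
#'
#' Charged once per (activity, round) in which a required staff member is
#' absent from an active activity, or the triage post is unstaffed.
#'
#' @param role_class `"red"`, `"normal"` or `"triage"`.
#' @param rules an [scoring_rules()] object.
#' @return A negative token delta.
#' @export
score_resource_management <- function(role_class = c("normal", "red", "triage"),
                                      rules = scoring_rules()) {
  role_class <- match.arg(role_class)
  unname(rules$rm_penalty[role_class])
}

#' Production-resilience penalty
#'
#' Evaluated once per module per round on the count of free (unallocated)
#' doctors at round end: zero free doctors means the module has no slack to
#' absorb a surge, and the role is penalised.  Triage is exempt.
#'
#' @param free_doctors free doctors in the module at round end.
#' @param role_class `"red"` or `"normal"` (`"triage"` returns 0).
#' @param rules an [scoring_rules()] object.
#' @return A token delta (0 or negative).
#' @export
score_resilience <- function(free_doctors,
                             role_class = c("normal", "red", "triage"),
                             rules = scoring_rules()) {
  role_class <- match.arg(role_class)
  assert_scalar_number(free_doctors, "free_doctors", lower = 0, integer = TRUE)
  if (role_class == "triage" || free_doctors > 0) return(0)
  unname(rules$pr_penalty[role_class])
}

#' Score a complete event log into a token ledger
#'
#' Deterministic and idempotent: rerunning on the same log gives the same
#' ledger.  Sources per indicator:
#' * PT — recomputed from `discharge` events (module reward + triage quarter
#'   share) and from `triage_refer_out` events (cumulative -1 per 2).
#' * AE — recomputed from `activity_complete` events, which carry the planned
#'   and realised durations.
#' * RM / PR — taken from `scoring_update` occurrence records flagging the
#'   staffing condition; the delta is recomputed from the rules.
#'
#' @param log an `ed_event_log` (or a path to a `.jsonl` log).
#' @param rules an [scoring_rules()] object.
#' @return An `ed_ledger`: data.frame (role, round, indicator, delta, source
#'   event seq) with per-role totals in `attr(, "totals")`.
#' @export
apply_scoring <- function(log, rules = scoring_rules()) {
  if (is.character(log)) log <- read_event_log(log)
  validate_event_log(log)
  red <- attr(log, "red_module")
  entries <- list()
  k <- 0L
  add <- function(role, round, indicator, delta, seq) {
    k <<- k + 1L
    entries[[k]] <<- data.frame(role = role, round = round,
                                indicator = indicator, delta = delta,
                                seq = seq, stringsAsFactors = FALSE)
  }
  rejections <- 0L
  charged <- 0L
  known <- character(0)
  for (i in seq_len(nrow(log))) {
    ev <- log[i, ]
    switch(
      ev$event_type,
      arrival = { known <- c(known, ev$profile_id) },
      discharge = {
        if (!is.na(ev$profile_id) && length(known) &&
            !(ev$profile_id %in% known)) {
          ed_stop("discharge of unknown patient ", ev$profile_id,
                  " at record ", ev$seq)
        }
        is_red <- identical(ev$module_id, red)
        d <- score_throughput(ev$module_id, is_red, rules)
        add(d$role[1], ev$round, "PT", d$delta[1], ev$seq)
        add("triage", ev$round, "PT", d$delta[2], ev$seq)
      },
      triage_refer_out = {
        rejections <- rejections + 1L
        due <- score_rejections(rejections, rules)
        if (due != charged) {
          add("triage", ev$round, "PT", due - charged, ev$seq)
          charged <- due
        }
      },
      activity_complete = {
        rc <- role_class(ev$actor_role, red)
        delta <- score_activity_execution(ev$planned_rounds, ev$actual_rounds,
                                          rc, rules)
        if (delta != 0) add(ev$actor_role, ev$round, "AE", delta, ev$seq)
      },
      scoring_update = {
        rc <- role_class(ev$actor_role, red)
        if (ev$indicator == "RM") {
          add(ev$actor_role, ev$round, "RM",
              score_resource_management(rc, rules), ev$seq)
        } else if (ev$indicator == "PR") {
          add(ev$actor_role, ev$round, "PR",
              score_resilience(0L, rc, rules), ev$seq)
        }
        # PT / AE scoring_update records are display telemetry; their causal
        # events (discharge, activity_complete) are scored above.
      },
      NULL
    )
  }
  ledger <- if (k) do.call(rbind, entries) else
    data.frame(role = character(), round = integer(), indicator = character(),
               delta = numeric(), seq = integer(), stringsAsFactors = FALSE)
  rownames(ledger) <- NULL
  totals <- tapply(ledger$delta, ledger$role, sum)
  structure(ledger, totals = as.list(totals),
            class = c("ed_ledger", "data.frame"))
}

#' Per-role token totals of a ledger
#'
#' @param ledger an `ed_ledger`.
#' @return Named list of per-role totals.
#' @export
ledger_totals <- function(ledger) {
  stopifnot(inherits(ledger, "ed_ledger"))
  attr(ledger, "totals")
}

#' Write a ledger as CSV (role, round, indicator, delta, total)
#'
#' `total` is the role's running total after each delta.
#'
#' @param ledger an `ed_ledger`.
#' @param path CSV path.
#' @return `path`, invisibly.
#' @export
write_ledger <- function(ledger, path) {
  stopifnot(inherits(ledger, "ed_ledger"))
  df <- as.data.frame(ledger)[, c("role", "round", "indicator", "delta")]
  df$total <- stats::ave(df$delta, df$role, FUN = cumsum)
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' Positive-to-negative feedback ratio of a ledger
#'
#' The mechanic is calibrated toward a 6:1 ratio of positive to negative
#' feedback events (the Losada design point).  This reports, per role and
#' overall, the count of positive and negative deltas and their ratio; a
#' ledger without negative deltas reports an infinite ratio with a flag.
#'
#' @param ledger an `ed_ledger`.
#' @return data.frame with columns role, n_positive, n_negative, ratio.
#' @export
feedback_ratio <- function(ledger) {
  stopifnot(inherits(ledger, "ed_ledger"))
  one <- function(d, role) {
    np <- sum(d > 0)
    nn <- sum(d < 0)
    data.frame(role = role, n_positive = np, n_negative = nn,
               ratio = if (nn == 0) Inf else np / nn,
               stringsAsFactors = FALSE)
  }
  roles <- sort(unique(ledger$role))
  out <- do.call(rbind, c(
    lapply(roles, function(r) one(ledger$delta[ledger$role == r], r)),
    list(one(ledger$delta, "overall"))
  ))
  rownames(out) <- NULL
  out
}
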