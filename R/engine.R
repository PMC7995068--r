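# Round-based game engine ----------------------------------------------------
#
# Executes a full session: triage, module assignment, staff allocation,
# activity execution, discharge — over discrete rounds, driven by bot
# policies, emitting the complete telemetry log.  Sub-phase order within a
# round is fixed (arrivals -> triage -> allocation -> ticks -> completions ->
# round-end scoring) so scoring always sees a consistent snapshot and a seed
# fully determines the log.

#' Session configuration
#'
#' Defaults mirror the published play format: 12 rounds of 30 simulated
#' minutes (a 6-hour shift), 5 modules of which exactly one is red (reserved
#' for urgent patients), one triage nurse.  Staff pools and module capacity
#' are not published and are declared assumptions.
#'
#' @param rounds rounds per session.
#' @param minutes_per_round simulated minutes per round.
#' @param n_modules number of care modules; module 1 is the red module.
#' @param module_capacity patients a module can hold (stretcher/room cap).
#' @param doctors_per_module,nurses_per_module per-module staff pools,
#'   recycled each round.
#' @param triage_nurses staff at the triage post (0 triggers a
#'   resource-management penalty every round).
#' @param rules token rules, see [scoring_rules()].
#' @param seed master seed for the session.
#' @return A list of class `ed_config`.
#' @export
session_config <- function(rounds = 12L, minutes_per_round = 30L,
                           n_modules = 5L, module_capacity = 4L,
                           doctors_per_module = 4L, nurses_per_module = 4L,
                           triage_nurses = 1L, rules = scoring_rules(),
                           seed = 1L) {
  assert_scalar_number(rounds, "rounds", lower = 1, integer = TRUE)
  assert_scalar_number(minutes_per_round, "minutes_per_round", lower = 1,
                       integer = TRUE)
  assert_scalar_number(n_modules, "n_modules", lower = 1, integer = TRUE)
  assert_scalar_number(module_capacity, "module_capacity", lower = 1,
                       integer = TRUE)
  assert_scalar_number(doctors_per_module, "doctors_per_module", lower = 0,
                       integer = TRUE)
  assert_scalar_number(nurses_per_module, "nurses_per_module", lower = 0,
                       integer = TRUE)
  assert_scalar_number(triage_nurses, "triage_nurses", lower = 0,
                       integer = TRUE)
  stopifnot(inherits(rules, "ed_rules"))
  modules <- sprintf("module_%d", seq_len(n_modules))
  structure(
    list(rounds = as.integer(rounds),
         minutes_per_round = as.integer(minutes_per_round),
         modules = modules, red_module = modules[1],
         module_capacity = as.integer(module_capacity),
         doctors_per_module = as.integer(doctors_per_module),
         nurses_per_module = as.integer(nurses_per_module),
         triage_nurses = as.integer(triage_nurses),
         rules = rules, seed = as.integer(seed)),
    class = "ed_config"
  )
}

#' Bot-player policies
#'
#' Simple parameterised stochastic heuristics standing in for human players;
#' they exist to exercise the mechanics and generate telemetry, not to play
#' well.
#'
#' @param refer_prob probability triage refers a non-urgent patient out.
#' @param edit_prob per-patient per-round probability a module nurse edits
#'   the profile (titles/tags/classification telemetry).
#' @param invite_prob per-module per-round probability of broadcasting a
#'   cooperation invite.
#' @return A list of class `ed_policies`.
#' @export
policy_set <- function(refer_prob = 0.2, edit_prob = 0.3,
                       invite_prob = 0.15) {
  assert_scalar_number(refer_prob, "refer_prob", lower = 0, upper = 1)
  assert_scalar_number(edit_prob, "edit_prob", lower = 0, upper = 1)
  assert_scalar_number(invite_prob, "invite_prob", lower = 0, upper = 1)
  structure(list(refer_prob = refer_prob, edit_prob = edit_prob,
                 invite_prob = invite_prob),
            class = "ed_policies")
}

#' Triage decision for one patient
#'
#' Urgent patients are admitted to the red module whatever the policy says
#' (hard rule); if the red module is full they wait at triage.  Non-urgent
#' patients are referred out with probability `refer_prob`, otherwise
#' admitted to the least-loaded normal module with free capacity (ties break
#' to the lowest module index), or wait when every normal module is full.
#'
#' @param urgent logical urgency flag.
#' @param occupancy named integer vector of module occupancy.
#' @param capacity module capacity.
#' @param red_module id of the red module.
#' @param refer_prob policy referral probability for non-urgent patients.
#' @param u uniform draw in `[0,1]` deciding the referral (supplied by the
#'   engine's RNG stream; exposed for deterministic testing).
#' @return list(action = "admit"|"refer"|"wait", module, overridden).
#'   `overridden` is TRUE when the red-module rule vetoed the policy's
#'   preferred module for an urgent patient.
#' @export
triage_decide <- function(urgent, occupancy, capacity, red_module,
                          refer_prob = 0.2, u = stats::runif(1)) {
  open <- names(occupancy)[occupancy < capacity]
  if (urgent) {
    preferred <- if (length(open)) open[which.min(occupancy[open])] else NA
    if (occupancy[red_module] >= capacity) {
      return(list(action = "wait", module = NA_character_, overridden = FALSE))
    }
    return(list(action = "admit", module = red_module,
                overridden = !identical(preferred, red_module)))
  }
  if (u < refer_prob) {
    return(list(action = "refer", module = NA_character_, overridden = FALSE))
  }
  normal_open <- setdiff(open, red_module)
  if (!length(normal_open)) {
    return(list(action = "wait", module = NA_character_, overridden = FALSE))
  }
  pick <- normal_open[which.min(occupancy[normal_open])]
  list(action = "admit", module = pick, overridden = FALSE)
}

# -- internal event accumulator ---------------------------------------------

new_recorder <- function() {
  env <- new.env(parent = emptyenv())
  env$rows <- vector("list", 256L)
  env$n <- 0L
  env
}

emit <- function(rec, round, actor, type, profile = NA_character_,
                 module = NA_character_, indicator = NA_character_,
                 delta = NA_real_, planned = NA_integer_,
                 actual = NA_integer_, note = NA_character_) {
  rec$n <- rec$n + 1L
  if (rec$n > length(rec$rows)) {
    rec$rows <- c(rec$rows, vector("list", length(rec$rows)))
  }
  rec$rows[[rec$n]] <- list(round = as.integer(round), actor_role = actor,
                            event_type = type, profile_id = profile,
                            module_id = module, indicator = indicator,
                            delta = as.numeric(delta),
                            planned_rounds = as.integer(planned),
                            actual_rounds = as.integer(actual), note = note)
}

recorder_log <- function(rec, red_module) {
  rows <- rec$rows[seq_len(rec$n)]
  pull <- function(f, template) vapply(rows, function(r) r[[f]], template)
  df <- data.frame(
    seq = seq_len(rec$n),
    round = pull("round", integer(1)),
    actor_role = pull("actor_role", character(1)),
    event_type = pull("event_type", character(1)),
    profile_id = pull("profile_id", character(1)),
    module_id = pull("module_id", character(1)),
    indicator = pull("indicator", character(1)),
    delta = pull("delta", numeric(1)),
    planned_rounds = pull("planned_rounds", integer(1)),
    actual_rounds = pull("actual_rounds", integer(1)),
    note = pull("note", character(1)),
    stringsAsFactors = FALSE
  )
  structure(df, red_module = red_module, schema = "edgame-events-1",
            class = c("ed_event_log", "data.frame"))
}

# -- session state -----------------------------------------------------------

init_state <- function(config, deck, schedule, policies) {
  patients <- list()
  for (i in seq_len(nrow(deck$profiles))) {
    pid <- deck$profiles$profile_id[i]
    acts <- deck$activities[deck$activities$profile_id == pid, , drop = FALSE]
    patients[[pid]] <- list(
      profile_id = pid, urgent = deck$profiles$urgent[i], acts = acts,
      act_idx = 1L, progress = 0L, act_rounds = 0L,
      module = NA_character_, status = "deck"
    )
  }
  occupancy <- stats::setNames(integer(length(config$modules)),
                               config$modules)
  list(config = config, policies = policies, patients = patients,
       schedule = schedule, occupancy = occupancy,
       triage_queue = character(0), admitted = character(0),
       rejections = 0L, rejection_charged = 0, round = 0L)
}

# -- one round ---------------------------------------------------------------

step_round_impl <- function(state, rec) {
  cfg <- state$config
  pol <- state$policies
  rules <- cfg$rules
  red <- cfg$red_module
  r <- state$round + 1L
  state$round <- r
  emit(rec, r, "triage", "round_start",
       note = sprintf("minute %d", (r - 1L) * cfg$minutes_per_round))

  ## 1. arrivals
  arr <- state$schedule$profile_id[state$schedule$round == r]
  for (pid in arr) {
    state$patients[[pid]]$status <- "triage"
    state$triage_queue <- c(state$triage_queue, pid)
    emit(rec, r, "triage", "arrival", profile = pid)
  }

  ## 2. triage decisions (FIFO; waiting patients retried each round)
  queue <- state$triage_queue
  state$triage_queue <- character(0)
  for (pid in queue) {
    p <- state$patients[[pid]]
    dec <- triage_decide(p$urgent, state$occupancy, cfg$module_capacity,
                         red, pol$refer_prob)
    if (dec$action == "refer") {
      state$patients[[pid]]$status <- "referred"
      state$rejections <- state$rejections + 1L
      emit(rec, r, "triage", "triage_refer_out", profile = pid)
      due <- score_rejections(state$rejections, rules)
      if (due != state$rejection_charged) {
        emit(rec, r, "triage", "scoring_update", profile = pid,
             indicator = "PT", delta = due - state$rejection_charged,
             note = sprintf("rejection penalty after %d referrals",
                            state$rejections))
        state$rejection_charged <- due
      }
    } else if (dec$action == "admit") {
      if (dec$overridden) {
        emit(rec, r, "triage", "rule_enforcement", profile = pid,
             module = dec$module,
             note = "urgent patient rerouted to red module")
      }
      state$patients[[pid]]$status <- "admitted"
      state$patients[[pid]]$module <- dec$module
      state$occupancy[dec$module] <- state$occupancy[dec$module] + 1L
      state$admitted <- c(state$admitted, pid)
      emit(rec, r, "triage", "triage_admit", profile = pid,
           module = dec$module)
      emit(rec, r, dec$module, "assign_module", profile = pid,
           module = dec$module)
    } else {
      state$triage_queue <- c(state$triage_queue, pid)
      emit(rec, r, "triage", "triage_wait", profile = pid,
           note = "no open module")
    }
  }

  ## 3. staff allocation (per module, admission order), plus bot telemetry
  staffed <- stats::setNames(logical(length(state$admitted)), state$admitted)
  free_doctors <- stats::setNames(
    rep(cfg$doctors_per_module, length(cfg$modules)), cfg$modules)
  free_nurses <- stats::setNames(
    rep(cfg$nurses_per_module, length(cfg$modules)), cfg$modules)
  for (m in cfg$modules) {
    here <- state$admitted[vapply(state$admitted, function(pid)
      identical(state$patients[[pid]]$module, m), logical(1))]
    for (pid in here) {
      p <- state$patients[[pid]]
      a <- p$acts[p$act_idx, ]
      rc <- role_class(m, red)
      if (free_doctors[m] >= a$required_doctors &&
          free_nurses[m] >= a$required_nurses) {
        free_doctors[m] <- free_doctors[m] - a$required_doctors
        free_nurses[m] <- free_nurses[m] - a$required_nurses
        staffed[pid] <- TRUE
        emit(rec, r, m, "allocate_staff", profile = pid, module = m,
             note = sprintf("doctors=%d nurses=%d", a$required_doctors,
                            a$required_nurses))
      } else {
        emit(rec, r, m, "scoring_update", profile = pid, module = m,
             indicator = "RM", delta = score_resource_management(rc, rules),
             note = sprintf("activity %s missing required staff",
                            a$activity_id))
      }
      if (stats::runif(1) < pol$edit_prob) {
        emit(rec, r, m, "edit_profile", profile = pid, module = m)
      }
    }
    if (length(here) && stats::runif(1) < pol$invite_prob) {
      emit(rec, r, m, "broadcast_invite", module = m)
    }
  }
  if (cfg$triage_nurses < 1L) {
    emit(rec, r, "triage", "scoring_update", indicator = "RM",
         delta = score_resource_management("triage", rules),
         note = "triage post unstaffed")
  }

  ## 4-5. activity ticks, completions, discharges
  for (pid in state$admitted) {
    p <- state$patients[[pid]]
    m <- p$module
    p$act_rounds <- p$act_rounds + 1L
    if (staffed[pid]) {
      p$progress <- p$progress + 1L
      emit(rec, r, m, "activity_tick", profile = pid, module = m,
           note = p$acts$activity_id[p$act_idx])
      if (p$progress >= p$acts$planned_rounds[p$act_idx]) {
        planned <- p$acts$planned_rounds[p$act_idx]
        actual <- p$act_rounds
        emit(rec, r, m, "activity_complete", profile = pid, module = m,
             planned = planned, actual = actual,
             note = p$acts$activity_id[p$act_idx])
        ae <- score_activity_execution(planned, actual, role_class(m, red),
                                       rules)
        if (ae != 0) {
          emit(rec, r, m, "scoring_update", profile = pid, module = m,
               indicator = "AE", delta = ae)
        }
        p$act_idx <- p$act_idx + 1L
        p$progress <- 0L
        p$act_rounds <- 0L
        if (p$act_idx > nrow(p$acts)) {
          p$status <- "discharged"
          state$occupancy[m] <- state$occupancy[m] - 1L
          state$admitted <- setdiff(state$admitted, pid)
          emit(rec, r, m, "discharge", profile = pid, module = m)
          d <- score_throughput(m, identical(m, red), rules)
          emit(rec, r, m, "scoring_update", profile = pid, module = m,
               indicator = "PT", delta = d$delta[1])
          emit(rec, r, "triage", "scoring_update", profile = pid, module = m,
               indicator = "PT", delta = d$delta[2])
        }
      }
    }
    state$patients[[pid]] <- p
  }

  ## 6. round-end resilience check (free doctors after this round's work)
  for (m in cfg$modules) {
    pr <- score_resilience(as.integer(free_doctors[m]), role_class(m, red),
                           rules)
    if (pr != 0) {
      emit(rec, r, m, "scoring_update", module = m, indicator = "PR",
           delta = pr, note = "no free doctors at round end")
    }
  }
  state
}

#' Advance a session state by one round
#'
#' Applies the fixed sub-phase order (arrivals, triage, staff allocation,
#' activity ticks, completions/discharges, round-end scoring) and returns
#' the updated state together with the events of that round.
#'
#' @param state a session state as returned in `run_session()$state` or by a
#'   previous `step_round()` call.
#' @return list(state, events): events is a data.frame of that round's rows.
#' @export
step_round <- function(state) {
  if (state$round >= state$config$rounds) {
    ed_stop("session already at final round")
  }
  rec <- new_recorder()
  state <- step_round_impl(state, rec)
  list(state = state, events = recorder_log(rec, state$config$red_module))
}

#' Run a complete game session
#'
#' Executes `config$rounds` rounds and returns the full telemetry log plus
#' final state.  Identical (config, deck, schedule, policies) including the
#' seed give a byte-identical serialised log.
#'
#' @param config an [session_config()].
#' @param deck an `ed_deck` (see [generate_deck()]).
#' @param schedule an `ed_schedule` (see [generate_arrivals()]); must not
#'   reference rounds beyond `config$rounds`.
#' @param policies an [policy_set()].
#' @return list with `log` (an `ed_event_log`), `state` (final engine
#'   state), and `summary` (per-patient status data.frame).
#' @export
run_session <- function(config = session_config(), deck,
                        schedule, policies = policy_set()) {
  stopifnot(inherits(config, "ed_config"))
  validate_deck(deck)
  validate_schedule(schedule, deck)
  if (nrow(schedule) && max(schedule$round) > config$rounds) {
    ed_stop("schedule covers round ", max(schedule$round),
            " beyond config rounds ", config$rounds)
  }
  stopifnot(inherits(policies, "ed_policies"))
  rec <- new_recorder()
  state <- init_state(config, deck, schedule, policies)
  with_seed(substream_seed(config$seed, "engine"), {
    for (r in seq_len(config$rounds)) {
      state <- step_round_impl(state, rec)
    }
  })
  log <- recorder_log(rec, config$red_module)
  status <- vapply(state$patients, function(p) p$status, character(1))
  summary <- data.frame(
    profile_id = names(state$patients),
    status = unname(status),
    module = vapply(state$patients, function(p) p$module, character(1),
                    USE.NAMES = FALSE),
    stringsAsFactors = FALSE
  )
  rownames(summary) <- NULL
  list(log = log, state = state, summary = summary)
}
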