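# Fixtures are built in code; no files are shipped.

`%||%` <- function(a, b) if (is.null(a)) b else a

# hand-built deck: one urgent single-activity card, one non-urgent two-activity
# card, one non-urgent single-activity card
tiny_deck <- function() {
  profiles <- data.frame(
    profile_id = c("U1", "N1", "N2"),
    urgent = c(TRUE, FALSE, FALSE),
    priority_class = c(1L, 4L, 5L),
    sbar_note = c("urgent card", "routine card", "routine card"),
    stringsAsFactors = FALSE
  )
  activities <- data.frame(
    profile_id = c("U1", "N1", "N1", "N2"),
    activity_id = c("U1-A1", "N1-A1", "N1-A2", "N2-A1"),
    planned_rounds = c(1L, 1L, 2L, 1L),
    required_doctors = c(1L, 0L, 1L, 0L),
    required_nurses = c(1L, 1L, 1L, 1L),
    stringsAsFactors = FALSE
  )
  validate_deck(structure(list(profiles = profiles, activities = activities),
                          class = "ed_deck"))
}

one_card_deck <- function(urgent, planned = 1L, doctors = 1L, nurses = 0L,
                          n_activities = 1L) {
  profiles <- data.frame(profile_id = "P1", urgent = urgent,
                         priority_class = if (urgent) 1L else 4L,
                         sbar_note = "fixture", stringsAsFactors = FALSE)
  activities <- data.frame(
    profile_id = "P1",
    activity_id = sprintf("P1-A%d", seq_len(n_activities)),
    planned_rounds = rep(as.integer(planned), n_activities),
    required_doctors = rep(as.integer(doctors), n_activities),
    required_nurses = rep(as.integer(nurses), n_activities),
    stringsAsFactors = FALSE
  )
  validate_deck(structure(list(profiles = profiles, activities = activities),
                          class = "ed_deck"))
}

schedule_of <- function(rounds, ids) {
  structure(data.frame(round = rounds, profile_id = ids,
                       stringsAsFactors = FALSE),
            class = c("ed_schedule", "data.frame"))
}

empty_schedule <- function() schedule_of(integer(0), character(0))

# assemble an ed_event_log from loose rows (lists with named fields)
make_log <- function(rows, red_module = "module_1") {
  tmpl <- list(round = 1L, actor_role = "triage", event_type = "arrival",
               profile_id = NA_character_, module_id = NA_character_,
               indicator = NA_character_, delta = NA_real_,
               planned_rounds = NA_integer_, actual_rounds = NA_integer_,
               note = NA_character_)
  full <- lapply(rows, function(r) {
    out <- tmpl
    out[names(r)] <- r
    out
  })
  df <- data.frame(
    seq = seq_along(full),
    round = vapply(full, function(r) as.integer(r$round), integer(1)),
    actor_role = vapply(full, `[[`, character(1), "actor_role"),
    event_type = vapply(full, `[[`, character(1), "event_type"),
    profile_id = vapply(full, `[[`, character(1), "profile_id"),
    module_id = vapply(full, `[[`, character(1), "module_id"),
    indicator = vapply(full, `[[`, character(1), "indicator"),
    delta = vapply(full, function(r) as.numeric(r$delta), numeric(1)),
    planned_rounds = vapply(full, function(r) as.integer(r$planned_rounds),
                            integer(1)),
    actual_rounds = vapply(full, function(r) as.integer(r$actual_rounds),
                           integer(1)),
    note = vapply(full, `[[`, character(1), "note"),
    stringsAsFactors = FALSE
  )
  structure(df, red_module = red_module, schema = "edgame-events-1",
            class = c("ed_event_log", "data.frame"))
}

# independent naive scorer: one pass per indicator over data.frame subsets,
# deliberately a different code path from apply_scoring's event loop
naive_totals <- function(log, rules = scoring_rules()) {
  red <- attr(log, "red_module")
  totals <- new.env(parent = emptyenv())
  bump <- function(role, delta) {
    assign(role, (get0(role, totals, ifnotfound = 0)) + delta, totals)
  }
  dis <- log[log$event_type == "discharge", , drop = FALSE]
  for (m in dis$module_id) {
    reward <- if (m == red) rules$throughput_reward[["red"]] else
      rules$throughput_reward[["normal"]]
    share <- reward * rules$triage_share
    share <- sign(share) * floor(abs(share) + 0.5)
    bump(m, reward)
    bump("triage", share)
  }
  n_rej <- sum(log$event_type == "triage_refer_out")
  bump("triage", rules$rejection_penalty * (n_rej %/% rules$rejection_unit))
  ac <- log[log$event_type == "activity_complete", , drop = FALSE]
  for (i in seq_len(nrow(ac))) {
    delay <- (ac$actual_rounds[i] - ac$planned_rounds[i]) / ac$planned_rounds[i]
    pen_row <- if (ac$actor_role[i] == red) rules$ae_penalty$red else
      rules$ae_penalty$normal
    pen <- 0
    if (delay >= 1.00) pen <- pen_row[4]
    else if (delay >= 0.75) pen <- pen_row[3]
    else if (delay >= 0.50) pen <- pen_row[2]
    else if (delay >= 0.25) pen <- pen_row[1]
    bump(ac$actor_role[i], pen)
  }
  su <- log[log$event_type == "scoring_update", , drop = FALSE]
  for (i in seq_len(nrow(su))) {
    role <- su$actor_role[i]
    cls <- if (role == "triage") "triage" else if (role == red) "red" else "normal"
    if (su$indicator[i] == "RM") bump(role, rules$rm_penalty[[cls]])
    if (su$indicator[i] == "PR" && cls != "triage") {
      bump(role, rules$pr_penalty[[cls]])
    }
  }
  as.list(totals)
}

# random synthetic telemetry, independent of the engine
random_log <- function(seed, n_events = NULL) {
  withr::local_seed(seed)
  n <- if (is.null(n_events)) sample(20:80, 1) else n_events
  modules <- c("module_1", "module_2", "module_3")
  types <- sample(c("discharge", "triage_refer_out", "activity_complete",
                    "scoring_update", "allocate_staff", "edit_profile",
                    "broadcast_invite"),
                  n, replace = TRUE,
                  prob = c(0.25, 0.1, 0.2, 0.2, 0.1, 0.1, 0.05))
  rows <- lapply(seq_len(n), function(i) {
    m <- sample(modules, 1)
    switch(
      types[i],
      discharge = list(event_type = "discharge", actor_role = m,
                       module_id = m,
                       profile_id = sprintf("R%03d", i)),
      triage_refer_out = list(event_type = "triage_refer_out",
                              actor_role = "triage",
                              profile_id = sprintf("R%03d", i)),
      activity_complete = {
        planned <- sample(1:4, 1)
        list(event_type = "activity_complete", actor_role = m,
             module_id = m, profile_id = sprintf("R%03d", i),
             planned_rounds = planned,
             actual_rounds = planned + sample(0:6, 1))
      },
      scoring_update = {
        ind <- sample(c("RM", "PR"), 1)
        role <- if (ind == "RM" && stats::runif(1) < 0.2) "triage" else m
        list(event_type = "scoring_update", actor_role = role,
             module_id = if (role == "triage") NA_character_ else role,
             indicator = ind, delta = -1)
      },
      list(event_type = types[i], actor_role = m, module_id = m)
    )
  })
  rounds <- sort(sample(1:12, n, replace = TRUE))
  rows <- Map(function(r, rd) c(r, list(round = rd)), rows, rounds)
  make_log(rows)
}

default_session_run <- function(seed) {
  deck <- generate_deck(90, 0.15, seed = seed)
  sched <- generate_arrivals(deck, rounds = 12, mean_per_round = 3,
                             seed = seed)
  cfg <- session_config(seed = seed)
  run_session(cfg, deck, sched, policy_set())
}
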