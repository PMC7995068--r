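test_that("an empty schedule runs all rounds with no discharges", {
  run <- run_session(session_config(seed = 1), tiny_deck(), empty_schedule(),
                     policy_set())
  expect_equal(sum(run$log$event_type == "round_start"), 12)
  expect_equal(sum(run$log$event_type == "discharge"), 0)
  expect_true(all(run$summary$status == "deck"))
})

test_that("urgent patients always land in the red module", {
  # three urgent cards with multi-round plans: the red module fills up, the
  # bot policy starts preferring emptier normal modules, the rule vetoes it
  profiles <- data.frame(profile_id = c("U1", "U2", "U3"),
                         urgent = TRUE, priority_class = 1L,
                         sbar_note = "urgent fixture",
                         stringsAsFactors = FALSE)
  activities <- data.frame(profile_id = profiles$profile_id,
                           activity_id = paste0(profiles$profile_id, "-A1"),
                           planned_rounds = 6L, required_doctors = 1L,
                           required_nurses = 1L, stringsAsFactors = FALSE)
  deck <- validate_deck(structure(list(profiles = profiles,
                                       activities = activities),
                                  class = "ed_deck"))
  run <- run_session(session_config(seed = 1), deck,
                     schedule_of(c(1L, 1L, 2L), c("U1", "U2", "U3")),
                     policy_set(refer_prob = 1))  # policy wants to refer; rule wins
  assign <- run$log[run$log$event_type == "assign_module", ]
  expect_equal(nrow(assign), 3)
  expect_true(all(assign$module_id == "module_1"))
  # by round 2 the policy preferred an empty normal module; the veto is logged
  expect_true(any(run$log$event_type == "rule_enforcement"))
})

test_that("identical inputs and seed give byte-identical JSONL logs", {
  f1 <- withr::local_tempfile(fileext = ".jsonl")
  f2 <- withr::local_tempfile(fileext = ".jsonl")
  write_event_log(default_session_run(42)$log, f1)
  write_event_log(default_session_run(42)$log, f2)
  expect_identical(unname(tools::md5sum(f1)), unname(tools::md5sum(f2)))
})

test_that("patient conservation holds at session end", {
  for (seed in 1:5) {
    run <- default_session_run(seed)
    arrivals <- sum(run$log$event_type == "arrival")
    st <- run$summary$status
    accounted <- sum(st == "referred") + sum(st == "discharged") +
      sum(st == "admitted") + sum(st == "triage")
    expect_equal(arrivals, accounted)
  }
})

test_that("activities stall without required staff and accrue RM penalties", {
  # card needs a doctor every round; the module pool has none
  deck <- one_card_deck(urgent = FALSE, planned = 1L, doctors = 1L)
  cfg <- session_config(rounds = 4L, doctors_per_module = 0L, seed = 1)
  run <- run_session(cfg, deck, schedule_of(1L, "P1"),
                     policy_set(refer_prob = 0))
  expect_equal(sum(run$log$event_type == "discharge"), 0)
  expect_equal(sum(run$log$event_type == "activity_tick"), 0)
  rm_events <- run$log[run$log$event_type == "scoring_update" &
                         run$log$indicator == "RM", ]
  expect_equal(nrow(rm_events), 4)  # one per round the activity starved
})

test_that("a delayed activity is completed with its realised duration", {
  # 2 doctors needed but only 1 available every second round via competing card
  deck <- one_card_deck(urgent = FALSE, planned = 2L, doctors = 2L)
  cfg <- session_config(rounds = 6L, doctors_per_module = 2L, seed = 1)
  run <- run_session(cfg, deck, schedule_of(1L, "P1"), policy_set(refer_prob = 0))
  ac <- run$log[run$log$event_type == "activity_complete", ]
  expect_equal(nrow(ac), 1)
  expect_equal(ac$planned_rounds, 2L)
  expect_equal(ac$actual_rounds, 2L)  # fully staffed: no delay
  expect_equal(sum(run$log$event_type == "discharge"), 1)
})

test_that("triage_decide enforces the red rule and capacity", {
  occ <- c(module_1 = 0L, module_2 = 0L, module_3 = 0L)
  d <- triage_decide(TRUE, occ, 4, "module_1", refer_prob = 0, u = 0.5)
  expect_equal(d$action, "admit")
  expect_equal(d$module, "module_1")

  occ_full_red <- c(module_1 = 4L, module_2 = 0L)
  expect_equal(triage_decide(TRUE, occ_full_red, 4, "module_1")$action, "wait")

  expect_equal(triage_decide(FALSE, occ, 4, "module_1", refer_prob = 1,
                             u = 0.99)$action, "refer")

  occ_all_full <- c(module_1 = 4L, module_2 = 4L)
  expect_equal(triage_decide(FALSE, occ_all_full, 4, "module_1",
                             refer_prob = 0, u = 0.5)$action, "wait")

  # least-loaded normal module wins, ties to the lowest index
  occ2 <- c(module_1 = 0L, module_2 = 2L, module_3 = 1L)
  expect_equal(triage_decide(FALSE, occ2, 4, "module_1", refer_prob = 0,
                             u = 0.5)$module, "module_3")
})

test_that("non-urgent patients wait when every normal module is full", {
  deck <- one_card_deck(urgent = FALSE)
  cfg <- session_config(rounds = 2L, n_modules = 2L, module_capacity = 1L,
                        seed = 1)
  # fill the single normal module first
  deck2 <- tiny_deck()
  run <- run_session(cfg, deck2, schedule_of(c(1L, 1L), c("N1", "N2")),
                     policy_set(refer_prob = 0))
  waits <- run$log[run$log$event_type == "triage_wait", ]
  expect_gte(nrow(waits), 1)
})

test_that("schedules beyond the configured rounds are rejected", {
  expect_error(
    run_session(session_config(rounds = 2L, seed = 1), tiny_deck(),
                schedule_of(3L, "N1"), policy_set()),
    "beyond config rounds")
})

test_that("step_round advances one round and stops at the end", {
  cfg <- session_config(rounds = 2L, seed = 1)
  run <- run_session(cfg, tiny_deck(), empty_schedule(), policy_set())
  st <- run$state
  expect_error(step_round(st), "final round")
})

test_that("per-activity progress is monotone and staff-gated", {
  run <- default_session_run(7)
  # ticks per (profile, activity) never exceed allocations for it
  ticks <- run$log[run$log$event_type == "activity_tick", ]
  allocs <- run$log[run$log$event_type == "allocate_staff", ]
  expect_lte(nrow(ticks), nrow(allocs))
  # completions report actual >= planned
  ac <- run$log[run$log$event_type == "activity_complete", ]
  expect_true(all(ac$actual_rounds >= ac$planned_rounds))
})
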