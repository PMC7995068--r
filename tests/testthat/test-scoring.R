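rules <- scoring_rules()

test_that("throughput rewards follow the rule card", {
  red <- score_throughput("module_1", is_red = TRUE, rules)
  expect_equal(red$delta[red$role == "module_1"], 16)
  expect_equal(red$delta[red$role == "triage"], 4)
  normal <- score_throughput("module_3", is_red = FALSE, rules)
  expect_equal(normal$delta[normal$role == "module_3"], 4)
  expect_equal(normal$delta[normal$role == "triage"], 1)  # quarter share
})

test_that("rejection penalty is -1 per two referrals, floored", {
  expect_equal(score_rejections(0, rules), 0)
  expect_equal(score_rejections(2, rules), -1)
  # oracle: integer division
  for (n in 0:11) expect_equal(score_rejections(n, rules), -(n %/% 2))
})

test_that("activity-execution penalties bucket by delay fraction", {
  expect_equal(score_activity_execution(4, 4, "red", rules), 0)
  expect_equal(score_activity_execution(4, 6, "red", rules), -8)    # +50%
  expect_equal(score_activity_execution(4, 7, "normal", rules), -3) # +75%
  expect_equal(score_activity_execution(4, 5, "red", rules), -4)    # +25%
  expect_equal(score_activity_execution(8, 9, "red", rules), 0)     # +12.5%
  expect_equal(score_activity_execution(2, 5, "normal", rules), -4) # capped
  expect_equal(score_activity_execution(1, 9, "red", rules), -16)   # capped
  expect_equal(score_activity_execution(4, 6, "triage", rules), 0)  # n/a
  expect_error(score_activity_execution(4, 3, "red", rules), "early completion")
})

test_that("activity-execution matches a table-lookup oracle on a grid", {
  lookup <- function(planned, actual, cls) {
    delay <- (actual - planned) / planned
    pen <- if (cls == "red") c(-4, -8, -12, -16) else c(-1, -2, -3, -4)
    if (delay >= 1) pen[4] else if (delay >= 0.75) pen[3] else
      if (delay >= 0.5) pen[2] else if (delay >= 0.25) pen[1] else 0
  }
  for (planned in 1:6) {
    for (actual in planned:(planned + 8)) {
      for (cls in c("red", "normal")) {
        expect_equal(score_activity_execution(planned, actual, cls, rules),
                     lookup(planned, actual, cls),
                     info = sprintf("planned=%d actual=%d %s", planned,
                                    actual, cls))
      }
    }
  }
})

test_that("resource-management and resilience penalties are role-scaled", {
  expect_equal(score_resource_management("red", rules), -4)
  expect_equal(score_resource_management("normal", rules), -1)
  expect_equal(score_resource_management("triage", rules), -1)
  expect_equal(score_resilience(0, "red", rules), -4)
  expect_equal(score_resilience(0, "normal", rules), -1)
  expect_equal(score_resilience(2, "red", rules), 0)
  expect_equal(score_resilience(0, "triage", rules), 0)  # exempt
})

test_that("red magnitudes are four times normal for every indicator", {
  expect_equal(rules$throughput_reward[["red"]],
               4 * rules$throughput_reward[["normal"]])
  expect_equal(rules$ae_penalty$red, 4 * rules$ae_penalty$normal)
  expect_equal(rules$rm_penalty[["red"]], 4 * rules$rm_penalty[["normal"]])
  expect_equal(rules$pr_penalty[["red"]], 4 * rules$pr_penalty[["normal"]])
})

test_that("apply_scoring on an empty log gives zero totals", {
  ledger <- apply_scoring(make_log(list()), rules)
  expect_equal(nrow(ledger), 0)
  expect_equal(length(ledger_totals(ledger)), 0)
})

test_that("a single red discharge credits +16 to red and +4 to triage", {
  log <- make_log(list(
    list(round = 3L, actor_role = "module_1", event_type = "discharge",
         profile_id = "P1", module_id = "module_1")
  ))
  totals <- ledger_totals(apply_scoring(log, rules))
  expect_equal(totals$module_1, 16)
  expect_equal(totals$triage, 4)
})

test_that("apply_scoring is deterministic and idempotent", {
  log <- random_log(99)
  l1 <- apply_scoring(log, rules)
  l2 <- apply_scoring(log, rules)
  expect_identical(l1, l2)
})

test_that("ledger conservation: totals equal the sum of deltas", {
  for (seed in c(5, 17, 23)) {
    ledger <- apply_scoring(random_log(seed), rules)
    totals <- ledger_totals(ledger)
    for (role in names(totals)) {
      expect_equal(totals[[role]], sum(ledger$delta[ledger$role == role]))
    }
  }
})

test_that("apply_scoring matches the naive per-event oracle on random logs", {
  for (seed in 1:100) {
    log <- random_log(seed)
    got <- ledger_totals(apply_scoring(log, rules))
    want <- naive_totals(log, rules)
    for (role in union(names(got), names(want))) {
      expect_equal(got[[role]] %||% 0, want[[role]] %||% 0,
                   info = sprintf("seed %d role %s", seed, role))
    }
  }
})

test_that("adding a discharge never decreases totals; a penalty never increases them", {
  base <- random_log(7)
  t0 <- ledger_totals(apply_scoring(base, rules))
  plus <- make_log(c(split(base[-1], seq_len(nrow(base))) |> lapply(as.list),
                     list(list(round = 12L, actor_role = "module_2",
                               event_type = "discharge", profile_id = "X1",
                               module_id = "module_2"))))
  t1 <- ledger_totals(apply_scoring(plus, rules))
  for (role in names(t0)) expect_gte(t1[[role]] %||% 0, t0[[role]])
  minus <- make_log(c(split(base[-1], seq_len(nrow(base))) |> lapply(as.list),
                      list(list(round = 12L, actor_role = "module_2",
                                event_type = "scoring_update",
                                indicator = "RM", delta = -1))))
  t2 <- ledger_totals(apply_scoring(minus, rules))
  for (role in names(t0)) expect_lte(t2[[role]] %||% 0, t0[[role]])
})

test_that("discharges of unknown patients are an integrity error", {
  log <- make_log(list(
    list(round = 1L, actor_role = "triage", event_type = "arrival",
         profile_id = "P1"),
    list(round = 2L, actor_role = "module_2", event_type = "discharge",
         profile_id = "GHOST", module_id = "module_2")
  ))
  expect_error(apply_scoring(log, rules), "unknown patient")
})

test_that("feedback_ratio reports counts, ratio, and the all-positive flag", {
  log <- make_log(c(
    lapply(1:6, function(i) list(round = i, actor_role = "module_2",
                                 event_type = "discharge",
                                 profile_id = sprintf("P%d", i),
                                 module_id = "module_2")),
    list(list(round = 7L, actor_role = "module_2",
              event_type = "scoring_update", indicator = "RM", delta = -1),
         list(round = 7L, actor_role = "module_3",
              event_type = "scoring_update", indicator = "PR", delta = -1))
  ))
  fr <- feedback_ratio(apply_scoring(log, rules))
  overall <- fr[fr$role == "overall", ]
  expect_equal(overall$n_positive, 12)  # 6 module + 6 triage shares
  expect_equal(overall$n_negative, 2)
  expect_equal(overall$ratio, 6)

  pos_only <- make_log(list(list(round = 1L, actor_role = "module_1",
                                 event_type = "discharge", profile_id = "P1",
                                 module_id = "module_1")))
  fr2 <- feedback_ratio(apply_scoring(pos_only, rules))
  expect_true(is.infinite(fr2$ratio[fr2$role == "overall"]))
})

test_that("scoring rules round-trip through JSON and reject bad tables", {
  p <- withr::local_tempfile(fileext = ".json")
  write_rules(rules, p)
  expect_equal(read_rules(p), rules)
  expect_error(scoring_rules(throughput_reward = c(red = -1, normal = 4)),
               "positive")
  expect_error(scoring_rules(rm_penalty = c(red = 4, normal = -1, triage = -1)),
               "negative")
})
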