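# Token rules ---------------------------------------------------------------
#
# The scoring mechanic attaches token rewards/penalties to four logistical
# indicators, with magnitudes differentiated by role: the red (urgent) module
# carries 4x the stakes of a normal module.  Defaults reproduce the published
# rule card of the game:
#
#   indicator              red module   normal module   triage place
#   production throughput  +16          +4              1/4 of receiving
#                                                       module's reward;
#                                                       -1 per 2 rejections
#   activity execution     -4/-8/-12/-16 at delay       n/a
#                          +25/+50/+75/+100%  (normal: -1/-2/-3/-4)
#   resource management    -4           -1              -1
#   production resilience  -4           -1              n/a

#' Construct the token scoring rules
#'
#' @param throughput_reward named numeric, tokens credited to the discharging
#'   module role, by role class (`red`, `normal`).
#' @param triage_share fraction of the receiving module's throughput reward
#'   credited to the triage role on every discharge.
#' @param rejection_penalty tokens (negative) per `rejection_unit` triage
#'   referrals out of the ED, cumulative over the session.
#' @param rejection_unit number of rejections per penalty increment.
#' @param ae_thresholds delay thresholds (fractions of the plan) defining the
#'   activity-execution penalty buckets.
#' @param ae_penalty_red,ae_penalty_normal penalties per bucket, by role.
#' @param rm_penalty resource-management penalty by role (`red`, `normal`,
#'   `triage`).
#' @param pr_penalty production-resilience penalty by role (`red`, `normal`);
#'   triage is exempt.
#' @return A list of class `ed_rules`.
#' @export
scoring_rules <- function(throughput_reward = c(red = 16, normal = 4),
                          triage_share = 1 / 4,
                          rejection_penalty = -1,
                          rejection_unit = 2L,
                          ae_thresholds = c(0.25, 0.50, 0.75, 1.00),
                          ae_penalty_red = c(-4, -8, -12, -16),
                          ae_penalty_normal = c(-1, -2, -3, -4),
                          rm_penalty = c(red = -4, normal = -1, triage = -1),
                          pr_penalty = c(red = -4, normal = -1)) {
  if (any(throughput_reward <= 0)) ed_stop("throughput rewards must be positive")
  if (any(c(ae_penalty_red, ae_penalty_normal, rm_penalty, pr_penalty) >= 0)) {
    ed_stop("penalties must be negative")
  }
  if (length(ae_thresholds) != length(ae_penalty_red) ||
      length(ae_thresholds) != length(ae_penalty_normal)) {
    ed_stop("activity-execution thresholds and penalties must align")
  }
  if (is.unsorted(ae_thresholds, strictly = TRUE)) {
    ed_stop("ae_thresholds must be strictly increasing")
  }
  structure(
    list(
      throughput_reward = throughput_reward,
      triage_share = triage_share,
      rejection_penalty = rejection_penalty,
      rejection_unit = as.integer(rejection_unit),
      ae_thresholds = ae_thresholds,
      ae_penalty = list(red = ae_penalty_red, normal = ae_penalty_normal),
      rm_penalty = rm_penalty,
      pr_penalty = pr_penalty
    ),
    class = "ed_rules"
  )
}

#' Read / write scoring rules as JSON
#'
#' @param rules an `ed_rules` object.
#' @param path JSON path.
#' @return `path` / an `ed_rules`.
#' @export
write_rules <- function(rules, path) {
  stopifnot(inherits(rules, "ed_rules"))
  out <- unclass(rules)
  # named vectors must become JSON objects, not bare arrays
  for (f in c("throughput_reward", "rm_penalty", "pr_penalty")) {
    out[[f]] <- as.list(out[[f]])
  }
  jsonlite::write_json(out, path, auto_unbox = TRUE, pretty = TRUE)
  invisible(path)
}

#' @rdname write_rules
#' @export
read_rules <- function(path) {
  if (!file.exists(path)) ed_stop("rules file not found: ", path)
  r <- jsonlite::read_json(path, simplifyVector = TRUE)
  scoring_rules(
    throughput_reward = unlist(r$throughput_reward),
    triage_share = r$triage_share,
    rejection_penalty = r$rejection_penalty,
    rejection_unit = r$rejection_unit,
    ae_thresholds = r$ae_thresholds,
    ae_penalty_red = r$ae_penalty$red,
    ae_penalty_normal = r$ae_penalty$normal,
    rm_penalty = unlist(r$rm_penalty),
    pr_penalty = unlist(r$pr_penalty)
  )
}

# role class of an actor: "triage", "red", or "normal"
role_class <- function(actor_role, red_module) {
  ifelse(actor_role == "triage", "triage",
         ifelse(actor_role == red_module, "red", "normal"))
}
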