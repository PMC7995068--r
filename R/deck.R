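# Synthetic patient-profile deck -------------------------------------------
#
# The physical game is played with 90 unique patient cards built from real
# pediatric ED flow data.  Those cards are not published, so the deck here is
# parametric: every distributional choice sits in `case_mix()` and is
# config-exposed rather than hard-coded truth.

#' Case-mix parameters for deck generation
#'
#' Defines the distributions from which per-patient activity plans are drawn.
#' The defaults emulate a low-acuity-heavy pediatric case mix: most patients
#' need one to three short activities, each staffed by one or two people.
#'
#' @param extra_activity_trials,extra_activity_prob number of activities per
#'   patient is `1 + Binomial(extra_activity_trials, extra_activity_prob)`.
#' @param planned_rounds_values,planned_rounds_weights support and weights of
#'   the per-activity planned duration, in rounds.
#' @param doctor_prob probability an activity requires one doctor.
#' @param nurse_values,nurse_weights support and weights of required nurses.
#' @return A list of class `ed_case_mix`.
#' @export
case_mix <- function(extra_activity_trials = 3L,
                     extra_activity_prob = 0.5,
                     planned_rounds_values = c(1L, 2L, 3L),
                     planned_rounds_weights = c(0.5, 0.3, 0.2),
                     doctor_prob = 0.6,
                     nurse_values = c(0L, 1L, 2L),
                     nurse_weights = c(0.2, 0.6, 0.2)) {
  assert_scalar_number(extra_activity_trials, "extra_activity_trials", lower = 0, integer = TRUE)
  assert_scalar_number(extra_activity_prob, "extra_activity_prob", lower = 0, upper = 1)
  assert_scalar_number(doctor_prob, "doctor_prob", lower = 0, upper = 1)
  if (length(planned_rounds_values) != length(planned_rounds_weights)) {
    ed_stop("planned_rounds values and weights must have equal length")
  }
  if (any(planned_rounds_values < 1)) ed_stop("planned_rounds values must be >= 1")
  structure(
    list(
      extra_activity_trials = as.integer(extra_activity_trials),
      extra_activity_prob = extra_activity_prob,
      planned_rounds_values = as.integer(planned_rounds_values),
      planned_rounds_weights = planned_rounds_weights / sum(planned_rounds_weights),
      doctor_prob = doctor_prob,
      nurse_values = as.integer(nurse_values),
      nurse_weights = nurse_weights / sum(nurse_weights)
    ),
    class = "ed_case_mix"
  )
}

#' Generate a synthetic patient-profile deck
#'
#' Each profile is a game card: an urgency flag (the only priority level
#' printed on the card that the rules act on — urgent patients must be routed
#' to the red module), a cosmetic ordinal priority class, an ordered activity
#' plan with staff requirements, and an SBAR-style free-text note for
#' narrative flavour.
#'
#' @param size number of profiles (the physical deck has 90 unique cards).
#' @param urgent_fraction probability a profile is urgent; urgency flags are
#'   drawn i.i.d. Bernoulli.
#' @param seed integer seed; identical arguments give a bit-identical deck.
#' @param mix an [case_mix()] object.
#' @return An object of class `ed_deck`: a list with `profiles` (one row per
#'   card) and `activities` (one row per activity, ordered within card).
#' @examples
#' d <- generate_deck(90, urgent_fraction = 0.15, seed = 7)
#' nrow(d$profiles)
#' @export
generate_deck <- function(size, urgent_fraction = 0.15, seed = 1L,
                          mix = case_mix()) {
  assert_scalar_number(size, "size", lower = 1, integer = TRUE)
  assert_scalar_number(urgent_fraction, "urgent_fraction", lower = 0, upper = 1)
  stopifnot(inherits(mix, "ed_case_mix"))
  with_seed(substream_seed(seed, "deck"), {
    ids <- sprintf("P%03d", seq_len(size))
    urgent <- stats::runif(size) < urgent_fraction
    # priority class 1 = urgent; non-urgent skew to low acuity (4-5)
    priority <- ifelse(urgent, 1L,
                       sample(2:5, size, replace = TRUE,
                              prob = c(0.10, 0.20, 0.35, 0.35)))
    n_act <- 1L + stats::rbinom(size, mix$extra_activity_trials,
                                mix$extra_activity_prob)
    act <- vector("list", size)
    for (i in seq_len(size)) {
      k <- n_act[i]
      doctors <- as.integer(stats::runif(k) < mix$doctor_prob)
      nurses <- sample(mix$nurse_values, k, replace = TRUE,
                       prob = mix$nurse_weights)
      none <- doctors + nurses == 0L
      nurses[none] <- 1L  # every activity needs at least one staff member
      act[[i]] <- data.frame(
        profile_id = ids[i],
        activity_id = sprintf("%s-A%d", ids[i], seq_len(k)),
        planned_rounds = sample(mix$planned_rounds_values, k, replace = TRUE,
                                prob = mix$planned_rounds_weights),
        required_doctors = doctors,
        required_nurses = as.integer(nurses),
        stringsAsFactors = FALSE
      )
    }
    deck <- structure(
      list(
        profiles = data.frame(
          profile_id = ids,
          urgent = urgent,
          priority_class = as.integer(priority),
          sbar_note = sprintf(
            "S: pediatric presentation, priority %d. B: synthetic card. A: %d planned activit%s. R: %s",
            priority, n_act, ifelse(n_act == 1L, "y", "ies"),
            ifelse(urgent, "route to red module", "routine module care")
          ),
          stringsAsFactors = FALSE
        ),
        activities = do.call(rbind, act)
      ),
      class = "ed_deck"
    )
    validate_deck(deck)
  })
}

#' Validate an `ed_deck`
#'
#' Enforces the deck invariants: unique profile ids, non-empty activity plans,
#' positive planned durations, at least one staff member per activity.
#'
#' @param deck an `ed_deck`.
#' @return The deck, invisibly usable in a pipeline; errors otherwise.
#' @export
validate_deck <- function(deck) {
  if (!inherits(deck, "ed_deck")) ed_stop("not an ed_deck object")
  p <- deck$profiles
  a <- deck$activities
  req <- c("profile_id", "urgent", "priority_class", "sbar_note")
  if (!all(req %in% names(p))) ed_stop("deck profiles missing columns")
  if (anyDuplicated(p$profile_id)) {
    ed_stop("duplicate profile_id in deck: ",
            paste(unique(p$profile_id[duplicated(p$profile_id)]), collapse = ", "))
  }
  if (nrow(p) == 0L) ed_stop("deck is empty")
  missing_acts <- setdiff(p$profile_id, a$profile_id)
  if (length(missing_acts)) {
    ed_stop("profiles with empty activity plan: ",
            paste(missing_acts, collapse = ", "))
  }
  orphans <- setdiff(a$profile_id, p$profile_id)
  if (length(orphans)) {
    ed_stop("activities reference unknown profiles: ",
            paste(orphans, collapse = ", "))
  }
  if (any(a$planned_rounds < 1)) ed_stop("planned_rounds must be >= 1")
  if (any(a$required_doctors < 0) || any(a$required_nurses < 0)) {
    ed_stop("staff requirements must be non-negative")
  }
  if (any(a$required_doctors + a$required_nurses < 1)) {
    ed_stop("every activity requires at least one staff member")
  }
  deck
}

#' @export
print.ed_deck <- function(x, ...) {
  cat(sprintf("<ed_deck> %d profiles (%d urgent), %d activities\n",
              nrow(x$profiles), sum(x$profiles$urgent), nrow(x$activities)))
  invisible(x)
}

#' Generate a per-round arrival schedule
#'
#' Emulates a predefined patient inflow triaged each round: per-round arrival
#' counts are Poisson(`mean_per_round`) draws, truncated so that sampling
#' without replacement from the deck never runs out of cards.  If the deck is
#' exhausted a warning is raised and remaining rounds receive no arrivals.
#'
#' @param deck an `ed_deck`.
#' @param rounds number of rounds covered by the schedule.
#' @param mean_per_round expected arrivals per round.
#' @param seed integer seed.
#' @return A data.frame of class `ed_schedule` with columns `round`,
#'   `profile_id`; every profile appears at most once.
#' @export
generate_arrivals <- function(deck, rounds = 12L, mean_per_round = 3,
                              seed = 1L) {
  validate_deck(deck)
  assert_scalar_number(rounds, "rounds", lower = 1, integer = TRUE)
  assert_scalar_number(mean_per_round, "mean_per_round", lower = 0)
  with_seed(substream_seed(seed, "arrivals"), {
    counts <- stats::rpois(rounds, mean_per_round)
    pool <- sample(deck$profiles$profile_id)
    avail <- length(pool)
    if (sum(counts) > avail) {
      warning(sprintf(
        "requested %d arrivals but deck holds %d profiles; schedule truncated",
        sum(counts), avail), call. = FALSE)
    }
    out <- vector("list", rounds)
    used <- 0L
    for (r in seq_len(rounds)) {
      take <- min(counts[r], avail - used)
      if (take > 0L) {
        out[[r]] <- data.frame(round = r,
                               profile_id = pool[used + seq_len(take)],
                               stringsAsFactors = FALSE)
        used <- used + take
      }
    }
    sched <- do.call(rbind, c(out, list(
      data.frame(round = integer(), profile_id = character(),
                 stringsAsFactors = FALSE))))
    rownames(sched) <- NULL
    structure(sched, class = c("ed_schedule", "data.frame"))
  })
}

validate_schedule <- function(schedule, deck = NULL) {
  if (!is.data.frame(schedule) ||
      !all(c("round", "profile_id") %in% names(schedule))) {
    ed_stop("schedule must have columns round, profile_id")
  }
  if (anyDuplicated(schedule$profile_id)) {
    ed_stop("schedule references a profile more than once")
  }
  if (!is.null(deck)) {
    unknown <- setdiff(schedule$profile_id, deck$profiles$profile_id)
    if (length(unknown)) {
      ed_stop("schedule references profiles not in deck: ",
              paste(unknown, collapse = ", "))
    }
  }
  invisible(schedule)
}
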