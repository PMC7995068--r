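# End-to-end pipeline ---------------------------------------------------------
#
# simulate -> score -> code -> lsa -> regress over a batch of sessions, with
# every artifact written as plain text (JSON / JSONL / CSV / DOT) and listed
# in a manifest.  All randomness flows from one top-level seed through named
# substreams, so a manifest plus the config reproduce byte-identical
# simulator outputs.

PIPELINE_KEYS <- c("deck", "arrivals", "session", "policies", "n_sessions")

#' Default pipeline configuration
#'
#' The reference scenario: a 90-card deck with 15% urgent patients, Poisson
#' arrivals of 3 patients per round over 12 rounds, the default session
#' format and bot policies, and 6 sessions per batch (6 player roles each —
#' triage plus 5 modules — giving a 36-player engagement table).
#'
#' @return A nested list understood by [run_pipeline()].
#' @export
default_pipeline_config <- function() {
  list(
    deck = list(size = 90L, urgent_fraction = 0.15),
    arrivals = list(mean_per_round = 3),
    session = list(rounds = 12L, minutes_per_round = 30L, n_modules = 5L,
                   module_capacity = 4L, doctors_per_module = 4L,
                   nurses_per_module = 4L, triage_nurses = 1L),
    policies = list(refer_prob = 0.2, edit_prob = 0.3, invite_prob = 0.15),
    n_sessions = 6L
  )
}

#' Read and validate a pipeline config (JSON)
#'
#' Unknown keys are rejected so silent typos cannot change a run.  Missing
#' sections fall back to [default_pipeline_config()].
#'
#' @param path JSON path; `NULL` yields the defaults.
#' @return A validated config list.
#' @export
read_pipeline_config <- function(path = NULL) {
  cfg <- default_pipeline_config()
  if (is.null(path)) return(cfg)
  if (!file.exists(path)) ed_stop("config file not found: ", path)
  user <- jsonlite::read_json(path, simplifyVector = TRUE)
  bad <- setdiff(names(user), PIPELINE_KEYS)
  if (length(bad)) ed_stop("unknown config key(s): ", paste(bad, collapse = ", "))
  for (sec in intersect(names(user), PIPELINE_KEYS)) {
    if (sec == "n_sessions") {
      cfg$n_sessions <- as.integer(user$n_sessions)
      next
    }
    extra <- setdiff(names(user[[sec]]), names(cfg[[sec]]))
    if (length(extra)) {
      ed_stop("unknown key(s) in config section `", sec, "`: ",
              paste(extra, collapse = ", "))
    }
    cfg[[sec]][names(user[[sec]])] <- user[[sec]]
  }
  cfg
}

#' Run the full demo pipeline
#'
#' Generates a deck and per-session arrival schedules, simulates
#' `n_sessions` bot-driven sessions, scores them, codes telemetry, pools the
#' coded sequences for lag sequential analysis, builds the engagement table
#' (one row per player role per session), fits the performance regression,
#' and writes every artifact plus a manifest under `out_dir`.
#'
#' @param config config list (see [read_pipeline_config()]) or a JSON path.
#' @param seed top-level integer seed.
#' @param out_dir output directory, created if needed.
#' @return The manifest, invisibly: config hash, seed, artifact paths with
#'   md5 checksums, package version, timestamp.
#' @export
run_pipeline <- function(config = default_pipeline_config(), seed = 1L,
                         out_dir = tempfile("edgame_run_")) {
  if (is.character(config)) config <- read_pipeline_config(config)
  assert_scalar_number(seed, "seed", integer = TRUE)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  p <- function(...) file.path(out_dir, paste0(...))

  deck <- generate_deck(config$deck$size, config$deck$urgent_fraction,
                        seed = substream_seed(seed, "pipeline-deck"))
  write_deck(deck, p("deck.json"))

  n_sessions <- config$n_sessions
  sessions <- vector("list", n_sessions)
  sequences_all <- list()
  attrs <- list()
  log_paths <- character(n_sessions)
  for (s in seq_len(n_sessions)) {
    s_seed <- substream_seed(seed, paste0("session", s))
    sched <- generate_arrivals(deck, rounds = config$session$rounds,
                               mean_per_round = config$arrivals$mean_per_round,
                               seed = s_seed)
    scfg <- session_config(
      rounds = config$session$rounds,
      minutes_per_round = config$session$minutes_per_round,
      n_modules = config$session$n_modules,
      module_capacity = config$session$module_capacity,
      doctors_per_module = config$session$doctors_per_module,
      nurses_per_module = config$session$nurses_per_module,
      triage_nurses = config$session$triage_nurses,
      seed = s_seed
    )
    pol <- policy_set(config$policies$refer_prob, config$policies$edit_prob,
                      config$policies$invite_prob)
    run <- run_session(scfg, deck, sched, pol)
    log_paths[s] <- p(sprintf("session_%02d.jsonl", s))
    write_event_log(run$log, log_paths[s])
    if (s == 1L) write_arrivals(sched, p("schedule_01.csv"))
    ledger <- apply_scoring(run$log, scfg$rules)
    seqs <- code_events(run$log)
    # every configured role is a player, even if it logged no events
    for (role in setdiff(c("triage", scfg$modules), names(seqs))) {
      seqs[[role]] <- structure(
        data.frame(player_id = character(), ordinal = integer(),
                   round = integer(), code = character(),
                   stringsAsFactors = FALSE),
        class = c("ed_coded_sequence", "data.frame"))
    }
    for (role in names(seqs)) {
      attr_row <- engagement_attributes(seqs[[role]], ledger,
                                        config$session$minutes_per_round)
      attr_row$player_id <- sprintf("s%02d_%s", s, role)  # unique across batch
      attrs[[length(attrs) + 1L]] <- attr_row
      sq <- seqs[[role]]
      sq$player_id <- attr_row$player_id
      sequences_all[[length(sequences_all) + 1L]] <- sq
    }
    sessions[[s]] <- list(config = scfg, ledger = ledger)
  }
  write_ledger(sessions[[1]]$ledger, p("ledger_01.csv"))
  write_sequences(sequences_all, p("sequences.csv"))

  counts <- count_transitions(sequences_all)
  lsa <- z_scores(counts)
  edges <- significant_edges(lsa)
  write_z_matrix(lsa, p("lsa_z.csv"))
  utils::write.csv(edges, p("lsa_edges.csv"), row.names = FALSE)
  write_dot(edges, p("lsa_graph.dot"))

  eng <- build_dataset(do.call(rbind, attrs))
  utils::write.csv(as.data.frame(eng), p("engagement.csv"),
                   row.names = FALSE)
  fit <- fit_engagement_model(eng)
  write_regression(fit, p("regression.csv"))

  cfg_path <- p("config.json")
  jsonlite::write_json(config, cfg_path, auto_unbox = TRUE, pretty = TRUE)
  artifacts <- c(cfg_path, p("deck.json"), p("schedule_01.csv"), log_paths,
                 p("ledger_01.csv"), p("sequences.csv"), p("lsa_z.csv"),
                 p("lsa_edges.csv"), p("lsa_graph.dot"), p("engagement.csv"),
                 p("regression.csv"))
  manifest <- list(
    tool = "edgame",
    version = as.character(utils::packageVersion("edgame")),
    seed = as.integer(seed),
    config_hash = unname(tools::md5sum(cfg_path)),
    created = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"),
    artifacts = lapply(artifacts, function(a) {
      list(path = basename(a), md5 = unname(tools::md5sum(a)))
    })
  )
  jsonlite::write_json(manifest, p("manifest.json"), auto_unbox = TRUE,
                       pretty = TRUE)
  invisible(manifest)
}
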