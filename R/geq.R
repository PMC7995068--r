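# Game-experience questionnaire scoring --------------------------------------
#
# Likert responses are scored into per-dimension means (Core module:
# competence, immersion, flow, tension/annoyance, challenge, negative and
# positive affect; Social Presence module: psychological involvement -
# empathy / negative feelings, behavioral involvement).  The bundled
# item->dimension map is a SYNTHETIC template with generic item ids — the
# real instrument's assignment is licensed separately and must be supplied
# by the user as JSON.  Anchors run 0 ("not at all") to 4 ("extremely");
# the source material calls this a 6-point scale while printing five
# anchors, so the bounds are configurable and default to 0..4.

#' Synthetic default item-to-dimension map
#'
#' A stand-in template (three items per dimension, generic ids `core_01`
#' ... / `sp_01` ...) so the scorer runs out of the box.  Non-normative: it
#' is NOT the published instrument's assignment.
#'
#' @return Named list of class `ed_dimension_map`: dimension -> item ids.
#' @export
default_geq_map <- function() {
  dims <- list(
    competence = 1:3, sensory_imaginative_immersion = 4:6, flow = 7:9,
    tension_annoyance = 10:12, challenge = 13:15, negative_affect = 16:18,
    positive_affect = 19:21
  )
  core <- lapply(dims, function(i) sprintf("core_%02d", i))
  sp <- list(
    psych_involvement_empathy = sprintf("sp_%02d", 1:3),
    psych_involvement_negative = sprintf("sp_%02d", 4:6),
    behavioral_involvement = sprintf("sp_%02d", 7:9)
  )
  new_dimension_map(c(core, sp))
}

new_dimension_map <- function(x, allow_overlap = FALSE) {
  if (!length(x) || is.null(names(x))) {
    ed_stop("dimension map must be a named list of item-id vectors")
  }
  items <- unlist(x, use.names = FALSE)
  if (!allow_overlap && anyDuplicated(items)) {
    ed_stop("items assigned to multiple dimensions: ",
            paste(unique(items[duplicated(items)]), collapse = ", "))
  }
  structure(lapply(x, as.character), class = "ed_dimension_map")
}

#' Read an item-to-dimension map from JSON
#'
#' Format: one object, dimension name -> array of item ids.
#'
#' @param path JSON path.
#' @param allow_overlap permit an item in several dimensions.
#' @return An `ed_dimension_map`.
#' @export
read_dimension_map <- function(path, allow_overlap = FALSE) {
  if (!file.exists(path)) ed_stop("map file not found: ", path)
  m <- jsonlite::read_json(path, simplifyVector = TRUE)
  m <- m[!startsWith(names(m), "_")]  # "_comment" and friends
  new_dimension_map(m, allow_overlap = allow_overlap)
}

#' Score Likert responses into dimension means
#'
#' @param responses data.frame with columns respondent_id, item_id, score and
#'   optionally modality (e.g. board vs digital).
#' @param map an `ed_dimension_map`.
#' @param scale_min,scale_max inclusive score bounds (default 0..4).
#' @return Long data.frame: respondent_id, (modality,) dimension, score
#'   (mean of that dimension's items), n_items, n_missing.  A respondent
#'   missing some of a dimension's items is scored over the available ones
#'   with `n_missing > 0` flagging it.
#' @export
score_dimensions <- function(responses, map = default_geq_map(),
                             scale_min = 0, scale_max = 4) {
  stopifnot(inherits(map, "ed_dimension_map"))
  need <- c("respondent_id", "item_id", "score")
  if (!all(need %in% names(responses))) {
    ed_stop("responses missing columns: ",
            paste(setdiff(need, names(responses)), collapse = ", "))
  }
  bad <- responses$score < scale_min | responses$score > scale_max |
    is.na(responses$score)
  if (any(bad)) {
    ed_stop("scores outside [", scale_min, ", ", scale_max, "] at row(s) ",
            paste(utils::head(which(bad), 5), collapse = ", "))
  }
  mapped <- unlist(map, use.names = FALSE)
  unknown <- setdiff(unique(responses$item_id), mapped)
  if (length(unknown)) {
    ed_stop("items not in the dimension map: ",
            paste(unknown, collapse = ", "))
  }
  has_mod <- "modality" %in% names(responses)
  key <- if (has_mod) {
    paste(responses$respondent_id, responses$modality, sep = "\r")
  } else {
    as.character(responses$respondent_id)
  }
  out <- list()
  for (kk in unique(key)) {
    sub <- responses[key == kk, ]
    for (dim in names(map)) {
      items <- map[[dim]]
      got <- sub[sub$item_id %in% items, ]
      if (!nrow(got)) next
      row <- data.frame(
        respondent_id = sub$respondent_id[1],
        dimension = dim,
        score = mean(got$score),
        n_items = nrow(got),
        n_missing = length(items) - nrow(got),
        stringsAsFactors = FALSE
      )
      if (has_mod) row$modality <- sub$modality[1]
      out[[length(out) + 1L]] <- row
    }
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Compare two questionnaire dimensions (paired)
#'
#' Default test is the paired Wilcoxon signed-rank (the scores are ordinal
#' means); a paired t-test is available.  All-zero differences are a
#' degenerate branch reported as "no difference" (p = 1) rather than an
#' error.
#'
#' @param scores long scores from [score_dimensions()].
#' @param dim_a,dim_b dimension names to compare.
#' @param method `"wilcoxon"` or `"t"`.
#' @return list: statistic, p_value, n, direction (`sign(median(a - b))` for
#'   wilcoxon, of the mean difference for t), method, degenerate flag.
#' @export
compare_dimensions <- function(scores, dim_a, dim_b,
                               method = c("wilcoxon", "t")) {
  method <- match.arg(method)
  key <- if ("modality" %in% names(scores)) {
    paste(scores$respondent_id, scores$modality, sep = "\r")
  } else {
    as.character(scores$respondent_id)
  }
  a <- scores[scores$dimension == dim_a, ]
  b <- scores[scores$dimension == dim_b, ]
  ka <- key[scores$dimension == dim_a]
  kb <- key[scores$dimension == dim_b]
  common <- intersect(ka, kb)
  if (length(common) < 2L) ed_stop("need >= 2 paired observations")
  va <- a$score[match(common, ka)]
  vb <- b$score[match(common, kb)]
  d <- va - vb
  if (all(d == 0)) {
    return(list(statistic = NA_real_, p_value = 1, n = length(d),
                direction = 0, method = method, degenerate = TRUE))
  }
  if (method == "wilcoxon") {
    ht <- signed_rank_test(d)
    direction <- sign(stats::median(d))
  } else {
    ht <- stats::t.test(va, vb, paired = TRUE)
    direction <- sign(mean(d))
  }
  list(statistic = unname(ht$statistic), p_value = ht$p.value,
       n = length(d), direction = direction, method = method,
       degenerate = FALSE)
}

# Paired Wilcoxon signed-rank on the differences.  Zero differences are
# dropped (Wilcoxon convention); |d| is midranked so tied Likert means are
# handled.  For n <= 14 the two-sided p comes from exact enumeration of all
# 2^n sign assignments (valid with ties, unlike the classical table); larger
# n uses the normal approximation with tie-corrected variance.
signed_rank_test <- function(d) {
  d <- d[d != 0]
  n <- length(d)
  r <- rank(abs(d))
  W <- sum(r[d > 0])
  if (n <= 14L) {
    signs <- as.matrix(expand.grid(rep(list(c(0, 1)), n)))
    Wperm <- as.vector(signs %*% r)
    p <- 2 * min(mean(Wperm <= W), mean(Wperm >= W))
  } else {
    mu <- sum(r) / 2
    sigma <- sqrt(sum(r^2) / 4)
    p <- 2 * stats::pnorm(-abs(W - mu) / sigma)
  }
  list(statistic = c(V = W), p.value = min(1, p))
}
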