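# Lag sequential analysis ----------------------------------------------------
#
# Tests whether one coded behavior follows another more often than chance.
# Lag-1 transitions are pooled over players (never counted across player
# boundaries); each cell gets an adjusted-residual z-score
#
#   E[i,j] = row_i * col_j / N
#   Z[i,j] = (O[i,j] - E[i,j]) /
#            sqrt( E[i,j] * (1 - row_i/N) * (1 - col_j/N) )
#
# (the Allison-Liker adjusted residual, the standard in the education-
# technology LSA literature).  Cells with zero variance are undefined and
# never become edges.

#' Count lag transitions over a collection of coded sequences
#'
#' @param sequences a list of `ed_coded_sequence` objects (or one such
#'   object), sharing one code alphabet.
#' @param lag positive integer lag (default 1).
#' @param alphabet optional fixed code alphabet; defaults to the sorted codes
#'   observed.
#' @return An `ed_transitions` object: observed matrix `O`, `N`, marginals.
#'   Sequences shorter than `lag + 1` contribute zero transitions (warning).
#' @export
count_transitions <- function(sequences, lag = 1L, alphabet = NULL) {
  assert_scalar_number(lag, "lag", lower = 1, integer = TRUE)
  if (inherits(sequences, "ed_coded_sequence")) sequences <- list(sequences)
  codes_per_seq <- lapply(sequences, function(s) {
    if (is.data.frame(s)) s$code else as.character(s)
  })
  if (is.null(alphabet)) {
    alphabet <- sort(unique(unlist(codes_per_seq)))
  }
  k <- length(alphabet)
  O <- matrix(0L, k, k, dimnames = list(alphabet, alphabet))
  short <- 0L
  for (cs in codes_per_seq) {
    n <- length(cs)
    if (n <= lag) {
      if (n > 0L) short <- short + 1L
      next
    }
    from <- factor(cs[seq_len(n - lag)], levels = alphabet)
    to <- factor(cs[seq_len(n - lag) + lag], levels = alphabet)
    if (anyNA(from) || anyNA(to)) {
      ed_stop("sequence contains codes outside the alphabet: ",
              paste(setdiff(unique(cs), alphabet), collapse = ", "))
    }
    O <- O + table(from, to)
  }
  if (short > 0L) {
    warning(sprintf("%d sequence(s) shorter than lag+1 contribute no transitions",
                    short), call. = FALSE)
  }
  O <- matrix(as.numeric(O), k, k, dimnames = dimnames(O))
  structure(
    list(alphabet = alphabet, O = O, row = rowSums(O), col = colSums(O),
         N = sum(O), lag = as.integer(lag)),
    class = "ed_transitions"
  )
}

#' Adjusted-residual z-scores of a transition matrix
#'
#' @param counts an `ed_transitions` from [count_transitions()].
#' @return An `ed_lsa` object: expected matrix `E`, z-matrix `Z` (NA where
#'   the variance term vanishes), `N`.
#' @export
z_scores <- function(counts) {
  stopifnot(inherits(counts, "ed_transitions"))
  if (counts$N < 2) ed_stop("need at least 2 transitions, got ", counts$N)
  N <- counts$N
  E <- outer(counts$row, counts$col) / N
  v <- E * outer(1 - counts$row / N, 1 - counts$col / N)
  Z <- matrix(NA_real_, nrow(E), ncol(E), dimnames = dimnames(E))
  ok <- v > 0
  Z[ok] <- (counts$O[ok] - E[ok]) / sqrt(v[ok])
  structure(list(alphabet = counts$alphabet, O = counts$O, E = E, Z = Z,
                 N = N),
            class = "ed_lsa")
}

#' Significant behavior transitions
#'
#' One-sided by default: an edge i -> j is drawn when `Z[i,j] > threshold`
#' (the published transition graphs display excitatory transitions only);
#' set `two_sided = TRUE` to also keep inhibitory cells `Z < -threshold`.
#'
#' @param result an `ed_lsa` from [z_scores()].
#' @param threshold z threshold (default 1.96).
#' @param two_sided include strongly negative cells.
#' @return data.frame (from, to, z) in deterministic (row-major) order.
#' @export
significant_edges <- function(result, threshold = 1.96, two_sided = FALSE) {
  stopifnot(inherits(result, "ed_lsa"))
  Z <- result$Z
  keep <- !is.na(Z) & (Z > threshold | (two_sided & Z < -threshold))
  idx <- which(keep, arr.ind = TRUE)
  idx <- idx[order(idx[, 1], idx[, 2]), , drop = FALSE]
  data.frame(
    from = result$alphabet[idx[, 1]],
    to = result$alphabet[idx[, 2]],
    z = Z[idx],
    stringsAsFactors = FALSE
  )
}

#' Write a transition graph as a Graphviz DOT file
#'
#' @param edges data.frame (from, to, z) from [significant_edges()].
#' @param path output `.dot` path.
#' @param name graph name.
#' @return `path`, invisibly.
#' @export
write_dot <- function(edges, path, name = "behavior_transitions") {
  lines <- c(
    sprintf("digraph %s {", name),
    "  rankdir=LR;",
    "  node [shape=circle];",
    sprintf('  "%s" -> "%s" [label="%.1f"];', edges$from, edges$to, edges$z),
    "}"
  )
  writeLines(lines, path)
  invisible(path)
}

#' Write an LSA z-matrix as CSV
#'
#' @param result an `ed_lsa`.
#' @param path CSV path (codes as row names in the first column).
#' @return `path`, invisibly.
#' @export
write_z_matrix <- function(result, path) {
  stopifnot(inherits(result, "ed_lsa"))
  df <- data.frame(code = result$alphabet, result$Z, check.names = FALSE)
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}
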