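seq_of <- function(codes, player = "p1") {
  structure(
    data.frame(player_id = player, ordinal = seq_along(codes),
               round = seq_along(codes), code = codes,
               stringsAsFactors = FALSE),
    class = c("ed_coded_sequence", "data.frame"))
}

test_that("lag-1 transitions are counted by direct enumeration", {
  tc <- count_transitions(seq_of(c("A", "B", "A", "B")))
  expect_equal(tc$O["A", "B"], 2)
  expect_equal(tc$O["B", "A"], 1)
  expect_equal(tc$O["A", "A"], 0)
  expect_equal(tc$N, 3)
})

test_that("empty collections and short sequences are handled", {
  tc <- count_transitions(list(), alphabet = c("A", "B"))
  expect_equal(tc$N, 0)
  expect_true(all(tc$O == 0))
  expect_warning(tc2 <- count_transitions(list(seq_of("A"), seq_of(c("A", "B")))),
                 "no transitions")
  expect_equal(tc2$N, 1)
  expect_error(z_scores(count_transitions(list(), alphabet = "A")), "at least 2")
})

test_that("transitions never cross player boundaries and N matches a recount", {
  withr::local_seed(1)
  seqs <- lapply(1:100, function(i) {
    seq_of(sample(c("MR", "EP", "IC", "FT"), sample(2:30, 1), replace = TRUE),
           player = paste0("p", i))
  })
  tc <- count_transitions(seqs)
  expect_equal(tc$N, sum(vapply(seqs, nrow, integer(1)) - 1))
  # pooled matrix is invariant to player ordering
  tc_rev <- count_transitions(rev(seqs))
  expect_identical(tc$O, tc_rev$O)
})

test_that("marginals are conserved", {
  tc <- count_transitions(seq_of(c("A", "B", "B", "C", "A", "C")))
  expect_equal(sum(tc$O), tc$N)
  expect_equal(rowSums(tc$O), tc$row)
  expect_equal(colSums(tc$O), tc$col)
})

test_that("O identical to E gives all-zero z-scores", {
  # uniform 2x2 counts: E = O exactly
  tc <- count_transitions(list(), alphabet = c("A", "B"))
  tc$O <- matrix(5, 2, 2, dimnames = list(c("A", "B"), c("A", "B")))
  tc$row <- rowSums(tc$O); tc$col <- colSums(tc$O); tc$N <- sum(tc$O)
  res <- z_scores(tc)
  expect_true(all(abs(res$Z) < 1e-12))
})

test_that("z-scores match an independent evaluation of the adjusted residual", {
  tc <- count_transitions(list(), alphabet = c("A", "B"))
  tc$O <- matrix(c(10, 0, 0, 10), 2, 2, byrow = TRUE,
                 dimnames = list(c("A", "B"), c("A", "B")))
  tc$row <- rowSums(tc$O); tc$col <- colSums(tc$O); tc$N <- sum(tc$O)
  res <- z_scores(tc)
  # oracle, computed cell by cell from scalars:
  # E = 10*10/20 = 5; var = 5 * (1 - 10/20) * (1 - 10/20) = 1.25
  # z = (10 - 5)/sqrt(1.25) = 4.47213595; off-diagonal = (0-5)/sqrt(1.25)
  expect_equal(res$Z["A", "A"], 5 / sqrt(1.25), tolerance = 1e-12)
  expect_equal(res$Z["A", "B"], -5 / sqrt(1.25), tolerance = 1e-12)
  expect_equal(res$E["A", "A"], 5)
})

test_that("z-scores on random small matrices equal the formula evaluated directly", {
  withr::local_seed(42)
  for (rep in 1:20) {
    k <- sample(2:5, 1)
    codes <- LETTERS[1:k]
    s <- seq_of(sample(codes, 200, replace = TRUE))
    res <- z_scores(count_transitions(s))
    O <- res$O; N <- res$N
    rs <- rowSums(O); cs <- colSums(O)
    for (i in 1:k) for (j in 1:k) {
      E <- unname(rs[i] * cs[j] / N)
      v <- unname(E * (1 - rs[i] / N) * (1 - cs[j] / N))
      if (v > 0) {
        expect_equal(res$Z[i, j], (O[i, j] - E) / sqrt(v), tolerance = 1e-10)
      } else {
        expect_true(is.na(res$Z[i, j]))
      }
    }
  }
})

test_that("significant_edges thresholds deterministically", {
  res <- structure(list(
    alphabet = c("MR", "EP"),
    O = matrix(0, 2, 2), E = matrix(0, 2, 2),
    Z = matrix(c(28.3, 1.0, NA, -3.0), 2, 2, byrow = TRUE,
               dimnames = list(c("MR", "EP"), c("MR", "EP"))),
    N = 100), class = "ed_lsa")
  e <- significant_edges(res, 1.96)
  expect_equal(nrow(e), 1)
  expect_equal(e$from, "MR")
  expect_equal(e$to, "MR")
  expect_equal(e$z, 28.3)
  # inhibitory cells only with two_sided
  e2 <- significant_edges(res, 1.96, two_sided = TRUE)
  expect_equal(nrow(e2), 2)
  # raising the threshold above max z empties the graph
  expect_equal(nrow(significant_edges(res, 30)), 0)
  # all-NA/zero z
  res$Z[] <- 0
  expect_equal(nrow(significant_edges(res, 1.96)), 0)
})

test_that("DOT and CSV exports are written", {
  s <- seq_of(rep(c("MR", "EP"), 50))
  res <- z_scores(count_transitions(s))
  dot <- withr::local_tempfile(fileext = ".dot")
  zcsv <- withr::local_tempfile(fileext = ".csv")
  write_dot(significant_edges(res), dot)
  write_z_matrix(res, zcsv)
  expect_true(any(grepl("->", readLines(dot))))
  expect_equal(nrow(utils::read.csv(zcsv, check.names = FALSE)), 2)
})

test_that("null sequences produce ~5% significant cells (quick check)", {
  # small version of the acceptance calibration: 40 replicates
  withr::local_seed(9)
  hits <- 0L; cells <- 0L
  for (r in 1:40) {
    s <- seq_of(sample(c("A", "B", "C", "D"), 2000, replace = TRUE))
    Z <- z_scores(count_transitions(s))$Z
    hits <- hits + sum(abs(Z) > 1.96, na.rm = TRUE)
    cells <- cells + sum(!is.na(Z))
  }
  expect_gt(hits / cells, 0.02)
  expect_lt(hits / cells, 0.09)
})
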