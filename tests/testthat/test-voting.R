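test_that("the voting score is the difference of two substitution scores", {
  expect_identical(v_score("A", "H", "L", blosum), -1)
  expect_identical(v_score("L", "L", "Y", blosum), 5)
  expect_identical(v_score("A", "-", "L", blosum), 1)   # gap term contributes 0
  expect_identical(v_score("A", "H", "-", blosum), -2)
  expect_error(v_score("-", "H", "L", blosum), "must not be a gap")
  expect_error(v_score("A", "U", "L", blosum), "'U'")
})

test_that("voting scores are antisymmetric and vanish on equal operands", {
  residues <- setdiff(blosum$alphabet, "*")
  set.seed(5)
  for (r in 1:60) {
    t <- sample(residues, 1); x <- sample(residues, 1); y <- sample(residues, 1)
    expect_identical(v_score(t, x, y, blosum), -v_score(t, y, x, blosum))
    expect_identical(v_score(t, x, x, blosum), 0)
  }
})

test_that("T-scores reduce to single votes and apply the gap rule", {
  aln <- hand_alignment("A", "H", "L")
  tab <- t_scores(aln, a_profile = 2, matrix = blosum)
  expect_identical(tab$raw_t, -1)
  expect_false(tab$gap_zeroed)

  # a gap in one group zeroes the whole column under the default rule
  aln <- hand_alignment("AL", "A-", "AL")
  tab <- t_scores(aln, a_profile = 2, matrix = blosum)
  expect_identical(tab$raw_t[2], 0)
  expect_true(tab$gap_zeroed[2])
  # ... but the column is still scored under target_gap_skip
  tab2 <- t_scores(aln, a_profile = 2, matrix = blosum, gap_rule = "target_gap_skip")
  expect_identical(tab2$raw_t[2], -score_pair(blosum, "L", "L"))
  expect_false(tab2$gap_zeroed[2])

  # m = 2 A-sequences, n = 2 ~A-sequences: 5 + 5 + (-1) + (-1)
  aln <- hand_alignment("L", c("L", "K"), c("Y", "Y"))
  expect_identical(t_scores(aln, 2, blosum)$raw_t, 8)
})

test_that("columns where the target is a gap are never reported", {
  aln <- hand_alignment("A-L", c("AHL", "AHL"), "AYL")
  tab <- t_scores(aln, 2, blosum)
  expect_identical(tab$position, c(1L, 2L))
  expect_identical(tab$residue, c("A", "L"))
})

test_that("raw column T-scores equal the direct m*n double sum", {
  set.seed(31)
  residues <- c("A", "R", "N", "D", "C", "Q", "E", "L", "K", "W", "Y", "V")
  for (r in 1:30) {
    m <- sample(1:5, 1); n <- sample(1:5, 1)
    t_res <- sample(residues, 1)
    a_col <- sample(residues, m, replace = TRUE)
    na_col <- sample(residues, n, replace = TRUE)
    aln <- hand_alignment(t_res, a_col, na_col)
    expect_equal(t_scores(aln, 2, blosum)$raw_t,
                 column_vote_oracle(t_res, a_col, na_col, blosum))
  }
})

test_that("swapping the group labels negates non-zeroed raw T-scores", {
  aln <- hand_alignment("ALWC", c("AHWC", "GLWC"), c("ALYC", "CLWC"))
  fwd <- t_scores(aln, a_profile = 2, matrix = blosum)
  rev <- t_scores(aln, a_profile = 3, matrix = blosum)
  expect_equal(rev$raw_t, -fwd$raw_t)
})

test_that("T-scores are a pure column computation, independent of alignment parameters", {
  fx <- generate_family(family_config(target_length = 30, planted = 2, seed = 3))
  tgt <- profile(fx$target, label = "target")
  pa <- profile(unname(fx$a_group), label = "A")
  pna <- profile(unname(fx$na_group), label = "~A")
  t1 <- t_scores(align_three(tgt, pa, pna, align_params(10, 0.5, blosum)), 2, blosum)
  t2 <- t_scores(align_three(tgt, pa, pna, align_params(4, 4, blosum)), 2, blosum)
  expect_identical(t1$raw_t, t2$raw_t)
})

test_that("normalization maps the range onto [0, 100] with fixed endpoints", {
  tab <- favat:::new_score_table(1:3, c("A", "C", "D"), c(0, 4, 8),
                                 rep(FALSE, 3))
  norm <- normalize_scores(tab)
  expect_equal(norm$norm_t, c(0, 50, 100))
  flat <- favat:::new_score_table(1:3, c("A", "C", "D"), c(2, 2, 2), rep(FALSE, 3))
  expect_warning(flat <- normalize_scores(flat), "all raw T-scores are equal")
  expect_identical(flat$norm_t, c(0, 0, 0))
})

test_that("normalization is invariant under positive affine transforms", {
  set.seed(13)
  for (r in 1:20) {
    raw <- round(stats::rnorm(sample(3:40, 1), sd = 20), 3)
    if (max(raw) == min(raw)) raw[1] <- raw[1] + 1
    tab <- favat:::new_score_table(seq_along(raw), rep("A", length(raw)), raw,
                                   rep(FALSE, length(raw)))
    norm <- normalize_scores(tab)$norm_t
    expect_true(all(norm >= 0 & norm <= 100))
    expect_equal(norm[which.min(raw)], 0)
    expect_equal(norm[which.max(raw)], 100)
    cc <- stats::runif(1, 0.1, 5); d <- stats::rnorm(1, sd = 10)
    tab2 <- favat:::new_score_table(seq_along(raw), rep("A", length(raw)),
                                    cc * raw + d, rep(FALSE, length(raw)))
    expect_equal(normalize_scores(tab2)$norm_t, norm, tolerance = 1e-9)
    expect_identical(order(norm), order(raw))
  }
})

test_that("candidate selection uses a strict threshold and stable ordering", {
  tab <- favat:::new_score_table(c(10L, 20L, 30L, 40L, 50L),
                                 c("A", "C", "D", "E", "F"),
                                 c(65, 59.9, 80, 0, 100), rep(FALSE, 5))
  tab <- normalize_scores(tab)   # raw already spans 0..100
  hits <- select_candidates(tab, 60)
  expect_identical(hits$position, c(50L, 30L, 10L))
  expect_identical(select_candidates(tab, 100)$position, integer(0))
  expect_identical(select_candidates(tab, 0)$position, c(50L, 30L, 10L, 20L))
  raw <- favat:::new_score_table(1L, "A", 1, FALSE)
  expect_error(select_candidates(raw, 60), "normalized")
})

test_that("merging two votes keeps positions that pass in both", {
  mk <- function(scores) {
    tab <- favat:::new_score_table(seq_along(scores), rep("A", length(scores)),
                                   scores, rep(FALSE, length(scores)))
    normalize_scores(tab)
  }
  t1 <- mk(c(0, 65, 70, 100))
  t2 <- mk(c(0, 70, 50, 100))
  expect_identical(merge_votes(t1, t2, 60), c(2L, 4L))
  other <- favat:::new_score_table(1:3, c("A", "C", "D"), c(0, 50, 100),
                                   rep(FALSE, 3))
  expect_error(merge_votes(t1, normalize_scores(other), 60), "same target")
})

test_that("score reports round-trip their essential columns through TSV", {
  aln <- hand_alignment("ALWC", c("AHWC", "GLWC"), c("ALYC", "CLWC"))
  tab <- normalize_scores(t_scores(aln, 2, blosum))
  path <- tempfile(fileext = ".tsv")
  write_score_table(tab, path, threshold = 60)
  again <- utils::read.delim(path, comment.char = "#")
  expect_equal(again$position, tab$position)
  expect_equal(again$raw_t, tab$raw_t)
  expect_equal(again$norm_t, tab$norm_t, tolerance = 1e-6)
  expect_identical(again$selected, tab$norm_t > 60)
})
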