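test_that("profile-pair column scores follow the weighted sum-of-pairs rule", {
  expect_identical(profile_pair_score("A", "H", 1, 1, blosum), -2)
  expect_identical(profile_pair_score("A", "-", 1, 1, blosum), 0)
  expect_identical(profile_pair_score("-", "A", 5, 1, blosum), 0)
  # all four pairs at weight 1/2 each: 0.25*(-2) + 0.25*(-1), twice
  expect_equal(profile_pair_score(c("A", "A"), c("H", "L"),
                                  c(0.5, 0.5), c(0.5, 0.5), blosum), -1.5)
  expect_error(profile_pair_score("A", "U", 1, 1, blosum), "'U'")
})

test_that("identical single sequences align gaplessly at the self-match score", {
  p <- profile("ACD")
  aln <- align_three(p, p, p, align_params(10, 0.5, blosum))
  expect_identical(aln$column_types, rep("rrr", 3))
  # single-sequence profiles have weight 1, so each column scores 3*M(r,r)
  expect_equal(aln$score,
               3 * (score_pair(blosum, "A", "A") + score_pair(blosum, "C", "C") +
                      score_pair(blosum, "D", "D")))
  oracle <- brute_force_align(p, p, p, align_params(10, 0.5, blosum))
  expect_equal(aln$score, oracle$score)
})

test_that("dynamic programming matches the exhaustive oracle on a gapped case", {
  pr <- align_params(2, 1, blosum)
  a <- align_three(profile("AC"), profile("AC"), profile("C"), pr)
  b <- brute_force_align(profile("AC"), profile("AC"), profile("C"), pr)
  expect_equal(a$score, b$score)
  expect_equal(rescore(a), a$score, tolerance = 1e-12)
})

test_that("empty and oversized profiles are rejected", {
  expect_error(align_three(profile("A"), profile("A"), profile("")), "empty profile")
  expect_error(brute_force_align(profile("A"), profile("A"), profile("")),
               "empty profile")
  long <- profile("ACDEACD")
  expect_error(brute_force_align(long, profile("A"), profile("A")), "length <= 6")
})

test_that("optimal scores equal the oracle across random instances", {
  set.seed(101)
  for (r in 1:25) {
    m <- random_matrix()
    g <- sort(runif(2, 0, 5), decreasing = TRUE)
    pr <- align_params(g[1], g[2], m, end_gaps_free = (r %% 4 == 0))
    p1 <- random_profile(); p2 <- random_profile(); p3 <- random_profile()
    dp <- align_three(p1, p2, p3, pr)
    oracle <- brute_force_align(p1, p2, p3, pr)
    expect_equal(dp$score, oracle$score, tolerance = 1e-9)
    expect_equal(rescore(dp), dp$score, tolerance = 1e-9)
  }
})

test_that("stripping inserted gap columns recovers the input profiles", {
  set.seed(7)
  for (r in 1:10) {
    p1 <- random_profile(); p2 <- random_profile(); p3 <- random_profile()
    aln <- align_three(p1, p2, p3, align_params(3, 1, blosum))
    inputs <- list(p1, p2, p3)
    for (x in 1:3) {
      rec <- favat:::strip_gap_columns(aln$profiles[[x]])
      expect_identical(rec$seqs, inputs[[x]]$seqs)
    }
    expect_false(any(aln$column_types == "---"))
  }
})

test_that("the objective is symmetric under profile permutation", {
  set.seed(11)
  p <- list(random_profile(), random_profile(), random_profile())
  pr <- align_params(4, 1, blosum)
  ref <- align_three(p[[1]], p[[2]], p[[3]], pr)$score
  for (perm in list(c(1, 3, 2), c(2, 1, 3), c(2, 3, 1), c(3, 1, 2), c(3, 2, 1)))
    expect_equal(align_three(p[[perm[1]]], p[[perm[2]]], p[[perm[3]]], pr)$score,
                 ref, tolerance = 1e-9)
})

test_that("with a duplicated third sequence and no gap costs the problem reduces to a pairwise alignment", {
  set.seed(23)
  for (r in 1:8) {
    s1 <- paste(sample(c("A", "C", "D", "E", "L"), sample(2:4, 1), replace = TRUE),
                collapse = "")
    s2 <- paste(sample(c("A", "C", "D", "E", "L"), sample(2:4, 1), replace = TRUE),
                collapse = "")
    pr <- align_params(0, 0, blosum)
    three <- brute_force_align(profile(s1), profile(s2), profile(s2), pr)$score
    selfsum <- sum(vapply(strsplit(s2, "")[[1]],
                          function(ch) score_pair(blosum, ch, ch), numeric(1)))
    expect_equal(three, 2 * nw_zero_gap(s1, s2, blosum) + selfsum, tolerance = 1e-9)
  }
})

test_that("free end gaps rescue terminal overhangs", {
  # a long overhang of p1 against short p2/p3: costed under default params,
  # free when end_gaps_free is set; both must match the oracle
  p1 <- profile("ACDEAC"); p2 <- profile("AC"); p3 <- profile("AC")
  for (free in c(FALSE, TRUE)) {
    pr <- align_params(5, 1, blosum, end_gaps_free = free)
    dp <- align_three(p1, p2, p3, pr)
    oracle <- brute_force_align(p1, p2, p3, pr)
    expect_equal(dp$score, oracle$score, tolerance = 1e-9)
    expect_equal(rescore(dp), dp$score, tolerance = 1e-9)
  }
  free_score <- align_three(p1, p2, p3, align_params(5, 1, blosum, TRUE))$score
  costed <- align_three(p1, p2, p3, align_params(5, 1, blosum, FALSE))$score
  expect_gt(free_score, costed)
})

test_that("rescore rejects malformed alignments", {
  aln <- align_three(profile("AC"), profile("AC"), profile("AC"),
                     align_params(2, 1, blosum))
  bad <- aln
  bad$profiles[[1]] <- profile("AC-", allow_gap_columns = TRUE)
  bad$profiles[[2]] <- profile("AC-", allow_gap_columns = TRUE)
  bad$profiles[[3]] <- profile("AC-", allow_gap_columns = TRUE)
  expect_error(rescore(bad), "all-gap")
  bad2 <- aln
  bad2$profiles[[1]] <- profile("ACD")
  expect_error(rescore(bad2), "unequal column counts")
})
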