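# shared fixtures and independent oracles, built in code

blosum <- load_matrix("BLOSUM62")

# write a random symmetric integer matrix (diagonal > off-diagonal) in NCBI
# flat layout and load it through the parser
random_matrix <- function(alphabet = c("A", "C", "D", "E"), lo = -4, hi = 3) {
  k <- length(alphabet)
  s <- matrix(sample(lo:hi, k * k, replace = TRUE), k, k)
  s[lower.tri(s)] <- t(s)[lower.tri(s)]
  diag(s) <- max(s) + sample(1:3, k, replace = TRUE)
  path <- tempfile(fileext = ".mat")
  writeLines(c(paste(alphabet, collapse = " "),
               vapply(seq_len(k), function(i)
                 paste(alphabet[i], paste(s[i, ], collapse = " ")), character(1))),
             path)
  load_matrix(path)
}

random_profile <- function(alphabet = c("A", "C", "D", "E"), max_len = 4,
                           max_seqs = 2, weights = "uniform") {
  n_seq <- sample(seq_len(max_seqs), 1)
  len <- sample(seq_len(max_len), 1)
  seqs <- vapply(seq_len(n_seq), function(i)
    paste(sample(alphabet, len, replace = TRUE), collapse = ""), character(1))
  profile(seqs, weights = weights)
}

# pairwise global alignment score with zero gap costs: best monotone
# matching of columns (simple Needleman-Wunsch, no affine machinery)
nw_zero_gap <- function(s1, s2, matrix) {
  a <- strsplit(s1, "")[[1]]; b <- strsplit(s2, "")[[1]]
  dp <- matrix(0, length(a) + 1, length(b) + 1)
  for (i in seq_along(a))
    for (j in seq_along(b))
      dp[i + 1, j + 1] <- max(dp[i, j + 1], dp[i + 1, j],
                              dp[i, j] + score_pair(matrix, a[i], b[j]))
  dp[length(a) + 1, length(b) + 1]
}

# direct m*n double-sum voting oracle for one column
column_vote_oracle <- function(t_res, a_col, na_col, matrix) {
  total <- 0
  for (a in a_col)
    for (b in na_col)
      total <- total + v_score(t_res, a, b, matrix)
  total
}

# hand-build a three-way alignment from gapped strings
hand_alignment <- function(target, a_seqs, na_seqs) {
  as_three_alignment(
    profile(target, label = "target", allow_gap_columns = TRUE),
    profile(a_seqs, label = "A", allow_gap_columns = TRUE),
    profile(na_seqs, label = "~A", allow_gap_columns = TRUE))
}

top_positions <- function(table, n) {
  stopifnot(isTRUE(attr(table, "normalized")))
  table$position[order(-table$norm_t, table$position)][seq_len(n)]
}
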