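# Column shapes of a three-profile alignment, in traceback-preference
# order.  A column either consumes the next column of a profile (r) or
# gives it an all-gap column (-); '---' is not a column.
SHAPE_NAMES <- c("rrr", "rr-", "r-r", "-rr", "r--", "-r-", "--r")
SHAPE_BITS <- matrix(c(1, 1, 1,
                       1, 1, 0,
                       1, 0, 1,
                       0, 1, 1,
                       1, 0, 0,
                       0, 1, 0,
                       0, 0, 1), ncol = 3, byrow = TRUE)

#' Alignment parameters
#'
#' @param gap_open Gap-opening penalty (GOP), charged when a pairwise
#'   projection enters a residue-vs-gap run. Must satisfy
#'   `gap_open >= gap_extend >= 0`.
#' @param gap_extend Gap-extension penalty (GEP), charged per additional
#'   column of a run.
#' @param matrix A `subst_matrix`; default built-in BLOSUM62.
#' @param end_gaps_free If `TRUE`, gap columns before the first and after
#'   the last residue-pair column of each pairwise projection are free.
#' @return An `align_params` object.
#' @export
align_params <- function(gap_open = 10, gap_extend = 0.5,
                         matrix = load_matrix("BLOSUM62"),
                         end_gaps_free = FALSE) {
  stopifnot(inherits(matrix, "subst_matrix"), is.logical(end_gaps_free))
  if (!(gap_open >= gap_extend && gap_extend >= 0))
    stop("gap penalties must satisfy gap_open >= gap_extend >= 0", call. = FALSE)
  structure(list(gap_open = gap_open, gap_extend = gap_extend,
                 matrix = matrix, end_gaps_free = isTRUE(end_gaps_free)),
            class = "align_params")
}

# per-column weighted residue counts: one row per alphabet symbol.
# Gaps contribute nothing; symbols outside the matrix alphabet are an error.
weight_counts <- function(p, matrix) {
  alpha <- matrix$alphabet
  seen <- setdiff(unique(as.vector(p$mat)), GAP)
  bad <- setdiff(seen, alpha)
  if (length(bad))
    stop("residue(s) ", paste(sQuote(bad), collapse = ", "),
         " not in the alphabet of matrix ", matrix$name, call. = FALSE)
  C <- matrix(0, length(alpha), p$length)
  idx <- match(p$mat, alpha)
  dim(idx) <- dim(p$mat)
  for (a in seq_along(p$seqs)) {
    nz <- which(!is.na(idx[a, ]))
    if (length(nz)) {
      cells <- cbind(idx[a, nz], nz)
      C[cells] <- C[cells] + p$weights[a]
    }
  }
  C
}

sp_matrix <- function(px, py, matrix) {
  crossprod(weight_counts(px, matrix), matrix$scores %*% weight_counts(py, matrix))
}

#' Weighted sum-of-pairs score of two profile columns
#'
#' Returns the sum over all sequence pairs (a, b) of
#' `W_a * W_b * M[r_x(a), r_y(b)]`; any pair in which either symbol is a
#' gap contributes 0 (alignment-level gap columns are costed separately by
#' the affine gap model, so intra-profile gaps are not charged twice).
#'
#' @param px_col,py_col Character vectors: one column from each profile.
#' @param wx,wy Sequence weights aligned to the column entries.
#' @param matrix A `subst_matrix`.
#' @return A numeric score.
#' @export
profile_pair_score <- function(px_col, py_col, wx, wy, matrix) {
  stopifnot(length(px_col) == length(wx), length(py_col) == length(wy))
  total <- 0
  for (a in seq_along(px_col)) {
    if (px_col[a] == GAP) next
    for (b in seq_along(py_col)) {
      if (py_col[b] == GAP) next
      total <- total + wx[a] * wy[b] * score_pair(matrix, px_col[a], py_col[b])
    }
  }
  total
}

# Objective on a complete column-shape sequence (quasi-natural affine gap
# costs per pairwise projection): RR columns add the pairwise Sp score, GG
# columns are free, and an RG/GR column costs GEP when the immediately
# preceding column has the same projected state, otherwise GOP.  With free
# end gaps, gap columns outside a projection's first..last RR column are
# free.  This scorer is definition-based and shared by rescore() and the
# brute-force oracle; it is independent of the DP internals.
score_shapes <- function(shapes, sp12, sp13, sp23, gap_open, gap_extend,
                         end_gaps_free) {
  d <- SHAPE_BITS[shapes, , drop = FALSE]
  i <- cumsum(d[, 1]); j <- cumsum(d[, 2]); k <- cumsum(d[, 3])
  total <- 0
  rr <- d[, 1] & d[, 2]
  if (any(rr)) total <- total + sum(sp12[cbind(i[rr], j[rr])])
  rr <- d[, 1] & d[, 3]
  if (any(rr)) total <- total + sum(sp13[cbind(i[rr], k[rr])])
  rr <- d[, 2] & d[, 3]
  if (any(rr)) total <- total + sum(sp23[cbind(j[rr], k[rr])])

  pair_cost <- function(f) {
    cost <- 0
    if (end_gaps_free) {
      rrpos <- which(f == 3L)
      if (length(rrpos) == 0L) return(0)
      lo <- min(rrpos); hi <- max(rrpos)
      for (t in seq_along(f)) {
        if (t <= lo || t >= hi) next
        if (f[t] == 1L || f[t] == 2L)
          cost <- cost + if (f[t] == f[t - 1L]) gap_extend else gap_open
      }
    } else {
      e <- -1L
      for (t in seq_along(f)) {
        if (f[t] == 1L || f[t] == 2L)
          cost <- cost + if (f[t] == e) gap_extend else gap_open
        e <- f[t]
      }
    }
    cost
  }
  total - pair_cost(2L * d[, 1] + d[, 2]) -
    pair_cost(2L * d[, 1] + d[, 3]) -
    pair_cost(2L * d[, 2] + d[, 3])
}

check_alignable <- function(p1, p2, p3) {
  for (p in list(p1, p2, p3)) {
    if (!inherits(p, "profile")) stop("inputs must be profile objects", call. = FALSE)
    if (p$length == 0L) stop("cannot align an empty profile", call. = FALSE)
  }
}

build_three_alignment <- function(p1, p2, p3, shapes, score, params) {
  profs <- list(p1, p2, p3)
  aligned <- vector("list", 3L)
  for (x in 1:3) {
    p <- profs[[x]]
    use <- SHAPE_BITS[shapes, x] == 1L
    m <- matrix(GAP, nrow = length(p$seqs), ncol = length(shapes))
    m[, use] <- p$mat
    seqs <- apply(m, 1L, paste, collapse = "")
    aligned[[x]] <- new_profile(seqs, p$ids, m, p$weights, p$label)
  }
  structure(list(profiles = aligned, score = score,
                 column_types = SHAPE_NAMES[shapes], params = params),
            class = "three_alignment")
}

#' Optimal three-profile alignment by dynamic programming
#'
#' Globally aligns three profiles under a sum-of-pairs objective: each
#' column contributes the pairwise column scores `Sp(1,2) + Sp(1,3) +
#' Sp(2,3)` of its three pairwise projections, with affine gap costs
#' charged independently to each projection (see [align_params()] and the
#' package vignette for the exact gap convention). Seven DP state layers,
#' one per column shape, are evaluated in `O(L1*L2*L3)` time; traceback
#' ties prefer shapes in the order `rrr > rr- > r-r > -rr > r-- > -r- >
#' --r`, so alignments are reproducible.
#'
#' @param p1,p2,p3 Validated `profile` objects.
#' @param params An `align_params` object.
#' @return A `three_alignment`: the three gapped profiles (equal column
#'   count), the optimal `score`, and the per-column shape in
#'   `column_types`.
#' @export
align_three <- function(p1, p2, p3, params = align_params()) {
  stopifnot(inherits(params, "align_params"))
  check_alignable(p1, p2, p3)
  sp12 <- sp_matrix(p1, p2, params$matrix)
  sp13 <- sp_matrix(p1, p3, params$matrix)
  sp23 <- sp_matrix(p2, p3, params$matrix)
  res <- .favat_dp(sp12, sp13, sp23, params$gap_open, params$gap_extend,
                   params$end_gaps_free)
  build_three_alignment(p1, p2, p3, res$shapes, res$score, params)
}

#' Exhaustive-enumeration alignment oracle
#'
#' Enumerates every legal sequence of column shapes that consumes all
#' columns of all three profiles, scores each complete alignment with the
#' same objective as [align_three()], and returns an argmax. Intended as an
#' independent correctness oracle; profile lengths are capped at 6.
#'
#' @inheritParams align_three
#' @return A `three_alignment` with the maximal score.
#' @export
brute_force_align <- function(p1, p2, p3, params = align_params()) {
  stopifnot(inherits(params, "align_params"))
  check_alignable(p1, p2, p3)
  n <- c(p1$length, p2$length, p3$length)
  if (any(n > 6L))
    stop("brute_force_align is limited to profiles of length <= 6", call. = FALSE)
  sp12 <- sp_matrix(p1, p2, params$matrix)
  sp13 <- sp_matrix(p1, p3, params$matrix)
  sp23 <- sp_matrix(p2, p3, params$matrix)
  gop <- params$gap_open; gep <- params$gap_extend
  env <- new.env()
  env$best <- -Inf
  env$shapes <- NULL
  maxlen <- sum(n)
  path <- integer(maxlen)

  if (params$end_gaps_free) {
    recurse <- function(depth, i, j, k) {
      if (i == n[1] && j == n[2] && k == n[3]) {
        sc <- score_shapes(path[seq_len(depth)], sp12, sp13, sp23, gop, gep, TRUE)
        if (sc > env$best) { env$best <- sc; env$shapes <- path[seq_len(depth)] }
        return(invisible())
      }
      for (s in 1:7) {
        ii <- i + SHAPE_BITS[s, 1]; jj <- j + SHAPE_BITS[s, 2]; kk <- k + SHAPE_BITS[s, 3]
        if (ii > n[1] || jj > n[2] || kk > n[3]) next
        path[depth + 1L] <<- s
        recurse(depth + 1L, ii, jj, kk)
      }
    }
    recurse(0L, 0L, 0L, 0L)
  } else {
    # incremental scoring: e12/e13/e23 are the previous column's projected
    # pair states (3 RR, 2 RG, 1 GR, 0 GG; -1 before the first column)
    recurse <- function(depth, i, j, k, acc, e12, e13, e23) {
      if (i == n[1] && j == n[2] && k == n[3]) {
        if (acc > env$best) { env$best <- acc; env$shapes <- path[seq_len(depth)] }
        return(invisible())
      }
      for (s in 1:7) {
        d1 <- SHAPE_BITS[s, 1]; d2 <- SHAPE_BITS[s, 2]; d3 <- SHAPE_BITS[s, 3]
        ii <- i + d1; jj <- j + d2; kk <- k + d3
        if (ii > n[1] || jj > n[2] || kk > n[3]) next
        sc <- acc
        f12 <- 2L * d1 + d2; f13 <- 2L * d1 + d3; f23 <- 2L * d2 + d3
        if (f12 == 3L) sc <- sc + sp12[ii, jj]
        else if (f12 != 0L) sc <- sc - (if (f12 == e12) gep else gop)
        if (f13 == 3L) sc <- sc + sp13[ii, kk]
        else if (f13 != 0L) sc <- sc - (if (f13 == e13) gep else gop)
        if (f23 == 3L) sc <- sc + sp23[jj, kk]
        else if (f23 != 0L) sc <- sc - (if (f23 == e23) gep else gop)
        path[depth + 1L] <<- s
        recurse(depth + 1L, ii, jj, kk, sc, f12, f13, f23)
      }
    }
    recurse(0L, 0L, 0L, 0L, 0, -1L, -1L, -1L)
  }
  build_three_alignment(p1, p2, p3, env$shapes, env$best, params)
}

#' Recompute an alignment's score from its columns alone
#'
#' Derives the column-shape sequence from the gapped profiles (a profile
#' contributes a column unless all its sequences show a gap there), strips
#' the inserted gap columns to recover the input profiles, and evaluates
#' the alignment objective from the definition, independently of any DP
#' internals.
#'
#' @param alignment A `three_alignment`.
#' @param params An `align_params`; defaults to the parameters stored in
#'   the alignment.
#' @return The numeric objective value.
#' @export
rescore <- function(alignment, params = alignment$params) {
  stopifnot(inherits(alignment, "three_alignment"), inherits(params, "align_params"))
  lens <- vapply(alignment$profiles, function(p) p$length, integer(1L))
  if (length(unique(lens)) != 1L)
    stop("malformed alignment: profiles have unequal column counts", call. = FALSE)
  used <- vapply(alignment$profiles,
                 function(p) colSums(p$mat == GAP) < nrow(p$mat), logical(lens[1L]))
  used <- matrix(used, nrow = lens[1L])
  if (any(rowSums(used) == 0L))
    stop("malformed alignment: a column is all-gap in all three profiles", call. = FALSE)
  shapes <- match(apply(used, 1L, function(u) paste(ifelse(u, "r", "-"), collapse = "")),
                  SHAPE_NAMES)
  inputs <- lapply(alignment$profiles, strip_gap_columns)
  sp12 <- sp_matrix(inputs[[1L]], inputs[[2L]], params$matrix)
  sp13 <- sp_matrix(inputs[[1L]], inputs[[3L]], params$matrix)
  sp23 <- sp_matrix(inputs[[2L]], inputs[[3L]], params$matrix)
  score_shapes(shapes, sp12, sp13, sp23, params$gap_open, params$gap_extend,
               params$end_gaps_free)
}

#' Assemble a three-way alignment from pre-aligned profiles
#'
#' For workflows where the three mutually aligned profiles already exist
#' (e.g. re-reading the FASTA files written by [write_alignment()]).
#'
#' @param p1,p2,p3 `profile` objects of equal column count; columns that
#'   are all-gap within a profile are interpreted as alignment gap columns.
#' @param params Optional `align_params` used to compute the score.
#' @return A `three_alignment`.
#' @export
as_three_alignment <- function(p1, p2, p3, params = align_params()) {
  lens <- c(p1$length, p2$length, p3$length)
  if (length(unique(lens)) != 1L)
    stop("aligned profiles must have equal column counts", call. = FALSE)
  aln <- structure(list(profiles = list(p1, p2, p3), score = NA_real_,
                        column_types = NULL, params = params),
                   class = "three_alignment")
  used <- vapply(aln$profiles,
                 function(p) colSums(p$mat == GAP) < nrow(p$mat), logical(lens[1L]))
  used <- matrix(used, nrow = lens[1L])
  if (any(rowSums(used) == 0L))
    stop("malformed alignment: a column is all-gap in all three profiles", call. = FALSE)
  aln$column_types <- apply(used, 1L, function(u)
    paste(ifelse(u, "r", "-"), collapse = ""))
  aln$score <- rescore(aln, params)
  aln
}

#' Write the three aligned profiles of an alignment
#'
#' One concatenated aligned-FASTA file; each header carries a
#' `group=<label>` tag so the three profiles can be recovered.
#'
#' @param alignment A `three_alignment`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_alignment <- function(alignment, path) {
  stopifnot(inherits(alignment, "three_alignment"))
  lines <- unlist(lapply(alignment$profiles, function(p) {
    lab <- if (nzchar(p$label)) p$label else "unlabelled"
    paste0(">", p$ids, " group=", lab, "\n", p$seqs)
  }))
  writeLines(lines, path)
  invisible(path)
}

#' @export
print.three_alignment <- function(x, ...) {
  cat("Three-profile alignment: ", length(x$column_types), " columns, score ",
      format(x$score), "\n", sep = "")
  cat("  shapes: ", paste(substr(x$column_types, 1, 1), collapse = ""), " / ",
      paste(substr(x$column_types, 2, 2), collapse = ""), " / ",
      paste(substr(x$column_types, 3, 3), collapse = ""), "\n", sep = "")
  invisible(x)
}
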