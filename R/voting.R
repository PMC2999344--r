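#' Voting score for one (target, A, ~A) residue triple
#'
#' `V = M[t, a] - M[t, na]`: positive when the target residue resembles the
#' functional (A) group more than the non-functional (~A) group. If `a` or
#' `na` is a gap, the corresponding matrix term is 0 (column-level gap
#' zeroing is handled separately by [t_scores()]).
#'
#' @param t Target residue (must not be a gap).
#' @param a Residue or gap from an A-group sequence.
#' @param na Residue or gap from a ~A-group sequence.
#' @param matrix A `subst_matrix`.
#' @return Integer voting score.
#' @examples
#' v_score("A", "H", "L", load_matrix("BLOSUM62"))  # -2 - (-1) = -1
#' @export
v_score <- function(t, a, na, matrix = load_matrix("BLOSUM62")) {
  if (t == GAP) stop("target residue must not be a gap", call. = FALSE)
  term_a <- if (a == GAP) 0 else score_pair(matrix, t, a)
  term_na <- if (na == GAP) 0 else score_pair(matrix, t, na)
  term_a - term_na
}

#' Accumulate per-residue T-scores from a three-way alignment
#'
#' For every alignment column where the target shows a residue, the raw
#' T-score is the sum of the `m * n` voting scores over all (A-sequence,
#' ~A-sequence) pairs. Under the default `"any_gap_zero"` rule, a column in
#' which any sequence of any group shows a gap receives a raw T-score of 0
#' (flagged `gap_zeroed`); under `"target_gap_skip"` only the per-pair gap
#' terms drop out and the column is still scored. Columns where the target
#' itself is a gap are never reported. Voting uses unweighted substitution
#' scores regardless of the weights used during alignment.
#'
#' @param alignment A `three_alignment` whose first profile is the target
#'   (exactly one sequence).
#' @param a_profile Which profile (2 or 3) is the functional A group; the
#'   other is the ~A group.
#' @param matrix A `subst_matrix`.
#' @param gap_rule `"any_gap_zero"` (default) or `"target_gap_skip"`.
#' @return A `favat_scores` data frame with columns `position` (1-based in
#'   the ungapped target), `residue`, `raw_t`, `norm_t` (`NA` until
#'   [normalize_scores()]), `gap_zeroed`.
#' @export
t_scores <- function(alignment, a_profile = 2L,
                     matrix = load_matrix("BLOSUM62"),
                     gap_rule = c("any_gap_zero", "target_gap_skip")) {
  stopifnot(inherits(alignment, "three_alignment"))
  gap_rule <- match.arg(gap_rule)
  if (!a_profile %in% c(2L, 3L))
    stop("a_profile must be 2 or 3", call. = FALSE)
  target <- alignment$profiles[[1L]]
  if (length(target$seqs) != 1L)
    stop("the target profile (profile 1) must contain exactly one sequence",
         call. = FALSE)
  pa <- alignment$profiles[[a_profile]]
  pna <- alignment$profiles[[if (a_profile == 2L) 3L else 2L]]
  tchars <- target$mat[1L, ]
  keep <- which(tchars != GAP)
  M <- matrix$scores
  n_a <- nrow(pa$mat); n_na <- nrow(pna$mat)

  raw <- numeric(length(keep))
  zeroed <- logical(length(keep))
  for (r in seq_along(keep)) {
    col <- keep[r]
    t_res <- tchars[col]
    acol <- pa$mat[, col]; nacol <- pna$mat[, col]
    if (gap_rule == "any_gap_zero" && (any(acol == GAP) || any(nacol == GAP))) {
      zeroed[r] <- TRUE
      next
    }
    ares <- acol[acol != GAP]; nares <- nacol[nacol != GAP]
    check <- setdiff(c(t_res, ares, nares), matrix$alphabet)
    if (length(check))
      stop("residue(s) ", paste(sQuote(check), collapse = ", "),
           " not in the alphabet of matrix ", matrix$name, call. = FALSE)
    sum_a <- if (length(ares)) sum(M[t_res, ares]) else 0
    sum_na <- if (length(nares)) sum(M[t_res, nares]) else 0
    raw[r] <- n_na * sum_a - n_a * sum_na
  }
  new_score_table(position = seq_along(keep),
                  residue = tchars[keep],
                  raw_t = raw, gap_zeroed = zeroed,
                  target_id = target$ids[1L],
                  gap_rule = gap_rule, matrix_name = matrix$name)
}

new_score_table <- function(position, residue, raw_t, gap_zeroed,
                            target_id = "", gap_rule = "", matrix_name = "") {
  df <- data.frame(position = as.integer(position), residue = residue,
                   raw_t = raw_t, norm_t = NA_real_, gap_zeroed = gap_zeroed,
                   stringsAsFactors = FALSE)
  structure(df, class = c("favat_scores", "data.frame"),
            min_raw = min(raw_t), max_raw = max(raw_t),
            normalized = FALSE, target_id = target_id,
            gap_rule = gap_rule, matrix_name = matrix_name)
}

#' Normalize raw T-scores to the 0-100 range
#'
#' `norm_t = (raw_t - min) / (max - min) * 100`, with the minimum and
#' maximum taken over all reported entries (gap-zeroed columns included).
#' If all raw scores are equal every normalized score is 0 and a warning is
#' issued.
#'
#' @param table A `favat_scores` table from [t_scores()].
#' @return The table with `norm_t` filled in.
#' @export
normalize_scores <- function(table) {
  stopifnot(inherits(table, "favat_scores"))
  if (nrow(table) == 0L) stop("cannot normalize an empty score table", call. = FALSE)
  lo <- min(table$raw_t); hi <- max(table$raw_t)
  if (hi == lo) {
    warning("all raw T-scores are equal; normalized scores set to 0", call. = FALSE)
    table$norm_t <- rep(0, nrow(table))
  } else {
    table$norm_t <- (table$raw_t - lo) / (hi - lo) * 100
  }
  attr(table, "min_raw") <- lo
  attr(table, "max_raw") <- hi
  attr(table, "normalized") <- TRUE
  table
}

#' Select candidate functional residues
#'
#' Entries whose normalized T-score strictly exceeds the threshold, sorted
#' by decreasing score (ties by increasing position).
#'
#' @param table A normalized `favat_scores` table.
#' @param threshold Normalized-score cutoff in `[0, 100]`; default 60.
#' @return A data frame with `position`, `residue`, `norm_t`.
#' @export
select_candidates <- function(table, threshold = 60) {
  stopifnot(inherits(table, "favat_scores"))
  if (!isTRUE(attr(table, "normalized")))
    stop("score table must be normalized before selection", call. = FALSE)
  if (threshold < 0 || threshold > 100)
    stop("threshold must be in [0, 100]", call. = FALSE)
  hit <- table[table$norm_t > threshold, c("position", "residue", "norm_t")]
  hit <- hit[order(-hit$norm_t, hit$position), ]
  rownames(hit) <- NULL
  hit
}

#' Merge two votes over the same target
#'
#' Positions whose normalized T-score exceeds the threshold in *both*
#' votes (e.g. the target voted against two different A groups), sorted in
#' ascending order.
#'
#' @param table1,table2 Normalized `favat_scores` tables over the same
#'   target sequence.
#' @param threshold Cutoff applied to each vote; default 60.
#' @return Integer vector of target positions.
#' @export
merge_votes <- function(table1, table2, threshold = 60) {
  for (tb in list(table1, table2)) {
    stopifnot(inherits(tb, "favat_scores"))
    if (!isTRUE(attr(tb, "normalized")))
      stop("both score tables must be normalized", call. = FALSE)
  }
  if (!identical(table1$position, table2$position) ||
      !identical(table1$residue, table2$residue))
    stop("score tables disagree on the target positions/residues; ",
         "they must describe the same target sequence", call. = FALSE)
  sort(table1$position[table1$norm_t > threshold & table2$norm_t > threshold])
}

#' Write a T-score report as TSV
#'
#' `#`-prefixed header lines record the parameters; then one row per
#' target residue with columns `position`, `residue`, `raw_t`, `norm_t`,
#' `gap_zeroed`, `selected`.
#'
#' @param table A normalized `favat_scores` table.
#' @param path Output path.
#' @param threshold Threshold used for the `selected` column.
#' @return `path`, invisibly.
#' @export
write_score_table <- function(table, path, threshold = 60) {
  stopifnot(inherits(table, "favat_scores"))
  if (!isTRUE(attr(table, "normalized")))
    stop("score table must be normalized before writing", call. = FALSE)
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(
    paste0("# target=", attr(table, "target_id")),
    paste0("# matrix=", attr(table, "matrix_name")),
    paste0("# gap_rule=", attr(table, "gap_rule")),
    paste0("# threshold=", format(threshold)),
    paste0("# min_raw=", format(attr(table, "min_raw")),
           " max_raw=", format(attr(table, "max_raw")))), con)
  out <- data.frame(position = table$position, residue = table$residue,
                    raw_t = table$raw_t, norm_t = round(table$norm_t, 6),
                    gap_zeroed = table$gap_zeroed,
                    selected = table$norm_t > threshold)
  utils::write.table(out, con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @export
print.favat_scores <- function(x, ...) {
  cat("FAVAT score table: ", nrow(x), " target residues",
      if (isTRUE(attr(x, "normalized"))) " (normalized)" else " (raw)",
      "\n", sep = "")
  NextMethod()
}
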