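#' Run the full voting pipeline
#'
#' Reads the target (single-record FASTA) and the pre-aligned A and ~A
#' group profiles, aligns the three jointly ([align_three()]), accumulates
#' and normalizes T-scores ([t_scores()], [normalize_scores()]), and
#' selects candidates above the threshold. If a second A-group profile is
#' supplied the vote is repeated against it and the two candidate sets are
#' intersected with [merge_votes()]. Optionally writes TSV report(s), the
#' three-way alignment(s) as FASTA, and the merged position list.
#'
#' @param target_path Single-record FASTA with the target sequence.
#' @param a_path Aligned FASTA of the functional A group.
#' @param na_path Aligned FASTA of the sequence-related ~A group.
#' @param a2_path Optional second A-group profile for two-vote merging.
#' @param matrix Matrix source for [load_matrix()].
#' @param gap_open,gap_extend,end_gaps_free Alignment parameters
#'   (see [align_params()]).
#' @param weights Profile weighting scheme, `"uniform"` or `"unit"`.
#' @param gap_rule Voting gap rule (see [t_scores()]).
#' @param threshold Selection threshold on normalized T-scores, in
#'   `[0, 100]`.
#' @param out_dir Optional output directory for report files.
#' @return A list with elements `tables` (one or two normalized
#'   `favat_scores`), `alignments`, `candidates` (per vote), `merged`
#'   (positions, if two votes) and `files` (paths written).
#' @export
run_favat <- function(target_path, a_path, na_path, a2_path = NULL,
                      matrix = "BLOSUM62", gap_open = 10, gap_extend = 0.5,
                      end_gaps_free = FALSE, weights = "uniform",
                      gap_rule = "any_gap_zero", threshold = 60,
                      out_dir = NULL) {
  if (!is.numeric(threshold) || threshold < 0 || threshold > 100)
    stop("threshold must be in [0, 100]", call. = FALSE)
  mat <- if (inherits(matrix, "subst_matrix")) matrix else load_matrix(matrix)
  params <- align_params(gap_open, gap_extend, mat, end_gaps_free)

  target <- read_profile(target_path, label = "target", weights = weights)
  if (length(target$seqs) != 1L)
    stop("target FASTA must contain exactly one record, found ",
         length(target$seqs), call. = FALSE)
  groups_a <- list(read_profile(a_path, label = "A", weights = weights))
  if (!is.null(a2_path))
    groups_a <- c(groups_a, list(read_profile(a2_path, label = "A2", weights = weights)))
  grp_na <- read_profile(na_path, label = "~A", weights = weights)

  tables <- list(); alignments <- list(); candidates <- list()
  for (v in seq_along(groups_a)) {
    aln <- align_three(target, groups_a[[v]], grp_na, params)
    message("vote ", v, ": alignment of ", length(aln$column_types),
            " columns, score ", format(aln$score))
    tab <- normalize_scores(t_scores(aln, a_profile = 2L, matrix = mat,
                                     gap_rule = gap_rule))
    tables[[v]] <- tab
    alignments[[v]] <- aln
    candidates[[v]] <- select_candidates(tab, threshold)
  }
  merged <- if (length(tables) == 2L)
    merge_votes(tables[[1L]], tables[[2L]], threshold) else NULL

  files <- character(0)
  if (!is.null(out_dir)) {
    if (!dir.exists(out_dir))
      dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    for (v in seq_along(tables)) {
      rp <- file.path(out_dir, sprintf("scores_vote%d.tsv", v))
      ap <- file.path(out_dir, sprintf("alignment_vote%d.fasta", v))
      write_score_table(tables[[v]], rp, threshold)
      write_alignment(alignments[[v]], ap)
      files <- c(files, rp, ap)
    }
    if (!is.null(merged)) {
      mp <- file.path(out_dir, "merged_positions.txt")
      writeLines(as.character(merged), mp)
      files <- c(files, mp)
    }
  }
  invisible(list(tables = tables, alignments = alignments,
                 candidates = candidates, merged = merged, files = files))
}
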