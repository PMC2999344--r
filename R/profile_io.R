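#' @useDynLib favat, .registration = TRUE
#' @importFrom Rcpp evalCpp
NULL

# residue symbols accepted on input (canonical NCBI matrix alphabet)
RESIDUE_ALPHABET <- c("A", "R", "N", "D", "C", "Q", "E", "G", "H", "I", "L",
                      "K", "M", "F", "P", "S", "T", "W", "Y", "V",
                      "B", "Z", "X", "*")
AA20 <- RESIDUE_ALPHABET[1:20]
GAP <- "-"

#' Construct a group profile
#'
#' A profile is a fixed (gapped) multiple alignment of one sequence group,
#' with one positive weight per sequence. Weights enter the sum-of-pairs
#' column scores of the three-profile alignment stage; voting always uses
#' unweighted substitution scores.
#'
#' @param seqs Character vector of gapped sequences (equal lengths, gaps
#'   `-`; `.` is normalized to `-`, residues are uppercased).
#' @param ids Sequence identifiers; defaults to `seq1`, `seq2`, ...
#' @param weights Per-sequence weights, or a scheme name (`"uniform"` for
#'   1/m each, `"unit"` for 1 each).
#' @param label Free-text group tag (e.g. `"A"`, `"~A"`, `"target"`).
#' @param allow_gap_columns Permit columns that are gap in every sequence.
#'   Input group profiles forbid them; profiles that are one member of a
#'   three-way alignment (where inserted columns are all-gap) need them.
#' @return A `profile` object.
#' @export
profile <- function(seqs, ids = NULL, weights = "uniform", label = "",
                    allow_gap_columns = FALSE) {
  if (length(seqs) == 0L) stop("a profile needs at least one sequence", call. = FALSE)
  seqs <- unname(chartr(".", "-", toupper(seqs)))
  if (is.null(ids)) ids <- paste0("seq", seq_along(seqs))
  bad <- setdiff(unique(unlist(strsplit(seqs, ""))), c(RESIDUE_ALPHABET, GAP))
  if (length(bad))
    stop("illegal character(s) in sequences: ", paste(sQuote(bad), collapse = ", "),
         call. = FALSE)
  lens <- nchar(seqs)
  if (length(unique(lens)) != 1L)
    stop("ragged alignment: record lengths differ (", paste(unique(lens), collapse = ", "),
         ")", call. = FALSE)
  mat <- matrix(unlist(strsplit(seqs, "")), nrow = length(seqs),
                ncol = nchar(seqs[1L]), byrow = TRUE)
  if (!allow_gap_columns && any(colSums(mat == GAP) == nrow(mat)))
    stop("profile has a column consisting entirely of gaps", call. = FALSE)
  new_profile(seqs, ids, mat, weights, label)
}

new_profile <- function(seqs, ids, mat, weights, label, allow_gap_columns = FALSE) {
  m <- length(seqs)
  if (is.character(weights)) {
    weights <- switch(weights,
                      uniform = rep(1 / m, m),
                      unit    = rep(1, m),
                      stop("unknown weighting scheme '", weights,
                           "' (use \"uniform\" or \"unit\")", call. = FALSE))
  }
  if (length(weights) != m || any(weights <= 0))
    stop("need one strictly positive weight per sequence", call. = FALSE)
  structure(list(ids = ids, seqs = seqs, mat = mat, weights = weights,
                 label = label, length = ncol(mat)),
            class = "profile")
}

#' Read a (possibly aligned) FASTA file into a profile
#'
#' Both `-` and `.` are accepted as gap characters on input; `-` is emitted
#' on output. Identifiers are the header text up to the first whitespace.
#'
#' @param path FASTA file with at least one record.
#' @param label Group tag attached to the profile.
#' @param weights Weighting scheme or numeric weights (see [profile()]).
#' @return A `profile`.
#' @export
read_profile <- function(path, label = "", weights = "uniform") {
  set <- tryCatch(Biostrings::readBStringSet(path),
                  error = function(e) stop("cannot read FASTA '", path, "': ",
                                           conditionMessage(e), call. = FALSE))
  if (length(set) == 0L) stop("FASTA file '", path, "' contains no records", call. = FALSE)
  ids <- sub("\\s.*$", "", names(set))
  profile(as.character(set), ids = ids, weights = weights, label = label)
}

#' Write a profile as aligned FASTA
#'
#' @param x A `profile`.
#' @param path Output path.
#' @param tags Optional extra header text appended after each identifier.
#' @return `path`, invisibly.
#' @export
write_profile <- function(x, path, tags = NULL) {
  stopifnot(inherits(x, "profile"))
  headers <- if (is.null(tags)) x$ids else paste(x$ids, tags)
  writeLines(paste0(">", headers, "\n", x$seqs), path)
  invisible(path)
}

#' Extract one alignment column
#'
#' @param x A `profile`.
#' @param index 1-based column index.
#' @return Character vector of residue-or-gap symbols, one per sequence.
#' @export
profile_column <- function(x, index) {
  stopifnot(inherits(x, "profile"))
  if (length(index) != 1L || is.na(index) || index < 1L || index > x$length)
    stop("column index ", index, " out of range [1, ", x$length, "]", call. = FALSE)
  x$mat[, index]
}

#' Reassign sequence weights
#'
#' @param x A `profile`.
#' @param scheme `"uniform"` (1/m per sequence) or `"unit"` (1 per sequence).
#' @return The updated profile.
#' @export
set_weights <- function(x, scheme = c("uniform", "unit")) {
  stopifnot(inherits(x, "profile"))
  if (!is.character(scheme) || !scheme[1L] %in% c("uniform", "unit"))
    stop("unknown weighting scheme '", scheme[1L], "' (use \"uniform\" or \"unit\")",
         call. = FALSE)
  m <- length(x$seqs)
  x$weights <- if (scheme[1L] == "uniform") rep(1 / m, m) else rep(1, m)
  x
}

# drop columns that are gaps in every sequence (used to recover inputs
# from an alignment and to validate the projection identity)
strip_gap_columns <- function(x) {
  keep <- colSums(x$mat == GAP) < nrow(x$mat)
  mat <- x$mat[, keep, drop = FALSE]
  seqs <- apply(mat, 1L, paste, collapse = "")
  new_profile(seqs, x$ids, mat, x$weights, x$label)
}

ungap <- function(s) gsub("-", "", s, fixed = TRUE)

#' @export
print.profile <- function(x, ...) {
  cat("Profile", if (nzchar(x$label)) paste0("[", x$label, "]") else "",
      ": ", length(x$seqs), " sequence(s) x ", x$length, " columns\n", sep = "")
  invisible(x)
}
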