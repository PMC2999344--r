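#' Load a residue substitution matrix
#'
#' Loads the built-in BLOSUM62 table (the canonical NCBI half-bit integer
#' matrix over the 20 standard amino acids plus the ambiguity codes B, Z, X
#' and the stop symbol `*`) or parses a matrix file in NCBI flat layout:
#' `#`-prefixed comment lines, a whitespace-separated header row of symbols,
#' then one labelled score row per symbol.
#'
#' @param source `"BLOSUM62"` for the vendored table, or a path to an
#'   NCBI-format matrix file.
#' @return A `subst_matrix` object: a list with `name`, `alphabet` (ordered
#'   character vector) and `scores` (symmetric integer matrix with dimnames).
#' @examples
#' m <- load_matrix("BLOSUM62")
#' score_pair(m, "A", "H")   # -2
#' @export
load_matrix <- function(source = "BLOSUM62") {
  stopifnot(is.character(source), length(source) == 1L)
  if (!file.exists(source)) {
    if (toupper(source) == "BLOSUM62") {
      source <- system.file("extdata", "BLOSUM62", package = "favat", mustWork = TRUE)
      name <- "BLOSUM62"
    } else {
      stop("unknown builtin matrix name and no such file: '", source, "'", call. = FALSE)
    }
  } else {
    name <- basename(source)
  }
  lines <- tryCatch(readLines(source, warn = FALSE),
                    error = function(e) stop("cannot read matrix file '", source, "': ",
                                             conditionMessage(e), call. = FALSE))
  lines <- lines[!grepl("^\\s*#", lines)]
  lines <- lines[nzchar(trimws(lines))]
  if (length(lines) < 2L)
    stop("matrix file '", source, "' has no score rows", call. = FALSE)
  header <- strsplit(trimws(lines[1L]), "\\s+")[[1L]]
  rows <- strsplit(trimws(lines[-1L]), "\\s+")
  labels <- vapply(rows, `[`, character(1L), 1L)
  if (length(rows) != length(header) || !identical(labels, header))
    stop("matrix is not square: header has ", length(header),
         " symbols but there are ", length(rows), " rows (labels must match the header)",
         call. = FALSE)
  vals <- lapply(rows, function(r) suppressWarnings(as.numeric(r[-1L])))
  if (any(vapply(vals, function(v) length(v) != length(header) || anyNA(v), logical(1L))))
    stop("matrix is not square: some rows do not have one numeric score per header symbol",
         call. = FALSE)
  scores <- do.call(rbind, vals)
  dimnames(scores) <- list(header, header)
  if (!isSymmetric(unname(scores)))
    stop("matrix is asymmetric: scores(a,b) must equal scores(b,a) for every pair",
         call. = FALSE)
  new_subst_matrix(name, header, scores)
}

new_subst_matrix <- function(name, alphabet, scores) {
  structure(list(name = name, alphabet = alphabet, scores = scores),
            class = "subst_matrix")
}

#' Look up a symmetric substitution score
#'
#' @param matrix A `subst_matrix` from [load_matrix()].
#' @param a,b Residue symbols; lowercase input is uppercased.
#' @return The integer score `scores[a, b]`.
#' @export
score_pair <- function(matrix, a, b) {
  stopifnot(inherits(matrix, "subst_matrix"))
  a <- toupper(a); b <- toupper(b)
  for (sym in c(a, b))
    if (!sym %in% matrix$alphabet)
      stop("symbol '", sym, "' is not in the alphabet of matrix ", matrix$name,
           call. = FALSE)
  unname(matrix$scores[a, b])
}

#' Write a substitution matrix in NCBI flat layout
#'
#' The output round-trips through [load_matrix()] bit-exactly.
#'
#' @param matrix A `subst_matrix`.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_matrix <- function(matrix, path) {
  stopifnot(inherits(matrix, "subst_matrix"))
  width <- max(nchar(format(matrix$scores)), 2L) + 1L
  fmt <- function(x) formatC(x, width = width)
  lines <- c(paste0("# ", matrix$name),
             paste0(" ", paste(fmt(matrix$alphabet), collapse = "")),
             vapply(seq_along(matrix$alphabet), function(i) {
               paste0(matrix$alphabet[i],
                      paste(fmt(matrix$scores[i, ]), collapse = ""))
             }, character(1L)))
  writeLines(lines, path)
  invisible(path)
}

#' @export
print.subst_matrix <- function(x, ...) {
  cat("Substitution matrix ", x$name, ": ", length(x$alphabet),
      " symbols (", paste(x$alphabet, collapse = ""), ")\n", sep = "")
  invisible(x)
}
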