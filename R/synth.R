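#' Configuration for a synthetic protein family
#'
#' Describes a target sequence, an A group of functionally-identical
#' proteins at low identity to the target, and a ~A group of
#' sequence-related but functionally-negative proteins at high identity,
#' with a set of planted functional positions: conserved in every A
#' sequence and forcibly substituted in every ~A sequence. This is the
#' identity-vs-function discrepancy the voting statistic amplifies.
#'
#' @param target_length Target length in residues.
#' @param n_a,n_na Number of A-group / ~A-group sequences.
#' @param planted Either an integer count of planted positions (sampled at
#'   generation time) or an explicit vector of 1-based target positions.
#' @param identity_a Target identity band centre for the A group (default
#'   0.35, the case study's 30-40% band).
#' @param identity_na Identity band centre for the ~A group (default 0.65,
#'   the 50-80% band). Must exceed `identity_a`.
#' @param indel_rate Per-position indel probability away from planted
#'   positions. With the default 0 the groups are natively aligned.
#' @param seed Integer seed; generation is fully reproducible.
#' @return A `family_config` object.
#' @export
family_config <- function(target_length = 120L, n_a = 4L, n_na = 4L,
                          planted = 6L, identity_a = 0.35,
                          identity_na = 0.65, indel_rate = 0,
                          seed = 1L) {
  target_length <- as.integer(target_length)
  stopifnot(target_length > 0L, n_a >= 1L, n_na >= 1L,
            identity_a > 0, identity_a < 1, identity_na > 0, identity_na < 1,
            indel_rate >= 0, indel_rate < 1)
  if (identity_na < identity_a)
    stop("identity_na must exceed identity_a: the ~A group is sequence-close, ",
         "the A group sequence-distant", call. = FALSE)
  if (length(planted) == 1L && planted == as.integer(planted) &&
      is.null(attr(planted, "explicit"))) {
    n_planted <- as.integer(planted)
    positions <- NULL
  } else {
    positions <- sort(unique(as.integer(planted)))
    n_planted <- length(positions)
  }
  if (n_planted > target_length ||
      (!is.null(positions) && (min(positions) < 1L || max(positions) > target_length)))
    stop("planted positions must lie within [1, target_length]", call. = FALSE)
  structure(list(target_length = target_length, n_a = as.integer(n_a),
                 n_na = as.integer(n_na), n_planted = n_planted,
                 planted_positions = positions, identity_a = identity_a,
                 identity_na = identity_na, indel_rate = indel_rate,
                 seed = as.integer(seed)),
            class = "family_config")
}

# exact matches over aligned non-gap positions divided by target length
sequence_identity <- function(target_chars, other_chars) {
  n <- min(length(target_chars), length(other_chars))
  sum(target_chars[seq_len(n)] != GAP & other_chars[seq_len(n)] != GAP &
        target_chars[seq_len(n)] == other_chars[seq_len(n)]) / length(target_chars)
}

#' Generate a synthetic target/A/~A family
#'
#' Draws a uniform-random target; A-group sequences are copies of the
#' target with enough non-planted positions substituted to land in the
#' `identity_a` band while planted residues are preserved; ~A-group
#' sequences land in the `identity_na` band but are forcibly substituted
#' at every planted position, drawing replacements among residues with
#' BLOSUM62 score <= 0 against the target residue so the functional
#' contrast is guaranteed. With `indel_rate > 0` the emitted group
#' sequences are unaligned (indels are placed away from planted
#' positions); the default 0 keeps them natively aligned.
#'
#' @param config A `family_config`.
#' @return A `family_fixture`: `target` (string), `a_group`, `na_group`
#'   (named character vectors), `truth` (sorted planted positions),
#'   `identity_a`, `identity_na` (measured per sequence), and the config.
#' @export
generate_family <- function(config = family_config()) {
  stopifnot(inherits(config, "family_config"))
  L <- config$target_length
  n_bg_a <- round((1 - config$identity_a) * L)
  n_mis_na <- round((1 - config$identity_na) * L)
  withr::with_seed(config$seed, {
    planted <- config$planted_positions
    if (is.null(planted))
      planted <- sort(sample.int(L, config$n_planted))
    free <- setdiff(seq_len(L), planted)
    if (n_bg_a > length(free))
      stop("identity_a band infeasible: ", n_bg_a, " substitutions needed but only ",
           length(free), " non-planted positions available", call. = FALSE)
    n_bg_na <- n_mis_na - length(planted)
    if (n_bg_na < 0L)
      stop("identity_na band infeasible: planted substitutions alone (",
           length(planted), ") exceed the ", n_mis_na,
           " mismatches the band allows", call. = FALSE)
    target <- sample(AA20, L, replace = TRUE)
    blosum <- load_matrix("BLOSUM62")

    mutate_bg <- function(chars, positions) {
      for (p in positions)
        chars[p] <- sample(setdiff(AA20, chars[p]), 1L)
      chars
    }
    a_group <- vapply(seq_len(config$n_a), function(s) {
      chars <- mutate_bg(target, sample(free, n_bg_a))
      paste(chars, collapse = "")
    }, character(1L))
    na_group <- vapply(seq_len(config$n_na), function(s) {
      chars <- mutate_bg(target, sample(free, n_bg_na))
      for (p in planted) {
        low <- AA20[blosum$scores[target[p], AA20] <= 0]
        chars[p] <- sample(low, 1L)
      }
      paste(chars, collapse = "")
    }, character(1L))

    target_str <- paste(target, collapse = "")
    id_a <- vapply(a_group, function(s)
      sequence_identity(target, strsplit(s, "")[[1L]]), numeric(1L), USE.NAMES = FALSE)
    id_na <- vapply(na_group, function(s)
      sequence_identity(target, strsplit(s, "")[[1L]]), numeric(1L), USE.NAMES = FALSE)

    if (config$indel_rate > 0) {
      apply_indels <- function(s) {
        chars <- strsplit(s, "")[[1L]]
        out <- character(0L)
        for (p in seq_along(chars)) {
          if (!(p %in% planted) && stats::runif(1L) < config$indel_rate) {
            if (stats::runif(1L) < 0.5) next                  # deletion
            out <- c(out, chars[p], sample(AA20, 1L))          # insertion
          } else out <- c(out, chars[p])
        }
        paste(out, collapse = "")
      }
      a_group <- vapply(a_group, apply_indels, character(1L), USE.NAMES = FALSE)
      na_group <- vapply(na_group, apply_indels, character(1L), USE.NAMES = FALSE)
    }

    names(a_group) <- paste0("A", seq_along(a_group))
    names(na_group) <- paste0("notA", seq_along(na_group))
    structure(list(target = target_str, a_group = a_group, na_group = na_group,
                   truth = planted, identity_a = id_a, identity_na = id_na,
                   config = config),
              class = "family_fixture")
  })
}

#' Write a fixture to disk
#'
#' Emits `target.fasta`, `group_A.fasta`, `group_notA.fasta`, a plain-text
#' `truth.txt` (one planted position per line) and `config.json`.
#'
#' @param fixture A `family_fixture`.
#' @param dir Writable output directory (created if needed).
#' @return Named character vector of the file paths, invisibly.
#' @export
write_fixture <- function(fixture, dir) {
  stopifnot(inherits(fixture, "family_fixture"))
  if (!dir.exists(dir))
    if (!dir.create(dir, recursive = TRUE, showWarnings = FALSE))
      stop("cannot create directory '", dir, "'", call. = FALSE)
  paths <- c(target = file.path(dir, "target.fasta"),
             a_group = file.path(dir, "group_A.fasta"),
             na_group = file.path(dir, "group_notA.fasta"),
             truth = file.path(dir, "truth.txt"),
             config = file.path(dir, "config.json"))
  writeLines(paste0(">target\n", fixture$target), paths["target"])
  writeLines(paste0(">", names(fixture$a_group), "\n", fixture$a_group),
             paths["a_group"])
  writeLines(paste0(">", names(fixture$na_group), "\n", fixture$na_group),
             paths["na_group"])
  writeLines(as.character(fixture$truth), paths["truth"])
  cfg <- fixture$config
  cfg$planted_positions <- fixture$truth
  jsonlite::write_json(unclass(cfg), paths["config"], auto_unbox = TRUE,
                       null = "null")
  invisible(paths)
}

#' @export
print.family_fixture <- function(x, ...) {
  cat("Synthetic family: target of ", nchar(x$target), " aa, ",
      length(x$a_group), " A + ", length(x$na_group), " ~A sequences, ",
      length(x$truth), " planted position(s)\n", sep = "")
  cat("  measured identity A: ", paste(format(x$identity_a, digits = 3), collapse = " "),
      "\n  measured identity ~A: ", paste(format(x$identity_na, digits = 3), collapse = " "),
      "\n", sep = "")
  invisible(x)
}
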