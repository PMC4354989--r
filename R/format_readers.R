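# Readers for three per-residue prediction formats and their conversion
# into annotation rows via run-length encoding plus threshold filtering.
#
# The programs themselves (psipred, Paircoil2, DISOPRED) must be run in
# advance; only their text output is read here.  Column layouts vary by
# program version, so the dialects below are this package's contract:
#   .ss2  : optional '#' comment/header lines and blank lines, then
#           whitespace-separated rows  pos aa state coil helix strand
#           with state in {C, H, E}  (psipred "VFORMAT")
#   .pc2  : '#' header lines, then rows with at least
#           pos aa register p_score   (register in a-g; extras ignored)
#   .diso : '#' header lines, then rows  pos aa state confidence
#           with state '*' (disordered) or '.' (ordered)
# Parsers are whitespace-tolerant (variable-width columns) and require
# residue positions to run contiguously 1..N.

split_format_lines <- function(text) {
  lines <- unlist(strsplit(paste(text, collapse = "\n"), "\n", fixed = TRUE))
  keep <- !grepl("^\\s*(#|$)", lines)
  list(lines = lines[keep], numbers = which(keep))
}

check_contiguous <- function(positions, line_numbers) {
  expected <- seq_along(positions)
  bad <- which(positions != expected)
  if (length(bad))
    ft_format_error(sprintf(
      "line %d: residue position %d out of order (expected %d); positions must run 1..N",
      line_numbers[bad[1]], positions[bad[1]], bad[1]),
      line = line_numbers[bad[1]])
  invisible(TRUE)
}

parse_residue_lines <- function(text, format, min_fields, parse_line) {
  sp <- split_format_lines(text)
  if (!length(sp$lines))
    ft_format_error(sprintf("no residue records found in %s input", format))
  recs <- vector("list", length(sp$lines))
  for (i in seq_along(sp$lines)) {
    ln <- sp$numbers[i]
    fields <- strsplit(trimws(sp$lines[i]), "\\s+")[[1]]
    if (length(fields) < min_fields)
      ft_format_error(sprintf(
        "line %d: expected at least %d whitespace-separated fields, found %d",
        ln, min_fields, length(fields)), line = ln)
    recs[[i]] <- parse_line(fields, ln)
  }
  out <- do.call(rbind, recs)
  out$line <- sp$numbers
  check_contiguous(out$position, sp$numbers)
  out
}

num_field <- function(x, what, ln) {
  v <- suppressWarnings(as.numeric(x))
  if (is.na(v))
    ft_format_error(sprintf("line %d: %s '%s' is not a number", ln, what, x),
                    line = ln)
  v
}

int_field <- function(x, what, ln) {
  v <- num_field(x, what, ln)
  if (abs(v - round(v)) > 1e-9)
    ft_format_error(sprintf("line %d: %s '%s' is not an integer", ln, what, x),
                    line = ln)
  as.integer(round(v))
}

#' Read a psipred `.ss2` secondary-structure file (VFORMAT)
#'
#' One record per residue with the predicted state -- C (coil), H (helix)
#' or E (strand) -- and the three per-state scores.
#'
#' @param text File contents (string or character vector of lines), or a
#'   path to an existing file.
#' @return A data frame with columns `position`, `residue`, `state`,
#'   `coil`, `helix`, `strand`, `line`.
#' @section Errors: `ft_format_error` with the offending line number for
#'   malformed lines, non-contiguous positions, or an empty file.
#' @export
read_ss2 <- function(text) {
  parse_residue_lines(read_text_arg(text), "ss2", 6L, function(f, ln) {
    if (length(f) != 6L)
      ft_format_error(sprintf("line %d: expected 6 fields, found %d",
                              ln, length(f)), line = ln)
    if (!f[3] %in% c("C", "H", "E"))
      ft_format_error(sprintf(
        "line %d: state '%s' is not one of C, H, E", ln, f[3]), line = ln)
    data.frame(position = int_field(f[1], "position", ln), residue = f[2],
               state = f[3],
               coil = num_field(f[4], "coil score", ln),
               helix = num_field(f[5], "helix score", ln),
               strand = num_field(f[6], "strand score", ln),
               stringsAsFactors = FALSE)
  })
}

#' Read a Paircoil2 `.pc2` coiled-coil file
#'
#' One record per residue with its heptad register (a-g) and p-score.
#' Lower p-scores mean stronger coiled-coil evidence.
#'
#' @inheritParams read_ss2
#' @return A data frame with columns `position`, `residue`, `register`,
#'   `p_score`, `line`.
#' @export
read_pc2 <- function(text) {
  parse_residue_lines(read_text_arg(text), "pc2", 4L, function(f, ln) {
    if (!f[3] %in% letters[1:7])
      ft_format_error(sprintf(
        "line %d: register '%s' is not one of a-g", ln, f[3]), line = ln)
    data.frame(position = int_field(f[1], "position", ln), residue = f[2],
               register = f[3],
               p_score = num_field(f[4], "p-score", ln),
               stringsAsFactors = FALSE)
  })
}

#' Read a DISOPRED `.diso` disorder file
#'
#' One record per residue with state `*` (disordered) or `.` (ordered)
#' and a confidence score.
#'
#' @inheritParams read_ss2
#' @return A data frame with columns `position`, `residue`, `state`,
#'   `confidence`, `line`.
#' @export
read_diso <- function(text) {
  parse_residue_lines(read_text_arg(text), "diso", 4L, function(f, ln) {
    if (!f[3] %in% c("*", "."))
      ft_format_error(sprintf(
        "line %d: state '%s' is not '*' or '.'", ln, f[3]), line = ln)
    data.frame(position = int_field(f[1], "position", ln), residue = f[2],
               state = f[3],
               confidence = num_field(f[4], "confidence", ln),
               stringsAsFactors = FALSE)
  })
}

# Accept either literal text or a path to an existing file.
read_text_arg <- function(text) {
  if (is_scalar_string(text) && !grepl("\n", text) && file.exists(text))
    return(readLines(text, warn = FALSE))
  text
}

#' Maximal runs of residues in kept states
#'
#' Run-length encodes a per-residue record table: returns one interval per
#' maximal run of consecutive positions whose state satisfies `keep`.
#' This is the shared primitive behind all format-to-row converters.
#'
#' @param records A per-residue data frame as returned by [read_ss2()],
#'   [read_pc2()] or [read_diso()] (any data frame with a contiguous
#'   1..N `position` column and the column named by `state_col`).
#' @param keep A predicate function on the state value, or a character
#'   vector of states to keep.
#' @param state_col Name of the column holding the state (default
#'   `"state"`).
#' @return A data frame with columns `start`, `end` (1-based inclusive
#'   positions) in left-to-right order.
#' @examples
#' r <- data.frame(position = 1:6, state = c("C","C","H","H","H","C"))
#' runs_of(r, "H")   # one run: 3..5
#' @export
runs_of <- function(records, keep, state_col = "state") {
  if (!is.data.frame(records) || !all(c("position", state_col) %in%
                                      names(records)))
    ft_schema_error(sprintf(
      "'records' must be a data frame with 'position' and '%s' columns",
      state_col))
  check_contiguous(records$position,
                   records$line %||% seq_len(nrow(records)))
  st <- records[[state_col]]
  kept <- if (is.function(keep)) vapply(st, function(s) isTRUE(keep(s)),
                                        logical(1)) else st %in% keep
  if (!length(kept) || !any(kept))
    return(data.frame(start = integer(), end = integer()))
  r <- rle(kept)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  data.frame(start = as.integer(starts[r$values]),
             end = as.integer(ends[r$values]))
}

# default colors for the three converters, echoing the customary palette
# of secondary-structure (green helix / blue strand), coiled-coil (cyan)
# and disorder (black) tracks
.ft_colors <- list(helix = "#2ca02c", strand = "#1f77b4",
                   coiled_coil = "#17becf", disorder = "#000000")

run_tooltip <- function(label, start, end, score_name, score) {
  sprintf("%s %d-%d (%s %.4g)", label, start, end, score_name, score)
}

#' Convert secondary-structure records to an annotation row
#'
#' Each maximal run of H becomes a "helix" annotation and each maximal run
#' of E a "strand" annotation; coil (C) residues produce no annotation.
#' An annotation's score is the mean of its own state's per-residue score
#' over the run; helix and strand carry distinct default colors.
#'
#' @param records Output of [read_ss2()].
#' @param label Row label.
#' @return An [annotation_row()], annotations sorted by position.
#' @export
ss2_to_row <- function(records, label = "secondary structure") {
  one_state <- function(state, name, col, score_col) {
    rr <- runs_of(records, state)
    lapply(seq_len(nrow(rr)), function(i) {
      idx <- rr$start[i]:rr$end[i]
      sc <- mean(records[[score_col]][idx])
      feature_annotation(rr$start[i], rr$end[i], label = name, score = sc,
                         color = col,
                         tooltip = run_tooltip(name, rr$start[i], rr$end[i],
                                               "mean score", sc))
    })
  }
  anns <- c(one_state("H", "helix", .ft_colors$helix, "helix"),
            one_state("E", "strand", .ft_colors$strand, "strand"))
  normalize_row(annotation_row(label = label, annotations = anns))
}

#' Convert coiled-coil records to an annotation row
#'
#' Annotations are maximal runs of residues whose Paircoil2 p-score is at
#' or below `p_threshold` (low p-score = confident coiled coil).  The
#' annotation score is the minimum p-score in the run -- the run's best
#' evidence.
#'
#' @param records Output of [read_pc2()].
#' @param p_threshold Positive p-score cutoff; the default 0.025 is the
#'   program's customary cutoff.
#' @param label Row label.
#' @return An [annotation_row()].
#' @export
pc2_to_row <- function(records, p_threshold = 0.025, label = "coiled coil") {
  if (!is_scalar_number(p_threshold) || p_threshold <= 0)
    ft_parameter_error("'p_threshold' must be a single number > 0")
  kept <- records$p_score <= p_threshold
  rr <- runs_of(cbind(records, keep = kept), TRUE, state_col = "keep")
  anns <- lapply(seq_len(nrow(rr)), function(i) {
    sc <- min(records$p_score[rr$start[i]:rr$end[i]])
    feature_annotation(rr$start[i], rr$end[i], label = "coiled coil",
                       score = sc, color = .ft_colors$coiled_coil,
                       tooltip = run_tooltip("coiled coil", rr$start[i],
                                             rr$end[i], "min p-score", sc))
  })
  annotation_row(label = label, annotations = anns)
}

#' Convert disorder records to an annotation row
#'
#' Annotations are maximal runs of residues marked disordered (`*`); the
#' annotation score is the mean per-residue confidence over the run.
#'
#' @param records Output of [read_diso()].
#' @param label Row label.
#' @return An [annotation_row()].
#' @export
diso_to_row <- function(records, label = "disorder") {
  rr <- runs_of(records, "*")
  anns <- lapply(seq_len(nrow(rr)), function(i) {
    sc <- mean(records$confidence[rr$start[i]:rr$end[i]])
    feature_annotation(rr$start[i], rr$end[i], label = "disordered",
                       score = sc, color = .ft_colors$disorder,
                       tooltip = run_tooltip("disordered", rr$start[i],
                                             rr$end[i], "mean confidence", sc))
  })
  annotation_row(label = label, annotations = anns)
}

#' Convert a prediction file to a one-row viewer specification
#'
#' Shared pathway behind `featuretrack convert`: reads a `.ss2`, `.pc2` or
#' `.diso` file and wraps the converted row in a [viewer_spec()] whose
#' sequence length is the residue count.
#'
#' @param text File contents or a path to an existing file.
#' @param format One of `"ss2"`, `"pc2"`, `"diso"`.
#' @param p_threshold Paircoil2 p-score cutoff (pc2 only).
#' @param label Row label; default depends on the format.
#' @param title Viewer title.
#' @return A `ft_viewer_spec` with one row.
#' @export
convert_prediction <- function(text, format = c("ss2", "pc2", "diso"),
                               p_threshold = 0.025, label = NULL,
                               title = "") {
  format <- match.arg(format)
  records <- switch(format, ss2 = read_ss2(text), pc2 = read_pc2(text),
                    diso = read_diso(text))
  row <- switch(format,
    ss2 = ss2_to_row(records, label = label %||% "secondary structure"),
    pc2 = pc2_to_row(records, p_threshold = p_threshold,
                     label = label %||% "coiled coil"),
    diso = diso_to_row(records, label = label %||% "disorder"))
  viewer_spec(sequence_length = nrow(records), rows = list(row),
              title = title)
}
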