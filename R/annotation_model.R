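# Domain model: one annotated sequence (a "viewer"), its rows of feature
# annotations, optional per-row summary values and vertical marker lines.
# Coordinates are 1-based and inclusive on both ends throughout: position 1
# is the first residue/base, `sequence_length` the last.  Only the length
# of the sequence is modeled, never its letters.

#' Create a feature annotation
#'
#' A feature annotation is one labeled region of a nucleotide or protein
#' sequence: a domain, binding site, helix, disordered region, observed
#' peptide, and so on.  Positions are 1-based and inclusive on both ends.
#'
#' @param start,end Integer sequence positions, 1-based, inclusive.
#' @param label Short text label ("" for none).
#' @param score Optional real-valued score (e.g. a prediction confidence);
#'   drives score-based shading in the default style.  Scores are stored
#'   unconstrained; mapping them to a shade is the style rule's job.
#' @param color Optional CSS color string overriding row/style colors.
#' @param tooltip Optional tooltip text (rendered as an SVG title element).
#' @param url Optional click-through link target (rendered as an SVG
#'   hyperlink).
#' @return An object of class `ft_annotation`.
#' @examples
#' feature_annotation(2, 10, label = "domain A")
#' @export
feature_annotation <- function(start, end, label = "", score = NULL,
                               color = NULL, tooltip = NULL, url = NULL) {
  if (!is_whole(start) || !is_whole(end))
    ft_schema_error("annotation 'start' and 'end' must be single whole numbers")
  if (!is_scalar_string(label))
    ft_schema_error("annotation 'label' must be a single string")
  if (!is.null(score) && !is_scalar_number(score))
    ft_schema_error("annotation 'score' must be a single finite number or NULL")
  check_opt_string(color, "color"); check_opt_string(tooltip, "tooltip")
  check_opt_string(url, "url")
  structure(
    list(start = as.integer(round(start)), end = as.integer(round(end)),
         label = label, score = if (is.null(score)) NULL else as.numeric(score),
         color = color, tooltip = tooltip, url = url),
    class = "ft_annotation"
  )
}

#' Create a row-level summary value
#'
#' A summary value is drawn as a horizontal bar at the right-hand side of a
#' row, its width proportional to `value`.  Typical uses: protein sequence
#' coverage or relative abundance for the experiment the row represents.
#'
#' @param value Real in \[0, 1\]: fraction of the full summary-bar width.
#' @param label Text label.
#' @param color,tooltip,url Optional CSS color, tooltip text and link.
#' @return An object of class `ft_summary_value`.
#' @export
summary_value <- function(value, label = "", color = NULL, tooltip = NULL,
                          url = NULL) {
  if (!is_scalar_number(value))
    ft_schema_error("summary 'value' must be a single finite number")
  if (!is_scalar_string(label))
    ft_schema_error("summary 'label' must be a single string")
  check_opt_string(color, "color"); check_opt_string(tooltip, "tooltip")
  check_opt_string(url, "url")
  structure(
    list(value = as.numeric(value), label = label, color = color,
         tooltip = tooltip, url = url),
    class = "ft_summary_value"
  )
}

#' Create an annotation row
#'
#' One row holds all annotations from a single source (one prediction
#' program, one mass-spectrometry run, ...) over the sequence, plus an
#' optional summary value and an optional row-level default color.
#'
#' @param label Left-hand row label text.
#' @param annotations List of [feature_annotation()] objects.
#' @param summary Optional [summary_value()].
#' @param default_color Optional CSS color applied to annotations that do
#'   not carry their own.
#' @return An object of class `ft_annotation_row`.
#' @export
annotation_row <- function(label, annotations = list(), summary = NULL,
                           default_color = NULL) {
  if (!is_scalar_string(label))
    ft_schema_error("row 'label' must be a single string")
  if (!is.list(annotations))
    ft_schema_error("row 'annotations' must be a list")
  for (a in annotations)
    if (!inherits(a, "ft_annotation"))
      ft_schema_error("row 'annotations' must contain feature_annotation objects")
  if (!is.null(summary) && !inherits(summary, "ft_summary_value"))
    ft_schema_error("row 'summary' must be a summary_value or NULL")
  check_opt_string(default_color, "default_color")
  structure(
    list(label = label, annotations = annotations, summary = summary,
         default_color = default_color),
    class = "ft_annotation_row"
  )
}

#' Create a marker line
#'
#' A marker line is a vertical line drawn across all rows of a viewer at a
#' fixed sequence position, noting a position of interest such as a
#' cleavage site or trypsin cut site.
#'
#' @param position 1-based sequence position.
#' @param color Optional CSS color (defaults to the configured marker color
#'   at render time).
#' @param label Optional text used as the line's tooltip.
#' @return An object of class `ft_marker`.
#' @export
marker_line <- function(position, color = NULL, label = NULL) {
  if (!is_whole(position))
    ft_schema_error("marker 'position' must be a single whole number")
  check_opt_string(color, "color"); check_opt_string(label, "label")
  structure(
    list(position = as.integer(round(position)), color = color, label = label),
    class = "ft_marker"
  )
}

#' Create a viewer specification
#'
#' A viewer is the unit that gets rendered: one sequence of known length,
#' its annotation rows, and any marker lines.  Several viewers sharing one
#' sequence length can be stacked on a page with aligned coordinates
#' (see [render_page()]).
#'
#' @param sequence_length Positive integer length of the sequence.
#' @param rows List of [annotation_row()] objects.
#' @param title Viewer title text ("" for none).
#' @param markers List of [marker_line()] objects.
#' @return An object of class `ft_viewer_spec`.
#' @export
viewer_spec <- function(sequence_length, rows = list(), title = "",
                        markers = list()) {
  if (!is_whole(sequence_length))
    ft_schema_error("'sequence_length' must be a single whole number")
  if (!is_scalar_string(title))
    ft_schema_error("'title' must be a single string")
  if (!is.list(rows)) ft_schema_error("'rows' must be a list")
  for (r in rows)
    if (!inherits(r, "ft_annotation_row"))
      ft_schema_error("'rows' must contain annotation_row objects")
  if (!is.list(markers)) ft_schema_error("'markers' must be a list")
  for (m in markers)
    if (!inherits(m, "ft_marker"))
      ft_schema_error("'markers' must contain marker_line objects")
  structure(
    list(title = title, sequence_length = as.integer(round(sequence_length)),
         rows = rows, markers = markers),
    class = "ft_viewer_spec"
  )
}

check_opt_string <- function(x, what) {
  if (!is.null(x) && !is_scalar_string(x))
    ft_schema_error(sprintf("'%s' must be a single string or NULL", what))
  invisible(x)
}

#' @export
print.ft_viewer_spec <- function(x, ...) {
  cat(sprintf("<viewer_spec> %s(length %d, %d row%s, %d marker%s)\n",
              if (nzchar(x$title)) paste0("\"", x$title, "\" ") else "",
              x$sequence_length, length(x$rows),
              if (length(x$rows) == 1L) "" else "s", length(x$markers),
              if (length(x$markers) == 1L) "" else "s"))
  for (r in x$rows)
    cat(sprintf("  row \"%s\": %d annotation%s%s\n", r$label,
                length(r$annotations),
                if (length(r$annotations) == 1L) "" else "s",
                if (is.null(r$summary)) "" else
                  sprintf(", summary %.3g", r$summary$value)))
  invisible(x)
}

# ---- validation -----------------------------------------------------------

violation <- function(row, annotation, rule, message) {
  data.frame(row = row, annotation = annotation, rule = rule,
             message = message, stringsAsFactors = FALSE)
}

no_violations <- function() {
  data.frame(row = integer(), annotation = integer(), rule = character(),
             message = character(), stringsAsFactors = FALSE)
}

#' Validate a viewer specification
#'
#' Checks every coordinate invariant of the model and returns one record
#' per violation; an empty data frame means the spec is valid.  Violations
#' are reported as data, never raised, so a whole document can be audited
#' in one pass (this is what `featuretrack validate` prints).
#'
#' Rules checked: `sequence_length_ge_1`; per annotation `start_ge_1`,
#' `start_le_end`, `end_le_sequence_length`; per summary
#' `summary_value_in_unit_interval`; per marker `marker_position_in_range`.
#'
#' @param spec An [viewer_spec()] object.
#' @return A data frame with columns `row`, `annotation`, `rule`,
#'   `message`.  Indices are 1-based; `NA` where not applicable.
#' @examples
#' s <- viewer_spec(30, list(annotation_row("r1",
#'   list(feature_annotation(2, 10)))))
#' validate_viewer(s)   # zero rows: valid
#' @export
validate_viewer <- function(spec) {
  stopifnot(inherits(spec, "ft_viewer_spec"))
  out <- list(no_violations())
  L <- spec$sequence_length
  if (L < 1L)
    out[[length(out) + 1L]] <- violation(NA_integer_, NA_integer_,
      "sequence_length_ge_1",
      sprintf("sequence_length is %d but must be >= 1", L))
  for (i in seq_along(spec$rows)) {
    row <- spec$rows[[i]]
    for (j in seq_along(row$annotations)) {
      a <- row$annotations[[j]]
      if (a$start < 1L)
        out[[length(out) + 1L]] <- violation(i, j, "start_ge_1",
          sprintf("annotation start %d must be >= 1", a$start))
      if (a$start > a$end)
        out[[length(out) + 1L]] <- violation(i, j, "start_le_end",
          sprintf("annotation start %d exceeds end %d", a$start, a$end))
      if (a$end > L)
        out[[length(out) + 1L]] <- violation(i, j, "end_le_sequence_length",
          sprintf("annotation end %d exceeds sequence length %d", a$end, L))
    }
    if (!is.null(row$summary) &&
        (row$summary$value < 0 || row$summary$value > 1))
      out[[length(out) + 1L]] <- violation(i, NA_integer_,
        "summary_value_in_unit_interval",
        sprintf("summary value %g must lie in [0, 1]", row$summary$value))
  }
  for (k in seq_along(spec$markers)) {
    m <- spec$markers[[k]]
    if (m$position < 1L || m$position > L)
      out[[length(out) + 1L]] <- violation(NA_integer_, k,
        "marker_position_in_range",
        sprintf("marker position %d outside [1, %d]", m$position, L))
  }
  do.call(rbind, out)
}

#' Normalize an annotation row
#'
#' Stably sorts the row's annotations by (start, end, original order); all
#' other fields are unchanged.  Idempotent.
#'
#' @param row An [annotation_row()] object.
#' @return The row with annotations sorted.
#' @export
normalize_row <- function(row) {
  stopifnot(inherits(row, "ft_annotation_row"))
  if (length(row$annotations) > 1L) {
    s <- vapply(row$annotations, `[[`, integer(1), "start")
    e <- vapply(row$annotations, `[[`, integer(1), "end")
    row$annotations <- row$annotations[order(s, e)]  # radix sort: stable ties
  }
  row
}

normalize_spec <- function(spec) {
  spec$rows <- lapply(spec$rows, normalize_row)
  spec
}

# ---- generic annotation JSON dialect --------------------------------------

# The dialect (UTF-8):
#   { "title": str?, "sequenceLength": int,
#     "rows": [ { "label": str, "defaultColor": str?,
#                 "summary": {"value": num, "label": str?, "color": str?,
#                             "tooltip": str?, "url": str?}?,
#                 "annotations": [ {"start": int, "end": int, "label": str?,
#                                   "score": num?, "color": str?,
#                                   "tooltip": str?, "url": str?} ] } ],
#     "markers": [ {"position": int, "color": str?, "label": str?} ]? }
# Required keys: sequenceLength, rows, rows[].label, rows[].annotations,
# annotations[].start, annotations[].end.  Unknown keys are ignored with a
# warning, so documents written for richer future dialects still load.

json_field <- function(obj, key, path, required = FALSE, default = NULL) {
  if (!is.null(obj[[key]])) return(obj[[key]])
  if (required)
    ft_schema_error(sprintf("missing required key '%s' at %s", key, path))
  default
}

warn_unknown_keys <- function(obj, known, path) {
  extra <- setdiff(names(obj), known)
  if (length(extra))
    warning(sprintf("ignoring unknown key%s at %s: %s",
                    if (length(extra) == 1L) "" else "s", path,
                    paste(extra, collapse = ", ")), call. = FALSE)
}

as_opt_string <- function(x, key, path) {
  if (is.null(x)) return(NULL)
  if (!is_scalar_string(x))
    ft_schema_error(sprintf("key '%s' at %s must be a string", key, path))
  x
}

as_req_whole <- function(x, key, path) {
  if (!is_whole(x))
    ft_schema_error(sprintf("key '%s' at %s must be an integer", key, path))
  as.integer(round(x))
}

#' Read a viewer specification from generic annotation JSON
#'
#' Parses the package's generic annotation JSON dialect (see
#' [write_generic_json()] for the schema) into a validated, normalized
#' [viewer_spec()].  Unknown keys are ignored with a warning.  Paths in
#' diagnostics use 1-based indices (`$.rows[1].annotations[2]`).
#'
#' @param text JSON document text (a single string or a character vector of
#'   lines).
#' @return A `ft_viewer_spec`.
#' @section Errors: a parse error (`ft_parse_error`) for malformed JSON; a
#'   schema error (`ft_schema_error`) for a missing required key or a wrong
#'   type; a validation error (`ft_validation_error`) listing coordinate
#'   violations with their JSON paths.
#' @export
read_generic_json <- function(text) {
  text <- paste(text, collapse = "\n")
  doc <- tryCatch(
    jsonlite::fromJSON(text, simplifyVector = FALSE),
    error = function(e) ft_parse_error(
      paste0("malformed JSON document: ", conditionMessage(e)))
  )
  if (!is.list(doc) || is.null(names(doc)))
    ft_schema_error("top-level JSON value must be an object")
  warn_unknown_keys(doc, c("title", "sequenceLength", "rows", "markers"), "$")

  len <- as_req_whole(json_field(doc, "sequenceLength", "$", required = TRUE),
                      "sequenceLength", "$")
  title <- as_opt_string(doc[["title"]], "title", "$") %||% ""
  rows_json <- json_field(doc, "rows", "$", required = TRUE)
  if (!is.list(rows_json) || !is.null(names(rows_json)))
    ft_schema_error("key 'rows' at $ must be an array")

  rows <- lapply(seq_along(rows_json), function(i) {
    path <- sprintf("$.rows[%d]", i)
    r <- rows_json[[i]]
    if (!is.list(r) || is.null(names(r)))
      ft_schema_error(sprintf("element at %s must be an object", path))
    warn_unknown_keys(r, c("label", "defaultColor", "summary", "annotations"),
                      path)
    lab <- json_field(r, "label", path, required = TRUE)
    if (!is_scalar_string(lab))
      ft_schema_error(sprintf("key 'label' at %s must be a string", path))
    anns_json <- json_field(r, "annotations", path, required = TRUE)
    if (!is.list(anns_json) || !is.null(names(anns_json)))
      ft_schema_error(sprintf("key 'annotations' at %s must be an array", path))
    anns <- lapply(seq_along(anns_json), function(j) {
      apath <- sprintf("%s.annotations[%d]", path, j)
      a <- anns_json[[j]]
      if (!is.list(a) || is.null(names(a)))
        ft_schema_error(sprintf("element at %s must be an object", apath))
      warn_unknown_keys(a, c("start", "end", "label", "score", "color",
                             "tooltip", "url"), apath)
      score <- a[["score"]]
      if (!is.null(score) && !is_scalar_number(score))
        ft_schema_error(sprintf("key 'score' at %s must be a number", apath))
      feature_annotation(
        start = as_req_whole(json_field(a, "start", apath, required = TRUE),
                             "start", apath),
        end = as_req_whole(json_field(a, "end", apath, required = TRUE),
                           "end", apath),
        label = as_opt_string(a[["label"]], "label", apath) %||% "",
        score = score,
        color = as_opt_string(a[["color"]], "color", apath),
        tooltip = as_opt_string(a[["tooltip"]], "tooltip", apath),
        url = as_opt_string(a[["url"]], "url", apath))
    })
    summ <- NULL
    if (!is.null(r[["summary"]])) {
      spath <- paste0(path, ".summary")
      s <- r[["summary"]]
      if (!is.list(s) || is.null(names(s)))
        ft_schema_error(sprintf("element at %s must be an object", spath))
      warn_unknown_keys(s, c("value", "label", "color", "tooltip", "url"),
                        spath)
      v <- json_field(s, "value", spath, required = TRUE)
      if (!is_scalar_number(v))
        ft_schema_error(sprintf("key 'value' at %s must be a number", spath))
      summ <- summary_value(
        value = v, label = as_opt_string(s[["label"]], "label", spath) %||% "",
        color = as_opt_string(s[["color"]], "color", spath),
        tooltip = as_opt_string(s[["tooltip"]], "tooltip", spath),
        url = as_opt_string(s[["url"]], "url", spath))
    }
    annotation_row(label = lab, annotations = anns, summary = summ,
                   default_color = as_opt_string(r[["defaultColor"]],
                                                 "defaultColor", path))
  })

  markers <- list()
  if (!is.null(doc[["markers"]])) {
    mk <- doc[["markers"]]
    if (!is.list(mk) || !is.null(names(mk)))
      ft_schema_error("key 'markers' at $ must be an array")
    markers <- lapply(seq_along(mk), function(k) {
      mpath <- sprintf("$.markers[%d]", k)
      m <- mk[[k]]
      if (!is.list(m) || is.null(names(m)))
        ft_schema_error(sprintf("element at %s must be an object", mpath))
      warn_unknown_keys(m, c("position", "color", "label"), mpath)
      marker_line(
        position = as_req_whole(json_field(m, "position", mpath,
                                           required = TRUE), "position", mpath),
        color = as_opt_string(m[["color"]], "color", mpath),
        label = as_opt_string(m[["label"]], "label", mpath))
    })
  }

  spec <- viewer_spec(sequence_length = len, rows = rows, title = title,
                      markers = markers)
  stop_if_invalid(spec)
  normalize_spec(spec)
}

stop_if_invalid <- function(spec) {
  v <- validate_viewer(spec)
  if (nrow(v)) {
    paths <- vapply(seq_len(nrow(v)), function(i) {
      if (v$rule[i] == "marker_position_in_range")
        sprintf("$.markers[%d]", v$annotation[i])
      else if (is.na(v$row[i])) "$"
      else if (is.na(v$annotation[i])) sprintf("$.rows[%d].summary", v$row[i])
      else sprintf("$.rows[%d].annotations[%d]", v$row[i], v$annotation[i])
    }, character(1))
    ft_validation_error(
      paste0("invalid viewer specification:\n",
             paste0("  ", paths, ": ", v$message, collapse = "\n")),
      violations = v)
  }
  invisible(spec)
}

#' Write a viewer specification as generic annotation JSON
#'
#' Serializes a valid [viewer_spec()] to the package's generic annotation
#' JSON dialect.  Absent optional fields are omitted, key order is fixed,
#' and two writes of the same spec are byte-identical, so
#' `read_generic_json(write_generic_json(spec))` reproduces `spec` exactly
#' (annotations are normalized to sorted order first).
#'
#' @param spec A valid `ft_viewer_spec`.
#' @return A single string of pretty-printed JSON.
#' @export
write_generic_json <- function(spec) {
  stopifnot(inherits(spec, "ft_viewer_spec"))
  stop_if_invalid(spec)
  spec <- normalize_spec(spec)
  drop_null <- function(x) x[!vapply(x, is.null, logical(1))]
  doc <- drop_null(list(
    title = if (nzchar(spec$title)) spec$title else NULL,
    sequenceLength = spec$sequence_length,
    rows = lapply(spec$rows, function(r) drop_null(list(
      label = r$label,
      defaultColor = r$default_color,
      summary = if (!is.null(r$summary)) drop_null(list(
        value = r$summary$value,
        label = if (nzchar(r$summary$label)) r$summary$label else NULL,
        color = r$summary$color, tooltip = r$summary$tooltip,
        url = r$summary$url)),
      annotations = lapply(r$annotations, function(a) drop_null(list(
        start = a$start, end = a$end,
        label = if (nzchar(a$label)) a$label else NULL,
        score = a$score, color = a$color, tooltip = a$tooltip,
        url = a$url)))))),
    markers = if (length(spec$markers)) lapply(spec$markers, function(m)
      drop_null(list(position = m$position, color = m$color,
                     label = m$label)))
  ))
  paste0(as.character(jsonlite::toJSON(doc, auto_unbox = TRUE, digits = NA,
                                       pretty = TRUE)), "\n")
}
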