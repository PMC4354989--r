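# Geometry and SVG emission: turns viewer specs plus layout results into
# standalone SVG 1.1 documents.  The sequence runs left to right across a
# fixed-width plot area (position 1 at the left edge, the final position
# at the right edge); rows stack downwards; tooltips become SVG <title>
# children and click-throughs become SVG hyperlinks, so the rendered
# document needs no scripting runtime.  Output is deterministic: the same
# spec, config and style always produce byte-identical SVG.

#' Rendering configuration
#'
#' Pixel geometry and default colors for the renderer.  All defaults are
#' this package's choices; change any of them per call or via a flat
#' `key: value` config file (see [read_render_config()]).
#'
#' @param row_height Height of one sub-track in px.
#' @param row_gap Vertical gap between rows and sub-tracks in px.
#' @param label_width Width of the left label gutter in px.
#' @param plot_width Width of the sequence plot area in px.
#' @param summary_bar_width Full width of a right-hand summary bar in px.
#' @param summary_gap Gap between plot area and summary bars in px.
#' @param font_size Label font size in px.
#' @param border_color CSS color of frames and outlines.
#' @param background CSS color of the page background.
#' @param marker_color Default CSS color of marker lines.
#' @param indicator_size Side length of the expand-indicator box in px.
#' @return An object of class `ft_render_config`.
#' @export
render_config <- function(row_height = 20, row_gap = 4, label_width = 150,
                          plot_width = 600, summary_bar_width = 80,
                          summary_gap = 10, font_size = 12,
                          border_color = "gray", background = "white",
                          marker_color = "green", indicator_size = 10) {
  cfg <- list(row_height = row_height, row_gap = row_gap,
              label_width = label_width, plot_width = plot_width,
              summary_bar_width = summary_bar_width,
              summary_gap = summary_gap, font_size = font_size,
              border_color = border_color, background = background,
              marker_color = marker_color, indicator_size = indicator_size)
  dims <- c("row_height", "row_gap", "label_width", "plot_width",
            "summary_bar_width", "summary_gap", "font_size",
            "indicator_size")
  for (d in dims)
    if (!is_scalar_number(cfg[[d]]) || cfg[[d]] <= 0)
      ft_parameter_error(sprintf("config dimension '%s' must be > 0", d))
  for (s in c("border_color", "background", "marker_color"))
    if (!is_scalar_string(cfg[[s]]))
      ft_parameter_error(sprintf("config '%s' must be a single string", s))
  structure(cfg, class = "ft_render_config")
}

#' Read a flat config file onto a rendering configuration
#'
#' The file holds one `key: value` (or `key = value`) pair per line, keys
#' named after [render_config()] arguments; `#` comments and blank lines
#' are ignored.  Values for unknown keys raise a parameter error.
#'
#' @param path Path to the config file.
#' @param base Configuration supplying defaults for keys the file omits.
#' @return An `ft_render_config`.
#' @export
read_render_config <- function(path, base = render_config()) {
  lines <- readLines(path, warn = FALSE)
  lines <- lines[!grepl("^\\s*(#|$)", lines)]
  cfg <- unclass(base)
  dims <- c("row_height", "row_gap", "label_width", "plot_width",
            "summary_bar_width", "summary_gap", "font_size",
            "indicator_size")
  for (i in seq_along(lines)) {
    m <- regmatches(lines[i], regexec("^\\s*([A-Za-z_]+)\\s*[:=]\\s*(.*?)\\s*$",
                                      lines[i]))[[1]]
    if (length(m) != 3L)
      ft_parse_error(sprintf("config line %d is not 'key: value': %s",
                             i, lines[i]))
    key <- m[2]; val <- m[3]
    if (!key %in% names(cfg))
      ft_parameter_error(sprintf("unknown config key '%s' (line %d)", key, i))
    cfg[[key]] <- if (key %in% dims) {
      v <- suppressWarnings(as.numeric(val))
      if (is.na(v))
        ft_parse_error(sprintf("config key '%s' needs a number, got '%s'",
                               key, val))
      v
    } else val
  }
  do.call(render_config, cfg)
}

#' Pluggable style rule
#'
#' A style rule maps each annotation, summary value and marker to a color,
#' a tooltip text and an optional link target.  Every function must be
#' total (defined for every record) and pure, so rendering stays
#' deterministic.  Annotation-facing functions receive the annotation and
#' its owning row; summary-facing functions the summary value and row.
#'
#' @param color_of `function(annotation, row) -> CSS color`.
#' @param tooltip_of `function(annotation, row) -> text`.
#' @param url_of `function(annotation, row) -> link or NULL`.
#' @param summary_color_of,summary_tooltip_of,summary_url_of Analogous
#'   functions for [summary_value()] records.
#' @param marker_color_of `function(marker) -> CSS color or NULL` (NULL
#'   falls back to the configured marker color).
#' @return An object of class `ft_style_rule`.
#' @seealso [default_style()], [shade_color()]
#' @export
style_rule <- function(color_of, tooltip_of, url_of,
                       summary_color_of, summary_tooltip_of, summary_url_of,
                       marker_color_of) {
  fns <- list(color_of = color_of, tooltip_of = tooltip_of, url_of = url_of,
              summary_color_of = summary_color_of,
              summary_tooltip_of = summary_tooltip_of,
              summary_url_of = summary_url_of,
              marker_color_of = marker_color_of)
  for (nm in names(fns))
    if (!is.function(fns[[nm]]))
      ft_parameter_error(sprintf("style component '%s' must be a function", nm))
  structure(fns, class = "ft_style_rule")
}

#' Interpolate a color towards black
#'
#' Linear interpolation in RGB from black (`frac = 0`) to `base`
#' (`frac = 1`); the default shading ramp for score-driven styles, where
#' darker means a weaker score.
#'
#' @param base CSS color understood by [grDevices::col2rgb()].
#' @param frac Fraction in \[0, 1\]; values outside are clamped.
#' @return A `#rrggbb` hex color string.
#' @export
shade_color <- function(base, frac) {
  frac <- max(0, min(1, frac))
  rgb <- grDevices::col2rgb(base)[, 1]
  grDevices::rgb(rgb[1] * frac, rgb[2] * frac, rgb[3] * frac,
                 maxColorValue = 255)
}

.ft_fallback_color <- "#4682b4"   # steelblue

#' Default style rule
#'
#' Colors: an annotation's own color wins; otherwise, if the annotation
#' has a score, the row's base color (its `default_color`, falling back
#' to steelblue) is shaded black-to-base linearly over the observed score
#' range of the row (a single-score row gets the full base color);
#' otherwise the base color is used directly.  Tooltips default to
#' "label start-end (score s)".  Summary bars behave analogously with the
#' summary's own color or a neutral gray.
#'
#' @return An `ft_style_rule`.
#' @export
default_style <- function() {
  row_base <- function(row) row$default_color %||% .ft_fallback_color
  style_rule(
    color_of = function(a, row) {
      if (!is.null(a$color)) return(a$color)
      base <- row_base(row)
      if (is.null(a$score)) return(base)
      scores <- unlist(lapply(row$annotations, `[[`, "score"))
      rng <- range(scores)
      frac <- if (diff(rng) <= 0) 1 else (a$score - rng[1]) / diff(rng)
      shade_color(base, frac)
    },
    tooltip_of = function(a, row) {
      a$tooltip %||% sprintf("%s%d-%d%s",
        if (nzchar(a$label)) paste0(a$label, " ") else "", a$start, a$end,
        if (is.null(a$score)) "" else sprintf(" (score %.4g)", a$score))
    },
    url_of = function(a, row) a$url,
    summary_color_of = function(s, row) s$color %||% "#666666",
    summary_tooltip_of = function(s, row) {
      s$tooltip %||% sprintf("%s%.3g",
        if (nzchar(s$label)) paste0(s$label, ": ") else "", s$value)
    },
    summary_url_of = function(s, row) s$url,
    marker_color_of = function(m) m$color
  )
}

#' Map a sequence position to horizontal pixel coordinates
#'
#' Position `pos` of a sequence of length `L` occupies the pixel band
#' `[x_left, x_right]` with `x_left = label_width + (pos-1) * plot_width/L`
#' and `x_right = label_width + pos * plot_width/L`, so position 1 starts
#' at the plot's left edge and position `L` ends at its right edge.  A
#' block spanning positions `(s, e)` runs from `x_left(s)` to
#' `x_right(e)`.
#'
#' @param pos 1-based sequence position.
#' @param sequence_length Sequence length `L`.
#' @param config An [render_config()].
#' @return Named numeric vector `c(left = x_left, right = x_right)`.
#' @export
position_to_x <- function(pos, sequence_length, config = render_config()) {
  if (!is_whole(pos) || pos < 1 || pos > sequence_length)
    ft_coordinate_error(sprintf("position %s outside [1, %d]",
                                format(pos), sequence_length))
  scale <- config$plot_width / sequence_length
  c(left = config$label_width + (pos - 1) * scale,
    right = config$label_width + pos * scale)
}

# ---- layout ---------------------------------------------------------------

layout_items <- function() {
  env <- new.env(parent = emptyenv())
  env$items <- list()
  env$add <- function(kind, x, y, width, height, fill = NA_character_,
                      stroke = NA_character_, text = NA_character_,
                      tooltip = NA_character_, url = NA_character_,
                      anchor = NA_character_, row = NA_integer_,
                      subtrack = NA_integer_) {
    env$items[[length(env$items) + 1L]] <- data.frame(
      kind = kind, x = x, y = y, width = width, height = height,
      fill = fill, stroke = stroke, text = text, tooltip = tooltip,
      url = url, anchor = anchor, row = row, subtrack = subtrack,
      stringsAsFactors = FALSE)
  }
  env
}

empty_rects <- function() {
  data.frame(kind = character(), x = numeric(), y = numeric(),
             width = numeric(), height = numeric(), fill = character(),
             stroke = character(), text = character(), tooltip = character(),
             url = character(), anchor = character(), row = integer(),
             subtrack = integer(), stringsAsFactors = FALSE)
}

#' Compute the geometric layout of one viewer
#'
#' Converts a validated [viewer_spec()] into pixel rectangles.  A
#' collapsed row shows one rectangle per merged block of overlapping
#' annotations ([merge_blocks()]) plus a plus-box indicator when the row
#' holds overlaps; an expanded row shows one rectangle per annotation,
#' stacked on sub-tracks assigned by greedy first-fit
#' ([assign_tracks()]).  Summary bars sit at the row's right with width
#' proportional to the summary value; marker lines span all rows at the
#' midpoint of their position's pixel band.  Requesting expansion of a
#' row without overlaps is a no-op (a message is emitted).
#'
#' @param spec A valid `ft_viewer_spec`.
#' @param config An [render_config()].
#' @param expanded Character vector of row labels to expand, or `TRUE`
#'   to expand every row that has overlaps.
#' @param style An [style_rule()]; defaults to [default_style()].
#' @return An object of class `ft_layout`: a list with the rectangle
#'   table `rects` (columns kind, x, y, width, height, fill, stroke,
#'   text, tooltip, url, anchor, row, subtrack), the document `width`
#'   and `height`, `sequence_length` and `config`.
#' @export
layout_viewer <- function(spec, config = render_config(),
                          expanded = character(), style = default_style()) {
  stopifnot(inherits(spec, "ft_viewer_spec"),
            inherits(config, "ft_render_config"),
            inherits(style, "ft_style_rule"))
  stop_if_invalid(spec)
  spec <- normalize_spec(spec)
  L <- spec$sequence_length
  acc <- layout_items()
  width <- config$label_width + config$plot_width + config$summary_gap +
    config$summary_bar_width

  title_h <- if (nzchar(spec$title)) config$font_size + config$row_gap else 0
  if (nzchar(spec$title))
    acc$add("title", x = config$label_width, y = config$font_size,
            width = 0, height = 0, text = spec$title, anchor = "start")

  rows_top <- title_h
  y <- rows_top
  body <- layout_items()   # blocks/annotations drawn above the frame
  for (i in seq_along(spec$rows)) {
    row <- spec$rows[[i]]
    iv <- annotations_as_intervals(row$annotations)
    ho <- has_overlaps(iv)
    want_expand <- isTRUE(expanded) || row$label %in% expanded
    if (want_expand && !ho && !isTRUE(expanded))
      message(sprintf(
        "row '%s' has no overlapping annotations; expansion is a no-op",
        row$label))
    expand_this <- want_expand && ho
    nsub <- if (expand_this) assign_tracks(iv)$n_tracks else 1L

    acc$add("label", x = config$label_width - 8,
            y = y + config$row_height / 2 + config$font_size * 0.35,
            width = 0, height = 0, text = row$label, anchor = "end",
            row = i)
    if (ho)
      acc$add("indicator", x = 4,
              y = y + (config$row_height - config$indicator_size) / 2,
              width = config$indicator_size, height = config$indicator_size,
              fill = "white", stroke = config$border_color,
              tooltip = "overlapping annotations present", row = i)

    if (expand_this) {
      ta <- assign_tracks(iv)
      for (j in seq_along(row$annotations)) {
        a <- row$annotations[[j]]
        x1 <- position_to_x(a$start, L, config)[["left"]]
        x2 <- position_to_x(a$end, L, config)[["right"]]
        body$add("annotation", x = x1,
                 y = y + ta$track_index[j] *
                   (config$row_height + config$row_gap),
                 width = x2 - x1, height = config$row_height,
                 fill = style$color_of(a, row),
                 tooltip = style$tooltip_of(a, row),
                 url = style$url_of(a, row) %||% NA_character_,
                 row = i, subtrack = ta$track_index[j])
      }
    } else {
      mb <- merge_blocks(iv)
      for (b in seq_len(nrow(mb))) {
        first <- row$annotations[[mb$members[[b]][1]]]
        x1 <- position_to_x(mb$start[b], L, config)[["left"]]
        x2 <- position_to_x(mb$end[b], L, config)[["right"]]
        single <- mb$n_members[b] == 1L
        body$add("block", x = x1, y = y, width = x2 - x1,
                 height = config$row_height,
                 fill = style$color_of(first, row),
                 tooltip = if (single) style$tooltip_of(first, row) else
                   sprintf("%d overlapping annotations spanning %d-%d",
                           mb$n_members[b], mb$start[b], mb$end[b]),
                 url = if (single) style$url_of(first, row) %||%
                   NA_character_ else NA_character_,
                 row = i, subtrack = 0L)
      }
    }

    if (!is.null(row$summary)) {
      sx <- config$label_width + config$plot_width + config$summary_gap
      acc$add("summary_frame", x = sx, y = y,
              width = config$summary_bar_width, height = config$row_height,
              fill = "none", stroke = config$border_color, row = i)
      body$add("summary", x = sx, y = y,
               width = row$summary$value * config$summary_bar_width,
               height = config$row_height,
               fill = style$summary_color_of(row$summary, row),
               tooltip = style$summary_tooltip_of(row$summary, row),
               url = style$summary_url_of(row$summary, row) %||%
                 NA_character_, row = i)
    }

    y <- y + nsub * config$row_height + (nsub - 1L) * config$row_gap +
      config$row_gap
  }
  rows_bottom <- if (length(spec$rows)) y - config$row_gap else
    rows_top + config$row_height
  height <- rows_bottom + config$row_gap

  frame <- layout_items()
  frame$add("background", x = 0, y = 0, width = width, height = height,
            fill = config$background)
  frame$add("frame", x = config$label_width, y = rows_top,
            width = config$plot_width, height = rows_bottom - rows_top,
            fill = "none", stroke = config$border_color)

  markers <- layout_items()
  for (k in seq_along(spec$markers)) {
    m <- spec$markers[[k]]
    band <- position_to_x(m$position, L, config)
    markers$add("marker", x = (band[["left"]] + band[["right"]]) / 2,
                y = rows_top, width = 0, height = rows_bottom - rows_top,
                fill = style$marker_color_of(m) %||% config$marker_color,
                tooltip = m$label %||% NA_character_)
  }

  rects <- do.call(rbind, c(list(empty_rects()), frame$items, acc$items,
                            body$items, markers$items))
  structure(list(rects = rects, width = width, height = height,
                 sequence_length = L, config = config),
            class = "ft_layout")
}

# ---- SVG emission ---------------------------------------------------------

svg_rect_kinds <- c("background", "frame", "summary_frame", "block",
                    "annotation", "summary", "indicator")

add_titled <- function(parent, node, tooltip) {
  if (!is.na(tooltip)) xml2::xml_add_child(node, "title", tooltip)
  invisible(node)
}

#' Render a layout as a standalone SVG document
#'
#' Emits SVG 1.1 with an XML declaration, explicit width/height and
#' viewBox.  Every annotation, block and summary rectangle carries its
#' tooltip as a `<title>` child (shown on hover by every major viewer)
#' and is wrapped in an `<a xlink:href=...>` hyperlink when a link target
#' is set.  Rectangles are tagged with `class` attributes named after
#' their layout kind so downstream tools can count or restyle them.
#' Output contains no timestamps and no randomness: identical layouts
#' yield byte-identical documents.
#'
#' @param layout An `ft_layout` from [layout_viewer()].
#' @return A single string: the SVG document.
#' @export
render_svg <- function(layout) {
  stopifnot(inherits(layout, "ft_layout"))
  cfg <- layout$config
  doc <- xml2::xml_new_root(
    "svg", xmlns = "http://www.w3.org/2000/svg",
    "xmlns:xlink" = "http://www.w3.org/1999/xlink", version = "1.1",
    width = fmt_px(layout$width), height = fmt_px(layout$height),
    viewBox = paste("0 0", fmt_px(layout$width), fmt_px(layout$height)),
    "font-family" = "sans-serif", "font-size" = fmt_px(cfg$font_size))
  r <- layout$rects
  for (i in seq_len(nrow(r))) {
    kind <- r$kind[i]
    parent <- doc
    if (kind %in% svg_rect_kinds && !is.na(r$url[i]))
      parent <- xml2::xml_add_child(doc, "a", "xlink:href" = r$url[i])
    if (kind %in% svg_rect_kinds) {
      node <- xml2::xml_add_child(
        parent, "rect", class = kind,
        x = fmt_px(r$x[i]), y = fmt_px(r$y[i]),
        width = fmt_px(r$width[i]), height = fmt_px(r$height[i]),
        fill = if (is.na(r$fill[i])) "none" else r$fill[i])
      if (!is.na(r$stroke[i])) {
        xml2::xml_set_attr(node, "stroke", r$stroke[i])
        xml2::xml_set_attr(node, "stroke-width", "1")
      }
      add_titled(doc, node, r$tooltip[i])
      if (kind == "indicator") {
        cx <- r$x[i] + r$width[i] / 2; cy <- r$y[i] + r$height[i] / 2
        m <- r$width[i] * 0.2
        xml2::xml_add_child(doc, "line", class = "indicator-plus",
          x1 = fmt_px(r$x[i] + m), y1 = fmt_px(cy),
          x2 = fmt_px(r$x[i] + r$width[i] - m), y2 = fmt_px(cy),
          stroke = r$stroke[i], "stroke-width" = "1")
        xml2::xml_add_child(doc, "line", class = "indicator-plus",
          x1 = fmt_px(cx), y1 = fmt_px(r$y[i] + m),
          x2 = fmt_px(cx), y2 = fmt_px(r$y[i] + r$height[i] - m),
          stroke = r$stroke[i], "stroke-width" = "1")
      }
    } else if (kind %in% c("label", "title")) {
      xml2::xml_add_child(doc, "text", r$text[i], class = kind,
                          x = fmt_px(r$x[i]), y = fmt_px(r$y[i]),
                          "text-anchor" = r$anchor[i])
    } else if (kind == "marker") {
      node <- xml2::xml_add_child(doc, "line", class = "marker",
        x1 = fmt_px(r$x[i]), y1 = fmt_px(r$y[i]),
        x2 = fmt_px(r$x[i]), y2 = fmt_px(r$y[i] + r$height[i]),
        stroke = r$fill[i], "stroke-width" = "1")
      add_titled(doc, node, r$tooltip[i])
    }
  }
  paste0(as.character(doc), if (!endsWith(as.character(doc), "\n")) "\n")
}

#' Render one or more viewers on a single aligned page
#'
#' Stacks the viewers vertically with identical label and plot widths, so
#' equal sequence positions land at equal x coordinates in every viewer
#' and annotations can be compared across viewers by eye.  All specs must
#' share one sequence length.  Page-level markers are drawn at the same x
#' in every viewer.
#'
#' @param specs A `ft_viewer_spec` or list of them.
#' @param config An [render_config()] shared by all viewers.
#' @param expanded Row labels to expand (or `TRUE` for all), applied to
#'   every viewer.
#' @param style An [style_rule()].
#' @param markers Optional page-level markers: a numeric vector of
#'   positions or a list of [marker_line()] objects, added to every
#'   viewer.
#' @return A single string: the combined SVG document.
#' @section Errors: `ft_alignment_error` listing the lengths when the
#'   specs disagree on sequence length.
#' @export
render_page <- function(specs, config = render_config(),
                        expanded = character(), style = default_style(),
                        markers = NULL) {
  if (inherits(specs, "ft_viewer_spec")) specs <- list(specs)
  stopifnot(length(specs) >= 1L)
  lens <- vapply(specs, `[[`, integer(1), "sequence_length")
  if (length(unique(lens)) != 1L)
    ft_alignment_error(sprintf(
      "viewers must share one sequence length to be aligned; got: %s",
      paste(lens, collapse = ", ")))
  if (!is.null(markers)) {
    extra <- if (is.numeric(markers)) lapply(markers, marker_line) else markers
    specs <- lapply(specs, function(s) {
      s$markers <- c(s$markers, extra)
      s
    })
  }
  layouts <- lapply(specs, layout_viewer, config = config,
                    expanded = expanded, style = style)
  gap <- 3 * config$row_gap
  offset <- 0
  rects <- list(empty_rects())
  for (lt in layouts) {
    rr <- lt$rects
    rr$y <- rr$y + offset
    rects[[length(rects) + 1L]] <- rr
    offset <- offset + lt$height + gap
  }
  combined <- structure(
    list(rects = do.call(rbind, rects), width = layouts[[1]]$width,
         height = offset - gap, sequence_length = lens[1], config = config),
    class = "ft_layout")
  render_svg(combined)
}
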