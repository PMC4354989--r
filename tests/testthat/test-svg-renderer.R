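worked_spec <- function() {
  spec1(list(feature_annotation(2, 10, label = "A"),
             feature_annotation(8, 19, label = "B")), len = 30L,
        label = "run")
}

test_that("position-to-pixel mapping hits the plot edges exactly", {
  cfg <- render_config()
  L <- 37L
  expect_equal(position_to_x(1, L, cfg)[["left"]], cfg$label_width)
  expect_equal(position_to_x(L, L, cfg)[["right"]],
               cfg$label_width + cfg$plot_width)
  expect_equal(position_to_x(51, 100,
                             render_config(label_width = 150))[["left"]],
               150 + 50 * 600 / 100)
  # strictly increasing and constant per-position width
  xs <- t(vapply(1:20, position_to_x, numeric(2), sequence_length = 20L,
                 config = cfg))
  expect_true(all(diff(xs[, 1]) > 0))
  expect_equal(xs[, 2] - xs[, 1], rep(cfg$plot_width / 20, 20))
  expect_error(position_to_x(0, 10, cfg), class = "ft_coordinate_error")
  expect_error(position_to_x(11, 10, cfg), class = "ft_coordinate_error")
})

test_that("collapsed rows show merged blocks plus an expand indicator", {
  lt <- layout_viewer(worked_spec())
  expect_identical(sum(lt$rects$kind == "block"), 1L)
  expect_identical(sum(lt$rects$kind == "indicator"), 1L)
  blk <- lt$rects[lt$rects$kind == "block", ]
  cfg <- lt$config
  expect_equal(blk$x, position_to_x(2, 30, cfg)[["left"]])
  expect_equal(blk$x + blk$width, position_to_x(19, 30, cfg)[["right"]])
  expect_equal(blk$width, (19 - 2 + 1) * cfg$plot_width / 30)
})

test_that("expanded rows give one rectangle per annotation on sub-tracks", {
  lt <- layout_viewer(worked_spec(), expanded = "run")
  ann <- lt$rects[lt$rects$kind == "annotation", ]
  expect_identical(nrow(ann), 2L)
  expect_setequal(ann$subtrack, c(0L, 1L))
  expect_identical(sum(lt$rects$kind == "block"), 0L)
  # expanding a row without overlaps is a logged no-op
  disj <- spec1(list(feature_annotation(1, 5), feature_annotation(6, 9)),
                len = 20L, label = "flat")
  expect_message(lt2 <- layout_viewer(disj, expanded = "flat"), "no-op")
  expect_identical(sum(lt2$rects$kind == "block"), 2L)
  expect_identical(sum(lt2$rects$kind == "indicator"), 0L)
})

test_that("summary bars scale with the summary value", {
  s <- viewer_spec(30, list(annotation_row(
    "r", list(feature_annotation(1, 10)),
    summary = summary_value(0.5, label = "coverage"))))
  lt <- layout_viewer(s)
  bar <- lt$rects[lt$rects$kind == "summary", ]
  expect_equal(bar$width, lt$config$summary_bar_width / 2)
  frame <- lt$rects[lt$rects$kind == "summary_frame", ]
  expect_equal(frame$width, lt$config$summary_bar_width)
})

test_that("every rectangle stays inside the document viewBox", {
  for (seed in 1:5) {
    lt <- layout_viewer(gen_viewer(seed, target_max_depth = 3L),
                        expanded = TRUE)
    r <- lt$rects[lt$rects$kind %in% c("block", "annotation", "summary"), ]
    expect_true(all(r$x >= 0 & r$x + r$width <= lt$width + 1e-9))
    expect_true(all(r$y >= 0 & r$y + r$height <= lt$height + 1e-9))
  }
})

test_that("rendered documents are well-formed SVG with titles and links", {
  s <- spec1(list(feature_annotation(2, 10, tooltip = "tip text",
                                     url = "https://example.org/a")),
             len = 30L)
  svg <- render_svg(layout_viewer(s))
  x <- xml2::read_xml(svg)
  expect_identical(xml2::xml_name(x), "svg")
  expect_identical(xml2::xml_text(xml2::xml_find_first(
    x, "//*[local-name()='rect'][@class='block']/*[local-name()='title']")),
    "tip text")
  a <- xml2::xml_find_first(x, "//*[local-name()='a']")
  expect_identical(xml2::xml_attr(a, "href"), "https://example.org/a")

  empty <- render_svg(layout_viewer(viewer_spec(10, title = "empty")))
  xe <- xml2::read_xml(empty)
  expect_identical(xml2::xml_name(xe), "svg")
  expect_identical(svg_count(empty, "frame"), 1L)
  expect_identical(svg_count(empty, "block"), 0L)
})

test_that("rect counts match the layout algebra for both view modes", {
  for (seed in 1:6) {
    s <- gen_viewer(seed, target_max_depth = 1L + seed %% 3L)
    collapsed <- render_svg(layout_viewer(s))
    expanded <- render_svg(layout_viewer(s, expanded = TRUE))
    n_blocks <- sum(vapply(s$rows, function(r)
      nrow(merge_blocks(annotations_df(r))), integer(1)))
    n_ann_overlap <- sum(vapply(s$rows, function(r) {
      iv <- annotations_df(r)
      if (has_overlaps(iv)) length(r$annotations) else nrow(merge_blocks(iv))
    }, integer(1)))
    expect_identical(svg_count(collapsed, "block"), n_blocks)
    expect_identical(svg_count(expanded, "annotation") +
                       svg_count(expanded, "block"), n_ann_overlap)
  }
})

test_that("re-rendering a spec is byte-identical", {
  s <- gen_viewer(11, target_max_depth = 3L)
  svg1 <- render_page(list(s, gen_viewer(12)), markers = c(40, 160))
  svg2 <- render_page(list(s, gen_viewer(12)), markers = c(40, 160))
  expect_identical(svg1, svg2)
})

test_that("viewers on one page place equal positions at equal x", {
  s1 <- gen_viewer(21, sequence_length = 120L)
  s2 <- gen_viewer(22, sequence_length = 120L)
  svg <- render_page(list(s1, s2), markers = c(30, 90))
  x <- xml2::read_xml(svg)
  lines <- xml2::xml_find_all(x, "//*[local-name()='line'][@class='marker']")
  x1 <- as.numeric(xml2::xml_attr(lines, "x1"))
  # each page marker appears once per viewer at one shared x
  expect_identical(length(x1), 2L * (2L + 2L))  # 2 page + 2 per-spec markers
  for (pos in c(30, 90)) {
    cfg <- render_config()
    want <- cfg$label_width + (pos - 0.5) * cfg$plot_width / 120
    hits <- x1[abs(x1 - want) < 1e-6]
    expect_identical(length(hits), 2L)
  }
  expect_error(render_page(list(gen_viewer(1, sequence_length = 100L),
                                gen_viewer(2, sequence_length = 120L))),
               "100.*120", class = "ft_alignment_error")
})

test_that("a singleton page renders identically to the direct pipeline", {
  s <- gen_viewer(31)
  expect_identical(render_page(s), render_svg(layout_viewer(s)))
})

test_that("default style shades scores over the observed row range", {
  row <- annotation_row("r", list(
    feature_annotation(1, 5, score = 0),
    feature_annotation(6, 9, score = 1)), default_color = "#ff0000")
  sty <- default_style()
  expect_identical(sty$color_of(row$annotations[[1]], row), "#000000")
  expect_identical(sty$color_of(row$annotations[[2]], row), "#FF0000")
  expect_identical(shade_color("#ff0000", 0.5), "#7F0000")
  # explicit annotation color wins over shading
  a <- feature_annotation(1, 2, score = 0.5, color = "#123456")
  expect_identical(sty$color_of(a, row), "#123456")
})
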