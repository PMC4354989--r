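# Independent oracles used by the property tests: brute-force position-set
# union and exact minimum coloring of the interval overlap graph.  These
# stay deliberately naive -- enumeration, not the algorithms under test.

# all sequence positions covered by any interval, sorted
bf_union_positions <- function(iv) {
  if (nrow(iv) == 0L) return(integer())
  sort(unique(unlist(lapply(seq_len(nrow(iv)),
                            function(i) iv$start[i]:iv$end[i]))))
}

# maximum coverage depth by direct per-position counting
bf_max_depth <- function(iv) {
  if (nrow(iv) == 0L) return(0L)
  pos <- bf_union_positions(iv)
  max(vapply(pos, function(p) sum(iv$start <= p & iv$end >= p), integer(1)))
}

# exact chromatic number of the interval overlap graph by backtracking
# (with first-fit symmetry breaking); feasible for n <= 10
bf_min_tracks <- function(iv) {
  n <- nrow(iv)
  if (n == 0L) return(0L)
  conflict <- matrix(FALSE, n, n)
  for (i in seq_len(n)) for (j in seq_len(n))
    conflict[i, j] <- i != j && iv$start[i] <= iv$end[j] &&
      iv$start[j] <= iv$end[i]
  assign <- integer(n)
  feasible <- function(k) {
    rec <- function(i) {
      if (i > n) return(TRUE)
      used <- if (i == 1L) 0L else max(assign[seq_len(i - 1L)])
      for (col in seq_len(min(k, used + 1L))) {
        clash <- FALSE
        for (j in seq_len(i - 1L))
          if (conflict[i, j] && assign[j] == col) { clash <- TRUE; break }
        if (!clash) {
          assign[i] <<- col
          if (rec(i + 1L)) return(TRUE)
        }
      }
      assign[i] <<- 0L
      FALSE
    }
    rec(1L)
  }
  k <- 1L
  while (!feasible(k)) k <- k + 1L
  k
}

rand_intervals <- function(n, len) {
  s <- sample.int(len, n, replace = TRUE)
  e <- pmin(len, s + sample.int(max(len %/% 4L, 1L), n, replace = TRUE) - 1L)
  data.frame(start = as.integer(s), end = as.integer(e))
}

# flatten a row's annotations into a comparable data frame
annotations_df <- function(row) {
  data.frame(
    start = vapply(row$annotations, `[[`, integer(1), "start"),
    end = vapply(row$annotations, `[[`, integer(1), "end"),
    label = vapply(row$annotations, `[[`, character(1), "label"),
    score = vapply(row$annotations, function(a) a$score %||% NA_real_,
                   numeric(1)),
    stringsAsFactors = FALSE)
}

`%||%` <- function(x, y) if (is.null(x)) y else x

spec1 <- function(anns, len = 30L, label = "r1", ...) {
  viewer_spec(len, list(annotation_row(label, anns)), ...)
}

svg_count <- function(svg, cls, tag = "rect") {
  x <- xml2::read_xml(svg)
  length(xml2::xml_find_all(
    x, sprintf("//*[local-name()='%s'][@class='%s']", tag, cls)))
}
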