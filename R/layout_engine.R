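# Interval algorithms behind the collapsed and expanded row views.
#
# Intervals are 1-based and inclusive on both ends, matching the sequence
# coordinate model: (2,10) and (8,19) share positions 8-10 and therefore
# overlap; (1,5) and (6,9) abut visually but share no position and do not.
# Lists of intervals are plain data frames with integer columns `start`
# and `end`; helpers accept anything coercible via as_intervals().

as_intervals <- function(x) {
  if (is.data.frame(x)) {
    if (!all(c("start", "end") %in% names(x)))
      ft_schema_error("interval data frame needs 'start' and 'end' columns")
    df <- data.frame(start = as.integer(x$start), end = as.integer(x$end))
  } else if (is.matrix(x) && ncol(x) == 2L) {
    df <- data.frame(start = as.integer(x[, 1]), end = as.integer(x[, 2]))
  } else if (is.list(x)) {
    df <- data.frame(
      start = vapply(x, function(i) as.integer(i[[1]]), integer(1)),
      end = vapply(x, function(i) as.integer(i[[2]]), integer(1)))
  } else if (is.numeric(x) && length(x) == 0L) {
    df <- data.frame(start = integer(), end = integer())
  } else {
    ft_schema_error("cannot interpret input as a list of intervals")
  }
  bad <- which(df$start > df$end)
  if (length(bad))
    ft_validation_error(sprintf(
      "invalid interval at index %d: start %d exceeds end %d",
      bad[1], df$start[bad[1]], df$end[bad[1]]))
  df
}

annotations_as_intervals <- function(annotations) {
  data.frame(
    start = vapply(annotations, `[[`, integer(1), "start"),
    end = vapply(annotations, `[[`, integer(1), "end"))
}

#' Do two intervals overlap?
#'
#' Two inclusive intervals overlap iff they share at least one sequence
#' position: `a[1] <= b[2] && b[1] <= a[2]`.  Intervals that merely abut,
#' such as (1,5) and (6,9), do not overlap.
#'
#' @param a,b Intervals as length-2 numeric vectors `c(start, end)`.
#' @return `TRUE` or `FALSE`.
#' @examples
#' overlaps(c(2, 10), c(8, 19))  # TRUE: positions 8-10 are shared
#' overlaps(c(1, 5), c(6, 9))    # FALSE: adjacency is not overlap
#' @export
overlaps <- function(a, b) {
  a <- as_interval2(a); b <- as_interval2(b)
  a[1] <= b[2] && b[1] <= a[2]
}

#' Overlap region of two intervals
#'
#' @inheritParams overlaps
#' @return The shared region `c(start, end)`, or `NULL` when the intervals
#'   are disjoint.
#' @examples
#' overlap_region(c(2, 10), c(8, 19))  # c(8, 10)
#' @export
overlap_region <- function(a, b) {
  a <- as_interval2(a); b <- as_interval2(b)
  s <- max(a[1], b[1]); e <- min(a[2], b[2])
  if (s > e) NULL else c(start = s, end = e)
}

as_interval2 <- function(x) {
  if (is.list(x)) x <- c(x$start, x$end)
  x <- as.integer(x)
  if (length(x) != 2L || anyNA(x))
    ft_schema_error("an interval must be two positions c(start, end)")
  if (x[1] > x[2])
    ft_validation_error(sprintf("invalid interval: start %d exceeds end %d",
                                x[1], x[2]))
  x
}

#' Merge overlapping intervals into disjoint blocks
#'
#' Produces the minimal set of disjoint blocks whose covered positions
#' equal the union of the inputs.  Overlapping intervals such as (2,10)
#' and (8,19) collapse into one block (2,19) -- this is what a collapsed
#' row displays.  Strictly adjacent intervals (no shared position) remain
#' separate blocks.  Each block records which input intervals it covers.
#'
#' @param intervals A data frame with `start`/`end` columns (or a 2-column
#'   matrix, or a list of length-2 vectors); input order is preserved in
#'   the membership indices.
#' @return A data frame sorted by `start` with integer columns `start`,
#'   `end`, `n_members` and a list column `members` of input indices.
#' @examples
#' merge_blocks(data.frame(start = c(2, 8), end = c(10, 19)))
#' @export
merge_blocks <- function(intervals) {
  iv <- as_intervals(intervals)
  n <- nrow(iv)
  empty <- data.frame(start = integer(), end = integer(),
                      n_members = integer())
  empty$members <- list()
  if (n == 0L) return(empty)
  ord <- order(iv$start, iv$end)
  bs <- be <- integer(0); members <- list()
  for (k in ord) {
    if (length(bs) && iv$start[k] <= be[length(be)]) {
      be[length(be)] <- max(be[length(be)], iv$end[k])
      members[[length(members)]] <- c(members[[length(members)]], k)
    } else {
      bs <- c(bs, iv$start[k]); be <- c(be, iv$end[k])
      members[[length(members) + 1L]] <- k
    }
  }
  out <- data.frame(start = bs, end = be,
                    n_members = lengths(members))
  out$members <- members
  out
}

#' Does any pair of intervals overlap?
#'
#' Drives the expand indicator: a row whose intervals contain at least one
#' overlapping pair gets a small plus-box left of its label, and may be
#' expanded onto sub-tracks.
#'
#' @inheritParams merge_blocks
#' @return `TRUE` or `FALSE`.
#' @export
has_overlaps <- function(intervals) {
  iv <- as_intervals(intervals)
  if (nrow(iv) < 2L) return(FALSE)
  ord <- order(iv$start, iv$end)
  s <- iv$start[ord]; e <- iv$end[ord]
  any(s[-1] <= cummax(e)[-length(e)])
}

#' Assign overlapping intervals to sub-tracks
#'
#' Greedy first-fit after a stable sort by (start, end, input order): each
#' interval is placed on the lowest-numbered sub-track whose last-placed
#' interval it does not overlap.  For interval graphs this greedy scheme
#' is optimal, so the number of sub-tracks equals the maximum coverage
#' depth ([max_depth()]) -- the fewest lanes in which every distinct
#' annotation can be shown.
#'
#' @inheritParams merge_blocks
#' @return A list with `track_index` (0-based integer vector aligned with
#'   the input order) and `n_tracks`.
#' @examples
#' assign_tracks(data.frame(start = c(2, 8), end = c(10, 19)))
#' @export
assign_tracks <- function(intervals) {
  iv <- as_intervals(intervals)
  n <- nrow(iv)
  if (n == 0L) return(list(track_index = integer(), n_tracks = 0L))
  ord <- order(iv$start, iv$end)
  track <- integer(n)
  last_end <- integer(0)   # rightmost occupied position per track
  for (k in ord) {
    free <- which(last_end < iv$start[k])
    if (length(free)) {
      t <- free[1]
    } else {
      t <- length(last_end) + 1L
      last_end <- c(last_end, 0L)
    }
    last_end[t] <- iv$end[k]
    track[k] <- t - 1L
  }
  list(track_index = track, n_tracks = length(last_end))
}

#' Maximum coverage depth of a set of intervals
#'
#' The largest number of intervals covering any single sequence position
#' (0 for no intervals).  Equals the minimum number of sub-tracks needed
#' to display all intervals without collision.
#'
#' @inheritParams merge_blocks
#' @return A non-negative integer.
#' @export
max_depth <- function(intervals) {
  iv <- as_intervals(intervals)
  if (nrow(iv) == 0L) return(0L)
  # sweep line: +1 at each start, -1 just past each end
  pos <- c(iv$start, iv$end + 1L)
  delta <- rep(c(1L, -1L), each = nrow(iv))
  ord <- order(pos, delta)   # at equal position, starts (+1) come after ends
  max(cumsum(delta[ord]))
}
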