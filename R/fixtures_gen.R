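# Deterministic generators of synthetic annotation sets and prediction
# files.  Every generator takes an explicit integer seed, runs under it
# and restores the caller's RNG state, so the same seed always yields the
# same output and no ambient randomness is consumed.  Generated format
# files carry their own ground truth, computed directly from the run
# structure the generator laid down -- independently of the run-length
# encoder the converters use -- so converter tests have an oracle.

.aa_letters <- strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]]

# uniform integer in [a, b]; safe when a == b (unlike sample(a:b, 1))
rint <- function(a, b) a + sample.int(b - a + 1L, 1L) - 1L

.row_palette <- c("#d62728", "#9467bd", "#2ca02c", "#1f77b4", "#17becf",
                  "#8c564b", "#e377c2", "#7f7f7f")

#' Generate a synthetic viewer specification
#'
#' Builds a valid, normalized [viewer_spec()] whose rows reach a
#' prescribed maximum overlap depth.  Each row is constructed from
#' disjoint segments of the sequence: one segment receives a stack of
#' `k` intervals sharing an anchor position (depth exactly `k` there),
#' the remaining segments one interval each, so the row's [max_depth()]
#' equals `k` by construction.  The first row uses
#' `k = target_max_depth`; later rows draw `k` from `1..target_max_depth`,
#' so the maximum depth over rows equals the target exactly.  With
#' `target_max_depth = 1` every row is overlap-free.
#'
#' @param seed Integer seed; the same seed always yields the same spec.
#' @param sequence_length Sequence length (default 200).
#' @param n_rows Number of rows (default 3).
#' @param annotations_per_row Annotations in each row (default 6).
#' @param target_max_depth Desired maximum overlap depth (default 2);
#'   must not exceed `annotations_per_row`.
#' @param score_range Bounds of the uniform score distribution.
#' @param n_markers Number of marker lines (default 2).
#' @param title Viewer title.
#' @return A valid `ft_viewer_spec`.
#' @export
gen_viewer <- function(seed, sequence_length = 200L, n_rows = 3L,
                       annotations_per_row = 6L, target_max_depth = 2L,
                       score_range = c(0, 1), n_markers = 2L,
                       title = "synthetic viewer") {
  if (!is_whole(seed)) ft_parameter_error("'seed' must be a whole number")
  if (target_max_depth < 1L || target_max_depth > annotations_per_row)
    ft_parameter_error(
      "'target_max_depth' must lie in [1, annotations_per_row]")
  if (n_rows < 1L || annotations_per_row < 1L || sequence_length < 2L)
    ft_parameter_error("viewer generator parameters must be positive")
  if (sequence_length %/% annotations_per_row < 2L)
    ft_parameter_error(
      "'sequence_length' too short for 'annotations_per_row' disjoint segments")
  with_seed(seed, {
    rows <- lapply(seq_len(n_rows), function(i) {
      k <- if (i == 1L) as.integer(target_max_depth) else
        sample.int(target_max_depth, 1L)
      n_groups <- annotations_per_row - k + 1L
      w <- sequence_length %/% n_groups
      stack_group <- sample.int(n_groups, 1L)
      anns <- list()
      for (g in seq_len(n_groups)) {
        s0 <- (g - 1L) * w + 1L
        s1 <- g * w
        n_here <- if (g == stack_group) k else 1L
        m <- s0 + w %/% 2L
        for (j in seq_len(n_here)) {
          st <- if (n_here > 1L) rint(s0, m) else rint(s0, s1 - 1L)
          en <- if (n_here > 1L) rint(m, s1) else rint(st, s1)
          idx <- length(anns) + 1L
          anns[[idx]] <- feature_annotation(
            st, en, label = sprintf("feat %d", idx),
            score = round(stats::runif(1, score_range[1], score_range[2]), 4),
            tooltip = if (idx %% 3L == 0L)
              sprintf("feature %d at %d-%d", idx, st, en),
            url = if (idx %% 5L == 0L)
              sprintf("https://example.org/feature/%d", idx))
        }
      }
      normalize_row(annotation_row(
        label = sprintf("row %d", i), annotations = anns,
        summary = summary_value(round(stats::runif(1), 3),
                                label = "coverage"),
        default_color = .row_palette[(i - 1L) %% length(.row_palette) + 1L]))
    })
    markers <- lapply(sort(sample.int(sequence_length,
                                      min(n_markers, sequence_length))),
                      marker_line)
    spec <- viewer_spec(sequence_length = sequence_length, rows = rows,
                        title = title, markers = markers)
    stop_if_invalid(spec)
    spec
  })
}

sample_runs <- function(n_residues, states, probs, min_len = 2L,
                        max_len = 8L) {
  runs <- list(); total <- 0L
  while (total < n_residues) {
    st <- states[sample.int(length(states), 1L, prob = probs)]
    len <- min(rint(min_len, max_len), n_residues - total)
    prev <- if (length(runs)) runs[[length(runs)]] else NULL
    if (!is.null(prev) && prev$state == st) {
      # same state drawn twice: extend the previous run so every run in
      # the truth is maximal
      runs[[length(runs)]]$end <- prev$end + len
    } else {
      runs[[length(runs) + 1L]] <- list(state = st, start = total + 1L,
                                        end = total + len)
    }
    total <- total + len
  }
  runs
}

truth_df <- function(start = integer(), end = integer(),
                     label = character(), score = numeric()) {
  data.frame(start = as.integer(start), end = as.integer(end),
             label = label, score = score, stringsAsFactors = FALSE)
}

#' Generate a synthetic prediction file with its ground truth
#'
#' Emits a dialect-conformant `.ss2`, `.pc2` or `.diso` text together
#' with the annotation intervals a converter must recover from it.  The
#' truth is computed from the run structure the generator itself laid
#' down (and from the rounded per-residue scores exactly as written), not
#' via the package's run-length encoder, so it can serve as an
#' independent oracle for the converters.
#'
#' @param seed Integer seed.
#' @param format One of `"ss2"`, `"pc2"`, `"diso"`.
#' @param n_residues Number of residues (default 80).
#' @param p_threshold For `pc2`: the cutoff the truth is computed at;
#'   generated p-scores keep clear of the boundary (at or below 80% of
#'   the threshold inside coiled-coil runs, at or above twice the
#'   threshold outside).
#' @return A list with `text` (the file contents, one string), `truth`
#'   (data frame with columns `start`, `end`, `label`, `score`),
#'   `states` (per-residue state vector) and `n_residues`.
#' @export
gen_format_file <- function(seed, format = c("ss2", "pc2", "diso"),
                            n_residues = 80L, p_threshold = 0.025) {
  format <- match.arg(format)
  if (!is_whole(seed)) ft_parameter_error("'seed' must be a whole number")
  if (n_residues < 1L) ft_parameter_error("'n_residues' must be >= 1")
  if (format == "pc2" && (!is_scalar_number(p_threshold) || p_threshold <= 0))
    ft_parameter_error("'p_threshold' must be a single number > 0")
  with_seed(seed, {
    aa <- sample(.aa_letters, n_residues, replace = TRUE)
    switch(format,
      ss2 = {
        runs <- sample_runs(n_residues, c("C", "H", "E"), c(0.5, 0.3, 0.2))
        states <- character(n_residues)
        for (r in runs) states[r$start:r$end] <- r$state
        own <- round(stats::runif(n_residues, 0.5, 1), 3)
        other1 <- round(stats::runif(n_residues, 0, 0.4), 3)
        other2 <- round(stats::runif(n_residues, 0, 0.4), 3)
        coil <- ifelse(states == "C", own, other1)
        helix <- ifelse(states == "H", own, other2)
        strand <- ifelse(states == "E", own, other1)
        lines <- sprintf("%4d %s %s  %.3f  %.3f  %.3f", seq_len(n_residues),
                         aa, states, coil, helix, strand)
        tr <- do.call(rbind, c(list(truth_df()), lapply(runs, function(r) {
          if (r$state == "C") return(NULL)
          col <- if (r$state == "H") helix else strand
          truth_df(r$start, r$end,
                   if (r$state == "H") "helix" else "strand",
                   mean(col[r$start:r$end]))
        })))
        list(text = paste(c("# PSIPRED VFORMAT (synthetic fixture)", "",
                            lines), collapse = "\n"),
             truth = tr, states = states, n_residues = n_residues)
      },
      pc2 = {
        runs <- sample_runs(n_residues, c("cc", "bg"), c(0.3, 0.7),
                            min_len = 3L, max_len = 10L)
        states <- character(n_residues)
        p <- numeric(n_residues)
        for (r in runs) {
          idx <- r$start:r$end
          states[idx] <- r$state
          p[idx] <- if (r$state == "cc")
            round(stats::runif(length(idx), 1e-4, p_threshold * 0.8), 5)
          else round(stats::runif(length(idx), p_threshold * 2, 1), 5)
        }
        reg <- sample(letters[1:7], n_residues, replace = TRUE)
        lines <- sprintf("%4d %s %s %9.5f", seq_len(n_residues), aa, reg, p)
        tr <- do.call(rbind, c(list(truth_df()), lapply(runs, function(r) {
          if (r$state != "cc") return(NULL)
          truth_df(r$start, r$end, "coiled coil", min(p[r$start:r$end]))
        })))
        list(text = paste(c("# Paircoil2 scores (synthetic fixture)",
                            lines), collapse = "\n"),
             truth = tr, states = states, n_residues = n_residues)
      },
      diso = {
        runs <- sample_runs(n_residues, c(".", "*"), c(0.65, 0.35))
        states <- character(n_residues)
        conf <- numeric(n_residues)
        for (r in runs) {
          idx <- r$start:r$end
          states[idx] <- r$state
          conf[idx] <- if (r$state == "*")
            round(stats::runif(length(idx), 0.5, 1), 2)
          else round(stats::runif(length(idx), 0, 0.49), 2)
        }
        lines <- sprintf("%5d %s %s %.2f", seq_len(n_residues), aa, states,
                         conf)
        tr <- do.call(rbind, c(list(truth_df()), lapply(runs, function(r) {
          if (r$state != "*") return(NULL)
          truth_df(r$start, r$end, "disordered",
                   mean(conf[r$start:r$end]))
        })))
        list(text = paste(c("# DISOPRED disorder (synthetic fixture)",
                            lines), collapse = "\n"),
             truth = tr, states = states, n_residues = n_residues)
      })
  })
}
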