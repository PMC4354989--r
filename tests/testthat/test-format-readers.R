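# A small hand-written VFORMAT fixture: states C,C,H,H,H,C over 6 residues.
ss2_fixture <- paste(c(
  "# PSIPRED VFORMAT (fixture)",
  "",
  "   1 M C  0.998 0.001 0.001",
  "   2 K C  0.900 0.050 0.050",
  "   3 L H  0.100 0.850 0.050",
  "   4 A H  0.050 0.900 0.050",
  "   5 V H  0.050 0.950 0.000",
  "   6 G C  0.800 0.100 0.100"), collapse = "\n")

test_that("ss2 parsing recovers per-residue states and scores", {
  r <- read_ss2(ss2_fixture)
  expect_identical(nrow(r), 6L)
  expect_identical(r$state, c("C", "C", "H", "H", "H", "C"))
  expect_identical(r$position, 1:6)
  expect_equal(r$helix[4], 0.9)
})

test_that("malformed ss2 input fails with the offending line number", {
  expect_error(read_ss2("# header only\n"), "no residue records",
               class = "ft_format_error")
  bad <- sub("   4 A H  0.050 0.900 0.050", "   4 A H  0.050",
             ss2_fixture, fixed = TRUE)
  err <- tryCatch(read_ss2(bad), ft_format_error = function(e) e)
  expect_match(conditionMessage(err), "line 6")
  gap <- sub("   5 V", "   9 V", ss2_fixture, fixed = TRUE)
  err <- tryCatch(read_ss2(gap), ft_format_error = function(e) e)
  expect_match(conditionMessage(err), "line 7.*position 9")
  expect_error(read_ss2(sub(" 3 L H", " 3 L X", ss2_fixture, fixed = TRUE)),
               "C, H, E", class = "ft_format_error")
})

test_that("runs_of encodes maximal runs under a state predicate", {
  r <- data.frame(position = 1:6, state = c("C", "C", "H", "H", "H", "C"))
  expect_identical(runs_of(r, "H"), data.frame(start = 3L, end = 5L))
  expect_identical(nrow(runs_of(r, "X")), 0L)
  expect_identical(runs_of(r, function(s) s %in% c("C")),
                   data.frame(start = c(1L, 6L), end = c(2L, 6L)))

  he <- data.frame(position = 1:4, state = c("H", "H", "E", "E"))
  expect_identical(runs_of(he, "H"), data.frame(start = 1L, end = 2L))
  expect_identical(runs_of(he, "E"), data.frame(start = 3L, end = 4L))
  # kept states grouped together still form one run
  expect_identical(runs_of(he, c("H", "E")), data.frame(start = 1L, end = 4L))
})

test_that("ss2 conversion yields helix/strand runs with mean scores", {
  row <- ss2_to_row(read_ss2(ss2_fixture))
  df <- annotations_df(row)
  expect_identical(df$start, 3L)
  expect_identical(df$end, 5L)
  expect_identical(df$label, "helix")
  expect_equal(df$score, mean(c(0.85, 0.9, 0.95)))

  all_c <- read_ss2(ss2_fixture)
  all_c$state <- "C"
  expect_length(ss2_to_row(all_c)$annotations, 0L)

  he <- read_ss2(ss2_fixture)
  he$state <- c("H", "H", "E", "E", "C", "C")
  df <- annotations_df(ss2_to_row(he))
  expect_identical(df$label, c("helix", "strand"))
  expect_identical(sum(df$end - df$start + 1L), sum(he$state != "C"))
})

pc2_fixture <- paste(c(
  "# Paircoil2 fixture",
  "  1 M a  0.50000",
  "  2 K b  0.01000",
  "  3 L c  0.02000",
  "  4 A d  0.60000"), collapse = "\n")

test_that("pc2 conversion keeps runs at or below the p-score threshold", {
  rec <- read_pc2(pc2_fixture)
  expect_identical(rec$register, c("a", "b", "c", "d"))
  df <- annotations_df(pc2_to_row(rec, p_threshold = 0.025))
  expect_identical(df$start, 2L)
  expect_identical(df$end, 3L)
  expect_equal(df$score, 0.01)   # minimum p-score in the run

  expect_length(pc2_to_row(rec, p_threshold = 0.005)$annotations, 0L)
  expect_error(pc2_to_row(rec, p_threshold = 0), class = "ft_parameter_error")
  expect_error(read_pc2("1 M z 0.5"), "register", class = "ft_format_error")
})

test_that("lowering the p-threshold never adds annotated residues", {
  set.seed(7)
  for (rep in 1:20) {
    n <- 50L
    rec <- data.frame(position = 1:n,
                      residue = sample(LETTERS[1:20], n, replace = TRUE),
                      register = sample(letters[1:7], n, replace = TRUE),
                      p_score = round(runif(n), 4))
    counts <- vapply(c(0.9, 0.5, 0.2, 0.05, 0.01), function(thr) {
      df <- annotations_df(pc2_to_row(rec, p_threshold = thr))
      if (nrow(df) == 0L) 0L else sum(df$end - df$start + 1L)
    }, integer(1))
    expect_true(all(diff(counts) <= 0L))
    # annotated residues equal residues passing the filter
    expect_identical(counts[3], sum(rec$p_score <= 0.2))
  }
})

diso_fixture <- paste(c(
  "# DISOPRED fixture",
  "    1 M . 0.12",
  "    2 K . 0.30",
  "    3 L * 0.91",
  "    4 A * 0.88",
  "    5 V . 0.22"), collapse = "\n")

test_that("diso conversion encodes disordered runs with mean confidence", {
  df <- annotations_df(diso_to_row(read_diso(diso_fixture)))
  expect_identical(df$start, 3L)
  expect_identical(df$end, 4L)
  expect_equal(df$score, mean(c(0.91, 0.88)))

  ordered <- read_diso(diso_fixture)
  ordered$state <- "."
  expect_length(diso_to_row(ordered)$annotations, 0L)

  leading <- read_diso(diso_fixture)
  leading$state <- c("*", "*", ".", ".", ".")
  df <- annotations_df(diso_to_row(leading))
  expect_identical(df$start, 1L)
  expect_identical(df$end, 2L)
  expect_error(read_diso("1 M x 0.5"), class = "ft_format_error")
})

test_that("convert_prediction wraps one row with the residue count", {
  s <- convert_prediction(ss2_fixture, "ss2")
  expect_identical(s$sequence_length, 6L)
  expect_length(s$rows, 1L)
  expect_identical(nrow(validate_viewer(s)), 0L)
  s <- convert_prediction(pc2_fixture, "pc2", p_threshold = 0.025)
  expect_identical(s$sequence_length, 4L)
})
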