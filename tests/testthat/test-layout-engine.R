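# The worked pair (2,10) / (8,19): overlapping on 8-10, merging to 2-19.
worked <- data.frame(start = c(2L, 8L), end = c(10L, 19L))

test_that("overlap predicate and region follow inclusive coordinates", {
  expect_true(overlaps(c(2, 10), c(8, 19)))
  expect_false(overlaps(c(1, 5), c(6, 9)))   # adjacency is not overlap
  expect_true(overlaps(c(1, 5), c(5, 9)))    # one shared position suffices

  expect_identical(overlap_region(c(2, 10), c(8, 19)),
                   c(start = 8L, end = 10L))
  expect_identical(overlap_region(c(1, 5), c(5, 9)),
                   c(start = 5L, end = 5L))
  expect_null(overlap_region(c(1, 3), c(7, 9)))
  expect_error(overlaps(c(7, 3), c(1, 2)), class = "ft_validation_error")
})

test_that("merge_blocks unions overlaps but keeps adjacent intervals apart", {
  mb <- merge_blocks(worked)
  expect_identical(mb$start, 2L)
  expect_identical(mb$end, 19L)
  expect_identical(mb$members[[1]], c(1L, 2L))

  expect_identical(nrow(merge_blocks(data.frame(start = integer(),
                                                end = integer()))), 0L)
  adj <- merge_blocks(data.frame(start = c(1L, 6L), end = c(5L, 9L)))
  expect_identical(adj$start, c(1L, 6L))
  expect_identical(adj$end, c(5L, 9L))
})

test_that("expand indicator predicate fires only on true overlaps", {
  expect_true(has_overlaps(worked))
  expect_false(has_overlaps(data.frame(start = c(1L, 6L), end = c(5L, 9L))))
  expect_false(has_overlaps(data.frame(start = integer(), end = integer())))
})

test_that("greedy first-fit packing matches hand-checked cases", {
  ta <- assign_tracks(worked)
  expect_identical(ta$track_index, c(0L, 1L))
  expect_identical(ta$n_tracks, 2L)

  disj <- data.frame(start = c(1L, 4L, 7L), end = c(3L, 6L, 9L))
  expect_identical(assign_tracks(disj)$track_index, c(0L, 0L, 0L))
  expect_identical(assign_tracks(disj)$n_tracks, 1L)
  expect_identical(assign_tracks(data.frame(start = integer(),
                                            end = integer()))$n_tracks, 0L)

  # duplicate identical intervals are distinct records: one track each
  dup <- data.frame(start = c(3L, 3L, 3L), end = c(7L, 7L, 7L))
  expect_identical(sort(assign_tracks(dup)$track_index), 0:2)
})

test_that("max_depth counts the deepest position coverage", {
  expect_identical(max_depth(worked), 2L)
  expect_identical(max_depth(data.frame(start = integer(), end = integer())),
                   0L)
  expect_identical(max_depth(data.frame(start = 1:3, end = c(10L, 9L, 8L))),
                   3L)
})

test_that("track packing is optimal and collision-free on random inputs", {
  set.seed(42)
  for (rep in 1:150) {
    iv <- rand_intervals(sample.int(8L, 1L), 60L)
    ta <- assign_tracks(iv)
    expect_identical(ta$n_tracks, bf_min_tracks(iv))
    expect_identical(ta$n_tracks, max_depth(iv))
    expect_identical(max_depth(iv), bf_max_depth(iv))
    # no two intervals on a common track overlap
    for (t in unique(ta$track_index)) {
      on_t <- which(ta$track_index == t)
      if (length(on_t) > 1L) {
        cmb <- utils::combn(on_t, 2L)
        for (c in seq_len(ncol(cmb)))
          expect_false(overlaps(c(iv$start[cmb[1, c]], iv$end[cmb[1, c]]),
                                c(iv$start[cmb[2, c]], iv$end[cmb[2, c]])))
      }
    }
  }
})

test_that("merged blocks are disjoint, sorted, and cover the exact union", {
  set.seed(43)
  for (rep in 1:60) {
    iv <- rand_intervals(sample.int(50L, 1L), 200L)
    mb <- merge_blocks(iv)
    if (nrow(mb) > 1L) {
      expect_true(all(diff(mb$start) > 0))
      expect_true(all(mb$start[-1] > mb$end[-nrow(mb)]))  # disjoint
    }
    covered <- unlist(lapply(seq_len(nrow(mb)),
                             function(i) mb$start[i]:mb$end[i]))
    expect_identical(sort(covered), bf_union_positions(iv))
    expect_identical(sort(unlist(mb$members)), seq_len(nrow(iv)))
  }
})

test_that("layout results are invariant under input permutation", {
  set.seed(44)
  for (rep in 1:25) {
    iv <- rand_intervals(7L, 50L)
    perm <- sample.int(nrow(iv))
    pv <- iv[perm, , drop = FALSE]
    mb1 <- merge_blocks(iv); mb2 <- merge_blocks(pv)
    expect_identical(mb1[c("start", "end")], mb2[c("start", "end")])
    expect_identical(assign_tracks(iv)$n_tracks, assign_tracks(pv)$n_tracks)
    expect_identical(max_depth(iv), max_depth(pv))
  }
})

test_that("merge and depth agree with the IRanges reference routines", {
  library(IRanges)
  set.seed(45)
  for (rep in 1:20) {
    iv <- rand_intervals(sample.int(30L, 1L), 150L)
    ir <- IRanges(iv$start, iv$end)
    red <- reduce(ir, min.gapwidth = 0L)   # merge only true overlaps
    mb <- merge_blocks(iv)
    expect_identical(mb$start, start(red))
    expect_identical(mb$end, end(red))
    expect_identical(max_depth(iv), max(max(coverage(ir)), 0L))
  }
})
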