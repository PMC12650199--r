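test_that("pairing honours the published lag windows", {
  d <- point_events(10.0, "DELTA")
  s1 <- point_events(10.5, "SPINDLE")
  p <- pair_events(d, s1, c(0.1, 1.3))
  expect_equal(nrow(p), 1)
  expect_equal(p$lag_s, 0.5)
  expect_equal(nrow(pair_events(d, point_events(11.5, "SPINDLE"),
                                c(0.1, 1.3))), 0)

  r <- point_events(5.00, "RIPPLE", "CA1")
  expect_equal(nrow(pair_events(r, point_events(5.10, "DELTA"),
                                c(0.05, 0.25))), 1)
  expect_equal(nrow(pair_events(r, point_events(5.40, "DELTA"),
                                c(0.05, 0.25))), 0)
})

test_that("window boundaries are half-open (lo, hi]", {
  d <- point_events(10.0, "DELTA")
  at_lo <- point_events(10.1, "SPINDLE")
  at_hi <- point_events(11.3, "SPINDLE")
  expect_equal(nrow(pair_events(d, at_lo, c(0.1, 1.3))), 0)
  expect_equal(nrow(pair_events(d, at_hi, c(0.1, 1.3))), 1)
})

test_that("greedy pairing uses each event once; all-pairs does not", {
  d <- point_events(10.0, "DELTA")
  s <- point_events(c(10.3, 10.6), "SPINDLE")
  g <- pair_events(d, s, c(0.1, 1.3), "GREEDY_ONE_TO_ONE")
  expect_equal(nrow(g), 1)
  expect_equal(g$lag_s, 0.3)     # earliest in-window follower
  a <- pair_events(d, s, c(0.1, 1.3), "ALL_PAIRS")
  expect_equal(nrow(a), 2)

  unsorted <- point_events(c(3, 1), "DELTA")
  unsorted$peak_s <- c(3, 1)  # break sorting by hand
  expect_error(pair_events(unsorted, s, c(0.1, 1.3)), "sorted")
})

test_that("triples require both windows through the shared delta", {
  r <- point_events(5.00, "RIPPLE", "CA1")
  d <- point_events(5.10, "DELTA")
  s <- point_events(5.60, "SPINDLE")
  tri <- triple_sequences(r, d, s)
  expect_equal(nrow(tri), 1)
  d_far <- point_events(5.40, "DELTA")
  s_far <- point_events(5.90, "SPINDLE")
  expect_equal(nrow(triple_sequences(r, d_far, s_far)), 0)
  empty <- point_events(numeric(0), "RIPPLE", "CA1")
  expect_equal(nrow(triple_sequences(empty, d, s)), 0)
})

test_that("coupling counts shift-invariantly match exhaustive enumeration", {
  set.seed(77)
  for (rep in 1:40) {
    nl <- sample(0:20, 1)
    nf <- sample(0:20, 1)
    lt <- sort(runif(nl, 0, 60))
    ft <- sort(runif(nf, 0, 60))
    L <- point_events(lt, "DELTA")
    FL <- point_events(ft, "SPINDLE")
    for (mode in c(TRUE, FALSE)) {
      got <- pair_events(L, FL, c(0.1, 1.3),
                         if (mode) "GREEDY_ONE_TO_ONE" else "ALL_PAIRS")
      want <- bf_pair(lt, ft, 0.1, 1.3, greedy = mode)
      expect_equal(nrow(got), length(want))
    }
    g <- nrow(pair_events(L, FL, c(0.1, 1.3), "GREEDY_ONE_TO_ONE"))
    a <- nrow(pair_events(L, FL, c(0.1, 1.3), "ALL_PAIRS"))
    expect_lte(g, a)
    # translation invariance
    L2 <- point_events(lt + 1234.5, "DELTA")
    F2 <- point_events(ft + 1234.5, "SPINDLE")
    expect_equal(nrow(pair_events(L2, F2, c(0.1, 1.3))), g)
  }
})

test_that("rates normalize by sleep minutes with guarded division", {
  h <- hypnogram(rep(c("NREM", "WAKE"), each = 90), 4)  # 6 min NREM
  d <- point_events(seq(2, 350, length.out = 12), "DELTA")
  s <- point_events(seq(2, 350, length.out = 12) + 0.5, "SPINDLE")
  r <- point_events(numeric(0), "RIPPLE", "CA1")
  cr <- coupling_rates(r, d, s, h, phase = "PRE")
  expect_equal(unname(cr$counts[["ds"]]), 12)
  expect_equal(unname(cr$rates_per_min[["ds"]]), 2)
  expect_equal(cr$sleep_minutes, 6)
  expect_true(cr$counts[["rds"]] <= min(cr$counts[["rd"]],
                                        cr$counts[["ds"]]))
  all_wake <- hypnogram(rep("WAKE", 10), 4)
  expect_error(coupling_rates(r, d, s, all_wake), "zero sleep")
})

test_that("greedy and all-pairs agree when no double pairing is possible", {
  lt <- c(10, 20, 30)
  ft <- lt + 0.5
  L <- point_events(lt, "DELTA")
  FL <- point_events(ft, "SPINDLE")
  g <- pair_events(L, FL, c(0.1, 1.3), "GREEDY_ONE_TO_ONE")
  a <- pair_events(L, FL, c(0.1, 1.3), "ALL_PAIRS")
  expect_equal(nrow(g), nrow(a))
})

test_that("phase comparison reports zero differences for identical phases", {
  h <- hypnogram(rep("NREM", 150), 4)
  d <- point_events(seq(5, 590, by = 7), "DELTA")
  s <- point_events(seq(5, 590, by = 7) + 0.4, "SPINDLE")
  r <- point_events(seq(3, 580, by = 11), "RIPPLE", "CA1")
  cr <- coupling_rates(r, d, s, h)
  out <- compare_phases(list(cr, cr, cr), list(cr, cr, cr), seed = 1)
  expect_equal(out$mean_diff, rep(0, 3))
  single <- compare_phases(list(cr), list(cr), seed = 1)
  expect_true(all(is.na(single$ci_lo)))
  expect_error(compare_phases(list(), list(cr)), "at least one")
  expect_error(compare_phases(list(cr), list(cr, cr)), "matched")
})
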