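test_that("Welch t-test matches hand-evaluated statistics and conventions", {
  expect_equal(welch_t_test(c(1, 2, 3), c(1, 2, 3))[c("t", "p")],
               list(t = 0, p = 1))
  w <- welch_t_test(c(1, 2, 3), c(2, 4, 6))
  expect_equal(w$t, -1.549, tolerance = 1e-3)
  expect_equal(w$df, 2.941, tolerance = 1e-3)
  d <- welch_t_test(c(5, 5), c(5, 5))
  expect_equal(d$p, 1)
  expect_false(d$degenerate)
  d2 <- welch_t_test(c(5, 5), c(7, 7))
  expect_equal(d2$p, 0)
  expect_true(d2$degenerate)
  expect_error(welch_t_test(1, c(1, 2)), ">= 2")
})

test_that("Welch and pooled t agree with stats::t.test on random data", {
  set.seed(10)
  for (i in 1:20) {
    a <- rnorm(sample(3:8, 1)); b <- rnorm(sample(3:8, 1), mean = runif(1))
    w <- welch_t_test(a, b)
    ref <- t.test(a, b)
    expect_equal(w$t, unname(ref$statistic), tolerance = 1e-12)
    expect_equal(w$p, ref$p.value, tolerance = 1e-12)
    expect_equal(w$df, unname(ref$parameter), tolerance = 1e-12)
    s <- welch_t_test(a, b, var_equal = TRUE)
    refp <- t.test(a, b, var.equal = TRUE)
    expect_equal(s$p, refp$p.value, tolerance = 1e-12)
  }
})

test_that("BH adjustment equals hand step-up on all permutations of 5 p-values", {
  base_p <- c(0.005, 0.01, 0.03, 0.04, 0.2)
  for (p in all_perms(base_p)) {
    expect_equal(bh_adjust(p), bh_oracle(p), tolerance = 1e-12)
  }
})

test_that("BH handles frozen examples, NAs and bad input", {
  expect_equal(bh_adjust(c(0.01, 0.04, 0.03, 0.005)),
               c(0.02, 0.04, 0.04, 0.02))
  expect_equal(bh_adjust(rep(1, 4)), rep(1, 4))
  expect_equal(bh_adjust(0.3), 0.3)
  q <- bh_adjust(c(0.01, NA, 0.04))
  expect_true(is.na(q[2]))
  expect_equal(q[c(1, 3)], bh_adjust(c(0.01, 0.04)))
  expect_error(bh_adjust(c(0.5, 1.2)), "\\[0, 1\\]")
  p <- runif(50); expect_true(all(bh_adjust(p) >= p))
})

test_that("signed fold change follows the +r / -1/r convention", {
  expect_equal(signed_fold_change(c(2, 2), c(1, 1)), 2)
  expect_equal(signed_fold_change(c(1, 1), c(2, 2)), -2)
  expect_equal(signed_fold_change(c(3, 3), c(3, 3)), 1)
  expect_error(signed_fold_change(numeric(0), 1), "empty")
})

test_that("regulation calls apply strict FC and FDR thresholds jointly", {
  # 40 reporters, one time point, 5v5; three crafted cases on top of noise
  set.seed(33)
  M <- matrix(rnorm(40 * 10, 0, 0.05), 40)
  # g001: strong clean up-effect -> called up
  M[1, 1:5] <- M[1, 1:5] + 1.5
  # g002: FC exactly 1.8 with zero within-group variance -> q tiny, not called
  M[2, ] <- rep(c(log2(1.8), 0), each = 5)
  # g003: big effect but huge variance -> q large, not called
  M[3, 1:5] <- c(-8, 4, -6, 5, -7.5)
  ds <- filter_expressed(toy_dataset(M, times = 1, n_rep = 5))
  calls <- call_regulated(ds)
  g1 <- calls[calls$reporter == "g001", ]
  expect_true(g1$called); expect_equal(g1$direction, "up")
  g2 <- calls[calls$reporter == "g002", ]
  expect_equal(g2$fc, 1.8, tolerance = 1e-12)
  expect_false(g2$called) # strict > 1.8
  g3 <- calls[calls$reporter == "g003", ]
  expect_false(g3$called)
  expect_equal(g3$direction, "none")
  # invariants: q >= p, direction consistent with FC sign when called
  expect_true(all(calls$q >= calls$p - 1e-15, na.rm = TRUE))
  called <- calls[calls$called, ]
  expect_true(all(ifelse(called$fc > 0, "up", "down") == called$direction))
})

test_that("per-row statistics match the scalar Welch test", {
  set.seed(12)
  M <- matrix(rnorm(20 * 10), 20)
  ds <- filter_expressed(toy_dataset(M, times = 1, n_rep = 5))
  calls <- call_regulated(ds)
  dep <- ds$design$array_id[ds$design$condition == "depleted"]
  ctl <- ds$design$array_id[ds$design$condition == "control"]
  for (i in c(1, 7, 20)) {
    w <- welch_t_test(ds$M[i, dep], ds$M[i, ctl])
    expect_equal(calls$p[calls$reporter == rownames(ds$M)[i]], w$p,
                 tolerance = 1e-12)
  }
})

test_that("swapping condition labels negates FC and preserves p", {
  set.seed(21)
  M <- matrix(rnorm(30 * 10), 30)
  ds <- toy_dataset(M, times = 1, n_rep = 5)
  swapped <- ds
  swapped$design$condition <- ifelse(ds$design$condition == "depleted",
                                     "control", "depleted")
  c1 <- call_regulated(filter_expressed(ds))
  c2 <- call_regulated(filter_expressed(swapped))
  # r = 1 exactly never occurs with continuous data, so negation is exact
  expect_equal(c1$fc, -c2$fc, tolerance = 1e-12)
  expect_equal(c1$p, c2$p, tolerance = 1e-12)
})

test_that("temporal summary counts events and persistent genes", {
  calls <- data.frame(
    reporter = c("a", "b", "c", "d", "e"),
    time = c(1, 1, 4, 4, 4),
    fc = c(2, 2.5, -2, -3, -2.2), p = 0.01, q = 0.02,
    direction = c("up", "up", "down", "down", "down"),
    called = TRUE)
  s <- temporal_summary(calls)
  expect_equal(s$pct_up, 40)
  expect_equal(s$pct_down, 60)
  expect_equal(s$per_time$n_total, c(2, 3))

  # one gene called down at every time point -> the persistent list
  calls2 <- data.frame(
    reporter = rep(c("mt2", "x"), each = 5),
    time = rep(c(0.3, 1, 4, 7, 14), 2),
    fc = c(rep(-3, 5), 2, rep(1.1, 4)), p = 0.01, q = 0.02,
    direction = c(rep("down", 5), "up", rep("none", 4)),
    called = c(rep(TRUE, 5), TRUE, rep(FALSE, 4)))
  expect_equal(temporal_summary(calls2)$persistent, "mt2")

  empty <- calls[0, ]
  s0 <- temporal_summary(empty)
  expect_true(is.na(s0$pct_up) && is.na(s0$pct_down))
  expect_equal(s0$n_events, 0)
})
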