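mk_tab <- function(cs, ts = rep(8, length(cs)), onset = 4.5, bin_size = 50) {
  tab <- data.frame(subject = seq_along(cs), corrected_steepness = cs, t_s = ts)
  attr(tab, "onset") <- onset
  attr(tab, "bin_size") <- bin_size
  tab
}

test_that("classification uses the strict control maximum", {
  calls <- classify_cohort(mk_tab(c(0.05, 0.2), ts = c(6, 8)), mk_tab(c(0.1, 0.02)))
  expect_equal(calls$insight, c(FALSE, TRUE))
  expect_equal(attr(calls, "threshold"), 0.1)
  expect_equal(calls$delay_bins, c(NA, 8 - 4.5))
  expect_equal(calls$delay_trials, c(NA, 3.5 * 50))
  # a value equal to the control maximum is NOT flagged (strict >)
  eq <- classify_cohort(mk_tab(c(0.1)), mk_tab(c(0.1, 0.02)))
  expect_false(any(eq$insight))
  expect_error(classify_cohort(mk_tab(0.1), mk_tab(numeric(0))), "control")
})

test_that("a control cohort defining its own threshold yields zero flags", {
  set.seed(121)
  cs <- rnorm(99, 0.1, 0.05)
  calls <- classify_cohort(mk_tab(cs), mk_tab(cs))
  expect_equal(sum(calls$insight), 0L)
})

test_that("classification against an independent control flags ~1 in 100 by exchangeability", {
  set.seed(131)
  flagged <- replicate(300, {
    exp_cs <- rnorm(99)
    ctl_cs <- rnorm(99)
    sum(classify_cohort(mk_tab(exp_cs), mk_tab(ctl_cs))$insight)
  })
  # each of 99 exchangeable values exceeds the max of 99 others w.p. 1/199ish;
  # the expected count is ~99/100 of one unit, i.e. about 0.5-1 per cohort
  expect_gt(mean(flagged), 0.1)
  expect_lt(mean(flagged), 3)
  expect_lt(median(flagged), 2)
})

test_that("classification is invariant to subject order", {
  set.seed(141)
  cs <- runif(20); ts <- runif(20, 5, 12)
  ctl <- runif(20, 0, 0.4)
  a <- classify_cohort(mk_tab(cs, ts), mk_tab(ctl))
  perm <- sample(20)
  b <- classify_cohort(mk_tab(cs[perm], ts[perm]), mk_tab(sample(ctl)))
  expect_equal(sum(a$insight), sum(b$insight))
  expect_equal(a$insight, b$insight[order(perm)])
})

test_that("synthetic sigmoid switchers are detected against null controls", {
  # single-subject power at ~15 lowest-coherence trials per bin is ~0.7
  # (binomial bin noise SD ~0.13 against a 0.35 step); the test guards the
  # lower tail of that oracle-computed detection rate
  set.seed(151)
  hits <- 0L
  for (r in 1:20) {
    sw <- make_fixtures("sigmoid_subject",
                        list(m = 50, t_s = 9, y_min = 0.6, y_max = 0.95))
    nulls <- lapply(1:20, function(i)
      make_fixtures("null_subject", list(p = 0.6), subject_id = i))
    f_exp <- fit_cohort(list(sw))
    f_ctl <- fit_cohort(nulls)
    hits <- hits + sum(classify_cohort(f_exp$table, f_ctl$table)$insight)
  }
  expect_gte(hits, 10L)
})

test_that("delay alignment reports pre/post accuracy and tests uniformity", {
  set.seed(161)
  n_ins <- 30L
  series <- lapply(1:n_ins, function(i)
    make_series(c(rep(0.6, 7), rep(0.9, 7)), y_min = 0.6))
  calls <- structure(
    data.frame(subject = 1:n_ins, corrected_steepness = 1, t_s = 7.5,
               insight = TRUE, delay_bins = 3, delay_trials = 150),
    class = c("insight_calls", "data.frame"),
    threshold = 0.5, onset = 4.5, bin_size = 50)
  out <- delay_and_alignment(calls, series)
  expect_equal(unname(out$pre_post["pre"]), 0.6)
  expect_equal(unname(out$pre_post["post"]), 0.9)
  # all delays identical: KS must reject uniformity over the window
  expect_lt(out$ks$p.value, 0.05)

  # no insight subjects: empty result, not an error
  calls0 <- calls; calls0$insight <- FALSE
  out0 <- delay_and_alignment(calls0, series)
  expect_length(out0$delays, 0)
  expect_null(out0$ks)
})

test_that("the exact KS test holds its size under uniform delays", {
  set.seed(171)
  W <- 9.5
  series <- lapply(1:49, function(i) make_series(rep(0.6, 14), y_min = 0.6))
  rej <- replicate(200, {
    d <- runif(49, 0, W)
    calls <- structure(
      data.frame(subject = 1:49, corrected_steepness = 1, t_s = 4.5 + d,
                 insight = TRUE, delay_bins = d, delay_trials = 50 * d),
      class = c("insight_calls", "data.frame"),
      threshold = 0.5, onset = 4.5, bin_size = 50)
    delay_and_alignment(calls, series)$ks$p.value < 0.05
  })
  expect_gt(mean(rej), 0.005)
  expect_lt(mean(rej), 0.12)
})
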