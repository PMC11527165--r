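test_that("binned accuracy tiles the motion+colour window correctly", {
  set.seed(81)
  mod <- input_model(M_m = c(0.03, 0.04, 0.1, 0.13, 0.17))
  tr <- train_network(sample_inputs(build_curriculum(), mod))
  s <- bin_accuracy(tr, bin_size = 50)
  expect_equal(nrow(s), 14L)                 # (200 + 500) / 50
  expect_equal(attr(s, "onset"), 4.5)        # colour starts after 4 motion bins
  expect_equal(attr(s, "n_filtered"), 7L * 30L)
  # y_min equals the motion-phase lowest-coherence accuracy
  mot <- tr[tr$phase == "motion" & tr$coherence == 5, ]
  expect_equal(attr(s, "y_min"), mean(mot$correct))

  # all-correct input gives flat 1.0; alternating gives 0.5
  tr2 <- tr; tr2$correct <- 1L
  expect_true(all(bin_accuracy(tr2)$acc == 1))
  tr3 <- tr; tr3$correct <- rep_len(c(1L, 0L), nrow(tr))
  s3 <- bin_accuracy(tr3, coherence = 45)   # 20/block, even per bin on average
  expect_true(all(abs(s3$acc - 0.5) <= 0.5))
  # an empty bin after filtering is an error naming the bin
  tr4 <- tr[!(tr$coherence == 5 & tr$trial > 1250), ]
  expect_error(bin_accuracy(tr4, bin_size = 50), "bin 14")
})

test_that("noiseless linear data is won by the linear model", {
  y <- 0.02 * (1:20) + 0.6
  f <- fit_switch_models(make_series(y, y_min = 0.6))
  expect_lt(f$linear$bic, f$sigmoid$bic)
  expect_lt(f$linear$bic, f$step$bic)
  expect_equal(unname(f$linear$params["m"]), 0.02, tolerance = 1e-8)
})

test_that("sigmoid parameters are recovered from noisy series", {
  set.seed(91)
  m_true <- 4; ts_true <- 10; y_min <- 0.6; y_max <- 0.95
  err_ts <- err_m <- numeric(100)
  for (r in 1:100) {
    y <- sigmoid_truth <- y_min + (y_max - y_min) /
      (1 + exp(-m_true * ((1:20) - ts_true))) + rnorm(20, 0, 0.02)
    f <- fit_switch_models(make_series(y, y_min = y_min))
    err_ts[r] <- f$sigmoid$params[["t_s"]] - ts_true
    err_m[r] <- (f$sigmoid$params[["m"]] - m_true) / m_true
  }
  expect_lte(median(abs(err_ts)), 1)
  expect_lte(median(abs(err_m)), 0.3)
})

test_that("the step model is the steep-slope limit of the sigmoid", {
  y <- c(rep(0.6, 9), rep(0.95, 11))  # clean step at t = 10
  f50 <- fit_switch_models(make_series(y, y_min = 0.6), m_max = 50)
  expect_equal(f50$sigmoid$sse, f50$step$sse, tolerance = 1e-4)
  # and the fitted step parameters are exact
  expect_equal(unname(f50$step$params), c(10, 0.35, 0.95), tolerance = 1e-10)
})

test_that("slope at inflection matches the analytic formula and its numeric derivative", {
  f <- list(params = c(m = 2, t_s = 5, y_max = 1, y_min = 0.5))
  expect_equal(steepness(f), 0.25)
  f0 <- list(params = c(m = 0, t_s = 5, y_max = 1, y_min = 0.5))
  expect_equal(steepness(f0), 0)
  set.seed(101)
  for (i in 1:50) {
    m <- runif(1, 0.1, 10); ts <- runif(1, 2, 18)
    ymin <- runif(1, 0.4, 0.7); ymax <- runif(1, ymin + 0.05, 1)
    h <- 1e-4
    num <- (sigmoid_curve(ts + h, m, ts, ymax, ymin) -
              sigmoid_curve(ts - h, m, ts, ymax, ymin)) / (2 * h)
    expect_equal(m * (ymax - ymin) / 4, num, tolerance = 1e-6)
  }
})

test_that("corrected steepness subtracts the declared fit penalty", {
  y <- 0.6 + 0.35 / (1 + exp(-3 * ((1:20) - 10)))
  s <- make_series(y, y_min = 0.6)
  f <- fit_switch_models(s)$sigmoid
  # essentially perfect fit: correction changes nothing
  expect_equal(corrected_steepness(f, s), steepness(f), tolerance = 1e-3)
  # declared arithmetic: steepness 0.25, RMSE 0.05 -> 0.20
  fake <- list(params = c(m = 2, t_s = 5, y_max = 1, y_min = 0.5),
               sse = 20 * 0.05^2)
  expect_equal(corrected_steepness(fake, s, penalty = "rmse"), 0.20)
  expect_equal(corrected_steepness(fake, s, penalty = "none"), 0.25)
})

test_that("equal penalties preserve the cohort ranking", {
  set.seed(111)
  fits <- lapply(1:5, function(i) {
    list(params = c(m = runif(1, 1, 6), t_s = 8, y_max = 0.95, y_min = 0.6),
         sse = 14 * 0.04^2)   # identical RMSE for all
  })
  s <- make_series(rep(0.6, 14), y_min = 0.6)
  raw <- vapply(fits, function(f) corrected_steepness(f, s, "none"), numeric(1))
  cor_ <- vapply(fits, function(f) corrected_steepness(f, s, "rmse"), numeric(1))
  expect_identical(order(raw), order(cor_))
})
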