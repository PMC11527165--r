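test_that("default curriculum has exact block structure and coherence counts", {
  set.seed(1)
  cur <- build_curriculum()
  expect_equal(nrow(cur), 1300L)
  expect_equal(unique(cur$phase[cur$block <= 6]), "training")
  expect_equal(unique(cur$phase[cur$block %in% 7:8]), "motion")
  expect_equal(unique(cur$phase[cur$block >= 9]), "colour")
  # exact per-block counts, not sampled
  for (b in 7:13) {
    tab <- table(cur$coherence[cur$block == b])
    expect_equal(as.integer(tab[c("5", "10", "20", "30", "45")]),
                 c(30L, 10L, 20L, 20L, 20L))
  }
  # training blocks contain only the three highest levels
  expect_setequal(unique(cur$coherence[cur$phase == "training"]), c(20, 30, 45))
  # labels exactly balanced within every block
  balance <- tapply(cur$y, cur$block, sum)
  expect_true(all(balance == 0))
})

test_that("curriculum generation is deterministic under a fixed seed", {
  set.seed(7); a <- build_curriculum()
  set.seed(7); b <- build_curriculum()
  expect_identical(a, b)
  set.seed(8); c <- build_curriculum()
  expect_false(identical(a$y, c$y))
})

test_that("curriculum_spec rejects invalid proportions", {
  expect_error(curriculum_spec(coherence_counts = c(`5` = 40, `10` = 10,
                                                    `20` = 20, `30` = 20,
                                                    `45` = 20)),
               "sum")
  expect_error(input_model(M_m = rep(-0.1, 5)), "non-negative")
})

test_that("sampled inputs have the specified conditional moments", {
  mod <- input_model(M_m = c(0.3, 0.3, 0.3, 0.3, 0.3))
  base <- data.frame(trial = 1:10000, block = 1L, phase = "colour",
                     coherence = 5, y = rep(c(-1, 1), 5000))
  set.seed(2)
  tr <- sample_inputs(base, mod)
  # colour predictive: mean x_c tracks the label, M_c = 0.22
  expect_equal(mean(tr$x_c[tr$y == 1]), 0.22, tolerance = 0.005)
  expect_equal(mean(tr$x_c[tr$y == -1]), -0.22, tolerance = 0.005)
  # motion: y = -1 trials centred at -M_m with SD sigma_m
  expect_equal(mean(tr$x_m[tr$y == -1]), -0.3, tolerance = 0.01)
  expect_equal(sd(tr$x_m[tr$y == -1]), 0.1, tolerance = 0.01)

  # non-predictive phases: zero encoding carries no label information
  base$phase <- "training"
  set.seed(3)
  tz <- sample_inputs(base, mod)
  expect_lt(abs(mean(tz$x_c)), 0.001)
  expect_equal(sd(tz$x_c), 0.01, tolerance = 0.01)
  # coin encoding: full contrast but sign independent of the label
  modc <- input_model(M_m = rep(0.3, 5), nonpredictive = "coin")
  set.seed(4)
  tc <- sample_inputs(base, modc)
  expect_equal(mean(abs(tc$x_c)), 0.22, tolerance = 0.005)
  expect_lt(abs(cor(sign(tc$x_c), tc$y)), 0.03)
})

test_that("control cohorts never receive predictive colour", {
  mod <- input_model(M_m = rep(0.2, 5), nonpredictive = "coin")
  base <- data.frame(trial = 1:6000, block = 9L, phase = "colour",
                     coherence = 5, y = rep(c(-1, 1), 3000))
  set.seed(5)
  tr <- sample_inputs(base, mod, colour_predictive = FALSE)
  expect_lt(abs(cor(sign(tr$x_c), tr$y)), 0.05)
})
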