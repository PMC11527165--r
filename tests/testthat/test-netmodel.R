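test_that("forward pass matches hand-evaluated outputs", {
  z0 <- forward(net_state(0, 0, 0, 0), x_m = 1, x_c = 1, eta = 0.03)
  expect_equal(z0$z, 0.03)
  expect_equal(z0$y_hat, 1)

  z1 <- forward(net_state(w_m = 1, g_m = 1, w_c = 0, g_c = 0), x_m = 0.5,
                x_c = 0, eta = 0)
  expect_equal(z1$z, 0.5)
  expect_equal(z1$y_hat, 1)

  z2 <- forward(net_state(w_m = 2, g_m = 0.5, w_c = 1, g_c = 0.1),
                x_m = -0.3, x_c = 0.22, eta = 0)
  expect_equal(z2$z, -0.278)
  expect_equal(z2$y_hat, -1)

  # sign(0) tie-break is +1
  expect_equal(forward(net_state(0, 0, 0, 0), 0, 0, eta = 0)$y_hat, 1)
})

test_that("one L1 step matches the hand-derived update", {
  st <- net_state()  # all 0.01
  hy <- net_hyper(l1_update = "subgradient")  # alpha 0.6, lambda 0.07
  out <- sgd_step(st, x_m = 0.3, x_c = 0.22, y = 1, hyper = hy)
  r <- 0.01 * 0.01 * 0.3 + 0.01 * 0.01 * 0.22 - 1
  expect_equal(r, -0.999948)
  expect_equal(out$state[["w_m"]] - 0.01, -0.6 * 0.3 * 0.01 * r)   # +0.00179990...
  expect_equal(out$state[["g_m"]] - 0.01,
               -0.6 * (0.3 * 0.01 * r + 0.07))                      # -0.04020009...
  # raw gradients are pre-noise and include the penalty
  expect_equal(out$gradients[["g_c"]], 0.22 * 0.01 * r + 0.07)

  # proximal convention: the same step soft-thresholds the tiny gate to zero
  # instead of overshooting to -0.03, and coincides away from the kink
  pr <- sgd_step(st, 0.3, 0.22, 1, net_hyper())
  expect_equal(pr$state[["g_m"]], 0)
  big <- net_state(g_m = 0.6, g_c = 0.5)
  a <- sgd_step(big, 0.3, 0.22, 1, net_hyper())
  b <- sgd_step(big, 0.3, 0.22, 1, net_hyper(l1_update = "subgradient"))
  expect_equal(unclass(a$state), unclass(b$state))
})

test_that("zero inputs with zero penalty leave the state unchanged", {
  st <- net_state(0.3, -0.2, 0.5, 0.1)
  hy <- net_hyper(lambda = 0)
  out <- sgd_step(st, x_m = 0, x_c = 0, y = 1, hyper = hy)
  expect_equal(unclass(out$state), unclass(st))
})

test_that("L2 penalises small gates less than L1", {
  st <- net_state(0.5, 0.5, g_m = 0.3, g_c = -0.4)   # |g| < 1
  l1 <- sgd_step(st, 0.1, 0.1, 1, net_hyper(regulariser = "l1"))
  l2 <- sgd_step(st, 0.1, 0.1, 1, net_hyper(regulariser = "l2"))
  pen1 <- l1$gradients[["g_m"]] - (0.1 * st[["w_m"]] * (forward(st, 0.1, 0.1)$z - 1))
  pen2 <- l2$gradients[["g_m"]] - (0.1 * st[["w_m"]] * (forward(st, 0.1, 0.1)$z - 1))
  expect_lt(abs(pen2), abs(pen1))
})

test_that("analytic gradients match finite differences of the loss", {
  set.seed(21)
  for (reg in c("l1", "l2", "none")) {
    hy <- net_hyper(regulariser = reg, sigma_eta = 0, sigma_xi = 0)
    for (i in 1:20) {
      st <- random_state()
      x_m <- runif(1, -1, 1); x_c <- runif(1, -1, 1)
      y <- sample(c(-1, 1), 1); eta <- rnorm(1, 0, 0.05)
      g <- sgd_step(st, x_m, x_c, y, hy, eta = eta)$gradients
      sgn <- sign(c(st[["g_m"]], st[["g_c"]]))   # frozen subgradient
      fd <- num_grad(function(p) net_loss(p, x_m, x_c, y, eta, hy$lambda,
                                          reg, TRUE, sgn),
                     unclass(st))
      expect_equal(unname(g[c("w_m", "w_c", "g_m", "g_c")]), fd,
                   tolerance = 1e-6)
    }
  }
  # gateless variant against its own loss
  hy <- net_hyper(gated = FALSE)
  for (i in 1:10) {
    st <- random_state()
    x_m <- runif(1, -1, 1); x_c <- runif(1, -1, 1); y <- sample(c(-1, 1), 1)
    g <- sgd_step(st, x_m, x_c, y, hy)$gradients
    fd <- num_grad(function(p) net_loss(p, x_m, x_c, y, 0, 0, "none", FALSE),
                   unclass(st))
    expect_equal(unname(g[c("w_m", "w_c")]), fd[1:2], tolerance = 1e-6)
  }
})

test_that("the compiled trainer reproduces stepwise R updates", {
  set.seed(31)
  spec <- small_spec()
  cur <- build_curriculum(spec)[1:40, ]
  mod <- input_model(M_m = c(0.03, 0.04, 0.1, 0.13, 0.17))
  cur <- sample_inputs(cur, mod)
  for (reg in c("l1", "l2")) {
    hy <- net_hyper(regulariser = reg)
    n <- nrow(cur)
    noise <- list(eta = rnorm(n, 0, 0.05),
                  xi = matrix(rnorm(n * 4, 0, 0.03), n, 4))
    tr <- train_network(cur, hy, noise = noise)
    st <- net_state()
    for (t in 1:n) {
      expect_equal(unname(unclass(st)),
                   unname(unlist(tr[t, c("w_m", "w_c", "g_m", "g_c")])))
      st <- sgd_step(st, cur$x_m[t], cur$x_c[t], cur$y[t], hy,
                     xi = stats::setNames(noise$xi[t, ],
                                          c("w_m", "w_c", "g_m", "g_c")),
                     eta = noise$eta[t])$state
    }
    expect_equal(unname(attr(tr, "final_state")), unname(unclass(st)))
  }
})

test_that("stored traces replay bit-identically", {
  set.seed(41)
  cur <- sample_inputs(build_curriculum(small_spec()),
                       input_model(M_m = c(0.03, 0.04, 0.1, 0.13, 0.17)))
  tr <- train_network(cur)
  re <- replay_trace(tr)
  expect_identical(tr$w_c, re$w_c)
  expect_identical(tr$correct, re$correct)
  expect_identical(attr(tr, "final_state"), attr(re, "final_state"))
})

test_that("identical seeds give identical traces", {
  mod <- input_model(M_m = c(0.03, 0.04, 0.1, 0.13, 0.17))
  run <- function() {
    set.seed(5)
    train_network(sample_inputs(build_curriculum(small_spec()), mod))
  }
  expect_identical(run()$z, run()$z)
})

test_that("L1 shrinks an uninformative colour gate under zero noise", {
  set.seed(51)
  mod <- input_model(M_m = c(0.03, 0.04, 0.1, 0.13, 0.17), nonpredictive = "coin")
  cur <- sample_inputs(build_curriculum(), mod, colour_predictive = FALSE)
  hy <- net_hyper(sigma_eta = 0, sigma_xi = 0)
  tr <- train_network(cur, hy)
  expect_lt(abs(attr(tr, "final_state")[["g_c"]]), 0.01)
})

test_that("the gateless model grows its colour weight after onset", {
  set.seed(61)
  mod <- input_model(M_m = c(0.03, 0.04, 0.1, 0.13, 0.17))
  cur <- sample_inputs(build_curriculum(), mod)
  hy <- net_hyper(gated = FALSE, sigma_eta = 0, sigma_xi = 0)
  tr <- train_network(cur, hy)
  onset <- match("colour", tr$phase)
  wc <- abs(tr$w_c)
  # block-averaged |w_c| increases monotonically through the colour phase
  blocks <- split(wc[onset:nrow(tr)], (seq_len(nrow(tr) - onset + 1) - 1) %/% 100)
  expect_true(all(diff(vapply(blocks, mean, numeric(1))) > 0))
  expect_gt(wc[nrow(tr)], wc[onset])
})

test_that("overflowing updates abort with a diagnostic", {
  cur <- data.frame(trial = 1:50, block = 1, phase = "training", coherence = 45,
                    y = rep(c(-1, 1), 25))
  cur$x_m <- cur$y * 10; cur$x_c <- 0
  expect_error(train_network(cur, net_hyper(alpha = 10, sigma_xi = 0)),
               "overflow")
})
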