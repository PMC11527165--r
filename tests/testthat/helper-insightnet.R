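# shared fixtures built in code; heavier objects are cached per test run
.cache <- new.env(parent = emptyenv())

cached <- function(key, expr) {
  if (!exists(key, envir = .cache)) assign(key, force(expr), envir = .cache)
  get(key, envir = .cache)
}

# a short curriculum (2 training + 2 motion + 3 colour blocks) for fast tests
small_spec <- function() {
  curriculum_spec(n_training_blocks = 2L, n_motion_blocks = 2L,
                  n_colour_blocks = 3L)
}

# a small matched cohort shared across structural tests
small_cohort <- function() {
  cached("small_cohort", {
    set.seed(99)
    run_cohort(n = 12, seed = 42, spec = small_spec())
  })
}

# build an accuracy series object directly from values (for fit tests)
make_series <- function(acc, y_min, bin_size = 50, onset = 4.5) {
  structure(data.frame(t = seq_along(acc), acc = acc),
            class = c("accuracy_series", "data.frame"),
            y_min = y_min, bin_size = bin_size, onset = onset,
            n_filtered = length(acc) * 15L, coherence = 5)
}

# random gated-net state away from the L1 kink (for gradient checks)
random_state <- function() {
  s <- rnorm(4, 0, 1)
  s <- s + sign(s) * 0.2
  net_state(w_m = s[1], w_c = s[2], g_m = s[3], g_c = s[4])
}

# scalar-model loss (data term + gate penalty) used as the finite-difference
# oracle; the sign subgradient is frozen at the expansion point by the caller
net_loss <- function(par, x_m, x_c, y, eta, lambda, regulariser, gated,
                     sgn = NULL) {
  w_m <- par[1]; w_c <- par[2]; g_m <- par[3]; g_c <- par[4]
  r <- if (gated) g_m * w_m * x_m + g_c * w_c * x_c + eta - y
       else w_m * x_m + w_c * x_c + eta - y
  pen <- if (!gated) 0
  else if (regulariser == "l1") lambda * (sgn[1] * g_m + sgn[2] * g_c)
  else if (regulariser == "l2") lambda / 2 * (g_m^2 + g_c^2)
  else 0
  0.5 * r^2 + pen
}

num_grad <- function(f, par, h = 1e-6) {
  vapply(seq_along(par), function(i) {
    up <- par; up[i] <- up[i] + h
    dn <- par; dn[i] <- dn[i] - h
    (f(up) - f(dn)) / (2 * h)
  }, numeric(1))
}
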