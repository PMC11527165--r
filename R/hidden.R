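#' Train the hidden-layer network variant
#'
#' A 2-input, 48-ReLU-hidden-unit, 2-output softmax network in which every
#' input-to-hidden weight carries its own multiplicative gate; the L1 penalty
#' applies to the gates only. Trained per trial on the cross-entropy loss by
#' noisy online SGD (labels recoded to classes 0/1), with output noise added
#' per logit and Gaussian gradient noise on every parameter, as in the scalar
#' model. Defaults follow the hidden-layer study conditions: `lambda = 0.002`,
#' `alpha = 0.1`.
#'
#' First-layer and output weights are initialised uniformly in
#' `[-1/sqrt(fan_in), 1/sqrt(fan_in)]`; gates start at 0.01 like the scalar
#' model's. Initialisation is drawn from the current RNG state, as are all
#' noise draws, so runs are reproducible under `set.seed()`.
#'
#' @param trials trial table from [sample_inputs()].
#' @param alpha learning rate.
#' @param lambda L1 penalty on the gates.
#' @param sigma_eta output (logit) noise SD.
#' @param sigma_xi gradient noise SD (all parameters).
#' @param xi_scale noise injection point, as in [net_hyper()].
#' @param n_hidden hidden units (default 48).
#' @return a data frame of class `hidden_trace`: trial metadata plus `correct`,
#'   `loss`, and per-input-channel mean absolute weight (`wnorm_m`, `wnorm_c`)
#'   and gate (`gnorm_m`, `gnorm_c`) magnitudes; attribute `final` holds the
#'   trained parameter matrices.
#' @export
train_hidden_network <- function(trials, alpha = 0.1, lambda = 0.002,
                                 sigma_eta = 0.05, sigma_xi = 0.05,
                                 xi_scale = c("gradient", "update"),
                                 n_hidden = 48L) {
  xi_scale <- match.arg(xi_scale)
  sxi <- if (xi_scale == "gradient") alpha * sigma_xi else sigma_xi
  n <- nrow(trials)
  ycls <- as.integer((trials$y + 1) / 2)
  W1 <- matrix(runif(2L * n_hidden, -1, 1) / sqrt(2), 2L, n_hidden)
  W2 <- matrix(runif(n_hidden * 2L, -1, 1) / sqrt(n_hidden), n_hidden, 2L)
  G <- matrix(0.01, 2L, n_hidden)
  X <- cbind(trials$x_m, trials$x_c)
  res <- cpp_train_hidden(X, ycls, W1, G, W2, alpha, lambda, sigma_eta, sxi)
  tr <- cbind(trials, correct = res$correct, loss = res$loss,
              wnorm_m = res$wnorm[, 1], wnorm_c = res$wnorm[, 2],
              gnorm_m = res$gnorm[, 1], gnorm_c = res$gnorm[, 2])
  structure(tr, class = c("hidden_trace", "data.frame"),
            final = list(W1 = res$W1, G = res$G, W2 = res$W2))
}

#' Run a matched hidden-layer cohort with its control cohort
#'
#' Same design as [run_cohort()] but training the hidden-layer variant. The
#' per-network input models come from the scalar-model matching; because the
#' softmax readout and the smaller learning rate change how input magnitude
#' translates into accuracy, a single cohort-wide gain on the motion means is
#' first calibrated on a pilot sample so that the hidden networks' mean
#' motion-phase accuracy matches the mean of the target profiles (baseline
#' performance equated across architectures). Classification against the
#' hidden-layer control cohort uses the identical switch-fit pipeline.
#'
#' @param n cohort size.
#' @param seed master seed.
#' @param matching optional precomputed [match_cohort()] result.
#' @param alpha,lambda,sigma_eta,sigma_xi hidden-network hyperparameters.
#' @param spec curriculum specification.
#' @param bin_size bins for the classification pipeline.
#' @param keep_traces retain per-trial traces.
#' @return an `insight_cohort`.
#' @export
run_hidden_cohort <- function(n = 99L, seed = 1L, matching = NULL,
                              alpha = 0.1, lambda = 0.002,
                              sigma_eta = 0.05, sigma_xi = 0.05,
                              xi_scale = c("gradient", "update"),
                              spec = curriculum_spec(), bin_size = 50,
                              keep_traces = FALSE) {
  xi_scale <- match.arg(xi_scale)
  if (is.null(matching)) matching <- match_cohort(n, seed, spec = spec)

  scale_model <- function(model, gain) {
    m <- model
    m$M_m <- pmin(model$M_m * gain, 1)
    m
  }
  # pilot calibration of a cohort-wide input gain: mean motion-phase accuracy
  # of a few hidden networks should match the mean target profile
  target <- mean(matching$profiles[seq_len(min(n, 8L)), ])
  pilot_acc <- function(gain) {
    acc <- numeric(min(n, 8L))
    for (i in seq_along(acc)) {
      set.seed(child_seed(seed, 6000L + i))
      cur <- sample_inputs(build_curriculum(spec),
                           scale_model(matching$models[[i]], gain),
                           colour_predictive = FALSE)
      tr <- train_hidden_network(cur, alpha, lambda, sigma_eta, sigma_xi,
                                 xi_scale)
      acc[i] <- mean(tr$correct[tr$phase == "motion"])
    }
    mean(acc)
  }
  gains <- 2^seq(-1, 4)                 # accuracy is monotone in the gain
  accs <- vapply(gains, pilot_acc, numeric(1))
  if (all(accs < target)) gain <- max(gains)
  else if (all(accs > target)) gain <- min(gains)
  else {
    hi <- which(accs >= target)[1]
    gain <- stats::uniroot(function(g) pilot_acc(g) - target,
                           c(gains[hi - 1L], gains[hi]), tol = 0.05)$root
  }

  traces <- vector("list", n)
  ctrl_traces <- vector("list", n)
  for (i in seq_len(n)) {
    mod <- scale_model(matching$models[[i]], gain)
    set.seed(child_seed(seed, 4000L + i))
    cur <- sample_inputs(build_curriculum(spec), mod, colour_predictive = TRUE)
    traces[[i]] <- train_hidden_network(cur, alpha, lambda, sigma_eta, sigma_xi,
                                        xi_scale)
    set.seed(child_seed(seed, 5000L + i))
    cur <- sample_inputs(build_curriculum(spec), mod, colour_predictive = FALSE)
    ctrl_traces[[i]] <- train_hidden_network(cur, alpha, lambda, sigma_eta,
                                             sigma_xi, xi_scale)
  }
  hyper <- list(alpha = alpha, lambda = lambda, sigma_eta = sigma_eta,
                sigma_xi = sigma_xi, xi_scale = xi_scale,
                regulariser = "l1", architecture = "hidden", input_gain = gain)
  finish_cohort(traces, ctrl_traces, matching, hyper, seed, bin_size,
                keep_traces, spec)
}
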