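#' Hyperparameters of the gated linear network
#'
#' @param alpha learning rate (default 0.6).
#' @param lambda regularisation strength on the gates (default 0.07; the
#'   hidden-layer variant uses 0.002).
#' @param sigma_eta output noise SD (default 0.05).
#' @param sigma_xi gradient-noise SD, either a single value for all four
#'   parameters or a named vector over `c("w_m", "w_c", "g_m", "g_c")`
#'   (default 0.05 each); component-wise values support noise sweeps.
#' @param xi_scale where the gradient noise enters the update: `"gradient"`
#'   (default) adds `xi` to the loss gradient, so the parameter receives
#'   `alpha * xi` — the convention whose trained-network statistics
#'   (parameter magnitudes, cohort accuracy) match the reference behaviour
#'   this model family was built to reproduce; `"update"` adds `xi` to the
#'   parameter directly, unscaled.
#' @param regulariser `"l1"`, `"l2"` or `"none"`.
#' @param l1_update how the L1 penalty is applied: `"proximal"` (default)
#'   soft-thresholds the gate after the data and noise terms, so the penalty
#'   alone can never carry a gate through zero — for `|g| > alpha * lambda`
#'   this coincides with the explicit subgradient step; `"subgradient"` adds
#'   `-alpha * lambda * sign(g)` explicitly, which makes gates smaller than
#'   `alpha * lambda` oscillate around zero instead of staying suppressed.
#' @param gated logical; `FALSE` selects the simplified gateless model
#'   (weights only, no penalty).
#' @return an object of class `net_hyper`.
#' @export
net_hyper <- function(alpha = 0.6, lambda = 0.07, sigma_eta = 0.05,
                      sigma_xi = 0.05, xi_scale = c("gradient", "update"),
                      regulariser = c("l1", "l2", "none"),
                      l1_update = c("proximal", "subgradient"), gated = TRUE) {
  regulariser <- match.arg(regulariser)
  xi_scale <- match.arg(xi_scale)
  l1_update <- match.arg(l1_update)
  if (alpha <= 0) stop("alpha must be > 0", call. = FALSE)
  if (lambda < 0) stop("lambda must be >= 0", call. = FALSE)
  if (sigma_eta < 0 || any(sigma_xi < 0)) stop("noise SDs must be >= 0", call. = FALSE)
  pars <- c("w_m", "w_c", "g_m", "g_c")
  if (length(sigma_xi) == 1L) {
    sigma_xi <- stats::setNames(rep(sigma_xi, 4L), pars)
  } else {
    if (!all(pars %in% names(sigma_xi)))
      stop("sigma_xi must be scalar or named over w_m, w_c, g_m, g_c", call. = FALSE)
    sigma_xi <- sigma_xi[pars]
  }
  structure(list(alpha = alpha, lambda = lambda, sigma_eta = sigma_eta,
                 sigma_xi = sigma_xi, xi_scale = xi_scale,
                 regulariser = regulariser, l1_update = l1_update,
                 gated = gated),
            class = "net_hyper")
}

# per-trial SD of the noise actually added to each parameter
xi_sd <- function(hyper) {
  s <- hyper$sigma_xi
  if (identical(hyper$xi_scale, "update")) s else hyper$alpha * s
}

#' Initial network state
#'
#' Weights and their multiplicative gates all start at 0.01.
#'
#' @param w_m,w_c,g_m,g_c initial parameter values.
#' @return a named numeric vector of class `net_state`.
#' @export
net_state <- function(w_m = 0.01, w_c = 0.01, g_m = 0.01, g_c = 0.01) {
  x <- c(w_m = w_m, w_c = w_c, g_m = g_m, g_c = g_c)
  if (!all(is.finite(x))) stop("state must be finite", call. = FALSE)
  structure(x, class = "net_state")
}

reg_code <- function(regulariser) {
  match(regulariser, c("l1", "l2", "none")) - 1L
}

#' Forward pass of the gated linear network
#'
#' Continuous output `z = g_m w_m x_m + g_c w_c x_c + eta` and the decision
#' `sign(z)`, with `sign(0)` defined as +1. For the gateless model the gates
#' are absent and `z = w_m x_m + w_c x_c + eta`.
#'
#' @param state a [net_state()].
#' @param x_m,x_c inputs.
#' @param eta output noise realisation (default 0).
#' @param gated logical.
#' @return list with `z` and `y_hat`.
#' @export
forward <- function(state, x_m, x_c, eta = 0, gated = TRUE) {
  em <- if (gated) state[["g_m"]] * state[["w_m"]] else state[["w_m"]]
  ec <- if (gated) state[["g_c"]] * state[["w_c"]] else state[["w_c"]]
  z <- em * x_m + ec * x_c + eta
  list(z = z, y_hat = ifelse(z >= 0, 1, -1))
}

#' One noisy SGD update (reference implementation)
#'
#' All four parameters are updated synchronously from the pre-update state;
#' the regularisation term applies to the gates only, with the L1 subgradient
#' convention `sign(0) = 0`. The same `eta` used in the forward pass enters
#' the residual. This scalar version is the reference against which the
#' compiled training loop is checked.
#'
#' @param state a [net_state()].
#' @param x_m,x_c,y trial inputs and label.
#' @param hyper a [net_hyper()].
#' @param xi named gradient-noise draws over `c("w_m","w_c","g_m","g_c")`
#'   (default all zero).
#' @param eta output-noise draw (default 0).
#' @return list with the updated `state` and the raw loss `gradients`
#'   (pre-noise, including the penalty term).
#' @export
sgd_step <- function(state, x_m, x_c, y, hyper,
                     xi = c(w_m = 0, w_c = 0, g_m = 0, g_c = 0), eta = 0) {
  w_m <- state[["w_m"]]; w_c <- state[["w_c"]]
  g_m <- state[["g_m"]]; g_c <- state[["g_c"]]
  sgn0 <- function(v) sign(v) * (v != 0)
  soft <- function(v, th) sign(v) * pmax(abs(v) - th, 0)
  if (hyper$gated) {
    r <- g_m * w_m * x_m + g_c * w_c * x_c + eta - y
    d_dat <- c(g_m = x_m * w_m * r, g_c = x_c * w_c * r)
    d <- c(w_m = x_m * g_m * r, w_c = x_c * g_c * r, d_dat)
    if (hyper$regulariser == "l1") {
      d[["g_m"]] <- d[["g_m"]] + hyper$lambda * sgn0(g_m)
      d[["g_c"]] <- d[["g_c"]] + hyper$lambda * sgn0(g_c)
    } else if (hyper$regulariser == "l2") {
      d[["g_m"]] <- d[["g_m"]] + hyper$lambda * g_m
      d[["g_c"]] <- d[["g_c"]] + hyper$lambda * g_c
    }
    new <- unclass(state) + c(-hyper$alpha * d[c("w_m", "w_c")] + xi[c("w_m", "w_c")],
                              -hyper$alpha * d[c("g_m", "g_c")] + xi[c("g_m", "g_c")])
    if (hyper$regulariser == "l1" && identical(hyper$l1_update, "proximal")) {
      new[c("g_m", "g_c")] <- soft(
        unclass(state)[c("g_m", "g_c")] - hyper$alpha * d_dat +
          xi[c("g_m", "g_c")],
        hyper$alpha * hyper$lambda)
    }
  } else {
    r <- w_m * x_m + w_c * x_c + eta - y
    d <- c(w_m = x_m * r, w_c = x_c * r, g_m = 0, g_c = 0)
    new <- unclass(state)
    new[c("w_m", "w_c")] <- new[c("w_m", "w_c")] -
      hyper$alpha * d[c("w_m", "w_c")] + xi[c("w_m", "w_c")]
  }
  if (!all(is.finite(new))) stop("non-finite parameter update (overflow)", call. = FALSE)
  list(state = structure(new, class = "net_state"), gradients = d)
}

#' Train a network on a trial sequence
#'
#' One online pass, one update per trial in curriculum order. The returned
#' trace records, per trial, the pre-update state, the raw loss gradients
#' (pre-noise), the injected noise draws, the continuous output, the decision
#' and its correctness — everything needed to replay the run bit-identically
#' via the `noise` argument.
#'
#' @param trials a data frame from [sample_inputs()] (columns `x_m`, `x_c`,
#'   `y` plus metadata).
#' @param hyper a [net_hyper()].
#' @param init a [net_state()].
#' @param noise optional list with vector `eta` (length n) and matrix `xi`
#'   (n x 4) to replay stored draws; if `NULL` they are drawn from the current
#'   RNG state with the SDs in `hyper`.
#' @param intervene optional list `list(trial =, abs_w_m =, abs_w_c =)`
#'   applying a sign-preserving reset of the absolute weights immediately
#'   before the given (1-based) trial; gates are untouched.
#' @return a data frame of class `net_trace`; attributes `final_state`,
#'   `hyper`, `init`.
#' @export
train_network <- function(trials, hyper = net_hyper(), init = net_state(),
                          noise = NULL, intervene = NULL) {
  n <- nrow(trials)
  if (is.null(noise)) {
    sxi <- xi_sd(hyper)
    eta <- rnorm(n, 0, hyper$sigma_eta)
    xi <- cbind(rnorm(n, 0, sxi[["w_m"]]),
                rnorm(n, 0, sxi[["w_c"]]),
                rnorm(n, 0, sxi[["g_m"]]),
                rnorm(n, 0, sxi[["g_c"]]))
  } else {
    eta <- noise$eta
    xi <- noise$xi
    stopifnot(length(eta) == n, nrow(xi) == n, ncol(xi) == 4L)
  }
  it <- if (is.null(intervene)) -1L else as.integer(intervene$trial) - 1L
  res <- cpp_train_scalar(trials$x_m, trials$x_c, trials$y, eta, xi,
                          hyper$alpha, hyper$lambda,
                          reg_code(hyper$regulariser), hyper$gated,
                          unclass(init), it,
                          if (is.null(intervene)) NA_real_ else intervene$abs_w_m,
                          if (is.null(intervene)) NA_real_ else intervene$abs_w_c,
                          identical(hyper$l1_update, "proximal"))
  tr <- cbind(trials,
              stats::setNames(as.data.frame(res$states), c("w_m", "w_c", "g_m", "g_c")),
              stats::setNames(as.data.frame(res$grads),
                              c("grad_w_m", "grad_w_c", "grad_g_m", "grad_g_c")),
              stats::setNames(as.data.frame(xi), c("xi_w_m", "xi_w_c", "xi_g_m", "xi_g_c")),
              eta = eta, z = res$z, y_hat = res$yhat, correct = res$correct)
  structure(tr, class = c("net_trace", "data.frame"),
            final_state = stats::setNames(res$final, c("w_m", "w_c", "g_m", "g_c")),
            hyper = hyper, init = unclass(init))
}

#' Replay a stored trace
#'
#' Re-applies the stored noise draws to the stored initial state and returns a
#' new trace, which must equal the original bit for bit.
#'
#' @param trace a `net_trace`.
#' @return a `net_trace`.
#' @export
replay_trace <- function(trace) {
  hyper <- attr(trace, "hyper")
  init <- structure(attr(trace, "init"), class = "net_state")
  meta <- trace[, c("trial", "block", "phase", "coherence", "y", "x_m", "x_c")]
  noise <- list(eta = trace$eta,
                xi = as.matrix(trace[, c("xi_w_m", "xi_w_c", "xi_g_m", "xi_g_c")]))
  train_network(meta, hyper, init, noise = noise)
}
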