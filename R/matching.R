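#' Synthetic per-subject target accuracy profiles
#'
#' Stand-in for the per-human motion-phase accuracies that each network is
#' matched to. Per-coherence targets are drawn around group anchors — 0.60 and
#' 0.63 for the two hardest conditions and 0.91 for the easiest, with the
#' middle two interpolated at 0.78 and 0.85 — with a between-subject SD,
#' truncated to (0.52, 0.98) and monotonised by sorting.
#'
#' @param n number of profiles.
#' @param anchors per-coherence group-mean accuracies (5-45% coherence).
#' @param sd between-subject SD (default 0.04).
#' @return an `n` x 5 matrix, rows non-decreasing.
#' @export
synth_target_profiles <- function(n, anchors = c(0.60, 0.63, 0.78, 0.85, 0.91),
                                  sd = 0.04) {
  stopifnot(n >= 1, length(anchors) == 5L)
  p <- matrix(rnorm(n * 5L, rep(anchors, each = n), sd), n, 5L)
  p <- pmin(pmax(p, 0.52), 0.98)
  t(apply(p, 1L, sort))
}

#' Fit motion-input mean shifts to a target accuracy profile
#'
#' Matches a simulated network to a subject: finds the five per-coherence
#' motion mean shifts such that the network's motion-phase accuracy equals the
#' targets. The objective is the squared deviation between targets and the
#' simulated per-coherence motion-phase accuracy, where simulated accuracy is
#' the trajectory average of the closed-form accuracy over `R` seeded training
#' replicates run under `hyper` (common random numbers across evaluations make
#' the objective deterministic). Minimised by derivative-free Nelder-Mead over
#' an absolute-value reparametrisation, so fitted means are non-negative; they
#' are monotonised by sorting afterwards.
#'
#' @param targets five per-coherence target accuracies in `[0.5, 1)`.
#' @param hyper a [net_hyper()].
#' @param spec a [curriculum_spec()].
#' @param M_c,sigma_m,sigma_c fixed input-model constants.
#' @param nonpredictive colour encoding while uncorrelated (see
#'   [input_model()]); the fitted model inherits it.
#' @param R number of training replicates averaged per evaluation (default 3).
#' @param seed integer seed for the replicate noise streams.
#' @param maxit Nelder-Mead evaluation budget.
#' @return an [input_model()] with fitted `M_m`; attribute `converged`.
#' @export
fit_motion_means <- function(targets, hyper = net_hyper(),
                             spec = curriculum_spec(),
                             M_c = 0.22, sigma_m = 0.1, sigma_c = 0.01,
                             nonpredictive = c("zero", "coin"),
                             R = 3L, seed = 1L, maxit = 400L) {
  nonpredictive <- match.arg(nonpredictive)
  stopifnot(length(targets) == 5L, all(targets >= 0.5), all(targets < 1))
  lev <- c(5, 10, 20, 30, 45)

  # frozen replicate draws (curriculum, input noise, eta, xi)
  reps <- vector("list", R)
  for (r in seq_len(R)) {
    set.seed(child_seed(seed, r - 1L))
    cur <- build_curriculum(spec)
    cur <- cur[cur$phase != "colour", ]  # matching concerns pre-onset accuracy only
    n <- nrow(cur)
    csign <- if (nonpredictive == "coin") sample(c(-1, 1), n, replace = TRUE) else 0
    reps[[r]] <- list(
      zm = rnorm(n), xc = rnorm(n, csign * M_c, sigma_c),
      y = cur$y, coh = match(cur$coherence, lev) - 1L,
      in_motion = cur$phase == "motion",
      eta = rnorm(n, 0, hyper$sigma_eta),
      xi = {
        sxi <- xi_sd(hyper)
        cbind(rnorm(n, 0, sxi[["w_m"]]), rnorm(n, 0, sxi[["w_c"]]),
              rnorm(n, 0, sxi[["g_m"]]), rnorm(n, 0, sxi[["g_c"]]))
      })
  }
  rc <- reg_code(hyper$regulariser)
  init <- unclass(net_state())
  Mc_var <- if (nonpredictive == "coin") M_c else 0  # Eq-11 colour variance term
  sim_acc <- function(M) {
    acc <- rep(0, 5L)
    for (r in seq_len(R)) {
      d <- reps[[r]]
      acc <- acc + cpp_match_accuracy(d$zm, d$xc, d$y, d$coh, d$in_motion,
                                      d$eta, d$xi, M, sigma_m, Mc_var, sigma_c,
                                      hyper$sigma_eta, hyper$alpha, hyper$lambda,
                                      rc, init,
                                      identical(hyper$l1_update, "proximal"))
    }
    acc / R
  }
  obj <- function(par) {
    a <- sim_acc(pmin(abs(par), 0.4))
    if (anyNA(a) || any(!is.finite(a))) return(10)
    sum((a - targets)^2)
  }

  # probit fixed point first: accuracy is ~ Phi(k_i M_i) per level, so
  # multiplicative updates M_i <- M_i qnorm(target_i)/qnorm(acc_i) converge in
  # a few sweeps despite the coupling through the learned trajectory; a
  # diverged replicate (non-finite accuracy: means too large) halves the means
  M <- c(0.05, 0.08, 0.18, 0.28, 0.42)
  for (it in 1:12) {
    acc <- sim_acc(M)
    bad <- !is.finite(acc)
    ratio <- ifelse(bad, 0.5,
                    ifelse(acc > 0.5, stats::qnorm(targets) / stats::qnorm(acc), 2))
    M <- pmin(M * pmin(pmax(ratio, 0.5), 2), 0.4)
    if (!any(bad) && max(abs(acc - targets)) < 0.005) break
  }
  fit <- optim(M, obj, method = "Nelder-Mead",
               control = list(maxit = maxit, reltol = 1e-10))
  M <- sort(pmin(abs(fit$par), 0.4))
  achieved <- sim_acc(M)
  ok <- all(abs(achieved - targets) <= 0.03)
  if (!ok) warning("accuracy matching outside +/-0.03 for at least one level")
  structure(input_model(M_m = M, M_c = M_c, sigma_m = sigma_m,
                        sigma_c = sigma_c, nonpredictive = nonpredictive),
            achieved = achieved, targets = targets, converged = ok)
}
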