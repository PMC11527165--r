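#' Curriculum specification for the two-feature decision task
#'
#' The task has three phases: a *training* phase containing only the three
#' highest motion-coherence levels, a *motion* phase in which all five levels
#' appear but colour is uncorrelated with the correct choice, and a
#' *motion-and-colour* phase in which colour becomes fully predictive. Blocks
#' have a fixed length and per-block per-coherence trial counts are exact, not
#' sampled. Defaults give the 13-block, 1300-trial curriculum used for the
#' network cohorts: 6 training + 2 motion + 5 colour blocks of 100 trials.
#'
#' @param n_training_blocks,n_motion_blocks,n_colour_blocks block counts.
#' @param trials_per_block trials per block (default 100).
#' @param coherence_levels the five motion-coherence percentages.
#' @param coherence_counts named counts per `trials_per_block` trials for the
#'   motion/colour phases; the hardest (5%) condition is over-represented
#'   (30 per 100 versus 10, 20, 20, 20).
#' @param training_counts counts for the training phase over the three highest
#'   levels (100 is not divisible by 3; the lowest of the three gets the
#'   extra trial).
#' @return an object of class `curriculum_spec`.
#' @export
curriculum_spec <- function(n_training_blocks = 6L,
                            n_motion_blocks = 2L,
                            n_colour_blocks = 5L,
                            trials_per_block = 100L,
                            coherence_levels = c(5, 10, 20, 30, 45),
                            coherence_counts = c(`5` = 30, `10` = 10, `20` = 20,
                                                 `30` = 20, `45` = 20),
                            training_counts = c(`20` = 34, `30` = 33, `45` = 33)) {
  if (length(coherence_levels) != 5L)
    stop("exactly five coherence levels are required", call. = FALSE)
  if (sum(coherence_counts) != trials_per_block)
    stop("motion/colour-phase coherence counts must sum to trials_per_block",
         call. = FALSE)
  if (sum(training_counts) != trials_per_block)
    stop("training-phase coherence counts must sum to trials_per_block",
         call. = FALSE)
  if (!all(as.numeric(names(training_counts)) %in%
           utils::tail(sort(coherence_levels), 3)))
    stop("training blocks may contain only the three highest coherence levels",
         call. = FALSE)
  structure(list(n_training_blocks = as.integer(n_training_blocks),
                 n_motion_blocks = as.integer(n_motion_blocks),
                 n_colour_blocks = as.integer(n_colour_blocks),
                 trials_per_block = as.integer(trials_per_block),
                 coherence_levels = coherence_levels,
                 coherence_counts = coherence_counts,
                 training_counts = training_counts),
            class = "curriculum_spec")
}

#' @export
print.curriculum_spec <- function(x, ...) {
  cat("Task curriculum:", x$n_training_blocks, "training /", x$n_motion_blocks,
      "motion /", x$n_colour_blocks, "colour blocks of", x$trials_per_block,
      "trials\n")
  invisible(x)
}

#' Input distribution model for the two scalar feature channels
#'
#' Each trial's inputs are Gaussian scalars. The motion input has mean
#' `y * M_m[coherence]` (direction-signed, coherence-dependent) and SD
#' `sigma_m`; the colour input has mean `c * M_c` with SD `sigma_c`, where `c`
#' equals the label `y` when colour is predictive and an independent fair coin
#' otherwise (the two visible colours keep appearing, just uncorrelated with
#' the correct response).
#'
#' @param M_m numeric vector of five non-negative motion mean shifts, one per
#'   coherence level (typically fitted; see [fit_motion_means()]).
#' @param M_c colour mean shift (default 0.22, fixed across a cohort).
#' @param sigma_m,sigma_c input SDs (defaults 0.1 and 0.01).
#' @param nonpredictive how the colour input is encoded while it is
#'   uncorrelated with the correct response: `"zero"` (default) gives a
#'   zero-mean input of SD `sigma_c` — the channel carries no signal, so the
#'   suppressed colour gate sees essentially no data gradient before onset —
#'   while `"coin"` keeps the full-contrast `+/-M_c` input with an independent
#'   random sign per trial.
#' @return an object of class `input_model`.
#' @export
input_model <- function(M_m, M_c = 0.22, sigma_m = 0.1, sigma_c = 0.01,
                        nonpredictive = c("zero", "coin")) {
  nonpredictive <- match.arg(nonpredictive)
  if (length(M_m) != 5L) stop("M_m must have five entries", call. = FALSE)
  if (any(M_m < 0)) stop("motion mean shifts must be non-negative", call. = FALSE)
  if (sigma_m <= 0 || sigma_c <= 0) stop("input SDs must be > 0", call. = FALSE)
  structure(list(M_m = as.numeric(M_m), M_c = M_c,
                 sigma_m = sigma_m, sigma_c = sigma_c,
                 nonpredictive = nonpredictive),
            class = "input_model")
}

#' Build the trial-by-trial curriculum
#'
#' Lays out phases, blocks, coherence conditions and correct labels. Coherence
#' counts per block are exact; labels are exactly balanced (50/50) within each
#' block and shuffled. Deterministic given the RNG state (`set.seed()` before
#' calling).
#'
#' @param spec a [curriculum_spec()].
#' @return a data frame with columns `trial` (1-based), `block`, `phase`
#'   (`"training"`, `"motion"`, `"colour"`), `coherence` (percent) and `y`
#'   (latent label, -1/+1).
#' @export
build_curriculum <- function(spec = curriculum_spec()) {
  stopifnot(inherits(spec, "curriculum_spec"))
  n_blocks <- spec$n_training_blocks + spec$n_motion_blocks + spec$n_colour_blocks
  tpb <- spec$trials_per_block
  if (tpb %% 2L != 0L)
    stop("trials_per_block must be even for exact label balance", call. = FALSE)
  phase_of <- function(b) {
    if (b <= spec$n_training_blocks) "training"
    else if (b <= spec$n_training_blocks + spec$n_motion_blocks) "motion"
    else "colour"
  }
  out <- vector("list", n_blocks)
  for (b in seq_len(n_blocks)) {
    ph <- phase_of(b)
    counts <- if (ph == "training") spec$training_counts else spec$coherence_counts
    coh <- rep(as.numeric(names(counts)), counts)
    coh <- sample(coh)
    y <- sample(rep(c(-1, 1), tpb / 2L))
    out[[b]] <- data.frame(block = b, phase = ph, coherence = coh, y = y)
  }
  res <- do.call(rbind, out)
  res <- cbind(trial = seq_len(nrow(res)), res)
  rownames(res) <- NULL
  res
}

#' Sample scalar inputs for a curriculum
#'
#' Draws the motion and colour inputs for every trial. Colour carries label
#' information only in the colour phase (and only if `colour_predictive` is
#' `TRUE`, which is how control cohorts are constructed); elsewhere its mean's
#' sign is an independent fair coin per trial.
#'
#' @param curriculum a data frame from [build_curriculum()].
#' @param model an [input_model()].
#' @param colour_predictive logical; if `FALSE` colour never becomes
#'   predictive, even in the colour phase.
#' @return the curriculum with added columns `x_m` and `x_c`.
#' @export
sample_inputs <- function(curriculum, model, colour_predictive = TRUE) {
  stopifnot(inherits(model, "input_model"))
  idx <- match(curriculum$coherence, c(5, 10, 20, 30, 45))
  if (anyNA(idx)) stop("unknown coherence level in curriculum", call. = FALSE)
  n <- nrow(curriculum)
  mu_m <- curriculum$y * model$M_m[idx]
  pred <- curriculum$phase == "colour" & colour_predictive
  csign <- ifelse(pred, curriculum$y,
                  if (identical(model$nonpredictive, "coin"))
                    sample(c(-1, 1), n, replace = TRUE) else 0)
  curriculum$x_m <- rnorm(n, mu_m, model$sigma_m)
  curriculum$x_c <- rnorm(n, csign * model$M_c, model$sigma_c)
  curriculum
}

#' Closed-form accuracy of the gated linear readout
#'
#' Probability that the sign of `g_m w_m x_m + g_c w_c x_c + eta` matches the
#' label, given Gaussian inputs with means `+/-M_m` and `+/-M_c`. With the
#' colour sign equal to the label (`colour_corr = 1`) this is
#' \deqn{P = \Phi\!\left(\frac{g_m w_m M_m + g_c w_c M_c}
#'   {\sqrt{(g_m w_m \sigma_m)^2 + (g_c w_c \sigma_c)^2 +
#'    \sigma_\eta^2}}\right).}
#' When the colour sign is an independent coin (`colour_corr = 0`) the colour
#' channel carries no signal, only disturbance: the output is a two-component
#' Gaussian mixture and the accuracy averages the two signed colour means,
#' \deqn{P = \tfrac12\,\Phi\!\left(\frac{\mu + g_c w_c M_c}{s}\right)
#'     + \tfrac12\,\Phi\!\left(\frac{\mu - g_c w_c M_c}{s}\right),}
#' with \eqn{\mu = g_m w_m M_m} and the same denominator \eqn{s}. A colour
#' input with no mean at all (the `"zero"` non-predictive encoding) is the
#' special case `M_c = 0`.
#'
#' @param w_m,w_c,g_m,g_c network parameters.
#' @param M_m motion mean shift for the condition of interest.
#' @param M_c colour mean shift.
#' @param sigma_m,sigma_c,sigma_eta input and output noise SDs.
#' @param colour_corr 1 if the colour sign equals the label, 0 if independent.
#' @return probability correct in `[0, 1]`; exactly 0.5 when both effective
#'   weights are zero and there is no signal.
#' @export
closed_form_accuracy <- function(w_m, g_m, w_c, g_c, M_m, M_c,
                                 sigma_m, sigma_c, sigma_eta,
                                 colour_corr = 1) {
  em <- g_m * w_m
  ec <- g_c * w_c
  v <- (em * sigma_m)^2 + (ec * sigma_c)^2 + sigma_eta^2
  mu <- em * M_m
  lim <- function(num) ifelse(num == 0, 0.5, ifelse(num > 0, 1, 0))
  ifelse(colour_corr == 1,
         ifelse(v > 0, pnorm((mu + ec * M_c) / sqrt(v)), lim(mu + ec * M_c)),
         ifelse(v > 0,
                0.5 * pnorm((mu + ec * M_c) / sqrt(v)) +
                  0.5 * pnorm((mu - ec * M_c) / sqrt(v)),
                0.5 * lim(mu + ec * M_c) + 0.5 * lim(mu - ec * M_c)))
}
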