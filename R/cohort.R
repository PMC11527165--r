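#' Fit switch models across a cohort
#'
#' Runs [bin_accuracy()], [fit_switch_models()] and [corrected_steepness()]
#' for every trial table in a list and assembles the per-subject fit table.
#'
#' @param traces list of trial tables (`net_trace` or behaviour tables).
#' @param bin_size task trials per bin.
#' @param penalty steepness correction passed to [corrected_steepness()]
#'   (the cohort pipeline defaults to `"r2"`: the dimensionless misfit share
#'   penalises noise-interpolating fits in proportion to how much of the
#'   series they fail to explain).
#' @param m_max sigmoid slope bound passed to [fit_switch_models()].
#' @return list with `table` (one row per subject: sigmoid parameters, SSE,
#'   per-model BIC, steepness, corrected steepness) and `series` (the binned
#'   accuracy series); the table carries attributes `onset` and `bin_size`.
#' @export
fit_cohort <- function(traces, bin_size = 50, penalty = "r2", m_max = 10) {
  series <- lapply(traces, bin_accuracy, bin_size = bin_size)
  rows <- vector("list", length(traces))
  for (i in seq_along(traces)) {
    f <- fit_switch_models(series[[i]], m_max = m_max)
    sg <- f$sigmoid
    rows[[i]] <- data.frame(
      subject = i,
      m = unname(sg$params["m"]), t_s = unname(sg$params["t_s"]),
      y_max = unname(sg$params["y_max"]), y_min = unname(sg$params["y_min"]),
      sse = sg$sse, bic_linear = f$linear$bic, bic_step = f$step$bic,
      bic_sigmoid = sg$bic, steepness = steepness(sg),
      corrected_steepness = corrected_steepness(sg, series[[i]], penalty = penalty))
  }
  tab <- do.call(rbind, rows)
  attr(tab, "onset") <- attr(series[[1]], "onset")
  attr(tab, "bin_size") <- bin_size
  list(table = tab, series = series)
}

#' Match a cohort of networks to synthetic subjects
#'
#' Draws `n` target accuracy profiles and fits each network's motion-input
#' means to its profile under the given hyperparameters. Fitted input models
#' are a property of the matched pair and are reused by the control cohort,
#' sweeps and intervention runs.
#'
#' @param n cohort size.
#' @param seed master seed.
#' @param hyper hyperparameters used during matching.
#' @param spec curriculum specification.
#' @param match_R training replicates per objective evaluation.
#' @return list with `profiles` (n x 5) and `models` (list of [input_model()]).
#' @export
match_cohort <- function(n = 99L, seed = 1L, hyper = net_hyper(),
                         spec = curriculum_spec(), match_R = 3L) {
  set.seed(child_seed(seed, 0L))
  profiles <- synth_target_profiles(n)
  models <- vector("list", n)
  for (i in seq_len(n)) {
    models[[i]] <- suppressWarnings(
      fit_motion_means(profiles[i, ], hyper = hyper, spec = spec,
                       R = match_R, seed = child_seed(seed, 1000L + i)))
  }
  list(profiles = profiles, models = models)
}

train_one <- function(i, seed, offset, spec, model, hyper, colour_predictive,
                      intervene = NULL) {
  set.seed(child_seed(seed, offset + i))
  cur <- build_curriculum(spec)
  cur <- sample_inputs(cur, model, colour_predictive = colour_predictive)
  train_network(cur, hyper, intervene = intervene)
}

#' Run a matched experimental cohort with its control cohort
#'
#' Trains `n` networks on the full curriculum (colour predictive after onset)
#' and `n` control networks (colour never predictive) with the same fitted
#' input models, fits the switch models on lowest-coherence binned accuracy,
#' classifies the experimental networks against the control maximum, and
#' summarises accuracy by phase and group.
#'
#' @param n cohort size (default 99, one per human subject).
#' @param hyper a [net_hyper()].
#' @param seed master seed; every downstream stream is derived from it.
#' @param matching optional precomputed [match_cohort()] result to reuse.
#' @param spec a [curriculum_spec()].
#' @param bin_size bins for the classification pipeline.
#' @param keep_traces retain full per-trial traces (needed for
#'   [dynamics_analysis()] and [weight_intervention()]).
#' @param intervene optional intervention passed to every experimental
#'   network (see [train_network()]).
#' @return object of class `insight_cohort`.
#' @export
run_cohort <- function(n = 99L, hyper = net_hyper(), seed = 1L,
                       matching = NULL, spec = curriculum_spec(),
                       bin_size = 50, keep_traces = TRUE, intervene = NULL) {
  if (is.null(matching)) matching <- match_cohort(n, seed, spec = spec)
  stopifnot(length(matching$models) >= n)

  traces <- vector("list", n)
  ctrl_traces <- vector("list", n)
  for (i in seq_len(n)) {
    traces[[i]] <- train_one(i, seed, 2000L, spec, matching$models[[i]], hyper,
                             colour_predictive = TRUE, intervene = intervene)
    ctrl_traces[[i]] <- train_one(i, seed, 3000L, spec, matching$models[[i]],
                                  hyper, colour_predictive = FALSE)
  }
  finish_cohort(traces, ctrl_traces, matching, hyper, seed, bin_size,
                keep_traces, spec)
}

finish_cohort <- function(traces, ctrl_traces, matching, hyper, seed, bin_size,
                          keep_traces, spec = curriculum_spec()) {
  n <- length(traces)
  fits <- fit_cohort(traces, bin_size = bin_size)
  ctrl_fits <- fit_cohort(ctrl_traces, bin_size = bin_size)
  calls <- classify_cohort(fits$table, ctrl_fits$table)

  acc_phase <- function(tr, ph, coh = NULL) {
    sel <- tr$phase == ph
    if (!is.null(coh)) sel <- sel & tr$coherence == coh
    mean(tr$correct[sel])
  }
  low <- min(traces[[1]]$coherence)
  train_acc <- vapply(traces, acc_phase, numeric(1), ph = "training")
  colour_low <- vapply(traces, acc_phase, numeric(1), ph = "colour", coh = low)
  motion_acc <- t(vapply(traces, function(tr) {
    vapply(sort(unique(tr$coherence)), function(cl)
      acc_phase(tr, "motion", cl), numeric(1))
  }, numeric(5)))
  colnames(motion_acc) <- sort(unique(traces[[1]]$coherence))

  ins <- calls$insight
  summary <- list(
    n = n,
    insight_fraction = mean(ins),
    n_insight = sum(ins),
    mean_delay_bins = if (any(ins)) mean(calls$delay_bins[ins]) else NA_real_,
    mean_delay_trials = if (any(ins)) mean(calls$delay_trials[ins]) else NA_real_,
    training_accuracy = mean(train_acc),
    motion_accuracy = colMeans(motion_acc),
    colour_low_insight = if (any(ins)) mean(colour_low[ins]) else NA_real_,
    colour_low_noinsight = if (any(!ins)) mean(colour_low[!ins]) else NA_real_,
    bic_sum = c(linear = sum(fits$table$bic_linear),
                step = sum(fits$table$bic_step),
                sigmoid = sum(fits$table$bic_sigmoid)),
    threshold = attr(calls, "threshold"))

  structure(list(calls = calls, fits = fits, ctrl_fits = ctrl_fits,
                 summary = summary, matching = matching, hyper = hyper,
                 seed = seed, bin_size = bin_size, spec = spec,
                 traces = if (keep_traces) traces else NULL,
                 ctrl_traces = if (keep_traces) ctrl_traces else NULL,
                 train_acc = train_acc, colour_low = colour_low,
                 motion_acc = motion_acc),
            class = "insight_cohort")
}

#' @export
print.insight_cohort <- function(x, ...) {
  s <- x$summary
  cat(sprintf("matched cohort of %d networks (+%d controls)\n", s$n, s$n))
  cat(sprintf("  insight: %d/%d (%.1f%%), threshold %.4f\n",
              s$n_insight, s$n, 100 * s$insight_fraction, s$threshold))
  if (!is.na(s$mean_delay_bins))
    cat(sprintf("  mean delay: %.2f bins (%.0f trials)\n",
                s$mean_delay_bins, s$mean_delay_trials))
  cat(sprintf("  training-phase accuracy: %.1f%%\n", 100 * s$training_accuracy))
  cat(sprintf("  colour-phase lowest-coherence accuracy: %.1f%% (insight) vs %.1f%% (no-insight)\n",
              100 * s$colour_low_insight, 100 * s$colour_low_noinsight))
  invisible(x)
}

#' Weight-intervention experiment
#'
#' Measures whether early "silent" colour knowledge causes later insight-like
#' switches. From a baseline cohort, takes the mean absolute colour and motion
#' weights of its insight networks at the first colour-phase trial (the start
#' of learning about colour), then trains a fresh cohort in which every
#' network's absolute weights are set to those donor means — sign-preserving,
#' gates untouched — at that trial, and classifies as usual.
#'
#' @param base_cohort an [run_cohort()] result with traces retained and at
#'   least one insight network.
#' @param n size of the fresh cohort.
#' @param seed master seed for the fresh cohort's training streams (the
#'   matched subjects and their fitted input models are reused from the base
#'   cohort, as in a paired design).
#' @param donor optional named vector `c(abs_w_m=, abs_w_c=)` overriding the
#'   donor means (e.g. for no-op control interventions).
#' @return an `insight_cohort`; attribute `donor` records the means applied.
#' @export
weight_intervention <- function(base_cohort, n = 99L, seed = base_cohort$seed + 1L,
                                donor = NULL) {
  if (is.null(donor)) {
    ins <- which(base_cohort$calls$insight)
    if (!length(ins)) stop("no insight networks in base cohort", call. = FALSE)
    if (is.null(base_cohort$traces)) stop("base cohort has no traces", call. = FALSE)
    first_col <- match("colour", base_cohort$traces[[1]]$phase)
    donor <- c(abs_w_m = mean(vapply(base_cohort$traces[ins],
                                     function(tr) abs(tr$w_m[first_col]), numeric(1))),
               abs_w_c = mean(vapply(base_cohort$traces[ins],
                                     function(tr) abs(tr$w_c[first_col]), numeric(1))))
  } else {
    first_col <- match("colour", base_cohort$traces[[1]]$phase)
  }
  res <- run_cohort(n = n, hyper = base_cohort$hyper, seed = seed,
                    matching = if (n <= length(base_cohort$matching$models))
                      base_cohort$matching else NULL,
                    spec = base_cohort$spec, bin_size = base_cohort$bin_size,
                    intervene = list(trial = first_col,
                                     abs_w_m = donor[["abs_w_m"]],
                                     abs_w_c = donor[["abs_w_c"]]))
  attr(res, "donor") <- donor
  res
}
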