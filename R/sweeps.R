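sweep_sigma_xi <- function(component, sigma) {
  base <- c(w_m = 0, w_c = 0, g_m = 0, g_c = 0)
  sel <- switch(component,
                all = c("w_m", "w_c", "g_m", "g_c"),
                weights_only = c("w_m", "w_c"),
                gates_only = c("g_m", "g_c"),
                colour_params = c("w_c", "g_c"),
                motion_params = c("w_m", "g_m"),
                stop("unknown component", call. = FALSE))
  base[sel] <- sigma
  base
}

#' Gradient-noise sweep
#'
#' Varies the gradient-noise SD applied to one parameter group — all four
#' parameters jointly (`"all"`, the gates+weights panel), weights only, gates
#' only, or both colour / both motion parameters — with the non-swept
#' components receiving *no* gradient noise. For each grid point and
#' repetition a fresh experimental and control cohort is trained (the control
#' threshold is re-derived per grid point, since the steepness null depends on
#' the hyperparameters); the fitted input models from the baseline matching
#' are reused.
#'
#' @param component parameter group to sweep.
#' @param sigma_grid noise SDs to evaluate.
#' @param reps repetitions (fresh seeds) per grid point (default 10).
#' @param n cohort size.
#' @param seed master seed.
#' @param matching optional [match_cohort()] result to reuse.
#' @param hyper baseline hyperparameters (sigma_xi is overridden).
#' @return object of class `sweep_result`: data frame with one row per grid
#'   point x repetition (`sigma`, `rep`, `insight_fraction`, `mean_delay_bins`).
#' @export
run_noise_sweep <- function(component = c("all", "weights_only", "gates_only",
                                          "colour_params", "motion_params"),
                            sigma_grid, reps = 10L, n = 99L, seed = 1L,
                            matching = NULL, hyper = net_hyper()) {
  component <- match.arg(component)
  stopifnot(length(sigma_grid) >= 1)
  if (is.null(matching)) matching <- match_cohort(n, seed)
  rows <- list()
  for (gi in seq_along(sigma_grid)) {
    sg <- sigma_grid[gi]
    h <- net_hyper(alpha = hyper$alpha, lambda = hyper$lambda,
                   sigma_eta = hyper$sigma_eta,
                   sigma_xi = sweep_sigma_xi(component, sg),
                   xi_scale = hyper$xi_scale,
                   regulariser = hyper$regulariser, gated = hyper$gated)
    for (r in seq_len(reps)) {
      co <- run_cohort(n = n, hyper = h,
                       seed = child_seed(seed, 50000L + 1000L * gi + r),
                       matching = matching, keep_traces = FALSE)
      rows[[length(rows) + 1L]] <- data.frame(
        sigma = sg, rep = r,
        insight_fraction = co$summary$insight_fraction,
        mean_delay_bins = co$summary$mean_delay_bins)
    }
  }
  structure(do.call(rbind, rows), class = c("sweep_result", "data.frame"),
            component = component, what = "sigma_xi")
}

#' Regularisation-strength sweep
#'
#' Varies the L1 penalty on the gates and records the insight fraction and
#' the mean switch delay per grid point and repetition, together with
#' Spearman trend statistics: the fraction is expected to decline, and the
#' delay to grow, with increasing lambda.
#'
#' @param lambda_grid non-negative penalty values.
#' @param reps repetitions per grid point.
#' @param n cohort size.
#' @param seed master seed.
#' @param matching optional [match_cohort()] result to reuse.
#' @param min_insight minimum flagged networks for a point to enter the
#'   delay trend (default 5).
#' @return `sweep_result` data frame; attributes `trend_fraction` and
#'   `trend_delay` hold Spearman correlation tests.
#' @export
run_lambda_sweep <- function(lambda_grid, reps = 3L, n = 99L, seed = 1L,
                             matching = NULL, min_insight = 5L) {
  stopifnot(length(lambda_grid) >= 2, all(lambda_grid >= 0))
  if (is.null(matching)) matching <- match_cohort(n, seed)
  rows <- list()
  for (gi in seq_along(lambda_grid)) {
    h <- net_hyper(lambda = lambda_grid[gi])
    for (r in seq_len(reps)) {
      co <- run_cohort(n = n, hyper = h,
                       seed = child_seed(seed, 70000L + 1000L * gi + r),
                       matching = matching, keep_traces = FALSE)
      rows[[length(rows) + 1L]] <- data.frame(
        lambda = lambda_grid[gi], rep = r,
        insight_fraction = co$summary$insight_fraction,
        n_insight = co$summary$n_insight,
        mean_delay_bins = co$summary$mean_delay_bins)
    }
  }
  out <- do.call(rbind, rows)
  tf <- suppressWarnings(cor.test(out$lambda, out$insight_fraction,
                                  method = "spearman"))
  del <- out[!is.na(out$mean_delay_bins) & out$n_insight >= min_insight, ]
  td <- if (nrow(del) >= 4)
    suppressWarnings(cor.test(del$lambda, del$mean_delay_bins,
                              method = "spearman")) else NULL
  structure(out, class = c("sweep_result", "data.frame"), what = "lambda",
            trend_fraction = tf, trend_delay = td)
}
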