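#' Single change point of a series by two-segment Gaussian cost
#'
#' Finds the split minimising the summed Gaussian negative log-likelihood of
#' two segments with free mean *and* variance per segment,
#' `sum_s n_s log(sigma2_s)`. Candidate splits exclude a margin at each end
#' to avoid degenerate segments. If no split improves on the single-segment
#' cost (e.g. a constant series), no change point is returned.
#'
#' @param x numeric series.
#' @param exclude boundary points excluded from the candidate set at each end
#'   (default 10).
#' @return list with `index` (first point of the post-change segment, or `NA`
#'   if none admissible), `mean_pre`, `mean_post`, `mean_diff` and
#'   `improvement` (cost reduction relative to no split).
#' @export
change_point <- function(x, exclude = 10L) {
  n <- length(x)
  eps <- 1e-12
  seg_cost <- function(v) length(v) * log(mean((v - mean(v))^2) + eps)
  if (n < 2L * exclude + 2L)
    return(list(index = NA_integer_, mean_pre = NA_real_, mean_post = NA_real_,
                mean_diff = NA_real_, improvement = 0))
  full <- seg_cost(x)
  best <- NULL
  for (k in (exclude + 1L):(n - exclude)) {
    cost <- seg_cost(x[1:(k - 1L)]) + seg_cost(x[k:n])
    if (is.null(best) || cost < best$cost) best <- list(k = k, cost = cost)
  }
  imp <- full - best$cost
  if (imp <= 1e-9)
    return(list(index = NA_integer_, mean_pre = NA_real_, mean_post = NA_real_,
                mean_diff = NA_real_, improvement = 0))
  pre <- x[1:(best$k - 1L)]
  post <- x[best$k:n]
  list(index = best$k, mean_pre = mean(pre), mean_post = mean(post),
       mean_diff = mean(post) - mean(pre), improvement = imp)
}

#' Switch-locked gradient and parameter dynamics of a cohort
#'
#' Summarises what distinguishes insight from no-insight networks in the raw
#' learning signal: (a) absolute colour/motion gate-gradient magnitudes
#' around each network's fitted switch trial and around colour onset, as
#' group means with SEM; (b) absolute gate and weight magnitudes at the first
#' and last colour-phase trial and at the switch trial, by group; (c) a
#' change-point analysis of each network's absolute colour-gate gradient
#' series over the motion + colour window.
#'
#' @param cohort an [run_cohort()] result with traces retained.
#' @param window trials either side of the alignment point for the gradient
#'   curves (default 100).
#' @return list with `grad_at_switch`, `aligned_switch`, `aligned_onset`,
#'   `params_by_group` and `change_points`.
#' @export
dynamics_analysis <- function(cohort, window = 100L) {
  if (is.null(cohort$traces)) stop("cohort has no traces", call. = FALSE)
  traces <- cohort$traces
  calls <- cohort$calls
  ins <- calls$insight
  bin_size <- cohort$bin_size
  first_col <- match("colour", traces[[1]]$phase)
  win_start <- match("motion", traces[[1]]$phase)
  n_trials <- nrow(traces[[1]])

  switch_trial <- pmin(pmax(round(win_start - 1L + (calls$t_s - 0.5) * bin_size),
                            1L), n_trials)

  grab <- function(tr, centre, col) {
    idx <- (centre - window):(centre + window)
    ok <- idx >= 1L & idx <= n_trials
    out <- rep(NA_real_, 2L * window + 1L)
    out[ok] <- abs(tr[[col]][idx[ok]])
    out
  }
  aligned_group <- function(centres, col, group) {
    if (!any(group)) return(data.frame())
    mats <- mapply(function(tr, ce) grab(tr, ce, col),
                   traces[group], centres[group], SIMPLIFY = FALSE)
    m <- do.call(rbind, mats)
    data.frame(rel = -window:window,
               mean = colMeans(m, na.rm = TRUE),
               sem = apply(m, 2L, function(v) sd(v, na.rm = TRUE) /
                             sqrt(sum(!is.na(v)))))
  }

  at_switch <- function(col, group) {
    vapply(which(group), function(i) abs(traces[[i]][[col]][switch_trial[i]]),
           numeric(1))
  }
  grad_at_switch <- data.frame(
    group = c("insight", "no_insight"),
    colour_gate = c(mean(at_switch("grad_g_c", ins)),
                    mean(at_switch("grad_g_c", !ins))),
    motion_gate = c(mean(at_switch("grad_g_m", ins)),
                    mean(at_switch("grad_g_m", !ins))))

  param_stats <- function(trial_at) {
    vals <- function(col, group) {
      v <- vapply(which(group), function(i)
        abs(traces[[i]][[col]][if (length(trial_at) == 1L) trial_at
                               else trial_at[i]]), numeric(1))
      c(mean = mean(v), sd = sd(v))
    }
    do.call(rbind, lapply(c("g_c", "g_m", "w_c", "w_m"), function(col) {
      a <- vals(col, ins); b <- vals(col, !ins)
      data.frame(param = col, insight_mean = a["mean"], insight_sd = a["sd"],
                 noinsight_mean = b["mean"], noinsight_sd = b["sd"],
                 row.names = NULL)
    }))
  }
  params_by_group <- list(first_colour = param_stats(first_col),
                          at_switch = param_stats(switch_trial),
                          last_trial = param_stats(n_trials))

  cps <- lapply(traces, function(tr)
    change_point(abs(tr$grad_g_c[win_start:n_trials])))
  cp_tab <- data.frame(subject = seq_along(traces),
                       insight = ins,
                       index = win_start - 1L +
                         vapply(cps, function(z) as.integer(z$index), integer(1)),
                       mean_diff = vapply(cps, function(z) z$mean_diff, numeric(1)))

  list(grad_at_switch = grad_at_switch,
       aligned_switch = list(insight = aligned_group(switch_trial, "grad_g_c", ins),
                             no_insight = aligned_group(switch_trial, "grad_g_c", !ins)),
       aligned_onset = list(insight = aligned_group(rep(first_col, length(traces)),
                                                    "grad_g_c", ins),
                            no_insight = aligned_group(rep(first_col, length(traces)),
                                                       "grad_g_c", !ins)),
       params_by_group = params_by_group,
       change_points = cp_tab)
}
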