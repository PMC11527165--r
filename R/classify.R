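#' Classify insight-like switches against a control cohort
#'
#' The control cohort — identical pipeline, but colour never becomes
#' predictive — defines the null distribution of corrected steepness. The
#' threshold is its 100th percentile (the maximum), and a subject is flagged
#' as insight iff its corrected steepness is strictly greater. For flagged
#' subjects the delay is the fitted inflection point minus the colour-onset
#' boundary, in bins and in trials.
#'
#' @param experimental,control per-subject fit tables (see [fit_cohort()])
#'   with columns `corrected_steepness` and `t_s`; `experimental` must carry
#'   attributes `onset` and `bin_size` (as produced by [fit_cohort()]).
#' @return data frame of class `insight_calls` with columns `subject`,
#'   `corrected_steepness`, `t_s`, `insight`, `delay_bins`, `delay_trials`
#'   (delays are `NA` for unflagged subjects); attribute `threshold`.
#' @export
classify_cohort <- function(experimental, control) {
  if (!nrow(control)) stop("empty control group", call. = FALSE)
  threshold <- max(control$corrected_steepness, na.rm = TRUE)
  onset <- attr(experimental, "onset")
  bin_size <- attr(experimental, "bin_size")
  insight <- experimental$corrected_steepness > threshold
  delay <- ifelse(insight, experimental$t_s - onset, NA_real_)
  out <- data.frame(subject = experimental$subject,
                    corrected_steepness = experimental$corrected_steepness,
                    t_s = experimental$t_s,
                    insight = insight,
                    delay_bins = delay,
                    delay_trials = delay * bin_size)
  structure(out, class = c("insight_calls", "data.frame"),
            threshold = threshold, onset = onset, bin_size = bin_size)
}

#' @export
print.insight_calls <- function(x, ...) {
  cat(sprintf("insight calls: %d/%d flagged (threshold %.4f)\n",
              sum(x$insight), nrow(x), attr(x, "threshold")))
  if (any(x$insight))
    cat(sprintf("mean delay %.2f bins (%.0f trials)\n",
                mean(x$delay_bins[x$insight]), mean(x$delay_trials[x$insight])))
  invisible(x)
}

#' Switch-aligned accuracy and the delay distribution
#'
#' Aligns each flagged subject's binned accuracy on its fitted switch point,
#' reports the group mean (+/- SEM) per relative bin, the mean accuracy in
#' the bin immediately before versus after the switch, and an exact two-sided
#' Kolmogorov-Smirnov test of the delays against a uniform distribution over
#' the post-onset window. The hazard-rate adjustment is handled by
#' conditioning: only switches that occur within the window enter the test,
#' which is the distribution of the delay given that a switch happened.
#'
#' @param calls an [classify_cohort()] result.
#' @param series_list list of [bin_accuracy()] series, parallel to the cohort.
#' @return list with `aligned` (data frame: `rel`, `mean`, `sem`, `n`),
#'   `pre_post` (named means), `delays` (vector, bins), and `ks`
#'   (`htest` or `NULL` when no insight subjects). Empty result (not an
#'   error) when nothing is flagged.
#' @export
delay_and_alignment <- function(calls, series_list) {
  idx <- which(calls$insight)
  if (!length(idx))
    return(list(aligned = data.frame(), pre_post = c(pre = NA, post = NA),
                delays = numeric(0), ks = NULL))
  onset <- attr(calls, "onset")
  rows <- list()
  pre <- post <- numeric(0)
  for (i in idx) {
    s <- series_list[[i]]
    ts <- calls$t_s[i]
    b <- floor(ts)
    rows[[length(rows) + 1L]] <- data.frame(rel = s$t - round(ts), acc = s$acc)
    if (b >= min(s$t) && b + 1 <= max(s$t)) {
      pre <- c(pre, s$acc[s$t == b])
      post <- c(post, s$acc[s$t == b + 1])
    }
  }
  al <- do.call(rbind, rows)
  agg <- do.call(rbind, lapply(split(al$acc, al$rel), function(v) {
    data.frame(mean = mean(v), sem = sd(v) / sqrt(length(v)), n = length(v))
  }))
  aligned <- cbind(rel = as.numeric(rownames(agg)), agg)
  rownames(aligned) <- NULL

  delays <- calls$delay_bins[idx]
  n_bins <- max(series_list[[idx[1]]]$t)
  W <- n_bins - onset
  d_in <- delays[delays > 0 & delays < W]
  ks <- if (length(d_in) >= 3)
    suppressWarnings(ks.test(d_in, "punif", 0, W, exact = TRUE)) else NULL
  list(aligned = aligned,
       pre_post = c(pre = mean(pre), post = mean(post)),
       delays = delays, window = W, ks = ks)
}
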