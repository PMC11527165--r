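#' Bin accuracy over the analysed task window
#'
#' Bins correctness into contiguous blocks of `bin_size` task trials over the
#' motion + colour phases (the fit window: the pre-switch motion-phase bins
#' provide the baseline), computing mean accuracy within each bin over the
#' trials of the filtered condition (by default the lowest coherence level).
#' With 100-trial blocks and `bin_size = 50` each bin is a halved task block
#' holding ~15 lowest-coherence trials.
#'
#' The baseline `y_min` is the subject's mean accuracy on lowest-coherence
#' trials across the motion-phase blocks.
#'
#' @param trials a trial table (e.g. a `net_trace` or behaviour table) with
#'   columns `trial`, `phase`, `coherence` (or `coherence_pct`) and `correct`.
#' @param bin_size task trials per bin (default 50; 15 supported for
#'   finer-grained suddenness checks).
#' @param coherence condition filter; default the lowest level present.
#' @return an object of class `accuracy_series`: data frame with `t` (bin
#'   index) and `acc`; attributes `y_min`, `bin_size`, `onset` (colour-onset
#'   boundary in bin coordinates) and `n_filtered`.
#' @export
bin_accuracy <- function(trials, bin_size = 50, coherence = NULL) {
  if (!"coherence" %in% names(trials) && "coherence_pct" %in% names(trials))
    trials$coherence <- trials$coherence_pct
  need <- c("trial", "phase", "coherence", "correct")
  miss <- setdiff(need, names(trials))
  if (length(miss)) stop("missing columns: ", paste(miss, collapse = ", "), call. = FALSE)
  if (is.null(coherence)) coherence <- min(trials$coherence)

  win <- trials[trials$phase %in% c("motion", "colour"), ]
  if (!nrow(win)) stop("no motion/colour-phase trials", call. = FALSE)
  offset <- min(win$trial) - 1L
  win$t <- ceiling((win$trial - offset) / bin_size)
  n_bins <- max(win$t)

  mot <- trials[trials$phase == "motion" & trials$coherence == coherence, ]
  y_min <- if (nrow(mot)) mean(mot$correct) else NA_real_

  sel <- win[win$coherence == coherence, ]
  acc <- vapply(seq_len(n_bins), function(b) {
    v <- sel$correct[sel$t == b]
    if (!length(v)) stop("bin ", b, " contains no trials after filtering", call. = FALSE)
    mean(v)
  }, numeric(1))

  onset <- if (any(win$phase == "colour")) {
    (min(win$trial[win$phase == "colour"]) - 1L - offset) / bin_size + 0.5
  } else NA_real_

  structure(data.frame(t = seq_len(n_bins), acc = acc),
            class = c("accuracy_series", "data.frame"),
            y_min = y_min, bin_size = bin_size, onset = onset,
            n_filtered = nrow(sel), coherence = coherence)
}

sigmoid_curve <- function(t, m, t_s, y_max, y_min) {
  y_min + (y_max - y_min) / (1 + exp(-m * (t - t_s)))
}

bic_gauss <- function(sse, n, k) n * log(max(sse, 1e-12) / n) + k * log(n)

#' Fit the three switch models to a binned accuracy series
#'
#' Least-squares fits of (i) a linear ramp `y = m t + y0`, (ii) a step
#' function with switch point `t_s`, step size `s` and ceiling `y_max`, and
#' (iii) a sigmoid `y = y_min + (y_max - y_min) / (1 + exp(-m (t - t_s)))`
#' with the baseline `y_min` fixed at the series baseline. The step model is
#' fitted by exhaustive search over integer switch points with closed-form
#' segment means; the sigmoid by bounded least squares (`m` in `[0, m_max]`,
#' `t_s` inside the window, `y_max` in `[y_min, 1]`) from multi-starts with
#' `t_s` spread over the window, ties broken by smaller `m`. Model comparison
#' uses a Gaussian-residual BIC, `n log(SSE/n) + k log(n)`, with k = 2
#' (linear) or 3 (step, sigmoid; the fixed `y_min` is not counted).
#'
#' The slope bound `m_max` is an identifiability limit: with bins one unit
#' apart, a sigmoid completing its rise within half a bin (`m` around 10) is
#' indistinguishable from any steeper one, while an unbounded slope lets the
#' fit interpolate single noisy bins ("needle" fits) and degrades the
#' steepness statistic's null distribution.
#'
#' @param series an [bin_accuracy()] series with at least 6 bins.
#' @param m_max upper bound for the sigmoid slope (default 10).
#' @param n_starts sigmoid multi-starts spread over the window (default 10).
#' @return list of class `switch_fits` with elements `linear`, `step`,
#'   `sigmoid`; each holds `params`, `sse`, `bic` (sigmoid adds `steepness`
#'   and `rmse`).
#' @export
fit_switch_models <- function(series, m_max = 10, n_starts = 10L) {
  t <- series$t
  y <- series$acc
  n <- length(t)
  if (n < 6L) stop("need at least 6 bins", call. = FALSE)
  y_min <- attr(series, "y_min")

  lin <- lm(y ~ t)
  sse_lin <- sum(lin$residuals^2)
  linear <- list(model = "linear",
                 params = c(m = unname(coef(lin)[2]), y_0 = unname(coef(lin)[1])),
                 sse = sse_lin, bic = bic_gauss(sse_lin, n, 2L))

  best <- NULL
  for (ts in 2:n) {
    pre <- y[t < ts]; post <- y[t >= ts]
    y_max <- mean(post); lo <- mean(pre)
    sse <- sum((pre - lo)^2) + sum((post - y_max)^2)
    if (is.null(best) || sse < best$sse)
      best <- list(ts = ts, y_max = y_max, s = y_max - lo, sse = sse)
  }
  step <- list(model = "step",
               params = c(t_s = best$ts, s = best$s, y_max = best$y_max),
               sse = best$sse, bic = bic_gauss(best$sse, n, 3L))

  obj <- function(p) sum((sigmoid_curve(t, p[1], p[2], p[3], y_min) - y)^2)
  lower <- c(0, min(t), y_min)
  upper <- c(m_max, max(t), 1)
  y_max0 <- min(max(max(y), y_min + 1e-3), 1)
  starts <- lapply(seq(min(t), max(t), length.out = n_starts),
                   function(ts0) c(2, ts0, y_max0))
  bestfit <- NULL
  for (st in starts) {
    f <- tryCatch(optim(st, obj, method = "L-BFGS-B", lower = lower, upper = upper,
                        control = list(maxit = 200L)),
                  error = function(e) NULL)
    if (is.null(f)) next
    if (is.null(bestfit) || f$value < bestfit$value - 1e-12 ||
        (abs(f$value - bestfit$value) <= 1e-12 && f$par[1] < bestfit$par[1]))
      bestfit <- f
  }
  if (is.null(bestfit)) {
    sigmoid <- list(model = "sigmoid", params = c(m = NA, t_s = NA, y_max = NA,
                                                  y_min = y_min),
                    sse = Inf, bic = Inf, steepness = NA, rmse = NA,
                    converged = FALSE)
  } else {
    p <- bestfit$par
    sse <- bestfit$value
    sigmoid <- list(model = "sigmoid",
                    params = c(m = p[1], t_s = p[2], y_max = p[3], y_min = y_min),
                    sse = sse, bic = bic_gauss(sse, n, 3L),
                    steepness = p[1] * (p[3] - y_min) / 4,
                    rmse = sqrt(sse / n), converged = TRUE)
  }
  structure(list(linear = linear, step = step, sigmoid = sigmoid),
            class = "switch_fits", n = n, onset = attr(series, "onset"))
}

#' Slope of the sigmoid at its inflection point
#'
#' Analytic derivative of the sigmoid switch model at `t = t_s`:
#' `m (y_max - y_min) / 4`.
#'
#' @param fit the `sigmoid` element of [fit_switch_models()] output.
#' @return the steepness (non-negative when `m >= 0`).
#' @export
steepness <- function(fit) {
  p <- fit$params
  unname(p["m"] * (p["y_max"] - p["y_min"]) / 4)
}

#' Goodness-of-fit-corrected steepness
#'
#' Irregular series can produce steep sigmoid fits without a genuine strategy
#' switch; the classification statistic therefore penalises the slope at the
#' inflection by the overall (mis)fit of the sigmoid to the series. The
#' default penalty is the fit RMSE; `"r2"` uses `1 - R^2`, `"none"` disables
#' the correction.
#'
#' @param fit sigmoid fit from [fit_switch_models()].
#' @param series the fitted [bin_accuracy()] series.
#' @param penalty `"rmse"`, `"r2"` or `"none"`.
#' @return corrected steepness (scalar).
#' @export
corrected_steepness <- function(fit, series, penalty = c("rmse", "r2", "none")) {
  penalty <- match.arg(penalty)
  s <- steepness(fit)
  pen <- switch(penalty,
                rmse = sqrt(fit$sse / length(series$t)),
                r2 = {
                  tss <- sum((series$acc - mean(series$acc))^2)
                  if (tss > 0) fit$sse / tss else 0
                },
                none = 0)
  s - pen
}
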