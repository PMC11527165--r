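#' Generate a synthetic behaviour table from a switch model
#'
#' Fixture generator: draws per-trial correctness Bernoulli with the success
#' probability given by one of the switch models evaluated at the trial's
#' bin. `"null_subject"` has a flat success probability (a control subject
#' for whom no switch exists); the other kinds realise the linear, step and
#' sigmoid curves over the motion + colour window.
#'
#' @param kind one of `"sigmoid_subject"`, `"linear_subject"`,
#'   `"step_subject"`, `"null_subject"`.
#' @param params named list of curve parameters: sigmoid needs `m`, `t_s`,
#'   `y_min`, `y_max`; linear `m`, `y_0`; step `t_s`, `s`, `y_max`; null `p`.
#' @param spec a [curriculum_spec()] defining the trial layout.
#' @param bin_size trials per bin used to evaluate the curve.
#' @param subject_id subject identifier.
#' @return a behaviour table (`subject_id`, `trial`, `block`, `phase`,
#'   `coherence_pct`, `correct`).
#' @export
make_fixtures <- function(kind = c("sigmoid_subject", "linear_subject",
                                   "step_subject", "null_subject"),
                          params, spec = curriculum_spec(), bin_size = 50,
                          subject_id = 1L) {
  kind <- match.arg(kind)
  cur <- build_curriculum(spec)
  win <- cur$phase %in% c("motion", "colour")
  offset <- min(cur$trial[win]) - 1L
  tbin <- ceiling((cur$trial - offset) / bin_size)
  pr <- switch(kind,
    null_subject = rep(params$p, nrow(cur)),
    linear_subject = params$m * tbin + params$y_0,
    step_subject = ifelse(tbin < params$t_s, params$y_max - params$s, params$y_max),
    sigmoid_subject = sigmoid_curve(tbin, params$m, params$t_s,
                                    params$y_max, params$y_min))
  pr[!win] <- if (kind == "null_subject") params$p else
    pr[which(win)[1]]  # pre-window trials sit at the curve's baseline
  if (any(pr < 0 | pr > 1))
    stop("switch-model probabilities outside [0, 1]", call. = FALSE)
  data.frame(subject_id = subject_id, trial = cur$trial, block = cur$block,
             phase = cur$phase, coherence_pct = cur$coherence,
             correct = rbinom(nrow(cur), 1L, pr))
}

behaviour_cols <- c("subject_id", "trial", "block", "phase", "coherence_pct",
                    "correct")

#' Validate a behaviour table
#'
#' Checks the schema used for human-style per-trial data: required columns,
#' one row per (subject, trial), binary `correct`, and coherence levels drawn
#' from \{5, 10, 20, 30, 45\}.
#'
#' @param tab data frame.
#' @return the table, invisibly; errors list every offending column.
#' @export
validate_behaviour <- function(tab) {
  miss <- setdiff(behaviour_cols, names(tab))
  if (length(miss))
    stop("behaviour table missing columns: ", paste(miss, collapse = ", "),
         call. = FALSE)
  bad <- character(0)
  if (!all(tab$correct %in% c(0L, 1L))) bad <- c(bad, "correct (must be 0/1)")
  if (!all(tab$coherence_pct %in% c(5, 10, 20, 30, 45)))
    bad <- c(bad, "coherence_pct (must be 5/10/20/30/45)")
  if (anyDuplicated(tab[, c("subject_id", "trial")]))
    bad <- c(bad, "subject_id/trial (duplicated rows)")
  if (length(bad))
    stop("invalid behaviour table: ", paste(bad, collapse = "; "), call. = FALSE)
  invisible(tab)
}

#' Read / write behaviour tables as CSV
#'
#' @param path file path.
#' @param tab a behaviour table.
#' @return `read_behaviour()` returns the validated table.
#' @export
read_behaviour <- function(path) {
  validate_behaviour(read.csv(path, stringsAsFactors = FALSE))
}

#' @rdname read_behaviour
#' @export
write_behaviour <- function(tab, path) {
  validate_behaviour(tab)
  write.csv(tab, path, row.names = FALSE)
  invisible(path)
}

#' Run configuration: serialisation and hashing
#'
#' A run configuration is a plain named list (curriculum spec, input model
#' constants, hyperparameters, seeds, grids). `config_hash()` gives an MD5
#' digest of its canonical serialisation, embedded in outputs so any change
#' to any field changes the hash; `save_config()` / `load_config()`
#' round-trip it through JSON (requires the jsonlite package).
#'
#' @param config named list.
#' @param path file path for JSON I/O.
#' @return `config_hash()` a character scalar; `load_config()` the list.
#' @export
config_hash <- function(config) {
  tmp <- tempfile()
  on.exit(unlink(tmp))
  saveRDS(rapply(config, unclass, how = "replace"), tmp, version = 2,
          compress = FALSE)
  unname(tools::md5sum(tmp))
}

#' @rdname config_hash
#' @export
save_config <- function(config, path) {
  if (!requireNamespace("jsonlite", quietly = TRUE))
    stop("jsonlite is required for config serialisation", call. = FALSE)
  config$config_hash <- config_hash(config)
  jsonlite::write_json(config, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname config_hash
#' @export
load_config <- function(path) {
  if (!requireNamespace("jsonlite", quietly = TRUE))
    stop("jsonlite is required for config serialisation", call. = FALSE)
  jsonlite::read_json(path, simplifyVector = TRUE)
}
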