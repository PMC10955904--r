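# Plain-text exchange formats. Profiles travel as long-format CSV
# (subject, trial, cut, sample_index, force), expert scores as
# (subject_trial, rater, score) CSV, and fitted models as versioned JSON.

#' Write a trial set as long-format CSV
#'
#' One row per sample with columns `subject, trial, cut, sample_index, force`;
#' full float64 precision (17 significant digits) so a write/read round trip
#' is lossless.
#'
#' @param ts A `trial_set`.
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_profiles_csv <- function(ts, path) {
  stopifnot(inherits(ts, "trial_set"))
  rows <- lapply(seq_along(ts$profiles), function(i) {
    s <- ts$profiles[[i]]$samples
    data.frame(subject = ts$meta$subject[i], trial = ts$meta$trial[i],
               cut = ts$meta$cut[i], sample_index = seq_along(s),
               force = sprintf("%.17g", s), stringsAsFactors = FALSE)
  })
  utils::write.csv(do.call(rbind, rows), path, row.names = FALSE,
                   quote = FALSE)
  invisible(path)
}

#' Read a trial set from long-format CSV
#'
#' Expects columns `subject, trial, cut, sample_index, force` (an optional
#' `time_s` column is ignored). Rows with non-finite force values are
#' rejected with their line numbers.
#'
#' @param path CSV path.
#' @param rate Sampling rate to attach (Hz, default 30).
#' @param normalized Whether the stored forces are already normalized.
#' @return A `trial_set`.
#' @export
read_profiles_csv <- function(path, rate = 30, normalized = FALSE) {
  if (!file.exists(path)) stop("no such file: ", path)
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  if (nrow(df) == 0) stop("empty profile file: ", path)
  need <- c("subject", "trial", "cut", "sample_index", "force")
  missing_cols <- setdiff(need, names(df))
  if (length(missing_cols) > 0) {
    stop("missing required column(s): ", paste(missing_cols, collapse = ", "))
  }
  bad <- which(!is.finite(suppressWarnings(as.numeric(df$force))))
  if (length(bad) > 0) {
    stop("non-numeric force value(s) at data row(s): ",
         paste(utils::head(bad, 10), collapse = ", "))
  }
  df$force <- as.numeric(df$force)
  key <- interaction(df$subject, df$trial, df$cut, drop = TRUE,
                     lex.order = TRUE)
  idx <- split(seq_len(nrow(df)), key)
  profiles <- vector("list", length(idx))
  meta <- vector("list", length(idx))
  for (i in seq_along(idx)) {
    rows <- idx[[i]][order(df$sample_index[idx[[i]]])]
    profiles[[i]] <- force_profile(
      df$force[rows], rate = rate, normalized = normalized,
      label = sprintf("%s_t%s_c%02d", df$subject[rows[1]],
                      df$trial[rows[1]], df$cut[rows[1]]))
    meta[[i]] <- data.frame(subject = df$subject[rows[1]],
                            trial = df$trial[rows[1]],
                            cut = df$cut[rows[1]], stringsAsFactors = FALSE)
  }
  trial_set(profiles, do.call(rbind, meta))
}

#' Write expert scores as CSV
#'
#' @param scores Data frame with columns `subject_trial`, `rater`, `score`.
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_scores_csv <- function(scores, path) {
  if (!all(c("subject_trial", "rater", "score") %in% names(scores))) {
    stop("scores require columns subject_trial, rater, score")
  }
  utils::write.csv(scores, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read expert scores from CSV
#'
#' @param path CSV path with columns `subject_trial`, `rater`, `score`.
#' @return Data frame of scores (integer grades 0-3).
#' @export
read_scores_csv <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("subject_trial", "rater", "score")
  missing_cols <- setdiff(need, names(df))
  if (length(missing_cols) > 0) {
    stop("missing required column(s): ", paste(missing_cols, collapse = ", "))
  }
  if (!all(df$score %in% 0:3)) stop("scores must be integers in 0-3")
  df
}

#' Convert a score table to a targets-by-raters matrix
#'
#' @param scores Data frame with `subject_trial`, `rater`, `score`.
#' @return Numeric matrix (rows = subject/trials, columns = raters) suitable
#'   for [icc_2_1()].
#' @export
scores_to_rater_table <- function(scores) {
  tab <- stats::xtabs(score ~ subject_trial + rater, data = scores)
  cnt <- stats::xtabs(~subject_trial + rater, data = scores)
  if (any(cnt != 1)) stop("score table must have exactly one grade per (subject_trial, rater)")
  M <- matrix(as.numeric(tab), nrow(tab), ncol(tab),
              dimnames = dimnames(tab))
  M
}

MODEL_SCHEMA_VERSION <- 1L

#' Serialize a fitted regime model to JSON
#'
#' Versioned structured-text representation holding the regime parameters and
#' the context needed to interpret them (Maxwell coefficients, sample
#' interval, normalization constant, velocity unit).
#'
#' @param m A `regime_model`.
#' @param path Output JSON path.
#' @param meta Optional named list merged into the model's metadata (e.g.
#'   `list(E = 1, eta = 0.5, dt = 1/30, normalization = 2.3)`).
#' @return `path`, invisibly.
#' @export
write_regime_model <- function(m, path, meta = list()) {
  stopifnot(inherits(m, "regime_model"))
  obj <- list(
    schema_version = MODEL_SCHEMA_VERSION,
    K = m$K,
    v = as.numeric(m$v),
    sigma2 = as.numeric(m$sigma2),
    Q = unname(as.matrix(m$Q)),
    pi0 = as.numeric(m$pi0),
    loglik = if (is.finite(m$loglik)) m$loglik else NULL,
    meta = utils::modifyList(m$meta, meta)
  )
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}

#' Read a regime model from JSON
#'
#' @param path JSON path written by [write_regime_model()].
#' @return A `regime_model` with its `meta` field restored.
#' @export
read_regime_model <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  if (is.null(obj$schema_version) ||
      obj$schema_version > MODEL_SCHEMA_VERSION) {
    stop("unsupported model schema version in ", path)
  }
  m <- regime_model(obj$v, obj$sigma2, as.matrix(obj$Q), obj$pi0,
                    relabel = FALSE)
  if (!is.null(obj$loglik)) m$loglik <- obj$loglik
  if (!is.null(obj$meta)) m$meta <- obj$meta
  m
}

RUN_CONFIG_KEYS <- c("rate", "target_len", "onset_fraction", "maxwell",
                     "hmm", "seed")

#' Run configuration for the analysis pipeline
#'
#' Collects the tunable parameters of the pipeline with the study defaults:
#' 30 Hz sampling, 120-sample analysis window, 10% onset threshold, Maxwell
#' body `E = 1` N/cm and `eta = 0.5` N s/cm, and a two-regime HMM. The seed
#' is mandatory for any stochastic command: there is no silent global
#' randomness.
#'
#' @param rate Sampling rate (Hz).
#' @param target_len Analysis window length (samples).
#' @param onset_fraction Onset threshold fraction for [align_and_crop()].
#' @param maxwell List with `E` and `eta`.
#' @param hmm List with `K`, `max_iter`, `tol`.
#' @param seed Integer seed.
#' @return A list of class `run_config`.
#' @export
run_config <- function(rate = 30, target_len = 120, onset_fraction = 0.10,
                       maxwell = list(E = 1, eta = 0.5),
                       hmm = list(K = 2, max_iter = 200, tol = 1e-6),
                       seed = 1) {
  cfg <- list(rate = rate, target_len = target_len,
              onset_fraction = onset_fraction, maxwell = maxwell, hmm = hmm,
              seed = seed)
  validate_run_config(cfg)
}

validate_run_config <- function(cfg) {
  unknown <- setdiff(names(cfg), RUN_CONFIG_KEYS)
  if (length(unknown) > 0) {
    stop("unknown config key(s): ", paste(unknown, collapse = ", "))
  }
  for (key in c("rate", "target_len", "seed")) {
    if (!is.numeric(cfg[[key]]) || cfg[[key]] <= 0) {
      stop("config field '", key, "' must be positive")
    }
  }
  if (cfg$onset_fraction < 0 || cfg$onset_fraction > 1) {
    stop("config field 'onset_fraction' must lie in [0, 1]")
  }
  if (cfg$maxwell$E <= 0 || cfg$maxwell$eta <= 0) {
    stop("Maxwell coefficients must be positive")
  }
  if (cfg$hmm$K < 1) stop("config field 'hmm$K' must be at least 1")
  class(cfg) <- "run_config"
  cfg
}

#' Read / write a run configuration (JSON)
#'
#' The parsed configuration re-serializes to the identical canonical form,
#' and unknown keys are rejected.
#'
#' @param path JSON path.
#' @return For `read_run_config`, a `run_config`; for `write_run_config`,
#'   `path` invisibly.
#' @export
read_run_config <- function(path) {
  cfg <- jsonlite::read_json(path, simplifyVector = TRUE)
  validate_run_config(cfg)
}

#' @rdname read_run_config
#' @param cfg A `run_config`.
#' @export
write_run_config <- function(cfg, path) {
  stopifnot(inherits(cfg, "run_config"))
  jsonlite::write_json(unclass(cfg), path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}
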