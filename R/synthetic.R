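# Synthetic cohorts: the generative direction of the model.
#
# An archetype is a named cutting style given as regime-model parameters;
# profiles are rendered by sampling a velocity path from the two-state Markov
# chain and passing it through the Maxwell body. Velocities are specified in
# mm/s following the physical range of the blade (0-8 mm/s, Gaussian noise
# with sd 0.35 mm/s); the Maxwell coefficients are expressed per cm, so
# velocities are converted to cm/s when rendering, which places steady-state
# forces (eta * v) on the same 0-0.4 amplitude scale as normalized recordings.

MM_PER_CM <- 10

#' Specify a synthetic cutting archetype
#'
#' Bundles the regime-model parameters of one cutting style with the Maxwell
#' parameters and trial geometry used to render it. Defaults follow the study
#' conditions: 120-sample profiles at 30 Hz, 12 profiles per trial (six
#' excisions, each an upper and a lower cut), velocity levels inside
#' 0-8 mm/s with noise sd 0.35 mm/s, Maxwell body E = 1 N/cm,
#' eta = 0.5 N s/cm.
#'
#' @param name Archetype name.
#' @param v_L,v_U Lower/upper regime mean velocities in mm/s (`v_L < v_U`),
#'   within `v_range`.
#' @param q12 Probability of switching from the lower to the upper regime.
#' @param q21 Probability of switching from the upper to the lower regime.
#' @param sigma_L,sigma_U Regime velocity noise standard deviations in mm/s.
#' @param maxwell A [maxwell_params()].
#' @param profiles_per_trial Profiles per trial (default 12).
#' @param length Samples per profile (default 120).
#' @param rate Sampling rate in Hz (default 30).
#' @param v_range Admissible range for the velocity means, mm/s.
#' @return An object of class `archetype_spec`.
#' @examples
#' archetype_spec("smooth_steady", v_L = 5, v_U = 8,
#'                q12 = 0.037, q21 = 0.037)
#' @export
archetype_spec <- function(name, v_L, v_U, q12, q21,
                           sigma_L = 0.35, sigma_U = 0.35,
                           maxwell = maxwell_params(),
                           profiles_per_trial = 12, length = 120, rate = 30,
                           v_range = c(0, 8)) {
  if (!is.character(name) || length(name) != 1) stop("name must be a string")
  if (v_L >= v_U) stop("archetype requires v_L < v_U")
  if (v_L < v_range[1] || v_U > v_range[2]) {
    stop(sprintf("velocity means must lie in [%g, %g] mm/s",
                 v_range[1], v_range[2]))
  }
  if (any(c(q12, q21) < 0) || any(c(q12, q21) > 1)) {
    stop("transition probabilities must lie in [0, 1]")
  }
  if (sigma_L <= 0 || sigma_U <= 0) stop("velocity noise sd must be positive")
  if (profiles_per_trial < 1) stop("profiles_per_trial must be at least 1")
  if (length < 2) stop("profile length must be at least 2 samples")
  stopifnot(inherits(maxwell, "maxwell_params"))
  structure(
    list(name = name, v_L = v_L, v_U = v_U, q12 = q12, q21 = q21,
         sigma_L = sigma_L, sigma_U = sigma_U, maxwell = maxwell,
         profiles_per_trial = as.integer(profiles_per_trial),
         length = as.integer(length), rate = rate, v_range = v_range),
    class = "archetype_spec"
  )
}

#' @export
print.archetype_spec <- function(x, ...) {
  cat(sprintf(
    "<archetype_spec '%s': v_L = %g, v_U = %g mm/s; q12 = %g, q21 = %g>\n",
    x$name, x$v_L, x$v_U, x$q12, x$q21))
  invisible(x)
}

#' Regime model corresponding to an archetype
#'
#' @param spec An [archetype_spec()].
#' @param unit `"mm/s"` (as specified) or `"cm/s"` (the scale on which the
#'   Maxwell body operates; 1 cm/s = 10 mm/s).
#' @return A [regime_model()] started in the lower regime with certainty
#'   (cuts begin from rest).
#' @export
archetype_model <- function(spec, unit = c("mm/s", "cm/s")) {
  stopifnot(inherits(spec, "archetype_spec"))
  unit <- match.arg(unit)
  sc <- if (unit == "cm/s") 1 / MM_PER_CM else 1
  regime_model(
    v = c(spec$v_L, spec$v_U) * sc,
    sigma2 = c(spec$sigma_L, spec$sigma_U)^2 * sc^2,
    Q = matrix(c(1 - spec$q12, spec$q12, spec$q21, 1 - spec$q21),
               2, 2, byrow = TRUE),
    pi0 = c(1, 0)
  )
}

#' Named archetypes shipped with the package
#'
#' Four qualitative cutting styles used as ground-truthed fixtures:
#' \describe{
#'   \item{smooth_steady}{slow, balanced force modulation: equal low
#'     transition probabilities (`q12 = q21 = 0.037`) and a narrow envelope.}
#'   \item{steady_high_persistence}{steady force application with rare drops:
#'     asymmetric transitions (`q12 = 0.124`, `q21 = 0.028`) keeping the chain
#'     in the upper regime ~82% of the time.}
#'   \item{abrupt_recovery}{frequent losses of force followed by rapid
#'     recovery: both transition probabilities large, wide envelope.}
#'   \item{interrupted}{hesitant low-force cutting with long interruptions.}
#' }
#' @return Named list of [archetype_spec()] objects.
#' @export
default_archetypes <- function() {
  list(
    smooth_steady = archetype_spec(
      "smooth_steady", v_L = 5, v_U = 8, q12 = 0.037, q21 = 0.037),
    steady_high_persistence = archetype_spec(
      "steady_high_persistence", v_L = 5.5, v_U = 8, q12 = 0.124, q21 = 0.028),
    abrupt_recovery = archetype_spec(
      "abrupt_recovery", v_L = 2, v_U = 7.5, q12 = 0.30, q21 = 0.15),
    interrupted = archetype_spec(
      "interrupted", v_L = 1, v_U = 6, q12 = 0.08, q21 = 0.12,
      sigma_L = 0.5, sigma_U = 0.5)
  )
}

#' Generate one synthetic force profile from an archetype
#'
#' Samples a regime/velocity path from the archetype's Markov chain, converts
#' it to the Maxwell body's cm scale and integrates the force dynamics forward
#' from rest ([simulate_force()] with `f0 = 0`). The simulated force is
#' rectified at zero: the instrument measures a unidirectional cutting force,
#' so the rare slightly-negative excursions the linear model produces when the
#' noisy velocity dips below zero are clipped, exactly as a real sensor trace
#' is bounded below by zero. Deterministic under a fixed seed.
#'
#' @param spec An [archetype_spec()].
#' @param seed Integer seed.
#' @param keep_path Also return the sampled states and velocity profile.
#' @return A [force_profile()], or when `keep_path = TRUE` a list with
#'   `force`, `velocity` (cm/s) and `states`.
#' @export
generate_profile <- function(spec, seed = NULL, keep_path = FALSE) {
  stopifnot(inherits(spec, "archetype_spec"))
  m <- archetype_model(spec, unit = "cm/s")
  path <- sample_regime_hmm(m, spec$length, seed = seed, rate = spec$rate)
  f <- simulate_force(path$velocity, spec$maxwell, f0 = 0)
  f$samples <- pmax(f$samples, 0)
  f$label <- spec$name
  if (keep_path) {
    list(force = f, velocity = path$velocity, states = path$states)
  } else {
    f
  }
}

#' Generate a full trial of profiles from an archetype
#'
#' One trial is six elliptical excisions, each consisting of an upper and a
#' lower cut, i.e. 12 independent force profiles by default. Per-profile seeds
#' are derived deterministically from `seed`, so a rerun is bit-identical.
#'
#' @param spec An [archetype_spec()].
#' @param seed Integer seed.
#' @param subject Subject label (defaults to the archetype name).
#' @param trial Trial number.
#' @return A `trial_set` (see [trial_set()]) with `spec$profiles_per_trial`
#'   profiles.
#' @export
generate_trial <- function(spec, seed = NULL, subject = spec$name, trial = 1) {
  stopifnot(inherits(spec, "archetype_spec"))
  seeds <- derive_seeds(seed, spec$profiles_per_trial)
  profiles <- vector("list", spec$profiles_per_trial)
  meta <- data.frame(subject = character(0), trial = integer(0),
                     cut = integer(0))
  for (i in seq_len(spec$profiles_per_trial)) {
    p <- generate_profile(spec, seed = seeds[[i]])
    p$label <- sprintf("%s_t%d_c%02d", subject, trial, i)
    profiles[[i]] <- p
  }
  meta <- data.frame(subject = subject, trial = trial,
                     cut = seq_len(spec$profiles_per_trial),
                     stringsAsFactors = FALSE)
  trial_set(profiles, meta)
}

#' Construct a trial set
#'
#' A collection of force profiles grouped by subject and trial, with optional
#' expert scores (integer grades 0-3 per rater and subject/trial).
#'
#' @param profiles List of [force_profile()] objects, all with the same length
#'   and rate.
#' @param meta Data frame with one row per profile: columns `subject`, `trial`,
#'   `cut`.
#' @param scores Optional data frame with columns `subject_trial`, `rater`,
#'   `score` (integers in 0-3).
#' @return An object of class `trial_set`.
#' @export
trial_set <- function(profiles, meta, scores = NULL) {
  if (!is.list(profiles) || length(profiles) == 0 ||
      !all(vapply(profiles, inherits, logical(1), "force_profile"))) {
    stop("profiles must be a non-empty list of force_profile objects")
  }
  lens <- vapply(profiles, function(p) length(p$samples), integer(1))
  rates <- vapply(profiles, function(p) p$rate, numeric(1))
  if (length(unique(lens)) != 1 || length(unique(rates)) != 1) {
    stop("all profiles in a trial set must share one length and rate")
  }
  if (nrow(meta) != length(profiles)) {
    stop("meta must have one row per profile")
  }
  if (!all(c("subject", "trial", "cut") %in% names(meta))) {
    stop("meta requires columns subject, trial, cut")
  }
  if (!is.null(scores)) {
    if (!all(c("subject_trial", "rater", "score") %in% names(scores))) {
      stop("scores require columns subject_trial, rater, score")
    }
    if (!all(scores$score %in% 0:3)) {
      stop("expert scores must be integers in 0-3")
    }
  }
  structure(list(profiles = profiles, meta = meta, scores = scores,
                 rate = rates[1], length = lens[1]),
            class = "trial_set")
}

#' @export
print.trial_set <- function(x, ...) {
  cat(sprintf("<trial_set: %d profiles (%d samples @ %g Hz), %d subject/trial group(s)%s>\n",
              length(x$profiles), x$length, x$rate,
              nrow(unique(x$meta[c("subject", "trial")])),
              if (is.null(x$scores)) "" else
                sprintf(", scores from %d rater(s)",
                        length(unique(x$scores$rater)))))
  invisible(x)
}

# Internal: bind several trial sets into one.
bind_trial_sets <- function(sets) {
  profiles <- do.call(c, lapply(sets, function(s) s$profiles))
  meta <- do.call(rbind, lapply(sets, function(s) s$meta))
  scores <- do.call(rbind, lapply(sets, function(s) s$scores))
  trial_set(profiles, meta, scores)
}

#' Generate a multi-archetype synthetic cohort
#'
#' Renders one trial per archetype (optionally several) and, when raters are
#' requested, attaches synthetic expert scores with known ground truth: each
#' archetype has a latent quality given by `score_rule`, and each rater grades
#' `round(latent + noise)` clamped to 0-3. With `rater_sd = 0` all raters
#' agree exactly (downstream ICC = 1); with `score_rule = "random"` grades are
#' independent uniform draws (downstream ICC ~ 0).
#'
#' @param archetypes List of [archetype_spec()] (at least 2 for any downstream
#'   group statistics).
#' @param trials_per_archetype Trials simulated per archetype.
#' @param raters Number of synthetic raters (0 = no scores).
#' @param score_rule Either `NULL` (archetypes graded 3, 2, 1, ... by list
#'   order, recycled), a named numeric vector of latent scores per archetype
#'   name, a function `function(spec) -> numeric`, or the string `"random"`.
#' @param rater_sd Standard deviation of per-rater grading noise.
#' @param seed Integer seed.
#' @return A `trial_set` covering all archetypes.
#' @export
generate_cohort <- function(archetypes, trials_per_archetype = 1, raters = 0,
                            score_rule = NULL, rater_sd = 0, seed = NULL) {
  if (!is.list(archetypes) || length(archetypes) == 0 ||
      !all(vapply(archetypes, inherits, logical(1), "archetype_spec"))) {
    stop("archetypes must be a non-empty list of archetype_spec objects")
  }
  n_arch <- length(archetypes)
  seeds <- derive_seeds(seed, n_arch * trials_per_archetype + 1)
  sets <- vector("list", n_arch * trials_per_archetype)
  k <- 0
  for (a in seq_len(n_arch)) {
    for (tr in seq_len(trials_per_archetype)) {
      k <- k + 1
      sets[[k]] <- generate_trial(archetypes[[a]], seed = seeds[[k]],
                                  subject = archetypes[[a]]$name, trial = tr)
    }
  }
  cohort <- bind_trial_sets(sets)
  if (raters > 0) {
    cohort$scores <- synth_scores(archetypes, trials_per_archetype, raters,
                                  score_rule, rater_sd,
                                  seed = seeds[[n_arch * trials_per_archetype + 1]])
  }
  cohort
}

synth_scores <- function(archetypes, trials_per_archetype, raters, score_rule,
                         rater_sd, seed = NULL) {
  names_ <- vapply(archetypes, function(a) a$name, character(1))
  latent_of <- function(spec, idx) {
    if (is.null(score_rule)) {
      return(max(0, 3 - (idx - 1) %% 4))
    }
    if (is.function(score_rule)) return(score_rule(spec))
    if (identical(score_rule, "random")) return(NA_real_)
    if (is.numeric(score_rule)) return(unname(score_rule[[spec$name]]))
    stop("unsupported score_rule")
  }
  with_seed(seed, {
    rows <- list()
    for (a in seq_along(archetypes)) {
      for (tr in seq_len(trials_per_archetype)) {
        st <- sprintf("%s_%d", names_[a], tr)
        latent <- latent_of(archetypes[[a]], a)
        for (r in seq_len(raters)) {
          grade <- if (is.na(latent)) {
            sample(0:3, 1)
          } else {
            min(3L, max(0L, as.integer(round(
              latent + stats::rnorm(1, 0, rater_sd)))))
          }
          rows[[length(rows) + 1]] <-
            data.frame(subject_trial = st, rater = sprintf("R%d", r),
                       score = grade, stringsAsFactors = FALSE)
        }
      }
    }
    do.call(rbind, rows)
  })
}
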