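#' Describe an event-related design
#'
#' Bundles the parameters of a jittered event-related fMRI design: how many
#' runs, which conditions, how many trials of each condition per run, trial
#' duration, the inter-stimulus-interval (ISI) range, the repetition time and
#' the rest periods that pad each run. The default values emulate a
#' 3-person x 2-emotion preference task: six conditions (H1, S1, H2, S2 for
#' the two individuals with emotion-dependent preferences; H3, S3 for the
#' no-preference control individual), six trials per condition per run, 2 s
#' trials separated by 4-10 s jittered fixation, TR = 1 s, ten runs.
#'
#' @param n_runs Number of runs (>= 1).
#' @param conditions Character vector of condition labels.
#' @param trials_per_condition Trials of each condition in every run.
#' @param trial_duration Trial duration in seconds.
#' @param isi_min,isi_max Bounds of the uniform ISI jitter, seconds.
#' @param tr Repetition time, seconds. ISIs are rounded to this grid.
#' @param initial_rest,final_rest Rest padding at run start/end, seconds.
#' @param seed Integer seed; the design is deterministic given the seed.
#' @return A `design_spec` list.
#' @examples
#' spec <- design_spec(n_runs = 2, seed = 1)
#' generate_design(spec)
#' @export
design_spec <- function(n_runs = 10,
                        conditions = c("H1", "S1", "H2", "S2", "H3", "S3"),
                        trials_per_condition = 6,
                        trial_duration = 2,
                        isi_min = 4,
                        isi_max = 10,
                        tr = 1,
                        initial_rest = 10,
                        final_rest = 10,
                        seed = 1L) {
  if (n_runs < 1 || trials_per_condition < 1) {
    abort("`n_runs` and `trials_per_condition` must be positive counts.",
          class = "decodelight_invalid_spec")
  }
  if (length(conditions) < 1 || anyDuplicated(conditions)) {
    abort("`conditions` must be a non-empty set of unique labels.",
          class = "decodelight_invalid_spec")
  }
  if (isi_min > isi_max) {
    abort("`isi_min` must not exceed `isi_max`.",
          class = "decodelight_invalid_spec")
  }
  if (any(c(trial_duration, tr, isi_min) <= 0) ||
      initial_rest < 0 || final_rest < 0) {
    abort("Durations must be positive (rests may be zero).",
          class = "decodelight_invalid_spec")
  }
  structure(
    list(
      n_runs = as.integer(n_runs),
      conditions = as.character(conditions),
      trials_per_condition = as.integer(trials_per_condition),
      trial_duration = trial_duration,
      isi_min = isi_min,
      isi_max = isi_max,
      tr = tr,
      initial_rest = initial_rest,
      final_rest = final_rest,
      seed = as.integer(seed)
    ),
    class = "design_spec"
  )
}

#' @export
print.design_spec <- function(x, ...) {
  cat("<design_spec> ", x$n_runs, " run(s), ",
      length(x$conditions), " conditions x ", x$trials_per_condition,
      " trials (", x$trial_duration, " s, ISI ", x$isi_min, "-", x$isi_max,
      " s, TR ", x$tr, " s)\n", sep = "")
  invisible(x)
}

#' Generate a randomized event table for every run
#'
#' Draws, for each run, a seeded random permutation of the condition labels
#' (each condition appearing exactly `trials_per_condition` times) and
#' uniform ISI jitter on `[isi_min, isi_max]` rounded to the TR grid, then
#' lays trials out from `initial_rest` onwards. Behavioral columns
#' (`responded`, `correct`) are initialized to `TRUE`; use
#' [simulate_behavior()] to fill them stochastically.
#'
#' @param spec A [design_spec()].
#' @return A tibble with one row per trial and columns `run` (0-based),
#'   `trial` (0-based within run), `onset`, `duration` (seconds), `condition`,
#'   `responded`, `correct`.
#' @examples
#' events <- generate_design(design_spec(n_runs = 1, seed = 7))
#' dplyr::count(events, condition)
#' @export
generate_design <- function(spec) {
  stopifnot(inherits(spec, "design_spec"))
  n_trials <- length(spec$conditions) * spec$trials_per_condition
  runs <- with_seed(derive_seed(spec$seed, "design"), {
    purrr::map(seq_len(spec$n_runs) - 1L, function(r) {
      cond <- sample(rep(spec$conditions, spec$trials_per_condition))
      isi <- round(runif(n_trials - 1L, spec$isi_min, spec$isi_max) /
                     spec$tr) * spec$tr
      onset <- spec$initial_rest +
        cumsum(c(0, isi + spec$trial_duration))
      tibble::tibble(
        run = r,
        trial = seq_len(n_trials) - 1L,
        onset = onset,
        duration = spec$trial_duration,
        condition = cond,
        responded = TRUE,
        correct = TRUE
      )
    })
  })
  dplyr::bind_rows(runs)
}

#' Run length implied by an event table
#'
#' Number of volumes needed to cover the last trial plus the final rest,
#' rounded up to whole volumes.
#'
#' @param events Event table for a single run (or with a `run` column, the
#'   maximum over runs is returned so all runs share one length).
#' @param spec The [design_spec()] that generated the events.
#' @return Integer number of volumes.
#' @export
run_n_volumes <- function(events, spec) {
  end <- max(events$onset + events$duration) + spec$final_rest
  as.integer(ceiling(end / spec$tr))
}

#' Simulate behavioral responses for an event table
#'
#' Fills the `responded` and `correct` columns with independent Bernoulli
#' draws. Conditions listed in `no_answer_conditions` have no objectively
#' correct response (the no-preference control trials), so for them
#' `correct` is set equal to `responded`: every response counts as usable.
#' The default `p_correct` reflects typical task accuracy near 94%.
#'
#' @param events Event table (tibble) from [generate_design()].
#' @param p_correct Probability a responded trial is correct.
#' @param p_respond Probability a trial receives any response.
#' @param no_answer_conditions Conditions with no correct answer.
#' @param seed Integer seed.
#' @return The event table with `responded` and `correct` filled.
#' @export
simulate_behavior <- function(events, p_correct = 0.94, p_respond = 0.98,
                              no_answer_conditions = c("H3", "S3"),
                              seed = 1L) {
  stopifnot(p_correct >= 0, p_correct <= 1, p_respond >= 0, p_respond <= 1)
  n <- nrow(events)
  with_seed(derive_seed(seed, "behavior"), {
    responded <- rbinom(n, 1L, p_respond) == 1L
    correct <- responded & (rbinom(n, 1L, p_correct) == 1L)
    no_answer <- events$condition %in% no_answer_conditions
    correct[no_answer] <- responded[no_answer]
    events$responded <- responded
    events$correct <- correct
    events
  })
}
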