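#' Stimulus specification for an intradimensional discrimination task
#'
#' Defines the CS+ and CS- orientations and the set of orientations probed
#' during the generalization test. The defaults reproduce the study design:
#' CS+/CS- at 39 and 51 degrees (counterbalanced across subjects) and a test
#' set of 15 orientations from 17 to 73 degrees in 4-degree steps, which
#' excludes both CS orientations.
#'
#' @param cs_plus orientation (degrees) of the rewarded stimulus.
#' @param cs_minus orientation (degrees) of the never-rewarded stimulus.
#' @param test_orientations strictly increasing orientations (degrees) shown
#'   during the extinction test; must not contain either CS.
#' @return An object of class `stimulus_spec`.
#' @export
#' @examples
#' stimulus_spec()
#' stimulus_spec(cs_plus = 51, cs_minus = 39)  # counterbalanced subject
stimulus_spec <- function(cs_plus = 39, cs_minus = 51,
                          test_orientations = seq(17, 73, by = 4)) {
  stopifnot(is.numeric(cs_plus), length(cs_plus) == 1L, is.finite(cs_plus),
            is.numeric(cs_minus), length(cs_minus) == 1L, is.finite(cs_minus),
            is.numeric(test_orientations))
  if (cs_plus == cs_minus)
    stop("cs_plus and cs_minus must differ")
  if (length(test_orientations) > 1L && any(diff(test_orientations) <= 0))
    stop("test_orientations must be strictly increasing")
  if (any(c(cs_plus, cs_minus) %in% test_orientations))
    stop("CS orientations must not appear in test_orientations")
  structure(list(cs_plus = cs_plus, cs_minus = cs_minus,
                 test_orientations = as.numeric(test_orientations)),
            class = "stimulus_spec")
}

#' @export
print.stimulus_spec <- function(x, ...) {
  cat("Stimulus specification\n")
  cat("  CS+ :", x$cs_plus, "deg   CS- :", x$cs_minus, "deg\n")
  cat("  test:", length(x$test_orientations), "orientations [",
      min(x$test_orientations), "-", max(x$test_orientations), "deg ]\n")
  invisible(x)
}

new_schedule <- function(phase, orientation, outcome, spec, seed) {
  n <- length(orientation)
  structure(
    data.frame(phase = phase,
               trial = seq_len(n),
               orientation_deg = orientation,
               outcome = as.integer(outcome),
               response = rep(NA_character_, n),
               valid = rep(TRUE, n),
               stringsAsFactors = FALSE),
    stimulus_spec = spec, seed = seed)
}

#' Generate a discrimination-training schedule
#'
#' Builds the training phase: `n_reps` CS+ and `n_reps` CS- presentations in
#' seeded pseudorandom order. The CS+ is rewarded on a proportion `p_reward`
#' of its presentations, the CS- never. By default the reinforcement is an
#' exact count (`p_reward * n_reps` rewarded CS+ trials, positions shuffled),
#' which guarantees the scheduled contingency in every realization;
#' `bernoulli = TRUE` instead draws each CS+ outcome independently.
#'
#' @param spec a [stimulus_spec()].
#' @param n_reps repetitions per CS (study design: 100).
#' @param p_reward CS+ reinforcement probability (study design: 0.5). Under
#'   the exact-count default, `p_reward * n_reps` must be an integer.
#' @param seed integer seed; equal seeds give identical schedules.
#' @param bernoulli draw CS+ outcomes i.i.d. instead of exact-count.
#' @return A schedule `data.frame` (phase, trial, orientation_deg, outcome,
#'   response, valid) with the `stimulus_spec` attached as an attribute.
#' @export
#' @examples
#' sch <- make_training_schedule(stimulus_spec(), n_reps = 10, seed = 1)
#' table(sch$orientation_deg, sch$outcome)
make_training_schedule <- function(spec, n_reps = 100, p_reward = 0.5,
                                   seed = 1L, bernoulli = FALSE) {
  stopifnot(inherits(spec, "stimulus_spec"), n_reps >= 1,
            p_reward >= 0, p_reward <= 1)
  n_reps <- as.integer(n_reps)
  orientation <- c(rep(spec$cs_plus, n_reps), rep(spec$cs_minus, n_reps))
  if (bernoulli) {
    outcome <- with_seed(derive_seed(seed, 1L),
                         c(rbinom(n_reps, 1L, p_reward), integer(n_reps)))
  } else {
    n_rew <- p_reward * n_reps
    if (abs(n_rew - round(n_rew)) > 1e-8)
      stop(sprintf(paste0("p_reward * n_reps = %g is not an integer; ",
                          "exact-count reinforcement needs a whole number of ",
                          "rewarded CS+ trials (use bernoulli = TRUE for ",
                          "i.i.d. outcomes)"), n_rew))
    n_rew <- as.integer(round(n_rew))
    outcome <- c(rep(1L, n_rew), rep(0L, n_reps - n_rew), rep(0L, n_reps))
  }
  ord <- with_seed(seed, sample.int(2L * n_reps))
  new_schedule("training", orientation[ord], outcome[ord], spec, seed)
}

#' Generate a generalization-test schedule (extinction)
#'
#' Each test orientation is presented exactly `n_reps_test` times in seeded
#' pseudorandom order and no outcome is ever delivered (all outcomes 0):
#' the test runs in extinction, so the model's prediction errors during the
#' test equal minus the current expected value.
#'
#' @inheritParams make_training_schedule
#' @param n_reps_test presentations per orientation (study design: 14).
#' @return A schedule `data.frame`; see [make_training_schedule()].
#' @export
#' @examples
#' sch <- make_test_schedule(stimulus_spec(), n_reps_test = 2, seed = 1)
#' nrow(sch)  # 15 orientations x 2
make_test_schedule <- function(spec, n_reps_test = 14, seed = 1L) {
  stopifnot(inherits(spec, "stimulus_spec"), n_reps_test >= 1)
  if (length(spec$test_orientations) == 0L)
    stop("spec has no test orientations")
  n_reps_test <- as.integer(n_reps_test)
  orientation <- rep(spec$test_orientations, each = n_reps_test)
  ord <- with_seed(seed, sample.int(length(orientation)))
  new_schedule("test", orientation[ord], 0L, spec, seed)
}

#' Map orientations onto the canonical counterbalance axis
#'
#' Counterbalanced subjects have their CS+ at either 39 or 51 degrees. To
#' aggregate gradients across subjects, orientations are reflected about the
#' CS+/CS- midpoint whenever `cs_plus > cs_minus`, so that on the canonical
#' axis the CS+ always lies on the low side. Applying the function twice with
#' the CS roles swapped recovers the input.
#'
#' @param orientations numeric vector of orientations (degrees).
#' @param spec a [stimulus_spec()] defining the subject's CS+ and CS-.
#' @return Numeric vector of canonical orientations.
#' @export
#' @examples
#' mirror_normalize(c(17, 73), stimulus_spec(cs_plus = 51, cs_minus = 39))
mirror_normalize <- function(orientations, spec) {
  stopifnot(inherits(spec, "stimulus_spec"), is.numeric(orientations))
  if (spec$cs_plus > spec$cs_minus) {
    (spec$cs_plus + spec$cs_minus) - orientations
  } else {
    orientations
  }
}
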