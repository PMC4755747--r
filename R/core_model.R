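#' Model parameters for similarity-based generalization
#'
#' The model has six free parameters: the widths `s_i` and `s_e` (degrees) of
#' the inhibitory and excitatory similarity kernels, the slope `beta` and
#' offset `offset_a` of the logistic response rule, and separate learning
#' rates for the training phase (`alpha_train`, with feedback) and the test
#' phase (`alpha_test`, extinction). The similarity kernel is either
#' `"gaussian"` or `"exponential"`.
#'
#' @param s_i inhibitory kernel width, degrees, > 0.
#' @param s_e excitatory kernel width, degrees, > 0.
#' @param beta logistic slope, > 0.
#' @param offset_a logistic offset (value units at which P(+) = 0.5).
#' @param alpha_train learning rate during training, in \[0, 1\].
#' @param alpha_test learning rate during test, in \[0, 1\].
#' @param kernel similarity kernel form.
#' @return An object of class `model_params`.
#' @export
#' @examples
#' model_params(s_i = 20.121, s_e = 17.599, beta = 3.093, offset_a = 0.370,
#'              alpha_train = 0.1, alpha_test = 0.002)
model_params <- function(s_i, s_e, beta, offset_a, alpha_train, alpha_test,
                         kernel = c("gaussian", "exponential")) {
  kernel <- match.arg(kernel)
  vals <- c(s_i = s_i, s_e = s_e, beta = beta, offset_a = offset_a,
            alpha_train = alpha_train, alpha_test = alpha_test)
  if (!all(is.finite(vals))) stop("all parameters must be finite")
  if (s_i <= 0 || s_e <= 0) stop("kernel widths must be positive")
  if (beta <= 0) stop("beta must be positive")
  if (alpha_train < 0 || alpha_train > 1 || alpha_test < 0 || alpha_test > 1)
    stop("learning rates must lie in [0, 1]")
  structure(list(s_i = s_i, s_e = s_e, beta = beta, offset_a = offset_a,
                 alpha_train = alpha_train, alpha_test = alpha_test,
                 kernel = kernel),
            class = "model_params")
}

#' @export
print.model_params <- function(x, ...) {
  cat(sprintf(paste0("Model parameters (%s kernel)\n",
                     "  s_i = %.4g  s_e = %.4g  beta = %.4g  a = %.4g\n",
                     "  alpha_train = %.4g  alpha_test = %.4g\n"),
              x$kernel, x$s_i, x$s_e, x$beta, x$offset_a,
              x$alpha_train, x$alpha_test))
  invisible(x)
}

#' Similarity (generalization) coefficient between two orientations
#'
#' How strongly an association at one orientation contributes to the value of
#' another, as a function of their distance. The Gaussian form is
#' `exp(-d^2 / (2 s^2))`; the exponential form is `exp(-d / (2 s^2))`. Both
#' equal 1 at zero distance and decrease strictly with distance.
#'
#' @param distance absolute orientation difference, degrees, >= 0.
#' @param width kernel width `s`, degrees, > 0.
#' @param kernel `"gaussian"` or `"exponential"`.
#' @return Coefficient in (0, 1].
#' @export
#' @examples
#' generalization_coefficient(12, 17.599)              # CS+ to CS- distance
#' generalization_coefficient(12, 17.599, "exponential")
generalization_coefficient <- function(distance, width,
                                       kernel = c("gaussian", "exponential")) {
  kernel <- match.arg(kernel)
  if (any(width <= 0)) stop("width must be positive")
  if (any(distance < 0)) stop("distance must be non-negative")
  switch(kernel,
         gaussian = exp(-distance^2 / (2 * width^2)),
         exponential = exp(-distance / (2 * width^2)))
}

#' Create an associative state
#'
#' Association strengths are stored at an explicit set of orientations; a
#' freshly created state holds zero excitatory and inhibitory strength
#' everywhere (equivalently, orientations never presented carry no
#' associations). Strengths can only grow over trials.
#'
#' @param orientations orientations (degrees) at which strengths are tracked.
#' @param E,I optional initial strengths (non-negative, same length).
#' @return An object of class `assoc_state` with fields `orientation`, `E`,
#'   `I`.
#' @export
assoc_state <- function(orientations = numeric(), E = NULL, I = NULL) {
  orientations <- as.numeric(orientations)
  if (anyDuplicated(orientations)) stop("duplicate orientations in state")
  n <- length(orientations)
  if (is.null(E)) E <- numeric(n)
  if (is.null(I)) I <- numeric(n)
  stopifnot(length(E) == n, length(I) == n)
  if (any(E < 0) || any(I < 0)) stop("association strengths must be >= 0")
  structure(list(orientation = orientations, E = as.numeric(E),
                 I = as.numeric(I)),
            class = "assoc_state")
}

#' Net associative strength of an orientation
#'
#' Sums, over every orientation holding associations, the excitatory strength
#' weighted by the excitatory similarity coefficient minus the inhibitory
#' strength weighted by the inhibitory coefficient. An empty state yields 0.
#'
#' @param state an [assoc_state()].
#' @param params a [model_params()].
#' @param x_k probed orientation, degrees.
#' @return Net value `V` (scalar).
#' @export
net_value <- function(state, params, x_k) {
  stopifnot(inherits(state, "assoc_state"), inherits(params, "model_params"))
  if (length(state$orientation) == 0L) return(0)
  d <- abs(state$orientation - x_k)
  eS <- generalization_coefficient(d, params$s_e, params$kernel)
  iS <- generalization_coefficient(d, params$s_i, params$kernel)
  sum(state$E * eS - state$I * iS)
}

#' Reward prediction error
#'
#' `delta = R - V`. During the extinction test no outcome is delivered
#' (`R = 0`), so `delta = -V`: prediction errors are perfectly negatively
#' related to the expected value.
#'
#' @param R scheduled outcome (0 or 1).
#' @param V net associative strength.
#' @return Prediction error.
#' @export
prediction_error <- function(R, V) R - V

#' Update association strengths at the presented orientation
#'
#' A positive prediction error increments the excitatory strength of the
#' presented orientation by `alpha * delta`; a negative one increments its
#' inhibitory strength by `alpha * |delta|`. No other orientation is touched
#' and a zero prediction error changes nothing, so both strengths are
#' non-decreasing over trials.
#'
#' @param state an [assoc_state()].
#' @param k presented orientation, degrees (added to the state if new).
#' @param delta prediction error.
#' @param alpha learning rate in \[0, 1\].
#' @return The updated `assoc_state`.
#' @export
apply_update <- function(state, k, delta, alpha) {
  stopifnot(inherits(state, "assoc_state"), alpha >= 0, alpha <= 1)
  i <- match(k, state$orientation)
  if (is.na(i)) {
    state$orientation <- c(state$orientation, k)
    state$E <- c(state$E, 0)
    state$I <- c(state$I, 0)
    i <- length(state$orientation)
  }
  if (delta > 0) state$E[i] <- state$E[i] + alpha * delta
  else if (delta < 0) state$I[i] <- state$I[i] - alpha * delta
  state
}

#' Probability of an approach ("+") response
#'
#' Logistic (softmax) read-out of the net value:
#' `P(+) = 1 / (1 + exp(-beta * (V - a)))`. Equals 0.5 exactly at `V = a` and
#' increases strictly in `V`.
#'
#' @param V net associative strength.
#' @param beta slope, > 0.
#' @param offset_a offset.
#' @return Probability in (0, 1).
#' @export
response_probability <- function(V, beta, offset_a) {
  if (any(beta <= 0)) stop("beta must be positive")
  plogis(beta * (V - offset_a))
}

#' Run the model through a trial sequence
#'
#' Iterates the model over an ordered trial table: computes the net value `V`
#' of the presented orientation, the response probability `P(+)`, the
#' prediction error against the scheduled outcome, and the learning update
#' (with `alpha_train` on training-phase trials and `alpha_test` on
#' test-phase trials, where outcomes are uniformly 0).
#'
#' In `"likelihood"` mode the observed responses are scored: each valid trial
#' contributes `log P(+)` for a `"plus"` response and `log(1 - P(+))`
#' otherwise (responses are reduced to plus vs not-plus; `"unsure"` counts as
#' not-plus unless `unsure_policy = "exclude"`). Invalid (missed) trials
#' never contribute a likelihood term but by default still drive the value
#' computation and update, since the stimulus and outcome were experienced;
#' `update_invalid = FALSE` skips their updates. `likelihood_phases`
#' restricts which phases contribute terms (state updates always run).
#'
#' In `"generative"` mode responses are sampled (`"plus"` with probability
#' `P(+)`, else `"minus"`), deterministically for a given `seed`. Responses
#' never feed back into learning, so the value trace is identical across
#' modes for identical schedules.
#'
#' @param params a [model_params()].
#' @param trials a schedule `data.frame` as produced by
#'   [make_training_schedule()] / [make_test_schedule()] (possibly
#'   row-bound), with columns phase, orientation_deg, outcome, response,
#'   valid.
#' @param mode `"likelihood"` or `"generative"`.
#' @param seed seed for generative sampling.
#' @param init_state optional [assoc_state()] carried in (e.g. from a
#'   preceding training run).
#' @param likelihood_phases phases whose valid trials enter the total
#'   log-likelihood.
#' @param unsure_policy score `"unsure"` responses as not-plus or exclude
#'   them from the likelihood.
#' @param update_invalid run learning updates on invalid trials.
#' @return A list with `evaluations` (data.frame: trial, phase,
#'   orientation_deg, V, p_plus, delta, loglik_term), `total_loglik`,
#'   `state` (final [assoc_state()]), and in generative mode `trials` (the
#'   input schedule with responses filled in).
#' @export
run_trials <- function(params, trials,
                       mode = c("likelihood", "generative"),
                       seed = NULL, init_state = NULL,
                       likelihood_phases = c("training", "test"),
                       unsure_policy = c("not_plus", "exclude"),
                       update_invalid = TRUE) {
  mode <- match.arg(mode)
  unsure_policy <- match.arg(unsure_policy)
  stopifnot(inherits(params, "model_params"), is.data.frame(trials))
  n <- nrow(trials)
  if (n == 0L) {
    return(list(evaluations = data.frame(trial = integer(), phase = character(),
                                         orientation_deg = numeric(),
                                         V = numeric(), p_plus = numeric(),
                                         delta = numeric(),
                                         loglik_term = numeric()),
                total_loglik = 0,
                state = if (is.null(init_state)) assoc_state() else init_state))
  }
  if (is.null(init_state)) init_state <- assoc_state()
  grid <- sort(unique(c(init_state$orientation, trials$orientation_deg)))
  E0 <- I0 <- numeric(length(grid))
  if (length(init_state$orientation)) {
    idx <- match(init_state$orientation, grid)
    E0[idx] <- init_state$E
    I0[idx] <- init_state$I
  }
  ori <- match(trials$orientation_deg, grid) - 1L
  is_test <- as.integer(trials$phase == "test")
  valid <- trials$valid
  generative <- mode == "generative"

  if (generative) {
    resp_plus <- rep(NA_integer_, n)
    u <- if (is.null(seed)) runif(n) else with_seed(seed, runif(n))
    lik_include <- integer(n)
  } else {
    resp <- trials$response
    if (any(valid & (is.na(resp) | resp == "missing")))
      stop("likelihood mode requires an observed response on every valid trial")
    resp_plus <- ifelse(resp == "plus", 1L, 0L)
    resp_plus[is.na(resp)] <- NA_integer_
    lik_include <- as.integer(valid & trials$phase %in% likelihood_phases)
    if (unsure_policy == "exclude")
      lik_include[!is.na(resp) & resp == "unsure"] <- 0L
    u <- numeric(0)
  }
  do_update <- if (update_invalid) rep(1L, n) else as.integer(valid)

  out <- run_trials_cpp(ori, grid, as.numeric(trials$outcome), is_test,
                        resp_plus, lik_include, do_update,
                        params$s_i, params$s_e, params$beta, params$offset_a,
                        params$alpha_train, params$alpha_test,
                        as.integer(params$kernel == "exponential"),
                        E0, I0, generative, u)
  evaluations <- data.frame(trial = trials$trial, phase = trials$phase,
                            orientation_deg = trials$orientation_deg,
                            V = out$V, p_plus = out$p_plus,
                            delta = out$delta, loglik_term = out$loglik_term)
  res <- list(evaluations = evaluations,
              total_loglik = out$total_loglik,
              state = assoc_state(grid, out$E, out$I))
  if (generative) {
    filled <- trials
    filled$response <- ifelse(out$resp_plus == 1L, "plus", "minus")
    filled$response[!valid] <- "missing"
    res$trials <- filled
  }
  res
}
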