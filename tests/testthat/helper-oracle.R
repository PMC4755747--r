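# Independent, naive per-trial trace of the generalization model, kept
# deliberately separate from the package implementation: associations in a
# named vector, explicit loops, likelihood via plogis. Used to cross-check
# run_trials and the pooled objective.

oracle_similarity <- function(d, s, kernel) {
  if (kernel == "gaussian") exp(-d^2 / (2 * s^2)) else exp(-d / (2 * s^2))
}

oracle_trace <- function(params, trials,
                         likelihood_phases = c("training", "test"),
                         update_invalid = TRUE) {
  E <- I <- numeric(0)  # named by orientation
  n <- nrow(trials)
  V <- p <- delta <- ll <- rep(NA_real_, n)
  total <- 0
  for (t in seq_len(n)) {
    x <- trials$orientation_deg[t]
    v <- 0
    for (nm in names(E)) {
      d <- abs(as.numeric(nm) - x)
      v <- v + E[[nm]] * oracle_similarity(d, params$s_e, params$kernel) -
        I[[nm]] * oracle_similarity(d, params$s_i, params$kernel)
    }
    z <- params$beta * (v - params$offset_a)
    p[t] <- plogis(z)
    if (trials$valid[t] && trials$phase[t] %in% likelihood_phases) {
      ll[t] <- if (trials$response[t] == "plus") plogis(z, log.p = TRUE)
               else plogis(-z, log.p = TRUE)
      total <- total + ll[t]
    }
    dl <- trials$outcome[t] - v
    if (update_invalid || trials$valid[t]) {
      alpha <- if (trials$phase[t] == "test") params$alpha_test
               else params$alpha_train
      key <- as.character(x)
      if (!key %in% names(E)) {
        E[key] <- 0
        I[key] <- 0
      }
      if (dl > 0) E[key] <- E[key] + alpha * dl
      else if (dl < 0) I[key] <- I[key] - alpha * dl
    }
    V[t] <- v
    delta[t] <- dl
  }
  list(V = V, p_plus = p, delta = delta, loglik_term = ll, total = total,
       E = E, I = I)
}

# Random short schedule with responses, for oracle-equivalence checks.
random_trials <- function(n = 20, seed = 1) {
  withr_seed <- function(code) {
    old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      get(".Random.seed", envir = globalenv()) else NULL
    on.exit(if (!is.null(old)) assign(".Random.seed", old, envir = globalenv()))
    set.seed(seed)
    code
  }
  withr_seed({
    phase <- sample(c("training", "test"), n, replace = TRUE)
    data.frame(
      phase = phase,
      trial = seq_len(n),
      orientation_deg = sample(seq(17, 73, by = 4), n, replace = TRUE),
      outcome = ifelse(phase == "test", 0L, rbinom(n, 1L, 0.5)),
      response = sample(c("plus", "minus", "unsure"), n, replace = TRUE),
      valid = runif(n) > 0.1,
      stringsAsFactors = FALSE)
  })
}

random_params <- function(seed = 1, kernel = NULL) {
  set.seed(seed)
  model_params(s_i = runif(1, 5, 60), s_e = runif(1, 5, 60),
               beta = runif(1, 0.5, 10), offset_a = runif(1, -0.5, 1),
               alpha_train = runif(1, 0.01, 0.8),
               alpha_test = runif(1, 1e-4, 0.2),
               kernel = if (is.null(kernel))
                 sample(c("gaussian", "exponential"), 1) else kernel)
}
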