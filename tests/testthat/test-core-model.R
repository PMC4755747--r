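pa_like <- function(kernel = "gaussian")
  model_params(s_i = 20.121, s_e = 17.599, beta = 3.093, offset_a = 0.370,
               alpha_train = 0.2, alpha_test = 0.002, kernel = kernel)

test_that("generalization coefficients match their closed forms", {
  # identity at zero distance, both kernels
  expect_equal(generalization_coefficient(0, 17.599), 1)
  expect_equal(generalization_coefficient(0, 17.599, "exponential"), 1)
  # gaussian at distance == width is exp(-1/2)
  expect_equal(generalization_coefficient(17.599, 17.599),
               0.6065306597126334, tolerance = 1e-12)
  # CS+/CS- distance at a typical excitatory width
  expect_equal(generalization_coefficient(12, 24.584),
               exp(-144 / (2 * 24.584^2)), tolerance = 1e-12)
  # exponential kernel uses distance (not squared) over 2 s^2
  expect_equal(generalization_coefficient(12, 24.584, "exponential"),
               exp(-12 / (2 * 24.584^2)), tolerance = 1e-12)
  # strictly decreasing in distance
  d <- seq(0, 60, by = 4)
  for (k in c("gaussian", "exponential"))
    expect_true(all(diff(generalization_coefficient(d, 20, k)) < 0))
  expect_error(generalization_coefficient(5, 0), "positive")
})

test_that("net value aggregates kernel-weighted associations", {
  p <- pa_like()
  expect_equal(net_value(assoc_state(), p, 45), 0)
  s1 <- assoc_state(39, E = 1, I = 0)
  expect_equal(net_value(s1, p, 39), 1)
  s2 <- assoc_state(c(39, 51), E = c(1, 0), I = c(0, 1))
  expected <- exp(-36 / (2 * 17.599^2)) - exp(-36 / (2 * 20.121^2))
  expect_equal(net_value(s2, p, 45), expected, tolerance = 1e-12)
})

test_that("prediction error and update rule follow the two-branch form", {
  expect_equal(prediction_error(1, 0), 1)
  expect_equal(prediction_error(0, 0.4), -0.4)
  # in extinction (R = 0) the error is minus the expected value
  expect_equal(prediction_error(0, 0.73), -0.73)

  s <- assoc_state(39)
  expect_identical(apply_update(s, 39, 0, 0.5), s)
  s1 <- apply_update(s, 39, 1, 0.1)
  expect_equal(s1$E, 0.1)
  expect_equal(s1$I, 0)
  s2 <- apply_update(s, 39, -0.5, 0.002)
  expect_equal(s2$I, 0.001)
  expect_equal(s2$E, 0)
  # only the presented orientation is touched
  s3 <- apply_update(assoc_state(c(39, 51), E = c(1, 2), I = c(3, 4)),
                     51, 1, 0.5)
  expect_equal(s3$E, c(1, 2.5))
  expect_equal(s3$I, c(3, 4))
})

test_that("response probability is a logistic in V", {
  expect_equal(response_probability(0.37, 3.093, 0.37), 0.5)
  expect_equal(response_probability(1, 3.093, 0.370),
               1 / (1 + exp(-3.093 * 0.630)), tolerance = 1e-12)
  expect_equal(response_probability(1e6, 3.093, 0.37), 1)
  v <- seq(-2, 2, by = 0.1)
  expect_true(all(diff(response_probability(v, 2, 0)) > 0))
  expect_error(response_probability(0, -1, 0), "positive")
})

test_that("run_trials matches the independent naive trace", {
  # hand-size deterministic check first
  p <- pa_like()
  trials <- random_trials(10, seed = 42)
  orc <- oracle_trace(p, trials)
  run <- run_trials(p, trials, mode = "likelihood")
  expect_equal(run$evaluations$V, orc$V, tolerance = 1e-10)
  expect_equal(run$evaluations$p_plus, orc$p_plus, tolerance = 1e-10)
  expect_equal(run$evaluations$delta, orc$delta, tolerance = 1e-10)
  expect_equal(run$total_loglik, orc$total, tolerance = 1e-10)
  # final state agrees with the named-vector bookkeeping
  for (nm in names(orc$E)) {
    i <- match(as.numeric(nm), run$state$orientation)
    expect_equal(run$state$E[i], unname(orc$E[nm]), tolerance = 1e-12)
    expect_equal(run$state$I[i], unname(orc$I[nm]), tolerance = 1e-12)
  }
})

test_that("empty and single-trial schedules behave as forced", {
  p <- pa_like()
  empty <- run_trials(p, random_trials(5)[0, ], mode = "likelihood")
  expect_equal(empty$total_loglik, 0)
  expect_equal(nrow(empty$evaluations), 0)

  one <- data.frame(phase = "training", trial = 1L, orientation_deg = 39,
                    outcome = 1L, response = "plus", valid = TRUE,
                    stringsAsFactors = FALSE)
  run <- run_trials(p, one, mode = "likelihood")
  expect_equal(run$evaluations$V, 0)
  expect_equal(run$evaluations$p_plus,
               response_probability(0, p$beta, p$offset_a))
  expect_equal(run$evaluations$delta, 1)
})

test_that("invalid trials update state but contribute no likelihood", {
  p <- pa_like()
  trials <- random_trials(20, seed = 5)
  trials$valid[c(3, 11)] <- FALSE
  run <- run_trials(p, trials, mode = "likelihood")
  expect_true(all(is.na(run$evaluations$loglik_term[c(3, 11)])))
  orc <- oracle_trace(p, trials)
  expect_equal(run$total_loglik, orc$total, tolerance = 1e-10)
  # with update_invalid = FALSE the skipped trials leave no trace on state
  run2 <- run_trials(p, trials, mode = "likelihood", update_invalid = FALSE)
  orc2 <- oracle_trace(p, trials, update_invalid = FALSE)
  expect_equal(run2$evaluations$V, orc2$V, tolerance = 1e-10)
  expect_false(isTRUE(all.equal(run$evaluations$V, run2$evaluations$V)))
})

test_that("unsure responses score as not-plus by default, excludable", {
  p <- pa_like()
  trials <- random_trials(20, seed = 6)
  run_incl <- run_trials(p, trials, mode = "likelihood")
  run_excl <- run_trials(p, trials, mode = "likelihood",
                         unsure_policy = "exclude")
  unsure <- which(trials$response == "unsure" & trials$valid)
  expect_gt(length(unsure), 0)
  expect_true(all(is.na(run_excl$evaluations$loglik_term[unsure])))
  expect_equal(run_excl$total_loglik,
               run_incl$total_loglik -
                 sum(run_incl$evaluations$loglik_term[unsure]),
               tolerance = 1e-10)
})

test_that("likelihood and generative modes share the identical value trace", {
  p <- random_params(3)
  spec <- stimulus_spec()
  sch <- rbind(make_training_schedule(spec, 10, 0.5, seed = 1),
               make_test_schedule(spec, 2, seed = 2))
  gen <- run_trials(p, sch, mode = "generative", seed = 99)
  expect_true(all(gen$trials$response %in% c("plus", "minus")))
  lik <- run_trials(p, gen$trials, mode = "likelihood")
  expect_equal(gen$evaluations$V, lik$evaluations$V)
  expect_equal(gen$evaluations$p_plus, lik$evaluations$p_plus)
  expect_equal(gen$evaluations$delta, lik$evaluations$delta)
  expect_identical(gen$state, lik$state)
  # seeded determinism
  gen2 <- run_trials(p, sch, mode = "generative", seed = 99)
  expect_identical(gen$trials, gen2$trials)
})

test_that("kernel-width limits kill or saturate generalization", {
  spec <- stimulus_spec()
  sch <- make_training_schedule(spec, 10, 0.5, seed = 1)
  narrow <- model_params(s_i = 1e-3, s_e = 1e-3, beta = 2, offset_a = 0,
                         alpha_train = 0.3, alpha_test = 0.1)
  run <- run_trials(narrow, sch, mode = "generative", seed = 1)
  # never-presented orientation receives nothing
  expect_equal(net_value(run$state, narrow, 45), 0, tolerance = 1e-10)
  wide <- model_params(s_i = 1e6, s_e = 1e6, beta = 2, offset_a = 0,
                       alpha_train = 0.3, alpha_test = 0.1)
  runw <- run_trials(wide, sch, mode = "generative", seed = 1)
  expect_equal(net_value(runw$state, wide, 45),
               sum(runw$state$E) - sum(runw$state$I), tolerance = 1e-8)
})

test_that("value traces are invariant to reflecting the orientation axis", {
  p <- random_params(11)
  trials <- random_trials(30, seed = 12)
  reflected <- trials
  reflected$orientation_deg <- 90 - trials$orientation_deg
  a <- run_trials(p, trials, mode = "likelihood")
  b <- run_trials(p, reflected, mode = "likelihood")
  expect_equal(a$evaluations$V, b$evaluations$V, tolerance = 1e-12)
  expect_equal(a$total_loglik, b$total_loglik, tolerance = 1e-12)
})

test_that("association strengths never decrease over trials", {
  p <- random_params(21)
  trials <- random_trials(40, seed = 22)
  # track E/I after each prefix via the naive trace bookkeeping
  prev_E <- prev_I <- numeric(0)
  for (t in seq_len(nrow(trials))) {
    orc <- oracle_trace(p, trials[seq_len(t), ])
    for (nm in names(prev_E)) {
      expect_gte(orc$E[[nm]], prev_E[[nm]])
      expect_gte(orc$I[[nm]], prev_I[[nm]])
    }
    prev_E <- orc$E
    prev_I <- orc$I
  }
  expect_true(all(orc$E >= 0) && all(orc$I >= 0))
})
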