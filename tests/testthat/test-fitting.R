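# Small synthetic cohorts for fitting tests.
tiny_cohort <- function(n_subj = 3, n_reps = 10, n_reps_test = 2, seed = 1,
                        params = random_params(50, kernel = "gaussian")) {
  lapply(seq_len(n_subj), function(i)
    simulate_subject(params, stimulus_spec(), n_reps = n_reps,
                     p_reward = 0.5, n_reps_test = n_reps_test,
                     seed = seed * 100 + i,
                     subject_id = sprintf("S%02d", i),
                     group = if (i %% 2) "PA" else "PP"))
}

test_that("pooled objective equals per-subject oracle sums and is additive", {
  p <- random_params(7, kernel = "gaussian")
  cohort <- tiny_cohort(3, seed = 4)
  # independent per-subject traces, test phase scored
  oracle_total <- sum(vapply(cohort, function(s)
    oracle_trace(p, rbind(s$training, s$test),
                 likelihood_phases = "test")$total, numeric(1)))
  expect_equal(pooled_negative_loglik(p, cohort), -oracle_total,
               tolerance = 1e-10)
  # additivity over subjects, exactly
  parts <- vapply(cohort, function(s) pooled_negative_loglik(p, list(s)),
                  numeric(1))
  expect_equal(pooled_negative_loglik(p, cohort), sum(parts),
               tolerance = 1e-12)
})

test_that("a single maximally uncertain trial contributes log 2", {
  p <- model_params(s_i = 20, s_e = 20, beta = 2, offset_a = 0,
                    alpha_train = 0.1, alpha_test = 0.1)
  test <- make_test_schedule(stimulus_spec(), 1, seed = 1)[1, ]
  test$response <- "plus"
  subject <- structure(list(subject_id = "S1", group = "PA",
                            spec = stimulus_spec(),
                            training = test[0, ], test = test),
                       class = "subject_data")
  # empty state gives V = 0 and offset 0 gives p = 1/2
  expect_equal(pooled_negative_loglik(p, list(subject)), log(2),
               tolerance = 1e-12)
})

test_that("information criteria follow their closed forms", {
  ic0 <- information_criteria(0, 0, 1)
  expect_equal(ic0$aic, 0)
  expect_equal(ic0$bic, 0)
  ic <- information_criteria(-100, 5, exp(2))
  expect_equal(ic$aic, 210)
  expect_equal(ic$bic, 210)
  fitlike <- information_criteria(-2803.4, 5, 5250)
  expect_equal(fitlike$aic, 2 * 5 + 2 * 2803.4)
  expect_equal(fitlike$bic, 5 * log(5250) + 2 * 2803.4)
})

test_that("group fits are deterministic, order-invariant and improve on the
           generating parameters", {
  truth <- default_group_params("PA")
  cohort <- tiny_cohort(4, n_reps = 20, n_reps_test = 4, seed = 9,
                        params = truth)
  cfg <- fit_config(n_starts = 6, seed = 2, maxit = 150)
  fit1 <- fit_group(cohort, truth$alpha_train, "gaussian", cfg)
  fit2 <- fit_group(cohort, truth$alpha_train, "gaussian", cfg)
  expect_identical(fit1$params, fit2$params)
  expect_identical(fit1$pooled_LLE, fit2$pooled_LLE)
  fit3 <- fit_group(rev(cohort), truth$alpha_train, "gaussian", cfg)
  expect_equal(fit3$pooled_LLE, fit1$pooled_LLE, tolerance = 1e-9)
  # the optimum is at least as good as the generating parameters
  lle_truth <- -pooled_negative_loglik(truth, cohort)
  expect_gte(fit1$pooled_LLE, lle_truth - 1e-6)
  # FitResult invariants
  expect_equal(fit1$aic, 2 * fit1$n_free - 2 * fit1$pooled_LLE)
  expect_equal(fit1$bic, fit1$n_free * log(fit1$n_obs) - 2 * fit1$pooled_LLE)
  expect_equal(fit1$n_obs, sum(vapply(cohort, function(s)
    sum(s$test$valid), numeric(1))))
  b <- cfg$bounds
  expect_true(fit1$params$s_i >= b$s_i[1] && fit1$params$s_i <= b$s_i[2])
  expect_true(fit1$params$alpha_test >= b$alpha_test[1])
})

test_that("two-stage fitting recovers the training learning rate direction", {
  # agents that learn fast vs slow produce clearly different estimates when
  # training responses are scored (the direct source of alpha_train signal)
  fast <- model_params(s_i = 15, s_e = 15, beta = 8, offset_a = 0.4,
                       alpha_train = 0.6, alpha_test = 0.01)
  slow <- model_params(s_i = 15, s_e = 15, beta = 8, offset_a = 0.4,
                       alpha_train = 0.02, alpha_test = 0.01)
  cfg <- fit_config(n_starts = 5, seed = 3, maxit = 150,
                    likelihood_phases = c("training", "test"))
  coh_fast <- tiny_cohort(6, n_reps = 30, n_reps_test = 4, seed = 11,
                          params = fast)
  coh_slow <- tiny_cohort(6, n_reps = 30, n_reps_test = 4, seed = 12,
                          params = slow)
  a_fast <- fit_alpha_train(coh_fast, "gaussian", cfg)$alpha_train
  a_slow <- fit_alpha_train(coh_slow, "gaussian", cfg)$alpha_train
  expect_gt(a_fast, a_slow)
})

test_that("per-subject logistic slopes behave under calibration, null and
           degenerate inputs", {
  set.seed(31)
  p <- runif(400, 0.05, 0.95)
  calibrated <- rbinom(400, 1, p)
  expect_gt(per_subject_logistic(calibrated, p), 0)
  # responses independent of p: slopes centred on zero across replicates
  slopes <- replicate(40, {
    y <- rbinom(200, 1, 0.5)
    per_subject_logistic(y, runif(200, 0.05, 0.95))
  })
  expect_lt(abs(mean(slopes)), 3 * sd(slopes) / sqrt(length(slopes)) + 0.2)
  expect_warning(s <- per_subject_logistic(rbinom(50, 1, 0.5),
                                           rep(0.4, 50)),
                 "unidentifiable")
  expect_true(is.na(s))
  expect_warning(s2 <- per_subject_logistic(rep(1, 20), runif(20)),
                 "one response class")
  expect_true(is.na(s2))
  # perfect separation is flagged and non-finite
  ps <- c(runif(20, 0, 0.4), runif(20, 0.6, 1))
  ys <- rep(c(0, 1), each = 20)
  expect_warning(s3 <- per_subject_logistic(ys, ps), "separation")
  expect_false(is.finite(s3))
})

test_that("kernel comparison prefers the generating kernel on small cohorts", {
  cfg <- fit_config(n_starts = 4, seed = 6, maxit = 150)
  gauss_truth <- default_group_params("PA")
  coh <- tiny_cohort(6, n_reps = 30, n_reps_test = 6, seed = 21,
                     params = gauss_truth)
  kc <- compare_kernels(coh, cfg)
  expect_lt(kc$gaussian$aic, kc$exponential$aic)
  expect_equal(kc$delta_aic, kc$gaussian$aic - kc$exponential$aic)
  expect_equal(nrow(kc$slopes), 6)
  # identical data under both kernels of the paired test: difference of a
  # fit against itself is exactly zero
  d <- kc$slopes$gaussian - kc$slopes$gaussian
  expect_true(all(d == 0))
})
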