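# Cohorts for gradient/inference tests.
sim_group <- function(n, params, seed, n_reps = 30, n_reps_test = 6,
                      group = "PA", counterbalance = TRUE) {
  lapply(seq_len(n), function(i) {
    spec <- if (counterbalance && i %% 2 == 0)
      stimulus_spec(cs_plus = 51, cs_minus = 39) else stimulus_spec()
    simulate_subject(params, spec, n_reps = n_reps, p_reward = 0.5,
                     n_reps_test = n_reps_test, seed = seed * 1000 + i,
                     subject_id = sprintf("%s%02d", group, i), group = group)
  })
}

test_that("gradients aggregate counterbalanced subjects on one axis", {
  p <- default_group_params("PA")
  cohort <- sim_group(6, p, seed = 3)
  grad <- behavioral_gradient(cohort)
  expect_equal(grad$orientations, seq(17, 73, by = 4))
  expect_true(all(grad$per_subject$p_plus >= 0 &
                    grad$per_subject$p_plus <= 1))
  # per-subject trial counts sum to the subject's valid test trials
  counts <- tapply(grad$per_subject$n_trials, grad$per_subject$subject_id,
                   sum)
  expect_true(all(counts == 15 * 6))
  # trial order within a subject is irrelevant
  shuffled <- cohort
  perm <- sample(nrow(shuffled[[1]]$test))
  shuffled[[1]]$test <- shuffled[[1]]$test[perm, ]
  grad2 <- behavioral_gradient(shuffled)
  expect_equal(grad2$group_stats, grad$group_stats)
})

test_that("gradient limit cases: deterministic responder and all-plus", {
  p <- default_group_params("PA")
  subject <- sim_group(1, p, seed = 8)[[1]]
  # threshold responder: + iff V > a; with alpha_test = 0 the value of each
  # orientation is constant over the test, so responses are per-orientation
  # deterministic
  p0 <- model_params(p$s_i, p$s_e, p$beta, p$offset_a, p$alpha_train, 0)
  run <- run_trials(p0, rbind(subject$training, subject$test),
                    mode = "generative", seed = 1)
  ev <- run$evaluations[run$evaluations$phase == "test", ]
  det <- subject
  det$test$response <- ifelse(ev$V > p$offset_a, "plus", "minus")
  gdet <- behavioral_gradient(list(det))
  expect_true(all(gdet$per_subject$p_plus %in% c(0, 1)))
  allplus <- subject
  allplus$test$response <- "plus"
  gall <- behavioral_gradient(list(allplus))
  expect_true(all(gall$per_subject$p_plus == 1))
})

test_that("subjects with empty cells are excluded from that orientation's
           mean with a warning", {
  p <- default_group_params("PA")
  cohort <- sim_group(3, p, seed = 5)
  # knock out all valid trials at one orientation for one subject
  hit <- cohort[[1]]$test$orientation_deg == 45
  cohort[[1]]$test$valid[hit] <- FALSE
  expect_warning(grad <- behavioral_gradient(cohort), "no valid trials")
  st <- grad$group_stats
  expect_equal(st$n_subjects[st$orientation == 45], 2)
  expect_equal(st$n_subjects[st$orientation == 17], 3)
})

test_that("peak shift is positive for model agents and zero for flat
           responders", {
  p <- default_group_params("PA")
  cohort <- sim_group(8, p, seed = 13)
  ps <- peak_shift_statistic(cohort)
  expect_gt(ps$statistic, 0)
  expect_lt(ps$p_value, 0.05)
  flat <- lapply(cohort, function(s) {
    s$test$response <- "plus"
    s
  })
  expect_equal(peak_shift_statistic(flat)$mean_diff, 0)
  expect_error(peak_shift_statistic(cohort[1]), "2 subjects")
})

test_that("Pearson VII self-fit recovers noise-free parameters", {
  x <- seq(17, 73, by = 4)
  y <- pearson7_curve(x, amplitude = 0.62, mu = 36, sigma = 14, m = 4)
  fit <- fit_pearson7(data.frame(orientation = x, mean = y))
  expect_equal(fit$amplitude, 0.62, tolerance = 1e-4)
  expect_equal(fit$mu, 36, tolerance = 1e-4)
  expect_equal(fit$sigma, 14, tolerance = 1e-3)
  expect_equal(fit$m, 4, tolerance = 1e-3)
  expect_lt(fit$resnorm, 1e-12)
})

test_that("a Gaussian-shaped gradient drives the shape parameter to the
           large-m limit", {
  x <- seq(17, 73, by = 4)
  y <- 0.7 * exp(-(x - 40)^2 / (2 * 12^2))
  fit <- fit_pearson7(data.frame(orientation = x, mean = y))
  expect_gt(fit$m, 20)
  expect_equal(as.numeric(kurtosis_of_fit(fit)), 3, tolerance = 0.05)
  expect_error(fit_pearson7(data.frame(orientation = x, mean = rep(0.4, 15))),
               "flat gradient")
})

test_that("quadrature kurtosis matches the scaled Student-t closed form", {
  for (m in c(2.8, 3.5, 5, 12, 40)) {
    fit <- list(sigma = 11, m = m, mu = 45)
    nu <- 2 * m - 1
    closed <- 3 * (nu - 2) / (nu - 4)
    expect_equal(as.numeric(kurtosis_of_fit(fit)), closed,
                 tolerance = 0.01 * closed)
  }
  # Gaussian limit
  fit <- list(sigma = 30, m = 1000, mu = 45)
  expect_equal(as.numeric(kurtosis_of_fit(fit)), 3, tolerance = 0.01)
  # non-integrable fourth moment is flagged infinite
  k <- kurtosis_of_fit(list(sigma = 10, m = 2.2, mu = 45))
  expect_true(is.infinite(k))
  expect_false(attr(k, "finite"))
})

test_that("quadrature kurtosis matches Monte-Carlo sampling", {
  m <- 5
  nu <- 2 * m - 1
  set.seed(414)
  x <- 10 * rt(2e6, df = nu) / sqrt(nu)
  mc <- mean((x - mean(x))^4) / (mean((x - mean(x))^2))^2
  quad <- as.numeric(kurtosis_of_fit(list(sigma = 10, m = m)))
  expect_equal(quad, mc, tolerance = 0.01 * quad)
})

test_that("kurtosis permutation test: identical cohorts give zero observed
           difference and valid p-values", {
  # fixed parameter set with long training: group-mean gradients stay in
  # the finite-kurtosis regime, keeping the permutation fits stable
  p <- default_group_params("PP", alpha_train = 0.2)
  cohort <- sim_group(8, p, seed = 23, n_reps = 60, n_reps_test = 14)
  res <- permutation_test_kurtosis(cohort, cohort, n_perm = 19, seed = 1,
                                   sigma_starts = c(10, 40),
                                   m_starts = c(2, 15))
  expect_equal(res$observed, 0)
  expect_true(res$p_value > 0 && res$p_value <= 1)
  # reproducibility under a fixed seed
  res2 <- permutation_test_kurtosis(cohort, cohort, n_perm = 19, seed = 1,
                                    sigma_starts = c(10, 40),
                                    m_starts = c(2, 15))
  expect_identical(res$null, res2$null)
  expect_error(permutation_test_kurtosis(cohort, cohort, n_perm = 0),
               "n_perm")
})

test_that("parameter permutation test is reproducible and respects the
           p-value convention", {
  truth <- default_group_params("PP")
  a <- sim_group(4, truth, seed = 31, n_reps = 10, n_reps_test = 2)
  b <- sim_group(4, truth, seed = 32, n_reps = 10, n_reps_test = 2,
                 group = "PP")
  cfg <- fit_config(n_starts = 1, seed = 2, maxit = 50, factr = 1e9)
  res <- permutation_test_parameters(a, b, truth$alpha_train, n_perm = 9,
                                     seed = 5, config = cfg)
  expect_named(res$observed,
               c("s_i", "s_e", "beta", "offset_a", "alpha_test"))
  expect_equal(dim(res$null), c(9, 5))
  expect_true(all(res$p_value > 0 & res$p_value <= 1))
  expect_true(all(res$p_value %in% (1:10 / 10)))
  res2 <- permutation_test_parameters(a, b, truth$alpha_train, n_perm = 9,
                                      seed = 5, config = cfg)
  expect_identical(res$null, res2$null)
  expect_error(permutation_test_parameters(a, b, truth$alpha_train,
                                           n_perm = 0), "n_perm")
})

test_that("leave-one-out scores: homogeneous cohorts give near-zero scores,
           a planted outlier gets the maximal s_e score, and the jackknife
           roughly balances", {
  truth <- default_group_params("PP", alpha_train = 0.2)
  base <- sim_group(7, truth, seed = 41, n_reps = 30, n_reps_test = 6,
                    group = "PP")
  outlier_params <- model_params(s_i = truth$s_i, s_e = 2 * truth$s_e,
                                 beta = truth$beta,
                                 offset_a = truth$offset_a,
                                 alpha_train = truth$alpha_train,
                                 alpha_test = truth$alpha_test)
  outlier <- sim_group(1, outlier_params, seed = 99, n_reps = 30,
                       n_reps_test = 6, group = "PP")[[1]]
  outlier$subject_id <- "PP99"
  cohort <- c(base, list(outlier))
  cfg <- fit_config(n_starts = 3, seed = 7, maxit = 150)
  loo <- loo_parameter_scores(cohort, truth$alpha_train, "gaussian", cfg)
  sc <- loo$scores
  expect_equal(nrow(sc), 8)
  expect_equal(which.max(sc$s_e), which(sc$subject_id == "PP99"))
  # jackknife balance on the homogeneous members alone: scores roughly
  # cancel relative to their dispersion
  loo_base <- loo_parameter_scores(base, truth$alpha_train, "gaussian", cfg)
  se_scores <- loo_base$scores$s_e
  expect_lt(abs(sum(se_scores)), sqrt(length(se_scores)) * sd(se_scores))
  expect_error(loo_parameter_scores(cohort[1:2], 0.2), "3 subjects")
})
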