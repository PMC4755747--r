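#' Optimizer and likelihood configuration
#'
#' Settings for the pooled maximum-likelihood fits: parameter bounds,
#' number of multi-start repetitions, optimizer tolerances, and the
#' likelihood conventions (which phases are scored, how unsure responses
#' and invalid trials are treated). Kernel widths and learning rates are
#' searched on a log10 scale; starts are drawn log-uniformly for widths and
#' learning rates and uniformly for slope and offset.
#'
#' @param n_starts number of seeded optimizer starts.
#' @param seed seed for drawing starts.
#' @param bounds named list of `c(lower, upper)` per parameter.
#' @param maxit maximum L-BFGS-B iterations per start.
#' @param factr L-BFGS-B convergence factor (objective tolerance is
#'   `factr * .Machine$double.eps`, i.e. ~1e-9 relative at the default).
#' @param likelihood_phases phases whose responses enter the likelihood.
#'   The model is fit to responses during the generalization test; training
#'   trials shape the associative state but are not scored.
#' @param unsure_policy see [run_trials()].
#' @param update_invalid see [run_trials()].
#' @return A list of class `fit_config`.
#' @export
fit_config <- function(n_starts = 20, seed = 1L,
                       bounds = list(s_i = c(1, 100), s_e = c(1, 100),
                                     beta = c(0.1, 20), offset_a = c(-1, 2),
                                     alpha_train = c(1e-4, 1),
                                     alpha_test = c(1e-4, 1)),
                       maxit = 300, factr = 1e7,
                       likelihood_phases = "test",
                       unsure_policy = "not_plus",
                       update_invalid = TRUE) {
  structure(list(n_starts = as.integer(n_starts), seed = as.integer(seed),
                 bounds = bounds, maxit = maxit, factr = factr,
                 likelihood_phases = likelihood_phases,
                 unsure_policy = unsure_policy,
                 update_invalid = update_invalid),
            class = "fit_config")
}

# Parameters searched on log10 scale.
.log_scale <- c("s_i", "s_e", "alpha_train", "alpha_test")

.to_opt <- function(x, names) {
  x <- as.numeric(x)
  i <- names %in% .log_scale
  x[i] <- log10(x[i])
  x
}
.from_opt <- function(x, names) {
  x <- as.numeric(x)
  i <- names %in% .log_scale
  x[i] <- 10^x[i]
  x
}

# Precompute the per-subject vectors the C++ runner needs, so the objective
# avoids data.frame manipulation inside the optimizer loop.
prepare_subject <- function(subject, likelihood_phases, unsure_policy,
                            update_invalid) {
  trials <- rbind(subject$training, subject$test)
  resp <- trials$response
  valid <- trials$valid
  if (any(valid & (is.na(resp) | resp == "missing")))
    stop(sprintf("subject %s has valid trials without responses",
                 subject$subject_id))
  resp_plus <- ifelse(!is.na(resp) & resp == "plus", 1L, 0L)
  lik_include <- as.integer(valid & trials$phase %in% likelihood_phases)
  if (unsure_policy == "exclude")
    lik_include[!is.na(resp) & resp == "unsure"] <- 0L
  grid <- sort(unique(trials$orientation_deg))
  list(ori = match(trials$orientation_deg, grid) - 1L,
       grid = grid,
       R = as.numeric(trials$outcome),
       is_test = as.integer(trials$phase == "test"),
       resp_plus = resp_plus,
       lik_include = lik_include,
       do_update = if (update_invalid) rep(1L, nrow(trials))
                   else as.integer(valid),
       zero = numeric(length(grid)))
}

subject_loglik_prepared <- function(prep, params) {
  run_trials_cpp(prep$ori, prep$grid, prep$R, prep$is_test, prep$resp_plus,
                 prep$lik_include, prep$do_update,
                 params$s_i, params$s_e, params$beta, params$offset_a,
                 params$alpha_train, params$alpha_test,
                 as.integer(params$kernel == "exponential"),
                 prep$zero, prep$zero, FALSE, numeric(0))$total_loglik
}

#' Pooled negative log-likelihood of a cohort
#'
#' Sums the model's log-likelihood over subjects — each subject's
#' associative state starts fresh and is carried from their training phase
#' into their test phase — and returns the negative. Only responses on valid
#' trials in `likelihood_phases` are scored (default: the test phase, the
#' phase the model is fit to).
#'
#' @param params a [model_params()].
#' @param cohort list of subject data as produced by [simulate_cohort()] or
#'   [read_cohort()].
#' @param likelihood_phases,unsure_policy,update_invalid see [fit_config()].
#' @return The pooled negative log-likelihood (scalar).
#' @export
pooled_negative_loglik <- function(params, cohort,
                                   likelihood_phases = "test",
                                   unsure_policy = "not_plus",
                                   update_invalid = TRUE) {
  stopifnot(inherits(params, "model_params"))
  preps <- lapply(cohort, prepare_subject, likelihood_phases,
                  unsure_policy, update_invalid)
  -sum(vapply(preps, subject_loglik_prepared, numeric(1), params = params))
}

# Concatenate prepared subjects over a union orientation grid so the pooled
# objective is a single C++ call (state resets at subject boundaries).
concat_preps <- function(preps) {
  grid <- sort(unique(unlist(lapply(preps, `[[`, "grid"))))
  ori <- unlist(lapply(preps, function(p) match(p$grid, grid)[p$ori + 1L] - 1L))
  lens <- vapply(preps, function(p) length(p$ori), integer(1))
  list(ori = as.integer(ori), grid = grid,
       R = unlist(lapply(preps, `[[`, "R")),
       is_test = unlist(lapply(preps, `[[`, "is_test")),
       resp_plus = unlist(lapply(preps, `[[`, "resp_plus")),
       lik_include = unlist(lapply(preps, `[[`, "lik_include")),
       do_update = unlist(lapply(preps, `[[`, "do_update")),
       subj_start = c(0L, cumsum(lens)))
}

# Shared multi-start machinery: fits `free` parameters, holding the rest at
# `fixed`, by bounded L-BFGS-B from `n_starts` seeded starts.
fit_pooled <- function(cohort, free, fixed, kernel, config) {
  preps <- lapply(cohort, prepare_subject, config$likelihood_phases,
                  config$unsure_policy, config$update_invalid)
  fit_prepped(concat_preps(preps), free, fixed, kernel, config)
}

# Core fit on an already concatenated cohort (see concat_preps); `light`
# trims the per-start diagnostics, for use inside permutation loops.
fit_prepped <- function(cc, free, fixed, kernel, config, light = FALSE) {
  n_obs <- sum(cc$lik_include)
  if (n_obs < 1) stop("no valid likelihood trials in cohort")
  kernel_exp <- as.integer(kernel == "exponential")

  make_params <- function(theta) {
    vals <- as.list(.from_opt(theta, free))
    names(vals) <- free
    all <- modifyList(fixed, vals)
    model_params(all$s_i, all$s_e, all$beta, all$offset_a,
                 all$alpha_train, all$alpha_test, kernel)
  }
  pnames_all <- c("s_i", "s_e", "beta", "offset_a", "alpha_train",
                  "alpha_test")
  pv0 <- setNames(rep(NA_real_, 6L), pnames_all)
  pv0[names(fixed)] <- unlist(fixed)
  objective <- function(theta) {
    pv <- pv0
    pv[free] <- .from_opt(theta, free)
    pooled_nll_cpp(cc$ori, cc$grid, cc$R, cc$is_test, cc$resp_plus,
                   cc$lik_include, cc$do_update, cc$subj_start,
                   pv[[1L]], pv[[2L]], pv[[3L]], pv[[4L]],
                   pv[[5L]], pv[[6L]], kernel_exp)
  }
  lower <- .to_opt(vapply(config$bounds[free], `[`, numeric(1), 1L), free)
  upper <- .to_opt(vapply(config$bounds[free], `[`, numeric(1), 2L), free)
  starts <- with_seed(config$seed, {
    vapply(seq_len(config$n_starts), function(i)
      runif(length(free), lower, upper), numeric(length(free)))
  })
  starts <- matrix(starts, nrow = length(free))

  runs <- lapply(seq_len(config$n_starts), function(i) {
    res <- tryCatch(
      optim(starts[, i], objective, method = "L-BFGS-B",
            lower = lower, upper = upper,
            control = list(maxit = config$maxit, factr = config$factr)),
      error = function(e) list(par = starts[, i], value = Inf,
                               convergence = 99L, message = conditionMessage(e)))
    list(par = res$par, value = res$value, convergence = res$convergence,
         message = if (is.null(res$message)) "" else res$message)
  })
  values <- vapply(runs, `[[`, numeric(1), "value")
  if (all(!is.finite(values)))
    stop("all optimizer starts failed; see diagnostics")
  best <- which.min(values)  # ties: first start index
  diagnostics <- if (light) NULL else data.frame(
    start = seq_len(config$n_starts),
    objective = values,
    convergence = vapply(runs, `[[`, numeric(1), "convergence"),
    message = vapply(runs, `[[`, character(1), "message"),
    stringsAsFactors = FALSE)

  params <- make_params(runs[[best]]$par)
  lle <- -values[best]
  ic <- information_criteria(lle, length(free), n_obs)
  structure(list(params = params, pooled_LLE = lle, n_obs = n_obs,
                 n_free = length(free), aic = ic$aic, bic = ic$bic,
                 free = free, kernel = kernel,
                 diagnostics = diagnostics, best_start = best,
                 converged = runs[[best]]$convergence == 0),
            class = "gg_fit")
}

#' @export
print.gg_fit <- function(x, ...) {
  cat(sprintf("Pooled ML fit (%s kernel, %d free parameters, n = %d)\n",
              x$kernel, x$n_free, x$n_obs))
  cat(sprintf("  LLE = %.3f   AIC = %.1f   BIC = %.1f\n",
              x$pooled_LLE, x$aic, x$bic))
  print(x$params)
  invisible(x)
}

#' Estimate the training learning rate on the full sample
#'
#' First stage of the two-stage procedure: all six parameters are fit by
#' pooled maximum likelihood on the combined cohort (both groups), and the
#' training learning rate is read off, to be held fixed in the group-wise
#' fits (both groups were drug-free during training, so a common training
#' learning rate is assumed).
#'
#' @param cohort combined cohort (both groups).
#' @param kernel similarity kernel form.
#' @param config a [fit_config()].
#' @return A list with `alpha_train` and the full `gg_fit` object.
#' @export
fit_alpha_train <- function(cohort, kernel = "gaussian",
                            config = fit_config()) {
  fit <- fit_pooled(cohort,
                    free = c("s_i", "s_e", "beta", "offset_a",
                             "alpha_train", "alpha_test"),
                    fixed = list(), kernel = kernel, config = config)
  list(alpha_train = fit$params$alpha_train, fit = fit)
}

#' Group-wise pooled maximum-likelihood fit
#'
#' Second stage: with the training learning rate fixed at its full-sample
#' estimate, the remaining five parameters (`s_i`, `s_e`, `beta`,
#' `offset_a`, `alpha_test`) are fit to one group's pooled likelihood by
#' bounded multi-start optimization.
#'
#' @param cohort the group's subjects.
#' @param fixed_alpha_train training learning rate, in \[0, 1\].
#' @param kernel similarity kernel form.
#' @param config a [fit_config()].
#' @return A `gg_fit`: fitted [model_params()], pooled log-likelihood,
#'   `n_obs`, AIC/BIC, and per-start optimizer diagnostics.
#' @export
fit_group <- function(cohort, fixed_alpha_train, kernel = "gaussian",
                      config = fit_config()) {
  stopifnot(fixed_alpha_train >= 0, fixed_alpha_train <= 1)
  fit_pooled(cohort,
             free = c("s_i", "s_e", "beta", "offset_a", "alpha_test"),
             fixed = list(alpha_train = fixed_alpha_train),
             kernel = kernel, config = config)
}

#' Akaike and Bayesian information criteria
#'
#' `AIC = 2k - 2 LLE`; `BIC = k ln(n) - 2 LLE`, where `n` counts the valid
#' trials entering the likelihood.
#'
#' @param pooled_LLE pooled log-likelihood at the optimum.
#' @param n_free number of free parameters `k`.
#' @param n_obs number of likelihood observations `n` (>= 1).
#' @return List with `aic` and `bic`.
#' @export
information_criteria <- function(pooled_LLE, n_free, n_obs) {
  stopifnot(n_obs >= 1)
  list(aic = 2 * n_free - 2 * pooled_LLE,
       bic = n_free * log(n_obs) - 2 * pooled_LLE)
}

#' Logistic regression of observed responses on modelled P(+)
#'
#' Per-subject goodness-of-fit check: the slope from a logistic regression
#' (with intercept) of the observed binary responses on the model's
#' trial-by-trial response probabilities. A positive slope means the model's
#' probabilities track the subject's behaviour.
#'
#' @param observed logical or 0/1 vector ("+" responses).
#' @param p_plus modelled response probabilities, same length.
#' @return The slope coefficient. Degenerate inputs (one response class or
#'   constant `p_plus`) and perfect separation are flagged with a warning
#'   and yield a non-finite slope.
#' @export
per_subject_logistic <- function(observed, p_plus) {
  observed <- as.numeric(observed)
  stopifnot(length(observed) == length(p_plus),
            all(observed %in% c(0, 1)))
  if (length(unique(observed)) < 2L) {
    warning("only one response class observed; slope unidentifiable")
    return(NA_real_)
  }
  if (isTRUE(all.equal(min(p_plus), max(p_plus)))) {
    warning("constant modelled p_plus; slope unidentifiable")
    return(NA_real_)
  }
  separated <- FALSE
  fit <- withCallingHandlers(
    glm(observed ~ p_plus, family = binomial()),
    warning = function(w) {
      if (grepl("fitted probabilities numerically 0 or 1", conditionMessage(w)))
        separated <<- TRUE
      invokeRestart("muffleWarning")
    })
  slope <- unname(coef(fit)[2L])
  if (separated || !fit$converged) {
    warning("separation or non-convergence in per-subject logistic regression")
    return(sign(slope) * Inf)
  }
  slope
}

#' Compare Gaussian and exponential similarity kernels
#'
#' Fits both kernel forms to the combined cohort (all six parameters free),
#' compares them by AIC/BIC, and additionally by the per-subject logistic
#' regression slopes of observed test responses on each model's P(+),
#' summarized by a paired t-test across subjects.
#'
#' @param cohort combined cohort (both groups).
#' @param config a [fit_config()].
#' @return A list of class `kernel_comparison`: `gaussian` and `exponential`
#'   `gg_fit`s, a `slopes` data.frame (subject, group, slope per kernel),
#'   one-sample t-tests of each kernel's slopes against zero, and the paired
#'   test of the slope difference.
#' @export
compare_kernels <- function(cohort, config = fit_config()) {
  fits <- lapply(c("gaussian", "exponential"), function(kern)
    fit_pooled(cohort,
               free = c("s_i", "s_e", "beta", "offset_a",
                        "alpha_train", "alpha_test"),
               fixed = list(), kernel = kern, config = config))
  names(fits) <- c("gaussian", "exponential")

  slope_for <- function(subject, fit) {
    trials <- rbind(subject$training, subject$test)
    run <- run_trials(fit$params, trials, mode = "likelihood",
                      likelihood_phases = config$likelihood_phases,
                      unsure_policy = config$unsure_policy,
                      update_invalid = config$update_invalid)
    keep <- trials$valid & trials$phase == "test"
    suppressWarnings(
      per_subject_logistic(trials$response[keep] == "plus",
                           run$evaluations$p_plus[keep]))
  }
  slopes <- data.frame(
    subject_id = vapply(cohort, `[[`, character(1), "subject_id"),
    group = vapply(cohort, `[[`, character(1), "group"),
    gaussian = vapply(cohort, slope_for, numeric(1), fit = fits$gaussian),
    exponential = vapply(cohort, slope_for, numeric(1),
                         fit = fits$exponential),
    stringsAsFactors = FALSE)
  ok <- is.finite(slopes$gaussian) & is.finite(slopes$exponential)
  paired <- if (sum(ok) >= 2 && sd(slopes$gaussian[ok] -
                                   slopes$exponential[ok]) > 0)
    t.test(slopes$gaussian[ok], slopes$exponential[ok], paired = TRUE)
  else NULL
  structure(list(
    gaussian = fits$gaussian, exponential = fits$exponential,
    slopes = slopes,
    slope_vs_zero = list(
      gaussian = t.test(slopes$gaussian[is.finite(slopes$gaussian)]),
      exponential = t.test(slopes$exponential[is.finite(slopes$exponential)])),
    paired_test = paired,
    delta_aic = fits$gaussian$aic - fits$exponential$aic,
    delta_bic = fits$gaussian$bic - fits$exponential$bic),
    class = "kernel_comparison")
}

#' @export
print.kernel_comparison <- function(x, ...) {
  cat("Kernel comparison (combined cohort)\n")
  cat(sprintf("  gaussian   : AIC = %.1f  BIC = %.1f\n",
              x$gaussian$aic, x$gaussian$bic))
  cat(sprintf("  exponential: AIC = %.1f  BIC = %.1f\n",
              x$exponential$aic, x$exponential$bic))
  cat(sprintf("  delta AIC (gauss - exp) = %.1f\n", x$delta_aic))
  if (!is.null(x$paired_test))
    cat(sprintf("  paired slope test: t = %.2f, p = %.3g\n",
                x$paired_test$statistic, x$paired_test$p.value))
  invisible(x)
}
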