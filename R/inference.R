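#' Behavioural generalization gradient
#'
#' For each subject, the proportion of "+" responses among valid test trials
#' at each orientation, on the canonical (mirror-normalized) axis so that
#' counterbalanced subjects aggregate with the CS+ always on the low side.
#' Group means and standard errors are computed across subjects.
#'
#' @param cohort list of subject data.
#' @return An object of class `gradient_summary` with `orientations`
#'   (canonical, sorted), `per_subject` (long data.frame: subject_id, group,
#'   orientation, p_plus, n_trials) and `group_stats` (group, orientation,
#'   mean, sem, n_subjects). Orientations at which a subject has no valid
#'   trials yield `NA` and are excluded from that orientation's mean with a
#'   warning.
#' @export
behavioral_gradient <- function(cohort) {
  stopifnot(length(cohort) >= 1)
  per <- do.call(rbind, lapply(cohort, function(subject) {
    test <- subject$test
    canon <- mirror_normalize(test$orientation_deg, subject$spec)
    oris <- sort(unique(canon))
    keep <- test$valid
    rows <- lapply(oris, function(o) {
      sel <- keep & canon == o
      n <- sum(sel)
      data.frame(subject_id = subject$subject_id, group = subject$group,
                 orientation = o,
                 p_plus = if (n > 0) mean(test$response[sel] == "plus")
                          else NA_real_,
                 n_trials = n, stringsAsFactors = FALSE)
    })
    do.call(rbind, rows)
  }))
  if (anyNA(per$p_plus))
    warning("some subject x orientation cells have no valid trials; ",
            "excluded from group means")
  stats <- do.call(rbind, lapply(split(per, list(per$group, per$orientation),
                                       drop = TRUE), function(d) {
    ok <- !is.na(d$p_plus)
    data.frame(group = d$group[1L], orientation = d$orientation[1L],
               mean = mean(d$p_plus[ok]),
               sem = if (sum(ok) > 1) sd(d$p_plus[ok]) / sqrt(sum(ok))
                     else NA_real_,
               n_subjects = sum(ok), stringsAsFactors = FALSE)
  }))
  stats <- stats[order(stats$group, stats$orientation), ]
  rownames(stats) <- NULL
  structure(list(orientations = sort(unique(per$orientation)),
                 per_subject = per, group_stats = stats),
            class = "gradient_summary")
}

# Mean gradient over an arbitrary set of subjects (labels ignored); used by
# the permutation machinery where group labels are reshuffled.
mean_gradient <- function(subjects) {
  per <- behavioral_gradient(subjects)$per_subject
  agg <- split(per$p_plus, per$orientation)
  data.frame(orientation = as.numeric(names(agg)),
             mean = vapply(agg, function(v) mean(v, na.rm = TRUE),
                           numeric(1)))
}

#' Peak-shift statistic
#'
#' Tests whether responding is stronger on the side of the CS+ that is
#' farther from the CS- (the classic peak shift). Per subject, the mean of
#' the per-orientation "+" proportions over canonical orientations below the
#' CS+ (farther from the CS-) minus the mean over orientations above it;
#' a paired comparison summarized by a one-sample t-test on the differences,
#' one-tailed by default (directed hypothesis).
#'
#' @param cohort list of subject data (>= 2 subjects).
#' @param alternative direction for the t-test, default `"greater"`.
#' @return List of class `peak_shift` with `statistic` (t), `p_value`, `df`,
#'   `mean_diff` and the per-subject differences.
#' @export
peak_shift_statistic <- function(cohort, alternative = "greater") {
  if (length(cohort) < 2) stop("peak-shift test needs at least 2 subjects")
  diffs <- vapply(cohort, function(subject) {
    test <- subject$test
    canon <- mirror_normalize(test$orientation_deg, subject$spec)
    csp <- min(subject$spec$cs_plus, subject$spec$cs_minus)
    prop <- function(side) {
      oris <- unique(canon[side])
      mean(vapply(oris, function(o) {
        sel <- test$valid & canon == o
        mean(test$response[sel] == "plus")
      }, numeric(1)), na.rm = TRUE)
    }
    prop(canon < csp) - prop(canon > csp)
  }, numeric(1))
  tt <- t.test(diffs, alternative = alternative)
  structure(list(statistic = unname(tt$statistic), p_value = tt$p.value,
                 df = unname(tt$parameter), mean_diff = mean(diffs),
                 diffs = diffs, alternative = alternative),
            class = "peak_shift")
}

#' Pearson type VII curve
#'
#' Amplitude-scaled symmetric bell `A * (1 + ((x - mu)/sigma)^2)^(-m)`.
#' Equivalent to a scaled Student-t density shape with `nu = 2m - 1` degrees
#' of freedom; the Gaussian is the limit `m -> Inf` at fixed `sigma^2 / m`.
#'
#' @param x evaluation points.
#' @param amplitude,mu,sigma,m curve parameters (`sigma > 0`, `m > 0`).
#' @return Curve values.
#' @export
pearson7_curve <- function(x, amplitude, mu, sigma, m) {
  amplitude * (1 + ((x - mu) / sigma)^2)^(-m)
}

#' Fit a Pearson type VII curve to a generalization gradient
#'
#' Least-squares fit of [pearson7_curve()] to a group's mean gradient
#' (the gradient is a curve, not a sample, so least squares rather than
#' density maximum likelihood applies). A small deterministic grid of
#' starting values for scale and shape guards against local minima; the
#' best residual norm wins.
#'
#' @param gradient a `gradient_summary` from [behavioral_gradient()], or a
#'   data.frame with columns `orientation` and `mean`.
#' @param group group label to extract when `gradient` is a
#'   `gradient_summary` with several groups.
#' @param sigma_starts,m_starts start grids for scale and shape; the
#'   defaults cover thin to heavy tails.
#' @return Object of class `pearson7_fit`: `amplitude`, `mu`, `sigma`, `m`,
#'   `resnorm`, `converged`, `n_points`.
#' @export
fit_pearson7 <- function(gradient, group = NULL,
                         sigma_starts = c(5, 10, 20, 40, 80),
                         m_starts = c(1, 2, 5, 15, 50)) {
  if (inherits(gradient, "gradient_summary")) {
    stats <- gradient$group_stats
    if (!is.null(group)) stats <- stats[stats$group == group, ]
    if (length(unique(stats$group)) > 1)
      stop("several groups present; specify `group`")
    x <- stats$orientation
    y <- stats$mean
  } else {
    x <- gradient$orientation
    y <- gradient$mean
  }
  ok <- is.finite(x) & is.finite(y)
  x <- x[ok]; y <- y[ok]
  if (length(x) < 5) stop("need at least 5 gradient points")
  if (max(y) - min(y) < 1e-8)
    stop("flat gradient: Pearson VII fit is degenerate")

  lower <- c(amplitude = 1e-6, mu = min(x) - 30, sigma = 0.5, m = 0.51)
  upper <- c(amplitude = 10, mu = max(x) + 30, sigma = Inf, m = Inf)
  mu0 <- x[which.max(y)]
  resid_fn <- function(par) y - pearson7_curve(x, par[1L], par[2L],
                                               par[3L], par[4L])
  best <- NULL
  for (sigma0 in sigma_starts) {
    for (m0 in m_starts) {
      start <- c(amplitude = max(y), mu = mu0, sigma = sigma0, m = m0)
      res <- tryCatch(
        minpack.lm::nls.lm(par = start, lower = lower, upper = upper,
                           fn = resid_fn,
                           control = minpack.lm::nls.lm.control(
                             maxiter = 200, ftol = 1e-12, ptol = 1e-12)),
        error = function(e) NULL)
      if (is.null(res)) next
      rn <- sum(res$fvec^2)
      if (is.null(best) || rn < best$rn - 1e-15)
        best <- list(par = res$par, rn = rn, info = res$info)
    }
  }
  if (is.null(best)) stop("Pearson VII fit failed to converge from any start")
  structure(list(amplitude = unname(best$par[1L]), mu = unname(best$par[2L]),
                 sigma = unname(best$par[3L]), m = unname(best$par[4L]),
                 resnorm = best$rn, converged = best$info %in% 1:4,
                 n_points = length(x)),
            class = "pearson7_fit")
}

#' @export
print.pearson7_fit <- function(x, ...) {
  cat(sprintf(paste0("Pearson VII fit: A = %.3f, mu = %.2f, sigma = %.2f, ",
                     "m = %.3f (resnorm %.2e)\n"),
              x$amplitude, x$mu, x$sigma, x$m, x$resnorm))
  invisible(x)
}

#' Kurtosis of a fitted Pearson VII distribution
#'
#' Fourth standardized moment `E[(X - mu)^4] / sigma_X^4` of the normalized
#' Pearson VII density, computed by numerical quadrature. The fourth moment
#' is finite only for shape `m > 2.5` (tail exponent `2m > 5`); otherwise
#' the kurtosis is flagged infinite. In the Gaussian limit `m -> Inf` the
#' kurtosis tends to 3.
#'
#' @param fit a `pearson7_fit` (or any list with `sigma` and `m`).
#' @return The kurtosis (scalar); `Inf` with attribute `finite = FALSE` when
#'   the tail does not admit a finite fourth moment.
#' @export
kurtosis_of_fit <- function(fit) {
  m <- fit$m
  stopifnot(is.finite(m), m > 0, fit$sigma > 0)
  if (m <= 2.5) {
    return(structure(Inf, finite = FALSE))
  }
  w <- function(t, pow) t^pow * (1 + t^2)^(-m)
  quad <- function(pow) integrate(w, -Inf, Inf, pow = pow,
                                  rel.tol = 1e-10, abs.tol = 0)$value
  z <- quad(0)
  m2 <- quad(2) / z
  m4 <- quad(4) / z
  structure(m4 / m2^2, finite = TRUE)
}

# Directed permutation p-value, (count + 1) / (n_perm + 1) convention.
perm_pvalue <- function(observed, null, alternative) {
  n <- length(null)
  switch(alternative,
         greater = (sum(null >= observed) + 1) / (n + 1),
         less = (sum(null <= observed) + 1) / (n + 1),
         two.sided = min(1, 2 * min(
           (sum(null >= observed) + 1) / (n + 1),
           (sum(null <= observed) + 1) / (n + 1))))
}

#' Permutation test on the kurtosis difference between groups
#'
#' Observed statistic: kurtosis of group A's fitted Pearson VII minus group
#' B's, each obtained from the group-mean gradient. The null distribution
#' reshuffles subjects into two groups of the original sizes and recomputes
#' the full gradient -> Pearson VII -> kurtosis pipeline. Permutations on
#' which a fit fails or the difference is undefined (e.g. both kurtoses
#' infinite) are redrawn and counted.
#'
#' @param cohort_a,cohort_b disjoint subject lists.
#' @param n_perm number of permutations (>= 1).
#' @param seed integer seed.
#' @param alternative direction, default `"greater"` (A more peaked than B).
#' @return Object of class `permutation_result`.
#' @export
permutation_test_kurtosis <- function(cohort_a, cohort_b, n_perm = 10000,
                                      seed = 1L, alternative = "greater",
                                      sigma_starts = c(5, 10, 20, 40, 80),
                                      m_starts = c(1, 2, 5, 15, 50)) {
  if (n_perm < 1) stop("n_perm must be >= 1")
  # Per-subject gradients do not change under relabelling, so compute the
  # subjects x orientations proportion matrix once; each permutation only
  # averages rows and refits the Pearson VII curve.
  pool <- c(cohort_a, cohort_b)
  grad <- behavioral_gradient(pool)
  oris <- grad$orientations
  P <- t(vapply(pool, function(s) {
    per1 <- behavioral_gradient(list(s))$per_subject
    v <- rep(NA_real_, length(oris))
    v[match(per1$orientation, oris)] <- per1$p_plus
    v
  }, numeric(length(oris))))
  kurt_of <- function(rows) {
    y <- colMeans(P[rows, , drop = FALSE], na.rm = TRUE)
    fit <- fit_pearson7(data.frame(orientation = oris, mean = y),
                        sigma_starts = sigma_starts, m_starts = m_starts)
    as.numeric(kurtosis_of_fit(fit))
  }
  n_a <- length(cohort_a)
  n <- length(pool)
  observed <- kurt_of(seq_len(n_a)) - kurt_of(n_a + seq_len(n - n_a))
  if (is.nan(observed))
    stop("kurtosis is infinite in both groups; the difference is undefined")
  redrawn <- 0L
  null <- with_seed(seed, {
    vapply(seq_len(n_perm), function(i) {
      repeat {
        idx <- sample.int(n, n_a)
        val <- tryCatch(kurt_of(idx) - kurt_of(setdiff(seq_len(n), idx)),
                        error = function(e) NaN)
        if (!is.nan(val)) return(val)
        redrawn <<- redrawn + 1L
        if (redrawn > 10L * n_perm)
          stop("too many failed permutations in kurtosis test")
      }
    }, numeric(1))
  })
  structure(list(observed = observed, null = null,
                 p_value = perm_pvalue(observed, null, alternative),
                 n_perm = n_perm, seed = seed, alternative = alternative,
                 n_redrawn = redrawn),
            class = "permutation_result")
}

#' Permutation test on group-wise model parameters
#'
#' Observed statistics: element-wise differences of the group-wise fitted
#' parameters (`s_i`, `s_e`, `beta`, `offset_a`, `alpha_test`), group A
#' minus group B, with the training learning rate held fixed. The null
#' distribution reassigns subjects at random into two groups of the original
#' sizes and refits both groups on each permutation. Directed p-values use a
#' fixed a-priori direction (default `"less"`: narrower generalization in
#' group A).
#'
#' @param cohort_a,cohort_b disjoint subject lists.
#' @param fixed_alpha_train training learning rate (full-sample estimate).
#'   By default it is not re-estimated inside permutations;
#'   `refit_alpha_train = TRUE` refits it on each permuted full sample.
#' @param n_perm number of permutations (>= 1).
#' @param seed integer seed.
#' @param kernel similarity kernel form.
#' @param config a [fit_config()]; permutation refits inherit it, so reduce
#'   `n_starts` there to trade accuracy for speed.
#' @param alternative direction (single value or named per-parameter vector).
#' @param refit_alpha_train refit the training rate within permutations.
#' @return Object of class `permutation_result` with per-parameter
#'   `observed`, `null` (matrix `n_perm x 5`) and `p_value`.
#' @export
permutation_test_parameters <- function(cohort_a, cohort_b,
                                        fixed_alpha_train,
                                        n_perm = 10000, seed = 1L,
                                        kernel = "gaussian",
                                        config = fit_config(),
                                        alternative = "less",
                                        refit_alpha_train = FALSE) {
  if (n_perm < 1) stop("n_perm must be >= 1")
  pnames <- c("s_i", "s_e", "beta", "offset_a", "alpha_test")
  # subjects are prepared once; each permutation only regroups and refits
  pool_preps <- lapply(c(cohort_a, cohort_b), prepare_subject,
                       config$likelihood_phases, config$unsure_policy,
                       config$update_invalid)
  n_a <- length(cohort_a)
  n <- length(pool_preps)
  diff_of <- function(idx_a, idx_b) {
    at <- if (refit_alpha_train)
      fit_prepped(concat_preps(pool_preps), c(pnames, "alpha_train"),
                  list(), kernel, config, light = TRUE)$params$alpha_train
    else fixed_alpha_train
    fa <- fit_prepped(concat_preps(pool_preps[idx_a]), pnames,
                      list(alpha_train = at), kernel, config,
                      light = TRUE)$params
    fb <- fit_prepped(concat_preps(pool_preps[idx_b]), pnames,
                      list(alpha_train = at), kernel, config,
                      light = TRUE)$params
    vapply(pnames, function(p) fa[[p]] - fb[[p]], numeric(1))
  }
  observed <- diff_of(seq_len(n_a), n_a + seq_len(n - n_a))
  redrawn <- 0L
  null <- with_seed(seed, {
    t(vapply(seq_len(n_perm), function(i) {
      repeat {
        idx <- sample.int(n, n_a)
        val <- tryCatch(diff_of(idx, setdiff(seq_len(n), idx)),
                        error = function(e) rep(NaN, length(pnames)))
        if (!anyNA(val)) return(val)
        redrawn <<- redrawn + 1L
        if (redrawn > 10L * n_perm)
          stop("too many failed permutations in parameter test")
      }
    }, numeric(length(pnames))))
  })
  colnames(null) <- pnames
  if (length(alternative) == 1L)
    alternative <- setNames(rep(alternative, length(pnames)), pnames)
  p <- vapply(pnames, function(pn)
    perm_pvalue(observed[[pn]], null[, pn], alternative[[pn]]), numeric(1))
  structure(list(observed = observed, null = null, p_value = p,
                 n_perm = n_perm, seed = seed, alternative = alternative,
                 n_redrawn = redrawn),
            class = "permutation_result")
}

#' @export
print.permutation_result <- function(x, ...) {
  cat(sprintf("Permutation test (n_perm = %d, seed = %d, redrawn = %d)\n",
              x$n_perm, x$seed, x$n_redrawn))
  obs <- x$observed
  if (length(obs) == 1L) {
    cat(sprintf("  observed = %.4g, p = %.4g (%s)\n", obs, x$p_value,
                x$alternative[1L]))
  } else {
    for (nm in names(obs))
      cat(sprintf("  %-10s observed = %+.4g  p = %.4g\n",
                  nm, obs[[nm]], x$p_value[[nm]]))
  }
  invisible(x)
}

#' Leave-one-out individual-difference scores for model parameters
#'
#' For each subject, the group's parameters are re-estimated with that
#' subject left out, and the subject's score is the full-group estimate
#' minus the leave-one-out estimate. A subject with a large latent parameter
#' thus receives a positive score (removing them lowers the reduced-sample
#' estimate). Scores are compared between groups by per-parameter two-sample
#' t-tests, one-tailed by default.
#'
#' @param cohort full cohort; subjects carry group labels.
#' @param fixed_alpha_train training learning rate (full-sample estimate).
#' @param kernel similarity kernel form.
#' @param config a [fit_config()].
#' @param alternative direction for the group comparison (first group level
#'   minus second), default `"less"`.
#' @param sign_convention `"full_minus_loo"` (default) or `"loo_minus_full"`.
#' @return Object of class `loo_estimates`: `scores` data.frame (one row per
#'   subject, one column per parameter), per-parameter group `tests`, and
#'   the full-group fits.
#' @export
loo_parameter_scores <- function(cohort, fixed_alpha_train,
                                 kernel = "gaussian", config = fit_config(),
                                 alternative = "less",
                                 sign_convention = c("full_minus_loo",
                                                     "loo_minus_full")) {
  sign_convention <- match.arg(sign_convention)
  if (length(cohort) < 3) stop("need at least 3 subjects")
  pnames <- c("s_i", "s_e", "beta", "offset_a", "alpha_test")
  groups <- vapply(cohort, `[[`, character(1), "group")
  full_fits <- lapply(unique(groups), function(g)
    fit_group(cohort[groups == g], fixed_alpha_train, kernel, config))
  names(full_fits) <- unique(groups)
  scores <- do.call(rbind, lapply(seq_along(cohort), function(i) {
    g <- groups[i]
    members <- which(groups == g)
    loo_fit <- tryCatch(
      fit_group(cohort[setdiff(members, i)], fixed_alpha_train, kernel,
                config),
      error = function(e) NULL)
    vals <- if (is.null(loo_fit)) rep(NA_real_, length(pnames))
    else vapply(pnames, function(p) {
      d <- full_fits[[g]]$params[[p]] - loo_fit$params[[p]]
      if (sign_convention == "loo_minus_full") -d else d
    }, numeric(1))
    cbind(data.frame(subject_id = cohort[[i]]$subject_id, group = g,
                     stringsAsFactors = FALSE),
          as.data.frame(as.list(setNames(vals, pnames))))
  }))
  lv <- unique(groups)
  tests <- if (length(lv) == 2L) {
    lapply(setNames(pnames, pnames), function(p) {
      a <- scores[[p]][scores$group == lv[1L]]
      b <- scores[[p]][scores$group == lv[2L]]
      t.test(a[is.finite(a)], b[is.finite(b)], alternative = alternative)
    })
  } else NULL
  structure(list(scores = scores, tests = tests, full_fits = full_fits,
                 sign_convention = sign_convention),
            class = "loo_estimates")
}
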