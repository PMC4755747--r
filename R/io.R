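#' Write a cohort to tab-separated files
#'
#' One TSV per subject (columns: subject_id, phase, trial, orientation_deg,
#' outcome, response, valid; orientations in degrees) plus `manifest.tsv`
#' mapping subject_id to group label and CS+ orientation.
#'
#' @param cohort a `cohort` from [simulate_cohort()], or a list with
#'   `subjects` and `manifest`.
#' @param dir output directory (created if needed).
#' @return Invisibly, the directory path.
#' @export
write_cohort <- function(cohort, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  write.table(cohort$manifest, file.path(dir, "manifest.tsv"),
              sep = "\t", quote = FALSE, row.names = FALSE)
  for (subject in cohort$subjects) {
    trials <- rbind(subject$training, subject$test)
    out <- cbind(subject_id = subject$subject_id,
                 trials[, c("phase", "trial", "orientation_deg", "outcome",
                            "response", "valid")])
    write.table(out, file.path(dir, paste0(subject$subject_id, ".tsv")),
                sep = "\t", quote = FALSE, row.names = FALSE)
  }
  invisible(dir)
}

#' Read a cohort from tab-separated files
#'
#' Reads the manifest and per-subject trial tables written by
#' [write_cohort()], validating the column schema, orientation range,
#' response codes and outcome codes; malformed rows are rejected with
#' line-numbered errors. The write-read round trip is lossless.
#'
#' @param dir directory containing `manifest.tsv` and one
#'   `<subject_id>.tsv` per subject.
#' @return A list of class `cohort` (see [simulate_cohort()]).
#' @export
read_cohort <- function(dir) {
  manifest_path <- file.path(dir, "manifest.tsv")
  if (!file.exists(manifest_path))
    stop("missing manifest.tsv in ", dir)
  manifest <- read.delim(manifest_path, stringsAsFactors = FALSE)
  need <- c("subject_id", "group", "cs_plus")
  if (!identical(names(manifest), need))
    stop("manifest.tsv columns must be: ", paste(need, collapse = ", "))
  subjects <- lapply(seq_len(nrow(manifest)), function(i) {
    sid <- manifest$subject_id[i]
    path <- file.path(dir, paste0(sid, ".tsv"))
    if (!file.exists(path))
      stop("manifest lists subject ", sid, " but ", path, " is missing")
    d <- read.delim(path, stringsAsFactors = FALSE,
                    colClasses = c(subject_id = "character",
                                   phase = "character", trial = "integer",
                                   orientation_deg = "numeric",
                                   outcome = "integer",
                                   response = "character",
                                   valid = "logical"))
    cols <- c("subject_id", "phase", "trial", "orientation_deg", "outcome",
              "response", "valid")
    if (!identical(names(d), cols))
      stop(path, ": columns must be: ", paste(cols, collapse = ", "))
    line <- seq_len(nrow(d)) + 1L  # header is line 1
    bad <- which(!(d$phase %in% c("training", "test")))
    if (length(bad))
      stop(path, " line ", line[bad[1L]], ": unknown phase '",
           d$phase[bad[1L]], "'")
    bad <- which(!is.finite(d$orientation_deg) | d$orientation_deg < 0 |
                   d$orientation_deg > 180)
    if (length(bad))
      stop(path, " line ", line[bad[1L]], ": orientation out of range [0, 180]")
    bad <- which(!(d$outcome %in% c(0L, 1L)))
    if (length(bad))
      stop(path, " line ", line[bad[1L]], ": outcome must be 0 or 1")
    bad <- which(d$phase == "test" & d$outcome != 0L)
    if (length(bad))
      stop(path, " line ", line[bad[1L]], ": test trials cannot carry reward")
    ok_resp <- is.na(d$response) |
      d$response %in% c("plus", "minus", "unsure", "missing")
    if (any(!ok_resp))
      stop(path, " line ", line[which(!ok_resp)[1L]],
           ": unknown response code '", d$response[which(!ok_resp)[1L]], "'")
    bad <- which(!d$valid & !is.na(d$response) & d$response != "missing")
    if (length(bad))
      stop(path, " line ", line[bad[1L]],
           ": invalid trial carries a response")
    training <- d[d$phase == "training", ]
    cs_plus <- manifest$cs_plus[i]
    train_oris <- unique(training$orientation_deg)
    if (!(cs_plus %in% train_oris))
      stop(path, ": manifest cs_plus ", cs_plus,
           " does not appear among training orientations")
    cs_minus <- setdiff(train_oris, cs_plus)
    if (length(cs_minus) != 1L)
      stop(path, ": training must contain exactly two orientations")
    test <- d[d$phase == "test", ]
    spec <- stimulus_spec(cs_plus, cs_minus,
                          sort(unique(test$orientation_deg)))
    strip <- function(x) {
      x <- x[, c("phase", "trial", "orientation_deg", "outcome", "response",
                 "valid")]
      rownames(x) <- NULL
      attr(x, "stimulus_spec") <- spec
      x
    }
    structure(list(subject_id = sid, group = manifest$group[i], spec = spec,
                   training = strip(training), test = strip(test)),
              class = "subject_data")
  })
  structure(list(subjects = subjects, manifest = manifest), class = "cohort")
}

#' Default pipeline configuration
#'
#' Every behavioural toggle of the package has an explicit default here:
#' cohort design (study sizes and trial counts), kernel, optimizer settings,
#' permutation settings, likelihood conventions and sign conventions.
#' The configuration round-trips through YAML unchanged.
#'
#' @return Named list of class `run_config`.
#' @export
default_config <- function() {
  structure(list(
    out_dir = "results",
    seed = 1L,
    kernel = "gaussian",
    stages = c("simulate", "fit", "gradient"),
    # cohort design
    n_pa = 25L, n_pp = 21L, n_reps = 100L, p_reward = 0.5,
    n_reps_test = 14L, p_miss = 0, bernoulli = FALSE, counterbalance = TRUE,
    # optimizer
    n_starts = 20L, maxit = 300L, factr = 1e7,
    # likelihood conventions
    likelihood_phases = "test", unsure_policy = "not_plus",
    update_invalid = TRUE,
    # permutation / LOO settings
    n_perm = 10000L, perm_n_starts = 3L, refit_alpha_train_in_perm = FALSE,
    alternative_params = "less", alternative_kurtosis = "greater",
    loo_sign = "full_minus_loo"),
    class = "run_config")
}

#' Read a pipeline configuration from a YAML file
#'
#' Keys not present fall back to [default_config()]; unknown keys are
#' rejected before anything runs.
#'
#' @param path YAML file.
#' @return A `run_config` list.
#' @export
read_config <- function(path) {
  user <- yaml::read_yaml(path)
  defaults <- default_config()
  unknown <- setdiff(names(user), names(defaults))
  if (length(unknown))
    stop("unknown config key(s): ", paste(unknown, collapse = ", "))
  cfg <- modifyList(unclass(defaults), user)
  class(cfg) <- "run_config"
  cfg
}

config_hash <- function(config) {
  tmp <- tempfile(fileext = ".yaml")
  on.exit(unlink(tmp))
  yaml::write_yaml(unclass(config), tmp)
  unname(tools::md5sum(tmp))
}

write_tsv <- function(d, path) {
  write.table(d, path, sep = "\t", quote = FALSE, row.names = FALSE)
}

#' Run the analysis pipeline
#'
#' Executes the requested stages in dependency order on a synthetic cohort:
#' `simulate` (cohort written under `out_dir/cohort`), `fit` (two-stage
#' pooled ML fit per group), `compare_kernels`, `gradient` (generalization
#' gradients and peak-shift test), `kurtosis` (Pearson VII kurtosis
#' permutation test), `permute_params` (group-parameter permutation test)
#' and `loo` (leave-one-out scores). Result tables are tab-separated; a
#' `summary.json` records the configuration, its hash and all seeds, so an
#' identical configuration reproduces identical outputs.
#'
#' @param config a `run_config` from [default_config()] / [read_config()].
#' @return Invisibly, a list with the in-memory stage results.
#' @export
run_pipeline <- function(config = default_config()) {
  defaults <- default_config()
  unknown <- setdiff(names(config), names(defaults))
  if (length(unknown))
    stop("unknown config key(s): ", paste(unknown, collapse = ", "))
  config <- modifyList(unclass(defaults), unclass(config))
  dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
  stages <- config$stages
  res <- list(config = config, hash = config_hash(config))

  fitcfg <- fit_config(n_starts = config$n_starts, seed = config$seed,
                       maxit = config$maxit, factr = config$factr,
                       likelihood_phases = config$likelihood_phases,
                       unsure_policy = config$unsure_policy,
                       update_invalid = config$update_invalid)

  cohort_dir <- file.path(config$out_dir, "cohort")
  if ("simulate" %in% stages || !dir.exists(cohort_dir)) {
    coh <- simulate_cohort(cohort_spec(
      n_pa = config$n_pa, n_pp = config$n_pp, n_reps = config$n_reps,
      p_reward = config$p_reward, n_reps_test = config$n_reps_test,
      p_miss = config$p_miss, bernoulli = config$bernoulli,
      counterbalance = config$counterbalance, seed = config$seed))
    write_cohort(coh, cohort_dir)
  } else {
    coh <- read_cohort(cohort_dir)
  }
  res$cohort <- coh
  groups <- vapply(coh$subjects, `[[`, character(1), "group")

  needs_fit <- any(c("fit", "permute_params", "loo") %in% stages)
  if (needs_fit) {
    stage1 <- fit_alpha_train(coh$subjects, config$kernel, fitcfg)
    group_fits <- lapply(c(PA = "PA", PP = "PP"), function(g)
      fit_group(coh$subjects[groups == g], stage1$alpha_train,
                config$kernel, fitcfg))
    res$alpha_train <- stage1$alpha_train
    res$group_fits <- group_fits
    ptab <- do.call(rbind, lapply(names(group_fits), function(g) {
      p <- group_fits[[g]]$params
      data.frame(group = g, s_i = p$s_i, s_e = p$s_e, beta = p$beta,
                 offset_a = p$offset_a, alpha_test = p$alpha_test,
                 alpha_train = p$alpha_train,
                 pooled_LLE = group_fits[[g]]$pooled_LLE,
                 aic = group_fits[[g]]$aic, bic = group_fits[[g]]$bic,
                 stringsAsFactors = FALSE)
    }))
    write_tsv(ptab, file.path(config$out_dir, "fit_parameters.tsv"))
  }

  if ("compare_kernels" %in% stages) {
    kc <- compare_kernels(coh$subjects, fitcfg)
    res$kernel_comparison <- kc
    write_tsv(kc$slopes, file.path(config$out_dir, "kernel_slopes.tsv"))
  }

  if (any(c("gradient", "kurtosis") %in% stages)) {
    grad <- behavioral_gradient(coh$subjects)
    res$gradient <- grad
    res$peak_shift <- peak_shift_statistic(coh$subjects)
    write_tsv(grad$group_stats, file.path(config$out_dir, "gradient.tsv"))
  }

  if ("kurtosis" %in% stages) {
    res$kurtosis <- permutation_test_kurtosis(
      coh$subjects[groups == "PA"], coh$subjects[groups == "PP"],
      n_perm = config$n_perm, seed = derive_seed(config$seed, 101L),
      alternative = config$alternative_kurtosis)
  }

  if ("permute_params" %in% stages) {
    permcfg <- fitcfg
    permcfg$n_starts <- config$perm_n_starts
    res$param_perm <- permutation_test_parameters(
      coh$subjects[groups == "PA"], coh$subjects[groups == "PP"],
      fixed_alpha_train = res$alpha_train,
      n_perm = config$n_perm, seed = derive_seed(config$seed, 102L),
      kernel = config$kernel, config = permcfg,
      alternative = config$alternative_params,
      refit_alpha_train = config$refit_alpha_train_in_perm)
  }

  if ("loo" %in% stages) {
    loo <- loo_parameter_scores(coh$subjects, res$alpha_train,
                                kernel = config$kernel, config = fitcfg,
                                sign_convention = config$loo_sign)
    res$loo <- loo
    write_tsv(loo$scores, file.path(config$out_dir, "loo_scores.tsv"))
  }

  summary <- list(
    config = unclass(config), config_hash = res$hash,
    alpha_train = res$alpha_train,
    peak_shift = if (!is.null(res$peak_shift))
      list(t = res$peak_shift$statistic, p = res$peak_shift$p_value),
    kurtosis = if (!is.null(res$kurtosis))
      list(observed = res$kurtosis$observed, p = res$kurtosis$p_value),
    param_perm = if (!is.null(res$param_perm))
      list(observed = as.list(res$param_perm$observed),
           p = as.list(res$param_perm$p_value)))
  jsonlite::write_json(summary[!vapply(summary, is.null, logical(1))],
                       file.path(config$out_dir, "summary.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(res)
}
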