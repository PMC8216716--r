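# End-to-end orchestration: behavior -> fits -> model comparison -> PEB ->
# prediction on a synthetic cohort, with seeding and a machine-readable
# report.

#' Read a pipeline configuration from YAML
#'
#' @param path YAML file; top-level keys as in [run_pipeline()]
#' @return configuration list
#' @export
read_pipeline_config <- function(path) {
  yaml::read_yaml(path)
}

#' Run the full analysis pipeline on a synthetic cohort
#'
#' Stages: score force traces and run group statistics; fit the full model
#' (and the hidden-IPL control model when model comparison is enabled) per
#' subject by variational Laplace; random-effects Bayesian model selection;
#' parametric empirical Bayes with greedy search and model averaging;
#' empirical-Bayes subject estimates; leave-one-out prediction of
#' performance and age plus age-group classification.
#'
#' @param config a list (or a `cohort_config` under `$cohort`): fields
#'   `cohort` (arguments for [cohort_config()]), `stages` (logical toggles
#'   `behavior`, `bms`, `peb`, `predict`), `fit_opts` (passed to
#'   [fit_dcm()]), `hyper`, `threshold`, `bms_samples`, `hidden_source`,
#'   `seed`
#' @return object of class `pipeline_report`
#' @export
run_pipeline <- function(config = list()) {
  defaults <- list(
    cohort = list(), stages = list(), fit_opts = list(max_iter = 24),
    hyper = list(hE = 18, hC = 1 / 128), threshold = 0.95,
    bms_samples = 1e5, hidden_source = "IPL", seed = 1
  )
  cfg <- modifyList(defaults, config)
  stages <- modifyList(list(behavior = TRUE, bms = TRUE, peb = TRUE,
                            predict = TRUE), cfg$stages)
  cc <- if (inherits(cfg$cohort, "cohort_config")) cfg$cohort
        else do.call(cohort_config, modifyList(list(seed = cfg$seed), cfg$cohort))
  report <- list(provenance = list(
    package = as.character(packageVersion("specdcm")),
    seed = cc$seed,
    config_hash = fnv1a32(jsonlite::toJSON(cfg[c("fit_opts", "hyper",
                                                 "threshold", "bms_samples",
                                                 "hidden_source", "seed")],
                                           auto_unbox = TRUE)),
    timestamp = format(Sys.time(), tz = "UTC")
  ))

  cohort <- generate_cohort(cc)
  report$cohort <- list(n = nrow(cohort$subjects),
                        groups = as.list(table(cohort$subjects$group)))

  scores <- vapply(cohort$traces, function(tr)
    compute_precision_score(tr)$score, numeric(1))
  if (stages$behavior) {
    report$behavior <- list(
      scores = scores,
      stats = group_statistics(scores, cohort$subjects$group)
    )
  }

  n <- nrow(cohort$subjects)
  fits_full <- vector("list", n)
  for (i in seq_len(n)) {
    fits_full[[i]] <- fit_dcm(cohort$spectra[[i]], cohort$model,
                              hyper = cfg$hyper, opts = cfg$fit_opts)
  }
  n_fits <- n
  report$fit <- list(
    mean_r2 = mean(vapply(fits_full, function(f) f$r2, numeric(1))),
    F = vapply(fits_full, function(f) f$F, numeric(1))
  )

  if (stages$bms) {
    hidden_model <- make_hidden_source_model(cohort$model, cfg$hidden_source)
    fits_hidden <- vector("list", n)
    for (i in seq_len(n)) {
      fits_hidden[[i]] <- fit_dcm(cohort$spectra[[i]], hidden_model,
                                  hyper = cfg$hyper, opts = cfg$fit_opts)
    }
    n_fits <- n_fits + n
    Ftab <- evidence_table(full = fits_full, hidden = fits_hidden)
    report$bms <- rfx_bms(Ftab, n_samples = cfg$bms_samples, seed = cc$seed)
    report$evidence <- Ftab
  }
  report$n_fits <- n_fits

  if (stages$peb || stages$predict) {
    X <- build_design_matrix(scores, cohort$subjects$group)
    peb <- fit_peb(fits_full, X)
    bma <- greedy_search_bma(peb, threshold = cfg$threshold)
    est <- extract_subject_estimates(peb, bma = bma)
    if (stages$peb) {
      report$peb <- list(fit = peb, bma = bma, effects = bma$effects,
                         estimates = est)
    }
    if (stages$predict) {
      report$predict <- list(
        performance = loocv_regression(est, scores),
        age_months = loocv_regression(est, cohort$subjects$age_months),
        age_group = qda_loocv(est, cohort$subjects$group)
      )
    }
  }
  class(report) <- "pipeline_report"
  report
}

#' @export
print.pipeline_report <- function(x, ...) {
  cat("Pipeline report\n")
  cat(sprintf("  cohort: %d subjects; %d first-level fits; mean r2 %.1f%%\n",
              x$cohort$n, x$n_fits, x$fit$mean_r2))
  if (!is.null(x$behavior))
    cat(sprintf("  behavior: F(%d, %d) = %.2f\n", x$behavior$stats$df[1],
                x$behavior$stats$df[2], x$behavior$stats$F))
  if (!is.null(x$bms))
    cat(sprintf("  BMS: pxp(full) = %.3f, bor = %.3f\n", x$bms$pxp["full"],
                x$bms$bor))
  if (!is.null(x$peb))
    cat(sprintf("  PEB: %d effects retained at pp > %.2f\n",
                sum(x$peb$effects$retained), x$peb$bma$threshold))
  if (!is.null(x$predict))
    cat(sprintf("  prediction: perf R2 %.2f, age R2 %.2f, QDA accuracy %.0f%%\n",
                x$predict$performance$r2, x$predict$age_months$r2,
                100 * x$predict$age_group$accuracy))
  invisible(x)
}

#' Write a pipeline report to JSON
#'
#' Serializes the numeric content of a report (provenance, behavior
#' statistics, fit summaries, model comparison, effect table, predictions).
#'
#' @param report a `pipeline_report`
#' @param path output file
#' @return invisibly, the path
#' @export
write_report_json <- function(report, path) {
  out <- list(
    provenance = report$provenance,
    cohort = report$cohort,
    n_fits = report$n_fits,
    mean_r2 = report$fit$mean_r2,
    free_energy = report$fit$F
  )
  if (!is.null(report$behavior))
    out$behavior <- list(F = report$behavior$stats$F,
                         df = report$behavior$stats$df,
                         p = report$behavior$stats$p,
                         pairwise = report$behavior$stats$pairwise)
  if (!is.null(report$bms))
    out$bms <- list(alpha = report$bms$alpha, xp = report$bms$xp,
                    pxp = report$bms$pxp, bor = report$bms$bor)
  if (!is.null(report$peb))
    out$peb <- list(effects = report$peb$effects)
  if (!is.null(report$predict))
    out$predict <- list(
      performance = list(rmse = report$predict$performance$rmse,
                         r2 = report$predict$performance$r2),
      age_months = list(rmse = report$predict$age_months$rmse,
                        r2 = report$predict$age_months$r2),
      qda = list(accuracy = report$predict$age_group$accuracy,
                 ci95 = report$predict$age_group$ci95,
                 p_vs_nir = report$predict$age_group$p_vs_nir)
    )
  jsonlite::write_json(out, path, auto_unbox = TRUE, digits = NA,
                       force = TRUE)
  invisible(path)
}
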