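#' Configure the design -> simulate -> fit pipeline
#'
#' Bundles the trial design, the observer population, and the fitting
#' options.  All randomness flows from the explicit seeds in the design and
#' population specs; no global generator state is consulted.
#'
#' @param design A [design_spec()] for the main experiment.
#' @param population A [population_spec()].
#' @param n_boot Bootstrap resamples for the group-level psychometric CIs
#'   (0 skips the bootstrap).
#' @param n_starts Multi-starts for the categorization-model fits.
#' @param fit_subject_category If `TRUE`, also fit the categorization model
#'   per subject (the per-subject estimates table).
#' @param out_dir Optional directory; when given, every intermediate table
#'   is persisted as CSV/JSON along with a run manifest.
#'
#' @return A list of class `"pipeline_config"`.
#' @export
pipeline_config <- function(design = design_spec(),
                            population = population_spec(),
                            n_boot = 0,
                            n_starts = 8,
                            fit_subject_category = TRUE,
                            out_dir = NULL) {
  stopifnot(inherits(design, "design_spec"),
            inherits(population, "population_spec"))
  structure(
    list(design = design, population = population,
         n_boot = n_boot, n_starts = n_starts,
         fit_subject_category = isTRUE(fit_subject_category),
         out_dir = out_dir),
    class = "pipeline_config"
  )
}

#' Run the full analysis pipeline on simulated observers
#'
#' Generates a main-experiment design for every observer, simulates their
#' trinomial responses, fits psychometric functions per subject and on the
#' pooled group data, converts the direct-gaze-point slopes to cue weights,
#' decomposes the whole-head weights into the eye-region and direct head
#' routes (group-level and per subject, with one-sample t tests on the
#' per-subject weights), fits the categorization model, and summarizes how
#' well the known generative parameters were recovered.
#'
#' @param config A [pipeline_config()].
#' @return A list of class `"gaze_run_report"` with elements `trials`,
#'   `observers` (ground truth), `psychometric_subject`,
#'   `psychometric_group`, `weights_subject`, `weights_group`,
#'   `decomposition_group`, `decomposition_subject`, `t_tests`,
#'   `category_group`, `category_subject` (if requested), and `recovery`.
#' @examples
#' cfg <- pipeline_config(
#'   design = design_spec(n_repetitions = 1),
#'   population = population_spec(n_observers = 4, seed = 3),
#'   fit_subject_category = FALSE)
#' report <- run_pipeline(cfg)
#' report$decomposition_group
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "pipeline_config"))
  designs <- lapply(seq_len(config$population$n_observers),
                    function(i) generate_main_design(config$design, i))
  sim <- simulate_experiment(config$population, designs)

  psy_subject <- fit_psychometric(sim$trials, level = "subject")
  psy_group <- fit_psychometric(sim$trials, level = "group",
                                n_boot = config$n_boot,
                                seed = config$population$seed)

  w_subject <- estimate_cue_weights(psy_subject)
  w_group <- estimate_cue_weights(psy_group)
  m <- stats::setNames(w_group$slope_m, w_group$condition)
  decomp_group <- decompose_routes(m[["whole_head"]], m[["eye_region"]])
  decomp_subject <- decompose_by_subject(w_subject)

  t_tests <- dplyr::bind_rows(
    whole_head = group_t_test(
      w_subject$w_head[w_subject$condition == "whole_head"]),
    eye_region = group_t_test(
      w_subject$w_head[w_subject$condition == "eye_region"]),
    direct_cue = group_t_test(decomp_subject$w_direct),
    .id = "weight"
  )

  cat_group <- fit_category_models(sim$trials, level = "group",
                                   n_starts = config$n_starts,
                                   seed = config$population$seed)
  cat_subject <- NULL
  if (config$fit_subject_category) {
    cat_subject <- fit_category_models(sim$trials, level = "subject",
                                       n_starts = config$n_starts,
                                       seed = config$population$seed)
  }

  recovery <- .pipeline_recovery(sim$observers, w_subject, decomp_subject,
                                 cat_subject)

  report <- structure(
    list(trials = sim$trials, observers = sim$observers,
         psychometric_subject = psy_subject, psychometric_group = psy_group,
         weights_subject = w_subject, weights_group = w_group,
         decomposition_group = decomp_group,
         decomposition_subject = decomp_subject,
         t_tests = t_tests,
         category_group = cat_group, category_subject = cat_subject,
         recovery = recovery,
         config = config),
    class = "gaze_run_report"
  )
  if (!is.null(config$out_dir)) .persist_report(report, config$out_dir)
  report
}

# ground truth vs fitted, where the mapping is closed-form:
# the eye-region slope estimates w_head(ER) = w_eye_route_head, the
# decomposition estimates w_direct_head, sigma comes from the category fits
.pipeline_recovery <- function(observers, w_subject, decomp_subject,
                               cat_subject) {
  er <- dplyr::filter(w_subject, .data$condition == "eye_region")
  pairs <- list(
    w_eye_route_head = dplyr::inner_join(
      dplyr::select(observers, "subject", true = "w_eye_route_head") |>
        dplyr::mutate(subject = as.character(.data$subject)),
      dplyr::select(er, "subject", fitted = "w_head"),
      by = "subject"),
    w_direct_head = dplyr::inner_join(
      dplyr::select(observers, "subject", true = "w_direct_head") |>
        dplyr::mutate(subject = as.character(.data$subject)),
      dplyr::select(decomp_subject, "subject", fitted = "w_direct"),
      by = "subject")
  )
  if (!is.null(cat_subject)) {
    sig <- cat_subject |>
      dplyr::group_by(.data$subject) |>
      dplyr::summarise(fitted = mean(.data$sigma_deg), .groups = "drop")
    pairs$sigma_rep_deg <- dplyr::inner_join(
      dplyr::select(observers, "subject", true = "sigma_rep_deg") |>
        dplyr::mutate(subject = as.character(.data$subject)),
      sig, by = "subject")
  }
  dplyr::bind_rows(lapply(pairs, recovery_summary), .id = "parameter")
}

#' Bias and RMSE of fitted parameters against ground truth
#'
#' @param matched Tibble with columns `true` and `fitted`, one row per
#'   observer (rows must correspond).
#' @return One-row tibble with `n`, `bias` (mean fitted - true), `rmse`.
#' @export
recovery_summary <- function(matched) {
  stopifnot(all(c("true", "fitted") %in% names(matched)))
  if (nrow(matched) == 0) {
    abort("No matched observers.", class = "gazecue_domain_error")
  }
  err <- matched$fitted - matched$true
  tibble::tibble(n = nrow(matched), bias = mean(err),
                 rmse = sqrt(mean(err^2)))
}

#' @export
print.gaze_run_report <- function(x, ...) {
  cat("<gaze_run_report>\n")
  cat("  trials:", nrow(x$trials), " observers:", nrow(x$observers), "\n")
  m <- x$decomposition_group
  cat(sprintf("  group slopes: m_WH = %.4f, m_ER = %.4f\n", m$m_wh, m$m_er))
  cat(sprintf("  direct head route weight (group): %.4f\n", m$w_direct))
  cat("  per-subject t tests:\n")
  print(x$t_tests)
  invisible(x)
}

.persist_report <- function(report, out_dir) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  write_trials(report$trials, file.path(out_dir, "trials.csv"))
  readr::write_csv(report$observers, file.path(out_dir, "observers_true.csv"))
  readr::write_csv(report$psychometric_subject,
                   file.path(out_dir, "psychometric_subject.csv"))
  readr::write_csv(report$psychometric_group,
                   file.path(out_dir, "psychometric_group.csv"))
  readr::write_csv(report$weights_subject,
                   file.path(out_dir, "weights_subject.csv"))
  readr::write_csv(report$weights_group,
                   file.path(out_dir, "weights_group.csv"))
  readr::write_csv(report$decomposition_subject,
                   file.path(out_dir, "decomposition_subject.csv"))
  readr::write_csv(report$t_tests, file.path(out_dir, "t_tests.csv"))
  readr::write_csv(report$category_group,
                   file.path(out_dir, "category_group.csv"))
  if (!is.null(report$category_subject)) {
    readr::write_csv(report$category_subject,
                     file.path(out_dir, "category_subject.csv"))
  }
  readr::write_csv(report$recovery, file.path(out_dir, "recovery.csv"))
  jsonlite::write_json(
    unclass(report$decomposition_group),
    file.path(out_dir, "decomposition_group.json"),
    auto_unbox = TRUE, digits = NA)
  manifest <- list(
    design_seed = report$config$design$seed,
    population_seed = report$config$population$seed,
    n_observers = report$config$population$n_observers,
    n_trials = nrow(report$trials),
    config_hash = rlang::hash(report$config)
  )
  jsonlite::write_json(manifest, file.path(out_dir, "run_manifest.json"),
                       auto_unbox = TRUE)
  invisible(report)
}

#' Plot direct-gaze points against head orientation
#'
#' Shows the fitted points of subjectively direct gaze per condition with
#' their regression lines — the relation whose slope carries the cue
#' weights.
#'
#' @param fits Tibble from [fit_psychometric()].
#' @return A ggplot object.
#' @export
plot_direct_gaze <- function(fits) {
  ggplot2::ggplot(fits, ggplot2::aes(x = .data$head_orientation_deg,
                                     y = .data$alpha_deg,
                                     colour = .data$condition)) +
    ggplot2::geom_point() +
    ggplot2::geom_smooth(method = "lm", formula = y ~ x, se = FALSE) +
    ggplot2::labs(x = "Head orientation (deg)",
                  y = "Subjectively direct gaze (deg)",
                  colour = "Condition") +
    ggplot2::theme_minimal()
}
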