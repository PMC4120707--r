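#' Recode categorical gaze responses as proportion-rightward scores
#'
#' Maps `left` to 0, `direct` to 0.5 and `right` to 1 (single-letter codes
#' `L`/`D`/`R` are accepted as synonyms).
#'
#' @param response Character vector of responses.
#' @return Numeric vector in `{0, 0.5, 1}`.
#' @export
recode_response <- function(response) {
  map <- c(left = 0, direct = 0.5, right = 1, L = 0, D = 0.5, R = 1)
  out <- unname(map[as.character(response)])
  if (anyNA(out) && !anyNA(response)) {
    bad <- unique(response[is.na(out)])
    abort(paste0("Unknown response label(s): ", paste(bad, collapse = ", ")),
          class = "gazecue_parse_error")
  }
  out
}

#' Per-cell proportion scores
#'
#' Aggregates trials into one row per subject x condition x head orientation
#' x eye deviation cell, with the proportion-rightward score (the mean of
#' the 0 / 0.5 / 1 recoding, i.e. `(n_right + 0.5 n_direct) / n`) and the
#' raw proportion of "direct" responses.
#'
#' @param trials Trial tibble with columns `subject`, `condition`,
#'   `head_orientation_deg`, `eye_deviation_deg`, `response`.
#' @return Tibble with columns `subject`, `condition`,
#'   `head_orientation_deg`, `eye_deviation_deg`, `n_trials`,
#'   `prop_rightward`, `prop_direct`.
#' @export
proportion_scores <- function(trials) {
  stopifnot(all(c("subject", "condition", "head_orientation_deg",
                  "eye_deviation_deg", "response") %in% names(trials)))
  trials |>
    dplyr::mutate(.score = recode_response(.data$response)) |>
    dplyr::group_by(.data$subject, .data$condition,
                    .data$head_orientation_deg, .data$eye_deviation_deg) |>
    dplyr::summarise(
      n_trials = dplyr::n(),
      prop_rightward = mean(.data$.score),
      prop_direct = mean(.data$response %in% c("direct", "D")),
      .groups = "drop"
    )
}

# core weighted least-squares logistic fit; no validation, used by the
# bootstrap hot loop.  psi(x) = 1 / (1 + exp(-(x - alpha) / beta))
.fit_logistic_core <- function(x, p, w, init = NULL) {
  sse <- function(theta) {
    psi <- 1 / (1 + exp(-(x - theta[1]) / exp(theta[2])))
    sum(w * (p - psi)^2)
  }
  if (is.null(init)) {
    q <- qlogis(pmin(pmax(p, 0.01), 0.99))
    b <- tryCatch(coef(lm(q ~ x)), error = function(e) c(0, NA))
    beta0 <- if (is.finite(b[2]) && b[2] > 0) 1 / b[2] else diff(range(x)) / 4
    alpha0 <- if (is.finite(b[2]) && b[2] != 0) -b[1] / b[2] else mean(x)
    alpha0 <- min(max(alpha0, min(x) - diff(range(x))), max(x) + diff(range(x)))
    init <- c(alpha0, log(beta0))
  }
  fit <- optim(init, sse, method = "Nelder-Mead",
               control = list(maxit = 500, reltol = 1e-12))
  fit <- optim(fit$par, sse, method = "BFGS",
               control = list(maxit = 200, reltol = 1e-14))
  list(alpha = fit$par[1], beta = exp(fit$par[2]), sse = fit$value,
       convergence = fit$convergence)
}

#' Fit a two-parameter logistic psychometric function
#'
#' Fits `psi(x) = 1 / (1 + exp(-(x - alpha) / beta))` to
#' proportion-rightward scores by weighted nonlinear least squares, with
#' weights equal to the number of trials per eye-deviation level.  `alpha`
#' is the 50% point: the eye deviation of subjectively direct gaze.  A
#' least-squares criterion is used because the 0.5 recoding of "direct"
#' responses breaks the binomial likelihood assumption behind a GLM fit.
#'
#' @param eye_deviations Eye deviations, degrees (at least 3 distinct
#'   levels).
#' @param proportions Proportion-rightward score at each level.
#' @param counts Trials per level (fit weights); default 1 per level.
#'
#' @return A list of class `"psychometric_fit"` with elements `alpha_deg`,
#'   `beta_deg`, `sse`, `n_levels`.
#' @examples
#' x <- seq(-20, 20, by = 5)
#' p <- 1 / (1 + exp(-(x - 3) / 5))
#' fit_logistic(x, p)
#' @export
fit_logistic <- function(eye_deviations, proportions, counts = NULL) {
  x <- as.numeric(eye_deviations)
  p <- as.numeric(proportions)
  if (length(x) != length(p)) {
    abort("`eye_deviations` and `proportions` must have equal length.",
          class = "gazecue_domain_error")
  }
  keep <- complete.cases(x, p)
  x <- x[keep]; p <- p[keep]
  w <- if (is.null(counts)) rep(1, length(x)) else as.numeric(counts)[keep]
  if (length(unique(x)) < 3) {
    abort("Need at least 3 distinct eye-deviation levels.",
          class = "gazecue_fit_error")
  }
  if (length(unique(p)) == 1) {
    abort("Proportions are constant; no psychometric slope to fit.",
          class = "gazecue_fit_error")
  }
  # sign convention: proportion-rightward must increase with eye deviation
  if (coef(lm(p ~ x, weights = w))[2] < 0) {
    abort(paste0("Proportions decrease with eye deviation; the logistic ",
                 "slope convention (beta > 0) is violated."),
          class = "gazecue_fit_error")
  }
  fit <- .fit_logistic_core(x, p, w)
  if (!is.finite(fit$alpha) || !is.finite(fit$beta)) {
    abort("Logistic fit failed to converge.", class = "gazecue_fit_error",
          data = list(x = x, p = p, w = w))
  }
  if (all(p %in% c(0, 1))) {
    warn("All proportions are 0 or 1; alpha clamped to the sampled range.",
         class = "gazecue_boundary_fit")
    fit$alpha <- min(max(fit$alpha, min(x)), max(x))
  }
  structure(
    list(alpha_deg = unname(fit$alpha), beta_deg = unname(fit$beta),
         sse = fit$sse, n_levels = length(unique(x))),
    class = "psychometric_fit"
  )
}

#' @export
print.psychometric_fit <- function(x, ...) {
  cat(sprintf("<psychometric_fit> alpha = %.3f deg, beta = %.3f deg (%d levels)\n",
              x$alpha_deg, x$beta_deg, x$n_levels))
  invisible(x)
}

#' Bootstrap confidence interval for the point of subjectively direct gaze
#'
#' Percentile bootstrap of the logistic 50% point: trials are resampled with
#' replacement within each eye-deviation cell (stratified), proportions are
#' recomputed and the logistic refit, and the interval is taken from the
#' quantiles of the resampled `alpha` values.
#'
#' @param trials Trial tibble for one subject x condition x head
#'   orientation, with columns `eye_deviation_deg` and `response`.
#' @param n_boot Number of bootstrap resamples (at least 100).
#' @param seed Seed for the resampling stream.
#' @param conf Confidence level.
#'
#' @return List with `ci_low_deg`, `ci_high_deg`, `alpha_deg` (point
#'   estimate), `n_failed` (resamples whose refit failed).  More than 20%
#'   failed refits is an error.
#' @export
bootstrap_direct_point <- function(trials, n_boot = 1000, seed = 1,
                                   conf = 0.95) {
  if (n_boot < 100) {
    abort("`n_boot` must be at least 100.", class = "gazecue_domain_error")
  }
  scores <- split(recode_response(trials$response),
                  trials$eye_deviation_deg)
  x <- as.numeric(names(scores))
  w <- lengths(scores)
  p0 <- vapply(scores, mean, numeric(1))
  point <- fit_logistic(x, p0, w)
  init <- c(point$alpha_deg, log(point$beta_deg))
  alphas <- rep(NA_real_, n_boot)
  withr::with_seed(seed, {
    for (b in seq_len(n_boot)) {
      pb <- vapply(scores, function(s)
        mean(s[sample.int(length(s), replace = TRUE)]), numeric(1))
      fit <- tryCatch(.fit_logistic_core(x, pb, w, init = init),
                      error = function(e) NULL)
      if (!is.null(fit) && is.finite(fit$alpha)) alphas[b] <- fit$alpha
    }
  })
  n_failed <- sum(is.na(alphas))
  if (n_failed > 0.2 * n_boot) {
    abort(sprintf("%d of %d bootstrap refits failed.", n_failed, n_boot),
          class = "gazecue_fit_error")
  }
  ci <- quantile(alphas, c((1 - conf) / 2, 1 - (1 - conf) / 2),
                 na.rm = TRUE, names = FALSE)
  list(ci_low_deg = ci[1], ci_high_deg = ci[2],
       alpha_deg = point$alpha_deg, n_failed = n_failed)
}

#' Fit psychometric functions across an experiment
#'
#' Fits one logistic per condition x head orientation, either per subject or
#' on the group data (all subjects' recoded scores pooled before fitting).
#' Optionally attaches bootstrap confidence intervals for the
#' subjectively-direct-gaze point.
#'
#' @param trials Trial tibble (see [proportion_scores()]).
#' @param level `"subject"` for per-subject fits or `"group"` for pooled
#'   fits.
#' @param n_boot Bootstrap resamples for the CI of `alpha`; 0 skips the
#'   bootstrap.
#' @param seed Seed for the bootstrap streams.
#'
#' @return Tibble with one row per fitted cell: `subject` (the label
#'   `"group"` for pooled fits), `condition`, `head_orientation_deg`,
#'   `alpha_deg`, `beta_deg`, `ci_low_deg`, `ci_high_deg`, `n_trials`.
#' @export
fit_psychometric <- function(trials, level = c("subject", "group"),
                             n_boot = 0, seed = 1) {
  level <- match.arg(level)
  if (level == "group") trials <- dplyr::mutate(trials, subject = "group")
  cells <- split(trials,
                 interaction(trials$subject, trials$condition,
                             trials$head_orientation_deg, drop = TRUE))
  rows <- lapply(cells, function(cell) {
    scores <- split(recode_response(cell$response), cell$eye_deviation_deg)
    x <- as.numeric(names(scores))
    w <- lengths(scores)
    p <- vapply(scores, mean, numeric(1))
    fit <- fit_logistic(x, p, w)
    ci <- c(NA_real_, NA_real_)
    if (n_boot > 0) {
      bs <- bootstrap_direct_point(
        cell, n_boot = n_boot,
        seed = seed + abs(sum(utf8ToInt(paste0(cell$subject[1],
                                               cell$condition[1])))) +
          as.integer(cell$head_orientation_deg[1] + 1000L))
      ci <- c(bs$ci_low_deg, bs$ci_high_deg)
    }
    tibble::tibble(
      subject = as.character(cell$subject[1]),
      condition = cell$condition[1],
      head_orientation_deg = cell$head_orientation_deg[1],
      alpha_deg = fit$alpha_deg, beta_deg = fit$beta_deg,
      ci_low_deg = ci[1], ci_high_deg = ci[2],
      n_trials = nrow(cell)
    )
  })
  dplyr::arrange(dplyr::bind_rows(rows), .data$subject, .data$condition,
                 .data$head_orientation_deg)
}
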