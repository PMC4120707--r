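#' Trinomial category probabilities under the two-criterion Gaussian model
#'
#' The internal representation of a gaze stimulus at direction `g` is
#' Gaussian with standard deviation `sigma`.  The probability of each
#' report is the area of that Gaussian falling below the left criterion
#' (`left`), between the criteria (`direct`), or above the right criterion
#' (`right`).
#'
#' @param g_deg Stimulus gaze direction(s), degrees.
#' @param b_l,b_r Left and right category criteria, degrees (`b_l < b_r`).
#' @param sigma Sensory noise SD, degrees (positive).
#' @return Tibble with columns `g_deg`, `p_left`, `p_direct`, `p_right`
#'   (rows sum to one).
#' @examples
#' category_probabilities(0, b_l = -3, b_r = 3, sigma = 3)
#' @export
category_probabilities <- function(g_deg, b_l, b_r, sigma) {
  if (sigma <= 0) {
    abort("`sigma` must be positive.", class = "gazecue_domain_error")
  }
  if (b_l >= b_r) {
    abort("`b_l` must lie below `b_r`.", class = "gazecue_domain_error")
  }
  p_left <- pnorm((b_l - g_deg) / sigma)
  cum_right <- pnorm((b_r - g_deg) / sigma)
  tibble::tibble(
    g_deg = g_deg,
    p_left = p_left,
    p_direct = cum_right - p_left,
    p_right = 1 - cum_right
  )
}

#' Count left/direct/right responses per eye-deviation level
#'
#' @param trials Trial tibble with `subject`, `condition`,
#'   `head_orientation_deg`, `eye_deviation_deg`, `response`.
#' @return Tibble with one row per cell and columns `n_left`, `n_direct`,
#'   `n_right`.
#' @export
count_categories <- function(trials) {
  trials |>
    dplyr::group_by(.data$subject, .data$condition,
                    .data$head_orientation_deg, .data$eye_deviation_deg) |>
    dplyr::summarise(
      n_left = sum(.data$response %in% c("left", "L")),
      n_direct = sum(.data$response %in% c("direct", "D")),
      n_right = sum(.data$response %in% c("right", "R")),
      .groups = "drop"
    )
}

# negative product-multinomial log-likelihood; theta = (peak, log w, log s)
.category_nll <- function(theta, x, n_l, n_d, n_r) {
  peak <- theta[1]
  width <- exp(theta[2])
  sigma <- exp(theta[3])
  b_l <- peak - width / 2
  b_r <- peak + width / 2
  p_l <- pnorm((b_l - x) / sigma)
  cum_r <- pnorm((b_r - x) / sigma)
  p_d <- cum_r - p_l
  p_r <- 1 - cum_r
  # zero counts contribute 0; probabilities floored inside the logs
  -sum(n_l * log(pmax(p_l, 1e-12)) +
       n_d * log(pmax(p_d, 1e-12)) +
       n_r * log(pmax(p_r, 1e-12)))
}

#' Maximum-likelihood fit of the trinomial categorization model
#'
#' Fits two category criteria and a sensory noise SD to left/direct/right
#' counts across eye-deviation levels by maximizing the product-multinomial
#' log-likelihood (see [category_probabilities()]).  The model is
#' reparameterized as (peak, log width, log sigma) so the invariants
#' `b_l < b_r` and `sigma > 0` hold by construction; the optimizer runs
#' from several jittered moment-based starting points and keeps the best.
#' The midpoint of the criteria is the peak direction of perceptually
#' direct gaze; their distance is the width of the cone of direct gaze.
#'
#' @param counts Tibble with columns `eye_deviation_deg`, `n_left`,
#'   `n_direct`, `n_right` (one head orientation's data).
#' @param n_starts Number of multi-start optimizations (default 8).
#' @param seed Seed for the start-point jitter.
#'
#' @return A list of class `"category_fit"` with `boundary_left_deg`,
#'   `boundary_right_deg`, `sigma_rep_deg`, `peak_deg`, `width_deg`,
#'   `log_lik`.
#' @examples
#' x <- seq(-20, 20, by = 5)
#' pr <- category_probabilities(x, b_l = -4, b_r = 4, sigma = 3)
#' counts <- tibble::tibble(eye_deviation_deg = x,
#'                          n_left = round(200 * pr$p_left),
#'                          n_direct = round(200 * pr$p_direct),
#'                          n_right = round(200 * pr$p_right))
#' fit_category_model(counts)
#' @export
fit_category_model <- function(counts, n_starts = 8, seed = 1) {
  need <- c("eye_deviation_deg", "n_left", "n_direct", "n_right")
  stopifnot(all(need %in% names(counts)))
  tot <- counts$n_left + counts$n_direct + counts$n_right
  counts <- counts[tot > 0, ]
  x <- counts$eye_deviation_deg
  n_l <- counts$n_left; n_d <- counts$n_direct; n_r <- counts$n_right
  if (length(unique(x)) < 3) {
    abort("Need at least 3 eye-deviation levels with trials.",
          class = "gazecue_fit_error")
  }
  observed <- c(sum(n_l) > 0, sum(n_d) > 0, sum(n_r) > 0)
  if (sum(observed) < 2) {
    abort("At least two response categories must be observed.",
          class = "gazecue_fit_error")
  }
  if (sum(n_d) == 0) {
    warn("No direct responses: the fitted criteria collapse together.",
         class = "gazecue_boundary_collapse")
  }

  # moment-based start: peak from the direct-response centroid, width from
  # the span where direct responses dominate, sigma from the level spacing
  n_tot <- n_l + n_d + n_r
  p_d <- n_d / n_tot
  peak0 <- if (sum(p_d) > 0) sum(x * p_d) / sum(p_d) else mean(x)
  dominant <- x[p_d >= 0.5 * max(p_d, 1 / max(n_tot))]
  span <- diff(range(x))
  width0 <- if (length(dominant)) {
    max(diff(range(dominant)), span / 8, 1)
  } else {
    max(span / 8, 1)
  }
  sigma0 <- max(mean(diff(sort(unique(x)))), 1)
  base <- c(peak0, log(width0), log(sigma0))

  best <- NULL
  withr::with_seed(seed, {
    starts <- c(list(base), lapply(seq_len(max(n_starts - 1, 0)), function(i) {
      base + c(rnorm(1, 0, span / 10), rnorm(1, 0, 0.4), rnorm(1, 0, 0.4))
    }))
    for (s in starts) {
      fit <- tryCatch({
        f <- optim(s, .category_nll, x = x, n_l = n_l, n_d = n_d, n_r = n_r,
                   method = "Nelder-Mead",
                   control = list(maxit = 1000, reltol = 1e-12))
        optim(f$par, .category_nll, x = x, n_l = n_l, n_d = n_d, n_r = n_r,
              method = "BFGS", control = list(maxit = 300, reltol = 1e-14))
      }, error = function(e) NULL)
      if (!is.null(fit) && (is.null(best) || fit$value < best$value)) {
        best <- fit
      }
    }
  })
  if (is.null(best)) {
    abort("Categorization-model fit failed from every starting point.",
          class = "gazecue_fit_error")
  }
  peak <- best$par[1]
  width <- exp(best$par[2])
  sigma <- exp(best$par[3])
  structure(
    list(boundary_left_deg = peak - width / 2,
         boundary_right_deg = peak + width / 2,
         sigma_rep_deg = sigma,
         peak_deg = peak,
         width_deg = width,
         log_lik = -best$value),
    class = "category_fit"
  )
}

#' @export
print.category_fit <- function(x, ...) {
  cat(sprintf(paste0("<category_fit> criteria [%.2f, %.2f] deg, ",
                     "sigma = %.2f deg\n  peak = %.2f, width = %.2f, ",
                     "logLik = %.2f\n"),
              x$boundary_left_deg, x$boundary_right_deg, x$sigma_rep_deg,
              x$peak_deg, x$width_deg, x$log_lik))
  invisible(x)
}

#' Centroid of the direct-response profile
#'
#' The proportion-direct-weighted mean eye deviation: a small-sample-robust
#' estimate of subjectively direct gaze computed from raw data rather than
#' from fitted model curves.
#'
#' @param eye_deviations_deg Eye-deviation levels, degrees.
#' @param prop_direct Proportion of "direct" responses at each level.
#' @return The centroid in degrees, or `NA` if no direct responses occurred.
#' @examples
#' centroid_direct(c(-5, 0, 5), c(0.2, 0.6, 0.2))  # 0
#' @export
centroid_direct <- function(eye_deviations_deg, prop_direct) {
  stopifnot(length(eye_deviations_deg) == length(prop_direct))
  total <- sum(prop_direct)
  if (!is.finite(total) || total <= 0) return(NA_real_)
  sum(eye_deviations_deg * prop_direct) / total
}

#' Overall proportion of "direct" responses
#'
#' @param trials Trial tibble (one subject x condition x head orientation).
#' @return Fraction of trials answered "direct".
#' @export
proportion_direct_overall <- function(trials) {
  if (nrow(trials) == 0) {
    abort("Need at least one trial.", class = "gazecue_domain_error")
  }
  mean(trials$response %in% c("direct", "D"))
}

#' Fit the categorization model across an experiment
#'
#' Fits one (criteria, sigma) triple per condition x head orientation,
#' per subject or on pooled group counts, and attaches the data-side
#' measures: the centroid of direct responses and the overall proportion
#' direct.  The returned tidy table is what downstream repeated-measures
#' analyses consume.
#'
#' @param trials Trial tibble.
#' @param level `"subject"` or `"group"` (counts pooled across subjects).
#' @param n_starts,seed Passed to [fit_category_model()].
#' @return Tibble with `subject`, `condition`, `head_orientation_deg`,
#'   `peak_deg`, `width_deg`, `sigma_deg`, `centroid_deg`, `prop_direct`,
#'   `log_lik`.
#' @export
fit_category_models <- function(trials, level = c("subject", "group"),
                                n_starts = 8, seed = 1) {
  level <- match.arg(level)
  if (level == "group") trials <- dplyr::mutate(trials, subject = "group")
  counts <- count_categories(trials)
  cells <- split(counts,
                 interaction(counts$subject, counts$condition,
                             counts$head_orientation_deg, drop = TRUE))
  rows <- lapply(cells, function(cell) {
    fit <- fit_category_model(cell, n_starts = n_starts, seed = seed)
    n_tot <- cell$n_left + cell$n_direct + cell$n_right
    tibble::tibble(
      subject = as.character(cell$subject[1]),
      condition = cell$condition[1],
      head_orientation_deg = cell$head_orientation_deg[1],
      peak_deg = fit$peak_deg,
      width_deg = fit$width_deg,
      sigma_deg = fit$sigma_rep_deg,
      centroid_deg = centroid_direct(cell$eye_deviation_deg,
                                     cell$n_direct / n_tot),
      prop_direct = sum(cell$n_direct) / sum(n_tot),
      log_lik = fit$log_lik
    )
  })
  dplyr::arrange(dplyr::bind_rows(rows), .data$subject, .data$condition,
                 .data$head_orientation_deg)
}
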