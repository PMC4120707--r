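#' Regress direct-gaze points on head orientation
#'
#' Ordinary least-squares line through the points of subjectively direct
#' gaze as a function of head orientation.  The slope `m` feeds the
#' cue-weight formulas; the intercept absorbs the constant leftward/
#' rightward bias and is reported but not used in the weights.
#'
#' @param head_orientations_deg Head orientations, degrees (at least 2
#'   distinct values).
#' @param direct_gaze_points_deg Fitted subjectively-direct-gaze points,
#'   degrees.
#' @return List with `slope_m` and `intercept_deg`.
#' @examples
#' fit_slope(c(-30, -15, 0, 15, 30), c(-3, -1.5, 0, 1.5, 3))  # m = 0.1
#' @export
fit_slope <- function(head_orientations_deg, direct_gaze_points_deg) {
  h <- as.numeric(head_orientations_deg)
  y <- as.numeric(direct_gaze_points_deg)
  if (length(unique(h)) < 2) {
    abort("Need at least 2 distinct head orientations.",
          class = "gazecue_domain_error")
  }
  b <- coef(lm(y ~ h))
  list(slope_m = unname(b[2]), intercept_deg = unname(b[1]))
}

#' Eye and head cue weights from a regression slope
#'
#' Under the constraint that the two weights sum to one, perceived gaze
#' direction is `G = (1 / (1 - m)) E + (m / (m - 1)) H`, where `m` is the
#' slope of the direct-gaze points against head orientation.  A negative
#' head weight means perceived gaze is repelled from the head orientation.
#'
#' @param m Regression slope (unitless); must differ from 1.
#' @return List with `w_eye = 1 / (1 - m)` and `w_head = m / (m - 1)`.
#' @examples
#' weights_from_slope(0.2)  # w_eye = 1.25, w_head = -0.25
#' @export
weights_from_slope <- function(m) {
  if (any(m == 1)) {
    abort("Slope m = 1 makes the cue weights singular.",
          class = "gazecue_singularity")
  }
  list(w_eye = 1 / (1 - m), w_head = m / (m - 1))
}

#' Dual-route decomposition of the whole-head cue weights
#'
#' Decomposes the whole-head percept into the eye-region signal and a
#' direct head route:
#' `G_WH = ((1 - m_ER) / (1 - m_WH)) G_ER + ((m_WH - m_ER) / (m_WH - 1)) H`,
#' where `m_WH` and `m_ER` are the regression slopes from the whole-head
#' and eye-region conditions.  The two route weights sum to one; the direct
#' weight is positive exactly when the repulsion is weaker with the head
#' visible (`m_WH < m_ER` for positive slopes), i.e. when head orientation
#' attracts perceived gaze.
#'
#' @param m_wh,m_er Slopes from the whole-head and eye-region conditions;
#'   `m_wh` must differ from 1.
#' @return List of class `"dual_route_decomposition"` with `m_wh`, `m_er`,
#'   `w_er_route = (1 - m_er) / (1 - m_wh)` and
#'   `w_direct = (m_wh - m_er) / (m_wh - 1)`.
#' @examples
#' decompose_routes(m_wh = 0.1, m_er = 0.3)  # w_direct = 2/9
#' @export
decompose_routes <- function(m_wh, m_er) {
  if (any(m_wh == 1)) {
    abort("Slope m_WH = 1 makes the decomposition singular.",
          class = "gazecue_singularity")
  }
  structure(
    list(m_wh = m_wh, m_er = m_er,
         w_er_route = (1 - m_er) / (1 - m_wh),
         w_direct = (m_wh - m_er) / (m_wh - 1)),
    class = "dual_route_decomposition"
  )
}

#' @export
print.dual_route_decomposition <- function(x, ...) {
  cat(sprintf(paste0("<dual_route_decomposition> m_WH = %.4f, m_ER = %.4f\n",
                     "  eye-region route weight: %.4f\n",
                     "  direct head route weight: %.4f\n"),
              x$m_wh, x$m_er, x$w_er_route, x$w_direct))
  invisible(x)
}

#' One-sample t test with Cohen's d
#'
#' Tests whether per-subject weight estimates differ from a null value,
#' reporting the t statistic, two-sided p value and the standardized effect
#' size `d = (mean - null) / SD`.
#'
#' @param values Per-subject estimates (at least 2, non-constant).
#' @param null_mean Null value, default 0.
#' @return Tibble with `mean`, `t_statistic`, `df`, `p_value`, `cohen_d`,
#'   `n`.
#' @export
group_t_test <- function(values, null_mean = 0) {
  values <- values[is.finite(values)]
  if (length(values) < 2) {
    abort("Need at least 2 finite values.", class = "gazecue_domain_error")
  }
  if (sd(values) == 0) {
    abort("Zero variance: the t statistic is undefined.",
          class = "gazecue_domain_error")
  }
  tt <- t.test(values, mu = null_mean)
  tibble::tibble(
    mean = mean(values),
    t_statistic = unname(tt$statistic),
    df = unname(tt$parameter),
    p_value = tt$p.value,
    cohen_d = (mean(values) - null_mean) / sd(values),
    n = length(values)
  )
}

#' Cue weights from a table of psychometric fits
#'
#' For every subject x condition, regresses the direct-gaze points on head
#' orientation and converts the slope to eye/head weights.
#'
#' @param fits Tibble from [fit_psychometric()] (columns `subject`,
#'   `condition`, `head_orientation_deg`, `alpha_deg`).
#' @return Tibble with `subject`, `condition`, `slope_m`, `intercept_deg`,
#'   `w_eye`, `w_head`.
#' @export
estimate_cue_weights <- function(fits) {
  fits |>
    dplyr::group_by(.data$subject, .data$condition) |>
    dplyr::summarise(
      {
        sl <- fit_slope(.data$head_orientation_deg, .data$alpha_deg)
        wt <- weights_from_slope(sl$slope_m)
        tibble::tibble(slope_m = sl$slope_m,
                       intercept_deg = sl$intercept_deg,
                       w_eye = wt$w_eye, w_head = wt$w_head)
      },
      .groups = "drop"
    )
}

#' Per-subject dual-route decompositions
#'
#' Joins each subject's whole-head and eye-region slopes and applies
#' [decompose_routes()].
#'
#' @param weights Tibble from [estimate_cue_weights()] containing both
#'   conditions for each subject.
#' @param whole_head,eye_region Names of the two conditions in `weights`.
#' @return Tibble with `subject`, `m_wh`, `m_er`, `w_er_route`, `w_direct`.
#' @export
decompose_by_subject <- function(weights, whole_head = "whole_head",
                                 eye_region = "eye_region") {
  wh <- dplyr::filter(weights, .data$condition == whole_head)
  er <- dplyr::filter(weights, .data$condition == eye_region)
  joined <- dplyr::inner_join(
    dplyr::select(wh, "subject", m_wh = "slope_m"),
    dplyr::select(er, "subject", m_er = "slope_m"),
    by = "subject"
  )
  if (nrow(joined) == 0) {
    abort("No subject has fits in both conditions.",
          class = "gazecue_domain_error")
  }
  joined |>
    dplyr::rowwise() |>
    dplyr::mutate(
      w_er_route = decompose_routes(.data$m_wh, .data$m_er)$w_er_route,
      w_direct = decompose_routes(.data$m_wh, .data$m_er)$w_direct
    ) |>
    dplyr::ungroup()
}
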