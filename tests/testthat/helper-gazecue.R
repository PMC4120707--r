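# shared fixtures: all data are generated in code at test time

tiny_spec <- function(seed = 1L) {
  design_spec(n_identities = 2, head_orientations = c(-30, 0, 30),
              eye_deviations = c(-20, -10, 0, 10, 20),
              n_repetitions = 1, seed = seed)
}

control_spec <- function(seed = 1L) {
  design_spec(head_orientations = 0,
              conditions = c("whole_head", "eye_region", "eyes_only"),
              seed = seed)
}

# trials for one subject x condition x head orientation cell
simulate_cell <- function(obs, condition = "eye_region", head = 0,
                          eye_levels = seq(-20, 20, by = 5),
                          n_per_level = 12, seed = 1) {
  stim <- tibble::tibble(
    subject = 1,
    condition = condition,
    head_orientation_deg = head,
    eye_deviation_deg = rep(eye_levels, each = n_per_level)
  )
  withr::with_seed(seed, {
    g <- perceive(obs, stim, noise_draw = rnorm(nrow(stim)))$g_perceived_deg
    stim$response <- respond(obs, g)
  })
  stim
}

# expected point of subjectively direct gaze of the generative model:
# the mean percept equals the criterion midpoint at the PSE
analytic_pse <- function(obs, condition, head) {
  mid <- (obs$boundary_left_deg + obs$boundary_right_deg) / 2
  if (condition == "whole_head") {
    num <- mid - ((1 - obs$w_direct_head) * obs$w_eye_route_head +
                    obs$w_direct_head) * head -
      (1 - obs$w_direct_head) * obs$bias_deg
    num / ((1 - obs$w_direct_head) * (1 - obs$w_eye_route_head))
  } else {
    (mid - obs$w_eye_route_head * head - obs$bias_deg) /
      (1 - obs$w_eye_route_head)
  }
}

# independent OLS oracle for fit_slope
slope_by_moments <- function(x, y) {
  sum((x - mean(x)) * (y - mean(y))) / sum((x - mean(x))^2)
}

# independent log-likelihood evaluation for the grid oracle (written
# directly from the Gaussian-area model, not via the package's objective)
trinomial_loglik <- function(counts, b_l, b_r, sigma) {
  x <- counts$eye_deviation_deg
  p_l <- pmax(pnorm((b_l - x) / sigma), 1e-12)
  cum_r <- pnorm((b_r - x) / sigma)
  p_d <- pmax(cum_r - pnorm((b_l - x) / sigma), 1e-12)
  p_r <- pmax(1 - cum_r, 1e-12)
  sum(counts$n_left * log(p_l) + counts$n_direct * log(p_d) +
        counts$n_right * log(p_r))
}

# brute-force grid search over (peak, width, sigma) for the trinomial MLE
grid_best_loglik <- function(counts, peak_range, width_range, sigma_range,
                             n_grid = 21) {
  best <- -Inf
  for (pk in seq(peak_range[1], peak_range[2], length.out = n_grid)) {
    for (wd in seq(width_range[1], width_range[2], length.out = n_grid)) {
      for (sg in seq(sigma_range[1], sigma_range[2], length.out = n_grid)) {
        ll <- trinomial_loglik(counts, pk - wd / 2, pk + wd / 2, sg)
        if (ll > best) best <- ll
      }
    }
  }
  best
}

# expected counts under the categorization model (deterministic rounding)
counts_from_model <- function(b_l, b_r, sigma, n_per_level,
                              x = seq(-20, 20, by = 5)) {
  pr <- category_probabilities(x, b_l, b_r, sigma)
  tibble::tibble(eye_deviation_deg = x,
                 n_left = round(n_per_level * pr$p_left),
                 n_direct = round(n_per_level * pr$p_direct),
                 n_right = round(n_per_level * pr$p_right))
}
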