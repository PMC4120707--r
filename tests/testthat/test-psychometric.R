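test_that("responses recode to the 0 / 0.5 / 1 scheme", {
  expect_equal(recode_response(c("left", "direct", "right")), c(0, 0.5, 1))
  expect_equal(recode_response(c("L", "D", "R")), c(0, 0.5, 1))
  expect_error(recode_response("sideways"), class = "gazecue_parse_error")
})

test_that("proportion scores equal (n_R + 0.5 n_D) / n per cell", {
  cell <- tibble::tibble(subject = 1, condition = "whole_head",
                         head_orientation_deg = 0, eye_deviation_deg = 0,
                         response = c("left", "direct", "right"))
  sc <- proportion_scores(cell)
  expect_equal(sc$prop_rightward, 0.5)
  expect_equal(sc$prop_direct, 1 / 3)
  all_d <- dplyr::mutate(cell, response = "direct")
  expect_equal(proportion_scores(all_d)$prop_rightward, 0.5)
  expect_equal(proportion_scores(all_d)$prop_direct, 1)
  expect_equal(proportion_scores(dplyr::mutate(cell, response = "right"))$
                 prop_rightward, 1)
  # property: random cells match the counting formula exactly
  withr::with_seed(4, {
    for (i in 1:20) {
      n <- sample(3:30, 1)
      resp <- sample(c("left", "direct", "right"), n, replace = TRUE)
      tr <- tibble::tibble(subject = 1, condition = "c",
                           head_orientation_deg = 0, eye_deviation_deg = 0,
                           response = resp)
      expected <- (sum(resp == "right") + 0.5 * sum(resp == "direct")) / n
      expect_equal(proportion_scores(tr)$prop_rightward, expected)
    }
  })
})

test_that("fit_logistic recovers noiseless parameters and respects contracts", {
  x <- seq(-20, 20, by = 5)
  p <- 1 / (1 + exp(-(x - 3) / 5))
  fit <- fit_logistic(x, p)
  expect_lt(abs(fit$alpha_deg - 3), 1e-6)
  expect_lt(abs(fit$beta_deg - 5), 1e-6)
  # symmetry about zero pins alpha at zero
  p_sym <- 1 / (1 + exp(-x / 4))
  expect_lt(abs(fit_logistic(x, p_sym)$alpha_deg), 1e-6)
  # translation equivariance on a grid of shifts
  for (shift in c(-7, -2, 4)) {
    p_s <- 1 / (1 + exp(-(x - 3 - shift) / 5))
    expect_lt(abs(fit_logistic(x, p_s)$alpha_deg - (3 + shift)), 1e-5)
  }
  expect_error(fit_logistic(x, rev(p)), class = "gazecue_fit_error")
  expect_error(fit_logistic(x, rep(0.5, length(x))),
               class = "gazecue_fit_error")
  expect_error(fit_logistic(c(0, 5), c(0.2, 0.8)),
               class = "gazecue_fit_error")
  expect_warning(fit0 <- fit_logistic(x, as.numeric(x > 0)),
                 class = "gazecue_boundary_fit")
  expect_true(fit0$alpha_deg >= min(x) && fit0$alpha_deg <= max(x))
})

test_that("bootstrap interval is deterministic and shrinks with data", {
  obs <- observer_params(w_eye_route_head = -0.25, w_direct_head = 0,
                         bias_deg = -1)
  small <- simulate_cell(obs, n_per_level = 8, seed = 31)
  big <- simulate_cell(obs, n_per_level = 120, seed = 31)
  ci_small <- bootstrap_direct_point(small, n_boot = 200, seed = 5)
  ci_small2 <- bootstrap_direct_point(small, n_boot = 200, seed = 5)
  expect_identical(ci_small, ci_small2)
  ci_big <- bootstrap_direct_point(big, n_boot = 200, seed = 5)
  width <- function(ci) ci$ci_high_deg - ci$ci_low_deg
  expect_lt(width(ci_big), width(ci_small))
  expect_error(bootstrap_direct_point(small, n_boot = 10),
               class = "gazecue_domain_error")
})

test_that("bootstrap interval covers the generative direct-gaze point", {
  obs <- observer_params(w_eye_route_head = -0.25, w_direct_head = 0,
                         bias_deg = -1)
  true_alpha <- analytic_pse(obs, "eye_region", head = 0)
  n_rep <- 150
  covered <- logical(n_rep)
  for (r in seq_len(n_rep)) {
    cell <- simulate_cell(obs, n_per_level = 12, seed = 1000 + r)
    ci <- bootstrap_direct_point(cell, n_boot = 199, seed = r)
    covered[r] <- ci$ci_low_deg <= true_alpha && true_alpha <= ci$ci_high_deg
  }
  expect_gt(mean(covered), 0.91)
  expect_lte(mean(covered), 1)
})

test_that("fitted direct-gaze points match the generative model's PSE", {
  obs <- observer_params(w_eye_route_head = -0.25, w_direct_head = 0.15,
                         bias_deg = -1, sigma_rep_deg = 3)
  pop <- population_spec(n_observers = 1, mean = obs, sd = list(), seed = 12)
  big_design <- generate_main_design(
    design_spec(n_identities = 4, n_repetitions = 60, seed = 12), 1)
  sim <- simulate_experiment(pop, list(big_design))
  fits <- fit_psychometric(sim$trials, level = "subject")
  fits$expected <- mapply(analytic_pse, condition = fits$condition,
                          head = fits$head_orientation_deg,
                          MoreArgs = list(obs = obs))
  expect_true(all(abs(fits$alpha_deg - fits$expected) < 0.3))
  # the PSE-vs-head slope follows the closed form -w / (1 - w) per route
  er <- fits[fits$condition == "eye_region", ]
  m_er <- fit_slope(er$head_orientation_deg, er$alpha_deg)$slope_m
  expect_lt(abs(m_er - (-obs$w_eye_route_head / (1 - obs$w_eye_route_head))),
            0.02)
  # adding the direct route strictly flattens the whole-head slope
  wh <- fits[fits$condition == "whole_head", ]
  m_wh <- fit_slope(wh$head_orientation_deg, wh$alpha_deg)$slope_m
  expect_lt(m_wh, m_er)
})

test_that("group-level fits pool the recoded scores across subjects", {
  pop <- population_spec(n_observers = 4, seed = 6)
  designs <- lapply(1:4, function(i) generate_main_design(tiny_spec(), i))
  sim <- simulate_experiment(pop, designs)
  grp <- fit_psychometric(sim$trials, level = "group")
  expect_setequal(unique(grp$subject), "group")
  expect_equal(nrow(grp), 2 * 3)  # condition x head orientation
  expect_true(all(grp$n_trials ==
                    nrow(sim$trials) / 6))
})
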