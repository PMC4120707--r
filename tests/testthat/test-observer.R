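test_that("perceive applies the dual-route combination rule", {
  stim <- function(cond, e, h) {
    tibble::tibble(condition = cond, head_orientation_deg = h,
                   eye_deviation_deg = e)
  }
  # zero head weights: veridical eyes
  veridical <- observer_params(w_eye_route_head = 0, w_direct_head = 0,
                               bias_deg = 0)
  expect_equal(perceive(veridical, stim("whole_head", 5, 30))$g_perceived_deg, 5)
  # repulsive eye route alone: G_ER = 1.25 * 0 - 0.25 * 30 = -7.5
  repelled <- observer_params(w_eye_route_head = -0.25, w_direct_head = 0,
                              bias_deg = 0)
  p <- perceive(repelled, stim("eye_region", 0, 30))
  expect_equal(p$g_eye_region_deg, -7.5)
  expect_equal(p$g_perceived_deg, -7.5)
  # direct attraction cancels the repulsion: 0.8 * (-7.5) + 0.2 * 30 = 0
  dual <- observer_params(w_eye_route_head = -0.25, w_direct_head = 0.2,
                          bias_deg = 0)
  expect_equal(perceive(dual, stim("whole_head", 0, 30))$g_perceived_deg, 0)
  # the direct route is inactive when the head context is hidden
  expect_equal(perceive(dual, stim("eye_region", 0, 30))$g_perceived_deg, -7.5)
  # bias shifts the eye-region signal additively
  biased <- observer_params(w_eye_route_head = 0, w_direct_head = 0,
                            bias_deg = -2)
  expect_equal(perceive(biased, stim("eye_region", 5, 0))$g_perceived_deg, 3)
})

test_that("respond categorizes against the two criteria", {
  obs <- observer_params(boundary_left_deg = -4, boundary_right_deg = 4,
                         lapse_rate = 0)
  expect_equal(respond(obs, c(0, -10, 10, -4, 4)),
               c("direct", "left", "right", "direct", "direct"))
})

test_that("full lapsing yields uniform response frequencies", {
  obs <- observer_params(lapse_rate = 0.999999)
  withr::with_seed(11, {
    resp <- respond(obs, rep(0, 10000))
  })
  freq <- table(factor(resp, levels = c("left", "direct", "right"))) / 10000
  expect_true(all(abs(freq - 1 / 3) < 0.02))
})

test_that("response frequencies match the analytic trinomial law", {
  obs <- observer_params(w_eye_route_head = -0.25, w_direct_head = 0.15,
                         bias_deg = -1, sigma_rep_deg = 3)
  for (g in c(-6, 0, 3.5)) {
    withr::with_seed(21, {
      resp <- respond(obs, g + obs$sigma_rep_deg * rnorm(10000))
    })
    emp <- table(factor(resp, levels = c("left", "direct", "right"))) / 10000
    theo <- category_probabilities(g, obs$boundary_left_deg,
                                   obs$boundary_right_deg,
                                   obs$sigma_rep_deg)
    tv <- 0.5 * sum(abs(as.numeric(emp) -
                          c(theo$p_left, theo$p_direct, theo$p_right)))
    expect_lt(tv, 0.02)
  }
})

test_that("observer and population specs enforce their domains", {
  expect_error(observer_params(sigma_rep_deg = 0),
               class = "gazecue_domain_error")
  expect_error(observer_params(boundary_left_deg = 4, boundary_right_deg = -4),
               class = "gazecue_domain_error")
  expect_error(observer_params(lapse_rate = 1),
               class = "gazecue_domain_error")
  expect_error(population_spec(sd = list(nonsense = 1)),
               class = "gazecue_invalid_spec")
  expect_error(population_spec(sd = list(bias_deg = -1)),
               class = "gazecue_invalid_spec")
  pop <- population_spec(n_observers = 50,
                         mean = observer_params(sigma_rep_deg = 0.5),
                         sd = list(sigma_rep_deg = 0.5, lapse_rate = 0.05),
                         seed = 8)
  params <- draw_population(pop)
  expect_true(all(params$sigma_rep_deg > 0))
  expect_true(all(params$lapse_rate >= 0 & params$lapse_rate < 1))
  expect_true(all(params$boundary_left_deg < params$boundary_right_deg))
  expect_identical(params, draw_population(pop))
})

test_that("simulate_experiment is reproducible and sized by the designs", {
  pop <- population_spec(n_observers = 3, seed = 17)
  designs <- lapply(1:3, function(i) generate_main_design(tiny_spec(), i))
  sim <- simulate_experiment(pop, designs)
  expect_equal(nrow(sim$trials), 3 * 2 * 2 * 3 * 5)
  expect_true(all(sim$trials$response %in% c("left", "direct", "right")))
  sim2 <- simulate_experiment(pop, designs)
  expect_identical(sim$trials, sim2$trials)
  # a flat tibble with a subject column works too
  sim3 <- simulate_experiment(pop, dplyr::bind_rows(designs))
  expect_identical(sort(table(sim3$trials$response)),
                   sort(table(sim$trials$response)))
  expect_error(simulate_experiment(pop, designs[1:2]),
               class = "gazecue_invalid_spec")
})

test_that("the noiseless limit is a deterministic function of E and H", {
  # bias chosen so no stimulus cell lands exactly on a criterion
  pop <- population_spec(
    n_observers = 1,
    mean = observer_params(sigma_rep_deg = 1e-9, lapse_rate = 0,
                           bias_deg = -0.7),
    sd = list(), seed = 2)
  sim <- simulate_experiment(pop, list(generate_main_design(tiny_spec(), 1)))
  by_cell <- dplyr::count(sim$trials, condition, head_orientation_deg,
                          eye_deviation_deg, response)
  # every (condition, E, H) cell maps to a single response
  expect_equal(anyDuplicated(by_cell[, 1:3]), 0)
})
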