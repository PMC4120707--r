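#' Parameters of the dual-route generative observer
#'
#' The observer combines the eye deviation `E` and head orientation `H` of a
#' stimulus through two routes.  The eye-region route yields an intermediate
#' signal
#' `G_ER = (1 - w_eye_route_head) * E + w_eye_route_head * H + bias_deg`,
#' where `w_eye_route_head` is expected negative: rotating the head changes
#' the visible iris/sclera geometry and *repels* perceived gaze away from the
#' head.  When the head context is visible (`whole_head` condition), head
#' orientation additionally acts as a direct, attractive cue:
#' `G = (1 - w_direct_head) * G_ER + w_direct_head * H`.  The weight pair at
#' each stage sums to one.  Gaussian sensory noise with standard deviation
#' `sigma_rep_deg` enters once, at the final percept, and the percept is
#' categorized as left/direct/right against two criteria.
#'
#' @param w_eye_route_head Signed head weight inside the eye-region route
#'   (unitless; negative = repulsive).
#' @param w_direct_head Head weight of the direct route (unitless; applied
#'   only when the head context is visible).
#' @param bias_deg Constant shift of perceived gaze, degrees (negative =
#'   leftward).
#' @param sigma_rep_deg Standard deviation of the sensory noise, degrees.
#' @param boundary_left_deg,boundary_right_deg Category criteria, degrees:
#'   percepts below the left criterion are judged "left", above the right
#'   criterion "right", otherwise "direct".
#' @param lapse_rate Probability of a uniformly random response.
#'
#' @return A list of class `"observer_params"`.
#' @examples
#' obs <- observer_params(w_eye_route_head = -0.25, w_direct_head = 0.15)
#' perceive(obs, tibble::tibble(condition = "whole_head",
#'                              head_orientation_deg = 30,
#'                              eye_deviation_deg = 0))
#' @export
observer_params <- function(w_eye_route_head = -0.25,
                            w_direct_head = 0.15,
                            bias_deg = -1,
                            sigma_rep_deg = 3,
                            boundary_left_deg = -4,
                            boundary_right_deg = 4,
                            lapse_rate = 0) {
  if (sigma_rep_deg <= 0) {
    abort("`sigma_rep_deg` must be positive.", class = "gazecue_domain_error")
  }
  if (boundary_left_deg >= boundary_right_deg) {
    abort("`boundary_left_deg` must lie below `boundary_right_deg`.",
          class = "gazecue_domain_error")
  }
  if (lapse_rate < 0 || lapse_rate >= 1) {
    abort("`lapse_rate` must lie in [0, 1).", class = "gazecue_domain_error")
  }
  structure(
    list(
      w_eye_route_head = w_eye_route_head,
      w_direct_head = w_direct_head,
      bias_deg = bias_deg,
      sigma_rep_deg = sigma_rep_deg,
      boundary_left_deg = boundary_left_deg,
      boundary_right_deg = boundary_right_deg,
      lapse_rate = lapse_rate
    ),
    class = "observer_params"
  )
}

#' @export
print.observer_params <- function(x, ...) {
  cat("<observer_params>\n")
  for (f in names(x)) cat(sprintf("  %-18s %g\n", f, x[[f]]))
  invisible(x)
}

#' Map stimuli to noiseless or noisy percepts
#'
#' Applies the dual-route combination rule to a table of stimuli.  The head
#' context is visible only in the `whole_head` condition; in the
#' `eye_region` and `eyes_only` conditions the percept is the eye-region
#' signal alone.
#'
#' @param obs An [observer_params()] object.
#' @param stimuli Tibble with columns `condition`, `head_orientation_deg`,
#'   `eye_deviation_deg`.
#' @param noise_draw Standard-normal deviates, recycled to the number of
#'   stimuli; scaled by `sigma_rep_deg` and added to the percept.  Default 0
#'   gives the noiseless (mean) percept.
#'
#' @return Tibble with columns `g_eye_region_deg` (the intermediate signal
#'   `G_ER`) and `g_perceived_deg` (the final percept `G`).
#' @export
perceive <- function(obs, stimuli, noise_draw = 0) {
  stopifnot(inherits(obs, "observer_params"))
  e <- stimuli$eye_deviation_deg
  h <- stimuli$head_orientation_deg
  g_er <- (1 - obs$w_eye_route_head) * e + obs$w_eye_route_head * h +
    obs$bias_deg
  head_visible <- stimuli$condition == "whole_head"
  g <- ifelse(head_visible,
              (1 - obs$w_direct_head) * g_er + obs$w_direct_head * h,
              g_er)
  g <- g + obs$sigma_rep_deg * rep_len(noise_draw, length(g))
  tibble::tibble(g_eye_region_deg = g_er, g_perceived_deg = g)
}

#' Categorize percepts as left, direct, or right
#'
#' Percepts below the left criterion are reported "left", above the right
#' criterion "right", otherwise "direct".  With probability `lapse_rate` the
#' report is instead drawn uniformly from the three categories.  Lapse draws
#' use the current RNG stream; wrap in [withr::with_seed()] for
#' reproducibility.
#'
#' @param obs An [observer_params()] object.
#' @param g_perceived Perceived gaze directions, degrees (e.g. the
#'   `g_perceived_deg` column of [perceive()]).
#'
#' @return Character vector in `c("left", "direct", "right")`.
#' @export
respond <- function(obs, g_perceived) {
  stopifnot(inherits(obs, "observer_params"), all(is.finite(g_perceived)))
  out <- ifelse(g_perceived < obs$boundary_left_deg, "left",
                ifelse(g_perceived > obs$boundary_right_deg, "right",
                       "direct"))
  if (obs$lapse_rate > 0) {
    n <- length(out)
    lapse <- runif(n) < obs$lapse_rate
    if (any(lapse)) {
      out[lapse] <- sample(.responses, sum(lapse), replace = TRUE)
    }
  }
  out
}

#' Specify a population of dual-route observers
#'
#' Observer parameters vary across subjects: each field is drawn
#' independently from a Gaussian with the given mean and standard deviation,
#' truncated to its valid domain (`sigma_rep_deg > 0`, `lapse_rate` in
#' `[0, 1)`, left boundary below right).  The defaults describe the study
#' regime: a clearly repulsive eye-route head weight, a moderate positive
#' direct head weight, a slight leftward bias, 3 degrees of sensory noise
#' and criteria at plus/minus 4 degrees.
#'
#' @param n_observers Number of observers.
#' @param mean An [observer_params()] object giving population means.
#' @param sd Named list of population standard deviations; fields not named
#'   default to 0 (no between-subject variation).
#' @param seed Seed governing both the parameter draws and, in
#'   [simulate_experiment()], the response streams.
#'
#' @return A list of class `"population_spec"`.
#' @export
population_spec <- function(n_observers = 20,
                            mean = observer_params(),
                            sd = list(w_eye_route_head = 0.05,
                                      w_direct_head = 0.05,
                                      bias_deg = 0.5),
                            seed = 1L) {
  stopifnot(inherits(mean, "observer_params"), n_observers >= 1)
  fields <- names(unclass(mean))
  bad <- setdiff(names(sd), fields)
  if (length(bad)) {
    abort(paste0("Unknown observer field(s) in `sd`: ",
                 paste(bad, collapse = ", ")),
          class = "gazecue_invalid_spec")
  }
  sds <- stats::setNames(rep(0, length(fields)), fields)
  sds[names(sd)] <- unlist(sd)
  if (any(sds < 0)) {
    abort("Population standard deviations must be non-negative.",
          class = "gazecue_invalid_spec")
  }
  structure(
    list(n_observers = as.integer(n_observers),
         mean = mean, sd = as.list(sds), seed = as.integer(seed)),
    class = "population_spec"
  )
}

# truncated-normal draw by rejection; bounds may be open (enforced by eps)
.rtrunc_norm <- function(n, mean, sd, lower = -Inf, upper = Inf) {
  if (sd == 0) return(rep(mean, n))
  x <- rnorm(n, mean, sd)
  bad <- which(x <= lower | x >= upper)
  while (length(bad)) {
    x[bad] <- rnorm(length(bad), mean, sd)
    bad <- which(x <= lower | x >= upper)
  }
  x
}

#' Draw per-observer parameters from a population specification
#'
#' @param population A [population_spec()].
#' @return Tibble with one row per observer (column `subject` = 1..n) and one
#'   column per [observer_params()] field.
#' @export
draw_population <- function(population) {
  stopifnot(inherits(population, "population_spec"))
  m <- unclass(population$mean)
  s <- population$sd
  n <- population$n_observers
  withr::with_seed(population$seed, {
    params <- tibble::tibble(
      subject = seq_len(n),
      w_eye_route_head = .rtrunc_norm(n, m$w_eye_route_head, s$w_eye_route_head),
      w_direct_head = .rtrunc_norm(n, m$w_direct_head, s$w_direct_head),
      bias_deg = .rtrunc_norm(n, m$bias_deg, s$bias_deg),
      sigma_rep_deg = .rtrunc_norm(n, m$sigma_rep_deg, s$sigma_rep_deg,
                                   lower = 0),
      boundary_left_deg = .rtrunc_norm(n, m$boundary_left_deg,
                                       s$boundary_left_deg),
      boundary_right_deg = .rtrunc_norm(n, m$boundary_right_deg,
                                        s$boundary_right_deg),
      lapse_rate = .rtrunc_norm(n, m$lapse_rate, s$lapse_rate,
                                lower = -1e-12, upper = 1)
    )
    # enforce ordered criteria jointly
    bad <- which(params$boundary_left_deg >= params$boundary_right_deg)
    while (length(bad)) {
      params$boundary_left_deg[bad] <-
        .rtrunc_norm(length(bad), m$boundary_left_deg, s$boundary_left_deg)
      params$boundary_right_deg[bad] <-
        .rtrunc_norm(length(bad), m$boundary_right_deg, s$boundary_right_deg)
      bad <- which(params$boundary_left_deg >= params$boundary_right_deg)
    }
    params$lapse_rate <- pmax(params$lapse_rate, 0)
  })
  params
}

.params_from_row <- function(row) {
  observer_params(
    w_eye_route_head = row$w_eye_route_head,
    w_direct_head = row$w_direct_head,
    bias_deg = row$bias_deg,
    sigma_rep_deg = row$sigma_rep_deg,
    boundary_left_deg = row$boundary_left_deg,
    boundary_right_deg = row$boundary_right_deg,
    lapse_rate = row$lapse_rate
  )
}

#' Simulate a full categorization experiment
#'
#' Draws a population of observers, then runs each observer through its
#' trial design: every design row gains a categorical response produced by
#' [perceive()] followed by [respond()].  Fully reproducible from the
#' population seed.
#'
#' @param population A [population_spec()].
#' @param designs Either a list of trial tibbles, one per observer, or a
#'   single tibble whose `subject` column distinguishes observers.  Subject
#'   labels in the output follow the observer index 1..n.
#'
#' @return A list of class `"gaze_simulation"` with elements `trials`
#'   (the design rows plus `response`) and `observers` (the ground-truth
#'   parameter tibble from [draw_population()]).
#' @examples
#' pop <- population_spec(n_observers = 2, seed = 7)
#' designs <- lapply(1:2, function(i)
#'   generate_main_design(design_spec(n_repetitions = 1), i))
#' sim <- simulate_experiment(pop, designs)
#' head(sim$trials)
#' @export
simulate_experiment <- function(population, designs) {
  stopifnot(inherits(population, "population_spec"))
  if (is.data.frame(designs)) {
    designs <- split(designs, designs$subject)
  }
  if (length(designs) != population$n_observers) {
    abort("Need exactly one design per observer.",
          class = "gazecue_invalid_spec")
  }
  observers <- draw_population(population)
  per_obs <- lapply(seq_len(population$n_observers), function(i) {
    obs <- .params_from_row(observers[i, ])
    d <- designs[[i]]
    withr::with_seed(population$seed + 10000L + i, {
      percept <- perceive(obs, d, noise_draw = rnorm(nrow(d)))
      d$response <- respond(obs, percept$g_perceived_deg)
    })
    d$subject <- i
    d
  })
  structure(
    list(trials = dplyr::bind_rows(per_obs), observers = observers),
    class = "gaze_simulation"
  )
}

#' @export
print.gaze_simulation <- function(x, ...) {
  cat("<gaze_simulation>: ", nrow(x$trials), " trials, ",
      nrow(x$observers), " observers\n", sep = "")
  invisible(x)
}
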