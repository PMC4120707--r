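#' Specify a factorial gaze-categorization design
#'
#' A design specification holds the factor levels of the categorization
#' experiment: facial identities, head orientations (degrees, positive =
#' rotated toward the observer's right), eye deviations (degrees, same sign
#' convention), display conditions, and the number of repetitions of each
#' factorial cell per condition.  The defaults reproduce the main
#' experiment's structure: 4 identities x 5 head orientations x 9 eye
#' deviations, each cell shown once per block, 3 blocks per condition.
#'
#' @param n_identities Number of facial identities.
#' @param head_orientations Head orientations in degrees.
#' @param eye_deviations Eye deviations in degrees.
#' @param n_repetitions Repetitions of each factorial cell per condition
#'   (equivalently, blocks per condition).
#' @param conditions Display conditions, ordered.  The main design uses
#'   `c("whole_head", "eye_region")`; the control design adds `"eyes_only"`.
#' @param seed Master seed; per-subject randomization streams are derived as
#'   `seed + subject_index`.
#'
#' @return A list of class `"design_spec"`.
#' @examples
#' spec <- design_spec()
#' nrow(generate_main_design(spec, subject_index = 1))  # 1080
#' @export
design_spec <- function(n_identities = 4,
                        head_orientations = c(-30, -15, 0, 15, 30),
                        eye_deviations = seq(-20, 20, by = 5),
                        n_repetitions = 3,
                        conditions = c("whole_head", "eye_region"),
                        seed = 1L) {
  if (n_identities < 1 || n_repetitions < 1) {
    abort("`n_identities` and `n_repetitions` must be positive counts.",
          class = "gazecue_invalid_spec")
  }
  if (length(head_orientations) == 0 || length(eye_deviations) == 0 ||
      length(conditions) == 0) {
    abort("Factor level lists must be non-empty.",
          class = "gazecue_invalid_spec")
  }
  if (anyDuplicated(conditions)) {
    abort("`conditions` must be distinct.", class = "gazecue_invalid_spec")
  }
  structure(
    list(
      n_identities = as.integer(n_identities),
      head_orientations = as.numeric(head_orientations),
      eye_deviations = as.numeric(eye_deviations),
      n_repetitions = as.integer(n_repetitions),
      conditions = as.character(conditions),
      seed = as.integer(seed)
    ),
    class = "design_spec"
  )
}

#' @export
print.design_spec <- function(x, ...) {
  cat("<design_spec>\n")
  cat("  identities:       ", x$n_identities, "\n")
  cat("  head orientations:", paste(x$head_orientations, collapse = ", "), "\n")
  cat("  eye deviations:   ", paste(x$eye_deviations, collapse = ", "), "\n")
  cat("  repetitions:      ", x$n_repetitions, "\n")
  cat("  conditions:       ", paste(x$conditions, collapse = ", "), "\n")
  cat("  seed:             ", x$seed, "\n")
  invisible(x)
}

# one presentation of every identity x head x eye cell
.design_cells <- function(spec) {
  tidyr::expand_grid(
    identity = seq_len(spec$n_identities),
    head_orientation_deg = spec$head_orientations,
    eye_deviation_deg = spec$eye_deviations
  )
}

.warn_if_degenerate <- function(spec) {
  if (spec$n_identities == 1 && length(spec$head_orientations) == 1 &&
      length(spec$eye_deviations) == 1) {
    warn("Degenerate design: a single factorial cell per block.",
         class = "gazecue_degenerate_spec")
  }
}

#' Generate the main-experiment trial sequence for one subject
#'
#' Builds the blocked, within-block randomized trial order of the main
#' experiment.  The two display conditions alternate across blocks
#' (`2 * n_repetitions` blocks in total); each block contains exactly one
#' presentation of every identity x head orientation x eye deviation cell,
#' shuffled with a seeded per-subject stream.  Which condition opens block 1
#' is counterbalanced across subjects by the parity of `subject_index`
#' (even starts with the first condition in the spec, odd with the second).
#'
#' @param spec A [design_spec()] with exactly two conditions.
#' @param subject_index Non-negative integer identifying the subject; drives
#'   both counterbalancing and the randomization stream.
#'
#' @return A tibble with columns `subject`, `block`, `trial_index`,
#'   `condition`, `identity`, `head_orientation_deg`, `eye_deviation_deg`.
#'   With the default spec: 1080 rows in 6 blocks of 180 trials.
#' @examples
#' d <- generate_main_design(design_spec(), subject_index = 2)
#' table(d$block)
#' @export
generate_main_design <- function(spec, subject_index = 0L) {
  stopifnot(inherits(spec, "design_spec"))
  if (length(spec$conditions) != 2) {
    abort("The main design requires exactly two conditions.",
          class = "gazecue_invalid_spec")
  }
  .warn_if_degenerate(spec)
  cells <- .design_cells(spec)
  n_blocks <- 2L * spec$n_repetitions
  first <- if (subject_index %% 2 == 0) spec$conditions else rev(spec$conditions)
  block_conditions <- rep_len(first, n_blocks)

  withr::with_seed(spec$seed + subject_index, {
    blocks <- lapply(seq_len(n_blocks), function(b) {
      shuffled <- cells[sample.int(nrow(cells)), ]
      shuffled$block <- b
      shuffled$condition <- block_conditions[b]
      shuffled
    })
  })
  out <- dplyr::bind_rows(blocks)
  out$subject <- subject_index
  out$trial_index <- seq_len(nrow(out))
  dplyr::select(out, "subject", "block", "trial_index", "condition",
                "identity", "head_orientation_deg", "eye_deviation_deg")
}

#' Generate the control-experiment trial sequence for one subject
#'
#' The control experiment fixes head orientation at 0 degrees and shows three
#' display conditions (whole head, eye region, eyes only) in separate blocks,
#' with all blocks of one condition consecutive and the condition order
#' randomized per subject.  Each block contains one presentation of every
#' identity x eye deviation cell, shuffled within block.
#'
#' @param spec A [design_spec()] with three conditions and
#'   `head_orientations = 0`.
#' @inheritParams generate_main_design
#'
#' @return A tibble in the same format as [generate_main_design()].  With the
#'   default control spec: 108 trials per condition in 3 blocks of 36.
#' @examples
#' spec <- design_spec(head_orientations = 0,
#'                     conditions = c("whole_head", "eye_region", "eyes_only"))
#' d <- generate_control_design(spec, subject_index = 0)
#' table(d$condition)
#' @export
generate_control_design <- function(spec, subject_index = 0L) {
  stopifnot(inherits(spec, "design_spec"))
  if (length(spec$conditions) != 3) {
    abort("The control design requires exactly three conditions.",
          class = "gazecue_invalid_spec")
  }
  if (!identical(unique(spec$head_orientations), 0)) {
    abort("The control design fixes head orientation at 0 degrees.",
          class = "gazecue_invalid_spec")
  }
  .warn_if_degenerate(spec)
  cells <- .design_cells(spec)
  withr::with_seed(spec$seed + subject_index, {
    condition_order <- sample(spec$conditions)
    blocks <- lapply(seq_len(3L * spec$n_repetitions), function(b) {
      shuffled <- cells[sample.int(nrow(cells)), ]
      shuffled$block <- b
      shuffled$condition <- condition_order[ceiling(b / spec$n_repetitions)]
      shuffled
    })
  })
  out <- dplyr::bind_rows(blocks)
  out$subject <- subject_index
  out$trial_index <- seq_len(nrow(out))
  dplyr::select(out, "subject", "block", "trial_index", "condition",
                "identity", "head_orientation_deg", "eye_deviation_deg")
}

#' Write or read a trial table in the package's CSV dialect
#'
#' Trial tables (designs or simulated data) are exchanged as plain CSV.
#' Responses, when present, are stored as single letters `L`/`D`/`R` and
#' mapped back to `left`/`direct`/`right` on read.
#'
#' @param trials A trial tibble.
#' @param path File path.
#' @return `write_trials()` returns `trials` invisibly; `read_trials()`
#'   returns a tibble.
#' @export
write_trials <- function(trials, path) {
  out <- trials
  if ("response" %in% names(out)) {
    out$response <- unname(.response_codes[out$response])
  }
  readr::write_csv(out, path)
  invisible(trials)
}

#' @rdname write_trials
#' @export
read_trials <- function(path) {
  out <- readr::read_csv(path, show_col_types = FALSE)
  if ("response" %in% names(out)) {
    decode <- stats::setNames(names(.response_codes), .response_codes)
    bad <- setdiff(unique(out$response), c(names(decode), .responses))
    if (length(bad)) {
      abort(paste0("Unknown response label(s): ",
                   paste(bad, collapse = ", ")),
            class = "gazecue_parse_error")
    }
    out$response <- ifelse(out$response %in% names(decode),
                           decode[out$response], out$response)
  }
  out
}
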