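#' Task design for a random-walk direction-estimation block
#'
#' A block presents a sequence of motion directions in which every direction
#' after the first differs from its predecessor by a relative step drawn from
#' a balanced multiset of multiples of 10 degrees within `+/- range_deg`.
#' The repetition counts per relative direction are fixed by the design so
#' that block lengths are 101, 100, 103 and 109 trials for ranges of 20, 40,
#' 80 and 180 degrees.
#'
#' @param range_deg Group range in degrees: one of 20, 40, 80, 180.
#' @return A list with elements `range_deg`, `step`, `rel_directions`,
#'   `repetitions` and `trials_per_block`.
#' @examples
#' task_design(20)$trials_per_block # 101
#' @export
task_design <- function(range_deg) {
  reps <- c(`20` = 20, `40` = 11, `80` = 6, `180` = 3)
  key <- as.character(range_deg)
  if (length(range_deg) != 1 || !key %in% names(reps)) {
    stop("`range_deg` must be one of 20, 40, 80, 180", call. = FALSE)
  }
  rel <- if (range_deg == 180) {
    seq(-170, 180, by = 10) # -180 and +180 coincide on the circle
  } else {
    seq(-range_deg, range_deg, by = 10)
  }
  list(
    range_deg = range_deg,
    step = 10,
    rel_directions = rel,
    repetitions = unname(reps[key]),
    trials_per_block = length(rel) * unname(reps[key]) + 1L
  )
}

#' Generate random-walk stimulus sequences
#'
#' The first trial of every block is uniform on \[0, 360); each later trial's
#' direction is the previous direction plus a relative step drawn without
#' replacement from the design's balanced multiset (each permitted relative
#' direction appears exactly `repetitions` times per block).
#'
#' @param design A [task_design()], or a group range in degrees.
#' @param n_blocks Blocks per subject (default 15, i.e. three 5-block sessions).
#' @param subjects Subject identifiers (an integer count or a vector of ids).
#' @param seed Optional integer seed for reproducible sequences.
#' @return A tibble with columns `subject`, `session`, `block`, `trial`,
#'   `group_range_deg`, `stimulus_deg`.
#' @export
simulate_stimuli <- function(design, n_blocks = 15, subjects = 1, seed = NULL) {
  if (is.numeric(design) && length(design) == 1) design <- task_design(design)
  ids <- if (length(subjects) == 1 && is.numeric(subjects)) seq_len(subjects) else subjects
  gen <- function() {
    purrr::map_dfr(ids, function(sid) {
      purrr::map_dfr(seq_len(n_blocks), function(b) {
        steps <- sample(rep(design$rel_directions, design$repetitions))
        stim <- wrap_360(cumsum(c(stats::runif(1, 0, 360), steps)))
        tibble::tibble(
          subject = sid,
          session = (b - 1L) %/% 5L + 1L,
          block = b,
          trial = seq_along(stim),
          group_range_deg = design$range_deg,
          stimulus_deg = stim
        )
      })
    })
  }
  if (is.null(seed)) gen() else withr::with_seed(seed, gen())
}

#' Generative parameters for synthetic responses
#'
#' Defaults are realistic effect sizes for this task family: a repulsive
#' derivative-of-Gaussian bias away from the previous stimulus (amplitude
#' -5 degrees, peak 38 degrees), an attractive one centred on the previous
#' response (amplitude +8, peak 29), response noise of 8 degrees, and no
#' cardinal-axis bias unless `cardinal` is supplied.
#'
#' @param a_rep,l_rep Amplitude (negative) and peak location of the repulsive
#'   curve, degrees.
#' @param a_att,l_att Amplitude (positive) and peak location of the attractive
#'   curve, degrees.
#' @param beta_rep,beta_att Normalised centres of the two curves: 0 is the
#'   previous stimulus, 1 the previous response.
#' @param sigma_resp Von Mises response noise SD in degrees.
#' @param cardinal Either `NULL` or a list with `beta0`, `a`, `v` describing a
#'   sinusoidal cardinal-axis bias (see [cardinal_bias()]).
#' @return A list of class `sb_gen_params`.
#' @export
generative_params <- function(a_rep = -5, l_rep = 38, a_att = 8, l_att = 29,
                              beta_rep = 0, beta_att = 1, sigma_resp = 8,
                              cardinal = NULL) {
  stopifnot(l_rep > 0, l_att > 0, sigma_resp > 0)
  structure(
    list(
      a_rep = a_rep, l_rep = l_rep, a_att = a_att, l_att = l_att,
      beta_rep = beta_rep, beta_att = beta_att, sigma_resp = sigma_resp,
      cardinal = cardinal
    ),
    class = "sb_gen_params"
  )
}

#' Sinusoidal cardinal-axis bias function
#'
#' `beta0 + a * sgn(x) * (sin(4|x| - asin(v)) + v)` where `x` is the stimulus
#' direction relative to the vertical axis (here taken at 90 degrees). The
#' asymmetry parameter `v` in \[-1, 1\] controls how much stronger biases
#' around the vertical axis are than around the horizontal axis; `sgn(0) = 0`
#' so the curve is continuous at the axis when `beta0 = 0`.
#'
#' @param theta Stimulus directions in degrees.
#' @param params List with components `beta0`, `a`, `v` (degrees, degrees,
#'   unitless).
#' @return Bias values in degrees.
#' @export
cardinal_bias <- function(theta, params) {
  v <- params$v
  if (abs(v) > 1) stop("`v` must lie in [-1, 1]", call. = FALSE)
  x <- wrap_signed(theta - 90)
  xr <- abs(x) * pi / 180
  params$beta0 + params$a * sign(x) * (sin(4 * xr - asin(v)) + v)
}

#' Generate responses with sequential and cardinal biases
#'
#' Forward model of the descriptive bias-curve mixture: the response on trial
#' t is the stimulus plus (optionally) a cardinal-axis bias, a repulsive DoG
#' bias centred at `beta_rep`-mixed history, an attractive DoG bias centred at
#' `beta_att`-mixed history, and von Mises noise. The recursion uses the
#' noisy realised previous response, so attraction is centred on what the
#' synthetic observer actually reported. The first trial of each block
#' carries no sequential terms.
#'
#' @param stimuli Tibble from [simulate_stimuli()].
#' @param params A [generative_params()] object.
#' @param seed Optional integer seed.
#' @return The input tibble with `response_deg` and `error_deg` columns added.
#' @export
simulate_responses <- function(stimuli, params = generative_params(), seed = NULL) {
  stopifnot(inherits(params, "sb_gen_params"))
  gen <- function() {
    df <- dplyr::arrange(stimuli, .data$subject, .data$block, .data$trial)
    noise <- vonmises_sample(nrow(df), 0, params$sigma_resp)
    card <- if (is.null(params$cardinal)) {
      rep(0, nrow(df))
    } else {
      cardinal_bias(df$stimulus_deg, params$cardinal)
    }
    resp <- numeric(nrow(df))
    key <- paste(df$subject, df$block)
    new_block <- c(TRUE, key[-1] != key[-nrow(df)])
    for (i in seq_len(nrow(df))) {
      s <- df$stimulus_deg[i]
      if (new_block[i]) {
        bias <- 0
      } else {
        xs <- circ_dist(df$stimulus_deg[i - 1], s)
        d <- circ_dist(resp[i - 1], df$stimulus_deg[i - 1])
        x_rep <- wrap_signed(xs + params$beta_rep * d)
        x_att <- wrap_signed(xs + params$beta_att * d)
        bias <- dog(x_rep, params$a_rep, params$l_rep) +
          dog(x_att, params$a_att, params$l_att)
      }
      resp[i] <- wrap_360(s + card[i] + bias + noise[i])
    }
    df$response_deg <- resp
    df$error_deg <- circ_dist(resp, df$stimulus_deg)
    df
  }
  if (is.null(seed)) gen() else withr::with_seed(seed, gen())
}

#' Simulate a full synthetic cohort
#'
#' Convenience wrapper mirroring the study layout: subjects split evenly over
#' the four range groups (20, 40, 80, 180 degrees), `n_blocks` blocks each,
#' responses generated from one set of generative parameters.
#'
#' @param n_subjects Total number of subjects (multiple of the number of
#'   groups used).
#' @param n_blocks Blocks per subject.
#' @param params A [generative_params()] object.
#' @param ranges Group ranges to use.
#' @param seed Optional integer seed.
#' @return A trial tibble covering all subjects.
#' @export
simulate_cohort <- function(n_subjects = 8, n_blocks = 15,
                            params = generative_params(),
                            ranges = c(20, 40, 80, 180), seed = NULL) {
  gen <- function() {
    group <- rep(ranges, length.out = n_subjects)
    purrr::map_dfr(seq_len(n_subjects), function(sid) {
      stim <- simulate_stimuli(task_design(group[sid]), n_blocks, subjects = 1)
      stim$subject <- sid
      simulate_responses(stim, params)
    })
  }
  if (is.null(seed)) gen() else withr::with_seed(seed, gen())
}

#' Attach one-trial-back history columns
#'
#' Adds, within each (subject, block), the previous stimulus and response and
#' their wrapped offsets from the current stimulus. First-of-block trials get
#' `NA` history.
#'
#' @param trials A trial tibble with `subject`, `block`, `trial`,
#'   `stimulus_deg`, `response_deg`.
#' @return The tibble with `prev_stim_deg`, `prev_resp_deg`,
#'   `prev_stim_offset`, `prev_resp_offset` and `resp_stim_gap` (previous
#'   response minus previous stimulus, wrapped) columns.
#' @export
add_history <- function(trials) {
  trials |>
    dplyr::arrange(.data$subject, .data$block, .data$trial) |>
    dplyr::group_by(.data$subject, .data$block) |>
    dplyr::mutate(
      prev_stim_deg = dplyr::lag(.data$stimulus_deg),
      prev_resp_deg = dplyr::lag(.data$response_deg),
      prev_stim_offset = ifelse(
        is.na(.data$prev_stim_deg), NA_real_,
        circ_dist(dplyr::coalesce(.data$prev_stim_deg, 0), .data$stimulus_deg)
      ),
      prev_resp_offset = ifelse(
        is.na(.data$prev_resp_deg), NA_real_,
        circ_dist(dplyr::coalesce(.data$prev_resp_deg, 0), .data$stimulus_deg)
      ),
      resp_stim_gap = ifelse(
        is.na(.data$prev_resp_deg), NA_real_,
        circ_dist(
          dplyr::coalesce(.data$prev_resp_deg, 0),
          dplyr::coalesce(.data$prev_stim_deg, 0)
        )
      )
    ) |>
    dplyr::ungroup()
}
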