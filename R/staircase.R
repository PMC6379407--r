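#' Adaptive staircase configuration
#'
#' The experiment's transformed up/down rule: two consecutive identical
#' responses move the matching-triangle contrast against the response
#' direction (2-down 2-up), the starting level is uniform on +/-20 Weber %,
#' the initial step is 10 Weber % and halves at each reversal, and a track
#' terminates after seven reversals. Levels are expressed in Weber contrast;
#' the corresponding luminance is `Lb * (1 + c/100)`.
#'
#' @param start_range half-width of the uniform starting interval (Weber %)
#' @param initial_step first step size (Weber %)
#' @param stop_reversals reversal count at which the track finishes
#' @param level_bounds clipping bounds for the level (Weber %); the defaults
#'   are the luminance limits 0 and 40 cd/m^2 at a 20 cd/m^2 background
#' @return object of class `staircase_config`
#' @export
staircase_config <- function(start_range = 20, initial_step = 10,
                             stop_reversals = 7, level_bounds = c(-100, 100)) {
  if (initial_step <= 0) stop("initial_step must be positive")
  if (stop_reversals < 1) stop("stop_reversals must be >= 1")
  structure(list(rule = "2-down 2-up", start_range = start_range,
                 initial_step = initial_step,
                 stop_reversals = as.integer(stop_reversals),
                 level_bounds = level_bounds),
            class = "staircase_config")
}

#' Initialise one staircase track
#'
#' @param cond_id condition identifier the track belongs to
#' @param cfg a [staircase_config()]
#' @return object of class `staircase_state`; the starting level is drawn
#'   uniformly from +/- `start_range` using the current RNG stream
#' @export
init_staircase <- function(cond_id, cfg = staircase_config()) {
  structure(list(cond_id = cond_id, cfg = cfg,
                 level = stats::runif(1, -cfg$start_range, cfg$start_range),
                 step = cfg$initial_step,
                 run_count = 0L, last_response = NA,
                 last_move = "none", reversals = 0L, finished = FALSE,
                 history = list(levels = numeric(0), responses = logical(0),
                                reversal = logical(0))),
            class = "staircase_state")
}

#' Advance a staircase by one response
#'
#' Two consecutive "lighter" reports (`TRUE`) lower the level (the matching
#' triangle is made darker); two consecutive "darker" reports raise it. Each
#' move resets the response run. A move whose direction differs from the
#' previous move is a reversal: the reversal count increments and the step
#' halves (so `step == initial_step / 2^reversals` after every update) before
#' the move is applied. The track finishes at the seventh reversal. Levels are
#' clipped to the configured bounds.
#'
#' @param state a [staircase_state][init_staircase()]
#' @param response logical, `TRUE` = "lighter"
#' @return the updated state
#' @export
staircase_update <- function(state, response) {
  stopifnot(inherits(state, "staircase_state"))
  if (state$finished) stop("cannot update a finished staircase (", state$cond_id, ")")
  presented <- state$level
  reversal_here <- FALSE
  if (!is.na(state$last_response) && state$last_response == response) {
    state$run_count <- state$run_count + 1L
  } else {
    state$run_count <- 1L
  }
  state$last_response <- response
  if (state$run_count >= 2L) {
    move <- if (response) "down" else "up"
    if (state$last_move != "none" && move != state$last_move) {
      reversal_here <- TRUE
      state$reversals <- state$reversals + 1L
      state$step <- state$cfg$initial_step / 2^state$reversals
      if (state$reversals >= state$cfg$stop_reversals) state$finished <- TRUE
    }
    delta <- if (move == "down") -state$step else state$step
    state$level <- min(max(state$level + delta, state$cfg$level_bounds[1]),
                       state$cfg$level_bounds[2])
    state$last_move <- move
    state$run_count <- 0L
    state$last_response <- NA
  }
  state$history$levels <- c(state$history$levels, presented)
  state$history$responses <- c(state$history$responses, response)
  state$history$reversal <- c(state$history$reversal, reversal_here)
  state
}

#' Weber contrast to matching-triangle luminance
#'
#' @param contrast Weber contrast (%)
#' @param background_lum background luminance Lb (cd/m^2)
#' @return luminance `Lb * (1 + contrast/100)` (cd/m^2)
#' @export
weber_to_lum <- function(contrast, background_lum = 20) {
  background_lum * (1 + contrast / 100)
}

#' Run one observer's full session
#'
#' Twenty interleaved staircases, one per condition. On every trial an
#' unfinished condition is chosen uniformly at random, the observer's response
#' at that track's current level is simulated, and the track is updated; the
#' session ends when all tracks have finished (seven reversals each).
#'
#' @param observer an [observer_params()]
#' @param cfg a [staircase_config()]
#' @param seed integer seed for the session (start levels, interleaving and
#'   responses all derive from it)
#' @param max_trials safety cap on total trials
#' @return list with `trials` (data frame: `observer_id`, `trial_index`,
#'   condition fields, `contrast_weber_pct`, `matching_lum_cdm2`,
#'   `response_lighter`, `reversal_flag`, `step_size`) and `states` (the 20
#'   finished [staircase_state][init_staircase()] objects)
#' @export
run_session <- function(observer, cfg = staircase_config(), seed = 1L,
                        max_trials = 20000L) {
  stopifnot(inherits(observer, "observer_params"))
  grid <- condition_grid()
  with_preserved_seed(seed, {
    states <- lapply(grid$condition_id, init_staircase, cfg = cfg)
    names(states) <- grid$condition_id
    n_alloc <- 4096L
    cond <- character(n_alloc); lev <- numeric(n_alloc)
    resp <- logical(n_alloc); revf <- logical(n_alloc); stp <- numeric(n_alloc)
    t <- 0L
    unfinished <- grid$condition_id
    while (length(unfinished) > 0L) {
      t <- t + 1L
      if (t > max_trials) stop("session exceeded max_trials without finishing")
      if (t > n_alloc) {
        n_alloc <- n_alloc * 2L
        length(cond) <- n_alloc; length(lev) <- n_alloc
        length(resp) <- n_alloc; length(revf) <- n_alloc; length(stp) <- n_alloc
      }
      id <- unfinished[sample.int(length(unfinished), 1L)]
      st <- states[[id]]
      r <- simulate_response(observer, id, st$level)
      cond[t] <- id; lev[t] <- st$level; resp[t] <- r
      st <- staircase_update(st, r)
      n_hist <- length(st$history$reversal)
      revf[t] <- st$history$reversal[n_hist]
      stp[t] <- st$step
      states[[id]] <- st
      if (st$finished) unfinished <- setdiff(unfinished, id)
    }
    idx <- seq_len(t)
    m <- match(cond[idx], grid$condition_id)
    trials <- data.frame(
      observer_id = observer$observer_id, trial_index = idx,
      condition_id = cond[idx],
      inducer_condition = grid$inducer_condition[m],
      cued_polarity = grid$cued_polarity[m],
      blur_level = grid$blur_level[m],
      contrast_weber_pct = lev[idx],
      matching_lum_cdm2 = weber_to_lum(lev[idx]),
      response_lighter = as.integer(resp[idx]),
      reversal_flag = as.integer(revf[idx]),
      step_size = stp[idx],
      stringsAsFactors = FALSE)
    list(trials = trials, states = states)
  })
}

#' Mean of the final reversal levels of a track
#'
#' Classical staircase threshold estimate; used as a fitting-free cross-check
#' on the psychometric PSE.
#'
#' @param state a finished [staircase_state][init_staircase()]
#' @param n_last number of terminal reversals to average
#' @return mean level at the last `n_last` reversals (Weber %)
#' @export
reversal_mean <- function(state, n_last = 4) {
  idx <- which(state$history$reversal)
  if (length(idx) < n_last) stop("track has fewer than ", n_last, " reversals")
  mean(state$history$levels[utils::tail(idx, n_last)])
}
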