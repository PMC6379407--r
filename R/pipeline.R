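#' Derive independent child seeds from a master seed
#'
#' One master seed drives the whole pipeline; per-observer and per-stage
#' streams are spawned by drawing integer seeds from a stream initialised with
#' the master, so any stage can be rerun in isolation.
#'
#' @param seed master integer seed
#' @param n number of child seeds
#' @return integer vector of length `n`, each in \[1, 2^31 - 2\]
#' @export
split_seed <- function(seed, n) {
  with_preserved_seed(seed, sample.int(.Machine$integer.max - 1L, n))
}

#' Full run configuration
#'
#' A simulated experiment is a pure function of this object: the same
#' configuration and seed always reproduce the same trial logs, fits and
#' summaries.
#'
#' @param seed master seed
#' @param population a [population_config()]
#' @param staircase a [staircase_config()]
#' @param fit_asymptotes estimate psychometric asymptotes instead of fixing
#'   them
#' @param r_scale Cauchy prior scale for Bayes factors
#' @param extent_deg rendered panel size (deg), for [run_render()]
#' @return object of class `run_config`
#' @export
run_config <- function(seed = 1L, population = population_config(),
                       staircase = staircase_config(), fit_asymptotes = FALSE,
                       r_scale = sqrt(2) / 2, extent_deg = 13) {
  structure(list(seed = as.integer(seed), population = population,
                 staircase = staircase, fit_asymptotes = fit_asymptotes,
                 r_scale = r_scale, extent_deg = extent_deg),
            class = "run_config")
}

#' Save / load a run configuration as YAML
#'
#' @param cfg a [run_config()]
#' @param path YAML file
#' @return `save_config` returns `path`; `load_config` returns the
#'   reconstructed [run_config()] (round-trips exactly)
#' @export
save_config <- function(cfg, path) {
  stopifnot(inherits(cfg, "run_config"))
  out <- list(seed = cfg$seed,
              population = unclass(cfg$population),
              staircase = unclass(cfg$staircase),
              fit_asymptotes = cfg$fit_asymptotes,
              r_scale = cfg$r_scale, extent_deg = cfg$extent_deg)
  out$population$group_pse <- as.list(cfg$population$group_pse)
  yaml::write_yaml(out, path)
  invisible(path)
}

#' @rdname save_config
#' @export
load_config <- function(path) {
  raw <- yaml::read_yaml(path)
  pop <- raw$population
  pop$group_pse <- unlist(pop$group_pse)
  stair <- raw$staircase
  stair$rule <- NULL  # fixed by construction, not a constructor argument
  stair$level_bounds <- unlist(stair$level_bounds)
  run_config(seed = raw$seed,
             population = do.call(population_config, pop),
             staircase = do.call(staircase_config, stair),
             fit_asymptotes = raw$fit_asymptotes,
             r_scale = raw$r_scale, extent_deg = raw$extent_deg)
}

#' Simulate one complete experiment
#'
#' Draws the observer population, runs every observer's interleaved staircase
#' session, fits psychometric functions to every cell, and computes the group
#' summary. Optionally writes the trial log and PSE table as CSV and the
#' summary as JSON.
#'
#' @param cfg a [run_config()]
#' @param out_dir if non-`NULL`, directory to write `trials.csv`,
#'   `pse_table.csv`, `observers.csv` and `summary.json`
#' @param quiet suppress progress messages
#' @return list with `population`, `trials`, `pse_table`, `summary`
#' @export
run_simulation <- function(cfg = run_config(), out_dir = NULL, quiet = TRUE) {
  stopifnot(inherits(cfg, "run_config"))
  seeds <- split_seed(cfg$seed, cfg$population$n_observers + 1L)
  t0 <- proc.time()[3]
  population <- make_population(cfg$population, seed = seeds[1])
  sessions <- lapply(seq_along(population), function(i)
    run_session(population[[i]], cfg$staircase, seed = seeds[i + 1L]))
  trials <- do.call(rbind, lapply(sessions, `[[`, "trials"))
  t1 <- proc.time()[3]
  pse_table <- build_pse_table(trials, fit_asymptotes = cfg$fit_asymptotes)
  t2 <- proc.time()[3]
  summary <- group_summary(pse_table, r_scale = cfg$r_scale)
  if (!quiet)
    message(sprintf("seed %d: %d observers, %d trials (%.1fs), %d fits (%.1fs)",
                    cfg$seed, length(population), nrow(trials), t1 - t0,
                    nrow(pse_table), t2 - t1))
  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    utils::write.csv(trials, file.path(out_dir, "trials.csv"), row.names = FALSE)
    utils::write.csv(pse_table, file.path(out_dir, "pse_table.csv"),
                     row.names = FALSE)
    utils::write.csv(population_to_df(population),
                     file.path(out_dir, "observers.csv"), row.names = FALSE)
    write_group_summary(summary, file.path(out_dir, "summary.json"))
  }
  list(population = population, trials = trials, pse_table = pse_table,
       summary = summary)
}

# does one experiment's summary reproduce the canonical effect structure?
# (a) black-cued > white-cued at blur 1-4 in both inducer types,
# (b) larger homogeneous than mixed differences (blur 1-4),
# (c) sign reversal at the most extreme blur in the mixed condition
sign_structure_ok <- function(differences) {
  d <- function(type, b)
    differences$mean_diff[differences$inducer_type == type &
                          differences$blur_level == b]
  mix <- vapply(1:4, function(b) d("mixed", b), numeric(1))
  hom <- vapply(1:4, function(b) d("homogeneous", b), numeric(1))
  all(mix < 0) && all(hom < 0) &&
    mean(abs(hom)) > mean(abs(mix)) &&
    d("mixed", 5) > 0
}

#' Repeat the pipeline and measure parameter recovery
#'
#' Runs [run_simulation()] `R` times under child seeds of `cfg$seed` and
#' compares fitted PSEs with each replicate's generative truth: per-condition
#' bias and RMSE of the fitted minus true PSE, and the fraction of replicates
#' whose group summary reproduces the canonical effect-sign structure
#' (black-cued lighter at blur levels 1-4 in both inducer types, homogeneous
#' effect larger than mixed, reversal at the most extreme mixed blur).
#'
#' @param cfg a [run_config()]
#' @param R number of replicate experiments (>= 2)
#' @param quiet suppress per-replicate progress
#' @return list with `per_condition` (data frame: `condition_id`, `bias`,
#'   `rmse`, `n_cells`), `sign_structure_rate`, `replicates` (logical vector)
#' @export
run_recovery <- function(cfg = run_config(), R = 50, quiet = TRUE) {
  if (R < 2) stop("R must be >= 2")
  seeds <- split_seed(cfg$seed, R)
  grid <- condition_grid()
  err_sum <- err_sq <- n_cells <- stats::setNames(numeric(nrow(grid)),
                                                  grid$condition_id)
  sign_ok <- logical(R)
  for (r in seq_len(R)) {
    cfg_r <- cfg
    cfg_r$seed <- seeds[r]
    res <- run_simulation(cfg_r, quiet = TRUE)
    truth <- population_to_df(res$population)
    m <- merge(res$pse_table, truth[, c("observer_id", "condition_id", "true_pse")],
               by = c("observer_id", "condition_id"))
    m <- m[m$converged & !is.na(m$pse_weber_pct), ]
    err <- m$pse_weber_pct - m$true_pse
    agg_n <- tapply(err, m$condition_id, length)
    agg_s <- tapply(err, m$condition_id, sum)
    agg_q <- tapply(err^2, m$condition_id, sum)
    ids <- names(agg_n)
    n_cells[ids] <- n_cells[ids] + agg_n
    err_sum[ids] <- err_sum[ids] + agg_s
    err_sq[ids] <- err_sq[ids] + agg_q
    sign_ok[r] <- sign_structure_ok(res$summary$differences)
    if (!quiet) message(sprintf("replicate %d/%d done (sign structure %s)",
                                r, R, if (sign_ok[r]) "ok" else "MISSED"))
  }
  per_condition <- data.frame(
    condition_id = grid$condition_id,
    bias = err_sum[grid$condition_id] / n_cells[grid$condition_id],
    rmse = sqrt(err_sq[grid$condition_id] / n_cells[grid$condition_id]),
    n_cells = as.integer(n_cells[grid$condition_id]),
    stringsAsFactors = FALSE)
  rownames(per_condition) <- NULL
  list(per_condition = per_condition,
       sign_structure_rate = mean(sign_ok), replicates = sign_ok)
}

#' Render the full stimulus set to PNG files
#'
#' One Kanizsa panel per inducer condition x blur level (15 panels) plus
#' matching panels at a set of probe contrasts for each blur level and
#' orientation. Filenames encode the condition; renders are deterministic
#' given the configuration (fixed noise seeds).
#'
#' @param cfg a [run_config()]
#' @param out_dir output directory
#' @param geom a [display_geometry()]
#' @param match_contrasts Weber contrasts (%) at which matching panels are
#'   rendered
#' @return character vector of files written, invisibly
#' @export
run_render <- function(cfg = run_config(), out_dir, geom = display_geometry(),
                       match_contrasts = c(-20, 0, 20)) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  files <- character(0)
  for (cond in c("homog_black", "homog_white", "mixed")) {
    for (b in 1:5) {
      sig <- blur_sigmas()[b]
      img <- render_kanizsa(kanizsa_spec(cond, sig), geom,
                            extent_deg = cfg$extent_deg)
      f <- file.path(out_dir, sprintf("kanizsa_%s_blur%d_sigma%.1f.png",
                                      cond, b, sig))
      write_stimulus_png(img, f)
      files <- c(files, f)
    }
  }
  for (orient in c("up", "down")) {
    for (b in 1:5) {
      sig <- blur_sigmas()[b]
      for (cw in match_contrasts) {
        sp <- match_spec(orient, weber_to_lum(cw), sig,
                         noise_seed = cfg$seed + 100L * b)
        img <- render_matching(sp, geom, extent_deg = cfg$extent_deg)
        f <- file.path(out_dir, sprintf("match_%s_blur%d_c%+05.1f.png",
                                        orient, b, cw))
        write_stimulus_png(img, f)
        files <- c(files, f)
      }
    }
  }
  invisible(files)
}
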