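#' Bernoulli negative log-likelihood of a cumulative Gaussian psychometric
#' function
#'
#' Psi(c) = gamma + (1 - gamma - lambda) * pnorm((c - mu)/sigma), evaluated on
#' raw trials (not binned proportions): staircase sampling leaves unequal
#' numbers of trials per level, and the trialwise likelihood lets every
#' observation constrain the PSE.
#'
#' @param mu,sigma location (PSE) and spread, Weber %
#' @param contrast numeric vector of presented Weber contrasts
#' @param response 0/1 (or logical) "lighter" reports
#' @param gamma,lambda fixed asymptote rates
#' @return scalar negative log-likelihood; Psi is clamped to
#'   \[1e-9, 1 - 1e-9\]
#' @export
psych_nll <- function(mu, sigma, contrast, response, gamma = 0.02, lambda = 0.02) {
  if (length(contrast) == 0) stop("no trials supplied")
  if (!all(is.finite(contrast))) stop("contrasts must be finite")
  y <- as.numeric(response)
  psi <- gamma + (1 - gamma - lambda) * stats::pnorm((contrast - mu) / sigma)
  psi <- pmin(pmax(psi, 1e-9), 1 - 1e-9)
  -sum(y * log(psi) + (1 - y) * log(1 - psi))
}

#' Fit a cumulative Gaussian psychometric function by maximum likelihood
#'
#' Optimises (mu, log sigma) with BFGS from five deterministic starting
#' points (quantiles of the presented levels crossed with two spread guesses
#' plus a response-weighted midpoint); the log parameterisation enforces
#' sigma > 0 and the multistart is deterministic so fits are exactly
#' reproducible. Asymptotes are fixed (default 0.02 each) unless
#' `fit_asymptotes = TRUE`, in which case gamma and lambda are profiled over
#' \[0, 0.06\] with L-BFGS-B.
#'
#' @inheritParams psych_nll
#' @param fit_asymptotes also estimate gamma and lambda
#' @return object of class `psych_fit` with fields `mu`, `sigma`, `gamma`,
#'   `lambda`, `neg_log_lik`, `converged`, `n_trials`
#' @export
fit_cumulative_gaussian <- function(contrast, response, gamma = 0.02,
                                    lambda = 0.02, fit_asymptotes = FALSE) {
  y <- as.numeric(response)
  if (length(unique(contrast)) < 2)
    stop("need >= 2 distinct contrast levels to fit a psychometric function")
  if (all(y == y[1]))
    stop("all responses identical (", if (y[1] == 1) "lighter" else "darker",
         "): psychometric location is not identifiable")
  spread0 <- max(stats::sd(contrast), 0.5)
  w_mid <- (mean(contrast[y == 1]) + mean(contrast[y == 0])) / 2
  starts <- rbind(
    c(stats::quantile(contrast, 0.25), log(spread0)),
    c(stats::median(contrast),         log(spread0)),
    c(stats::quantile(contrast, 0.75), log(spread0)),
    c(mean(contrast),                  log(spread0 / 3)),
    c(w_mid,                           log(spread0 * 2)))
  a <- 1 - gamma - lambda
  obj2 <- function(th) {
    psi <- gamma + a * stats::pnorm((contrast - th[1]) / exp(th[2]))
    psi <- pmin(pmax(psi, 1e-9), 1 - 1e-9)
    -sum(y * log(psi) + (1 - y) * log(1 - psi))
  }
  grad2 <- function(th) {
    s <- exp(th[2]); z <- (contrast - th[1]) / s
    psi <- pmin(pmax(gamma + a * stats::pnorm(z), 1e-9), 1 - 1e-9)
    w <- (y / psi - (1 - y) / (1 - psi)) * a * stats::dnorm(z)
    c(sum(w) / s, sum(w * z))
  }
  best <- NULL
  for (i in seq_len(nrow(starts))) {
    f <- tryCatch(stats::optim(starts[i, ], obj2, grad2, method = "BFGS",
                               control = list(maxit = 300, reltol = 1e-10)),
                  error = function(e) NULL)
    if (!is.null(f) && (is.null(best) || f$value < best$value)) best <- f
  }
  if (is.null(best)) stop("all optimiser starts failed")
  mu <- best$par[1]; sigma <- exp(best$par[2])
  conv <- best$convergence == 0 && abs(best$par[2]) < log(200)

  if (fit_asymptotes) {
    obj4 <- function(th) psych_nll(th[1], exp(th[2]), contrast, y, th[3], th[4])
    f4 <- tryCatch(stats::optim(c(best$par, gamma, lambda), obj4,
                                method = "L-BFGS-B",
                                lower = c(-200, log(1e-3), 0, 0),
                                upper = c(200, log(200), 0.06, 0.06),
                                control = list(maxit = 500)),
                   error = function(e) NULL)
    if (!is.null(f4) && f4$value <= best$value) {
      mu <- f4$par[1]; sigma <- exp(f4$par[2])
      gamma <- f4$par[3]; lambda <- f4$par[4]
      conv <- f4$convergence == 0 && abs(f4$par[2]) < log(200)
      best <- f4
    }
  }
  structure(list(mu = unname(mu), sigma = unname(sigma), gamma = gamma,
                 lambda = lambda, neg_log_lik = best$value, converged = conv,
                 n_trials = length(y)),
            class = "psych_fit")
}

#' @export
print.psych_fit <- function(x, ...) {
  cat(sprintf("psych_fit: mu = %.3f, sigma = %.3f (gamma = %.3f, lambda = %.3f), NLL = %.3f, n = %d%s\n",
              x$mu, x$sigma, x$gamma, x$lambda, x$neg_log_lik, x$n_trials,
              if (x$converged) "" else " [NOT CONVERGED]"))
  invisible(x)
}

#' Luminance to Weber contrast (percent)
#'
#' 100 * (Lm - Lb) / Lb, the contrast of the matching triangle against the
#' mean background luminance.
#'
#' @param Lm matching luminance (cd/m^2)
#' @param Lb background luminance (cd/m^2), > 0
#' @return Weber contrast in percent
#' @examples
#' pse_to_weber(30, 20)  # 50
#' @export
pse_to_weber <- function(Lm, Lb) {
  if (any(!is.finite(Lb)) || any(Lb <= 0)) stop("Lb must be positive")
  100 * (Lm - Lb) / Lb
}

#' Fit every observer x condition cell of a trial log
#'
#' One maximum-likelihood psychometric fit per cell; the PSE is the contrast
#' at which the fitted function crosses gamma + (1 - gamma - lambda)/2, which
#' equals mu by construction. Cells whose fit fails (e.g. all-identical
#' responses) are kept with `NA` estimates and `converged = FALSE`, with a
#' warning naming the cell.
#'
#' @param trials trial data frame as produced by [run_session()] (rows from
#'   several observers may be concatenated)
#' @param ... passed to [fit_cumulative_gaussian()]
#' @return data frame ("PSE table") with one row per observer x condition:
#'   `observer_id`, `condition_id`, `inducer_condition`, `cued_polarity`,
#'   `blur_level`, `pse_weber_pct`, `sigma`, `gamma`, `lambda`, `nll`,
#'   `n_trials`, `converged`
#' @export
build_pse_table <- function(trials, ...) {
  need <- c("observer_id", "condition_id", "contrast_weber_pct", "response_lighter")
  if (!all(need %in% names(trials)))
    stop("trials is missing columns: ", paste(setdiff(need, names(trials)), collapse = ", "))
  grid <- condition_grid()
  cells <- unique(trials[, c("observer_id", "condition_id")])
  cells <- cells[order(cells$observer_id,
                       match(cells$condition_id, grid$condition_id)), ]
  out <- vector("list", nrow(cells))
  for (i in seq_len(nrow(cells))) {
    sel <- trials$observer_id == cells$observer_id[i] &
      trials$condition_id == cells$condition_id[i]
    fit <- tryCatch(
      fit_cumulative_gaussian(trials$contrast_weber_pct[sel],
                              trials$response_lighter[sel], ...),
      error = function(e) {
        warning("fit failed for ", cells$observer_id[i], " / ",
                cells$condition_id[i], ": ", conditionMessage(e), call. = FALSE)
        list(mu = NA_real_, sigma = NA_real_, gamma = NA_real_,
             lambda = NA_real_, neg_log_lik = NA_real_, converged = FALSE,
             n_trials = sum(sel))
      })
    m <- match(cells$condition_id[i], grid$condition_id)
    out[[i]] <- data.frame(
      observer_id = cells$observer_id[i], condition_id = cells$condition_id[i],
      inducer_condition = grid$inducer_condition[m],
      cued_polarity = grid$cued_polarity[m], blur_level = grid$blur_level[m],
      pse_weber_pct = fit$mu, sigma = fit$sigma, gamma = fit$gamma,
      lambda = fit$lambda, nll = fit$neg_log_lik, n_trials = fit$n_trials,
      converged = fit$converged, stringsAsFactors = FALSE)
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}
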