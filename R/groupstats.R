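#' Per-observer white-minus-black PSE difference scores
#'
#' For each observer and blur level, the PSE when the white inducers were cued
#' minus the PSE when the black inducers were cued. Negative values mean the
#' white-cued illusory surface appeared darker than the black-cued one.
#'
#' @param pse_table a PSE table from [build_pse_table()]
#' @param inducer_type `"mixed"` or `"homogeneous"` (the two homogeneous
#'   arrangements supply the black- and white-cued cells)
#' @return data frame `observer_id`, `blur_level`, `diff_weber_pct`
#' @export
difference_scores <- function(pse_table, inducer_type = c("mixed", "homogeneous")) {
  inducer_type <- match.arg(inducer_type)
  sel <- if (inducer_type == "mixed") pse_table$inducer_condition == "mixed"
         else pse_table$inducer_condition %in% c("homog_black", "homog_white")
  tab <- pse_table[sel, ]
  obs <- sort(unique(pse_table$observer_id))
  out <- expand.grid(observer_id = obs, blur_level = 1:5,
                     KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  pick <- function(o, b, pol) {
    v <- tab$pse_weber_pct[tab$observer_id == o & tab$blur_level == b &
                           tab$cued_polarity == pol]
    if (length(v) != 1 || is.na(v))
      stop("missing or unusable PSE for observer ", o, ", blur ", b,
           ", ", pol, "-cued (", inducer_type, ")")
    v
  }
  out$diff_weber_pct <- mapply(function(o, b)
    pick(o, b, "white") - pick(o, b, "black"), out$observer_id, out$blur_level)
  out[order(out$blur_level, out$observer_id), ]
}

# JZS integrand: g mixed over InverseGamma(1/2, 1/2), effect-size Cauchy scale r
.jzs_bf10 <- function(t, n, r) {
  nu <- n - 1
  num <- stats::integrate(function(g) {
    (1 + n * g * r^2)^(-1 / 2) *
      (1 + t^2 / ((1 + n * g * r^2) * nu))^(-(nu + 1) / 2) *
      exp(stats::dgamma(1 / g, 0.5, 0.5, log = TRUE) - 2 * log(g))
  }, 0, Inf, rel.tol = 1e-8)$value
  num / (1 + t^2 / nu)^(-(nu + 1) / 2)
}

#' JZS paired-samples Bayes factor
#'
#' Default Bayesian paired t-test: a Cauchy prior with scale `r_scale` on the
#' standardised effect size of the paired differences (the JASP/BayesFactor
#' default scale sqrt(2)/2), evaluated by adaptive numerical integration of
#' the Jeffreys-Zellner-Siow g-mixture to relative tolerance 1e-8.
#'
#' @param x,y equal-length paired samples (`y` may be omitted to test `x`
#'   against zero)
#' @param r_scale Cauchy prior scale on effect size
#' @return object of class `bf_result` with `t_stat`, `n`, `r_scale`, `bf10`
#' @export
paired_bf10 <- function(x, y = NULL, r_scale = sqrt(2) / 2) {
  d <- if (is.null(y)) x else {
    if (length(x) != length(y)) stop("paired samples must have equal length")
    x - y
  }
  n <- length(d)
  if (n < 3) stop("need at least 3 pairs")
  if (stats::sd(d) == 0)
    stop("zero-variance differences: t statistic undefined, no evidence computable")
  t_stat <- mean(d) / (stats::sd(d) / sqrt(n))
  structure(list(t_stat = t_stat, n = n, r_scale = r_scale,
                 bf10 = .jzs_bf10(t_stat, n, r_scale)),
            class = "bf_result")
}

#' @export
print.bf_result <- function(x, ...) {
  cat(sprintf("BF10 = %.4g (t = %.3f, n = %d, Cauchy scale = %.3f)\n",
              x$bf10, x$t_stat, x$n, x$r_scale))
  invisible(x)
}

#' Student-t 95% confidence interval for a mean
#'
#' mean +/- t(0.975, n-1) * SE.
#'
#' @param x numeric vector, length >= 2
#' @return named numeric `c(mean, lower, upper)`
#' @export
ci95 <- function(x) {
  n <- length(x)
  if (n < 2) stop("need at least 2 observations")
  se <- stats::sd(x) / sqrt(n)
  m <- mean(x)
  q <- stats::qt(0.975, n - 1)
  c(mean = m, lower = m - q * se, upper = m + q * se)
}

#' Per-blur Bayes factors on fitted psychometric slopes
#'
#' For each inducer type and blur level, a JZS paired Bayes factor comparing
#' the fitted spreads (sigma) of the black- versus white-cued conditions
#' across observers. BF10 < 1 is evidence that the slopes do not differ.
#' Zero-variance slope pairs yield an `NA` Bayes factor with an explanatory
#' note rather than an error.
#'
#' @param pse_table a PSE table from [build_pse_table()]
#' @param r_scale Cauchy prior scale
#' @return data frame `inducer_type`, `blur_level`, `t_stat`, `bf10`, `note`
#' @export
slope_comparison <- function(pse_table, r_scale = sqrt(2) / 2) {
  rows <- expand.grid(inducer_type = c("mixed", "homogeneous"), blur_level = 1:5,
                      KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  rows$t_stat <- NA_real_; rows$bf10 <- NA_real_; rows$note <- ""
  for (i in seq_len(nrow(rows))) {
    sel <- if (rows$inducer_type[i] == "mixed")
      pse_table$inducer_condition == "mixed"
    else pse_table$inducer_condition %in% c("homog_black", "homog_white")
    tab <- pse_table[sel & pse_table$blur_level == rows$blur_level[i], ]
    tab <- tab[order(tab$observer_id), ]
    sb <- tab$sigma[tab$cued_polarity == "black"]
    sw <- tab$sigma[tab$cued_polarity == "white"]
    res <- tryCatch(paired_bf10(sb, sw, r_scale = r_scale),
                    error = function(e) conditionMessage(e))
    if (is.character(res)) {
      rows$note[i] <- res
    } else {
      rows$t_stat[i] <- res$t_stat
      rows$bf10[i] <- res$bf10
    }
  }
  rows
}

#' Group-level summary of the attention effect
#'
#' For each inducer type and blur level: the mean white-minus-black PSE
#' difference with its 95% CI, and the JZS paired Bayes factor comparing
#' black- versus white-cued PSEs; plus the per-blur slope comparisons and a
#' classical repeated-measures ANOVA on the difference scores (blur level x
#' inducer type, both within observers).
#'
#' @param pse_table a PSE table from [build_pse_table()]
#' @param r_scale Cauchy prior scale for all Bayes factors
#' @return list with `differences` (data frame), `slopes` (data frame) and
#'   `rm_anova` (data frame of F-tests); serialisable with
#'   [write_group_summary()]
#' @export
group_summary <- function(pse_table, r_scale = sqrt(2) / 2) {
  diffs <- rbind(cbind(inducer_type = "mixed",
                       difference_scores(pse_table, "mixed")),
                 cbind(inducer_type = "homogeneous",
                       difference_scores(pse_table, "homogeneous")))
  out <- expand.grid(inducer_type = c("mixed", "homogeneous"), blur_level = 1:5,
                     KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  out$n <- NA_integer_; out$mean_diff <- NA_real_
  out$ci95_low <- NA_real_; out$ci95_high <- NA_real_
  out$t_stat <- NA_real_; out$bf10 <- NA_real_
  for (i in seq_len(nrow(out))) {
    d <- diffs$diff_weber_pct[diffs$inducer_type == out$inducer_type[i] &
                              diffs$blur_level == out$blur_level[i]]
    ci <- ci95(d)
    out$n[i] <- length(d); out$mean_diff[i] <- ci["mean"]
    out$ci95_low[i] <- ci["lower"]; out$ci95_high[i] <- ci["upper"]
    # undefined for < 3 observers or zero-variance differences; keep the row
    bf <- tryCatch(paired_bf10(d), error = function(e) NULL)
    if (!is.null(bf)) {
      out$t_stat[i] <- bf$t_stat; out$bf10[i] <- bf$bf10
    }
  }
  list(differences = out,
       slopes = slope_comparison(pse_table, r_scale = r_scale),
       rm_anova = rm_anova_differences(diffs))
}

#' Repeated-measures ANOVA on difference scores
#'
#' Classical within-observer 5 (blur) x 2 (inducer type) ANOVA on the
#' white-minus-black difference scores, as an effect summary alongside the
#' per-blur Bayes factors.
#'
#' @param diffs stacked difference-score data frame with columns
#'   `inducer_type`, `observer_id`, `blur_level`, `diff_weber_pct`
#' @return data frame of effect, df, F and p
#' @export
rm_anova_differences <- function(diffs) {
  diffs$observer_id <- factor(diffs$observer_id)
  diffs$blur_level <- factor(diffs$blur_level)
  diffs$inducer_type <- factor(diffs$inducer_type)
  fit <- stats::aov(diff_weber_pct ~ blur_level * inducer_type +
                      Error(observer_id / (blur_level * inducer_type)),
                    data = diffs)
  s <- summary(fit)
  rows <- list()
  for (stratum in s) {
    tab <- stratum[[1]]
    eff <- trimws(rownames(tab))
    keep <- eff != "Residuals"
    if (!any(keep)) next
    rows[[length(rows) + 1]] <- data.frame(
      effect = eff[keep], df = tab$Df[keep],
      df_error = tab$Df[!keep][1],
      F = tab$`F value`[keep], p = tab$`Pr(>F)`[keep],
      stringsAsFactors = FALSE)
  }
  res <- do.call(rbind, rows)
  rownames(res) <- NULL
  res
}

#' Write a group summary to JSON
#'
#' @param summary result of [group_summary()]
#' @param path output file
#' @export
write_group_summary <- function(summary, path) {
  jsonlite::write_json(summary, path, dataframe = "rows", auto_unbox = TRUE,
                       digits = NA, na = "null")
  invisible(path)
}
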