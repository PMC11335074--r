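#' Paired midpoint shift between two divalent conditions
#'
#' The modulation measure is computed per oocyte: the midpoint (pH50 or
#' pHD50) fitted in the low-divalent arm minus the midpoint fitted in the
#' high-divalent arm of the *same* oocyte, then averaged. Oocytes present
#' in only one arm are dropped (and counted).
#'
#' @param fits_low,fits_high Data frames with columns `oocyte_id` and
#'   `value` (fitted midpoints per oocyte).
#' @return A `paired_shift` object: per-oocyte `deltas`, `mean`, `sd`,
#'   `n`, and `n_dropped`.
#' @export
#' @examples
#' low <- data.frame(oocyte_id = 1:3, value = c(6.74, 6.77, 6.73))
#' high <- data.frame(oocyte_id = 1:3, value = c(6.50, 6.51, 6.49))
#' paired_shift(low, high)
paired_shift <- function(fits_low, fits_high) {
  m <- merge(fits_low, fits_high, by = "oocyte_id",
             suffixes = c("_low", "_high"))
  n_dropped <- nrow(fits_low) + nrow(fits_high) - 2 * nrow(m)
  if (nrow(m) < 2) {
    stop("insufficient-pairs: need >= 2 oocytes present in both arms",
         call. = FALSE)
  }
  if (n_dropped > 0) {
    message(n_dropped, " unpaired fit(s) dropped from the paired shift")
  }
  deltas <- m$value_low - m$value_high
  structure(list(deltas = tibble(oocyte_id = m$oocyte_id, delta = deltas),
                 mean = mean(deltas), sd = stats::sd(deltas),
                 n = length(deltas), n_dropped = n_dropped),
            class = "paired_shift")
}

#' @export
print.paired_shift <- function(x, ...) {
  cat(sprintf("<paired_shift> %.4g +/- %.4g (s.d.), n = %d\n",
              x$mean, x$sd, x$n))
  invisible(x)
}

#' Per-oocyte time-constant ratios
#'
#' The modulatory effect on kinetics is summarized per oocyte as a ratio
#' of fitted time constants across the two divalent arms. The orientation
#' follows the protocol's convention: recovery reports `tau(low) /
#' tau(high)` (slower recovery at low divalent), onset reports
#' `tau(high) / tau(low)` (slower onset at high divalent), so both ratios
#' exceed 1 under divalent modulation.
#'
#' @param fits_low,fits_high Data frames with `oocyte_id` and `value`
#'   (fitted tau, s).
#' @param protocol `"recovery"` or `"onset"`.
#' @return A `tau_ratio` object: per-oocyte `ratios`, `mean`, `sd`, `n`.
#' @export
tau_ratio <- function(fits_low, fits_high,
                      protocol = c("recovery", "onset")) {
  protocol <- match.arg(protocol)
  m <- merge(fits_low, fits_high, by = "oocyte_id",
             suffixes = c("_low", "_high"))
  if (nrow(m) < 2) {
    stop("insufficient-pairs: need >= 2 oocytes present in both arms",
         call. = FALSE)
  }
  if (any(m$value_low <= 0) || any(m$value_high <= 0)) {
    stop("domain error: non-positive tau", call. = FALSE)
  }
  r <- if (protocol == "recovery") m$value_low / m$value_high
       else m$value_high / m$value_low
  structure(list(ratios = tibble(oocyte_id = m$oocyte_id, ratio = r),
                 mean = mean(r), sd = stats::sd(r), n = length(r),
                 protocol = protocol),
            class = "tau_ratio")
}

#' @export
print.tau_ratio <- function(x, ...) {
  cat(sprintf("<tau_ratio:%s> %.4g +/- %.4g (s.d.), n = %d\n",
              x$protocol, x$mean, x$sd, x$n))
  invisible(x)
}

#' Group comparisons: paired t, ANOVA with Dunnett or Tukey contrasts
#'
#' `"paired-t"` compares two conditions within subjects (two-sided).
#' `"anova-dunnett"` fits a one-way ANOVA and compares every group against
#' the control; `"anova-tukey"` compares all pairs. Multiplicity-adjusted
#' two-sided p-values use the multivariate-t quantiles of the contrast
#' family (single-step adjustment) at alpha = 0.05.
#'
#' Identical paired arms (all differences exactly zero) return statistic 0
#' and p = 1; constant non-zero differences are degenerate for the t
#' statistic and raise an error.
#'
#' @param data Data frame with `value`, `group`, and for the paired test a
#'   subject column `id`.
#' @param test One of `"paired-t"`, `"anova-dunnett"`, `"anova-tukey"`.
#' @param control Control group label for Dunnett contrasts.
#' @return A `stats_result`: `test`, `statistic`, `p_value`, and for the
#'   ANOVA variants a `contrasts` tibble with per-contrast estimates and
#'   adjusted p-values.
#' @export
compare_groups <- function(data,
                           test = c("paired-t", "anova-dunnett",
                                    "anova-tukey"),
                           control = NULL) {
  test <- match.arg(test)
  data$group <- as.character(data$group)
  if (test == "paired-t") {
    groups <- unique(data$group)
    if (length(groups) != 2) {
      stop("paired-t needs exactly two groups", call. = FALSE)
    }
    wide <- merge(data[data$group == groups[1], c("id", "value")],
                  data[data$group == groups[2], c("id", "value")],
                  by = "id")
    d <- wide$value.x - wide$value.y
    if (length(d) < 2) {
      stop("paired-t needs >= 2 complete pairs", call. = FALSE)
    }
    if (all(d == 0)) {
      return(structure(list(test = test, statistic = 0, p_value = 1,
                            groups = groups, n = length(d)),
                       class = "stats_result"))
    }
    if (stats::sd(d) == 0) {
      stop("degenerate-test: paired differences have zero variance",
           call. = FALSE)
    }
    tt <- stats::t.test(d)
    return(structure(list(test = test,
                          statistic = unname(tt$statistic),
                          p_value = tt$p.value, groups = groups,
                          n = length(d)),
                     class = "stats_result"))
  }
  data$group <- factor(data$group)
  if (nlevels(data$group) < 3) {
    stop("ANOVA comparisons need >= 3 groups", call. = FALSE)
  }
  if (test == "anova-dunnett") {
    if (is.null(control)) control <- levels(data$group)[1]
    data$group <- stats::relevel(data$group, ref = control)
  }
  fit <- stats::aov(value ~ group, data = data)
  an <- summary(fit)[[1]]
  glht_type <- if (test == "anova-dunnett") "Dunnett" else "Tukey"
  mc <- multcomp::glht(fit, linfct = multcomp::mcp(group = glht_type))
  sm <- summary(mc)
  contrasts <- tibble(
    contrast = names(sm$test$coefficients),
    estimate = unname(sm$test$coefficients),
    statistic = unname(sm$test$tstat),
    p_adj = unname(as.numeric(sm$test$pvalues)))
  structure(list(test = test,
                 statistic = an$`F value`[1],
                 p_value = an$`Pr(>F)`[1],
                 groups = levels(data$group),
                 contrasts = contrasts),
            class = "stats_result")
}

#' @export
print.stats_result <- function(x, ...) {
  cat(sprintf("<stats_result:%s> statistic = %.4g, p = %.3g\n",
              x$test, x$statistic, x$p_value))
  if (!is.null(x$contrasts)) print(x$contrasts)
  invisible(x)
}
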