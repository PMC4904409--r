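# Inferential layer for group comparisons: Mann-Whitney-Wilcoxon tests,
# ANCOVA (factor effect given a covariate, Type-II sums of squares),
# wind-shear binning of climb-rate differences, and AICc selection among
# no-effect / linear / hump-shaped (quadratic) models.

#' Mann-Whitney-Wilcoxon two-sample test
#'
#' U statistic via rank sums with midranks for ties; two-sided p-value by
#' exact enumeration when `n1 * n2 <= 400` and there are no ties, otherwise
#' by the normal approximation with tie correction. An all-identical pooled
#' sample gives p = 1.
#'
#' @param x,y numeric samples (non-empty).
#' @return list of class `group_comparison`: `statistic` (U for `x`),
#'   `p_value`, `group_summaries` (mean, SE, n per group).
#' @export
mww_test <- function(x, y) {
  stopifnot(length(x) > 0, length(y) > 0)
  if (length(unique(c(x, y))) == 1) {
    wt <- list(statistic = c(W = length(x) * length(y) / 2), p.value = 1)
  } else {
    exact <- length(x) * length(y) <= 400 && !anyDuplicated(c(x, y))
    wt <- suppressWarnings(wilcox.test(x, y, exact = exact, correct = TRUE))
  }
  structure(list(
    statistic = unname(wt$statistic),
    p_value = wt$p.value,
    group_summaries = data.frame(
      group = c("x", "y"),
      mean = c(mean(x), mean(y)),
      se = c(sd(x) / sqrt(length(x)), sd(y) / sqrt(length(y))),
      n = c(length(x), length(y))
    )
  ), class = "group_comparison")
}

#' ANCOVA: factor effect on a response given a covariate
#'
#' Fits `response ~ factor + covariate` and reports the Type-II F test of
#' the factor given the covariate (e.g. the effect of age class on
#' circling radius controlling for wind shear).
#'
#' @param response numeric response (e.g. per-thermal circling radius).
#' @param covariate numeric covariate (e.g. wind shear).
#' @param factor_ grouping factor with at least 2 levels.
#' @return list of class `group_comparison` with `statistic` (F for the
#'   factor), `p_value`, `group_summaries` and the fitted `model`.
#' @export
ancova_test <- function(response, covariate, factor_) {
  factor_ <- as.factor(factor_)
  if (nlevels(droplevels(factor_)) < 2) stop("ancova_test: need at least 2 groups")
  if (length(unique(covariate)) < 2) stop("ancova_test: covariate does not vary")
  d <- data.frame(response = response, covariate = covariate, factor_ = factor_)
  fit <- lm(response ~ factor_ + covariate, data = d)
  if (fit$rank < length(coef(fit))) stop("ancova_test: rank-deficient design")
  aov2 <- car::Anova(fit, type = 2)
  sm <- vapply(split(response, factor_), function(v) {
    c(mean(v), sd(v) / sqrt(length(v)), length(v))
  }, numeric(3))
  structure(list(
    statistic = aov2["factor_", "F value"],
    p_value = aov2["factor_", "Pr(>F)"],
    group_summaries = data.frame(
      group = colnames(sm), mean = sm[1, ], se = sm[2, ], n = sm[3, ],
      row.names = NULL
    ),
    model = fit
  ), class = "group_comparison")
}

#' Bin climb-rate differences between two groups by wind shear
#'
#' Bins per-thermal climb rates into wind-shear bins of `bin_width` m/s and
#' returns, per bin, the difference of group means (first group minus
#' second, e.g. adult minus juvenile) with its standard error. Bins where
#' either group is absent are dropped (with a message).
#'
#' @param climb per-thermal climb rates (m/s).
#' @param shear per-thermal wind shear (m/s).
#' @param group two-level factor (first level minus second).
#' @param bin_width shear bin width (m/s).
#' @return data.frame with `shear` (bin centre), `difference`, `se`,
#'   `n1`, `n2`.
#' @export
bin_climb_difference <- function(climb, shear, group, bin_width = 1) {
  group <- as.factor(group)
  stopifnot(nlevels(droplevels(group)) == 2)
  lv <- levels(droplevels(group))
  bin <- floor(shear / bin_width)
  out <- list()
  dropped <- 0
  for (b in sort(unique(bin))) {
    sel <- bin == b
    g1 <- climb[sel & group == lv[1]]
    g2 <- climb[sel & group == lv[2]]
    if (!length(g1) || !length(g2)) {
      dropped <- dropped + 1
      next
    }
    se <- sqrt(
      (if (length(g1) > 1) stats::var(g1) / length(g1) else 0) +
      (if (length(g2) > 1) stats::var(g2) / length(g2) else 0)
    )
    out[[length(out) + 1]] <- data.frame(
      shear = (b + 0.5) * bin_width,
      difference = mean(g1) - mean(g2),
      se = se, n1 = length(g1), n2 = length(g2)
    )
  }
  if (dropped) message("bin_climb_difference: dropped ", dropped, " single-class bin(s)")
  if (!length(out)) {
    return(data.frame(shear = numeric(), difference = numeric(), se = numeric(),
                      n1 = integer(), n2 = integer()))
  }
  do.call(rbind, out)
}

# Akaike information criterion for an RSS-form Gaussian fit, small-sample
# corrected; k counts all regression coefficients including the intercept
aicc <- function(rss, n, k) {
  if (n <= k + 1) return(NA_real_)
  n * log(rss / n) + 2 * k + 2 * k * (k + 1) / (n - k - 1)
}

adjusted_r2 <- function(r2, n, k) 1 - (1 - r2) * (n - 1) / (n - k)

#' Fit and compare no-effect, linear and hump-shaped shear models
#'
#' Least-squares fits of `y = c0`, `y = c1 x + c0` and
#' `y = c2 x^2 + c1 x + c0` to binned climb-rate differences, compared by
#' the small-sample-corrected Akaike criterion
#' `AICc = n ln(RSS/n) + 2k + 2k(k+1)/(n-k-1)` (k = number of regression
#' coefficients) with adjusted `R^2 = 1 - (1-R^2)(n-1)/(n-k)`. The model
#' with the smallest AICc is selected. Models with `n <= k + 1` are skipped
#' with a reason. The reported per-model p-value is the F test of the full
#' regression against the intercept-only model (a package convention).
#'
#' @param bins data.frame with columns `shear` (or `x`) and `difference`
#'   (or `y`); at least 4 rows.
#' @return list with `models` (data.frame: model, k, rss, aicc,
#'   adjusted_r2, p_value, coefficients as c0/c1/c2) and `selected`.
#' @export
fit_shear_models <- function(bins) {
  x <- if ("shear" %in% names(bins)) bins$shear else bins$x
  y <- if ("difference" %in% names(bins)) bins$difference else bins$y
  stopifnot(length(x) == length(y))
  n <- length(y)
  if (n < 4) stop("fit_shear_models: need at least 4 bins")
  tss <- sum((y - mean(y))^2)
  specs <- list(
    none = y ~ 1,
    linear = y ~ x,
    quadratic = y ~ x + I(x^2)
  )
  rows <- list()
  skipped <- character(0)
  for (m in names(specs)) {
    k <- match(m, names(specs)) # 1, 2, 3 coefficients
    if (n <= k + 1) {
      skipped <- c(skipped, paste0(m, " (n <= k + 1)"))
      next
    }
    fit <- lm(specs[[m]], data = data.frame(x = x, y = y))
    rss <- sum(stats::residuals(fit)^2)
    r2 <- if (tss > 0) 1 - rss / tss else 0
    cf <- coef(fit)
    p_val <- if (m == "none" || tss == 0) {
      NA_real_
    } else {
      f <- ((tss - rss) / (k - 1)) / (rss / (n - k))
      stats::pf(f, k - 1, n - k, lower.tail = FALSE)
    }
    rows[[m]] <- data.frame(
      model = m, k = k, rss = rss,
      aicc = aicc(rss, n, k),
      adjusted_r2 = adjusted_r2(r2, n, k),
      p_value = p_val,
      c0 = unname(cf["(Intercept)"]),
      c1 = if ("x" %in% names(cf)) unname(cf["x"]) else NA_real_,
      c2 = if ("I(x^2)" %in% names(cf)) unname(cf["I(x^2)"]) else NA_real_
    )
  }
  models <- do.call(rbind, rows)
  rownames(models) <- NULL
  sel <- models$model[which.min(models$aicc)]
  list(models = models, selected = sel, skipped = skipped)
}
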