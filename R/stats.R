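#' Two-proportion z-test (pooled variance)
#'
#' The z-score between two population proportions with the pooled-variance
#' standard error and a two-sided normal p-value; no continuity correction.
#' When the pooled proportion is 0 or 1 the statistic is undefined and
#' reported as missing.
#'
#' @param x1,n1 Successes and size of arm 1.
#' @param x2,n2 Successes and size of arm 2.
#' @param conf_level Confidence level for the (unpooled) difference CI.
#' @return One-row tibble: `estimate` (p1 - p2), `statistic`, `p`,
#'   `conf_low`, `conf_high`, `n1`, `n2`.
#' @export
two_proportion_z <- function(x1, n1, x2, n2, conf_level = 0.95) {
  if (n1 < 1 || n2 < 1) abort("both arms need at least one observation")
  if (x1 < 0 || x1 > n1 || x2 < 0 || x2 > n2) {
    abort("counts must satisfy 0 <= x <= n")
  }
  p1 <- x1 / n1
  p2 <- x2 / n2
  pooled <- (x1 + x2) / (n1 + n2)
  if (pooled %in% c(0, 1)) {
    return(tibble(estimate = p1 - p2, statistic = NA_real_, p = NA_real_,
                  conf_low = NA_real_, conf_high = NA_real_,
                  n1 = n1, n2 = n2))
  }
  se_pooled <- sqrt(pooled * (1 - pooled) * (1 / n1 + 1 / n2))
  z <- (p1 - p2) / se_pooled
  se_diff <- sqrt(p1 * (1 - p1) / n1 + p2 * (1 - p2) / n2)
  crit <- qnorm(1 - (1 - conf_level) / 2)
  tibble(estimate = p1 - p2, statistic = z, p = 2 * pnorm(-abs(z)),
         conf_low = p1 - p2 - crit * se_diff,
         conf_high = p1 - p2 + crit * se_diff, n1 = n1, n2 = n2)
}

#' Unpaired two-sample t-test
#'
#' Student's (pooled) or Welch's (Satterthwaite) two-tailed t-test.
#'
#' @param a,b Numeric vectors, each with at least 2 values.
#' @param welch Use Welch's unequal-variance form; default Student's.
#' @return One-row tibble: `estimate` (mean difference), `statistic`, `df`,
#'   `p`, `conf_low`, `conf_high`.
#' @export
two_sample_t <- function(a, b, welch = FALSE) {
  if (length(a) < 2L || length(b) < 2L) {
    abort("each arm needs at least 2 values")
  }
  fit <- t.test(a, b, var.equal = !welch)
  tibble(estimate = unname(fit$estimate[1] - fit$estimate[2]),
         statistic = unname(fit$statistic), df = unname(fit$parameter),
         p = fit$p.value, conf_low = fit$conf.int[1],
         conf_high = fit$conf.int[2])
}

#' One-way ANOVA with Tukey-adjusted pairwise comparisons
#'
#' Fixed-effects one-way F-test followed by all pairwise contrasts with
#' p-values from the studentized-range distribution (Tukey's honest
#' significant difference, k groups, N - k error df).
#'
#' @param values Numeric response vector.
#' @param groups Group labels, same length; at least 2 groups with at least
#'   2 values each.
#' @return List with `anova` (one-row tibble `statistic`, `df1`, `df2`,
#'   `p`) and `pairwise` (tibble `comparison`, `diff`, `conf_low`,
#'   `conf_high`, `p_adj`).
#' @export
anova_tukey <- function(values, groups) {
  groups <- factor(groups)
  if (nlevels(groups) < 2L) abort("need at least 2 groups")
  if (any(table(groups) < 2L)) abort("each group needs at least 2 values")
  fit <- aov(values ~ groups)
  av <- anova(fit)
  tk <- TukeyHSD(fit)$groups
  list(
    anova = tibble(statistic = av[1, "F value"], df1 = av[1, "Df"],
                   df2 = av[2, "Df"], p = av[1, "Pr(>F)"]),
    pairwise = tibble(comparison = rownames(tk), diff = tk[, "diff"],
                      conf_low = tk[, "lwr"], conf_high = tk[, "upr"],
                      p_adj = tk[, "p adj"])
  )
}

#' Pearson correlation with t-based p-value
#'
#' @param a,b Numeric vectors of equal length >= 3, neither constant.
#' @return One-row tibble: `estimate` (r), `statistic`, `df`, `p`,
#'   `conf_low`, `conf_high`.
#' @export
pearson_cor <- function(a, b) {
  if (length(a) != length(b)) abort("vectors must have equal length")
  if (length(a) < 3L) abort("need at least 3 observations")
  if (sd(a) == 0 || sd(b) == 0) abort("correlation undefined for a constant vector")
  ct <- cor.test(a, b, method = "pearson")
  tibble(estimate = unname(ct$estimate), statistic = unname(ct$statistic),
         df = unname(ct$parameter), p = ct$p.value,
         conf_low = if (!is.null(ct$conf.int)) ct$conf.int[1] else NA_real_,
         conf_high = if (!is.null(ct$conf.int)) ct$conf.int[2] else NA_real_)
}

#' Storey q-values
#'
#' False-discovery-rate adjustment with Storey's single-lambda estimate of
#' the null proportion: `pi0 = min(1, #{p > lambda} / ((1 - lambda) m))`,
#' then `q_(i)` is the running minimum of `pi0 * m * p_(i) / i` taken from
#' the largest p-value downward. When `pi0 = 1` this reduces exactly to the
#' Benjamini-Hochberg adjustment. Q-values are monotone in p.
#'
#' @param p Vector of p-values in `[0, 1]`.
#' @param lambda Tuning parameter of the pi0 estimate, default 0.5.
#' @return Vector of q-values aligned with `p`.
#' @export
storey_q <- function(p, lambda = 0.5) {
  if (length(p) == 0L) return(numeric())
  if (any(is.na(p)) || any(p < 0 | p > 1)) {
    abort("p-values must lie in [0, 1] with no missing values")
  }
  m <- length(p)
  pi0 <- min(1, sum(p > lambda) / ((1 - lambda) * m))
  o <- order(p, decreasing = TRUE)
  q_sorted <- cummin(pi0 * m * p[o] / (m:1))
  q <- numeric(m)
  q[o] <- q_sorted
  pmin(q, 1)
}

#' Multinomial logistic regression with Wald inference
#'
#' Maximum-likelihood multinomial logit (iteratively reweighted
#' optimization) against a chosen baseline outcome level, with standard
#' errors from the inverse observed information and two-sided Wald
#' p-values per coefficient. Numeric predictors can be standardized so
#' coefficients are comparable across genes. Perfect collinearity among
#' predictors is detected up front; non-convergence and likely separation
#' are flagged on the returned fit rather than silently ignored.
#'
#' @param data Data frame holding outcome and predictors.
#' @param outcome Name of the categorical outcome column.
#' @param predictors Character vector of predictor column names.
#' @param baseline Baseline outcome level (reference category).
#' @param standardize Standardize numeric predictors to mean 0, SD 1.
#' @param maxit Maximum iterations for the optimizer.
#' @return Object of class `mnl_fit` with [tidy()] and [glance()] methods.
#' @export
multinomial_logit <- function(data, outcome, predictors, baseline = NULL,
                              standardize = TRUE, maxit = 500L) {
  data <- as.data.frame(data)[c(outcome, predictors)]
  data <- data[complete.cases(data), , drop = FALSE]
  y <- factor(data[[outcome]])
  if (nlevels(y) < 2L) abort("outcome needs at least 2 levels")
  if (any(table(y) < 1L)) abort("every outcome level needs at least 1 sample")
  baseline <- baseline %||% levels(y)[1]
  if (!baseline %in% levels(y)) {
    abort(sprintf("baseline level '%s' not found in outcome", baseline))
  }
  y <- stats::relevel(y, ref = baseline)
  X <- data[predictors]
  if (standardize) {
    for (j in seq_along(X)) {
      if (is.numeric(X[[j]])) X[[j]] <- as.numeric(scale(X[[j]]))
    }
  }
  mm <- model.matrix(~ ., data = X)
  if (qr(mm)$rank < ncol(mm)) {
    abort("predictors are perfectly collinear; drop the redundant column")
  }
  df <- cbind(.y = y, X)
  fit <- nnet::multinom(.y ~ ., data = df, Hess = TRUE, trace = FALSE,
                        maxit = maxit)
  co <- coef(fit)
  if (is.null(dim(co))) co <- matrix(co, nrow = 1,
                                     dimnames = list(levels(y)[2], names(co)))
  H <- fit$Hessian
  se_ok <- TRUE
  se <- tryCatch(sqrt(diag(solve(H))), error = function(e) {
    se_ok <<- FALSE
    rep(NA_real_, length(co))
  })
  se_mat <- matrix(se, nrow = nrow(co), byrow = FALSE,
                   dimnames = dimnames(co))
  est <- as.vector(t(co))
  ses <- as.vector(t(se_mat))
  zval <- est / ses
  tidy_tab <- tibble(
    y_level = rep(rownames(co), each = ncol(co)),
    term = rep(colnames(co), times = nrow(co)),
    estimate = est, std_error = ses, statistic = zval,
    p = 2 * pnorm(-abs(zval))
  )
  converged <- fit$convergence == 0
  separated <- !se_ok || any(abs(est) > 15, na.rm = TRUE)
  if (!converged) warn("multinomial fit did not converge within maxit")
  if (separated) warn("possible separation: unstable coefficients or singular information")
  structure(list(fit = fit, coef_table = tidy_tab, baseline = baseline,
                 converged = converged, separated = separated,
                 n = length(y)),
            class = "mnl_fit")
}

#' @export
print.mnl_fit <- function(x, ...) {
  cat(sprintf("<mnl_fit> multinomial logit, baseline '%s', n = %d%s\n",
              x$baseline, x$n,
              if (!x$converged) " [NOT CONVERGED]" else ""))
  print(x$coef_table)
  invisible(x)
}

#' @rdname multinomial_logit
#' @param x An `mnl_fit` object.
#' @param ... Unused.
#' @export
tidy.mnl_fit <- function(x, ...) x$coef_table

#' @rdname multinomial_logit
#' @export
glance.mnl_fit <- function(x, ...) {
  tibble(n = x$n, deviance = x$fit$deviance,
         edf = x$fit$edf, AIC = x$fit$AIC,
         converged = x$converged, separated = x$separated)
}

#' Kaplan-Meier curves, log-rank test and univariate hazard ratio
#'
#' Product-limit survival curves for a binary grouping, the standard
#' log-rank test, and the hazard ratio from a univariate proportional
#' hazards fit with Breslow tie handling (`exp(beta +/- 1.96 SE)` CI).
#' When an arm has no events the hazard ratio is reported missing while
#' the log-rank test is still computed.
#'
#' @param time Follow-up times (>= 0).
#' @param event Event indicator (TRUE/1 = event, FALSE/0 = censored).
#' @param group Binary group labels; the hazard ratio is for the second
#'   factor level relative to the first.
#' @param conf_level Confidence level for the HR interval.
#' @return Object of class `km_fit` with [tidy()], [glance()] and
#'   [autoplot()] methods; elements `survfit`, `logrank` (tibble) and `hr`
#'   (tibble).
#' @export
km_logrank_hr <- function(time, event, group, conf_level = 0.95) {
  if (any(time < 0, na.rm = TRUE)) abort("survival times must be >= 0")
  group <- factor(group)
  if (nlevels(group) != 2L) abort("group must have exactly 2 levels")
  event <- as.integer(as.logical(event))
  dat <- data.frame(time = time, event = event, group = group)
  sf <- survival::survfit(survival::Surv(time, event) ~ group, data = dat)
  sd_ <- survival::survdiff(survival::Surv(time, event) ~ group, data = dat)
  df <- length(sd_$n) - 1
  logrank <- tibble(statistic = sd_$chisq, df = df,
                    p = stats::pchisq(sd_$chisq, df, lower.tail = FALSE))
  events_per_arm <- tapply(event, group, sum)
  if (any(events_per_arm == 0)) {
    hr <- tibble(hr = NA_real_, conf_low = NA_real_, conf_high = NA_real_,
                 p = NA_real_)
  } else {
    cx <- survival::coxph(survival::Surv(time, event) ~ group, data = dat,
                          ties = "breslow")
    beta <- unname(coef(cx))
    se <- sqrt(unname(diag(cx$var)))
    crit <- qnorm(1 - (1 - conf_level) / 2)
    hr <- tibble(hr = exp(beta), conf_low = exp(beta - crit * se),
                 conf_high = exp(beta + crit * se),
                 p = 2 * pnorm(-abs(beta / se)))
  }
  structure(list(survfit = sf, logrank = logrank, hr = hr,
                 levels = levels(group), n = nrow(dat)),
            class = "km_fit")
}

#' @export
print.km_fit <- function(x, ...) {
  cat(sprintf("<km_fit> %s vs %s, n = %d\n", x$levels[2], x$levels[1], x$n))
  cat(sprintf("  log-rank chi-sq = %.3f (df %d), p = %.4g\n",
              x$logrank$statistic, x$logrank$df, x$logrank$p))
  if (is.na(x$hr$hr)) {
    cat("  HR undefined (an arm has no events)\n")
  } else {
    cat(sprintf("  HR = %.3f [%.3f-%.3f], p = %.4g\n", x$hr$hr,
                x$hr$conf_low, x$hr$conf_high, x$hr$p))
  }
  invisible(x)
}

#' @rdname km_logrank_hr
#' @param x A `km_fit` object.
#' @param ... Unused.
#' @export
tidy.km_fit <- function(x, ...) {
  sf <- x$survfit
  strata <- rep(names(sf$strata) %||% "all", sf$strata %||% length(sf$time))
  tibble(group = sub("^group=", "", strata), time = sf$time,
         n_risk = sf$n.risk, n_event = sf$n.event,
         n_censor = sf$n.censor, estimate = sf$surv,
         std_error = sf$std.err, conf_low = sf$lower, conf_high = sf$upper)
}

#' @rdname km_logrank_hr
#' @export
glance.km_fit <- function(x, ...) {
  tibble(n = x$n, logrank_statistic = x$logrank$statistic,
         logrank_p = x$logrank$p, hr = x$hr$hr,
         hr_conf_low = x$hr$conf_low, hr_conf_high = x$hr$conf_high,
         hr_p = x$hr$p)
}
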