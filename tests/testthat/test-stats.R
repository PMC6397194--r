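test_that("two-proportion z matches the pooled-variance hand computation", {
  # (30/50) vs (15/50): pooled p = 0.45, z = 0.3/sqrt(0.2475*0.04) = 3.0151
  res <- two_proportion_z(30, 50, 15, 50)
  expect_equal(res$statistic, 3.015113, tolerance = 1e-6)
  expect_equal(res$p, 0.002569, tolerance = 1e-4)
  # equal proportions: z = 0, p = 1
  eq <- two_proportion_z(10, 40, 5, 20)
  expect_equal(eq$statistic, 0)
  expect_equal(eq$p, 1)
  # swapping arms negates z, p unchanged
  sw <- two_proportion_z(15, 50, 30, 50)
  expect_equal(sw$statistic, -res$statistic)
  expect_equal(sw$p, res$p)
  # degenerate pooled proportion -> missing statistic
  deg <- two_proportion_z(0, 10, 0, 10)
  expect_true(is.na(deg$statistic))
  expect_error(two_proportion_z(5, 0, 1, 10), "at least one")
  expect_error(two_proportion_z(11, 10, 1, 10), "0 <= x <= n")
})

test_that("t-test matches the textbook value and Welch reduces to Student", {
  res <- two_sample_t(c(1, 2, 3), c(4, 5, 6))
  expect_equal(res$statistic, -3.674235, tolerance = 1e-6)
  expect_equal(res$p, 0.0213116, tolerance = 1e-5)
  # identical arms -> p = 1
  expect_equal(two_sample_t(c(1, 2, 3), c(1, 2, 3))$p, 1)
  # equal variances and n: Welch equals Student
  a <- c(1.2, 2.1, 2.9, 4.3); b <- c(2.2, 3.1, 3.9, 5.3)
  expect_equal(two_sample_t(a, b, welch = TRUE)$statistic,
               two_sample_t(a, b, welch = FALSE)$statistic)
  expect_error(two_sample_t(1, c(1, 2)), "at least 2")
})

test_that("ANOVA+Tukey identities hold and match a permutation reference", {
  vals <- c(1, 2, 3, 1, 2, 3)
  grp <- rep(c("a", "b"), each = 3)
  same <- anova_tukey(c(1, 2, 3, 1, 2, 3), grp)
  expect_equal(same$anova$statistic, 0)
  expect_equal(same$anova$p, 1)
  # with k = 2 the Tukey pairwise p equals the ANOVA p
  two <- anova_tukey(c(1, 2, 3, 4, 5, 7), grp)
  expect_equal(two$pairwise$p_adj, two$anova$p, tolerance = 1e-3)
  # and equals the Student t-test p (F = t^2)
  tt <- two_sample_t(c(1, 2, 3), c(4, 5, 7))
  expect_equal(two$anova$p, tt$p, tolerance = 1e-12)
  expect_equal(two$anova$statistic, tt$statistic^2, tolerance = 1e-9)

  # 3-group fixture against a brute-force permutation F reference
  set.seed(19)
  y <- c(2.1, 3.4, 1.8, 4.2, 5.0, 4.4, 2.9, 3.3, 3.8)
  g <- rep(c("a", "b", "c"), each = 3)
  obs <- anova_tukey(y, g)
  f_of <- function(y, g) {
    summary(aov(y ~ factor(g)))[[1]][["F value"]][1]
  }
  f_obs <- f_of(y, g)
  perm <- replicate(4000, f_of(sample(y), g))
  p_perm <- mean(perm >= f_obs)
  expect_equal(obs$anova$p, p_perm, tolerance = 0.03)
  expect_error(anova_tukey(1:4, rep("a", 4)), "2 groups")
})

test_that("Pearson correlation hits the closed-form extremes and oracle", {
  a <- c(1, 3, 2, 5, 4)
  expect_equal(pearson_cor(a, a)$estimate, 1)
  expect_equal(pearson_cor(a, -a)$estimate, -1)
  set.seed(4)
  x <- rnorm(20); y <- 0.5 * x + rnorm(20)
  r_oracle <- sum((x - mean(x)) * (y - mean(y))) /
    sqrt(sum((x - mean(x))^2) * sum((y - mean(y))^2))
  expect_equal(pearson_cor(x, y)$estimate, r_oracle, tolerance = 1e-12)
  expect_error(pearson_cor(c(1, 1, 1), c(1, 2, 3)), "constant")
  expect_error(pearson_cor(1:2, 1:2), "at least 3")
})

test_that("Storey q reproduces the hand example and the BH identity", {
  p <- c(0.2, 0.4, 0.6, 0.8)
  # lambda 0.5: pi0 = 2/(0.5*4) = 1, all q collapse to 0.8
  expect_equal(storey_q(p), rep(0.8, 4))
  # whenever pi0 = 1 Storey q equals the BH adjustment exactly
  set.seed(8)
  for (i in 1:20) {
    pv <- runif(sample(3:40, 1))
    m <- length(pv)
    pi0 <- min(1, sum(pv > 0.5) / (0.5 * m))
    if (pi0 == 1) {
      expect_equal(storey_q(pv), p.adjust(pv, method = "BH"))
    } else {
      expect_equal(storey_q(pv), pi0 * p.adjust(pv, method = "BH"))
    }
  }
  expect_equal(storey_q(rep(1, 5)), rep(1, 5))
  # q is monotone in p
  pv <- runif(50)
  q <- storey_q(pv)
  expect_true(all(diff(q[order(pv)]) >= -1e-12))
  expect_error(storey_q(c(0.5, 1.2)), "\\[0, 1\\]")
})

test_that("multinomial logit reduces to binary logistic with 2 levels", {
  set.seed(12)
  n <- 300
  x <- rnorm(n)
  y <- rbinom(n, 1, plogis(-0.3 + 0.8 * x))
  d <- data.frame(y = factor(ifelse(y == 1, "case", "ctrl"),
                             levels = c("ctrl", "case")), x = x)
  fit <- multinomial_logit(d, "y", "x", baseline = "ctrl",
                           standardize = FALSE)
  ref <- glm(y ~ x, data = d, family = binomial)
  tt <- tidy(fit)
  expect_equal(tt$estimate[tt$term == "x"], unname(coef(ref)["x"]),
               tolerance = 1e-3)
  expect_equal(tt$std_error[tt$term == "x"],
               unname(sqrt(diag(vcov(ref)))["x"]), tolerance = 1e-3)
  expect_true(glance(fit)$converged)
})

test_that("multinomial logit recovers planted coefficients and flags collinearity", {
  set.seed(13)
  n <- 2000
  x <- rnorm(n)
  # three outcome levels; level B has beta = 1 on x, level C has beta = -1
  eta_b <- 0.2 + 1.0 * x
  eta_c <- -0.1 - 1.0 * x
  pr <- cbind(1, exp(eta_b), exp(eta_c))
  pr <- pr / rowSums(pr)
  y <- apply(pr, 1, function(p) sample(c("A", "B", "C"), 1, prob = p))
  d <- data.frame(y = y, x = x)
  fit <- multinomial_logit(d, "y", "x", baseline = "A", standardize = FALSE)
  tt <- tidy(fit)
  expect_equal(tt$estimate[tt$y_level == "B" & tt$term == "x"], 1.0,
               tolerance = 0.15)
  expect_equal(tt$estimate[tt$y_level == "C" & tt$term == "x"], -1.0,
               tolerance = 0.15)
  d$x2 <- 2 * d$x
  expect_error(multinomial_logit(d, "y", c("x", "x2")), "collinear")
})

test_that("under the null, multinomial Wald p-values are roughly uniform", {
  set.seed(14)
  rej <- vapply(1:60, function(i) {
    d <- data.frame(y = sample(c("A", "B", "C"), 400, replace = TRUE),
                    x = rnorm(400))
    tt <- tidy(multinomial_logit(d, "y", "x", baseline = "A"))
    any(tt$p[tt$term == "x"] < 0.05)
  }, TRUE)
  # two tests per fit at alpha 0.05 -> family rejection ~< 0.10
  expect_lte(mean(rej), 0.25)
  expect_gte(mean(rej), 0.0)
})

test_that("KM/log-rank/HR behave on identical arms and validate input", {
  t1 <- c(5, 8, 12, 20, 25, 31)
  e1 <- c(1, 0, 1, 1, 0, 1)
  fit <- km_logrank_hr(c(t1, t1), c(e1, e1), rep(c("a", "b"), each = 6))
  expect_equal(fit$logrank$statistic, 0, tolerance = 1e-12)
  expect_equal(fit$logrank$p, 1)
  expect_equal(fit$hr$hr, 1, tolerance = 1e-9)
  # no events in one arm: HR missing, log-rank still defined
  fit2 <- km_logrank_hr(c(t1, t1), c(e1, rep(0, 6)),
                        rep(c("a", "b"), each = 6))
  expect_true(is.na(fit2$hr$hr))
  expect_false(is.na(fit2$logrank$p))
  expect_error(km_logrank_hr(c(-1, 2), c(1, 1), c("a", "b")), ">= 0")
  expect_error(km_logrank_hr(t1, e1, rep("a", 6)), "2 levels")
})

test_that("Cox beta matches a brute-force grid of the Breslow partial likelihood", {
  # 6-observation toy data, all events, one binary covariate
  time <- c(2, 4, 5, 7, 9, 12)
  event <- rep(1, 6)
  group <- c(0, 1, 0, 1, 1, 0)
  fit <- km_logrank_hr(time, event, group)
  breslow_loglik <- function(beta) {
    # all times distinct: standard partial likelihood
    ll <- 0
    for (i in order(time)) {
      risk <- time >= time[i]
      ll <- ll + beta * group[i] - log(sum(exp(beta * group[risk])))
    }
    ll
  }
  grid <- seq(-3, 3, by = 1e-4)
  beta_hat <- grid[which.max(vapply(grid, breslow_loglik, 0))]
  expect_lt(abs(log(fit$hr$hr) - beta_hat), 1e-4)
})
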