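# ROC ------------------------------------------------------------------------

test_that("roc handles separation, ties and refuses one-class input", {
  r <- roc(c(0.1, 0.2, 2, 3), c(0, 0, 1, 1))
  expect_equal(r$auc, 1.0)
  expect_equal(r$youden_cutoff, 2)
  expect_equal(r$j_at_cutoff, 1.0)
  expect_equal(roc(rep(1, 10), rep(0:1, 5))$auc, 0.5)
  expect_error(roc(1:4, rep(1, 4)), "both classes")
})

test_that("roc AUC equals the pairwise oracle and Youden the exhaustive sweep", {
  set.seed(101)
  for (i in 1:40) {
    n <- sample(6:60, 1)
    labels <- c(0, 1, rbinom(n - 2, 1, 0.4))
    scores <- round(rlnorm(n), sample(c(1, 2, Inf), 1))  # force some ties
    r <- roc(scores, labels)
    expect_equal(r$auc, auc_pairwise(scores, labels), tolerance = 1e-12)
    # exhaustive Youden sweep through sens_spec_at
    thr <- sort(unique(scores))
    j <- vapply(thr, function(t) {
      ss <- sens_spec_at(scores, labels, t)
      ss$sensitivity + ss$specificity - 1
    }, numeric(1))
    best <- thr[which(j >= max(j) - 1e-15)][1]
    expect_equal(r$youden_cutoff, best)
    expect_equal(r$j_at_cutoff, max(j), tolerance = 1e-12)
  }
})

test_that("roc AUC is invariant under strictly increasing transforms", {
  set.seed(102)
  scores <- rlnorm(50); labels <- rbinom(50, 1, 0.3) + c(1, rep(0, 49))
  a <- roc(scores, labels)$auc
  expect_equal(roc(log(scores + 1), labels)$auc, a, tolerance = 1e-12)
  expect_equal(roc(scores^3, labels)$auc, a, tolerance = 1e-12)
})

test_that("roc agrees with pROC on random data", {
  skip_if_not_installed("pROC")
  set.seed(103)
  scores <- rnorm(80); labels <- rbinom(80, 1, 0.5)
  a <- roc(scores, labels)$auc
  b <- as.numeric(pROC::auc(pROC::roc(labels, scores, direction = "<",
                                      quiet = TRUE)))
  expect_equal(a, b, tolerance = 1e-12)
})

test_that("sens_spec_at counts exceedances per class", {
  expect_equal(sens_spec_at(c(0.1, 0.2, 2, 3), c(0, 0, 1, 1), 2),
               list(sensitivity = 1.0, specificity = 1.0))
  expect_equal(sens_spec_at(c(1, 2, 3, 4), c(0, 1, 0, 1), 0.5),
               list(sensitivity = 1.0, specificity = 0.0))
  set.seed(104)
  s <- rnorm(60); l <- rbinom(60, 1, 0.5); cut <- 0.2
  ss <- sens_spec_at(s, l, cut)
  expect_equal(ss$sensitivity, sum(s >= cut & l == 1) / sum(l == 1))
  expect_equal(ss$specificity, sum(s < cut & l == 0) / sum(l == 0))
  expect_error(sens_spec_at(1:3, c(1, 1, 1), 2), "both classes")
})

# Logistic regression --------------------------------------------------------

test_that("logistic_fit recovers symmetry, 2x2 closed form, and satisfies scores", {
  # outcome independent of a symmetric covariate -> zero slope
  x <- rep(c(-2, -1, 1, 2), 2); y <- rep(c(0, 1), each = 4)
  f <- logistic_fit(data.frame(x = x), y)
  expect_lt(abs(f$coefficients["x"]), 1e-6)
  # 2x2 closed form: adult mortality by relapse outcome
  cov <- c(rep(1, 18), rep(0, 69))
  out <- c(rep(1, 12), rep(0, 6), rep(1, 11), rep(0, 58))
  f2 <- logistic_fit(data.frame(relapse = cov), out)
  expect_equal(unname(f2$or["relapse"]), (12 * 58) / (6 * 11), tolerance = 1e-8)
  # score equations at the optimum
  set.seed(105)
  X <- cbind(a = rnorm(40), b = rbinom(40, 1, 0.5))
  yy <- rbinom(40, 1, plogis(0.3 + 0.8 * X[, 1]))
  f3 <- logistic_fit(X, yy)
  resid <- yy - f3$fitted
  expect_lt(abs(sum(resid)), 1e-8)
  expect_lt(max(abs(crossprod(X, resid))), 1e-8)
})

test_that("logistic_fit log-likelihood beats a surrounding coefficient grid", {
  set.seed(106)
  x <- rnorm(20); y <- rbinom(20, 1, plogis(0.5 * x))
  f <- logistic_fit(data.frame(x = x), y)
  ll <- function(b0, b1) {
    p <- plogis(b0 + b1 * x)
    sum(y * log(p) + (1 - y) * log(1 - p))
  }
  grid <- expand.grid(b0 = f$coefficients[1] + seq(-1, 1, 0.1),
                      b1 = f$coefficients[2] + seq(-1, 1, 0.1))
  lls <- mapply(ll, grid$b0, grid$b1)
  expect_gte(f$log_lik + 1e-9, max(lls))
})

test_that("logistic_fit matches glm and flags pathologies", {
  set.seed(107)
  X <- data.frame(x = rnorm(60), z = rbinom(60, 1, 0.4))
  y <- rbinom(60, 1, plogis(-0.5 + X$x))
  f <- logistic_fit(X, y)
  g <- glm(y ~ x + z, data = cbind(X, y = y), family = binomial,
           control = glm.control(epsilon = 1e-12))
  expect_equal(unname(f$coefficients), unname(coef(g)), tolerance = 1e-7)
  expect_equal(unname(f$se), unname(sqrt(diag(vcov(g)))), tolerance = 1e-6)
  expect_false(f$separation)
  # complete separation flagged
  xs <- c(-3, -2, -1, 1, 2, 3); ys <- c(0, 0, 0, 1, 1, 1)
  expect_warning(fs <- logistic_fit(data.frame(x = xs), ys), "separation")
  expect_true(fs$separation)
  # rank deficiency refused
  expect_error(logistic_fit(data.frame(a = 1:6, b = 2 * (1:6)), ys),
               "rank deficient")
})

# Kaplan-Meier and log-rank --------------------------------------------------

test_that("km reproduces hand product-limit fixtures", {
  # no events: flat at 1
  k0 <- km(c(3, 6, 9), c(0, 0, 0))
  expect_true(all(k0$table$surv == 1))
  # censoring shrinks a later risk set: S(5) = 2/3, S(15) = 0
  k1 <- km(c(5, 10, 15), c(1, 0, 1))
  expect_equal(survival_at(k1, 5)$estimate, 2 / 3)
  expect_equal(survival_at(k1, 15)$estimate, 0)
  # no censoring: S = 1 - ECDF
  set.seed(108)
  t2 <- sample(1:100, 12)
  k2 <- km(t2, rep(1, 12))
  expect_equal(k2$table$surv, 1 - ecdf(t2)(k2$table$time))
  # all-events distinct times: S(t_(k)) = (n-k)/n
  expect_equal(k2$table$surv, (12 - seq_len(12)) / 12)
})

test_that("km matches the survival package including Greenwood errors", {
  skip_if_not_installed("survival")
  set.seed(109)
  t <- rexp(50, 0.01); e <- rbinom(50, 1, 0.7)
  k <- km(t, e)
  sf <- survival::survfit(survival::Surv(t, e) ~ 1, conf.type = "plain")
  sm <- summary(sf, times = k$table$time)
  expect_equal(k$table$surv, sm$surv, tolerance = 1e-12)
  expect_equal(k$table$se, sm$std.err, tolerance = 1e-10)
})

test_that("survival_at is a right-continuous step with extrapolation flag", {
  k <- km(c(5, 10, 15), c(1, 0, 1))
  expect_equal(survival_at(k, 0)$estimate, 1)
  expect_equal(survival_at(k, 7)$estimate, 2 / 3)   # between event times
  expect_false(survival_at(k, 12)$extrapolated)
  at <- survival_at(k, 100)
  expect_true(at$extrapolated)
  expect_equal(at$estimate, 0)
})

test_that("logrank matches a hand O-E computation and survdiff", {
  # identical groups: statistic 0, p 1
  same <- logrank(c(2, 5, 8), c(1, 0, 1), c(2, 5, 8), c(1, 0, 1))
  expect_equal(same$statistic, 0)
  expect_equal(same$p_value, 1)
  # hand fixture: a = {2+, 4c}, b = {3+, 5+}
  lr <- logrank(c(2, 4), c(1, 0), c(3, 5), c(1, 1))
  O <- 1
  E <- 1 * 2 / 4 + 1 * 1 / 3 + 0          # events at t = 2, 3, 5
  V <- 1 * (2 / 4) * (1 - 2 / 4) * (4 - 1) / (4 - 1) +
    1 * (1 / 3) * (2 / 3) * (3 - 1) / (3 - 1)
  expect_equal(lr$observed, O)
  expect_equal(lr$expected, E, tolerance = 1e-12)
  expect_equal(lr$statistic, (O - E)^2 / V, tolerance = 1e-12)
  skip_if_not_installed("survival")
  set.seed(110)
  t <- rexp(40, 0.02); e <- rbinom(40, 1, 0.8); g <- rep(1:2, each = 20)
  ours <- logrank(t[g == 1], e[g == 1], t[g == 2], e[g == 2])
  sd <- survival::survdiff(survival::Surv(t, e) ~ g)
  expect_equal(ours$statistic, sd$chisq, tolerance = 1e-10)
})

test_that("logrank p-values are uniform under an exchangeable null", {
  set.seed(111)
  t <- rexp(40, 0.02); e <- rbinom(40, 1, 0.8)
  ps <- replicate(500, {
    g <- sample(rep(1:2, each = 20))
    logrank(t[g == 1], e[g == 1], t[g == 2], e[g == 2])$p_value
  })
  expect_gt(suppressWarnings(ks.test(ps, "punif")$p.value), 0.01)
})

test_that("logrank warns and returns p = 1 without events", {
  expect_warning(lr <- logrank(c(1, 2), c(0, 0), c(3, 4), c(0, 0)), "no events")
  expect_equal(lr$p_value, 1)
})

# Fisher exact, chi-squared, Mann-Whitney ------------------------------------

test_that("fisher_exact enumerates the hypergeometric exactly", {
  expect_equal(fisher_exact(matrix(c(1, 0, 0, 1), 2))$p_value, 1.0)
  # adult mortality by relapse: strongly associated
  tab <- matrix(c(12, 11, 6, 58), 2)  # [[12,6],[11,58]] in row-major terms
  expect_lt(fisher_exact(tab)$p_value, 1e-4)
  set.seed(112)
  for (i in 1:25) {
    t2 <- matrix(rpois(4, sample(2:12, 1)), 2)
    p <- fisher_exact(t2)$p_value
    expect_equal(p, fisher_enum(t2), tolerance = 1e-12)
    expect_equal(p, fisher.test(t2)$p.value, tolerance = 1e-9)
    # invariance under transposition and row/column swaps
    expect_equal(fisher_exact(t(t2))$p_value, p, tolerance = 1e-12)
    expect_equal(fisher_exact(t2[2:1, ])$p_value, p, tolerance = 1e-12)
    expect_equal(fisher_exact(t2[, 2:1])$p_value, p, tolerance = 1e-12)
  }
  expect_error(fisher_exact(matrix(c(-1, 2, 3, 4), 2)))
})

test_that("chi2_test computes the Pearson statistic for 2 x k tables", {
  # observed equals expected exactly
  even <- matrix(c(10, 10, 20, 20, 30, 30), 2)
  r <- chi2_test(even)
  expect_equal(r$statistic, 0)
  expect_equal(r$p_value, 1)
  expect_equal(r$df, 2)
  # direct formula oracle on a 2x3 table
  tab <- matrix(c(12, 5, 8, 9, 4, 11), 2)
  E <- outer(rowSums(tab), colSums(tab)) / sum(tab)
  expect_equal(chi2_test(tab)$statistic, sum((tab - E)^2 / E), tolerance = 1e-12)
  cs <- suppressWarnings(chisq.test(tab, correct = FALSE))
  expect_equal(chi2_test(tab)$statistic, unname(cs$statistic), tolerance = 1e-12)
  expect_equal(chi2_test(tab)$p_value, cs$p.value, tolerance = 1e-12)
  # simulated mean of the statistic is about df under the multinomial null
  set.seed(113)
  stats <- replicate(300, {
    t <- matrix(rmultinom(1, 120, rep(1 / 6, 6)), 2)
    chi2_test(t)$statistic
  })
  expect_equal(mean(stats), 2, tolerance = 0.15)
  expect_error(chi2_test(matrix(c(0, 0, 1, 2), 2)), "zero marginal")
})

test_that("mann_whitney matches exact enumeration and the normal approximation", {
  # identical multisets: U = nx * ny / 2
  expect_equal(mann_whitney(c(1, 2, 3), c(1, 2, 3))$statistic, 4.5)
  # x wholly above y: maximal U, one-sided p = 1 / choose(n, nx)
  r <- mann_whitney(c(10, 11, 12), c(1, 2, 3, 4))
  expect_equal(r$statistic, 12)
  expect_true(r$exact)
  expect_equal(r$p_greater, 1 / choose(7, 3), tolerance = 1e-12)
  # exact two-sided p against wilcox.test for small tie-free samples
  set.seed(114)
  for (i in 1:15) {
    nx <- sample(3:6, 1); ny <- sample(3:6, 1)
    x <- rnorm(nx); y <- rnorm(ny)
    ours <- mann_whitney(x, y)
    expect_true(ours$exact)
    expect_equal(ours$p_value, wilcox.test(x, y, exact = TRUE)$p.value,
                 tolerance = 1e-12)
  }
  # normal approximation with ties and continuity correction
  for (i in 1:10) {
    x <- sample(1:6, 15, replace = TRUE); y <- sample(2:8, 12, replace = TRUE)
    ours <- mann_whitney(x, y)
    expect_false(ours$exact)
    ref <- suppressWarnings(wilcox.test(x, y, exact = FALSE, correct = TRUE))
    expect_equal(ours$p_value, ref$p.value, tolerance = 1e-10)
  }
})

# LOESS ----------------------------------------------------------------------

test_that("loess_fit reproduces lines, constants, and the single-point WLS solve", {
  x <- seq(0, 10, length.out = 25)
  y <- 2 * x + 1
  f <- loess_fit(x, y, span = 0.5, degree = 1, grid = x)
  expect_equal(f$fitted, y, tolerance = 1e-10)
  yc <- rep(3.5, 25)
  expect_equal(loess_fit(x, yc, grid = x)$fitted, yc, tolerance = 1e-10)
  # query at a data point with span covering all points: direct WLS oracle
  set.seed(115)
  yr <- sin(x) + rnorm(25, sd = 0.1)
  x0 <- x[7]
  f2 <- loess_fit(x, yr, span = 1, degree = 1, grid = x0)
  d <- abs(x - x0); h <- max(d)
  w <- (1 - (d / h)^3)^3
  beta <- lm.wfit(cbind(1, x - x0), yr, w)$coefficients
  expect_equal(f2$fitted, unname(beta[1]), tolerance = 1e-10)
  # degenerate local design is an error
  expect_error(loess_fit(rep(1, 5), 1:5, degree = 1, grid = 1),
               NA) # replicated x collapses to the local mean, not an error
  expect_equal(loess_fit(rep(1, 5), 1:5, degree = 1, grid = 1)$fitted, 3)
  expect_error(loess_fit(c(1, 1, 1, 1, 2), 1:5, span = 1, degree = 1, grid = 1),
               "degenerate local design")
})
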