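test_that("Kaplan-Meier estimates match closed forms and the brute-force
           product-limit oracle", {
  # all censored: S = 1 everywhere
  km0 <- kmFit(c(3, 5, 7), c(0, 0, 0))
  expect_true(all(km0$surv == 1))
  expect_identical(medianSurvival(km0), Inf)

  # three events: S = 2/3, 1/3, 0
  km1 <- kmFit(1:3, rep(1, 3))
  expect_equal(km1$surv, c(2 / 3, 1 / 3, 0), tolerance = 1e-12)
  expect_equal(medianSurvival(km1), 2)

  # 100 random small instances against the independent oracle
  set.seed(42)
  for (i in 1:100) {
    n <- sample(5:50, 1)
    tt <- round(rexp(n, 0.1), 1)
    ev <- rbinom(n, 1, 0.7)
    if (sum(ev) == 0) ev[1] <- 1
    km <- kmFit(tt, ev)
    oracle <- bruteKM(tt, ev)
    at_events <- km$surv[match(oracle$time, km$time)]
    expect_lt(max(abs(at_events - oracle$surv)), 1e-12)
  }
  expect_error(kmFit(numeric(), numeric()), "empty")
})

test_that("survivalAt is a right-continuous step function", {
  km <- kmFit(c(1, 2, 4), c(1, 1, 1))
  expect_equal(survivalAt(km, 0), 1)
  expect_equal(survivalAt(km, 1), 2 / 3)       # right-continuous at events
  expect_equal(survivalAt(km, 3.9), 1 / 3)
  expect_equal(survivalAt(km, 100), 0)          # beyond last time
  expect_error(survivalAt(km, -1), "negative")
})

test_that("median survival uses the first S(t) <= 0.5 crossing", {
  # S = 1, .75, .5, .25 at t = 0,1,2,3 -> median 2 (first crossing)
  tt <- c(rep(1, 1), rep(2, 1), rep(3, 1), 4)
  km <- kmFit(c(1, 2, 3, 4), c(1, 1, 1, 1))   # S = .75,.5,.25,0
  expect_equal(medianSurvival(km), 2)
})

test_that("log-rank test matches a hand-enumerated risk-set computation", {
  # A: events at 1, 2; B: events at 3, 4. Risk sets by hand:
  # t=1: n=4, nA=2, dA=1 -> E=1/2, V=1*2*2*3/(16*3)=1/4
  # t=2: n=3, nA=1, dA=1 -> E=1/3, V=1*1*2*2/(9*2)=2/9
  # t=3,4: nA=0 -> E=0, V=0.  O-E = 2 - 5/6; chi2 = (7/6)^2 / (1/4+2/9)
  res <- logrankTest(c(1, 2, 3, 4), rep(1, 4), c("A", "A", "B", "B"))
  expect_equal(res$statistic, (2 - 5 / 6)^2 / (1 / 4 + 2 / 9),
               tolerance = 1e-10)
  expect_identical(res$df, 1L)

  # identical groups: statistic 0, p 1
  tt <- c(1, 2, 3, 1, 2, 3); ev <- rep(1, 6)
  res0 <- logrankTest(tt, ev, rep(c("X", "Y"), each = 3))
  expect_lt(res0$statistic, 1e-10)
  expect_equal(res0$p_value, 1, tolerance = 1e-6)

  # all censored: defined as statistic 0, p 1
  resC <- logrankTest(c(1, 1, 2, 2), rep(0, 4), c(1, 2, 1, 2))
  expect_identical(resC$statistic, 0)
  expect_identical(resC$p_value, 1)

  expect_error(logrankTest(1:3, rep(1, 3), rep("A", 3)), "two groups")
})

test_that("log-rank is invariant to label permutation and to censoring
           outside every risk set", {
  set.seed(5)
  tt <- rexp(40); ev <- rbinom(40, 1, 0.8)
  g <- rep(c("a", "b"), 20)
  base <- logrankTest(tt, ev, g)
  perm <- logrankTest(tt, ev, ifelse(g == "a", "b", "a"))
  expect_equal(base$statistic, perm$statistic, tolerance = 1e-12)
  # a patient censored before the first event never enters an O-E term
  eps <- min(tt[ev == 1]) / 2
  aug <- logrankTest(c(tt, eps), c(ev, 0), c(g, "a"))
  expect_equal(base$statistic, aug$statistic, tolerance = 1e-12)
})

test_that("BH adjustment matches the hand step-up example and its
           invariants", {
  expect_equal(bhAdjust(0.03), 0.03)
  expect_equal(bhAdjust(c(0.01, 0.02, 0.03, 0.04)), rep(0.04, 4),
               tolerance = 1e-12)
  set.seed(8)
  for (i in 1:20) {
    p <- runif(sample(1:30, 1))
    q <- bhAdjust(p)
    expect_true(all(q >= p - 1e-15) && all(q <= 1))
    # reapplication can only push values further toward 1, never back down
    expect_true(all(bhAdjust(q) >= q - 1e-15))
    expect_true(all(diff(q[order(p)]) >= -1e-15))    # monotone in ranks
  }
  expect_error(bhAdjust(c(0.5, 1.2)), "\\[0, 1\\]")
})

test_that("Cox fit matches a direct partial-likelihood grid search on a
           worked dataset", {
  # 6 observations, one binary covariate, no ties
  tt <- c(1, 2, 3, 4, 5, 6)
  ev <- c(1, 1, 0, 1, 1, 1)
  x <- c(1, 0, 1, 1, 0, 0)
  fit <- coxphFit(tt, ev, matrix(x, ncol = 1))
  # brute-force: maximize the written-out partial likelihood over a grid
  pll <- function(b) {
    s <- 0
    for (i in which(ev == 1)) {
      risk <- tt >= tt[i]
      s <- s + b * x[i] - log(sum(exp(b * x[risk])))
    }
    s
  }
  grid <- seq(-4, 4, by = 1e-4)
  bhat <- grid[which.max(vapply(grid, pll, numeric(1)))]
  expect_equal(unname(fit$coefficients), bhat, tolerance = 1e-3)
  expect_equal(unname(fit$hazard_ratio), exp(bhat), tolerance = 1e-3)
  expect_true(fit$converged)
  expect_true(fit$ci_lower <= fit$hazard_ratio &&
                fit$hazard_ratio <= fit$ci_upper)
})

test_that("Cox fit is null for exchangeable groups and flags separation", {
  tt <- rep(c(1, 2, 3, 4), 2)
  ev <- rep(1, 8)
  x <- rep(c(0, 1), each = 4)
  fit <- coxphFit(tt, ev, matrix(x, ncol = 1))
  expect_lt(abs(fit$coefficients), 1e-8)
  expect_equal(unname(fit$hazard_ratio), 1, tolerance = 1e-6)

  # complete separation: earliest deaths all in one group -> no convergence
  sep <- suppressWarnings(
    coxphFit(c(1, 2, 3, 10, 11, 12), rep(1, 6),
             matrix(c(1, 1, 1, 0, 0, 0), ncol = 1)))
  expect_false(sep$converged)

  expect_error(coxphFit(1:3, rep(1, 3), matrix(1, 3, 1)), "constant")
})
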