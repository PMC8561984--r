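test_that("any-use totals are ORs of the service indicators", {
  ds <- tiny_survey()
  tot <- build_total_use(ds)
  expect_equal(tot$total_outpatient, c(1, 0, 1, 1, 1))
  expect_equal(tot$total_inpatient, c(0, 0, 0, 1, 0))
  # OR-monotonicity over all four indicator combinations
  grid <- expand.grid(pub = 0:1, priv = 0:1)
  or <- as.integer(grid$pub | grid$priv)
  expect_true(all(or >= grid$pub & or >= grid$priv))
  expect_equal(or[grid$pub + grid$priv == 2], 1)   # no double count
})

test_that("LPM partial effects equal weighted least squares exactly", {
  set.seed(41)
  n <- 300
  X <- cbind(x1 = rnorm(n), x2 = rbinom(n, 1, 0.4))
  w <- runif(n, 0.5, 2)
  y <- rbinom(n, 1, plogis(-0.5 + 0.8 * X[, 1]))
  fit <- fit_partial_effects(y, X, w, method = "lpm")
  ref <- lm(y ~ X, weights = w)
  expect_equal(unname(fit$coef), unname(coef(ref)[-1]), tolerance = 1e-10)
  expect_equal(fit$intercept, unname(coef(ref)[1]), tolerance = 1e-10)
  # mean preservation of the linearization
  expect_equal(sum(w * fit$linear_pred) / sum(w), fit$mu, tolerance = 1e-12)
})

test_that("probit marginal effects at means recover the truth at large n", {
  set.seed(43)
  n <- 20000
  x1 <- rnorm(n); x2 <- rbinom(n, 1, 0.3)
  theta <- c(-0.8, 0.5, -0.4)
  y <- rbinom(n, 1, pnorm(theta[1] + theta[2] * x1 + theta[3] * x2))
  fit <- fit_partial_effects(y, cbind(x1 = x1, x2 = x2))
  expect_identical(fit$method, "probit")
  true_me <- dnorm(theta[1] + theta[2] * mean(x1) + theta[3] * mean(x2)) *
    theta[2:3]
  # MC slack ~ 3 asymptotic sd of a probit marginal effect at this n
  expect_lt(max(abs(unname(fit$coef) - true_me)), 0.025)
  expect_equal(sum(fit$linear_pred) / n, fit$mu, tolerance = 1e-12)
})

test_that("intercept-only and degenerate designs are handled", {
  y <- rbinom(50, 1, 0.4)
  fit <- fit_partial_effects(y, NULL)
  expect_length(fit$coef, 0)
  expect_equal(fit$intercept, mean(y))
  X <- cbind(a = rnorm(50))
  X2 <- cbind(X, b = 2 * X[, 1])
  expect_error(fit_partial_effects(y, X2), "collinear")
  # perfectly separated outcome falls back to the LPM with a warning
  xs <- c(rep(-2, 25), rep(2, 25))
  ys <- as.integer(xs > 0)
  expect_warning(fs <- fit_partial_effects(ys, cbind(x = xs)),
                 "linear probability")
  expect_identical(fs$method, "lpm")
})

test_that("contributions plus residual reproduce the CI exactly", {
  ranked <- default_ranked()
  for (oc in c("total_outpatient", "total_inpatient")) {
    for (m in c("probit", "lpm")) {
      tab <- decompose_use(ranked, oc, method = m)
      expect_equal(sum(tab$contribution) + attr(tab, "residual"),
                   attr(tab, "ci_plain"), tolerance = 1e-10)
      # residual equals the generalized CI of the linearization error / mu
      expect_equal(attr(tab, "residual"), attr(tab, "residual_gc"),
                   tolerance = 1e-10)
      expect_equal(sum(tab$pct_contribution),
                   1 - attr(tab, "residual") / attr(tab, "ci_plain"),
                   tolerance = 1e-10)
    }
  }
})

test_that("single-factor world attributes all inequality to consumption", {
  set.seed(47)
  n <- 6000
  v <- rlnorm(n)
  r <- fractional_rank(v)
  y <- rbinom(n, 1, pnorm(-1.2 + 1.0 * r))
  X <- cbind(consumption = r)
  tab <- decompose_ci(y, X, rank = r, method = "lpm")
  expect_equal(tab$pct_contribution[1], 1,
               tolerance = 0.05)            # ~100% of the CI
  expect_lt(abs(attr(tab, "residual")), 0.02 * abs(attr(tab, "ci_plain")))
  # covariate uncorrelated with rank contributes ~0 whatever its elasticity
  z <- rbinom(n, 1, 0.5)
  y2 <- rbinom(n, 1, pnorm(-1 + 0.8 * z + 0.6 * r))
  tab2 <- decompose_ci(y2, cbind(z = z, consumption = r), rank = r,
                       method = "lpm")
  expect_lt(abs(tab2$contribution[1]), 0.015)
  expect_gt(abs(tab2$elasticity[1]), 0.1)
  # sign logic: covariate concentrated among the rich with positive effect
  # contributes positively
  rich <- rbinom(n, 1, pmin(0.9, 0.2 + 0.6 * r))
  y3 <- rbinom(n, 1, pnorm(-1 + 0.9 * rich))
  tab3 <- decompose_ci(y3, cbind(rich = rich), rank = r, method = "lpm")
  expect_gt(tab3$covariate_ci[1], 0)
  expect_gt(tab3$elasticity[1], 0)
  expect_gt(tab3$contribution[1], 0)
})

test_that("merging dummies into a group sums their contributions exactly", {
  ranked <- default_ranked()
  tab <- decompose_use(ranked, "total_outpatient")
  grp <- group_contributions(tab)
  gov <- sum(tab$contribution[tab$group == "governorate"])
  expect_equal(grp$contribution[grp$group == "governorate"], gov,
               tolerance = 1e-14)
  expect_equal(sum(grp$contribution), sum(tab$contribution),
               tolerance = 1e-12)
})
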