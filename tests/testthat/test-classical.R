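test_that("balanced additive data decompose in closed form", {
  tab <- estimate_table(c("a1", "a2"), c("s1", "s2"),
                        y = matrix(c(10, 30, 20, 40), 2, 2),
                        se = matrix(1, 2, 2))
  fit <- weighted_two_way_anova(tab, matrix(1, 2, 2), anchor = 25)
  expect_equal(unname(fit$theta_hat), c(15, 35), tolerance = 1e-10)
  expect_equal(unname(fit$mu_hat), c(-5, 5), tolerance = 1e-10)
  expect_equal(fit$objective, 0, tolerance = 1e-10)

  flat <- estimate_table(c("a1", "a2", "a3"), c("s1", "s2"),
                         y = matrix(23, 3, 2), se = matrix(1, 3, 2))
  f <- weighted_two_way_anova(flat, matrix(1, 3, 2), anchor = 23)
  expect_equal(unname(f$theta_hat), rep(23, 3), tolerance = 1e-10)
  expect_equal(unname(f$mu_hat), c(0, 0), tolerance = 1e-10)
})

test_that("weighted ANOVA matches the constrained-WLS oracle", {
  for (s in 1:12) {
    A <- sample(3:8, 1); S <- sample(2:6, 1)
    tab <- random_table(A, S, seed = 300 + s,
                        missing = if (s %% 3 == 0) 2 else 0)
    set.seed(400 + s)
    w <- matrix(runif(A * S, 0.2, 3), A, S)
    fit <- weighted_two_way_anova(tab, w, anchor = 23)
    oracle <- anova_oracle(tab, w, anchor = 23)
    expect_lt(max(abs(fit$theta_hat - oracle$theta)), 1e-8)
    expect_lt(max(abs(fit$mu_hat - oracle$mu)), 1e-8)
    expect_equal(fit$objective, oracle$objective, tolerance = 1e-8)
    expect_equal(mean(fit$theta_hat), 23, tolerance = 1e-10)
  }
})

test_that("disconnected designs are rejected as singular", {
  # areas {1,2} seen only by source 1, areas {3,4} only by source 2
  present <- rbind(c(TRUE, FALSE), c(TRUE, FALSE),
                   c(FALSE, TRUE), c(FALSE, TRUE))
  tab <- estimate_table(paste0("a", 1:4), c("s1", "s2"),
                        y = matrix(23, 4, 2), se = matrix(1, 4, 2),
                        present = present)
  expect_error(weighted_two_way_anova(tab, matrix(1, 4, 2), 23),
               "singular|disconnected")
})

test_that("DerSimonian-Laird estimator reproduces its closed form", {
  expect_equal(dl_moment_estimator(c(0, 0, 0), c(1, 2, 3)), 0)
  # Q = 8, k - 1 = 2, denominator = 3 - 3/3 = 2 -> tau2 = 3
  expect_equal(dl_moment_estimator(c(-2, 0, 2), c(1, 1, 1)), 3,
               tolerance = 1e-12)
  # Q below k - 1 truncates to zero
  expect_equal(dl_moment_estimator(c(-0.1, 0, 0.1), c(1, 1, 1)), 0)
  expect_error(dl_moment_estimator(1, 1), "at least 2")

  # translation invariance and quadratic scaling (pre-truncation regime)
  set.seed(77)
  d <- rnorm(8, 0, 3); v <- runif(8, 0.5, 2)
  t0 <- dl_moment_estimator(d, v)
  expect_gt(t0, 0)
  expect_equal(dl_moment_estimator(d + 5, v), t0, tolerance = 1e-10)
  # c^2 scaling when deviations and variances scale together
  expect_equal(dl_moment_estimator(3 * d, 9 * v), 9 * t0, tolerance = 1e-9)
})

test_that("noiseless additive tables are recovered in one iteration", {
  theta <- c(20, 22, 24, 26); mu <- c(-2, 1, 1)
  y <- outer(theta, rep(1, 3)) + outer(rep(1, 4), mu)
  tab <- estimate_table(paste0("a", 1:4), paste0("s", 1:3), y,
                        matrix(0.5, 4, 3))
  expect_warning(fit <- iterative_anova_fit(tab, anchor = mean(theta)),
                 "residual-free")
  expect_equal(fit$n_iterations, 1L)
  expect_true(fit$converged)
  expect_equal(unname(fit$tau2_hat), rep(0, 3))
  expect_equal(unname(fit$theta_hat), theta, tolerance = 1e-9)
  expect_equal(unname(fit$mu_hat), mu, tolerance = 1e-9)
  expect_equal(fit$mse_factor, 0)
})

test_that("the iterative fixed point is self-consistent", {
  for (s in c(2, 8)) {
    gen <- simulate_dataset(sim_config(n_areas = 20, n_sources = 5,
                                       seed = s))
    tab <- gen$table
    fit <- iterative_anova_fit(tab, 23, accelerate = "anderson")
    expect_true(fit$converged)
    # ANOVA normal equations hold at the converged weights
    w <- 1 / sweep(tab$se^2, 2, fit$tau2_hat, "+")
    re <- weighted_two_way_anova(tab, w, 23)
    expect_lt(max(abs(re$theta_hat - fit$theta_hat)), 1e-6)
    expect_lt(max(abs(re$mu_hat - fit$mu_hat)), 1e-6)
    # DL equations hold at the converged deviations
    for (j in 1:5) {
      d <- tab$y[, j] - fit$theta_hat
      expect_equal(dl_moment_estimator(d, tab$se[, j]^2),
                   unname(fit$tau2_hat[j]), tolerance = 1e-6)
    }
    expect_equal(mean(fit$theta_hat), 23, tolerance = 1e-9)
    # plain alternation approaches the same fixed point (its linear rate
    # leaves a larger residual at the iteration cap)
    plain <- iterative_anova_fit(tab, 23, accelerate = "none",
                                 max_iter = 200)
    expect_lt(max(abs(plain$tau2_hat - fit$tau2_hat)), 1e-5)
  }
})

test_that("the mse adjustment scales as the residuals do", {
  gen <- simulate_dataset(sim_config(n_areas = 15, n_sources = 4, seed = 4))
  fit <- iterative_anova_fit(gen$table, 23)
  expect_gt(fit$mse_factor, 0)
  # doubling residuals around the fit quadruples MSE, doubling the factor
  tab2 <- gen$table
  fitted <- outer(unname(fit$theta_hat), rep(1, 4)) +
    outer(rep(1, 15), unname(fit$mu_hat))
  tab2$y <- fitted + 2 * (gen$table$y - fitted)
  refit <- weighted_two_way_anova(
    tab2, 1 / sweep(tab2$se^2, 2, fit$tau2_hat, "+"), 23)
  # same fitted values (doubling residuals preserves the LS solution)
  expect_lt(max(abs(refit$theta_hat - fit$theta_hat)), 1e-8)
  f1 <- fit
  f2 <- mse_adjust(f1, tab2)
  expect_equal(f2$mse_factor, 2 * fit$mse_factor, tolerance = 1e-8)
  expect_equal(unname(f2$se_theta), unname(2 * fit$se_theta),
               tolerance = 1e-8)
  # floor option never shrinks
  f3 <- mse_adjust(fit, gen$table, floor_1 = TRUE)
  expect_gte(f3$mse_factor, 1)
})

test_that("the REML mixed model agrees with the iterative ANOVA", {
  for (s in c(6, 16)) {
    gen <- simulate_dataset(sim_config(seed = s))
    a <- iterative_anova_fit(gen$table, 23, accelerate = "anderson")
    r <- fit_mixed_model(gen$table, 23)
    expect_true(r$converged)
    expect_lt(max(abs(a$theta_hat - r$theta_hat)), 0.1)
    expect_lt(max(abs(a$mu_hat - r$mu_hat)), 0.1)
  }
})

test_that("REML finds the zero boundary and a local optimum", {
  # tau-truth zero: every source variance should sit at or near zero,
  # within the sampling spread of a variance estimate (~ sqrt(2/A) * v)
  cfg <- sim_config(n_areas = 100, n_sources = 4, seed = 13,
                    tau = rep(0, 4), sample_size = rep(3000, 4))
  gen <- simulate_dataset(cfg)
  r <- fit_mixed_model(gen$table, 23)
  expect_lt(max(r$tau2_hat), 3 * sqrt(2 / 100) * mean(gen$table$se^2))

  # local-optimality audit on a generic table
  gen <- simulate_dataset(sim_config(n_areas = 20, n_sources = 5, seed = 14))
  tab <- gen$table
  r <- fit_mixed_model(tab, 23)
  idx <- which(tab$present, arr.ind = TRUE)
  A <- 20; S <- 5
  X <- matrix(0, nrow(idx), A + S - 1)
  X[cbind(seq_len(nrow(idx)), idx[, 1])] <- 1
  keep <- idx[, 2] > 1
  X[cbind(which(keep), A + idx[keep, 2] - 1L)] <- 1
  at_opt <- biasblend:::reml_criterion(r$tau2_hat, tab, idx, X)
  set.seed(15)
  for (k in 1:50) {
    pert <- pmax(r$tau2_hat + rnorm(S, 0, 0.2), 0)
    expect_lte(biasblend:::reml_criterion(pert, tab, idx, X),
               at_opt + 1e-6)
  }
})

test_that("anchor equivariance holds for the classical fits", {
  gen <- simulate_dataset(sim_config(n_areas = 12, n_sources = 4, seed = 31))
  f23 <- iterative_anova_fit(gen$table, 23, accelerate = "anderson")
  f25 <- iterative_anova_fit(gen$table, 25, accelerate = "anderson")
  expect_equal(unname(f25$theta_hat - f23$theta_hat), rep(2, 12),
               tolerance = 1e-6)
  expect_equal(unname(f25$mu_hat - f23$mu_hat), rep(-2, 4),
               tolerance = 1e-6)
  expect_equal(f25$tau2_hat, f23$tau2_hat, tolerance = 1e-6)
})
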