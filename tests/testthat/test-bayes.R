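short_mcmc <- function(seed, n_iter = 2500, n_burnin = 800, thin = 1)
  mcmc_config(n_iter = n_iter, n_burnin = n_burnin, thin = thin, seed = seed)

test_that("recentring identifies draws without touching the likelihood", {
  set.seed(1)
  n <- 50; A <- 6; S <- 3
  draws <- list(theta = matrix(rnorm(n * A, 20, 5), n, A),
                mu = matrix(rnorm(n * S), n, S),
                delta = array(rnorm(n * A * S), c(n, A, S)))
  cell_before <- draws$theta[, 2] + draws$delta[, 2, 3]
  diffs_before <- draws$theta[, 1] - draws$theta[, 4]
  out <- recenter_draws(draws, anchor = 23)
  expect_equal(rowMeans(out$theta), rep(23, n), tolerance = 1e-9)
  expect_equal(out$theta[, 1] - out$theta[, 4], diffs_before,
               tolerance = 1e-12)
  expect_equal(out$theta[, 2] + out$delta[, 2, 3], cell_before,
               tolerance = 1e-12)
  # mu absorbs exactly what theta gives up
  expect_equal(rowMeans(draws$theta) + rowMeans(draws$mu),
               rowMeans(out$theta) + rowMeans(out$mu), tolerance = 1e-12)
})

test_that("DIC components satisfy their defining identities", {
  ff <- full_fit_rep1()
  dic <- ff$fit$dic
  expect_equal(dic$DIC, dic$Dbar + dic$pD, tolerance = 1e-9)
  expect_gt(dic$pD, 0)

  # degenerate posterior: all draws identical -> pD = 0, DIC = Dbar
  tab <- tiny_table()
  one <- list(theta = matrix(23, 2, 4),
              delta = array(0.3, c(2, 4, 3)))
  d0 <- compute_dic(one, tab)
  expect_equal(d0$pD, 0, tolerance = 1e-9)
  expect_equal(d0$DIC, d0$Dbar, tolerance = 1e-9)
  expect_error(compute_dic(list(theta = matrix(23, 1, 4),
                                delta = array(0, c(1, 4, 3))), tab),
               "at least 2")
})

test_that("bias means are recovered on a noiseless additive table", {
  # tau-truth 0 with tiny sampling error: posterior mu pins the offsets
  theta <- c(20, 22, 24, 26, 21, 25); mu <- c(-2, 0.5, 1.5)
  y <- outer(theta, rep(1, 3)) + outer(rep(1, 6), mu)
  tab <- estimate_table(paste0("a", 1:6), paste0("s", 1:3), y,
                        matrix(0.05, 6, 3))
  fit <- fit_model1(tab, anchor = mean(theta), mcmc = short_mcmc(2))
  s <- fit$summary
  mu_rows <- s[startsWith(s$parameter, "mu["), ]
  expect_true(all(abs(mu_rows$mean - mu) <
                    3 * pmax(mu_rows$mcse, 0.01) + 0.05))
  th_rows <- s[startsWith(s$parameter, "theta["), ]
  expect_lt(max(abs(th_rows$mean - theta)), 0.1)
})

test_that("marginal and hierarchical samplers agree on the same posterior", {
  gen <- simulate_dataset(sim_config(n_areas = 12, n_sources = 3, seed = 8))
  h <- fit_model1(gen$table, 23, mcmc = short_mcmc(8, 6000, 1500, 2))
  m <- fit_model1(gen$table, 23, mcmc = short_mcmc(9, 6000, 1500, 2),
                  marginal = TRUE)
  for (grp in c("theta[", "mu[", "tau[")) {
    sh <- h$summary[startsWith(h$summary$parameter, grp), ]
    sm <- m$summary[startsWith(m$summary$parameter, grp), ]
    tol <- 4 * sqrt(pmax(sh$mcse, 0.01)^2 + pmax(sm$mcse, 0.01)^2) + 0.05
    expect_true(all(abs(sh$mean - sm$mean) < tol),
                label = paste("agreement for", grp))
  }
})

test_that("identification variants behave as specified", {
  gen <- simulate_dataset(sim_config(n_areas = 16, n_sources = 4, seed = 55,
                                     mu = c(0, 1.5, -1, 2),
                                     tau = rep(1, 4)))
  # anchored-source: declared source has exactly zero mean bias
  va <- fit_model1_variant(gen$table, "anchored_source",
                           anchored_source = gen$table$sources[1],
                           mcmc = short_mcmc(10))
  s <- va$summary
  expect_equal(s$mean[s$parameter == paste0("mu[", gen$table$sources[1], "]")],
               0, tolerance = 1e-12)
  # after recentring both to a common mean, prevalences agree with model 1
  m1 <- fit_model1(gen$table, 23, mcmc = short_mcmc(11))
  va_theta <- colMeans(va$draws$theta)
  va_centered <- va_theta - mean(va_theta) + 23
  m1_theta <- colMeans(m1$draws$theta)
  sh <- m1$summary[startsWith(m1$summary$parameter, "theta["), ]
  expect_true(all(abs(va_centered - m1_theta) < 6 * pmax(sh$mcse, 0.02) + 0.1))

  # equal-tau on common-tau data recovers the shared value
  gen2 <- simulate_dataset(sim_config(n_areas = 40, n_sources = 5, seed = 56,
                                      tau = rep(1.2, 5),
                                      sample_size = rep(4000, 5)))
  ve <- fit_model1_variant(gen2$table, "equal_tau", 23,
                           mcmc = short_mcmc(12))
  tau_rows <- ve$summary[startsWith(ve$summary$parameter, "tau["), ]
  expect_true(all(abs(tau_rows$mean - tau_rows$mean[1]) < 1e-9))
  expect_lt(abs(tau_rows$mean[1] - 1.2), 3 * max(tau_rows$mcse) + 0.35)

  # exchangeable-tau runs at S = 2 and returns a finite sigma_tau
  gen3 <- simulate_dataset(sim_config(n_areas = 10, n_sources = 2, seed = 57))
  vx <- fit_model1_variant(gen3$table, "exchangeable_tau", 23,
                           mcmc = short_mcmc(13))
  st <- vx$summary[vx$summary$parameter == "sigma_tau", ]
  expect_true(is.finite(st$mean) && st$mean > 0)

  expect_error(fit_model1_variant(gen$table, "anchored_source",
                                  anchored_source = "nope"),
               "must name a source")
})

test_that("time-trend fit collapses to the static model when x is zero", {
  gen <- simulate_dataset(sim_config(n_areas = 12, n_sources = 4, seed = 60))
  tab <- gen$table
  tab$year <- rep(2005L, 4)
  expect_error(fit_model3(tab, 23), "unidentifiable")
  suppressWarnings(
    f3 <- fit_model3(tab, 23, mcmc = short_mcmc(60),
                     priors = prior_config(slope_sd_upper = 1),
                     allow_constant_year = TRUE))
  f1 <- fit_model1(tab, 23, mcmc = short_mcmc(61))
  a3 <- f3$summary[startsWith(f3$summary$parameter, "alpha["), ]
  t1 <- f1$summary[startsWith(f1$summary$parameter, "theta["), ]
  tol <- 5 * sqrt(pmax(a3$mcse, 0.02)^2 + pmax(t1$mcse, 0.02)^2) + 0.05
  expect_true(all(abs(a3$mean - t1$mean) < tol))
})

test_that("predictions extrapolate the fitted trends with growing width", {
  cfg <- sim_config(n_areas = 12, n_sources = 5, seed = 61,
                    source_years = c(2001L, 2002L, 2003L, 2004L, 2005L),
                    slope_mean = -0.2, slope_sd = 0.1)
  gen <- simulate_time_trend_dataset(cfg)
  f3 <- fit_model3(gen$table, 23, mcmc = short_mcmc(62))
  p05 <- predict_prevalence(f3, 2005)
  p06 <- predict_prevalence(f3, 2006)
  p09 <- predict_prevalence(f3, 2009)
  # 2005 prediction is the intercept summary itself
  alpha_mean <- colMeans(f3$draws$alpha)
  expect_equal(p05$mean[match(f3$table$areas, p05$area)],
               unname(alpha_mean), tolerance = 1e-9)
  # widths grow with extrapolation distance, for every area
  w06 <- (p06$q97.5 - p06$q2.5)[order(p06$area)]
  w09 <- (p09$q97.5 - p09$q2.5)[order(p09$area)]
  expect_true(all(w09 >= w06 - 1e-9))
  # ranks are a permutation with sensible bounds
  expect_equal(sort(round(rank(-p09$mean))), 1:12)
  expect_error(predict_prevalence(full_fit_rep1()$fit, 2009),
               "lacks slope")
})

test_that("the correlated-bias model agrees with Model 1 on independent data", {
  gen <- simulate_dataset(sim_config(n_areas = 20, n_sources = 3, seed = 90,
                                     tau = c(1, 1.5, 0.8),
                                     sample_size = rep(4000, 3)))
  f1 <- fit_model1(gen$table, 23, mcmc = short_mcmc(90, 6000, 1500, 2))
  f2 <- fit_model2(gen$table, 23,
                   mcmc = mcmc_config(n_iter = 16000, n_burnin = 4000,
                                      thin = 6, seed = 90))
  for (grp in c("theta[", "mu[")) {
    s1 <- f1$summary[startsWith(f1$summary$parameter, grp), ]
    s2 <- f2$summary[startsWith(f2$summary$parameter, grp), ]
    tol <- 5 * sqrt(pmax(s1$mcse, 0.02)^2 + pmax(s2$mcse, 0.02)^2) + 0.1
    expect_true(all(abs(s1$mean - s2$mean) < tol),
                label = paste("model 1 vs model 2 agreement for", grp))
  }
  # per-draw correlation matrices are valid: unit diagonal, PD
  rho <- f2$draws$rho
  expect_true(all(abs(rho[, 1, 1] - 1) < 1e-9))
  set.seed(91)
  for (k in sample(nrow(rho), 25)) {
    ev <- eigen(rho[k, , ], symmetric = TRUE, only.values = TRUE)$values
    expect_gt(min(ev), 0)
  }
})

test_that("a zero between-area slope SD is detected as such", {
  # slopes are measurable only when biases are small relative to the time
  # spread, so this degenerate-recovery design uses modest bias SDs and
  # precise sources
  cfg <- sim_config(seed = 820,
                    source_years = c(2001L, 2002L, 2003L, 2003L, 2004L,
                                     2005L, 2005L),
                    slope_mean = -0.08, slope_sd = 0,
                    tau = rep(0.5, 7), sample_size = rep(12000, 7))
  gen <- simulate_time_trend_dataset(cfg)
  f0 <- fit_model3(gen$table, 23, mcmc = mcmc_config(seed = 820))
  sb <- f0$summary[f0$summary$parameter == "sigma_beta", ]
  expect_lt(sb$q97.5, 3 * 0.14)
})

test_that("misstated standard errors are absorbed by the bias variance", {
  # source 1 truly noisy (sd 1.2) but claims sd 0.6; correcting the claim
  # should barely move the inferred marginal variance se^2 + tau^2
  set.seed(70)
  cfg <- sim_config(seed = 70, tau = c(1.5, runif(6, 0.8, 1.5)),
                    sample_size = c(1230, round(runif(6, 2000, 5000))))
  gen <- simulate_dataset(cfg)   # source-1 true sampling sd ~ 1.2
  tab_claim <- gen$table
  tab_claim$se[, 1] <- tab_claim$se[, 1] / 2        # overprecise claim
  f_claim <- fit_model1(tab_claim, 23, mcmc = short_mcmc(70))
  f_true <- fit_model1(gen$table, 23, mcmc = short_mcmc(71))
  marg <- function(f, tab) mean(tab$se[, 1]^2) +
    mean(f$draws$tau[, 1])^2
  m_claim <- marg(f_claim, tab_claim)
  m_true <- marg(f_true, gen$table)
  expect_lt(abs(m_claim - m_true) / m_true, 0.25)
})
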