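#' Prior configuration for the hierarchical bias models
#'
#' Vague-but-proper defaults: `mu_j ~ N(0, mu_prior_sd^2)` for the bias
#' means, `tau_j ~ Uniform(0, tau_upper)` for the bias SDs, and a flat
#' working prior on the area prevalences (identified afterwards by
#' recentring, see [recenter_draws()]).  Variant-specific entries cover the
#' half-normal exchangeable-tau variant, the scaled inverse-Wishart
#' covariance of the correlated-bias model, and the slope priors of the
#' time-trend model.
#'
#' @param mu_prior_sd normal prior SD for each bias mean (percentage points).
#' @param tau_upper upper bound of the uniform prior on each bias SD.
#' @param theta_bounds support used for area prevalences in the
#'   anchored-source variant (that variant has no regional anchor, so the
#'   prevalences get proper `Uniform(theta_bounds)` priors).
#' @param sigma_tau_upper upper bound of the uniform prior on the
#'   half-normal scale in the exchangeable-tau variant.
#' @param wishart_df Wishart degrees of freedom for the correlated-bias
#'   model; `NULL` means S + 1 (marginally near-uniform correlations).
#' @param wishart_scale_shape,wishart_scale_rate gamma hyperprior on the
#'   stochastic diagonal scales of the Wishart; the defaults imply a
#'   weakly-informative heavy-tailed marginal on each bias SD with median
#'   around 2 percentage points.
#' @param slope_prior_sd normal prior SD for the mean slope of the
#'   time-trend model.
#' @param slope_sd_upper upper bound of the uniform prior on the
#'   between-area slope SD.
#' @param anchor_se optional SE attached to the regional anchor itself
#'   (0 = anchor treated as exact).  A positive value propagates anchor
#'   uncertainty into every prevalence while leaving all between-area
#'   differences untouched.
#' @return A `prior_config` list.
#' @export
prior_config <- function(mu_prior_sd = 100, tau_upper = 100,
                         theta_bounds = c(0, 100),
                         sigma_tau_upper = 100,
                         wishart_df = NULL,
                         wishart_scale_shape = 0.5,
                         wishart_scale_rate = 0.04,
                         slope_prior_sd = 100, slope_sd_upper = 100,
                         anchor_se = 0) {
  stopifnot(mu_prior_sd > 0, tau_upper > 0, sigma_tau_upper > 0,
            slope_prior_sd > 0, slope_sd_upper > 0, anchor_se >= 0,
            theta_bounds[1] >= 0, theta_bounds[2] <= 100,
            theta_bounds[2] > theta_bounds[1])
  structure(list(
    mu_prior_sd = mu_prior_sd, tau_upper = tau_upper,
    theta_bounds = theta_bounds, sigma_tau_upper = sigma_tau_upper,
    wishart_df = wishart_df,
    wishart_scale_shape = wishart_scale_shape,
    wishart_scale_rate = wishart_scale_rate,
    slope_prior_sd = slope_prior_sd, slope_sd_upper = slope_sd_upper,
    anchor_se = anchor_se
  ), class = "prior_config")
}

#' MCMC configuration
#'
#' @param n_chains number of chains (1--3; R-hat needs at least 2).
#' @param n_iter total iterations per chain, including burn-in.
#' @param n_burnin burn-in iterations discarded per chain.
#' @param thin thinning interval for retained draws.
#' @param n_adapt JAGS adaptation iterations.
#' @param seed integer master seed; each chain gets a derived RNG seed.
#' @param rhat_threshold flag parameters whose potential scale reduction
#'   factor exceeds this.
#' @param mcse_fraction_threshold flag parameters whose Monte Carlo SE
#'   exceeds this fraction of the posterior SD.
#' @return An `mcmc_config` list.
#' @export
mcmc_config <- function(n_chains = 2, n_iter = 5000, n_burnin = 1500,
                        thin = 2, n_adapt = 500, seed = 1,
                        rhat_threshold = 1.05,
                        mcse_fraction_threshold = 0.03) {
  stopifnot(n_chains >= 1, n_chains <= 3, n_iter > n_burnin, thin >= 1)
  structure(list(
    n_chains = as.integer(n_chains), n_iter = as.integer(n_iter),
    n_burnin = as.integer(n_burnin), thin = as.integer(thin),
    n_adapt = as.integer(n_adapt), seed = as.integer(seed),
    rhat_threshold = rhat_threshold,
    mcse_fraction_threshold = mcse_fraction_threshold
  ), class = "mcmc_config")
}

chain_seed <- function(seed, chain)
  as.integer((as.numeric(seed) * 97 + chain * 131) %% 2147483647)

# run a JAGS model and return the coda mcmc.list
run_jags <- function(model_string, data, monitors, mcmc, inits = NULL) {
  make_inits <- function(chain) {
    ini <- list(.RNG.name = "base::Mersenne-Twister",
                .RNG.seed = chain_seed(mcmc$seed, chain))
    if (!is.null(inits)) ini <- c(ini, inits(chain))
    ini
  }
  jm <- rjags::jags.model(
    textConnection(model_string), data = data,
    n.chains = mcmc$n_chains, n.adapt = mcmc$n_adapt, quiet = TRUE,
    inits = lapply(seq_len(mcmc$n_chains), make_inits))
  stats::update(jm, mcmc$n_burnin, progress.bar = "none")
  rjags::coda.samples(jm, monitors, n.iter = mcmc$n_iter - mcmc$n_burnin,
                      thin = mcmc$thin, progress.bar = "none")
}

# stack an mcmc.list into a plain matrix plus chain ids
stack_chains <- function(samples) {
  mats <- lapply(samples, as.matrix)
  list(draws = do.call(rbind, mats),
       chain = rep(seq_along(mats), vapply(mats, nrow, integer(1))))
}

# columns of a vector-valued JAGS monitor, in index order
monitor_cols <- function(draws, name, n) {
  if (n == 1 && name %in% colnames(draws))
    return(draws[, name, drop = FALSE])
  draws[, sprintf("%s[%d]", name, seq_len(n)), drop = FALSE]
}

# n x A x S array for a matrix-valued JAGS monitor
monitor_array <- function(draws, name, A, S) {
  out <- array(NA_real_, c(nrow(draws), A, S))
  for (j in seq_len(S))
    out[, , j] <- draws[, sprintf("%s[%d,%d]", name, seq_len(A), j)]
  out
}

summarize_param <- function(x, chain, rhat_ok = TRUE) {
  m <- mean(x); s <- stats::sd(x)
  q <- stats::quantile(x, c(0.025, 0.975), names = FALSE)
  ess <- tryCatch(
    as.numeric(coda::effectiveSize(coda::mcmc(x))), error = function(e) NA)
  rhat <- NA_real_
  if (rhat_ok && length(unique(chain)) >= 2 && s > 0) {
    ml <- coda::mcmc.list(lapply(split(x, chain), coda::mcmc))
    rhat <- tryCatch(coda::gelman.diag(ml, autoburnin = FALSE)$psrf[1],
                     error = function(e) NA_real_)
  }
  c(mean = m, sd = s, q2.5 = q[1], q97.5 = q[2],
    ess = ess, mcse = if (is.na(ess) || ess <= 0) NA_real_ else s / sqrt(ess),
    rhat = rhat)
}

# summary table over named draw matrices (one column per scalar parameter)
build_summary <- function(groups, chain) {
  rows <- list()
  for (g in names(groups)) {
    m <- groups[[g]]
    if (is.null(m)) next
    for (k in seq_len(ncol(m))) {
      nm <- colnames(m)[k]
      if (is.null(nm) || nm == "") nm <- sprintf("%s[%d]", g, k)
      rows[[length(rows) + 1L]] <-
        data.frame(parameter = nm, t(summarize_param(m[, k], chain)))
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

convergence_report <- function(summary, mcmc) {
  bad_rhat <- !is.na(summary$rhat) & summary$rhat > mcmc$rhat_threshold
  bad_mcse <- !is.na(summary$mcse) & summary$sd > 0 &
    summary$mcse > mcmc$mcse_fraction_threshold * summary$sd
  list(
    converged = !any(bad_rhat),
    max_rhat = suppressWarnings(max(summary$rhat, na.rm = TRUE)),
    flagged_rhat = summary$parameter[bad_rhat],
    flagged_mcse = summary$parameter[bad_mcse],
    rhat_threshold = mcmc$rhat_threshold,
    mcse_fraction_threshold = mcmc$mcse_fraction_threshold
  )
}

#' Log joint density of the independent-bias hierarchical model
#'
#' The additive-bias model: for every present cell,
#' `y_ij ~ N(theta_i + delta_ij, se_ij^2)` with `delta_ij ~ N(mu_j, tau_j^2)`,
#' bias means `mu_j ~ N(0, mu_prior_sd^2)`, bias SDs
#' `tau_j ~ Uniform(0, tau_upper)` and a flat working prior on the
#' prevalences.  A `tau` outside its prior support yields `-Inf` rather
#' than an error, so the function can serve as a target density for any
#' sampler.
#'
#' @param state list with numeric elements `theta` (length A), `mu`, `tau`
#'   (length S) and `delta` (A x S matrix of biases, mean included).
#' @param table an [estimate_table()].
#' @param priors a [prior_config()].
#' @return A single finite number for interior states; `-Inf` outside the
#'   prior support.
#' @export
log_joint_model1 <- function(state, table, priors = prior_config()) {
  A <- length(table$areas); S <- length(table$sources)
  stopifnot(length(state$theta) == A, length(state$mu) == S,
            length(state$tau) == S, all(dim(state$delta) == c(A, S)))
  if (any(state$tau <= 0) || any(state$tau >= priors$tau_upper))
    return(-Inf)
  lp <- 0
  idx <- which(table$present, arr.ind = TRUE)
  for (r in seq_len(nrow(idx))) {
    i <- idx[r, 1]; j <- idx[r, 2]
    lp <- lp +
      stats::dnorm(table$y[i, j], state$theta[i] + state$delta[i, j],
                   table$se[i, j], log = TRUE) +
      stats::dnorm(state$delta[i, j], state$mu[j], state$tau[j], log = TRUE)
  }
  lp + sum(stats::dnorm(state$mu, 0, priors$mu_prior_sd, log = TRUE)) +
    S * log(1 / priors$tau_upper)
}

#' Identify posterior draws by recentring onto the anchor
#'
#' The additive model is invariant to adding a constant to every prevalence
#' and subtracting it from every bias, so the raw draws are non-identified.
#' Per draw, the shift `phi = mean(theta) - anchor` is subtracted from every
#' `theta_i` and added to every `mu_j` and every `delta_ij`, leaving all
#' fitted cell means `theta_i + delta_ij` (and hence the likelihood) exactly
#' unchanged while pinning `mean(theta)` to the anchor.
#'
#' @param draws list with draw matrices `theta` (n x A) and `mu` (n x S),
#'   optionally `delta` (n x A x S array).
#' @param anchor regional mean prevalence in percent.
#' @param anchor_draws optional length-n vector of per-draw anchor values
#'   (used when the anchor itself carries uncertainty).
#' @return The draws list with identified `theta`, `mu`, `delta`.
#' @export
recenter_draws <- function(draws, anchor, anchor_draws = NULL) {
  a <- if (is.null(anchor_draws)) anchor else anchor_draws
  phi <- rowMeans(draws$theta) - a
  draws$theta <- draws$theta - phi
  draws$mu <- draws$mu + phi
  if (!is.null(draws$delta)) {
    for (j in seq_len(dim(draws$delta)[3]))
      draws$delta[, , j] <- draws$delta[, , j] + phi
  }
  draws
}

new_bias_posterior <- function(model, draws, chain, anchor, table, summary,
                               mcmc, extra = list()) {
  dic <- compute_dic(draws, table)
  structure(c(list(
    model = model, draws = draws, chain = chain, anchor = anchor,
    table = table, summary = summary, dic = dic,
    convergence = convergence_report(summary, mcmc), mcmc = mcmc
  ), extra), class = "bias_posterior")
}

#' @export
print.bias_posterior <- function(x, ...) {
  cat(sprintf("<bias_posterior: %s> %d areas x %d sources, anchor %s\n",
              x$model, length(x$table$areas), length(x$table$sources),
              if (is.null(x$anchor)) "none" else format(x$anchor)))
  cat(sprintf("  %d retained draws, %d chain(s)\n",
              nrow(x$draws$theta), length(unique(x$chain))))
  cat(sprintf("  DIC %.1f (Dbar %.1f, pD %.1f)\n",
              x$dic$DIC, x$dic$Dbar, x$dic$pD))
  if (!x$convergence$converged)
    cat(sprintf("  WARNING: %d parameter(s) with R-hat > %.2f (max %.3f)\n",
                length(x$convergence$flagged_rhat),
                x$convergence$rhat_threshold, x$convergence$max_rhat))
  invisible(x)
}

# shared data preparation: JAGS chokes on NA se, so absent cells get a
# placeholder; their y stays NA and is imputed from the prior predictive,
# contributing no information
jags_data_common <- function(table) {
  y <- table$y
  y[!table$present] <- NA
  se <- table$se
  se[!table$present] <- 1
  list(y = y, se = se, A = nrow(y), S = ncol(y))
}

model1_string <- function(tau_prior = c("uniform", "halfnormal", "equal"),
                          anchored_source = FALSE) {
  tau_prior <- match.arg(tau_prior)
  tau_block <- switch(tau_prior,
    uniform = "    tau[j] ~ dunif(0, tau_upper)",
    halfnormal = "    tau[j] ~ dnorm(0, 1/(sigma_tau^2)) T(0,)",
    equal = "    tau[j] <- tau_common")
  extra <- switch(tau_prior,
    uniform = "",
    halfnormal = "  sigma_tau ~ dunif(0, sigma_tau_upper)\n",
    equal = "  tau_common ~ dunif(0, tau_upper)\n")
  mu_block <- if (anchored_source)
    "    mu_free[j] ~ dnorm(0, 1/(mu_prior_sd^2))\n    mu[j] <- mu_free[j] * (1 - equals(j, jstar))"
  else
    "    mu[j] ~ dnorm(0, 1/(mu_prior_sd^2))"
  theta_block <- if (anchored_source)
    "    theta[i] ~ dunif(theta_lo, theta_hi)"
  else
    "    theta[i] ~ dnorm(theta_center, 1.0E-4)"
  paste0(
"model {
  for (i in 1:A) {
    for (j in 1:S) {
      y[i,j] ~ dnorm(eta[i,j], 1/(se[i,j]^2))
      eta[i,j] ~ dnorm(theta[i] + mu[j], 1/(tau[j]^2))
    }
", theta_block, "
  }
  for (j in 1:S) {
", mu_block, "
", tau_block, "
  }
", extra, "}")
}

#' Fit the independent-bias hierarchical model (Model 1)
#'
#' Fits `y_ij ~ N(theta_i + delta_ij, se_ij^2)`,
#' `delta_ij ~ N(mu_j, tau_j^2)` by MCMC (JAGS), then identifies each draw
#' by recentring so the mean prevalence equals the external regional
#' `anchor` ([recenter_draws()]).  Non-convergence is flagged in the result,
#' never silently ignored.
#'
#' @param table an [estimate_table()].
#' @param anchor regional mean prevalence in percent, from external
#'   information.
#' @param priors a [prior_config()]; set `anchor_se > 0` there to propagate
#'   uncertainty in the anchor itself.
#' @param mcmc an [mcmc_config()].
#' @param marginal if `TRUE`, sample the marginal form
#'   `y_ij ~ N(theta_i + mu_j, se_ij^2 + tau_j^2)` (biases integrated out)
#'   instead of the hierarchical form; posteriors for `theta`, `mu`, `tau`
#'   agree between the two parameterizations.  The marginal fit carries no
#'   bias draws, so its DIC focus differs.
#' @return A `bias_posterior` with identified draws (`theta`, `mu`, `tau`,
#'   `delta`), a summary table (mean, sd, 2.5%, 97.5%, ESS, MCSE, R-hat),
#'   DIC components and a convergence report.
#' @export
fit_model1 <- function(table, anchor = 23, priors = prior_config(),
                       mcmc = mcmc_config(), marginal = FALSE) {
  assert_valid_table(table)
  stopifnot(anchor > 0, anchor < 100)
  dat <- jags_data_common(table)
  A <- dat$A; S <- dat$S

  if (marginal) {
    ms <- "model {
  for (i in 1:A) {
    for (j in 1:S) {
      y[i,j] ~ dnorm(theta[i] + mu[j], 1/(se[i,j]^2 + tau[j]^2))
    }
    theta[i] ~ dnorm(theta_center, 1.0E-4)
  }
  for (j in 1:S) {
    mu[j] ~ dnorm(0, 1/(mu_prior_sd^2))
    tau[j] ~ dunif(0, tau_upper)
  }
}"
    samples <- run_jags(ms, c(dat, list(
      theta_center = anchor, mu_prior_sd = priors$mu_prior_sd,
      tau_upper = priors$tau_upper)), c("theta", "mu", "tau"), mcmc)
  } else {
    ms <- model1_string("uniform")
    samples <- run_jags(ms, c(dat, list(
      theta_center = anchor, mu_prior_sd = priors$mu_prior_sd,
      tau_upper = priors$tau_upper)),
      c("theta", "mu", "tau", "eta"), mcmc,
      inits = function(chain) list(eta = ifelse(is.na(dat$y), anchor, dat$y)))
  }

  st <- stack_chains(samples)
  draws <- list(theta = monitor_cols(st$draws, "theta", A),
                mu = monitor_cols(st$draws, "mu", S),
                tau = monitor_cols(st$draws, "tau", S))
  if (!marginal) {
    eta <- monitor_array(st$draws, "eta", A, S)
    draws$delta <- eta
    for (j in seq_len(S)) draws$delta[, , j] <- eta[, , j] - draws$theta
  }

  anchor_draws <- NULL
  if (priors$anchor_se > 0) {
    set.seed(chain_seed(mcmc$seed, 999L))
    anchor_draws <- stats::rnorm(nrow(draws$theta), anchor, priors$anchor_se)
  }
  draws <- recenter_draws(draws, anchor, anchor_draws)

  groups <- list(theta = name_cols(draws$theta, "theta", table$areas),
                 mu = name_cols(draws$mu, "mu", table$sources),
                 tau = name_cols(draws$tau, "tau", table$sources))
  summary <- build_summary(groups, st$chain)
  new_bias_posterior(if (marginal) "model1-marginal" else "model1",
                     draws, st$chain, anchor, table, summary, mcmc)
}

name_cols <- function(m, prefix, labels) {
  colnames(m) <- paste0(prefix, "[", labels, "]")
  m
}

#' Fit an alternative identification or bias-variance variant of Model 1
#'
#' Three variants of the independent-bias model:
#' * `"anchored_source"`: no regional anchor; instead one named source is
#'   declared unbiased on average (`mu_{j*} = 0`) and the prevalences get
#'   proper `Uniform(theta_bounds)` priors.
#' * `"exchangeable_tau"`: the bias SDs are pooled through a half-normal,
#'   `tau_j ~ HN(sigma_tau^2)`, `sigma_tau ~ Uniform(0, sigma_tau_upper)`.
#' * `"equal_tau"`: a single shared bias SD for all sources.
#'
#' @param table an [estimate_table()].
#' @param variant one of `"anchored_source"`, `"exchangeable_tau"`,
#'   `"equal_tau"`.
#' @param anchor regional anchor (ignored by `"anchored_source"`).
#' @param anchored_source source label fixed to zero mean bias (required
#'   for the `"anchored_source"` variant).
#' @param priors,mcmc see [fit_model1()].
#' @return A `bias_posterior`; the exchangeable variant carries `sigma_tau`
#'   draws, the equal-tau variant a common `tau`.
#' @export
fit_model1_variant <- function(table,
                               variant = c("anchored_source",
                                           "exchangeable_tau", "equal_tau"),
                               anchor = 23, anchored_source = NULL,
                               priors = prior_config(),
                               mcmc = mcmc_config()) {
  variant <- match.arg(variant)
  assert_valid_table(table)
  dat <- jags_data_common(table)
  A <- dat$A; S <- dat$S
  base <- list(mu_prior_sd = priors$mu_prior_sd,
               tau_upper = priors$tau_upper)

  if (variant == "anchored_source") {
    if (is.null(anchored_source) || !(anchored_source %in% table$sources))
      stop("anchored_source must name a source in the table")
    jstar <- match(anchored_source, table$sources)
    ms <- model1_string("uniform", anchored_source = TRUE)
    data <- c(dat, base, list(jstar = jstar,
                              theta_lo = priors$theta_bounds[1],
                              theta_hi = priors$theta_bounds[2]))
    monitors <- c("theta", "mu", "tau", "eta")
  } else if (variant == "exchangeable_tau") {
    ms <- model1_string("halfnormal")
    data <- c(dat, base[1], list(theta_center = anchor,
                                 sigma_tau_upper = priors$sigma_tau_upper))
    monitors <- c("theta", "mu", "tau", "eta", "sigma_tau")
  } else {
    ms <- model1_string("equal")
    data <- c(dat, base, list(theta_center = anchor))
    monitors <- c("theta", "mu", "tau", "eta")
  }

  samples <- run_jags(ms, data, monitors, mcmc,
                      inits = function(chain)
                        list(eta = ifelse(is.na(dat$y),
                                          mean(dat$y, na.rm = TRUE), dat$y)))
  st <- stack_chains(samples)
  draws <- list(theta = monitor_cols(st$draws, "theta", A),
                mu = monitor_cols(st$draws, "mu", S),
                tau = monitor_cols(st$draws, "tau", S))
  eta <- monitor_array(st$draws, "eta", A, S)
  draws$delta <- eta
  for (j in seq_len(S)) draws$delta[, , j] <- eta[, , j] - draws$theta
  if (variant == "exchangeable_tau")
    draws$sigma_tau <- monitor_cols(st$draws, "sigma_tau", 1)

  if (variant != "anchored_source")
    draws <- recenter_draws(draws, anchor)

  groups <- list(theta = name_cols(draws$theta, "theta", table$areas),
                 mu = name_cols(draws$mu, "mu", table$sources),
                 tau = name_cols(draws$tau, "tau", table$sources))
  if (!is.null(draws$sigma_tau))
    groups$sigma_tau <- draws$sigma_tau
  summary <- build_summary(groups, st$chain)
  new_bias_posterior(paste0("model1-", variant), draws, st$chain,
                     if (variant == "anchored_source") NULL else anchor,
                     table, summary, mcmc,
                     extra = list(anchored_source = anchored_source))
}

#' Fit the correlated-bias model (Model 2)
#'
#' Generalizes Model 1 by making each area's bias vector multivariate:
#' `delta_i. ~ MVN(mu, Sigma)`.  The covariance gets a scaled
#' inverse-Wishart prior in which the scales are separated from the
#' correlations: the precision is Wishart with `wishart_df` degrees of
#' freedom and a *stochastic diagonal* scale matrix whose entries carry
#' gamma hyperpriors.  Every full conditional is then conjugate, which is
#' what makes the correlation block mix well.  Identification is the same
#' anchor recentring as Model 1.
#'
#' @inheritParams fit_model1
#' @return A `bias_posterior` additionally carrying draw arrays `Sigma`
#'   and `rho` (n x S x S) for the bias covariance and correlation
#'   matrices.
#' @export
fit_model2 <- function(table, anchor = 23, priors = prior_config(),
                       mcmc = mcmc_config(n_iter = 14000, n_burnin = 3000,
                                          thin = 6)) {
  assert_valid_table(table)
  dat <- jags_data_common(table)
  A <- dat$A; S <- dat$S
  if (S < 2) stop("the correlated-bias model needs at least 2 sources")
  df <- if (is.null(priors$wishart_df)) S + 1 else priors$wishart_df

  ms <- "model {
  for (i in 1:A) {
    for (j in 1:S) {
      y[i,j] ~ dnorm(eta[i,j], 1/(se[i,j]^2))
      m[i,j] <- theta[i] + mu[j]
    }
    eta[i,1:S] ~ dmnorm(m[i,1:S], Omega[1:S,1:S])
    theta[i] ~ dnorm(theta_center, 1.0E-4)
  }
  Omega ~ dwish(R[1:S,1:S], df)
  Sigma <- inverse(Omega)
  for (j in 1:S) {
    mu[j] ~ dnorm(0, 1/(mu_prior_sd^2))
    lam[j] ~ dgamma(scale_shape, scale_rate)
    for (k in 1:S) { R[j,k] <- equals(j,k) * lam[j] }
    tau[j] <- sqrt(Sigma[j,j])
  }
  for (j in 1:S) { for (k in 1:S) {
    rho[j,k] <- Sigma[j,k] / sqrt(Sigma[j,j] * Sigma[k,k])
  }}
}"
  samples <- run_jags(ms, c(dat, list(
    theta_center = anchor, mu_prior_sd = priors$mu_prior_sd, df = df,
    scale_shape = priors$wishart_scale_shape,
    scale_rate = priors$wishart_scale_rate)),
    c("theta", "mu", "tau", "eta", "Sigma", "rho"), mcmc,
    inits = function(chain)
      list(eta = ifelse(is.na(dat$y), anchor, dat$y)))

  st <- stack_chains(samples)
  draws <- list(theta = monitor_cols(st$draws, "theta", A),
                mu = monitor_cols(st$draws, "mu", S),
                tau = monitor_cols(st$draws, "tau", S))
  eta <- monitor_array(st$draws, "eta", A, S)
  draws$delta <- eta
  for (j in seq_len(S)) draws$delta[, , j] <- eta[, , j] - draws$theta
  draws$Sigma <- monitor_array(st$draws, "Sigma", S, S)
  draws$rho <- monitor_array(st$draws, "rho", S, S)
  draws <- recenter_draws(draws, anchor)

  rho_cols <- NULL
  pair_names <- c()
  if (S >= 2) {
    pairs <- utils::combn(S, 2)
    rho_cols <- matrix(NA_real_, nrow(st$draws), ncol(pairs))
    for (p in seq_len(ncol(pairs))) {
      rho_cols[, p] <- draws$rho[, pairs[1, p], pairs[2, p]]
      pair_names[p] <- sprintf("rho[%s,%s]", table$sources[pairs[1, p]],
                               table$sources[pairs[2, p]])
    }
    colnames(rho_cols) <- pair_names
  }
  groups <- list(theta = name_cols(draws$theta, "theta", table$areas),
                 mu = name_cols(draws$mu, "mu", table$sources),
                 tau = name_cols(draws$tau, "tau", table$sources),
                 rho = rho_cols)
  summary <- build_summary(groups, st$chain)
  new_bias_posterior("model2", draws, st$chain, anchor, table, summary, mcmc)
}

#' Fit the linear time-trend model (Model 3)
#'
#' Each area gets an intercept `alpha_i` (its prevalence at 2005, the
#' reference year) and a random slope `beta_i ~ N(mu_beta, sigma_beta^2)` on
#' `x_j = 2005 - year_j`, so
#' `y_ij ~ N(alpha_i + beta_i x_j + delta_ij, se_ij^2)` with the same
#' independent-bias structure as Model 1.  The anchor constraint applies to
#' the mean of the `alpha_i` (the regional 2005 level).  Note that with this
#' time coding a *decline* over calendar years corresponds to a *positive*
#' slope on `x`; summaries therefore also report the calendar-year slope
#' `-beta`.
#'
#' Because the time covariate is constant within a source, the model has a
#' second non-identified direction besides the overall level: adding `c` to
#' every slope while subtracting `c * x_j` from every bias mean leaves the
#' likelihood unchanged, so the mean slope is confounded with a
#' linear-in-time pattern in the bias means.  Each draw is identified by
#' attributing any such linear component of the `mu_j` to the regional
#' trend (the least-squares slope of `mu_j` on `x_j` is moved into
#' `mu_beta` and the `beta_i`), mirroring the level recentring.
#'
#' @inheritParams fit_model1
#' @param allow_constant_year permit fitting when every source shares one
#'   year.  The slope is then likelihood-unidentified (its posterior is the
#'   prior) and by default such tables are rejected; allowing them is only
#'   useful to verify that the trend model collapses to the independent-bias
#'   model when the time covariate vanishes.
#' @return A `bias_posterior` with draws `alpha` (alias `theta`), `beta`,
#'   `mu_beta`, `sigma_beta` in addition to the Model-1 components.
#' @export
fit_model3 <- function(table, anchor = 23, priors = prior_config(),
                       mcmc = mcmc_config(), allow_constant_year = FALSE) {
  assert_valid_table(table)
  if (is.null(table$year) || any(is.na(table$year)))
    stop("every source needs a year for the time-trend model")
  if (length(unique(table$year)) < 2) {
    if (!allow_constant_year)
      stop("all sources share one year: the slope is unidentifiable")
    warning("all sources share one year: slope draws reflect the prior only")
  }
  dat <- jags_data_common(table)
  A <- dat$A; S <- dat$S
  x <- 2005 - table$year

  ms <- "model {
  for (i in 1:A) {
    for (j in 1:S) {
      y[i,j] ~ dnorm(eta[i,j], 1/(se[i,j]^2))
      eta[i,j] ~ dnorm(alpha[i] + beta[i] * x[j] + mu[j], 1/(tau[j]^2))
    }
    alpha[i] ~ dnorm(theta_center, 1.0E-4)
    beta[i] ~ dnorm(mu_beta, 1/(sigma_beta^2))
  }
  mu_beta ~ dnorm(0, 1/(slope_prior_sd^2))
  sigma_beta ~ dunif(0, slope_sd_upper)
  for (j in 1:S) {
    mu[j] ~ dnorm(0, 1/(mu_prior_sd^2))
    tau[j] ~ dunif(0, tau_upper)
  }
}"
  samples <- run_jags(ms, c(dat, list(
    x = x, theta_center = anchor, mu_prior_sd = priors$mu_prior_sd,
    tau_upper = priors$tau_upper, slope_prior_sd = priors$slope_prior_sd,
    slope_sd_upper = priors$slope_sd_upper)),
    c("alpha", "beta", "mu_beta", "sigma_beta", "mu", "tau", "eta"), mcmc,
    inits = function(chain)
      list(eta = ifelse(is.na(dat$y), anchor, dat$y)))

  st <- stack_chains(samples)
  draws <- list(theta = monitor_cols(st$draws, "alpha", A),
                mu = monitor_cols(st$draws, "mu", S),
                tau = monitor_cols(st$draws, "tau", S),
                beta = monitor_cols(st$draws, "beta", A),
                mu_beta = monitor_cols(st$draws, "mu_beta", 1),
                sigma_beta = monitor_cols(st$draws, "sigma_beta", 1))
  eta <- monitor_array(st$draws, "eta", A, S)
  draws$delta <- eta
  for (j in seq_len(S))
    draws$delta[, , j] <- eta[, , j] - draws$theta - draws$beta * x[j]
  draws <- recenter_draws(draws, anchor)
  # second identification: no linear-in-x component may remain in the bias
  # means; move it into the slopes (likelihood-invariant shear)
  if (stats::var(x) > 0) {
    xc <- x - mean(x)
    cshift <- as.vector(draws$mu %*% xc) / sum(xc^2)
    draws$mu <- draws$mu - outer(cshift, x)
    draws$beta <- draws$beta + cshift
    draws$mu_beta <- draws$mu_beta + cshift
    for (j in seq_len(S)) draws$delta[, , j] <- draws$delta[, , j] -
      cshift * x[j]
  }
  draws$alpha <- draws$theta
  draws$x <- x

  groups <- list(alpha = name_cols(draws$alpha, "alpha", table$areas),
                 beta = name_cols(draws$beta, "beta", table$areas),
                 mu = name_cols(draws$mu, "mu", table$sources),
                 tau = name_cols(draws$tau, "tau", table$sources),
                 mu_beta = draws$mu_beta, sigma_beta = draws$sigma_beta)
  summary <- build_summary(groups, st$chain)
  new_bias_posterior("model3", draws, st$chain, anchor, table, summary, mcmc)
}

#' Predict area prevalences for a calendar year from a Model-3 fit
#'
#' Per retained draw computes `alpha_i + beta_i * (2005 - year)` and
#' summarizes the predictive distribution for each area, including the
#' distribution of each area's rank (1 = highest predicted prevalence), so
#' the result can be read as a league table with uncertainty.
#'
#' @param posterior a `bias_posterior` from [fit_model3()].
#' @param year calendar year to predict for.
#' @return A data frame sorted by predictive mean (highest first) with
#'   columns `area`, `mean`, `sd`, `q2.5`, `q97.5`, `rank_mean`,
#'   `rank_q2.5`, `rank_q97.5`.
#' @export
predict_prevalence <- function(posterior, year) {
  stopifnot(inherits(posterior, "bias_posterior"))
  if (is.null(posterior$draws$beta))
    stop("posterior lacks slope draws: fit the time-trend model first")
  x <- 2005 - year
  pred <- posterior$draws$alpha + posterior$draws$beta * x
  rk <- t(apply(-pred, 1, rank, ties.method = "average"))
  out <- data.frame(
    area = posterior$table$areas,
    mean = colMeans(pred),
    sd = apply(pred, 2, stats::sd),
    q2.5 = apply(pred, 2, stats::quantile, 0.025),
    q97.5 = apply(pred, 2, stats::quantile, 0.975),
    rank_mean = colMeans(rk),
    rank_q2.5 = apply(rk, 2, stats::quantile, 0.025),
    rank_q97.5 = apply(rk, 2, stats::quantile, 0.975)
  )
  out[order(-out$mean), ]
}

#' Deviance information criterion at the fitted-cell-mean focus
#'
#' The deviance of a draw is `-2 * sum(log N(y_ij | m_ij, se_ij^2))` over
#' present cells, where `m_ij` is the draw's fitted cell mean
#' (`theta_i + delta_ij`, plus the trend term when present).  `Dbar` is the
#' posterior mean deviance, `pD = Dbar - D(posterior mean of m)` the
#' effective number of parameters, and `DIC = Dbar + pD`.  DICs are
#' comparable only between fits sharing this focus.
#'
#' @param draws a `bias_posterior`, or a draws list with elements `theta`
#'   and `delta` (plus `beta`, `x` for trend fits).
#' @param table the [estimate_table()] the model was fitted to.
#' @return list with `Dbar`, `pD`, `DIC`.
#' @export
compute_dic <- function(draws, table) {
  if (inherits(draws, "bias_posterior")) draws <- draws$draws
  if (is.null(draws$delta)) return(list(Dbar = NA, pD = NA, DIC = NA))
  n <- nrow(draws$theta)
  if (n < 2) stop("need at least 2 retained draws for DIC")
  A <- ncol(draws$theta); S <- dim(draws$delta)[3]
  pres <- table$present
  dev <- numeric(n)
  mhat <- matrix(0, A, S)
  for (j in seq_len(S)) {
    m_j <- draws$theta + draws$delta[, , j]
    if (!is.null(draws$beta)) m_j <- m_j + draws$beta * draws$x[j]
    mhat[, j] <- colMeans(m_j)
    pj <- which(pres[, j])
    if (length(pj)) {
      ym <- matrix(table$y[pj, j], n, length(pj), byrow = TRUE)
      sem <- matrix(table$se[pj, j], n, length(pj), byrow = TRUE)
      dev <- dev - 2 * rowSums(stats::dnorm(ym, m_j[, pj, drop = FALSE],
                                            sem, log = TRUE))
    }
  }
  Dbar <- mean(dev)
  Dhat <- -2 * sum(stats::dnorm(table$y[pres], mhat[pres], table$se[pres],
                                log = TRUE))
  pD <- Dbar - Dhat
  list(Dbar = Dbar, pD = pD, DIC = Dbar + pD)
}
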