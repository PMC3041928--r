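#' Simulation configuration for multi-source prevalence data
#'
#' Describes the generating process the hierarchical models assume: true area
#' prevalences centred on a regional anchor, per-source additive biases with
#' source-specific means and standard deviations (optionally correlated
#' across sources within an area), and known per-cell sampling error.
#'
#' Defaults emulate a regional smoking-prevalence setting: 48 areas, 7
#' sources, anchor 23%, between-area SD 3 percentage points, bias means
#' drawn uniformly on [-3, 3], bias SDs uniformly on [0.5, 2], and per-cell
#' sampling SDs derived from per-source nominal sample sizes via
#' `sqrt(p (100 - p) / n)` at `p = anchor` (sources with larger samples are
#' more precise).  Sample sizes default to uniform draws on [1500, 5000].
#' Set `se_range` to draw per-cell SDs uniformly instead.
#'
#' @param n_areas,n_sources grid dimensions A and S.
#' @param anchor regional mean prevalence in percent; the generated true
#'   prevalences average to it exactly.
#' @param theta_sd between-area SD of true prevalences (percentage points).
#' @param mu length-S vector of true bias means, or `NULL` to draw them
#'   uniformly on `mu_range`.
#' @param tau length-S vector of true bias SDs (>= 0), or `NULL` to draw
#'   them uniformly on `tau_range`.
#' @param mu_range,tau_range ranges used when `mu` / `tau` are `NULL`.
#' @param correlation S x S correlation matrix for within-area biases
#'   (identity = independent biases, the Model-1 structure).
#' @param sample_size length-S nominal sample sizes, or `NULL` to draw them
#'   uniformly on `sample_size_range`.  Ignored when `se_range` is given.
#' @param sample_size_range range for drawn sample sizes.
#' @param se_range optional `(low, high)`: draw per-cell sampling SDs
#'   uniformly instead of deriving them from sample sizes.
#' @param source_years optional length-S mid-survey calendar years (needed
#'   for time-trend generation).
#' @param slope_mean,slope_sd mean and SD of the area-specific slopes on
#'   `x = 2005 - year` used by [simulate_time_trend_dataset()].
#' @param seed integer seed; all draws derive from it through fixed
#'   sub-streams, so area-level draws do not change when sources are added.
#' @return A `sim_config` list.
#' @export
sim_config <- function(n_areas = 48, n_sources = 7, anchor = 23,
                       theta_sd = 3, mu = NULL, tau = NULL,
                       mu_range = c(-3, 3), tau_range = c(0.5, 2),
                       correlation = NULL,
                       sample_size = NULL, sample_size_range = c(1500, 5000),
                       se_range = NULL, source_years = NULL,
                       slope_mean = 0, slope_sd = 0, seed = 1) {
  if (anchor <= 0 || anchor >= 100) stop("anchor must be in (0, 100)")
  if (!is.null(tau) && any(tau < 0)) stop("tau entries must be >= 0")
  if (!is.null(correlation)) {
    correlation <- as.matrix(correlation)
    if (!isTRUE(all.equal(correlation, t(correlation))) ||
        any(abs(diag(correlation) - 1) > 1e-12))
      stop("correlation must be symmetric with unit diagonal")
    ev <- eigen(correlation, symmetric = TRUE, only.values = TRUE)$values
    if (min(ev) < -1e-8)
      stop("correlation matrix is not positive semi-definite")
  }
  structure(list(
    n_areas = n_areas, n_sources = n_sources, anchor = anchor,
    theta_sd = theta_sd, mu = mu, tau = tau,
    mu_range = mu_range, tau_range = tau_range,
    correlation = correlation,
    sample_size = sample_size, sample_size_range = sample_size_range,
    se_range = se_range, source_years = source_years,
    slope_mean = slope_mean, slope_sd = slope_sd,
    seed = as.integer(seed)
  ), class = "sim_config")
}

# evaluate code under a derived seed without disturbing the caller's RNG
with_substream <- function(seed, stream, code) {
  if (exists(".Random.seed", envir = globalenv())) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()))
  }
  set.seed(as.integer((as.numeric(seed) * 1009 + stream) %% 2147483647))
  code
}

# symmetric PSD square root; tolerates exactly singular matrices (rho = 1)
psd_sqrt <- function(M) {
  e <- eigen(M, symmetric = TRUE)
  if (min(e$values) < -1e-8 * max(abs(e$values), 1))
    stop("matrix is not positive semi-definite")
  e$vectors %*% (sqrt(pmax(e$values, 0)) * t(e$vectors))
}

#' Draw correlated per-area bias vectors
#'
#' Each area's length-S bias vector is an independent multivariate normal
#' draw with mean `mu` and covariance `diag(tau) %*% correlation %*%
#' diag(tau)`.  Degenerate cases (a zero `tau`, a correlation of exactly 1)
#' are supported through a PSD square root.
#'
#' @param mu,tau length-S bias means and SDs.
#' @param correlation S x S correlation matrix.
#' @param n_areas number of rows to draw.
#' @param seed integer seed.
#' @return n_areas x S matrix of biases.
#' @export
simulate_correlated_biases <- function(mu, tau, correlation, n_areas, seed) {
  S <- length(mu)
  stopifnot(length(tau) == S, all(dim(correlation) == c(S, S)))
  if (any(tau < 0)) stop("tau entries must be >= 0")
  Sigma <- diag(tau, S) %*% correlation %*% diag(tau, S)
  root <- psd_sqrt((Sigma + t(Sigma)) / 2)
  Z <- with_substream(seed, 3L,
                      matrix(stats::rnorm(n_areas * S), n_areas, S))
  sweep(Z %*% root, 2, mu, "+")
}

# resolve NULL fields of a config into concrete generating values
resolve_config <- function(config) {
  S <- config$n_sources
  with_substream(config$seed, 2L, {
    if (is.null(config$mu))
      config$mu <- stats::runif(S, config$mu_range[1], config$mu_range[2])
    if (is.null(config$tau))
      config$tau <- stats::runif(S, config$tau_range[1], config$tau_range[2])
    if (is.null(config$se_range) && is.null(config$sample_size))
      config$sample_size <- round(stats::runif(S, config$sample_size_range[1],
                                               config$sample_size_range[2]))
  })
  if (is.null(config$correlation)) config$correlation <- diag(S)
  config
}

# per-cell sampling SD matrix implied by a resolved config
se_matrix <- function(config) {
  A <- config$n_areas; S <- config$n_sources
  if (!is.null(config$se_range)) {
    with_substream(config$seed, 5L,
                   matrix(stats::runif(A * S, config$se_range[1],
                                       config$se_range[2]), A, S))
  } else {
    p <- config$anchor
    matrix(rep(sqrt(p * (100 - p) / config$sample_size), each = A), A, S)
  }
}

#' Simulate a multi-source prevalence dataset with known truth
#'
#' Generates data under the additive-bias model: true prevalences
#' `theta_i ~ N(anchor, theta_sd^2)` recentred so their mean equals the
#' anchor exactly, per-area bias vectors from
#' [simulate_correlated_biases()], and observations
#' `y_ij ~ N(theta_i + delta_ij, se_ij^2)` with the generating `se` reported
#' as known.
#'
#' @param config a [sim_config()].
#' @return A list with `table` (an [estimate_table()]) and `truth` (a
#'   `truth_record` holding `theta`, `mu`, `tau`, `correlation`, the drawn
#'   `delta` matrix and the resolved config).
#' @export
simulate_dataset <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  config <- resolve_config(config)
  A <- config$n_areas; S <- config$n_sources

  theta <- with_substream(config$seed, 1L,
                          stats::rnorm(A, config$anchor, config$theta_sd))
  theta <- theta - mean(theta) + config$anchor

  delta <- simulate_correlated_biases(config$mu, config$tau,
                                      config$correlation, A, config$seed)
  se <- se_matrix(config)
  y <- theta + delta +
    with_substream(config$seed, 4L,
                   matrix(stats::rnorm(A * S, 0, 1), A, S)) * se
  y <- pmin(pmax(y, 1e-6), 100 - 1e-6)

  tab <- estimate_table(
    areas = sprintf("area%02d", seq_len(A)),
    sources = sprintf("source%d", seq_len(S)),
    y = y, se = se, year = config$source_years
  )
  truth <- structure(
    list(theta = theta, mu = config$mu, tau = config$tau,
         correlation = config$correlation, delta = delta, config = config),
    class = "truth_record")
  list(table = tab, truth = truth)
}

#' Simulate a dataset with area-specific linear time trends
#'
#' Trend variant of [simulate_dataset()]: each area has intercept `alpha_i`
#' (recentred so `mean(alpha) = anchor`, the 2005 level) and slope
#' `beta_i ~ N(slope_mean, slope_sd^2)` on `x_j = 2005 - year_j`, so
#' `y_ij ~ N(alpha_i + beta_i * x_j + delta_ij, se_ij^2)`.
#'
#' @param config a [sim_config()] with `source_years` set.
#' @return As [simulate_dataset()]; `truth` additionally carries `alpha`
#'   (same as `theta`) and `beta`.
#' @export
simulate_time_trend_dataset <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  if (is.null(config$source_years))
    stop("source_years must be set for time-trend simulation")
  config <- resolve_config(config)
  A <- config$n_areas; S <- config$n_sources
  stopifnot(length(config$source_years) == S)

  alpha <- with_substream(config$seed, 1L,
                          stats::rnorm(A, config$anchor, config$theta_sd))
  alpha <- alpha - mean(alpha) + config$anchor
  beta <- with_substream(config$seed, 6L,
                         stats::rnorm(A, config$slope_mean, config$slope_sd))
  x <- 2005 - config$source_years

  delta <- simulate_correlated_biases(config$mu, config$tau,
                                      config$correlation, A, config$seed)
  se <- se_matrix(config)
  y <- alpha + outer(beta, x) + delta +
    with_substream(config$seed, 4L,
                   matrix(stats::rnorm(A * S, 0, 1), A, S)) * se
  y <- pmin(pmax(y, 1e-6), 100 - 1e-6)

  tab <- estimate_table(
    areas = sprintf("area%02d", seq_len(A)),
    sources = sprintf("source%d", seq_len(S)),
    y = y, se = se, year = config$source_years
  )
  truth <- structure(
    list(theta = alpha, alpha = alpha, beta = beta,
         mu = config$mu, tau = config$tau,
         correlation = config$correlation, delta = delta, config = config),
    class = "truth_record")
  list(table = tab, truth = truth)
}

#' @export
print.truth_record <- function(x, ...) {
  cat(sprintf("<truth_record> %d areas x %d sources, anchor %.1f\n",
              length(x$theta), length(x$mu), x$config$anchor))
  cat("  mu:", paste(sprintf("%.2f", x$mu), collapse = " "), "\n")
  cat("  tau:", paste(sprintf("%.2f", x$tau), collapse = " "), "\n")
  if (!is.null(x$beta))
    cat(sprintf("  slopes: mean %.3f sd %.3f\n", mean(x$beta),
                stats::sd(x$beta)))
  invisible(x)
}
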