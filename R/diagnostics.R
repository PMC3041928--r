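#' Inverse-variance pooling weights per area and source
#'
#' Within each area the sources are combined as a fixed-effect
#' meta-analysis of the bias-adjusted estimates, so source `j` receives
#' weight `w_ij` proportional to `1 / (se_ij^2 + tau_j^2)`, normalized over
#' that area's present cells.  The per-source averages `w_bar_j` across
#' areas summarize how much each source drives the pooled results; they
#' sum to 1 over sources when the table is complete.
#'
#' @param se A x S matrix of sampling SDs (percentage points).
#' @param tau length-S bias SDs.
#' @param present optional A x S logical mask (default: all present).
#' @param areas,sources optional dimension labels.
#' @return A `weight_table`: list with `w` (A x S, rows summing to 1 over
#'   present cells), `w_bar` (length S) and the labels.
#' @export
pooling_weights <- function(se, tau, present = NULL, areas = NULL,
                            sources = NULL) {
  se <- as.matrix(se)
  A <- nrow(se); S <- ncol(se)
  stopifnot(length(tau) == S, all(tau >= 0))
  if (is.null(present)) present <- matrix(TRUE, A, S)
  if (any(rowSums(present) == 0)) stop("area with zero present cells")
  stopifnot(all(se[present] > 0))
  prec <- 1 / sweep(se^2, 2, tau^2, "+")
  prec[!present] <- 0
  w <- prec / rowSums(prec)
  w_bar <- colMeans(w)
  structure(list(
    w = w, w_bar = w_bar,
    areas = areas %||% rownames(se), sources = sources %||% colnames(se)
  ), class = "weight_table")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' @export
print.weight_table <- function(x, ...) {
  cat(sprintf("<weight_table> %d areas x %d sources\n",
              nrow(x$w), ncol(x$w)))
  wb <- round(x$w_bar, 3)
  names(wb) <- x$sources %||% paste0("source", seq_along(wb))
  cat("  average weights:\n")
  print(wb)
  invisible(x)
}

#' Pooling weights for a fitted model, with uncertainty
#'
#' Evaluates [pooling_weights()] either at point estimates (classical fits)
#' or per retained posterior draw of `tau` (Bayesian fits), in which case
#' both per-cell weights and their per-source averages are summarized with
#' means and 95% intervals.
#'
#' @param fit a `bias_posterior` or `classical_fit`.
#' @return For classical fits, a `weight_table`.  For Bayesian fits, a
#'   `weight_table` computed at the posterior mean `tau` with extra
#'   elements `w_bar_q2.5`, `w_bar_q97.5` (interval of the per-draw source
#'   averages) and `w_mean` (posterior mean of the per-draw cell weights).
#' @export
model_weights <- function(fit) {
  if (inherits(fit, "classical_fit")) {
    tab <- attr(fit, "table")
    stop_if_null_table(tab)
    return(pooling_weights(tab$se, sqrt(fit$tau2_hat), tab$present,
                           tab$areas, tab$sources))
  }
  stopifnot(inherits(fit, "bias_posterior"))
  tab <- fit$table
  tau_draws <- fit$draws$tau
  n <- nrow(tau_draws)
  wt <- pooling_weights(tab$se, colMeans(tau_draws), tab$present,
                        tab$areas, tab$sources)
  S <- ncol(tab$se)
  wbar_draws <- matrix(NA_real_, n, S)
  w_mean <- matrix(0, nrow(tab$se), S)
  for (k in seq_len(n)) {
    wk <- pooling_weights(tab$se, tau_draws[k, ], tab$present)
    wbar_draws[k, ] <- wk$w_bar
    w_mean <- w_mean + wk$w / n
  }
  wt$w_mean <- w_mean
  wt$w_bar_mean <- colMeans(wbar_draws)
  wt$w_bar_q2.5 <- apply(wbar_draws, 2, stats::quantile, 0.025)
  wt$w_bar_q97.5 <- apply(wbar_draws, 2, stats::quantile, 0.975)
  wt
}

stop_if_null_table <- function(tab) {
  if (is.null(tab))
    stop("fit carries no table; pass one explicitly")
}

#' Bias-adjusted source estimates
#'
#' Shifts every estimate by its source's estimated mean bias
#' (`y_ij - mu_hat_j`) and widens its standard error to include the bias
#' variability (`sqrt(se_ij^2 + tau_hat_j^2)`).  These half-way quantities
#' show how each source is repositioned before pooling.
#'
#' @param table an [estimate_table()].
#' @param mu_hat,tau_hat length-S estimates of bias mean and SD (posterior
#'   means for Bayesian fits, point estimates for classical fits).
#' @return An [estimate_table()] flagged `adjusted = TRUE`.
#' @export
bias_adjusted_estimates <- function(table, mu_hat, tau_hat) {
  S <- length(table$sources)
  stopifnot(length(mu_hat) == S, length(tau_hat) == S, all(tau_hat >= 0))
  y_adj <- sweep(table$y, 2, mu_hat, "-")
  se_adj <- sqrt(sweep(table$se^2, 2, tau_hat^2, "+"))
  estimate_table(table$areas, table$sources, y_adj, se_adj,
                 table$present, table$year, adjusted = TRUE)
}

#' Standardized residuals and their sum of squares
#'
#' `r_ij = (y_ij - theta_hat_i - mu_hat_j) / sqrt(se_ij^2 + tau_hat_j^2)`
#' over present cells.  Under a well-specified model the sum of squares is
#' compatible with a chi-squared distribution on one degree of freedom per
#' present cell; because the fitted values absorb A + S - 1 parameters the
#' reference is approximate, so the report states compatibility with the
#' central 95% of that reference rather than a p-value.
#'
#' @param table an [estimate_table()].
#' @param theta_hat length-A fitted prevalences.
#' @param mu_hat,tau_hat length-S fitted bias means and SDs.
#' @return A `residual_report`: `r` (A x S with NA at absent cells), `ssr`,
#'   `df` (number of present cells), `compatible` (logical), and the
#'   reference-interval bounds.
#' @export
standardized_residuals <- function(table, theta_hat, mu_hat, tau_hat) {
  A <- length(table$areas); S <- length(table$sources)
  stopifnot(length(theta_hat) == A, length(mu_hat) == S,
            length(tau_hat) == S)
  fitted <- outer(theta_hat, rep(1, S)) + outer(rep(1, A), mu_hat)
  denom <- sqrt(sweep(table$se^2, 2, tau_hat^2, "+"))
  r <- (table$y - fitted) / denom
  r[!table$present] <- NA
  df <- sum(table$present)
  ssr <- sum(r^2, na.rm = TRUE)
  lo <- stats::qchisq(0.025, df); hi <- stats::qchisq(0.975, df)
  structure(list(
    r = r, ssr = ssr, df = df,
    compatible = ssr >= lo && ssr <= hi,
    reference = c(q2.5 = lo, mean = df, q97.5 = hi),
    note = paste("reference chi-squared distribution is approximate:",
                 "residuals share fitted parameters")
  ), class = "residual_report")
}

#' @export
print.residual_report <- function(x, ...) {
  cat(sprintf("<residual_report> SSR %.1f on %d present cells\n",
              x$ssr, x$df))
  cat(sprintf("  %s with the null chi-squared reference (central 95%%: %.1f-%.1f, mean %d)\n",
              if (x$compatible) "compatible" else "NOT compatible",
              x$reference["q2.5"], x$reference["q97.5"], x$df))
  invisible(x)
}

#' Posterior distribution of the standardized residuals
#'
#' For an MCMC fit the residual diagnostic is evaluated per retained draw,
#' `r_ij = (y_ij - theta_i - mu_j) / sqrt(se_ij^2 + tau_j^2)` at that
#' draw's parameters, and the sum of squares is summarized over draws.
#' Unlike the plug-in version ([standardized_residuals()]), the posterior
#' mean SSR does not understate the residual variation absorbed by fitted
#' parameters, so it is the quantity to hold against the chi-squared
#' reference with one degree of freedom per present cell.
#'
#' @param fit a `bias_posterior`.
#' @return A `residual_report` whose `ssr` is the posterior mean sum of
#'   squares, with extra elements `ssr_sd` and `ssr_draws`; `r` holds the
#'   posterior means of the per-cell residuals.
#' @export
posterior_residuals <- function(fit) {
  stopifnot(inherits(fit, "bias_posterior"))
  tab <- fit$table
  A <- length(tab$areas); S <- length(tab$sources)
  n <- nrow(fit$draws$theta)
  ssr_draws <- numeric(n)
  r_mean <- matrix(NA_real_, A, S, dimnames = dimnames(tab$y))
  for (j in seq_len(S)) {
    pj <- which(tab$present[, j])
    if (!length(pj)) next
    m_j <- fit$draws$theta[, pj, drop = FALSE] + fit$draws$mu[, j]
    if (!is.null(fit$draws$beta))
      m_j <- m_j + fit$draws$beta[, pj, drop = FALSE] * fit$draws$x[j]
    denom <- sqrt(outer(fit$draws$tau[, j]^2, tab$se[pj, j]^2, "+"))
    r <- (matrix(tab$y[pj, j], n, length(pj), byrow = TRUE) - m_j) / denom
    ssr_draws <- ssr_draws + rowSums(r^2)
    r_mean[pj, j] <- colMeans(r)
  }
  df <- sum(tab$present)
  ssr <- mean(ssr_draws)
  lo <- stats::qchisq(0.025, df); hi <- stats::qchisq(0.975, df)
  structure(list(
    r = r_mean, ssr = ssr, ssr_sd = stats::sd(ssr_draws),
    ssr_draws = ssr_draws, df = df,
    compatible = ssr >= lo && ssr <= hi,
    reference = c(q2.5 = lo, mean = df, q97.5 = hi),
    note = "posterior-mean SSR against an approximate chi-squared reference"
  ), class = "residual_report")
}

#' Compare fitted models by DIC
#'
#' Tabulates `Dbar`, `pD` and DIC for fits of the same table at the same
#' DIC focus, with differences to the best model.  Differences of at most
#' about 2 are flagged as not distinguishing the models.
#'
#' @param ... two or more `bias_posterior` fits (or a single list of them).
#' @param labels optional model labels.
#' @return A `model_comparison` data frame with columns `model`, `Dbar`,
#'   `pD`, `DIC`, `delta_DIC`, `verdict`.
#' @export
compare_models <- function(..., labels = NULL) {
  fits <- list(...)
  if (length(fits) == 1 && !inherits(fits[[1]], "bias_posterior"))
    fits <- fits[[1]]
  stopifnot(length(fits) >= 1,
            all(vapply(fits, inherits, logical(1), "bias_posterior")))
  ref <- fits[[1]]$table
  same <- vapply(fits, function(f)
    identical(dim(f$table$y), dim(ref$y)) &&
      isTRUE(all.equal(f$table$y, ref$y)) &&
      isTRUE(all.equal(f$table$present, ref$present)), logical(1))
  if (!all(same))
    stop("fits must all be on the same table for DIC comparison")
  dics <- vapply(fits, function(f) unlist(f$dic), numeric(3))
  lab <- labels %||% vapply(fits, function(f) f$model, character(1))
  delta <- dics["DIC", ] - min(dics["DIC", ])
  out <- data.frame(
    model = lab, Dbar = dics["Dbar", ], pD = dics["pD", ],
    DIC = dics["DIC", ], delta_DIC = delta,
    verdict = ifelse(delta <= 2, "not distinguishable", "disfavoured")
  )
  out$verdict[which.min(out$DIC)] <-
    if (length(delta) == 1 || sort(delta)[2] > 2) "preferred"
    else "not distinguishable"
  class(out) <- c("model_comparison", "data.frame")
  out[order(out$DIC), ]
}

#' Pooled fixed-effect combination of bias-adjusted estimates
#'
#' The marginal counterpart of the hierarchical pooled estimate: per area,
#' `theta_pooled_i = sum_j w_ij (y_ij - mu_hat_j)` with the weights of
#' [pooling_weights()].  Used mainly to verify that weighting plus bias
#' adjustment reproduces the fixed-effect meta-analytic combination.
#'
#' @param table an [estimate_table()].
#' @param mu_hat,tau_hat length-S bias means and SDs.
#' @return Length-A vector of pooled estimates.
#' @export
pooled_fixed_effect <- function(table, mu_hat, tau_hat) {
  wt <- pooling_weights(table$se, tau_hat, table$present)
  adj <- sweep(table$y, 2, mu_hat, "-")
  adj[!table$present] <- 0
  rowSums(wt$w * adj)
}
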