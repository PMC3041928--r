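#' Weighted two-way ANOVA of prevalences by area and source
#'
#' Minimizes `sum(w_ij * (y_ij - theta_i - mu_j)^2)` over present cells
#' subject to `mean(theta) = anchor`.  The additive model has a
#' one-dimensional null space (a constant can move between the area and
#' source effects), so the fit uses a reduced design and shifts the
#' solution onto the anchor afterwards; standard errors are those of the
#' identified functionals `theta_i - mean(theta) + anchor` under the
#' constraint, treating the weights as inverse variances.
#'
#' @param table an [estimate_table()].
#' @param weights A x S positive weight matrix (only present cells used).
#' @param anchor regional mean prevalence in percent.
#' @return list with `theta_hat`, `mu_hat`, `se_theta`, `se_mu`,
#'   `fitted` (A x S matrix), `objective`.
#' @export
weighted_two_way_anova <- function(table, weights, anchor) {
  A <- length(table$areas); S <- length(table$sources)
  stopifnot(all(dim(weights) == c(A, S)))
  idx <- which(table$present, arr.ind = TRUE)
  if (any(weights[idx] <= 0)) stop("weights must be positive on present cells")

  # connectivity of the area/source bipartite graph determines estimability
  comp <- bipartite_components(idx, A, S)
  if (comp > 1)
    stop("singular design: areas and sources form ", comp,
         " disconnected blocks")

  n <- nrow(idx)
  X <- matrix(0, n, A + S - 1)
  X[cbind(seq_len(n), idx[, 1])] <- 1
  keep <- idx[, 2] > 1
  X[cbind(which(keep), A + idx[keep, 2] - 1L)] <- 1
  w <- weights[idx]
  y <- table$y[idx]

  fit <- stats::lm.wfit(X, y, w)
  coefs <- fit$coefficients
  theta_raw <- coefs[seq_len(A)]
  mu_raw <- c(0, coefs[A + seq_len(S - 1)])
  phi <- mean(theta_raw) - anchor
  theta_hat <- theta_raw - phi
  mu_hat <- mu_raw + phi

  # covariance of the raw coefficients with known weights (sigma^2 = 1)
  XtWX <- crossprod(X * sqrt(w))
  V <- tryCatch(solve(XtWX), error = function(e)
    stop("singular design in weighted two-way ANOVA"))
  # identified functionals: theta_i - mean(theta), mu_j + mean(theta)
  Ct <- diag(A) - matrix(1 / A, A, A)
  Lt <- cbind(Ct, matrix(0, A, S - 1))
  Mm <- matrix(1 / A, S, A)
  Lm <- cbind(Mm, rbind(0, diag(S - 1)))
  se_theta <- sqrt(pmax(0, diag(Lt %*% V %*% t(Lt))))
  se_mu <- sqrt(pmax(0, diag(Lm %*% V %*% t(Lm))))

  fitted <- outer(theta_hat, rep(1, S)) + outer(rep(1, A), mu_hat)
  r <- y - (theta_hat[idx[, 1]] + mu_hat[idx[, 2]])
  list(theta_hat = stats::setNames(theta_hat, table$areas),
       mu_hat = stats::setNames(mu_hat, table$sources),
       se_theta = stats::setNames(se_theta, table$areas),
       se_mu = stats::setNames(se_mu, table$sources),
       fitted = fitted, objective = sum(w * r^2))
}

# number of connected components of the bipartite (area, source) graph
bipartite_components <- function(idx, A, S) {
  lab <- c(seq_len(A), A + seq_len(S))
  find <- function(x) { while (lab[x] != x) x <- lab[x]; x }
  for (r in seq_len(nrow(idx))) {
    a <- find(idx[r, 1]); b <- find(A + idx[r, 2])
    if (a != b) lab[min(a, b)] <- max(a, b)
  }
  length(unique(vapply(c(seq_len(A), A + seq_len(S)), find, integer(1))))
}

#' DerSimonian-Laird moment estimator of a between-area variance
#'
#' Given one source's per-area deviations `d` with known sampling variances
#' `v`, computes weights `w = 1/v`, the weighted mean `dbar`, the
#' heterogeneity statistic `Q = sum(w * (d - dbar)^2)` and the moment
#' estimator `tau2 = (Q - (k - 1)) / (sum(w) - sum(w^2)/sum(w))`, truncated
#' at zero.
#'
#' @param d numeric vector of deviations (length k >= 2).
#' @param v positive sampling variances, same length.
#' @return The truncated between-area variance estimate.
#' @export
dl_moment_estimator <- function(d, v) {
  k <- length(d)
  if (k < 2) stop("need at least 2 observations")
  stopifnot(length(v) == k, all(v > 0))
  w <- 1 / v
  dbar <- sum(w * d) / sum(w)
  Q <- sum(w * (d - dbar)^2)
  denom <- sum(w) - sum(w^2) / sum(w)
  max(0, (Q - (k - 1)) / denom)
}

#' Iterative weighted-ANOVA estimation of the additive-bias model
#'
#' The classical counterpart of the hierarchical fit.  Starting from
#' `tau2 = 0`, the algorithm alternates: (1) a weighted two-way ANOVA with
#' weights `1/(se_ij^2 + tau2_j)`; (2) recentring of the area effects onto
#' the anchor; (3) per-source DerSimonian-Laird estimation of `tau2_j` from
#' the deviations `d_ij = y_ij - theta_i` with variances `se_ij^2`; until
#' the largest change in any `tau2_j` falls below `tol`.  Finally the
#' reported SEs are rescaled by the root mean-square error
#' ([mse_adjust()]), since weights that are true reciprocal variances give
#' MSE 1.
#'
#' One iteration counts one pass through the ANOVA and meta-analysis
#' steps.  The plain alternation (`accelerate = "none"`) converges
#' linearly, with a data-dependent rate that can approach 0.75 and so may
#' need several dozen passes to reach tight tolerances;
#' `accelerate = "anderson"` combines the last few iterates (Anderson
#' mixing, one ANOVA/meta-analysis pass per iteration, same fixed point)
#' and typically converges in a dozen passes.
#'
#' @param table an [estimate_table()].
#' @param anchor regional mean prevalence in percent.
#' @param tol convergence tolerance on `max |change in tau2|`.
#' @param max_iter iteration cap; hitting it returns `converged = FALSE`.
#' @param mse_floor_1 if `TRUE`, never shrink SEs (the multiplicative
#'   factor is floored at 1).
#' @param accelerate `"none"` for plain alternation, `"anderson"` for the
#'   accelerated update.
#' @return A `classical_fit`: `theta_hat`, `se_theta`, `mu_hat`, `se_mu`,
#'   `tau2_hat`, the final deviation matrix `d`, `n_iterations`,
#'   `converged`, `mse_factor`, `tau2_trace` and `method = "iterative_anova"`.
#' @export
iterative_anova_fit <- function(table, anchor = 23, tol = 1e-8,
                                max_iter = 200, mse_floor_1 = FALSE,
                                accelerate = c("none", "anderson")) {
  accelerate <- match.arg(accelerate)
  assert_valid_table(table)
  A <- length(table$areas); S <- length(table$sources)

  # steps 1-3 as one map: weighted ANOVA at the current tau2, recentre,
  # then the per-source DL moment estimate from the deviations
  anova_dl_pass <- function(tau2) {
    w <- 1 / sweep(table$se^2, 2, pmax(tau2, 0), "+")
    fit <- weighted_two_way_anova(table, w, anchor)
    vapply(seq_len(S), function(j) {
      pj <- which(table$present[, j])
      d <- table$y[pj, j] - fit$theta_hat[pj]
      dl_moment_estimator(d, table$se[pj, j]^2)
    }, numeric(1))
  }

  tau2 <- rep(0, S)
  trace <- list()
  converged <- FALSE
  iter <- 0
  hist_x <- list(); hist_f <- list()  # Anderson history
  cooldown <- 0L                       # plain steps after boundary trouble
  best_resid <- Inf; stagnant <- 0L    # fall back for good if not improving
  repeat {
    iter <- iter + 1
    tau2_new <- anova_dl_pass(tau2)
    trace[[iter]] <- tau2_new
    resid <- max(abs(tau2_new - tau2))
    if (resid < tol) {
      tau2 <- tau2_new; converged <- TRUE; break
    }
    if (iter >= max_iter) { tau2 <- tau2_new; break }
    if (resid < 0.9 * best_resid) {
      best_resid <- resid; stagnant <- 0L
    } else {
      stagnant <- stagnant + 1L
      # a limit cycle near the truncation boundary: the plain linear
      # iteration always converges, so abandon extrapolation entirely
      if (stagnant >= 8L) cooldown <- .Machine$integer.max
    }
    if (accelerate == "none" || cooldown > 0L) {
      if (cooldown > 0L && cooldown < .Machine$integer.max)
        cooldown <- cooldown - 1L
      tau2 <- tau2_new
    } else {
      f <- tau2_new - tau2
      hist_x[[length(hist_x) + 1L]] <- tau2
      hist_f[[length(hist_f) + 1L]] <- f
      if (length(hist_x) > 6) { hist_x <- hist_x[-1]; hist_f <- hist_f[-1] }
      k <- length(hist_x)
      if (k == 1) { tau2 <- tau2_new; next }
      dF <- vapply(2:k, function(i) hist_f[[i]] - hist_f[[i - 1]],
                   numeric(S))
      dX <- vapply(2:k, function(i) hist_x[[i]] - hist_x[[i - 1]],
                   numeric(S))
      gam <- tryCatch(qr.solve(dF, f), error = function(e) NULL)
      if (is.null(gam)) {
        tau2 <- tau2_new
      } else {
        xn <- as.vector(tau2 + f - (dX + dF) %*% gam)
        # safeguard near the tau2 = 0 boundary: the truncated map is not
        # smooth there, so clipped or wild extrapolations reset the history
        # and trigger a few plain passes (repeated resets would cycle)
        if (any(xn < 0) ||
            sqrt(sum((xn - tau2_new)^2)) > 10 * sqrt(sum(f^2))) {
          hist_x <- list(); hist_f <- list()
          cooldown <- 3L
          tau2 <- pmax(xn, 0)
        } else {
          tau2 <- xn
        }
      }
    }
  }
  tau2 <- pmax(tau2, 0)
  # refit at the converged weights so estimates and tau2 are self-consistent
  w <- 1 / sweep(table$se^2, 2, tau2, "+")
  fit <- weighted_two_way_anova(table, w, anchor)
  d <- table$y - matrix(fit$theta_hat, A, S)
  d[!table$present] <- NA

  out <- structure(list(
    theta_hat = fit$theta_hat, se_theta = fit$se_theta,
    mu_hat = fit$mu_hat, se_mu = fit$se_mu,
    tau2_hat = stats::setNames(tau2, table$sources),
    d = d, n_iterations = iter, converged = converged,
    mse_factor = NA_real_, anchor = anchor,
    tau2_trace = do.call(rbind, trace),
    method = "iterative_anova"
  ), class = "classical_fit")
  mse_adjust(out, table, floor_1 = mse_floor_1)
}

#' Rescale classical standard errors by the root mean-square error
#'
#' With weights equal to true reciprocal variances the weighted mean-square
#' error has expectation 1; the observed
#' `MSE = sum(w * r^2) / (N - A - S + 1)` (residuals `r` at the fitted
#' additive model, one degree of freedom returned by the identification
#' constraint) therefore calibrates the reported SEs, which are multiplied
#' by `sqrt(MSE)`.
#'
#' @param fit a `classical_fit`.
#' @param table the [estimate_table()] it was fitted to.
#' @param floor_1 if `TRUE` the factor is floored at 1 (never shrinks SEs).
#' @return The fit with rescaled `se_theta`, `se_mu` and `mse_factor` set.
#' @export
mse_adjust <- function(fit, table, floor_1 = FALSE) {
  stopifnot(inherits(fit, "classical_fit"))
  A <- length(table$areas); S <- length(table$sources)
  N <- sum(table$present)
  df <- N - A - S + 1
  if (df <= 0) stop("non-positive degrees of freedom for the MSE adjustment")
  idx <- which(table$present, arr.ind = TRUE)
  w <- 1 / (table$se[idx]^2 + fit$tau2_hat[idx[, 2]])
  r <- table$y[idx] - (fit$theta_hat[idx[, 1]] + fit$mu_hat[idx[, 2]])
  mse <- sum(w * r^2) / df
  factor <- sqrt(mse)
  if (factor < 1e-8)
    warning("residual-free fit: MSE is zero and all SEs collapse to 0")
  if (floor_1) factor <- max(1, factor)
  # undo any previous adjustment before applying this one
  prev <- if (is.na(fit$mse_factor)) 1 else fit$mse_factor
  fit$se_theta <- fit$se_theta / prev * factor
  fit$se_mu <- fit$se_mu / prev * factor
  fit$mse_factor <- factor
  fit
}

#' @export
print.classical_fit <- function(x, ...) {
  cat(sprintf("<classical_fit: %s> %d areas, %d sources\n",
              x$method, length(x$theta_hat), length(x$mu_hat)))
  if (!is.null(x$n_iterations))
    cat(sprintf("  %d iterations, converged: %s\n", x$n_iterations,
                x$converged))
  cat(sprintf("  mean prevalence %.2f (anchor %.2f), mse factor %.3f\n",
              mean(x$theta_hat), x$anchor, x$mse_factor))
  cat("  tau:", paste(sprintf("%.2f", sqrt(x$tau2_hat)), collapse = " "),
      "\n")
  invisible(x)
}

# restricted log-likelihood of the marginal additive model at given tau2,
# with the known-variance structure V = diag(se^2 + tau2_j)
reml_criterion <- function(tau2, table, idx, X) {
  v <- table$se[idx]^2 + tau2[idx[, 2]]
  if (any(v <= 0)) return(-Inf)
  y <- table$y[idx]
  XtVX <- crossprod(X / sqrt(v))
  ch <- tryCatch(chol(XtVX), error = function(e) NULL)
  if (is.null(ch)) return(-Inf)
  b <- backsolve(ch, forwardsolve(t(ch), crossprod(X, y / v)))
  r <- y - X %*% b
  -0.5 * (sum(log(v)) + 2 * sum(log(diag(ch))) + sum(r^2 / v))
}

#' REML mixed-model fit of the additive-bias model
#'
#' Fits the marginal form `y_ij ~ N(theta_i + mu_j, se_ij^2 + tau_j^2)` as
#' a mixed model whose within-cell variances are fixed and known: the
#' restricted likelihood is maximized over the source bias variances
#' `tau2_j >= 0` (GLS profiling out the fixed effects at each evaluation),
#' then the fixed effects are estimated at the optimum and recentred onto
#' the anchor exactly as in [iterative_anova_fit()].
#'
#' @param table an [estimate_table()].
#' @param anchor regional mean prevalence in percent.
#' @return A `classical_fit` with `method = "reml_mixed"`, including the
#'   maximized restricted log-likelihood `reml_logLik` and the optimizer
#'   convergence flag.
#' @export
fit_mixed_model <- function(table, anchor = 23) {
  assert_valid_table(table)
  A <- length(table$areas); S <- length(table$sources)
  idx <- which(table$present, arr.ind = TRUE)
  n <- nrow(idx)
  X <- matrix(0, n, A + S - 1)
  X[cbind(seq_len(n), idx[, 1])] <- 1
  keep <- idx[, 2] > 1
  X[cbind(which(keep), A + idx[keep, 2] - 1L)] <- 1

  # optimize on the tau scale: smoother near the zero boundary
  obj <- function(tau) -reml_criterion(tau^2, table, idx, X)
  start <- sqrt(vapply(seq_len(S), function(j) {
    pj <- which(table$present[, j])
    d <- table$y[pj, j] - rowMeans(table$y, na.rm = TRUE)[pj]
    max(0.01, dl_moment_estimator(d, table$se[pj, j]^2))
  }, numeric(1)))
  opt <- stats::optim(start, obj, method = "L-BFGS-B",
                      lower = rep(0, S), upper = rep(50, S),
                      control = list(maxit = 500))
  tau2 <- opt$par^2

  w <- 1 / sweep(table$se^2, 2, tau2, "+")
  fit <- weighted_two_way_anova(table, w, anchor)
  d <- table$y - matrix(fit$theta_hat, A, S)
  d[!table$present] <- NA
  structure(list(
    theta_hat = fit$theta_hat, se_theta = fit$se_theta,
    mu_hat = fit$mu_hat, se_mu = fit$se_mu,
    tau2_hat = stats::setNames(tau2, table$sources),
    d = d, n_iterations = opt$counts[1],
    converged = opt$convergence == 0,
    mse_factor = 1, anchor = anchor,
    reml_logLik = -opt$value,
    method = "reml_mixed"
  ), class = "classical_fit")
}
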