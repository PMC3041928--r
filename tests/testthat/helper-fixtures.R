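# deterministic miniature table: additive truth plus fixed perturbations
tiny_table <- function(A = 4, S = 3, anchor = 23) {
  theta <- seq(anchor - 3, anchor + 3, length.out = A)
  theta <- theta - mean(theta) + anchor
  mu <- seq(-1.5, 1.5, length.out = S)
  bump <- outer(sin(seq_len(A)), cos(seq_len(S)))  # fixed "noise"
  y <- outer(theta, rep(1, S)) + outer(rep(1, A), mu) + 0.5 * bump
  se <- matrix(0.8, A, S) + 0.1 * abs(bump)
  estimate_table(sprintf("a%d", seq_len(A)), sprintf("s%d", seq_len(S)),
                 y, se)
}

# random valid table for property-style loops
random_table <- function(A, S, seed, missing = 0) {
  set.seed(seed)
  theta <- rnorm(A, 23, 3)
  mu <- runif(S, -3, 3)
  tau <- runif(S, 0.3, 1.5)
  se <- matrix(runif(A * S, 0.5, 2), A, S)
  y <- outer(theta, rep(1, S)) + outer(rep(1, A), mu) +
    sapply(seq_len(S), function(j) rnorm(A, 0, tau[j])) +
    matrix(rnorm(A * S), A, S) * se
  present <- matrix(TRUE, A, S)
  if (missing > 0) {
    drop <- sample(A * S, missing)
    # keep every area >= 1 cell and every source >= 2 cells
    for (d in drop) {
      pr <- present; pr[d] <- FALSE
      if (all(rowSums(pr) >= 1) && all(colSums(pr) >= 2)) present <- pr
    }
  }
  estimate_table(sprintf("a%d", seq_len(A)), sprintf("s%d", seq_len(S)),
                 y, se, present)
}

# independent constrained weighted-least-squares oracle for the two-way
# additive model: full (A+S) design with a Lagrange row for mean(theta)
anova_oracle <- function(table, weights, anchor) {
  A <- length(table$areas); S <- length(table$sources)
  idx <- which(table$present, arr.ind = TRUE)
  n <- nrow(idx)
  X <- matrix(0, n, A + S)
  X[cbind(seq_len(n), idx[, 1])] <- 1
  X[cbind(seq_len(n), A + idx[, 2])] <- 1
  W <- weights[idx]
  M <- crossprod(X * sqrt(W))
  C <- c(rep(1 / A, A), rep(0, S))
  K <- rbind(cbind(2 * M, C), c(C, 0))
  rhs <- c(2 * crossprod(X, W * table$y[idx]), anchor)
  sol <- solve(K, rhs)
  list(theta = sol[seq_len(A)], mu = sol[A + seq_len(S)],
       objective = {
         r <- table$y[idx] - sol[idx[, 1]] - sol[A + idx[, 2]]
         sum(W * r^2)
       })
}
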