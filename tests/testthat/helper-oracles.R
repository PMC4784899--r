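# Independent oracles used to validate the coordinate-descent solver and
# the penalty constructors.  None of these share code with the package's
# optimization path.

# random symmetric 0/1 adjacency with zero diagonal
random_adjacency <- function(p, prob = 0.2) {
  A <- matrix(rbinom(p * p, 1, prob), p, p)
  A[lower.tri(A, diag = TRUE)] <- 0
  A + t(A)
}

random_network <- function(p, prob = 0.2) {
  featureNetwork(random_adjacency(p, prob))
}

# brute-force double sum 0.5 * sum_ij (w_i - w_j)^2 A_ij
laplacian_quadform_bruteforce <- function(A, w) {
  p <- length(w)
  acc <- 0
  for (i in seq_len(p)) {
    for (j in seq_len(p)) {
      acc <- acc + (w[i] - w[j])^2 * A[i, j]
    }
  }
  acc / 2
}

# closed-form weighted least squares with intercept
wls_oracle <- function(X, y, a = rep(1, nrow(X))) {
  Z <- cbind(1, X)
  W <- diag(a)
  beta <- solve(t(Z) %*% W %*% Z, t(Z) %*% W %*% y)
  list(b = beta[1], w = beta[-1])
}

# Exact minimizer of the generalized elastic net objective by exhaustive
# enumeration of sign patterns (feasible only for small p).  For each
# pattern s in {-1,0,+1}^p, solve the stationarity system restricted to
# the active set, then keep sign-consistent solutions whose inactive
# coordinates satisfy the subgradient condition; the objective is strictly
# convex for lambda2 > 0, so the feasible solution is the global minimum.
sign_pattern_oracle <- function(X, y, lambda1, lambda2,
                                a = rep(1, nrow(X)),
                                d = rep(1, ncol(X)),
                                P = diag(ncol(X)), tol = 1e-7) {
  n <- nrow(X); p <- ncol(X)
  stopifnot(p <= 6)
  objective <- function(w, b) {
    r <- y - X %*% w - b
    sum(a * r^2) / (2 * n) + lambda1 * sum(d * abs(w)) +
      lambda2 / 2 * as.numeric(t(w) %*% P %*% w)
  }
  best <- NULL
  patterns <- as.matrix(expand.grid(rep(list(c(-1, 0, 1)), p)))
  Da <- diag(a)
  for (r in seq_len(nrow(patterns))) {
    s <- patterns[r, ]
    act <- which(s != 0)
    k <- length(act)
    # unknowns: w_act, b
    M <- matrix(0, k + 1, k + 1)
    rhs <- numeric(k + 1)
    if (k > 0) {
      Xa <- X[, act, drop = FALSE]
      M[seq_len(k), seq_len(k)] <-
        t(Xa) %*% Da %*% Xa / n + lambda2 * P[act, act, drop = FALSE]
      M[seq_len(k), k + 1] <- t(Xa) %*% a / n
      M[k + 1, seq_len(k)] <- t(a) %*% Xa
      rhs[seq_len(k)] <- t(Xa) %*% (a * y) / n - lambda1 * d[act] * s[act]
    }
    M[k + 1, k + 1] <- sum(a)
    rhs[k + 1] <- sum(a * y)
    sol <- tryCatch(solve(M, rhs), error = function(e) NULL)
    if (is.null(sol)) next
    w <- numeric(p)
    w[act] <- sol[seq_len(k)]
    b <- sol[k + 1]
    if (k > 0 && any(sign(w[act]) != s[act])) next
    # subgradient condition on the inactive set
    resid <- y - X %*% w - b
    grad0 <- as.numeric(t(X) %*% (a * resid)) / n - lambda2 * (P %*% w)
    inact <- setdiff(seq_len(p), act)
    if (length(inact) &&
        any(abs(grad0[inact]) > lambda1 * d[inact] + tol)) next
    obj <- objective(w, b)
    if (is.null(best) || obj < best$objective)
      best <- list(w = w, b = b, objective = obj)
  }
  best
}

# KKT residuals of a fitted model for the same objective
kkt_residuals <- function(X, y, w, b, lambda1, lambda2,
                          a = rep(1, nrow(X)), d = rep(1, ncol(X)),
                          P = diag(ncol(X))) {
  n <- nrow(X)
  r <- y - X %*% w - b
  grad <- as.numeric(t(X) %*% (a * r)) / n - lambda2 * as.numeric(P %*% w)
  active <- which(w != 0)
  res <- numeric(length(w))
  res[active] <- abs(grad[active] - lambda1 * d[active] * sign(w[active]))
  inact <- setdiff(seq_along(w), active)
  res[inact] <- pmax(abs(grad[inact]) - lambda1 * d[inact], 0)
  res
}

# glmnet solves (1/2n)||y - Xw - b||^2 + lam * [alpha ||w||_1 +
# (1-alpha)/2 ||w||^2], but for gaussian fits it standardizes y
# internally in a way that leaves the effective L1 penalty on the
# original scale while dividing the effective ridge penalty by the
# (1/n-normalized) sd of y; the mapping below compensates (verified to
# 1e-8 against the exact sign-pattern oracle).
glmnet_oracle <- function(X, y, lambda1, lambda2) {
  sy <- sqrt(mean((y - mean(y))^2))
  lam <- lambda1 + lambda2 * sy
  fit <- glmnet::glmnet(X, y, alpha = lambda1 / lam, lambda = lam,
                        standardize = FALSE, intercept = TRUE,
                        thresh = 1e-14, maxit = 1e6)
  list(w = as.numeric(fit$beta), b = as.numeric(fit$a0))
}

glmnet_logistic_oracle <- function(X, y, lambda1, lambda2) {
  lam <- lambda1 + lambda2
  fit <- glmnet::glmnet(X, y, family = "binomial",
                        alpha = lambda1 / lam, lambda = lam,
                        standardize = FALSE, intercept = TRUE,
                        thresh = 1e-14, maxit = 1e6)
  list(w = as.numeric(fit$beta), b = as.numeric(fit$a0))
}
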