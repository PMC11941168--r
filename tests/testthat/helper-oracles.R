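# Independent oracles and fixture builders shared across test files.

# Euler-Maruyama trajectory simulation of dx = A x dt + L dW; empirical
# covariance of the post-burn-in trajectory. Independent of the package's
# Lyapunov solver. For symmetric A with scalar Q = qI the identical Euler
# recursion is evaluated mode-wise (x = V y with per-mode AR(1) updates
# y_i[t+1] = (1 + lambda_i dt) y_i[t] + sqrt(q dt) e), which lets the chain
# run long enough for tight tolerances; otherwise a plain time loop is used.
em_covariance <- function(A, Q, n_steps, dt, seed, burn = 0.1) {
  n <- nrow(A)
  q <- Q[1L, 1L]
  burn_steps <- floor(n_steps * burn)
  set.seed(seed)
  if (isSymmetric(A, tol = 1e-12) && all(Q == diag(q, n))) {
    e <- eigen(A, symmetric = TRUE)
    keep <- n_steps - burn_steps
    Y <- matrix(0, keep, n)
    for (i in seq_len(n)) {
      innov <- rnorm(n_steps, sd = sqrt(q * dt))
      yi <- stats::filter(innov, 1 + e$values[i] * dt, method = "recursive")
      Y[, i] <- yi[(burn_steps + 1L):n_steps]
    }
    return(e$vectors %*% stats::cov(Y) %*% t(e$vectors))
  }
  eq <- eigen((Q + t(Q)) / 2, symmetric = TRUE)
  L <- eq$vectors %*% diag(sqrt(pmax(eq$values, 0)), n)
  x <- numeric(n)
  S <- matrix(0, n, n)
  mu <- numeric(n)
  kept <- 0L
  sdt <- sqrt(dt)
  for (i in seq_len(n_steps)) {
    x <- x + dt * (A %*% x)[, 1L] + sdt * (L %*% rnorm(n))[, 1L]
    if (i > burn_steps) {
      S <- S + tcrossprod(x)
      mu <- mu + x
      kept <- kept + 1L
    }
  }
  mu <- mu / kept
  S / kept - tcrossprod(mu)
}

# Power-iteration dominant eigenpair oracle for symmetric PSD matrices.
power_iteration <- function(S, iters = 1e4, seed = 1) {
  set.seed(seed)
  v <- rnorm(nrow(S))
  v <- v / sqrt(sum(v^2))
  for (i in seq_len(iters)) {
    w <- S %*% v
    v <- w[, 1L] / sqrt(sum(w^2))
  }
  list(value = drop(crossprod(v, S %*% v)), vector = v)
}

# Brute-force module oracle: maximal connected components of the graph with
# an edge wherever |r| >= threshold (valid when within-module correlations
# all exceed the threshold and between-module ones all fall below).
threshold_components <- function(R, threshold) {
  n <- nrow(R)
  adj <- R >= threshold
  diag(adj) <- TRUE
  seen <- rep(FALSE, n)
  comps <- list()
  for (i in seq_len(n)) {
    if (seen[i]) next
    comp <- i
    repeat {
      nb <- which(apply(adj[, comp, drop = FALSE], 1L, any) & !seen)
      nb <- setdiff(nb, comp)
      if (!length(nb)) break
      comp <- sort(c(comp, nb))
      seen[comp] <- TRUE
    }
    seen[comp] <- TRUE
    comps[[length(comps) + 1L]] <- comp
  }
  comps
}

# Random PSD matrix with a fixed seed.
random_psd <- function(n, seed) {
  set.seed(seed)
  M <- matrix(rnorm(n * n), n)
  crossprod(M) / n
}

# Small deterministic expression fixture.
toy_expression <- function(values, label = "toy") {
  expression_matrix(values,
                    sprintf("g%02d", seq_len(nrow(values))),
                    sprintf("s%02d", seq_len(ncol(values))),
                    label)
}

# Two-block correlated fixture: genes 1:3 follow one latent factor, genes
# 4:6 another, genes 7:8 independent noise; n samples.
two_block_fixture <- function(n = 40, seed = 5) {
  set.seed(seed)
  z1 <- rnorm(n); z2 <- rnorm(n)
  V <- rbind(
    t(sapply(1:3, function(i) z1 + rnorm(n, sd = 0.2))),
    t(sapply(1:3, function(i) z2 + rnorm(n, sd = 0.2))),
    matrix(rnorm(2 * n), 2)
  )
  toy_expression(V, "blocks")
}

# The default planted-module model scaled as in the shipped demo.
demo_model <- function(seed = 42L) build_network(500, 10, seed = seed)
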