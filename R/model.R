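#' Build a stochastic gene-network model with a planted DNB module
#'
#' Constructs a linear (Ornstein-Uhlenbeck) gene-network model
#' \deqn{dx = A(p)\,x\,dt + L\,dW, \qquad A(p) = A_0 + p B, \quad Q = L L^T,}
#' whose drift is pushed toward the stability boundary by a scalar control
#' parameter \eqn{p \in [0, 1)}. The baseline drift \eqn{A_0} is pure
#' self-degradation (\eqn{-I}). The perturbation \eqn{B} is zero outside a
#' planted module of `dnb_size` genes; inside the module it combines symmetric
#' positive couplings of magnitude `intra_coupling / dnb_size` with a uniform
#' diagonal increment calibrated so that the leading eigenvalue of
#' \eqn{A(p)} equals \eqn{-(1 - p)} exactly. As \eqn{p} rises the module's
#' collective mode slows down, its stationary variance grows like
#' \eqn{1/(1 - p)}, and its genes become strongly mutually correlated --
#' the dynamical-network-biomarker (DNB) signature of an impending critical
#' transition.
#'
#' With coupling weight \eqn{w = c/m} (for `intra_coupling` \eqn{c} and module
#' size \eqn{m}) the module block of \eqn{A(p)} has leading eigenvalue
#' \eqn{-(1-p)} along the uniform (ones) direction and transverse eigenvalues
#' \eqn{-(1 + p(c - 1))}; both branches stay strictly negative for all
#' \eqn{p \in [0, 1)} and any \eqn{c \ge 0}, so the system is stable at every
#' stage.
#'
#' @param n_genes Number of genes (network nodes).
#' @param dnb_size Size of the planted DNB module; must satisfy
#'   `1 <= dnb_size < n_genes`.
#' @param intra_coupling Total within-module coupling strength \eqn{c \ge 0};
#'   off-diagonal drift couplings are `intra_coupling / dnb_size`. The default
#'   (20) places the module deep in the strongly co-fluctuating near-critical
#'   regime (within-module |correlation| ~ 0.97 at `p = 0.95`).
#' @param seed Integer seed controlling the baseline expression vector and the
#'   placement of the module genes.
#' @param schedule Ordered control-parameter values in `[0, 1)`, one per stage.
#' @param noise_scale Scalar \eqn{q}; the diffusion matrix is \eqn{Q = qI}.
#' @param mu_range Range of the per-gene baseline expression means, drawn
#'   uniformly (reproducibly from `seed`).
#' @return An object of class `network_model` with fields `n_genes`,
#'   `gene_ids`, `dnb_genes` (indices), `drift_base` (\eqn{A_0}),
#'   `drift_mod` (\eqn{B}), `noise_cov` (\eqn{Q}), `control_schedule`,
#'   `critical_stage` (index of the maximal schedule entry),
#'   `baseline_expression`, and the construction parameters.
#' @examples
#' mod <- build_network(50, 5, intra_coupling = 1, seed = 1)
#' max(Re(eigen(drift_matrix(mod, 0.9))$values))  # -0.1
#' @export
build_network <- function(n_genes, dnb_size, intra_coupling = 20, seed = 1L,
                          schedule = c(0.1, 0.3, 0.5, 0.7, 0.95),
                          noise_scale = 1, mu_range = c(6, 10)) {
  if (!is_count(n_genes, 2L)) {
    stop2("n_genes must be an integer >= 2", "dnbscreen_invalid_config")
  }
  if (!is_count(dnb_size) || dnb_size >= n_genes) {
    stop2("dnb_size must satisfy 1 <= dnb_size < n_genes",
          "dnbscreen_invalid_config")
  }
  if (!is_scalar_num(intra_coupling) || intra_coupling < 0) {
    stop2("intra_coupling must be a nonnegative scalar",
          "dnbscreen_invalid_config")
  }
  if (length(schedule) && (!is.numeric(schedule) ||
                           any(schedule < 0 | schedule >= 1))) {
    stop2("schedule values must lie in [0, 1)", "dnbscreen_invalid_config")
  }
  if (!is_scalar_num(noise_scale) || noise_scale < 0) {
    stop2("noise_scale must be a nonnegative scalar",
          "dnbscreen_invalid_config")
  }
  n <- as.integer(n_genes)
  m <- as.integer(dnb_size)
  gene_ids <- sprintf("g%04d", seq_len(n))

  dnb <- with_seed(seed, sort(sample.int(n, m)))
  mu <- with_seed(child_seed(seed, 999L),
                  stats::runif(n, mu_range[1], mu_range[2]))

  # Module block of B: off-diagonal couplings w, diagonal increment d chosen
  # so that the leading eigenvalue of A(p) is exactly -(1 - p):
  #   -1 + p * (w (m - 1) + d) = -(1 - p)  =>  d = 1 - w (m - 1).
  w <- if (m > 1L) intra_coupling / m else 0
  d <- 1 - w * (m - 1L)
  B <- matrix(0, n, n)
  blk <- matrix(w, m, m)
  diag(blk) <- d
  B[dnb, dnb] <- blk

  structure(list(
    n_genes = n,
    gene_ids = gene_ids,
    dnb_genes = dnb,
    drift_base = diag(-1, n),
    drift_mod = B,
    noise_cov = diag(noise_scale, n),
    control_schedule = as.numeric(schedule),
    critical_stage = if (length(schedule)) which.max(schedule) else NA_integer_,
    baseline_expression = mu,
    intra_coupling = intra_coupling,
    dnb_size = m,
    noise_scale = noise_scale,
    seed = as.integer(seed)
  ), class = "network_model")
}

#' @export
print.network_model <- function(x, ...) {
  cat(sprintf(
    "network_model: %d genes, planted DNB module of %d, intra_coupling = %g\n",
    x$n_genes, x$dnb_size, x$intra_coupling))
  cat(sprintf("  schedule: %s (critical stage %d)\n",
              paste(x$control_schedule, collapse = ", "), x$critical_stage))
  invisible(x)
}

#' Drift matrix at a control-parameter value
#'
#' @param model A `network_model`.
#' @param p Control-parameter value.
#' @return The matrix \eqn{A(p) = A_0 + p B}.
#' @export
drift_matrix <- function(model, p) {
  stopifnot(inherits(model, "network_model"), is_scalar_num(p))
  model$drift_base + p * model$drift_mod
}

#' Solve the continuous-time Lyapunov equation
#'
#' Finds the unique symmetric solution \eqn{\Sigma} of
#' \eqn{A \Sigma + \Sigma A^T + Q = 0}, the stationary covariance of the
#' linear stochastic system \eqn{dx = A x\,dt + L\,dW} with \eqn{Q = LL^T},
#' provided all eigenvalues of \eqn{A} have strictly negative real part.
#'
#' For symmetric \eqn{A} the solver diagonalizes \eqn{A = V \Lambda V^T} and
#' uses \eqn{\tilde\Sigma_{ij} = -\tilde Q_{ij} / (\lambda_i + \lambda_j)}
#' in the eigenbasis; for small non-symmetric systems it falls back to the
#' Kronecker vectorized linear solve.
#'
#' @param A Square drift matrix, all eigenvalue real parts `< 0`.
#' @param Q Symmetric positive-semidefinite diffusion matrix.
#' @return Symmetric positive-semidefinite matrix \eqn{\Sigma}.
#' @export
solve_lyapunov <- function(A, Q) {
  if (!is.matrix(A) || nrow(A) != ncol(A)) {
    stop2("A must be square", "dnbscreen_invalid_input")
  }
  if (!is.matrix(Q) || any(dim(Q) != dim(A))) {
    stop2("Q must match the dimensions of A", "dnbscreen_invalid_input")
  }
  n <- nrow(A)
  sym <- isSymmetric(A, tol = 1e-10)
  ev <- if (sym) eigen(A, symmetric = TRUE) else eigen(A)
  if (max(Re(ev$values)) >= -1e-12) {
    stop2("drift matrix is not strictly stable: no stationary distribution",
          "dnbscreen_no_stationary")
  }
  if (sym) {
    V <- ev$vectors
    lam <- ev$values
    Qt <- crossprod(V, Q %*% V)
    St <- -Qt / outer(lam, lam, "+")
    S <- V %*% St %*% t(V)
  } else {
    if (n > 200L) {
      stop2("non-symmetric Lyapunov solve limited to n <= 200",
            "dnbscreen_invalid_input")
    }
    K <- diag(n) %x% A + A %x% diag(n)
    S <- matrix(solve(K, -as.vector(Q)), n, n)
  }
  (S + t(S)) / 2
}

#' Stationary expression covariance at a stage
#'
#' Covariance of the model's stationary (Ornstein-Uhlenbeck) distribution at
#' control value `p`, i.e. the solution of
#' \eqn{A(p)\Sigma + \Sigma A(p)^T + Q = 0}. Near the transition
#' (\eqn{p \to 1}) the variance of the planted module diverges along its
#' collective mode -- the increased fluctuation and correlation that the DNB
#' statistics detect.
#'
#' @inheritParams drift_matrix
#' @return Symmetric positive-semidefinite `n_genes x n_genes` matrix.
#' @export
stationary_covariance <- function(model, p) {
  solve_lyapunov(drift_matrix(model, p), model$noise_cov)
}
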