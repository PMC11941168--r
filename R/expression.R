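#' Construct an expression matrix for one stage
#'
#' A light container for a genes-by-samples matrix of continuous expression
#' values with unique gene and sample identifiers and a stage label.
#'
#' @param values Numeric matrix, genes in rows, samples in columns.
#' @param gene_ids Character vector of unique gene identifiers (rows).
#' @param sample_ids Character vector of unique sample identifiers (columns).
#' @param stage_label Single identifier for the stage.
#' @return An object of class `expression_matrix`.
#' @export
expression_matrix <- function(values, gene_ids, sample_ids, stage_label) {
  values <- as.matrix(values)
  if (!is.numeric(values) || anyNA(values) || any(!is.finite(values))) {
    stop2("expression values must be finite and non-missing",
          "dnbscreen_invalid_input")
  }
  gene_ids <- as.character(gene_ids)
  sample_ids <- as.character(sample_ids)
  if (nrow(values) != length(gene_ids) || ncol(values) != length(sample_ids)) {
    stop2("dimensions inconsistent with id lists", "dnbscreen_invalid_input")
  }
  if (anyDuplicated(gene_ids)) {
    stop2("gene_ids must be unique", "dnbscreen_invalid_input")
  }
  if (anyDuplicated(sample_ids)) {
    stop2("sample_ids must be unique", "dnbscreen_invalid_input")
  }
  dimnames(values) <- list(gene_ids, sample_ids)
  structure(list(values = values, gene_ids = gene_ids,
                 sample_ids = sample_ids,
                 stage_label = as.character(stage_label)[1]),
            class = "expression_matrix")
}

#' @export
print.expression_matrix <- function(x, ...) {
  cat(sprintf("expression_matrix '%s': %d genes x %d samples\n",
              x$stage_label, length(x$gene_ids), length(x$sample_ids)))
  invisible(x)
}

#' Construct a stage series
#'
#' An ordered collection of [expression_matrix()] objects sharing the same
#' genes in the same order -- the multi-stage (e.g. multi-age) design on which
#' DNB statistics are computed.
#'
#' @param stages List of `expression_matrix` objects with identical `gene_ids`.
#' @param stage_order Optional explicit ordering of stage labels; defaults to
#'   the order of `stages`.
#' @param provenance Free-form list (e.g. generator parameters and seed).
#' @return An object of class `stage_series`.
#' @export
stage_series <- function(stages, stage_order = NULL, provenance = list()) {
  if (!length(stages)) {
    stop2("a stage series needs at least one stage", "dnbscreen_invalid_config")
  }
  if (!all(vapply(stages, inherits, TRUE, "expression_matrix"))) {
    stop2("stages must be expression_matrix objects", "dnbscreen_invalid_input")
  }
  g0 <- stages[[1]]$gene_ids
  ok <- vapply(stages, function(s) identical(s$gene_ids, g0), TRUE)
  if (!all(ok)) {
    stop2("all stages must share identical gene_ids in the same order",
          "dnbscreen_invalid_input")
  }
  labels <- unname(vapply(stages, `[[`, "", "stage_label"))
  if (anyDuplicated(labels)) {
    stop2("stage labels must be unique", "dnbscreen_invalid_input")
  }
  stage_order <- if (is.null(stage_order)) labels else
    unname(as.character(stage_order))
  if (!setequal(stage_order, labels)) {
    stop2("stage_order must be a permutation of the stage labels",
          "dnbscreen_invalid_input")
  }
  stages <- stages[match(stage_order, labels)]
  names(stages) <- stage_order
  structure(list(stages = stages, stage_order = stage_order,
                 gene_ids = g0, provenance = provenance),
            class = "stage_series")
}

#' @export
print.stage_series <- function(x, ...) {
  cat(sprintf("stage_series: %d stages x %d genes (%s)\n",
              length(x$stages), length(x$gene_ids),
              paste(x$stage_order, collapse = " -> ")))
  invisible(x)
}

# Symmetric PSD square-root factor used for exact stationary sampling.
cov_factor <- function(S) {
  e <- eigen(S, symmetric = TRUE)
  e$vectors %*% diag(sqrt(pmax(e$values, 0)), nrow(S))
}

# Square-root factor of the stationary covariance. Fast path: for symmetric
# A(p) and scalar Q = qI the Lyapunov solution shares A's eigenvectors,
# Sigma = V diag(q / (-2 lambda)) V^T, so one eigendecomposition suffices.
stationary_factor <- function(model, p) {
  A <- drift_matrix(model, p)
  Q <- model$noise_cov
  q <- Q[1L, 1L]
  scalar_q <- all(abs(Q - diag(q, nrow(Q))) == 0)
  if (scalar_q && isSymmetric(A, tol = 1e-10)) {
    e <- eigen(A, symmetric = TRUE)
    if (max(e$values) >= -1e-12) {
      stop2("drift matrix is not strictly stable: no stationary distribution",
            "dnbscreen_no_stationary")
    }
    e$vectors %*% diag(sqrt(q / (-2 * e$values)), nrow(A))
  } else {
    cov_factor(solve_lyapunov(A, Q))
  }
}

#' Sample one stage of expression data
#'
#' Draws `n_samples` independent samples from the model's exact stationary
#' distribution at control value `p` (mean `baseline_expression`, covariance
#' [stationary_covariance()]), then adds i.i.d. per-gene Gaussian measurement
#' noise. Identical arguments always yield identical output.
#'
#' @inheritParams drift_matrix
#' @param n_samples Number of samples (columns) to draw.
#' @param meas_noise_sd Standard deviation of the additive measurement noise.
#' @param seed Integer seed for this stage's draw.
#' @param stage_label Stage label for the result.
#' @return An [expression_matrix()].
#' @export
sample_stage <- function(model, p, n_samples, meas_noise_sd = 0.1,
                         seed = 1L, stage_label = sprintf("p%.2f", p)) {
  if (!is_count(n_samples)) {
    stop2("n_samples must be a positive integer", "dnbscreen_invalid_config")
  }
  if (!is_scalar_num(meas_noise_sd) || meas_noise_sd < 0) {
    stop2("meas_noise_sd must be nonnegative", "dnbscreen_invalid_config")
  }
  n <- model$n_genes
  L <- stationary_factor(model, p)
  X <- with_seed(seed, {
    Z <- matrix(stats::rnorm(n * n_samples), n, n_samples)
    E <- matrix(stats::rnorm(n * n_samples, sd = meas_noise_sd), n, n_samples)
    model$baseline_expression + L %*% Z + E
  })
  expression_matrix(X, model$gene_ids,
                    sprintf("%s_s%02d", stage_label, seq_len(n_samples)),
                    stage_label)
}

#' Generate a full stage series from a network model
#'
#' Produces one [expression_matrix()] per entry of the model's control
#' schedule. Stage draws use child seeds derived from the master `seed` by
#' [child_seed()], so the whole series is reproducible and individual stages
#' are independent. The default configuration is high-dimensional
#' low-sample-size (HDLSS): many more genes than samples per stage.
#'
#' @inheritParams sample_stage
#' @param n_samples_per_stage Samples drawn at every stage.
#' @param seed Master seed.
#' @return A [stage_series()]; `provenance` records all generator parameters,
#'   the planted module and the critical stage.
#' @export
generate_stage_series <- function(model, n_samples_per_stage = 8,
                                  meas_noise_sd = 0.1, seed = 42L) {
  sched <- model$control_schedule
  if (!length(sched)) {
    stop2("model has an empty control schedule", "dnbscreen_invalid_config")
  }
  stages <- lapply(seq_along(sched), function(i) {
    sample_stage(model, sched[i], n_samples_per_stage, meas_noise_sd,
                 seed = child_seed(seed, i),
                 stage_label = sprintf("stage%02d", i))
  })
  stage_series(stages, provenance = list(
    generator = "dnbscreen OU network",
    seed = as.integer(seed),
    n_samples_per_stage = as.integer(n_samples_per_stage),
    meas_noise_sd = meas_noise_sd,
    schedule = sched,
    critical_stage = model$critical_stage,
    dnb_genes = model$gene_ids[model$dnb_genes],
    intra_coupling = model$intra_coupling,
    noise_scale = model$noise_scale
  ))
}
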