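#' Sample covariance of an expression matrix
#'
#' Genes are the variables, samples the observations; columns are mean
#' centered and the `n - 1` denominator is used. The result is symmetric
#' positive-semidefinite (of rank at most `n_samples - 1` in the HDLSS
#' regime).
#'
#' @param x An [expression_matrix()] with at least 2 samples.
#' @return Symmetric `n_genes x n_genes` covariance matrix.
#' @export
sample_covariance <- function(x) {
  stopifnot(inherits(x, "expression_matrix"))
  if (length(x$sample_ids) < 2L) {
    stop2("at least 2 samples are required for a sample covariance",
          "dnbscreen_insufficient_samples")
  }
  S <- stats::cov(t(x$values))
  (S + t(S)) / 2
}

# Sign convention: the entry of largest magnitude is nonnegative
# (ties resolve to the lowest index).
fix_sign <- function(v) {
  i <- which.max(abs(v))
  if (length(i) && v[i] < 0) -v else v
}

#' Dominant eigenpair of a symmetric covariance matrix
#'
#' Dense symmetric eigendecomposition; the eigenvector sign is fixed so that
#' its largest-magnitude entry is nonnegative. An `eigengap_warning` is set
#' when the relative gap between the two leading eigenvalues,
#' \eqn{(\lambda_1 - \lambda_2)/\lambda_1}, falls below 0.05 -- the dominant
#' direction is then poorly determined.
#'
#' @param cov Symmetric, finite covariance matrix.
#' @return List with `value` (\eqn{\lambda_1}), `vector` (unit eigenvector),
#'   `values` (descending spectrum), `eigengap_warning`.
#' @export
dominant_eigen <- function(cov) {
  if (!is.matrix(cov) || !is.numeric(cov) || anyNA(cov) ||
      any(!is.finite(cov))) {
    stop2("covariance must be a finite numeric matrix",
          "dnbscreen_invalid_input")
  }
  if (!isSymmetric(unname(cov), tol = 1e-8)) {
    stop2("covariance matrix is not symmetric", "dnbscreen_invalid_input")
  }
  e <- eigen((cov + t(cov)) / 2, symmetric = TRUE)
  v1 <- fix_sign(e$vectors[, 1L])
  gap_warn <- length(e$values) > 1L && e$values[1L] > 0 &&
    (e$values[1L] - e$values[2L]) / e$values[1L] < 0.05
  list(value = e$values[1L], vector = v1, values = e$values,
       eigengap_warning = gap_warn)
}

# HDLSS path: dominant eigenpair of the sample covariance via the SVD of the
# centered data matrix, avoiding the p x p eigenproblem when n << p.
dominant_eigen_hdlss <- function(values) {
  n <- ncol(values)
  Xc <- values - rowMeans(values)
  sv <- svd(Xc, nu = min(2L, n), nv = 0L)
  lam <- sv$d^2 / (n - 1L)
  v1 <- fix_sign(sv$u[, 1L])
  gap_warn <- length(lam) > 1L && lam[1L] > 0 &&
    (lam[1L] - lam[2L]) / lam[1L] < 0.05
  list(value = lam[1L], vector = v1, values = lam,
       eigengap_warning = gap_warn)
}

#' Per-gene intervention index from the dominant covariance eigenvector
#'
#' The intervention index of gene *i* is \eqn{|v_{1,i}|}, the absolute value
#' of its entry in the dominant eigenvector of the pre-disease sample
#' covariance matrix. Genes with large entries dominate the direction along
#' which the network fluctuates as it approaches the transition, and are
#' ranked as the most promising intervention targets (stabilization-method
#' reasoning of control theory). The eigenvector is computed through the SVD
#' of the centered data when samples < genes (the HDLSS path) and through the
#' dense symmetric eigensolver otherwise; both paths agree to numerical
#' accuracy.
#'
#' @param x An [expression_matrix()] (preferred; enables the HDLSS path) or a
#'   symmetric covariance matrix.
#' @param gene_ids Gene identifiers; required when `x` is a plain matrix.
#' @return An object of class `intervention_ranking` with fields
#'   `stage_label`, `eigenvalues`, `dominant_eigenvector`, `index`
#'   (named, `|v1|`), `ranking` (gene ids in decreasing index order, ties by
#'   gene id), `eigengap_warning`, `reliable`, and empty selection fields
#'   (see [select_top()]).
#' @export
intervention_index <- function(x, gene_ids = NULL) {
  if (inherits(x, "expression_matrix")) {
    gene_ids <- x$gene_ids
    stage_label <- x$stage_label
    if (length(x$sample_ids) < 2L) {
      stop2("at least 2 samples are required", "dnbscreen_insufficient_samples")
    }
    de <- if (length(x$sample_ids) < length(x$gene_ids)) {
      dominant_eigen_hdlss(x$values)
    } else {
      dominant_eigen(sample_covariance(x))
    }
  } else {
    if (is.null(gene_ids)) gene_ids <- rownames(x)
    if (is.null(gene_ids)) {
      stop2("gene_ids are required for a plain covariance matrix",
            "dnbscreen_invalid_input")
    }
    stage_label <- NA_character_
    de <- dominant_eigen(x)
  }
  idx <- abs(de$vector)
  names(idx) <- gene_ids
  ord <- order(-idx, gene_ids)
  structure(list(
    stage_label = stage_label,
    eigenvalues = de$values,
    dominant_eigenvector = de$vector,
    index = idx,
    ranking = gene_ids[ord],
    selected = character(0),
    k = NA_integer_,
    threshold = NA_real_,
    eigengap_warning = de$eigengap_warning,
    reliable = !de$eigengap_warning
  ), class = "intervention_ranking")
}

#' @export
print.intervention_ranking <- function(x, ...) {
  cat(sprintf("intervention_ranking: %d genes, lambda1 = %.4g%s\n",
              length(x$index), x$eigenvalues[1L],
              if (x$eigengap_warning) " [degenerate spectrum: unreliable]"
              else ""))
  top <- utils::head(x$ranking, 5L)
  cat(sprintf("  top: %s\n",
              paste(sprintf("%s (%.3f)", top, x$index[top]), collapse = ", ")))
  if (length(x$selected)) {
    cat(sprintf("  selected (k = %d, threshold %.4g): %s\n", x$k, x$threshold,
                paste(x$selected, collapse = ", ")))
  }
  invisible(x)
}

#' Select top-ranked intervention candidates
#'
#' `method = "topk"` (default) selects the first `k` genes of the ranking;
#' the reported `threshold` is the index value of the k-th gene, the level a
#' horizontal cut-off line would take in an index-versus-gene plot.
#' `method = "gap"` instead selects all genes above the largest consecutive
#' drop in the sorted index values (a data-driven cut-off), still capped at
#' `k`.
#'
#' @param ranking An [intervention_index()] result.
#' @param k Number of genes to select (`1 <= k <= n_genes`).
#' @param method `"topk"` or `"gap"`.
#' @return The ranking with `selected`, `k` and `threshold` filled in.
#' @export
select_top <- function(ranking, k = 10L, method = c("topk", "gap")) {
  stopifnot(inherits(ranking, "intervention_ranking"))
  method <- match.arg(method)
  n <- length(ranking$ranking)
  if (!is_count(k) || k > n) {
    stop2("k must be an integer in [1, n_genes]", "dnbscreen_invalid_config")
  }
  sorted <- ranking$index[ranking$ranking]
  if (method == "gap" && n > 1L) {
    drops <- sorted[-n] - sorted[-1L]
    k <- min(k, which.max(drops))
  }
  ranking$selected <- ranking$ranking[seq_len(k)]
  ranking$k <- as.integer(k)
  ranking$threshold <- unname(sorted[k])
  ranking
}

#' Remove selected candidates by gene biotype
#'
#' Order-preserving removal of genes whose annotated biotype is in
#' `excluded_biotypes` (by default lncRNA, mirroring the exclusion of
#' non-coding genes from a candidate list before experimental follow-up).
#'
#' @param selected Character vector of gene ids (order preserved).
#' @param annotation Data frame with columns `gene_id` and `biotype`; on
#'   duplicated `gene_id` the last row wins (with a warning).
#' @param excluded_biotypes Character set of biotypes to remove.
#' @param on_missing What to do with selected genes absent from the
#'   annotation: `"keep"` (default, with a warning), `"drop"`, or `"error"`.
#' @return Character vector of retained gene ids.
#' @export
filter_by_biotype <- function(selected, annotation,
                              excluded_biotypes = "lncRNA",
                              on_missing = c("keep", "drop", "error")) {
  on_missing <- match.arg(on_missing)
  if (!is.data.frame(annotation) ||
      !all(c("gene_id", "biotype") %in% names(annotation))) {
    stop2("annotation must have columns gene_id and biotype",
          "dnbscreen_parse_error")
  }
  if (anyDuplicated(annotation$gene_id)) {
    warn2("duplicated gene_id in annotation: last entry wins",
          "dnbscreen_duplicate_annotation")
    annotation <- annotation[!duplicated(annotation$gene_id,
                                         fromLast = TRUE), ]
  }
  bt <- stats::setNames(as.character(annotation$biotype),
                        annotation$gene_id)
  missing <- setdiff(selected, names(bt))
  if (length(missing)) {
    if (on_missing == "error") {
      stop2(paste("genes missing from annotation:",
                  paste(missing, collapse = ", ")),
            "dnbscreen_invalid_input")
    }
    warn2(paste("genes missing from annotation:",
                paste(missing, collapse = ", "),
                if (on_missing == "keep") "(retained)" else "(dropped)"),
          "dnbscreen_missing_annotation")
    if (on_missing == "drop") selected <- setdiff(selected, missing)
  }
  keep <- selected[!(bt[selected] %in% excluded_biotypes) |
                     !(selected %in% names(bt))]
  if (!length(keep) && length(selected)) {
    warn2("all selected genes were removed by the biotype filter",
          "dnbscreen_empty_selection")
  }
  keep
}

#' Simulate a stabilizing intervention on target genes
#'
#' Intervention is modeled as added self-degradation: each target gene's
#' drift diagonal is decreased by `strength`
#' (\eqn{A_{ii} \leftarrow A_{ii} - c}). This is a magnitude-only
#' stabilization -- whether a real intervention should suppress or promote a
#' gene cannot be decided from the covariance eigenvector, but added damping
#' can never destabilize this model class. The outcome compares the leading
#' drift eigenvalue and the stationary variance (total, and restricted to the
#' planted DNB module) before and after.
#'
#' @inheritParams drift_matrix
#' @param targets Gene ids or indices; must be a subset of the model's genes.
#' @param strength Added self-degradation rate `c >= 0`.
#' @return An object of class `intervention_outcome` with fields `targets`,
#'   `strength`, `leading_eig_before`, `leading_eig_after`,
#'   `total_var_before`, `total_var_after`, `dnb_var_before`,
#'   `dnb_var_after`.
#' @export
simulate_intervention <- function(model, p, targets, strength) {
  stopifnot(inherits(model, "network_model"))
  if (!is_scalar_num(strength) || strength < 0) {
    stop2("strength must be a nonnegative scalar", "dnbscreen_invalid_config")
  }
  if (is.character(targets)) {
    idx <- match(targets, model$gene_ids)
    if (anyNA(idx)) {
      stop2("unknown target gene ids", "dnbscreen_invalid_input")
    }
  } else {
    idx <- as.integer(targets)
    if (length(idx) && (min(idx) < 1L || max(idx) > model$n_genes)) {
      stop2("target indices out of range", "dnbscreen_invalid_input")
    }
  }
  A <- drift_matrix(model, p)
  Sb <- solve_lyapunov(A, model$noise_cov)
  lb <- max(Re(eigen(A, only.values = TRUE)$values))
  if (strength == 0 || !length(idx)) {
    Sa <- Sb
    la <- lb
  } else {
    A2 <- A
    diag(A2)[idx] <- diag(A2)[idx] - strength
    Sa <- solve_lyapunov(A2, model$noise_cov)
    la <- max(Re(eigen(A2, only.values = TRUE)$values))
  }
  structure(list(
    targets = model$gene_ids[idx],
    strength = strength,
    leading_eig_before = lb, leading_eig_after = la,
    total_var_before = sum(diag(Sb)), total_var_after = sum(diag(Sa)),
    dnb_var_before = sum(diag(Sb)[model$dnb_genes]),
    dnb_var_after = sum(diag(Sa)[model$dnb_genes])
  ), class = "intervention_outcome")
}

#' @export
print.intervention_outcome <- function(x, ...) {
  cat(sprintf(
    "intervention_outcome: %d targets, strength %g\n", length(x$targets),
    x$strength))
  cat(sprintf("  leading eigenvalue: %.4g -> %.4g\n",
              x$leading_eig_before, x$leading_eig_after))
  cat(sprintf("  total variance: %.4g -> %.4g (DNB: %.4g -> %.4g)\n",
              x$total_var_before, x$total_var_after,
              x$dnb_var_before, x$dnb_var_after))
  invisible(x)
}

#' Compare the top-ranked intervention against random target sets
#'
#' Stabilizes the `k` top-ranked genes and `n_draws` uniformly random k-gene
#' sets with the same `strength`, and reports the fraction of random sets
#' whose post-intervention total stationary variance is *worse* (larger) than
#' the top set's. Exact ties count one half (Mann-Whitney convention), so a
#' fully homogeneous network -- where every k-set is equally effective --
#' yields exactly 0.5, the no-advantage value.
#'
#' @inheritParams simulate_intervention
#' @param ranking An [intervention_index()] result.
#' @param k Targets per set.
#' @param n_draws Number of random sets.
#' @param seed Integer seed for the draws.
#' @return Scalar fraction in `[0, 1]`; attribute `"top_var"` and
#'   `"random_var"` carry the underlying post-intervention variances.
#' @export
compare_to_random <- function(model, p, ranking, k, strength,
                              n_draws = 100L, seed = 1L) {
  stopifnot(inherits(model, "network_model"),
            inherits(ranking, "intervention_ranking"))
  if (!is_count(n_draws)) {
    stop2("n_draws must be a positive integer", "dnbscreen_invalid_config")
  }
  if (!is_count(k) || k > model$n_genes) {
    stop2("k must be an integer in [1, n_genes]", "dnbscreen_invalid_config")
  }
  if (k == model$n_genes) {
    warn2("k equals n_genes: only one possible target set, comparison degenerate",
          "dnbscreen_degenerate_comparison")
    return(structure(0.5, top_var = NA_real_, random_var = NA_real_))
  }
  top <- ranking$ranking[seq_len(k)]
  vt <- simulate_intervention(model, p, top, strength)$total_var_after
  draws <- with_seed(seed, {
    replicate(n_draws, sample.int(model$n_genes, k), simplify = FALSE)
  })
  vr <- vapply(draws, function(tg) {
    simulate_intervention(model, p, tg, strength)$total_var_after
  }, 0)
  tol <- 1e-9 * max(1, abs(vt))
  frac <- mean((vr > vt + tol) + 0.5 * (abs(vr - vt) <= tol))
  structure(frac, top_var = vt, random_var = vr)
}
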