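#' Per-stage fluctuation and correlation statistics
#'
#' Computes, for one stage, the per-gene sample standard deviation (n-1
#' denominator) and the matrix of absolute Pearson correlation coefficients
#' on the expression values as given (no internal transformation). Genes with
#' zero standard deviation are masked: their correlations are stored as 0 and
#' flagged in `mask`, so gene indexing stays stable across stages.
#'
#' @param x An [expression_matrix()] with at least 3 samples.
#' @return An object of class `stage_stats` with fields `stage_label`,
#'   `gene_sd`, `abs_corr` (entries in `[0, 1]`, diagonal 1 where sd > 0) and
#'   `mask` (logical vector, `TRUE` for constant genes).
#' @export
compute_stage_stats <- function(x) {
  stopifnot(inherits(x, "expression_matrix"))
  if (length(x$sample_ids) < 3L) {
    stop2("at least 3 samples are required for correlation statistics",
          "dnbscreen_insufficient_samples")
  }
  V <- x$values
  sds <- apply(V, 1L, stats::sd)
  mask <- sds == 0
  R <- matrix(0, nrow(V), nrow(V), dimnames = list(x$gene_ids, x$gene_ids))
  ok <- !mask
  if (sum(ok) >= 2L) {
    R[ok, ok] <- abs(stats::cor(t(V[ok, , drop = FALSE])))
  } else if (sum(ok) == 1L) {
    R[ok, ok] <- 1
  }
  names(sds) <- x$gene_ids
  structure(list(stage_label = x$stage_label, gene_sd = sds,
                 abs_corr = R, mask = mask),
            class = "stage_stats")
}

#' Prefilter candidate genes by fluctuation increase
#'
#' Keeps genes whose maximal standard deviation over the stages is at least
#' `sd_fold_min` times their standard deviation at the reference (first)
#' stage. Genes with zero reference sd are kept whenever their maximal sd is
#' positive; genes that are constant at every stage are always dropped.
#'
#' The default `sd_fold_min = 1` is a pass-through (any gene with nonzero
#' fluctuation is kept): with few samples per stage, per-gene sd ratios carry
#' F-distributed noise large enough that an informative threshold discards
#' genuine module genes, so fold-filtering is left to the caller's judgement.
#'
#' @param series A [stage_series()] with at least 2 stages.
#' @param stats List of per-stage [compute_stage_stats()] results; computed
#'   from `series` when `NULL`.
#' @param sd_fold_min Minimal max-to-reference sd ratio.
#' @return Integer vector of candidate gene indices (into
#'   `series$gene_ids`).
#' @export
prefilter_candidates <- function(series, stats = NULL, sd_fold_min = 1) {
  stopifnot(inherits(series, "stage_series"))
  if (length(series$stages) < 2L) {
    stop2("prefiltering needs at least 2 stages",
          "dnbscreen_insufficient_stages")
  }
  if (is.null(stats)) stats <- lapply(series$stages, compute_stage_stats)
  sdm <- vapply(stats, `[[`, numeric(length(series$gene_ids)), "gene_sd")
  mx <- apply(sdm, 1L, max)
  ref <- sdm[, 1L]
  unname(which(mx > 0 & (ref == 0 | mx >= sd_fold_min * ref)))
}

#' Cluster candidate genes into correlated modules
#'
#' Average-linkage hierarchical clustering of the candidate genes on the
#' distance `1 - |r|` (absolute Pearson correlation at one stage), cut at
#' height `1 - corr_link_min`. Clusters smaller than `min_size` are dropped;
#' the rest are returned in decreasing size order (ties by first gene index).
#' Distances involving masked (constant) genes are treated as maximal.
#'
#' @param stats A [compute_stage_stats()] result.
#' @param candidates Integer indices (or gene ids) of the candidate genes;
#'   at least 2.
#' @param corr_link_min Minimal |correlation| for linkage, in `[0, 1]`.
#' @param min_size Minimal cluster size retained (default 2: singletons are
#'   dropped).
#' @return List of integer index vectors, possibly empty.
#' @export
cluster_members <- function(stats, candidates, corr_link_min = 0.9,
                            min_size = 2L) {
  stopifnot(inherits(stats, "stage_stats"))
  if (is.character(candidates)) {
    candidates <- match(candidates, colnames(stats$abs_corr))
  }
  candidates <- as.integer(candidates)
  if (length(candidates) < 2L) {
    stop2("clustering needs at least 2 candidate genes",
          "dnbscreen_invalid_config")
  }
  usable <- candidates[!stats$mask[candidates]]
  if (length(usable) < 2L) return(list())
  D <- 1 - stats$abs_corr[usable, usable]
  hc <- stats::hclust(stats::as.dist(D), method = "average")
  ct <- stats::cutree(hc, h = 1 - corr_link_min)
  cl <- split(usable, ct)
  cl <- cl[lengths(cl) >= max(2L, min_size)]
  names(cl) <- NULL
  cl[order(-lengths(cl), vapply(cl, min, 1L))]
}

#' Composite early-warning index of a gene module
#'
#' The DNB composite index
#' \deqn{I = \mathrm{sd}_{in} \cdot r_{in} / \max(r_{out}, \epsilon),}
#' where `sd_in` is the members' mean standard deviation, `r_in` the mean
#' absolute correlation over member pairs, and `r_out` the mean absolute
#' correlation between members and all non-members. A genuine DNB module
#' shows a sharp peak of `I` at the pre-disease stage: fluctuation and
#' internal correlation rise while coupling to the rest of the network does
#' not.
#'
#' @inheritParams cluster_members
#' @param members Indices (or ids) of the module genes; at least 2.
#' @param eps Guard for a vanishing `r_out`.
#' @return List with `index`, `sd_in`, `r_in`, `r_out`.
#' @export
composite_index <- function(stats, members, eps = 1e-6) {
  stopifnot(inherits(stats, "stage_stats"))
  if (is.character(members)) {
    members <- match(members, colnames(stats$abs_corr))
  }
  members <- as.integer(members)
  if (length(members) < 2L) {
    stop2("a module needs at least 2 members", "dnbscreen_invalid_config")
  }
  # All-constant members: masked correlations are stored as 0 and sd_in = 0,
  # so the formula correctly degrades to index 0 (no fluctuation, no signal).
  R <- stats$abs_corr
  sd_in <- mean(stats$gene_sd[members])
  pairs <- R[members, members][upper.tri(diag(length(members)))]
  r_in <- mean(pairs)
  r_out <- mean(R[members, -members, drop = FALSE])
  list(index = sd_in * r_in / max(r_out, eps),
       sd_in = sd_in, r_in = r_in, r_out = r_out)
}

#' Detection parameters
#'
#' Defaults reflect the HDLSS regime the package targets (thousands of genes,
#' ~8 samples per stage): a pass-through sd prefilter (see
#' [prefilter_candidates()]), a strict linkage threshold (`corr_link_min =
#' 0.9`) so that average-linkage chaining cannot assemble spurious modules
#' from chance correlations, and a minimal module size of 6, below which
#' cliques of chance correlations at `n ~ 8` are not distinguishable from a
#' real module.
#'
#' @param sd_fold_min Prefilter fold threshold.
#' @param corr_link_min Linkage |correlation| threshold.
#' @param min_module_size Minimal module size considered by
#'   [detect_predisease()].
#' @param eps Guard for `r_out` in [composite_index()].
#' @param peak_ratio_min Significance rule: the peak composite index must be
#'   at least this multiple of the median of the other stages' best indices.
#' @param log2 Apply `log2(x + 1)` to expression values before analysis.
#' @return A list of class `dnb_config`.
#' @export
dnb_config <- function(sd_fold_min = 1, corr_link_min = 0.9,
                       min_module_size = 6L, eps = 1e-6,
                       peak_ratio_min = 2, log2 = FALSE) {
  if (!is_scalar_num(sd_fold_min) || sd_fold_min < 0) {
    stop2("sd_fold_min must be a nonnegative scalar",
          "dnbscreen_invalid_config")
  }
  if (!is_scalar_num(corr_link_min) || corr_link_min < 0 || corr_link_min > 1) {
    stop2("corr_link_min must lie in [0, 1]", "dnbscreen_invalid_config")
  }
  if (!is_count(min_module_size, 2L)) {
    stop2("min_module_size must be an integer >= 2",
          "dnbscreen_invalid_config")
  }
  if (!is_scalar_num(eps) || eps <= 0) {
    stop2("eps must be positive", "dnbscreen_invalid_config")
  }
  if (!is_scalar_num(peak_ratio_min) || peak_ratio_min < 1) {
    stop2("peak_ratio_min must be >= 1", "dnbscreen_invalid_config")
  }
  structure(list(sd_fold_min = sd_fold_min, corr_link_min = corr_link_min,
                 min_module_size = as.integer(min_module_size), eps = eps,
                 peak_ratio_min = peak_ratio_min, log2 = isTRUE(log2)),
            class = "dnb_config")
}

#' Detect the pre-disease stage and DNB members
#'
#' For every stage, candidate genes (see [prefilter_candidates()]) are
#' clustered on that stage's absolute correlations and the cluster maximizing
#' the [composite_index()] (among clusters of at least `min_module_size`
#' genes) becomes the stage's best module. The pre-disease stage is the stage
#' with the maximal best index (ties broken toward the earlier stage -- an
#' earlier warning is preferred); its best module is the DNB member set. The
#' peak is flagged significant when it is at least `peak_ratio_min` times the
#' median of the other stages' best indices (a zero peak is never
#' significant; a positive peak against an all-zero background always is).
#'
#' @param series A [stage_series()] with >= 2 stages, >= 3 samples each.
#' @param config A [dnb_config()].
#' @return An object of class `dnb_result`: `members` (gene ids),
#'   `predisease_stage` (label), `composite_index_by_stage`,
#'   `components_by_stage` (sd_in, r_in, r_out per stage), `candidate_pool`,
#'   `is_significant`, `config`.
#' @export
detect_predisease <- function(series, config = dnb_config()) {
  stopifnot(inherits(series, "stage_series"), inherits(config, "dnb_config"))
  if (length(series$stages) < 2L) {
    stop2("detection needs at least 2 stages", "dnbscreen_insufficient_stages")
  }
  if (any(vapply(series$stages, function(s) length(s$sample_ids), 1L) < 3L)) {
    stop2("every stage needs at least 3 samples",
          "dnbscreen_insufficient_samples")
  }
  work <- series
  if (config$log2) {
    work$stages <- lapply(series$stages, function(s) {
      expression_matrix(log2(s$values + 1), s$gene_ids, s$sample_ids,
                        s$stage_label)
    })
  }
  stats <- lapply(work$stages, compute_stage_stats)
  cand <- prefilter_candidates(work, stats, config$sd_fold_min)

  nst <- length(work$stages)
  best <- numeric(nst)
  comp <- matrix(NA_real_, nst, 3,
                 dimnames = list(series$stage_order,
                                 c("sd_in", "r_in", "r_out")))
  best_members <- vector("list", nst)
  for (t in seq_len(nst)) {
    if (length(cand) < 2L) next
    clusters <- cluster_members(stats[[t]], cand, config$corr_link_min,
                                min_size = config$min_module_size)
    for (cl in clusters) {
      ci <- composite_index(stats[[t]], cl, config$eps)
      if (ci$index > best[t]) {
        best[t] <- ci$index
        comp[t, ] <- c(ci$sd_in, ci$r_in, ci$r_out)
        best_members[[t]] <- cl
      }
    }
  }
  peak_stage <- which.max(best)  # ties resolve to the earliest stage
  peak <- best[peak_stage]
  others <- best[-peak_stage]
  med <- stats::median(others)
  is_sig <- peak > 0 && (med == 0 || peak >= config$peak_ratio_min * med)
  members <- best_members[[peak_stage]]
  structure(list(
    members = series$gene_ids[members],
    predisease_stage = series$stage_order[peak_stage],
    composite_index_by_stage = stats::setNames(best, series$stage_order),
    components_by_stage = comp,
    candidate_pool = series$gene_ids[cand],
    is_significant = is_sig,
    config = config
  ), class = "dnb_result")
}

#' @export
print.dnb_result <- function(x, ...) {
  cat(sprintf("dnb_result: pre-disease stage '%s' (%ssignificant)\n",
              x$predisease_stage, if (x$is_significant) "" else "not "))
  cat(sprintf("  %d members; composite index by stage: %s\n",
              length(x$members),
              paste(sprintf("%.3g", x$composite_index_by_stage),
                    collapse = ", ")))
  invisible(x)
}
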