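#' Assemble and validate a pipeline configuration
#'
#' Four blocks mirror the pipeline stages: `simulate` (generator), `detect`
#' (DNB detection), `rank` (intervention ranking/selection), `intervene`
#' (in-silico validation). Every field is validated against the owning
#' operation's preconditions before any computation starts. Omitted fields
#' take the package defaults.
#'
#' @param simulate,detect,rank,intervene Named lists overriding defaults.
#' @return An object of class `pipeline_config`.
#' @export
pipeline_config <- function(simulate = list(), detect = list(),
                            rank = list(), intervene = list()) {
  sim <- utils::modifyList(list(
    n_genes = 500L, dnb_size = 10L, intra_coupling = 20,
    schedule = c(0.1, 0.3, 0.5, 0.7, 0.95), n_samples = 8L,
    meas_noise_sd = 0.1, noise_scale = 1, seed = 42L
  ), simulate)
  det <- utils::modifyList(list(
    sd_fold_min = 1, corr_link_min = 0.9, min_module_size = 6L,
    eps = 1e-6, peak_ratio_min = 2, log2 = FALSE
  ), detect)
  rnk <- utils::modifyList(list(
    k = 10L, select = "topk", restrict_to_dnb = FALSE,
    excluded_biotypes = "lncRNA", annotation = NULL
  ), rank)
  itv <- utils::modifyList(list(
    strength = 0.5, n_draws = 100L, seed = 7L
  ), intervene)

  # Validate eagerly, before any computation.
  if (!is_count(sim$n_genes, 2L) || !is_count(sim$dnb_size) ||
      sim$dnb_size >= sim$n_genes) {
    stop2("simulate: need 1 <= dnb_size < n_genes", "dnbscreen_invalid_config")
  }
  if (!length(sim$schedule) || any(sim$schedule < 0 | sim$schedule >= 1)) {
    stop2("simulate: schedule must be nonempty with values in [0, 1)",
          "dnbscreen_invalid_config")
  }
  if (!is_count(sim$n_samples) || sim$meas_noise_sd < 0 ||
      sim$noise_scale < 0 || sim$intra_coupling < 0) {
    stop2("simulate: invalid sampling parameters", "dnbscreen_invalid_config")
  }
  det_cfg <- dnb_config(det$sd_fold_min, det$corr_link_min,
                        det$min_module_size, det$eps, det$peak_ratio_min,
                        det$log2)
  if (!is_count(rnk$k)) {
    stop2("rank: k must be a positive integer", "dnbscreen_invalid_config")
  }
  if (!rnk$select %in% c("topk", "gap")) {
    stop2("rank: select must be 'topk' or 'gap'", "dnbscreen_invalid_config")
  }
  if (!is_scalar_num(itv$strength) || itv$strength < 0 ||
      !is_count(itv$n_draws)) {
    stop2("intervene: invalid parameters", "dnbscreen_invalid_config")
  }
  structure(list(simulate = sim, detect = det_cfg, rank = rnk,
                 intervene = itv),
            class = "pipeline_config")
}

#' Read a pipeline configuration from a YAML file
#'
#' The file may define any subset of the `simulate` / `detect` / `rank` /
#' `intervene` blocks; missing values take package defaults. Validation
#' happens at load time.
#'
#' @param path YAML file path.
#' @return A [pipeline_config()].
#' @export
read_pipeline_config <- function(path) {
  raw <- yaml::read_yaml(path)
  if (!is.list(raw)) {
    stop2("config file must define a mapping", "dnbscreen_parse_error")
  }
  pipeline_config(simulate = raw$simulate %||% list(),
                  detect = raw$detect %||% list(),
                  rank = raw$rank %||% list(),
                  intervene = raw$intervene %||% list())
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Run the full detection-and-intervention pipeline
#'
#' Executes simulate (or ingest) -> detect -> rank -> filter -> intervene and
#' writes all artifacts under `out_dir`: `stages/` + `metadata.tsv` (+
#' `ground_truth.json` for synthetic data), `detect/`, `rank/ranking.tsv`,
#' `intervene/intervention.json`, and a machine-readable `report.json`. A
#' failing step writes a `FAILED` marker naming the step and re-raises, so
#' partial outputs remain inspectable. Reports are bit-identical across
#' re-runs of the same configuration except for the wall-clock field.
#'
#' The in-silico intervention step requires the generative model, so it runs
#' only when the pipeline simulated its own data; for ingested data the
#' pipeline stops after ranking and filtering.
#'
#' @param config A [pipeline_config()].
#' @param out_dir Output directory.
#' @param series Optional [stage_series()] of user data; when `NULL`
#'   (default) data are simulated from the `simulate` block.
#' @return The run report, invisibly (also written as `report.json`).
#' @export
run_pipeline <- function(config = pipeline_config(), out_dir, series = NULL) {
  stopifnot(inherits(config, "pipeline_config"))
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  t0 <- Sys.time()
  step <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      writeLines(sprintf("step '%s' failed: %s", name, conditionMessage(e)),
                 file.path(out_dir, "FAILED"))
      stop2(sprintf("[%s] %s", name, conditionMessage(e)),
            class(e)[1L])
    })
  }

  model <- NULL
  if (is.null(series)) {
    sim <- config$simulate
    model <- step("simulate", build_network(
      sim$n_genes, sim$dnb_size, sim$intra_coupling, seed = sim$seed,
      schedule = sim$schedule, noise_scale = sim$noise_scale))
    series <- step("simulate", generate_stage_series(
      model, sim$n_samples, sim$meas_noise_sd, seed = sim$seed))
  }
  step("simulate", write_stage_series(series, out_dir))

  result <- step("detect", detect_predisease(series, config$detect))
  step("detect", write_dnb_result(result, file.path(out_dir, "detect")))

  pre <- series$stages[[result$predisease_stage]]
  rnk_conf <- config$rank
  if (isTRUE(rnk_conf$restrict_to_dnb) && length(result$members) >= 2L) {
    keep <- match(result$members, pre$gene_ids)
    pre <- expression_matrix(pre$values[keep, , drop = FALSE],
                             pre$gene_ids[keep], pre$sample_ids,
                             pre$stage_label)
  }
  ranking <- step("rank", {
    r <- intervention_index(pre)
    select_top(r, min(rnk_conf$k, length(r$ranking)), rnk_conf$select)
  })
  dir.create(file.path(out_dir, "rank"), showWarnings = FALSE)
  step("rank", write_ranking_tsv(ranking,
                                 file.path(out_dir, "rank", "ranking.tsv")))

  filtered <- ranking$selected
  if (!is.null(rnk_conf$annotation)) {
    ann <- step("rank", read_annotation_tsv(rnk_conf$annotation))
    filtered <- step("rank", filter_by_biotype(
      ranking$selected, ann, rnk_conf$excluded_biotypes))
  }

  intervention <- NULL
  superiority <- NA_real_
  if (!is.null(model)) {
    itv <- config$intervene
    p_star <- model$control_schedule[model$critical_stage]
    intervention <- step("intervene", simulate_intervention(
      model, p_star, ranking$selected, itv$strength))
    superiority <- step("intervene", as.numeric(compare_to_random(
      model, p_star, ranking, ranking$k, itv$strength,
      itv$n_draws, itv$seed)))
    dir.create(file.path(out_dir, "intervene"), showWarnings = FALSE)
    jsonlite::write_json(
      c(unclass(intervention), list(superiority_fraction = superiority)),
      file.path(out_dir, "intervene", "intervention.json"),
      auto_unbox = TRUE, digits = NA, pretty = TRUE)
  }

  report <- list(
    package_version = as.character(utils::packageVersion("dnbscreen")),
    config = list(simulate = config$simulate,
                  detect = unclass(config$detect),
                  rank = config$rank[!vapply(config$rank, is.null, TRUE)],
                  intervene = config$intervene),
    detected_stage = result$predisease_stage,
    is_significant = result$is_significant,
    composite_index_by_stage = as.list(result$composite_index_by_stage),
    n_members = length(result$members),
    members = result$members,
    ranking_top = as.list(stats::setNames(
      unname(ranking$index[ranking$selected]), ranking$selected)),
    selection_threshold = ranking$threshold,
    eigengap_warning = ranking$eigengap_warning,
    filtered_candidates = filtered,
    intervention = if (!is.null(intervention)) {
      c(unclass(intervention), list(superiority_fraction = superiority))
    },
    wall_clock_s = as.numeric(difftime(Sys.time(), t0, units = "secs"))
  )
  jsonlite::write_json(report, file.path(out_dir, "report.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(report)
}
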