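#' Configuration for a full pipeline run
#'
#' Collects every threshold the pipeline uses, with defaults at the
#' platform's recommended values: binding density 0.05--2.25, FOV ratio
#' 0.75, positive factor range \[0.3, 3\], content factor range
#' \[0.1, 10\], strict >50% missingness cutoffs, top-75 content pool,
#' alpha 0.05, 100000 permutations. Input is either a path (with
#' dialect) or simulation parameters.
#'
#' @param input_path counts on disk (RCC directory or CSV); `NULL` to
#'   simulate.
#' @param dialect passed to [load_counts()].
#' @param sim a [sim_params()] object when simulating.
#' @param bd_range,min_fov_ratio lane QC thresholds.
#' @param pos_factor_range,content_factor_range,top_n,missing_threshold
#'   normalization settings.
#' @param alpha dual-test cutoff.
#' @param n_permutations,tsp_mode permutation-test settings.
#' @param seed master seed for the run.
#' @param out_dir artifact directory (`NULL` for none).
#' @return list of class `"pipeline_config"`.
#' @export
pipeline_config <- function(input_path = NULL, dialect = "count_table",
                            sim = NULL, bd_range = c(0.05, 2.25),
                            min_fov_ratio = 0.75,
                            pos_factor_range = c(0.3, 3),
                            content_factor_range = c(0.1, 10),
                            top_n = 75L, missing_threshold = 0.5,
                            alpha = 0.05, n_permutations = 100000L,
                            tsp_mode = "search", seed = 1L,
                            out_dir = NULL) {
  if (is.null(input_path) && is.null(sim)) {
    sim <- sim_params(seed = seed)
  }
  structure(list(
    input_path = input_path, dialect = dialect, sim = sim,
    bd_range = bd_range, min_fov_ratio = min_fov_ratio,
    pos_factor_range = pos_factor_range,
    content_factor_range = content_factor_range, top_n = top_n,
    missing_threshold = missing_threshold, alpha = alpha,
    n_permutations = as.integer(n_permutations), tsp_mode = tsp_mode,
    seed = as.integer(seed), out_dir = out_dir
  ), class = "pipeline_config")
}

config_hash <- function(config) {
  x <- config[setdiff(names(config), "out_dir")]
  if (!is.null(x$sim)) x$sim <- unclass(x$sim)
  f <- tempfile(fileext = ".json")
  on.exit(unlink(f))
  jsonlite::write_json(x, f, auto_unbox = TRUE, digits = NA, null = "null",
                       force = TRUE)
  unname(tools::md5sum(f))
}

#' Run the full two-path analysis
#'
#' From one set of raw counts, executes both analysis paths: (i) lane QC,
#' three-step normalization and missingness filtering
#' (samples-then-genes), then the per-gene dual-test differential
#' expression table; and (ii) background correction and genes-then-
#' samples filtering only, then the top-scoring-pair search and its
#' label-permutation test. The two paths share raw ingestion and lane QC
#' but no post-processing state. Lanes removed by the univariate path's
#' factor gate are also removed from the TSP path, keeping the sample
#' sets consistent.
#'
#' With `out_dir` set, writes: `qc_report.tsv`, `factors.tsv`,
#' `de_table.tsv`, exclusion ledgers, `tsp_result.json`,
#' `null_scores.tsv`, `tsp_scatter.tsv`, `report.txt` and
#' `manifest.json` (config, seed, config hash, package version).
#' Identical config and seed give identical artifacts.
#'
#' @param config a [pipeline_config()].
#' @return list of class `"stroma_run"` with elements `counts`, `qc`,
#'   `normalized`, `de`, `tsp_input`, `tsp`, `permutation`, `manifest`.
#' @export
run_pipeline <- function(config = pipeline_config()) {
  stopifnot(inherits(config, "pipeline_config"))
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      stop_ctx("pipeline stage '%s' failed: %s", name, conditionMessage(e))
    })
  }
  truth <- NULL
  counts <- stage("ingest", {
    if (!is.null(config$input_path)) {
      load_counts(config$input_path, config$dialect)
    } else {
      sim <- simulate_cohort(generate_codeset(), config$sim)
      truth <- sim$truth
      sim$counts
    }
  })
  qc <- stage("lane QC", lane_qc(counts, config$bd_range,
                                 config$min_fov_ratio))
  qc_fail <- qc$lane_id[!qc$pass]
  if (length(qc_fail)) {
    keep <- setdiff(colnames(counts$counts), qc_fail)
    counts$counts <- counts$counts[, keep, drop = FALSE]
    counts$lane_meta <- counts$lane_meta[counts$lane_meta$lane_id %in% keep, ]
  }
  normalized <- stage("normalization", normalize_counts(
    counts, top_n = config$top_n,
    pos_factor_range = config$pos_factor_range,
    content_factor_range = config$content_factor_range,
    missing_threshold = config$missing_threshold,
    filter_order = "samples_then_genes"))
  de <- stage("univariate DE", run_univariate(normalized,
                                              alpha = config$alpha))
  gate_lanes <- normalized$ledger$entity[
    normalized$ledger$axis == "lane" &
      grepl("factor gate", normalized$ledger$stage)]
  tsp_input <- stage("TSP preprocessing", tsp_preprocess(
    counts, config$missing_threshold, drop_lanes = gate_lanes))
  fit <- stage("TSP search", tsp_search(tsp_input$values, tsp_input$group))
  perm <- stage("TSP permutation test", tsp_permutation_p(
    tsp_input$values, tsp_input$group,
    n_permutations = config$n_permutations, seed = config$seed,
    mode = config$tsp_mode))
  fit$permutation <- perm[c("p", "p_corrected", "n_permutations", "mode")]
  manifest <- list(
    package = "stromaTSP",
    version = as.character(utils::packageVersion("stromaTSP")),
    config = config[setdiff(names(config), "out_dir")],
    config_hash = config_hash(config),
    seed = config$seed,
    n_lanes_in = nrow(qc), n_lanes_qc_pass = sum(qc$pass),
    n_genes_univariate = nrow(de),
    n_samples_univariate = ncol(normalized$values),
    n_genes_tsp = nrow(tsp_input$values),
    n_samples_tsp = ncol(tsp_input$values)
  )
  run <- structure(list(
    counts = counts, truth = truth, qc = qc, normalized = normalized,
    de = de, tsp_input = tsp_input, tsp = fit, permutation = perm,
    manifest = manifest
  ), class = "stroma_run")
  if (!is.null(config$out_dir)) write_artifacts(run, config$out_dir)
  run
}

write_tsv <- function(df, path) {
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
}

write_artifacts <- function(run, dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  write_tsv(as.data.frame(run$qc), file.path(dir, "qc_report.tsv"))
  write_tsv(run$normalized$factors, file.path(dir, "factors.tsv"))
  write_tsv(as.data.frame(run$de), file.path(dir, "de_table.tsv"))
  write_tsv(run$normalized$ledger, file.path(dir, "ledger_univariate.tsv"))
  write_tsv(run$tsp_input$ledger, file.path(dir, "ledger_tsp.tsv"))
  fit <- run$tsp
  jsonlite::write_json(list(
    pair = fit$pair, score = fit$score, orientation = fit$orientation,
    p_by_class = as.list(fit$p_by_class), accuracy = fit$accuracy,
    permutation_p = run$permutation$p,
    permutation_p_corrected = run$permutation$p_corrected,
    n_permutations = run$permutation$n_permutations,
    mode = run$permutation$mode
  ), file.path(dir, "tsp_result.json"), auto_unbox = TRUE, digits = NA)
  write_tsv(data.frame(null_score = run$permutation$null_scores),
            file.path(dir, "null_scores.tsv"))
  scatter <- data.frame(
    lane_id = colnames(fit$values), group = unname(fit$labels),
    t(fit$values), check.names = FALSE)
  write_tsv(scatter, file.path(dir, "tsp_scatter.tsv"))
  jsonlite::write_json(run$manifest, file.path(dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, null = "null",
                       force = TRUE)
  writeLines(format_report(run), file.path(dir, "report.txt"))
  invisible(dir)
}

format_report <- function(run) {
  de <- run$de; fit <- run$tsp; perm <- run$permutation
  g <- attr(de, "groups")
  fmt_row <- function(i) sprintf(
    "  %-10s p_welch=%.4g  p_mwu=%.4g  q=%.4g  auc=%.3f  log2fc=%+.3f",
    de$gene[i], de$p_welch[i], de$p_mwu[i], de$q[i], de$auc[i], de$log2fc[i])
  calls <- sum(de$de_dual)
  c(
    "== lane quality control ==",
    sprintf("%d/%d lanes pass (binding density, FOV)", sum(run$qc$pass),
            nrow(run$qc)),
    "",
    "== exclusions (univariate path) ==",
    if (nrow(run$normalized$ledger)) {
      sprintf("  %s '%s': %s", run$normalized$ledger$axis,
              run$normalized$ledger$entity, run$normalized$ledger$reason)
    } else "  none",
    "",
    sprintf("== differential expression (%s vs %s, %d genes) ==",
            g[1], g[2], nrow(de)),
    if (calls == 0) {
      sprintf("zero dual-test calls at alpha = %g", attr(de, "alpha"))
    } else {
      c(sprintf("%d dual-test calls at alpha = %g:", calls,
                attr(de, "alpha")),
        vapply(which(de$de_dual), fmt_row, character(1)))
    },
    "",
    "== top-scoring pair ==",
    sprintf("pair: %s / %s  (ordering %s > %s votes %s)", fit$pair[1],
            fit$pair[2], fit$pair[1], fit$pair[2], fit$orientation),
    sprintf("score = %.3f, accuracy = %d/%d (%.1f%%)", fit$score,
            round(fit$accuracy * sum(fit$n_by_class)), sum(fit$n_by_class),
            100 * fit$accuracy),
    sprintf("permutation p = %.4g (corrected %.4g, %d permutations, %s mode)",
            perm$p, perm$p_corrected, perm$n_permutations, perm$mode)
  )
}

#' Human-readable run summary
#'
#' Emits the ranked gene table, exclusion ledgers, and the
#' top-scoring-pair section (pair, score, accuracy, both permutation p
#' variants) as plain text; a run with zero dual-test calls says so
#' rather than omitting the section.
#'
#' @param run a `"stroma_run"` from [run_pipeline()].
#' @param path optional file to write; otherwise printed.
#' @return the report lines, invisibly.
#' @export
write_report <- function(run, path = NULL) {
  stopifnot(inherits(run, "stroma_run"))
  lines <- format_report(run)
  if (is.null(path)) cat(lines, sep = "\n") else writeLines(lines, path)
  invisible(lines)
}

#' @export
print.stroma_run <- function(x, ...) {
  cat(sprintf("stroma_run (seed %d, config %s)\n", x$manifest$seed,
              substr(x$manifest$config_hash, 1, 8)))
  cat(sprintf("  univariate: %d genes x %d samples, %d dual-test calls\n",
              nrow(x$de), x$manifest$n_samples_univariate, sum(x$de$de_dual)))
  cat(sprintf("  TSP: %s/%s, score %.3f, p = %.4g\n", x$tsp$pair[1],
              x$tsp$pair[2], x$tsp$score, x$permutation$p))
  invisible(x)
}

#' Read a pipeline configuration from YAML
#'
#' Top-level keys mirror the [pipeline_config()] arguments; a `sim` block
#' is forwarded to [sim_params()].
#'
#' @param path YAML file.
#' @return a [pipeline_config()].
#' @export
read_pipeline_config <- function(path) {
  y <- yaml::read_yaml(path)
  if (!is.null(y$sim)) y$sim <- do.call(sim_params, y$sim)
  do.call(pipeline_config, y)
}
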