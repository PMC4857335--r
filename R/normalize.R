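#' Per-lane positive-control normalization factors
#'
#' For each lane the geometric mean of its six spiked positive-control
#' counts is computed; the lane's factor is the grand geometric mean of
#' the positive counts across all lanes divided by the lane's own
#' geometric mean. Multiplying a lane by its factor equalizes positive
#' signal across lanes. Factors outside \[0.3, 3\] (inclusive endpoints)
#' are flagged out of range.
#'
#' @param x a [count_matrix()] carrying positive-control probes.
#' @param range acceptance interval for the factors.
#' @return data.frame: `lane_id`, `pos_geo_mean`, `pos_factor`,
#'   `pos_in_range`.
#' @export
positive_factors <- function(x, range = c(0.3, 3)) {
  stopifnot(inherits(x, "count_matrix"))
  pidx <- probe_rows(x, "positive")
  if (!length(pidx)) stop_ctx("no positive-control probes present")
  pm <- x$counts[pidx, , drop = FALSE]
  zero <- which(pm <= 0, arr.ind = TRUE)
  if (nrow(zero)) {
    stop_ctx("zero positive-control count in lane '%s' (geometric mean undefined)",
             colnames(pm)[zero[1, 2]])
  }
  g <- apply(pm, 2, geo_mean)
  G <- geo_mean(as.vector(pm))
  f <- G / g
  data.frame(lane_id = colnames(pm), pos_geo_mean = unname(g),
             pos_factor = unname(f),
             pos_in_range = unname(f >= range[1] & f <= range[2]),
             stringsAsFactors = FALSE)
}

# Background-correct a gene-value matrix against a negative-control
# matrix from the same lanes: subtract the per-lane mean negative count,
# floor at zero; zeros after correction are "missing" (failed to
# register above background).
bg_correct <- function(gene_values, neg_values) {
  b <- colMeans(neg_values)
  corrected <- sweep(gene_values, 2, b, "-")
  corrected[corrected < 0] <- 0
  list(values = corrected, background = b, missing = corrected == 0)
}

#' Mean-of-negatives background correction
#'
#' Estimates each lane's background as the arithmetic mean of its eight
#' negative-control counts and subtracts it from every endogenous and
#' housekeeping count, flooring at zero. Values at zero after correction
#' enter the missing mask: the probe failed to register above background
#' in that lane.
#'
#' @param x a [count_matrix()] with negative-control probes.
#' @return list with `values` (gene rows only), `background` (per lane),
#'   `missing` (logical mask over `values`).
#' @export
subtract_background <- function(x) {
  stopifnot(inherits(x, "count_matrix"))
  nidx <- probe_rows(x, "negative")
  if (!length(nidx)) stop_ctx("no negative-control probes present")
  gidx <- c(probe_rows(x, "endogenous"), probe_rows(x, "housekeeping"))
  bg_correct(x$counts[gidx, , drop = FALSE], x$counts[nidx, , drop = FALSE])
}

#' Per-lane sample-content normalization factors
#'
#' Each lane is summarized by the geometric mean of its own `top_n`
#' highest background-corrected gene values (endogenous plus
#' housekeeping; spike-ins never enter the pool). The lane factor is the
#' grand geometric mean of these summaries divided by the lane's own.
#' Factors outside \[0.1, 10\] (inclusive) are flagged; lanes with fewer
#' than `top_n` nonzero values are unevaluable (`NA` factor).
#'
#' @param values background-corrected gene-by-lane matrix.
#' @param top_n pool size per lane (default 75).
#' @param range acceptance interval for the factors.
#' @return data.frame: `lane_id`, `content_geo_mean`, `content_factor`,
#'   `content_in_range`, `content_evaluable`.
#' @export
content_factors <- function(values, top_n = 75L, range = c(0.1, 10)) {
  if (!is.matrix(values)) stop_ctx("values must be a gene-by-lane matrix")
  r <- apply(values, 2, function(v) {
    v <- sort(v[v > 0], decreasing = TRUE)
    if (length(v) < top_n) NA_real_ else geo_mean(v[seq_len(top_n)])
  })
  evaluable <- !is.na(r)
  if (!any(evaluable)) stop_ctx("no lane has %d nonzero values", top_n)
  G <- geo_mean(r[evaluable])
  f <- G / r
  data.frame(lane_id = colnames(values), content_geo_mean = unname(r),
             content_factor = unname(f),
             content_in_range = unname(!is.na(f) & f >= range[1] & f <= range[2]),
             content_evaluable = unname(evaluable),
             stringsAsFactors = FALSE)
}

#' Exclude genes and samples with excess missingness
#'
#' Removes, in the stated order, entities whose missing fraction strictly
#' exceeds `threshold`; the second pass is computed on the matrix left by
#' the first. The univariate path uses `samples_then_genes`; the
#' top-scoring-pair path uses `genes_then_samples`.
#'
#' @param values gene-by-lane matrix.
#' @param missing logical mask, same shape.
#' @param threshold strict missing-fraction cutoff (default 0.5).
#' @param order `"samples_then_genes"` or `"genes_then_samples"`.
#' @return list `values`, `missing`, `ledger` (data.frame: `entity`,
#'   `axis`, `stage`, `reason`).
#' @export
filter_missing <- function(values, missing, threshold = 0.5,
                           order = c("samples_then_genes",
                                     "genes_then_samples")) {
  order <- match.arg(order)
  stopifnot(identical(dim(values), dim(missing)))
  ledger <- data.frame(entity = character(), axis = character(),
                       stage = character(), reason = character(),
                       stringsAsFactors = FALSE)
  drop_pass <- function(axis) {
    frac <- if (axis == "lane") colMeans(missing) else rowMeans(missing)
    bad <- !is.nan(frac) & frac > threshold
    if (any(bad)) {
      nm <- if (axis == "lane") colnames(values) else rownames(values)
      ledger <<- rbind(ledger, data.frame(
        entity = nm[bad], axis = axis, stage = "missingness filter",
        reason = sprintf(">%.0f%% missing (%.0f%%)", 100 * threshold,
                         100 * frac[bad]),
        stringsAsFactors = FALSE))
      if (axis == "lane") {
        values <<- values[, !bad, drop = FALSE]
        missing <<- missing[, !bad, drop = FALSE]
      } else {
        values <<- values[!bad, , drop = FALSE]
        missing <<- missing[!bad, , drop = FALSE]
      }
    }
  }
  passes <- if (order == "samples_then_genes") c("lane", "gene") else
    c("gene", "lane")
  for (ax in passes) drop_pass(ax)
  if (nrow(values) == 0L || ncol(values) == 0L) {
    stop_ctx("empty after filtering: no %s survive the missingness filter",
             if (nrow(values) == 0L) "genes" else "samples")
  }
  list(values = values, missing = missing, ledger = ledger)
}

#' Full three-step normalization for the univariate analysis path
#'
#' Applies, in order: positive-control factors, mean-of-negatives
#' background correction, top-`top_n` sample-content factors, then the
#' missingness filters (samples then genes by default). Lanes whose
#' content factor falls outside `content_factor_range` are removed before
#' the missingness filters and recorded in the exclusion ledger; positive
#' factors out of `pos_factor_range` are flagged (and optionally also
#' removed via `drop_pos_out_of_range`).
#'
#' @param x a [count_matrix()].
#' @param top_n content-normalization pool size (default 75).
#' @param pos_factor_range acceptance range for positive factors
#'   (default \[0.3, 3\]).
#' @param content_factor_range acceptance range for content factors
#'   (default \[0.1, 10\]).
#' @param missing_threshold strict missing-fraction cutoff (default 0.5).
#' @param filter_order pass order for [filter_missing()].
#' @param drop_pos_out_of_range also remove lanes with out-of-range
#'   positive factors (default `FALSE`: flagged only).
#' @param apply_filters run the missingness filters (default `TRUE`).
#' @param content_basis `"top_n"` (default) summarizes each lane by its
#'   own top-`top_n` genes; `"housekeeping"` uses the geometric mean of
#'   the housekeeping probes instead. The housekeeping basis is off by
#'   default: on panels like this one most reference genes are not
#'   reproducible enough across lanes to anchor on.
#' @return An object of class `"normalized_matrix"`: `values` (gene-by-
#'   lane normalized expression), `missing` mask, `factors` (per input
#'   lane: positive factor, background, content factor, flags), `ledger`
#'   of every removed lane/gene with reasons, and the configuration used.
#' @export
normalize_counts <- function(x, top_n = 75L,
                             pos_factor_range = c(0.3, 3),
                             content_factor_range = c(0.1, 10),
                             missing_threshold = 0.5,
                             filter_order = "samples_then_genes",
                             drop_pos_out_of_range = FALSE,
                             apply_filters = TRUE,
                             content_basis = c("top_n", "housekeeping")) {
  stopifnot(inherits(x, "count_matrix"))
  content_basis <- match.arg(content_basis)
  pf <- positive_factors(x, pos_factor_range)
  scaled <- sweep(x$counts, 2, pf$pos_factor, "*")
  gidx <- c(probe_rows(x, "endogenous"), probe_rows(x, "housekeeping"))
  nidx <- probe_rows(x, "negative")
  if (!length(nidx)) stop_ctx("no negative-control probes present")
  bg <- bg_correct(scaled[gidx, , drop = FALSE], scaled[nidx, , drop = FALSE])
  cf <- if (content_basis == "housekeeping") {
    hk <- rownames(x$counts)[probe_rows(x, "housekeeping")]
    if (!length(hk)) stop_ctx("no housekeeping probes for content_basis")
    content_factors(bg$values[hk, , drop = FALSE], length(hk),
                    content_factor_range)
  } else {
    content_factors(bg$values, top_n, content_factor_range)
  }
  values <- sweep(bg$values, 2, cf$content_factor, "*")
  missing <- bg$missing

  factors <- merge(pf, cf, by = "lane_id", sort = FALSE)
  factors$background <- bg$background[match(factors$lane_id,
                                            names(bg$background))]
  ledger <- data.frame(entity = character(), axis = character(),
                       stage = character(), reason = character(),
                       stringsAsFactors = FALSE)
  drop_lanes <- function(bad, stage, reason) {
    if (!any(bad)) return()
    ledger <<- rbind(ledger, data.frame(
      entity = colnames(values)[bad], axis = "lane", stage = stage,
      reason = reason[bad], stringsAsFactors = FALSE))
    values <<- values[, !bad, drop = FALSE]
    missing <<- missing[, !bad, drop = FALSE]
  }
  cfm <- cf[match(colnames(values), cf$lane_id), ]
  drop_lanes(!cfm$content_in_range | !cfm$content_evaluable,
             "content factor gate",
             ifelse(cfm$content_evaluable,
                    sprintf("content factor %.3g outside [%g, %g]",
                            cfm$content_factor, content_factor_range[1],
                            content_factor_range[2]),
                    sprintf("fewer than %d nonzero values", top_n)))
  if (drop_pos_out_of_range) {
    pfm <- pf[match(colnames(values), pf$lane_id), ]
    drop_lanes(!pfm$pos_in_range, "positive factor gate",
               sprintf("positive factor %.3g outside [%g, %g]",
                       pfm$pos_factor, pos_factor_range[1],
                       pos_factor_range[2]))
  }
  if (apply_filters) {
    flt <- filter_missing(values, missing, missing_threshold, filter_order)
    values <- flt$values; missing <- flt$missing
    ledger <- rbind(ledger, flt$ledger)
  }
  groups <- x$lane_meta$group[match(colnames(values), x$lane_meta$lane_id)]
  structure(list(
    values = values, missing = missing,
    group = stats::setNames(groups, colnames(values)),
    factors = factors, ledger = ledger,
    config = list(top_n = top_n, content_basis = content_basis,
                  pos_factor_range = pos_factor_range,
                  content_factor_range = content_factor_range,
                  missing_threshold = missing_threshold,
                  filter_order = filter_order,
                  drop_pos_out_of_range = drop_pos_out_of_range)
  ), class = "normalized_matrix")
}

#' @export
print.normalized_matrix <- function(x, ...) {
  cat(sprintf("normalized_matrix: %d genes x %d lanes (%d exclusions)\n",
              nrow(x$values), ncol(x$values), nrow(x$ledger)))
  if (nrow(x$ledger)) {
    for (i in seq_len(nrow(x$ledger))) {
      cat(sprintf("  removed %s '%s': %s\n", x$ledger$axis[i],
                  x$ledger$entity[i], x$ledger$reason[i]))
    }
  }
  invisible(x)
}

#' Minimal preprocessing for the top-scoring-pair path
#'
#' The pair statistics depend only on within-sample orderings, so this
#' path deliberately avoids positive-control and content normalization:
#' raw counts are mean-background corrected, then genes and then samples
#' with more than `threshold` zero values are excluded.
#'
#' @param x a [count_matrix()].
#' @param threshold strict zero-fraction cutoff (default 0.5).
#' @param drop_lanes lane ids to remove up front (e.g. lanes excluded by
#'   the univariate path's factor gate, for consistency between paths).
#' @return list `values`, `missing`, `group`, `ledger`.
#' @export
tsp_preprocess <- function(x, threshold = 0.5, drop_lanes = character()) {
  stopifnot(inherits(x, "count_matrix"))
  bg <- subtract_background(x)
  values <- bg$values; missing <- bg$missing
  ledger <- data.frame(entity = character(), axis = character(),
                       stage = character(), reason = character(),
                       stringsAsFactors = FALSE)
  if (length(drop_lanes)) {
    bad <- colnames(values) %in% drop_lanes
    ledger <- rbind(ledger, data.frame(
      entity = colnames(values)[bad], axis = "lane",
      stage = "carried exclusion",
      reason = "removed for consistency with the normalized path",
      stringsAsFactors = FALSE))
    values <- values[, !bad, drop = FALSE]
    missing <- missing[, !bad, drop = FALSE]
  }
  flt <- filter_missing(values, missing, threshold, "genes_then_samples")
  groups <- x$lane_meta$group[match(colnames(flt$values),
                                    x$lane_meta$lane_id)]
  list(values = flt$values, missing = flt$missing,
       group = stats::setNames(groups, colnames(flt$values)),
       ledger = rbind(ledger, flt$ledger))
}
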