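#' Two-sided Mann-Whitney U test p value
#'
#' Exact by enumeration when the pooled sample size is at most 12 and the
#' data are tie-free; otherwise the normal approximation with tie and
#' continuity corrections.
#'
#' @param x,y numeric vectors, one per group; both nonempty.
#' @return two-sided p value.
#' @export
mwu_p <- function(x, y) {
  if (!length(x) || !length(y)) stop_ctx("both groups must be nonempty")
  ties <- anyDuplicated(c(x, y)) > 0L
  exact <- (length(x) + length(y) <= 12L) && !ties
  suppressWarnings(
    stats::wilcox.test(x, y, exact = exact, correct = TRUE)$p.value
  )
}

#' Welch two-sample t test p value
#'
#' Unequal-variance t statistic with Welch-Satterthwaite degrees of
#' freedom. If both groups are (numerically) constant the limit
#' convention applies: p = 1 for equal means, p = 0 otherwise, with a
#' message.
#'
#' @param x,y numeric vectors with at least 2 values each.
#' @return two-sided p value.
#' @export
welch_p <- function(x, y) {
  if (length(x) < 2L || length(y) < 2L) {
    stop_ctx("Welch t test needs at least 2 values per group")
  }
  tryCatch(stats::t.test(x, y, var.equal = FALSE)$p.value,
           error = function(e) {
             p <- if (isTRUE(all.equal(mean(x), mean(y)))) 1 else 0
             message(sprintf(
               "welch_p: degenerate variances, limit convention p = %g", p))
             p
           })
}

#' Benjamini-Hochberg step-up adjustment
#'
#' Returns, in input order, `q_(i) = min_{j >= i} (m/j) p_(j)` capped at
#' 1 (the step-up false discovery rate adjustment).
#'
#' @param pvals probabilities in \[0, 1\].
#' @return adjusted probabilities, same order.
#' @export
bh_adjust <- function(pvals) {
  if (!length(pvals)) return(numeric())
  if (anyNA(pvals) || any(pvals < 0 | pvals > 1)) {
    stop_ctx("p values must lie in [0, 1]")
  }
  stats::p.adjust(pvals, method = "BH")
}

#' Two-group ROC area from the rank statistic
#'
#' AUC computed as U/(n1*n2) with ties counted one half, then folded to
#' `max(A, 1 - A)` so the report is orientation-free (the direction of
#' regulation is carried by the fold change's sign, not by the AUC).
#'
#' @param values numeric vector of per-sample expression.
#' @param labels two-level grouping of the same length.
#' @return folded AUC in \[0.5, 1\].
#' @export
gene_auc <- function(values, labels) {
  labels <- check_labels(labels, length(values))
  g <- sort(unique(labels))
  i1 <- labels == g[1]
  n1 <- sum(i1); n2 <- sum(!i1)
  r <- rank(values)
  u <- sum(r[i1]) - n1 * (n1 + 1) / 2
  a <- u / (n1 * n2)
  max(a, 1 - a)
}

#' Log2 ratio of group means
#'
#' `log2(mean(values_num) / mean(values_den))` on the normalized linear
#' scale. With the GP4 group as numerator a gene upregulated in GP3
#' yields a negative value.
#'
#' @param values_num,values_den non-missing values of the numerator and
#'   denominator groups.
#' @return signed log2 ratio, or `NA` (with a warning) when either mean
#'   is nonpositive.
#' @export
log2_ratio <- function(values_num, values_den) {
  m1 <- mean(values_num); m0 <- mean(values_den)
  if (!is.finite(m1) || !is.finite(m0) || m1 <= 0 || m0 <= 0) {
    warning("log2_ratio undefined: nonpositive group mean")
    return(NA_real_)
  }
  log2(m1 / m0)
}

#' Per-gene two-group differential expression table
#'
#' For every surviving gene: Welch t and Mann-Whitney U p values, the
#' Benjamini-Hochberg q value computed from the MWU p values across all
#' tested genes (a Welch-based q is also reported), the folded ROC AUC,
#' and the log2 ratio of group means (second group over first, i.e.
#' GP4/GP3 for GP3/GP4 labels). A gene is called differentially expressed
#' by the dual-test rule iff both p values fall below `alpha`.
#'
#' Masked (missing) values are dropped per gene; genes with fewer than 2
#' usable values in either group are skipped and listed in the
#' `"skipped"` attribute.
#'
#' @param x a `"normalized_matrix"` from [normalize_counts()], or a plain
#'   gene-by-sample matrix.
#' @param labels group labels per sample; taken from `x$group` when
#'   omitted and `x` is a normalized matrix.
#' @param alpha dual-test significance cutoff (default 0.05).
#' @return A `data.frame` of class `"de_table"`, one row per tested gene,
#'   ordered by MWU p value: `gene`, `p_welch`, `p_mwu`, `q`, `q_welch`,
#'   `auc`, `log2fc`, `n_used_a`, `n_used_b`, `de_dual`.
#' @export
run_univariate <- function(x, labels = NULL, alpha = 0.05) {
  if (inherits(x, "normalized_matrix")) {
    values <- x$values; missing <- x$missing
    if (is.null(labels)) labels <- x$group
  } else {
    values <- x
    missing <- matrix(FALSE, nrow(values), ncol(values))
  }
  labels <- check_labels(labels, ncol(values))
  g <- sort(unique(labels))
  ia <- labels == g[1]; ib <- labels == g[2]
  rows <- vector("list", nrow(values))
  skipped <- character()
  for (k in seq_len(nrow(values))) {
    use <- !missing[k, ]
    va <- values[k, use & ia]; vb <- values[k, use & ib]
    if (length(va) < 2L || length(vb) < 2L) {
      skipped <- c(skipped, rownames(values)[k])
      next
    }
    vals <- c(va, vb)
    lab <- rep(g, c(length(va), length(vb)))
    rows[[k]] <- data.frame(
      gene = rownames(values)[k],
      p_welch = welch_p(va, vb),
      p_mwu = mwu_p(va, vb),
      auc = gene_auc(vals, lab),
      log2fc = suppressWarnings(log2_ratio(vb, va)),
      n_used_a = length(va), n_used_b = length(vb),
      stringsAsFactors = FALSE
    )
  }
  tab <- do.call(rbind, rows)
  if (is.null(tab) || !nrow(tab)) stop_ctx("no gene has 2 usable values per group")
  tab$q <- bh_adjust(tab$p_mwu)
  tab$q_welch <- bh_adjust(tab$p_welch)
  tab$de_dual <- tab$p_welch < alpha & tab$p_mwu < alpha
  tab <- tab[order(tab$p_mwu, tab$p_welch, tab$gene),
             c("gene", "p_welch", "p_mwu", "q", "q_welch", "auc", "log2fc",
               "n_used_a", "n_used_b", "de_dual")]
  rownames(tab) <- NULL
  attr(tab, "groups") <- g
  attr(tab, "alpha") <- alpha
  attr(tab, "skipped") <- skipped
  class(tab) <- c("de_table", "data.frame")
  tab
}

#' @export
print.de_table <- function(x, digits = 4, ...) {
  g <- attr(x, "groups")
  cat(sprintf("differential expression: %d genes tested (%s vs %s), %d dual-test calls at alpha = %g\n",
              nrow(x), g[1], g[2], sum(x$de_dual), attr(x, "alpha")))
  print.data.frame(utils::head(as.data.frame(x), 10), digits = digits,
                   row.names = FALSE)
  if (nrow(x) > 10) cat(sprintf("  ... and %d more rows\n", nrow(x) - 10))
  sk <- attr(x, "skipped")
  if (length(sk)) cat("  skipped (too few usable values):",
                      paste(sk, collapse = ", "), "\n")
  invisible(x)
}
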