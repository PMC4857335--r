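#' Top-scoring-pair score for two genes
#'
#' The ordering indicator of a sample is `gene_i > gene_j` (strict; a
#' within-sample tie counts as false). The pair score is the absolute
#' difference between the two classes' indicator frequencies,
#' `|P(i>j | A) - P(i>j | B)|`, and the orientation points the ordering
#' at the class in which it is more frequent. Because only within-sample
#' orderings enter, the score is invariant under any strictly increasing
#' per-sample transform — which is why this path runs on raw,
#' background-corrected counts rather than normalized values.
#'
#' @param x_i,x_j per-sample values of the two genes.
#' @param labels two-level grouping.
#' @return list: `score`, `orientation` (the class the ordering votes
#'   for), `p_by_class` (named indicator frequencies).
#' @export
pair_score <- function(x_i, x_j, labels) {
  labels <- check_labels(labels, length(x_i))
  if (length(x_j) != length(x_i)) stop_ctx("gene value vectors differ in length")
  g <- sort(unique(labels))
  ind <- x_i > x_j
  p <- c(mean(ind[labels == g[1]]), mean(ind[labels == g[2]]))
  names(p) <- g
  list(score = abs(p[[1]] - p[[2]]),
       orientation = if (p[[1]] >= p[[2]]) g[1] else g[2],
       p_by_class = p)
}

# All unordered gene-pair ordering indicators of a gene-by-sample matrix,
# as a pairs-by-samples 0/1 matrix plus the pair index.
pair_indicators <- function(values) {
  G <- nrow(values)
  if (G < 2L) stop_ctx("need at least 2 genes for pair search")
  ij <- which(upper.tri(matrix(0, G, G)), arr.ind = TRUE)
  ij <- ij[order(ij[, 1], ij[, 2]), , drop = FALSE]
  ind <- matrix(0, nrow = nrow(ij), ncol = ncol(values))
  for (p in seq_len(nrow(ij))) {
    ind[p, ] <- as.numeric(values[ij[p, 1], ] > values[ij[p, 2], ])
  }
  list(ij = ij, ind = ind)
}

# Pair scores for given class weights: w = +1/nA on class-A samples,
# -1/nB on class-B samples, so |ind %*% w| is the score vector.
class_weights <- function(labels, g = sort(unique(labels))) {
  w <- ifelse(labels == g[1], 1 / sum(labels == g[1]),
              -1 / sum(labels == g[2]))
  w
}

#' Fit a top-scoring-pair classifier
#'
#' Exhaustively maximizes the pair score over all unordered gene pairs.
#' Ties on the primary score are broken by the larger secondary rank
#' score (the between-class difference in mean within-sample rank
#' difference of the two genes), then lexicographically by gene names,
#' so the search is deterministic.
#'
#' The input should be background-corrected, missingness-filtered counts
#' (see [tsp_preprocess()]); no positive-control or content normalization
#' is wanted, since the statistic only reads within-sample orderings.
#'
#' @param values gene-by-sample matrix.
#' @param labels two-level grouping per sample.
#' @return An object of class `"tsp"`: `pair` (gene names, oriented so
#'   `pair[1] > pair[2]` votes for `orientation`), `score`, `orientation`,
#'   `p_by_class`, `secondary`, `majority_class` (tie vote), `n_by_class`,
#'   `accuracy` (training resubstitution), `labels`, and the fitted pair's
#'   training values.
#' @seealso [predict.tsp()], [tsp_permutation_p()]
#' @export
tsp_search <- function(values, labels) {
  labels <- check_labels(labels, ncol(values))
  if (nrow(values) < 2L) stop_ctx("fewer than 2 genes after filtering")
  g <- sort(unique(labels))
  pi <- pair_indicators(values)
  w <- class_weights(labels, g)
  scores <- abs(as.vector(pi$ind %*% w))
  best <- which(scores >= max(scores) - 1e-12)
  if (length(best) > 1L) {
    # secondary: between-class difference of mean within-sample rank gap
    rk <- apply(values, 2, rank)
    sec <- vapply(best, function(p) {
      d <- rk[pi$ij[p, 1], ] - rk[pi$ij[p, 2], ]
      abs(mean(d[labels == g[1]]) - mean(d[labels == g[2]]))
    }, numeric(1))
    best <- best[sec >= max(sec) - 1e-12]
    if (length(best) > 1L) {
      nm <- cbind(rownames(values)[pi$ij[best, 1]],
                  rownames(values)[pi$ij[best, 2]])
      best <- best[order(nm[, 1], nm[, 2])[1]]
    } else best <- best[1]
  }
  i <- pi$ij[best, 1]; j <- pi$ij[best, 2]
  ps <- pair_score(values[i, ], values[j, ], labels)
  pair <- rownames(values)[c(i, j)]
  rk <- apply(values, 2, rank)
  d <- rk[i, ] - rk[j, ]
  secondary <- abs(mean(d[labels == g[1]]) - mean(d[labels == g[2]]))
  n_by_class <- stats::setNames(c(sum(labels == g[1]), sum(labels == g[2])), g)
  majority <- g[which.max(n_by_class)]
  fit <- structure(list(
    pair = pair, score = ps$score, orientation = ps$orientation,
    p_by_class = ps$p_by_class, secondary = secondary,
    majority_class = majority, n_by_class = n_by_class,
    labels = stats::setNames(labels, colnames(values)),
    values = values[c(i, j), , drop = FALSE]
  ), class = "tsp")
  pred <- predict(fit, values)
  fit$accuracy <- mean(pred == labels)
  fit
}

#' Classify samples with a fitted top-scoring pair
#'
#' A sample with `pair[1] > pair[2]` is assigned the orientation class;
#' otherwise the other class. A within-sample tie between the two genes
#' is assigned the majority class of the training labels and reported in
#' the `"ties"` attribute.
#'
#' @param object a fitted `"tsp"` object.
#' @param newdata gene-by-sample matrix containing both pair genes
#'   (default: the training values).
#' @param ... unused.
#' @return character vector of class labels, one per sample, with
#'   attribute `"ties"` naming tied samples (if any).
#' @export
predict.tsp <- function(object, newdata = NULL, ...) {
  if (is.null(newdata)) newdata <- object$values
  if (!all(object$pair %in% rownames(newdata))) {
    stop_ctx("sample unclassifiable: pair gene(s) %s not measured",
             paste(setdiff(object$pair, rownames(newdata)), collapse = ", "))
  }
  xi <- newdata[object$pair[1], ]
  xj <- newdata[object$pair[2], ]
  g <- names(object$n_by_class)
  other <- setdiff(g, object$orientation)
  out <- ifelse(xi > xj, object$orientation, other)
  tie <- xi == xj
  if (any(tie)) {
    out[tie] <- object$majority_class
    message(sprintf("predict.tsp: %d tied sample(s) assigned majority class %s",
                    sum(tie), object$majority_class))
  }
  names(out) <- colnames(newdata)
  attr(out, "ties") <- colnames(newdata)[tie]
  out
}

#' @export
print.tsp <- function(x, ...) {
  cat(sprintf("top-scoring pair: %s / %s\n", x$pair[1], x$pair[2]))
  cat(sprintf("  ordering %s > %s votes for %s\n", x$pair[1], x$pair[2],
              x$orientation))
  cat(sprintf("  score = %.3f  (P = %.3f in %s, %.3f in %s)\n", x$score,
              x$p_by_class[[1]], names(x$p_by_class)[1],
              x$p_by_class[[2]], names(x$p_by_class)[2]))
  cat(sprintf("  training accuracy = %d/%d (%.1f%%)\n",
              round(x$accuracy * sum(x$n_by_class)), sum(x$n_by_class),
              100 * x$accuracy))
  if (!is.null(x$permutation)) {
    cat(sprintf("  permutation p = %.4g (corrected %.4g, %d permutations)\n",
                x$permutation$p, x$permutation$p_corrected,
                x$permutation$n_permutations))
  }
  invisible(x)
}

#' @export
summary.tsp <- function(object, ...) {
  print(object)
  cat("\nper-sample classification (training):\n")
  pred <- suppressMessages(predict(object))
  print(table(truth = object$labels, predicted = pred))
  invisible(object)
}

#' Scatterplot of the fitted pair
#'
#' Training samples plotted in the expression plane of the two pair
#' genes; the identity line is the decision boundary of the ordering
#' rule.
#'
#' @param x a `"tsp"` object.
#' @param log axes log specification passed to `plot` (default `"xy"`,
#'   dropped automatically if zeros are present).
#' @param ... passed to `plot`.
#' @export
plot.tsp <- function(x, log = "xy", ...) {
  xi <- x$values[1, ]; xj <- x$values[2, ]
  if (any(c(xi, xj) <= 0)) log <- ""
  g <- names(x$n_by_class)
  col <- ifelse(x$labels == g[1], "#1b6ca8", "#c0392b")
  plot(xj, xi, col = col, pch = 19, log = log,
       xlab = x$pair[2], ylab = x$pair[1], ...)
  abline(0, 1, lty = 2)
  legend("topleft", legend = g, col = c("#1b6ca8", "#c0392b"), pch = 19,
         bty = "n")
  invisible(x)
}

#' Label-permutation significance of the top score
#'
#' Class labels are reassigned uniformly at random preserving group
#' sizes. In mode `"search"` the full pair search is re-run on every
#' permutation (the honest, selection-adjusted null); mode `"fixed_pair"`
#' rescores only the given pair. The p value is the fraction of null top
#' scores at or above the observed score; the `(k+1)/(n+1)` corrected
#' value is reported alongside and is never zero.
#'
#' @param values gene-by-sample matrix (background-corrected, filtered).
#' @param labels two-level grouping.
#' @param n_permutations number of random label assignments
#'   (default 100000; fewer than 100 is rejected).
#' @param seed integer seed for the permutation stream.
#' @param mode `"search"` (re-maximize over all pairs) or `"fixed_pair"`.
#' @param pair gene pair for `"fixed_pair"` mode; defaults to the
#'   observed top pair.
#' @param observed observed top score; computed from the data if `NULL`.
#' @return list of class `"tsp_permutation"`: `p`, `p_corrected`,
#'   `observed`, `null_scores`, `n_permutations`, `mode`, `seed`.
#' @export
tsp_permutation_p <- function(values, labels, n_permutations = 100000L,
                              seed = 1L, mode = c("search", "fixed_pair"),
                              pair = NULL, observed = NULL) {
  mode <- match.arg(mode)
  labels <- check_labels(labels, ncol(values))
  n_permutations <- as.integer(n_permutations)
  if (n_permutations < 100L) {
    stop_ctx("n_permutations < 100 is meaningless; use at least 100")
  }
  g <- sort(unique(labels))
  n <- length(labels); n_a <- sum(labels == g[1]); n_b <- n - n_a
  if (mode == "fixed_pair") {
    if (is.null(pair)) pair <- tsp_search(values, labels)$pair
    ind <- matrix(as.numeric(values[pair[1], ] > values[pair[2], ]),
                  nrow = 1)
    if (is.null(observed)) {
      observed <- pair_score(values[pair[1], ], values[pair[2], ],
                             labels)$score
    }
  } else {
    pi <- pair_indicators(values)
    ind <- pi$ind
    if (is.null(observed)) observed <- tsp_search(values, labels)$score
  }
  set.seed(seed)
  block <- 2000L
  null_scores <- numeric(n_permutations)
  done <- 0L
  wa <- 1 / n_a; wb <- -1 / n_b
  while (done < n_permutations) {
    b <- min(block, n_permutations - done)
    W <- matrix(wb, nrow = n, ncol = b)
    for (k in seq_len(b)) W[sample.int(n, n_a), k] <- wa
    s <- abs(ind %*% W)
    null_scores[done + seq_len(b)] <-
      if (nrow(s) == 1L) as.vector(s) else apply(s, 2, max)
    done <- done + b
  }
  k <- sum(null_scores >= observed - 1e-12)
  structure(list(
    p = k / n_permutations,
    p_corrected = (k + 1) / (n_permutations + 1),
    observed = observed, null_scores = null_scores,
    n_permutations = n_permutations, mode = mode, seed = seed
  ), class = "tsp_permutation")
}

#' @export
print.tsp_permutation <- function(x, ...) {
  cat(sprintf("permutation test (%s mode, %d permutations): observed score %.3f\n",
              x$mode, x$n_permutations, x$observed))
  cat(sprintf("  p = %.4g  (corrected (k+1)/(n+1) = %.4g)\n",
              x$p, x$p_corrected))
  invisible(x)
}

#' Exact permutation tail for one fixed gene pair
#'
#' Under label permutation preserving group sizes, the number `a` of
#' indicator-positive samples assigned to class A is hypergeometric:
#' `a ~ Hypergeom(N, K, n_A)` with `K` indicator-positive samples
#' overall. The score is `|a/n_A - (K - a)/n_B|`, so the two-sided tail
#' `P(score >= observed)` is an exact finite sum — no Monte Carlo needed.
#'
#' @param x_i,x_j per-sample values of the two genes.
#' @param labels two-level grouping.
#' @param observed score whose tail is wanted; defaults to the pair's own
#'   score.
#' @return list: `p` (exact tail probability), `observed`, `K`, `n_a`,
#'   `n_b`.
#' @export
tsp_exact_pair_p <- function(x_i, x_j, labels, observed = NULL) {
  labels <- check_labels(labels, length(x_i))
  g <- sort(unique(labels))
  n_a <- sum(labels == g[1]); n_b <- sum(labels == g[2])
  ind <- x_i > x_j
  K <- sum(ind)
  if (is.null(observed)) observed <- pair_score(x_i, x_j, labels)$score
  a <- 0:min(K, n_a)
  sc <- abs(a / n_a - (K - a) / n_b)
  p <- sum(stats::dhyper(a[sc >= observed - 1e-12], K, n_a + n_b - K, n_a))
  list(p = p, observed = observed, K = K, n_a = n_a, n_b = n_b)
}
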