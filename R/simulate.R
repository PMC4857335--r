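#' Simulation parameters for a synthetic nCounter cohort
#'
#' Defaults describe the study conditions the pipeline is designed around:
#' a 20-vs-21-lane two-group cohort (pre-exclusion), lane-to-lane scale
#' variation, overdispersed counts, low-level background on the negative
#' controls, and enough zero-inflation to exercise the >50%-missing
#' filters.
#'
#' @param n_group_a,n_group_b lanes per group (defaults 20 and 21).
#' @param baseline_log2 per-endogenous/housekeeping-gene baseline log2
#'   expression; recycled or named by probe. Default `NULL` draws one
#'   baseline per gene uniformly on \[3, 9\] log2 counts.
#' @param planted_effects named numeric vector of log2 fold changes
#'   (group B over group A) applied to the named genes.
#' @param planted_pair optional list `list(genes = c(g1, g2), p_a =, p_b =)`
#'   forcing, per sample, the within-sample ordering `g1 > g2` with
#'   probability `p_a` in group A and `p_b` in group B (values swapped
#'   where the drawn indicator disagrees).
#' @param lane_factor_sigma sdlog of the log-normal per-lane scale factors
#'   (default 0.35).
#' @param dispersion negative-binomial overdispersion; variance is
#'   `mu + dispersion * mu^2`; 0 gives Poisson counts (default 0.5).
#' @param background_lambda Poisson mean of negative-control counts
#'   (default 5).
#' @param dropout_prob per-cell zero-inflation probability on endogenous
#'   and housekeeping counts (default 0.15).
#' @param positive_scale expected counts per fM for the spiked positive
#'   controls at lane factor 1 (default 150, so the 128 fM probe sits
#'   near 2e4 counts).
#' @param seed integer seed; all randomness is drawn from it.
#' @return A list of class `"sim_params"`.
#' @export
sim_params <- function(n_group_a = 20L, n_group_b = 21L,
                       baseline_log2 = NULL, planted_effects = NULL,
                       planted_pair = NULL, lane_factor_sigma = 0.35,
                       dispersion = 0.5, background_lambda = 5,
                       dropout_prob = 0.15, positive_scale = 150,
                       seed = 1L) {
  if (n_group_a < 1L || n_group_b < 1L) {
    stop_ctx("each group needs at least one lane")
  }
  if (dispersion < 0) stop_ctx("dispersion must be >= 0")
  if (dropout_prob < 0 || dropout_prob >= 1) {
    stop_ctx("dropout_prob must lie in [0, 1)")
  }
  if (lane_factor_sigma < 0) stop_ctx("lane_factor_sigma must be >= 0")
  if (background_lambda < 0) stop_ctx("background_lambda must be >= 0")
  structure(list(
    n_group_a = as.integer(n_group_a), n_group_b = as.integer(n_group_b),
    baseline_log2 = baseline_log2, planted_effects = planted_effects,
    planted_pair = planted_pair, lane_factor_sigma = lane_factor_sigma,
    dispersion = dispersion, background_lambda = background_lambda,
    dropout_prob = dropout_prob, positive_scale = positive_scale,
    seed = as.integer(seed)
  ), class = "sim_params")
}

# NB draw with var = mu + dispersion*mu^2; Poisson when dispersion == 0.
rcounts <- function(n, mu, dispersion) {
  if (dispersion == 0) stats::rpois(n, mu) else {
    stats::rnbinom(n, size = 1 / dispersion, mu = mu)
  }
}

#' Simulate a NanoString-like cohort with recorded ground truth
#'
#' Endogenous and housekeeping probe counts are negative-binomial with
#' mean `lane_factor * 2^(baseline + group_effect)`, then zero-inflated;
#' negative controls are Poisson background; positive controls have means
#' proportional to their spiked concentration times the lane factor.
#' Identical parameters (including seed) give bit-identical output.
#'
#' @param codeset a [generate_codeset()] catalogue.
#' @param params a [sim_params()] object.
#' @return A list: `counts` (a [count_matrix()]) and `truth` (per-lane
#'   true scale factors, per-gene true log2 fold change, and the planted
#'   ordering pair with its per-group ordering probabilities, if any).
#' @export
simulate_cohort <- function(codeset, params) {
  stopifnot(inherits(params, "sim_params"))
  codeset <- validate_codeset(codeset)
  genes <- codeset$probe_name[codeset$probe_class %in%
                                c("endogenous", "housekeeping")]
  if (length(genes) == 0L) stop_ctx("codeset has no endogenous/housekeeping probes")
  n_a <- params$n_group_a; n_b <- params$n_group_b
  n <- n_a + n_b
  lane_ids <- c(sprintf("GP3-%02d", seq_len(n_a)),
                sprintf("GP4-%02d", seq_len(n_b)))
  group <- rep(c("GP3", "GP4"), c(n_a, n_b))

  set.seed(params$seed)

  base <- params$baseline_log2
  if (is.null(base)) {
    base <- stats::runif(length(genes), 3, 9)
  } else if (!is.null(names(base))) {
    miss <- setdiff(genes, names(base))
    if (length(miss)) stop_ctx("baseline_log2 missing genes: %s",
                               paste(miss, collapse = ", "))
    base <- unname(base[genes])
  } else {
    base <- rep_len(base, length(genes))
  }
  lfc <- stats::setNames(rep(0, length(genes)), genes)
  if (!is.null(params$planted_effects)) {
    bad <- setdiff(names(params$planted_effects), genes)
    if (length(bad)) stop_ctx("planted_effects name unknown genes: %s",
                              paste(bad, collapse = ", "))
    lfc[names(params$planted_effects)] <- params$planted_effects
  }
  lane_factor <- if (params$lane_factor_sigma == 0) rep(1, n) else {
    stats::rlnorm(n, meanlog = 0, sdlog = params$lane_factor_sigma)
  }

  counts <- matrix(0, nrow = nrow(codeset), ncol = n,
                   dimnames = list(codeset$probe_name, lane_ids))
  gidx <- match(genes, codeset$probe_name)
  # group effect applies to group B (GP4) lanes
  eff <- outer(lfc, as.numeric(group == "GP4"))
  mu <- (2 ^ (base + eff)) * rep(lane_factor, each = length(genes))
  counts[gidx, ] <- rcounts(length(mu), mu, params$dispersion)
  if (params$dropout_prob > 0) {
    drop <- matrix(stats::runif(length(mu)) < params$dropout_prob,
                   nrow = length(genes))
    counts[gidx, ][drop] <- 0
  }
  nidx <- which(codeset$probe_class == "negative")
  counts[nidx, ] <- stats::rpois(length(nidx) * n, params$background_lambda)
  # spike-in hybridization is technical noise, modelled as Poisson; the
  # biological overdispersion applies to endogenous probes only
  pidx <- which(codeset$probe_class == "positive")
  pmu <- outer(params$positive_scale * codeset$concentration[pidx], lane_factor)
  counts[pidx, ] <- stats::rpois(length(pmu), pmu)

  pair_truth <- NULL
  if (!is.null(params$planted_pair)) {
    pp <- params$planted_pair
    if (!all(pp$genes %in% genes)) stop_ctx("planted_pair genes not in codeset")
    i <- match(pp$genes[1], rownames(counts))
    j <- match(pp$genes[2], rownames(counts))
    want <- stats::runif(n) < ifelse(group == "GP3", pp$p_a, pp$p_b)
    for (s in seq_len(n)) {
      if (counts[i, s] == counts[j, s]) counts[i, s] <- counts[i, s] + 1
      have <- counts[i, s] > counts[j, s]
      if (have != want[s]) {
        tmp <- counts[i, s]; counts[i, s] <- counts[j, s]; counts[j, s] <- tmp
      }
    }
    pair_truth <- list(genes = pp$genes, p_a = pp$p_a, p_b = pp$p_b)
  }

  meta <- data.frame(
    lane_id = lane_ids,
    binding_density = round(stats::runif(n, 0.2, 1.8), 2),
    fov_counted = 280, fov_attempted = 280,
    group = group, stringsAsFactors = FALSE
  )
  cm <- count_matrix(counts, codeset, meta)
  truth <- list(
    lane_factor = stats::setNames(lane_factor, lane_ids),
    log2_fc = lfc,
    baseline_log2 = stats::setNames(base, genes),
    planted_pair = pair_truth,
    group = stats::setNames(group, lane_ids),
    seed = params$seed
  )
  list(counts = cm, truth = truth)
}

#' Deterministic two-gene ordering fixture
#'
#' Builds a two-gene count matrix over `n_a` group-A (GP3) and `n_b`
#' group-B (GP4) samples in which the within-sample ordering
#' `gene1 > gene2` holds in exactly `k_a` group-A and exactly `k_b`
#' group-B samples. All values are strictly positive with no within-sample
#' ties, so ordering counts are exact by construction. This reproduces
#' worked-example geometry for the top-scoring-pair statistics: with
#' `construct_tsp_fixture(13, 18, 10, 4)` the pair score is
#' |10/13 - 4/18| = 0.547 and the ordering rule classifies 24 of 31
#' samples correctly.
#'
#' @param n_a,n_b samples per group.
#' @param k_a,k_b samples per group in which `gene1 > gene2` must hold.
#' @return A [count_matrix()] with endogenous probes `gene1` and `gene2`;
#'   the control probes exist only in the attached codeset, not as count
#'   rows — the fixture serves the pair statistics, not normalization.
#' @export
construct_tsp_fixture <- function(n_a, n_b, k_a, k_b) {
  if (k_a > n_a || k_b > n_b || min(n_a, n_b, k_a, k_b) < 0) {
    stop_ctx("infeasible ordering counts: need 0 <= k_a <= n_a, 0 <= k_b <= n_b")
  }
  n <- n_a + n_b
  ordered <- c(seq_len(n_a) <= k_a, seq_len(n_b) <= k_b)
  g2 <- 100 + seq_len(n) * 3          # distinct strictly positive baselines
  g1 <- ifelse(ordered, g2 + 10, g2 - 10)
  counts <- rbind(gene1 = g1, gene2 = g2)
  lane_ids <- c(sprintf("A-%02d", seq_len(n_a)), sprintf("B-%02d", seq_len(n_b)))
  colnames(counts) <- lane_ids
  cs <- data.frame(
    probe_name = c("gene1", "gene2",
                   sprintf("POS_%s", LETTERS[1:6]), sprintf("NEG_%s", LETTERS[1:8])),
    probe_class = c("endogenous", "endogenous", rep("positive", 6),
                    rep("negative", 8)),
    concentration = c(NA, NA, c(128, 32, 8, 2, 0.5, 0.128), rep(NA, 8)),
    stringsAsFactors = FALSE
  )
  class(cs) <- c("codeset", "data.frame")
  meta <- data.frame(
    lane_id = lane_ids, binding_density = 1.0,
    fov_counted = 280, fov_attempted = 280,
    group = rep(c("GP3", "GP4"), c(n_a, n_b)), stringsAsFactors = FALSE
  )
  count_matrix(counts, cs, meta)
}
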