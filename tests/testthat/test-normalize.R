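pos_cm <- function(lane_counts) {
  # lanes given as a list of 6-vectors of positive counts, plus one
  # endogenous row so the container is non-degenerate
  counts <- rbind(
    g1 = rep(10, length(lane_counts)),
    do.call(cbind, lane_counts))
  rownames(counts) <- c("g1", sprintf("POS_%s", LETTERS[1:6]))
  colnames(counts) <- paste0("L", seq_along(lane_counts))
  manual_cm(counts, c("endogenous", rep("positive", 6)),
            conc = c(NA, 128, 32, 8, 2, 0.5, 0.128))
}

test_that("positive factors follow the grand/lane geometric-mean rule", {
  cm <- pos_cm(list(rep(100, 6), rep(400, 6)))
  pf <- positive_factors(cm)
  expect_equal(pf$pos_factor, c(2, 0.5))  # G = 200 = geomean(100, 400)
  # symmetry: identical lanes get factor 1
  cm2 <- pos_cm(list(c(800, 200, 50, 12, 3, 1), c(800, 200, 50, 12, 3, 1),
                     c(800, 200, 50, 12, 3, 1)))
  expect_equal(positive_factors(cm2)$pos_factor, rep(1, 3))
  # out-of-range flag: lanes at 4 and 49 give factors sqrt(49/4) = 3.5
  # and 2/7, both outside [0.3, 3]
  cm3 <- pos_cm(list(rep(4, 6), rep(49, 6)))
  pf3 <- positive_factors(cm3)
  expect_equal(pf3$pos_factor, c(3.5, 2 / 7))
  expect_false(any(pf3$pos_in_range))
  expect_error(positive_factors(pos_cm(list(c(0, 1, 1, 1, 1, 1)))),
               "lane 'L1'")
})

test_that("background is the lane mean of negatives, floored at zero", {
  counts <- rbind(
    matrix(c(12, 3), 2, 1, dimnames = list(c("gA", "gB"), "L1")),
    matrix(c(4, 6, 8, 2, 4, 6, 8, 2), 8, 1,
           dimnames = list(sprintf("NEG_%s", LETTERS[1:8]), "L1")))
  cm <- manual_cm(counts, c("endogenous", "endogenous", rep("negative", 8)))
  bg <- subtract_background(cm)
  expect_equal(bg$background[["L1"]], 5)
  expect_equal(unname(bg$values["gA", 1]), 7)
  expect_equal(unname(bg$values["gB", 1]), 0)  # floored
  expect_true(bg$missing["gB", 1])
  expect_false(bg$missing["gA", 1])
  # zero negatives: values unchanged, nothing positive masked
  counts0 <- counts; counts0[3:10, ] <- 0
  bg0 <- subtract_background(manual_cm(counts0, c("endogenous",
                                                  "endogenous",
                                                  rep("negative", 8))))
  expect_equal(bg0$values, counts0[1:2, , drop = FALSE])
  expect_false(any(bg0$missing[counts0[1:2, , drop = FALSE] > 0]))
})

test_that("content factors use each lane's own top-n pool", {
  set.seed(8)
  v <- matrix(rlnorm(200 * 2, 5, 1), 200, 2,
              dimnames = list(sprintf("g%03d", 1:200), c("L1", "L2")))
  v[, 2] <- v[, 1] * 2  # lane 2 is lane 1 doubled
  cf <- content_factors(v, top_n = 75)
  expect_equal(cf$content_factor, c(sqrt(2), 1 / sqrt(2)))
  # identical lanes: all factors 1
  v2 <- cbind(L1 = v[, 1], L2 = v[, 1], L3 = v[, 1])
  expect_equal(content_factors(v2, 75)$content_factor, rep(1, 3))
  # out-of-range flag
  v3 <- cbind(L1 = v[, 1], L2 = v[, 1] / 150)
  cf3 <- content_factors(v3, 75)
  expect_false(cf3$content_in_range[2])
  # unevaluable lane: too few nonzero values
  v4 <- cbind(L1 = v[, 1], L2 = c(rep(1, 50), rep(0, 150)))
  cf4 <- content_factors(v4, 75)
  expect_false(cf4$content_evaluable[2])
  expect_true(is.na(cf4$content_factor[2]))
})

test_that("missingness filters respect threshold, strictness and order", {
  v <- matrix(1, 4, 4, dimnames = list(paste0("g", 1:4), paste0("s", 1:4)))
  m <- matrix(FALSE, 4, 4, dimnames = dimnames(v))
  m[1:3, 1] <- TRUE  # s1 missing 3/4 genes
  f <- filter_missing(v, m, 0.5, "samples_then_genes")
  expect_false("s1" %in% colnames(f$values))
  expect_equal(f$ledger$entity, "s1")
  # exactly 50% is not strictly greater: survives
  m2 <- matrix(FALSE, 4, 4, dimnames = dimnames(v))
  m2[1:2, 1] <- TRUE
  expect_equal(ncol(filter_missing(v, m2, 0.5)$values), 4)
  # second pass runs on the matrix left by the first
  m3 <- matrix(FALSE, 4, 4, dimnames = dimnames(v))
  m3[1:3, 1] <- TRUE        # s1 dies first
  m3[2, c(2, 3)] <- TRUE    # g2 then missing 2/3 of remaining samples
  f3 <- filter_missing(v, m3, 0.5, "samples_then_genes")
  expect_setequal(f3$ledger$entity, c("s1", "g2"))
  expect_equal(dim(f3$values), c(3, 3))
})

test_that("filter order changes the survivor set where it should", {
  # hand-enumerated 3x4 case where the two orders disagree
  v <- matrix(1, 3, 4, dimnames = list(paste0("g", 1:3), paste0("s", 1:4)))
  m <- matrix(FALSE, 3, 4, dimnames = dimnames(v))
  m[1, c(1, 2, 3)] <- TRUE  # g1: 3/4 missing
  m[2, 1] <- TRUE; m[3, 1] <- TRUE  # s1: 3/3 missing
  # genes first: g1 dies (3/4); then s1 has 2/2 missing among g2,g3 -> dies
  fg <- filter_missing(v, m, 0.5, "genes_then_samples")
  expect_setequal(rownames(fg$values), c("g2", "g3"))
  expect_setequal(colnames(fg$values), c("s2", "s3", "s4"))
  # samples first: s1 dies (3/3); then g1 has 2/3 missing -> dies too,
  # but the LEDGER attributes the removals in a different order/stage
  fs <- filter_missing(v, m, 0.5, "samples_then_genes")
  expect_equal(fs$ledger$entity[1], "s1")
  expect_equal(fg$ledger$entity[1], "g1")
  # and a case where survivor sets differ between orders:
  v2 <- matrix(1, 3, 4, dimnames = dimnames(v))
  m2 <- matrix(FALSE, 3, 4, dimnames = dimnames(v))
  m2[1, 1:3] <- TRUE   # g1 missing 3/4
  m2[2:3, 4] <- TRUE   # s4 missing 2/3
  # genes first: g1 dies; s4 then missing 2/2 -> dies. survivors 2x3.
  # samples first: s4 dies (2/3 > .5); g1 then missing 3/3 -> dies; same
  # here, so tighten: s4 missing only g2
  m3 <- matrix(FALSE, 3, 4, dimnames = dimnames(v))
  m3[1, 1:3] <- TRUE
  m3[2, 4] <- TRUE
  fg3 <- filter_missing(v, m3, 0.5, "genes_then_samples")
  # g1 dies; s4 then missing 1/2 = 50%, survives
  expect_setequal(colnames(fg3$values), paste0("s", 1:4))
  fs3 <- filter_missing(v, m3, 0.5, "samples_then_genes")
  # no sample exceeds 50% over 3 genes (s1..s3 miss 1/3, s4 1/3); g1 dies
  expect_setequal(colnames(fs3$values), paste0("s", 1:4))
  expect_error(filter_missing(v, matrix(TRUE, 3, 4), 0.5), "empty after")
})

test_that("full normalization equals the manual chaining of its steps", {
  sim <- small_cohort(seed = 31, n_a = 6, n_b = 6, n_genes = 90,
                      dropout = 0.1)
  cm <- sim$counts
  nm <- normalize_counts(cm, top_n = 50)
  pf <- positive_factors(cm)
  scaled <- sweep(cm$counts, 2, pf$pos_factor, "*")
  gidx <- grep("^GENE", rownames(scaled))
  nidx <- grep("^NEG", rownames(scaled))
  b <- colMeans(scaled[nidx, ])
  corr <- pmax(sweep(scaled[gidx, ], 2, b, "-"), 0)
  cf <- content_factors(corr, 50)
  manual <- sweep(corr, 2, cf$content_factor, "*")
  flt <- filter_missing(manual, corr == 0, 0.5, "samples_then_genes")
  expect_equal(nm$values, flt$values)
  expect_equal(nm$missing, flt$missing)
})

test_that("planted lane factors are inverted by normalization", {
  base <- rep(8, 60)
  sim <- simulate_cohort(
    generate_codeset(60, 0),
    sim_params(n_group_a = 5, n_group_b = 5, lane_factor_sigma = 0.4,
               dispersion = 0, dropout_prob = 0, background_lambda = 0,
               baseline_log2 = base, seed = 17))
  nm <- normalize_counts(sim$counts, top_n = 40)
  # with no dropout and Poisson noise at mean 256, normalized per-gene
  # profiles agree across lanes up to sampling noise
  cv <- apply(nm$values, 1, function(v) sd(v) / mean(v))
  raw <- sim$counts$counts[grep("^GENE", rownames(sim$counts$counts)), ]
  cv_raw <- apply(raw, 1, function(v) sd(v) / mean(v))
  expect_lt(median(cv), median(cv_raw))  # factors removed lane spread
  # and the content factors recover the planted factors up to a constant
  f <- nm$factors$pos_factor * nm$factors$content_factor
  lf <- sim$truth$lane_factor[nm$factors$lane_id]
  rel <- f * lf
  expect_lt(max(abs(rel / mean(rel) - 1)), 0.05)
})

test_that("a 20x-scale lane is gated out by its content factor", {
  sim <- small_cohort(seed = 23, n_a = 5, n_b = 5, n_genes = 80,
                      dropout = 0)
  cm <- sim$counts
  # plant an extreme lane: only gene content scaled, controls left alone,
  # so the content factor (not the positive factor) must catch it
  gidx <- grep("^GENE", rownames(cm$counts))
  cm$counts[gidx, 1] <- cm$counts[gidx, 1] * 400
  nm <- normalize_counts(cm, top_n = 40)
  lane1 <- cm$lane_meta$lane_id[1]
  expect_true(lane1 %in% nm$ledger$entity[nm$ledger$stage ==
                                            "content factor gate"])
  expect_false(lane1 %in% colnames(nm$values))
})

test_that("factor geometric means are exactly one and ledger conserves", {
  for (s in c(51, 52, 53)) {
    sim <- small_cohort(seed = s, n_a = 8, n_b = 8, n_genes = 100,
                        dropout = 0.25)
    nm <- normalize_counts(sim$counts, top_n = 60)
    expect_equal(exp(mean(log(nm$factors$pos_factor))), 1, tolerance = 1e-12)
    f <- nm$factors$content_factor
    expect_equal(exp(mean(log(f[!is.na(f)]))), 1, tolerance = 1e-12)
    # ledger conservation, per axis
    n_lane_out <- sum(nm$ledger$axis == "lane")
    n_gene_out <- sum(nm$ledger$axis == "gene")
    expect_equal(ncol(nm$values) + n_lane_out, 16)
    expect_equal(nrow(nm$values) + n_gene_out, 100)
  }
})

test_that("scaling one lane rescales the matrix by one global constant", {
  # multiplying a lane's raw counts by c multiplies every lane's
  # normalized values by exactly c^(1/L): the grand geometric means in
  # both factor constructions each absorb c^(1/L). Relative expression
  # is therefore exactly invariant.
  sim <- small_cohort(seed = 61, n_a = 5, n_b = 5, n_genes = 80,
                      dropout = 0)
  cm <- sim$counts
  nm0 <- normalize_counts(cm, top_n = 50, apply_filters = FALSE)
  cm2 <- cm
  cm2$counts[, 3] <- cm2$counts[, 3] * 2
  nm2 <- normalize_counts(cm2, top_n = 50, apply_filters = FALSE)
  L <- ncol(cm$counts)
  expect_equal(nm2$values, nm0$values * 2^(1 / L), tolerance = 1e-10)
  # the scaled lane's own profile is unchanged relative to the cohort
  # (ratio checked where the floor at zero leaves a nonzero value)
  nz <- nm0$values[, 3] > 0
  expect_equal(nm2$values[nz, 3] / nm0$values[nz, 3],
               rep(2^(1 / L), sum(nz)), tolerance = 1e-10,
               ignore_attr = TRUE)
})

test_that("housekeeping content basis is available but not the default", {
  sim <- simulate_cohort(
    generate_codeset(50, 5),
    sim_params(n_group_a = 5, n_group_b = 5, dropout_prob = 0,
               dispersion = 0.1, baseline_log2 = 8,
               lane_factor_sigma = 0.4, seed = 93))
  nm_hk <- normalize_counts(sim$counts, top_n = 30,
                            content_basis = "housekeeping")
  nm_top <- normalize_counts(sim$counts, top_n = 30)
  expect_equal(nm_top$config$content_basis, "top_n")
  # both bases invert the planted lane factors up to probe-sampling
  # noise: the combined factor tracks 1/lane_factor tightly in log space
  for (nm in list(nm_hk, nm_top)) {
    f <- nm$factors$pos_factor * nm$factors$content_factor
    lf <- sim$truth$lane_factor[nm$factors$lane_id]
    expect_gt(cor(log(f), -log(lf)), 0.9)
  }
  # the housekeeping summary pools 5 probes, so its factors are noisier
  expect_false(identical(nm_hk$factors$content_factor,
                         nm_top$factors$content_factor))
  expect_error(
    normalize_counts(simulate_cohort(generate_codeset(20, 0),
                                     sim_params(n_group_a = 3, n_group_b = 3,
                                                seed = 1))$counts,
                     top_n = 10, content_basis = "housekeeping"),
    "housekeeping")
})
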