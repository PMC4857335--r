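fixture_31 <- construct_tsp_fixture(13, 18, 10, 4)

test_that("pair score is the between-class ordering-frequency gap", {
  fx <- fixture_31
  ps <- pair_score(fx$counts["gene1", ], fx$counts["gene2", ],
                   fx$lane_meta$group)
  expect_equal(ps$score, abs(10 / 13 - 4 / 18))
  expect_equal(round(ps$score, 3), 0.547)
  expect_equal(ps$orientation, "GP3")
  # equal proportions give zero; perfect asymmetry gives one
  fx0 <- construct_tsp_fixture(10, 10, 5, 5)
  expect_equal(pair_score(fx0$counts[1, ], fx0$counts[2, ],
                          fx0$lane_meta$group)$score, 0)
  fx1 <- construct_tsp_fixture(5, 5, 5, 0)
  ps1 <- pair_score(fx1$counts[1, ], fx1$counts[2, ],
                    fx1$lane_meta$group)
  expect_equal(ps1$score, 1)
  expect_equal(ps1$orientation, "GP3")
  expect_error(pair_score(1:4, 1:4, rep("A", 4)), "two groups")
})

test_that("ties count against the ordering indicator", {
  x_i <- c(5, 5, 7, 1)
  x_j <- c(5, 4, 3, 2)  # sample 1 tied -> indicator FALSE
  lab <- c("A", "A", "B", "B")
  ps <- pair_score(x_i, x_j, lab)
  expect_equal(unname(ps$p_by_class), c(0.5, 0.5))
  expect_equal(ps$score, 0)
})

test_that("search equals exhaustive enumeration on random matrices", {
  for (s in 1:50) {
    set.seed(900 + s)
    v <- matrix(rpois(30 * 20, 40), 30, 20,
                dimnames = list(sprintf("g%02d", 1:30), sprintf("s%02d", 1:20)))
    lab <- sample(rep(c("GP3", "GP4"), 10))
    fit <- tsp_search(v, lab)
    oracle <- brute_force_tsp(v, lab)
    expect_equal(fit$score, oracle$score)
    # the oracle keeps the first maximal pair in scan order; the search
    # must agree on the score and, when unique, on the pair itself
    n_max <- 0
    for (i in 1:29) for (j in (i + 1):30) {
      if (abs(pair_score(v[i, ], v[j, ], lab)$score - oracle$score) < 1e-12)
        n_max <- n_max + 1
    }
    if (n_max == 1) expect_equal(sort(fit$pair), sort(oracle$pair))
  }
})

test_that("score ties break on the secondary rank score", {
  # two planted pairs with identical indicator split but different
  # within-sample rank gaps
  v <- rbind(
    a1 = c(100, 100, 100, 100, 10, 10, 10, 10),
    c1 = c(90, 90, 90, 90, 20, 20, 20, 20),
    c2 = c(80, 80, 80, 80, 30, 30, 30, 30),
    a2 = c(50, 50, 50, 50, 60, 60, 60, 60))
  # every pair scores 1 (all orderings flip between classes), but the
  # within-sample rank gap of (a1, a2) spans the whole rank range in
  # both classes, so its secondary score (6) is strictly maximal
  colnames(v) <- paste0("s", 1:8)
  lab <- rep(c("A", "B"), each = 4)
  fit <- tsp_search(v, lab)
  expect_equal(fit$score, 1)
  expect_setequal(fit$pair, c("a1", "a2"))
})

test_that("classification on the worked-example fixture is 24/31", {
  fit <- tsp_search(fixture_31$counts, fixture_31$lane_meta$group)
  expect_equal(round(fit$score, 3), 0.547)
  pred <- predict(fit)
  acc <- mean(pred == fixture_31$lane_meta$group)
  expect_equal(acc, 24 / 31)
  expect_equal(round(100 * acc, 1), 77.4)
  # perfect-separation fixture classifies everything
  fx1 <- construct_tsp_fixture(6, 6, 6, 0)
  fit1 <- tsp_search(fx1$counts, fx1$lane_meta$group)
  expect_equal(fit1$accuracy, 1)
})

test_that("within-sample ties classify to the majority class, logged", {
  fx <- construct_tsp_fixture(13, 18, 10, 4)
  fit <- tsp_search(fx$counts, fx$lane_meta$group)
  nd <- fx$counts[, 1:3]
  nd["gene1", 2] <- nd["gene2", 2]  # force a tie
  expect_message(pred <- predict(fit, nd), "majority class GP4")
  expect_equal(unname(pred[2]), "GP4")  # 18 GP4 vs 13 GP3 in training
  expect_equal(attr(pred, "ties"), colnames(nd)[2])
  expect_error(predict(fit, nd[1, , drop = FALSE]), "unclassifiable")
})

test_that("monotone per-sample transforms leave the TSP analysis fixed", {
  set.seed(77)
  v <- matrix(rpois(25 * 16, 30), 25, 16,
              dimnames = list(sprintf("g%02d", 1:25), sprintf("s%02d", 1:16)))
  lab <- rep(c("GP3", "GP4"), 8)
  fit0 <- tsp_search(v, lab)
  pred0 <- suppressMessages(predict(fit0, v))
  for (k in 1:20) {
    a <- runif(16, 0.5, 4); b <- runif(16, 0, 10); pw <- runif(16, 0.5, 3)
    v2 <- sweep(sweep(v^rep(pw, each = 25), 2, a, "*"), 2, b, "+")
    dimnames(v2) <- dimnames(v)
    fit2 <- tsp_search(v2, lab)
    expect_equal(fit2$pair, fit0$pair)
    expect_equal(fit2$score, fit0$score)
    expect_equal(unname(suppressMessages(predict(fit2, v2))), unname(pred0))
  }
})

test_that("permutation p matches the exact hypergeometric tail", {
  fx <- fixture_31
  grp <- fx$lane_meta$group
  ex <- tsp_exact_pair_p(fx$counts["gene1", ], fx$counts["gene2", ], grp)
  expect_equal(ex$p, sum(dhyper(10:13, 14, 17, 13)) +
                 sum(dhyper(0:1, 14, 17, 13)))
  expect_equal(ex$p, 0.0039794, tolerance = 1e-5)
  pm <- tsp_permutation_p(fx$counts, grp, n_permutations = 20000,
                          seed = 15, mode = "fixed_pair")
  se <- sqrt(ex$p * (1 - ex$p) / 20000)
  expect_lt(abs(pm$p - ex$p), 3 * se)
  expect_gt(pm$p_corrected, 0)
  expect_error(tsp_permutation_p(fx$counts, grp, 50), "meaningless")
})

test_that("full-search permutation p is reproducible and bounded", {
  set.seed(88)
  v <- matrix(rpois(15 * 14, 25), 15, 14,
              dimnames = list(sprintf("g%02d", 1:15), sprintf("s%02d", 1:14)))
  lab <- rep(c("GP3", "GP4"), 7)
  p1 <- tsp_permutation_p(v, lab, 500, seed = 2)
  p2 <- tsp_permutation_p(v, lab, 500, seed = 2)
  expect_identical(p1$null_scores, p2$null_scores)
  expect_identical(p1$p, p2$p)
  expect_gt(p1$p_corrected, 0)
  expect_true(all(p1$null_scores >= 0 & p1$null_scores <= 1))
  # observed score is one of the achievable values: p is never > 1
  expect_lte(p1$p, 1)
})
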