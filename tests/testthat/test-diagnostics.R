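# brute-force oracle: (concordant pairs + half ties) / (m * n)
pair_auc <- function(cases, controls) {
  s <- 0
  for (x in cases) for (y in controls) s <- s + (x > y) + 0.5 * (x == y)
  s / (length(cases) * length(controls))
}

test_that("exact binomial intervals behave at the boundaries and contain the estimate", {
  expect_equal(unname(clopper_pearson(0, 10)[1]), 0)
  expect_equal(unname(clopper_pearson(10, 10)[2]), 1)
  for (k in c(0, 3, 7, 10)) {
    ci <- clopper_pearson(k, 10)
    expect_true(ci[1] <= k / 10 && k / 10 <= ci[2])
  }
  # interval width shrinks with n at a fixed proportion
  w <- sapply(c(20, 80, 320), function(n) diff(clopper_pearson(n * 0.75, n)))
  expect_true(all(diff(w) < 0))
  # cross-check against the exact binomial test
  for (k in c(2, 17, 28)) {
    expect_equal(unname(clopper_pearson(k, 30)),
                 as.numeric(binom.test(k, 30)$conf.int), tolerance = 1e-10)
  }
  expect_error(clopper_pearson(5, 4), "successes")
  expect_error(clopper_pearson(1, 10, level = 1.2), "level")
})

test_that("empirical ROC AUC equals the pair-counting oracle and handles limits", {
  # perfect separation
  roc <- empirical_roc(c(10, 12, 11, 3, 4, 2), c(TRUE, TRUE, TRUE, FALSE, FALSE, FALSE))
  expect_equal(roc$auc, 1)
  # no signal at large n
  set.seed(8)
  s <- rnorm(4000); y <- rep(c(TRUE, FALSE), 2000)
  expect_equal(empirical_roc(s, y)$auc, 0.5, tolerance = 0.05)
  # random small instances vs the brute-force pair statistic (heavy ties)
  set.seed(9)
  for (i in 1:40) {
    m <- sample(2:6, 1); n <- sample(2:6, 1)
    sc <- sample(0:6, m + n, replace = TRUE)
    y <- c(rep(TRUE, m), rep(FALSE, n))
    expect_equal(empirical_roc(sc, y)$auc, pair_auc(sc[y], sc[!y]))
  }
  expect_error(empirical_roc(c(1, 2), c(TRUE, TRUE)), "case and")
})

test_that("empirical ROC agrees with an independent ROC implementation", {
  skip_if_not_installed("pROC")
  set.seed(12)
  for (i in 1:10) {
    sc <- sample(0:25, 30, replace = TRUE)
    y <- rbinom(30, 1, 0.5)
    if (length(unique(y)) < 2) next
    ours <- empirical_roc(sc, y == 1)$auc
    ref <- as.numeric(pROC::auc(pROC::roc(y, sc, quiet = TRUE, direction = "<")))
    expect_equal(ours, ref, tolerance = 1e-10)
  }
})

test_that("Youden cut-off matches exhaustive search, ties broken upward", {
  roc <- empirical_roc(c(10, 12, 3, 4), c(TRUE, TRUE, FALSE, FALSE))
  expect_equal(roc$optimal_cutoff, 7)  # midpoint of (4, 10), J = 1
  j <- roc$sensitivity + roc$specificity - 1
  expect_equal(max(j), 1)

  set.seed(21)
  for (i in 1:20) {
    sc <- sample(0:10, 12, replace = TRUE)
    y <- c(rep(TRUE, 6), rep(FALSE, 6))
    roc <- empirical_roc(sc, y)
    grid <- sort(unique(c(-Inf, Inf, seq(-0.5, 10.5, by = 0.5))))
    j_grid <- sapply(grid, function(t) mean(sc[y] > t) + mean(sc[!y] <= t) - 1)
    expect_equal(mean(sc[y] > roc$optimal_cutoff) + mean(sc[!y] <= roc$optimal_cutoff) - 1,
                 max(j_grid), tolerance = 1e-12)
  }

  # degenerate: all scores equal -> J = 0 everywhere, +Inf sentinel by tie rule
  roc <- empirical_roc(rep(5, 6), c(TRUE, TRUE, TRUE, FALSE, FALSE, FALSE))
  expect_equal(roc$optimal_cutoff, Inf)
})

test_that("sensitivity and specificity at a cut-off are direct counts with exact CIs", {
  sc <- c(rep(10:14, length.out = 5), 2:13)          # 5 cases, 12 controls
  y <- c(rep(TRUE, 5), rep(FALSE, 12))
  ss <- sens_spec_at(sc, y, cutoff = 6)
  expect_equal(ss$estimate[ss$measure == "sensitivity"], 1)
  expect_equal(ss$estimate[ss$measure == "specificity"], sum(2:13 <= 6) / 12)
  expect_equal(unname(unlist(ss[1, c("lower", "upper")])),
               unname(clopper_pearson(5, 5)))
  # cut-off above every score
  ss <- sens_spec_at(sc, y, cutoff = 99)
  expect_equal(ss$estimate, c(0, 1))
})

test_that("cut-offs 8.5 and 8 classify integer scores identically", {
  set.seed(2)
  sc <- sample(0:29, 100, replace = TRUE)
  y <- rbinom(100, 1, 0.6) == 1
  expect_identical(sc > 8.5, sc > 8)
  expect_equal(sens_spec_at(sc, y, 8.5)[, c("estimate", "lower", "upper")],
               sens_spec_at(sc, y, 8)[, c("estimate", "lower", "upper")])
})

test_that("AUC significance is calibrated against a permutation oracle", {
  # constructed null: all scores tied -> AUC exactly 0.5, p = 1
  roc <- empirical_roc(rep(3, 10), rep(c(TRUE, FALSE), 5))
  expect_equal(auc_significance(roc)$p_value, 1)
  # perfect separation -> overwhelming evidence
  roc <- empirical_roc(c(11:20, 1:8), c(rep(TRUE, 10), rep(FALSE, 8)))
  expect_lt(auc_significance(roc)$p_value, 1e-4)
  # weak-signal toy instance vs a label-permutation reference (the
  # asymptotic and permutation nulls coincide away from the extreme tail)
  set.seed(31)
  sc <- round(c(rnorm(15, 0.35), rnorm(15, 0)), 1)
  y <- c(rep(TRUE, 15), rep(FALSE, 15))
  p_asy <- auc_significance(empirical_roc(sc, y))$p_value
  obs <- abs(pair_auc(sc[y], sc[!y]) - 0.5)
  perm <- replicate(4000, {
    yp <- sample(y)
    abs(pair_auc(sc[yp], sc[!yp]) - 0.5)
  })
  p_perm <- mean(perm >= obs - 1e-12)
  expect_equal(p_asy, p_perm, tolerance = 0.1)
})

test_that("paired DeLong comparison is coherent", {
  set.seed(41)
  y <- c(rep(TRUE, 12), rep(FALSE, 10))
  a <- ifelse(y, rnorm(22, 2), rnorm(22))
  # identical scores: zero difference, p = 1
  same <- delong_paired_compare(a, a, y)
  expect_equal(same$difference, 0)
  expect_equal(same$p_value, 1)
  # sign of the difference matches direct AUC computation
  b <- -a
  cmp <- delong_paired_compare(a, b, y)
  expect_equal(cmp$difference, pair_auc(a[y], a[!y]) - pair_auc(b[y], b[!y]))
  expect_lt(cmp$auc_b, 0.5)
  expect_error(delong_paired_compare(a[-1], a, y), "length")
})

test_that("paired DeLong agrees with pROC's implementation", {
  skip_if_not_installed("pROC")
  set.seed(51)
  y <- rbinom(40, 1, 0.5)
  a <- rnorm(40) + y; b <- rnorm(40) + 0.5 * y
  ours <- delong_paired_compare(a, b, y == 1)
  ref <- pROC::roc.test(pROC::roc(y, a, quiet = TRUE, direction = "<"),
                        pROC::roc(y, b, quiet = TRUE, direction = "<"),
                        method = "delong", paired = TRUE)
  expect_equal(ours$p_value, ref$p.value, tolerance = 1e-8)
})
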