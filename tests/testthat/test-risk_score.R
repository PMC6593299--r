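make_logfpm <- function(values, features, samples = NULL) {
  if (is.null(samples)) samples <- sprintf("S%02d", seq_len(ncol(values)))
  matrix(values, nrow = length(features), dimnames = list(features, samples))
}

test_that("polygenic score is the weighted sum of panel log-FPM values", {
  L <- make_logfpm(rbind(c(5, 1), c(4, 2)), c("a", "b"))
  rs <- polygenic_score(L, c(a = -2, b = 3))
  expect_equal(unname(rs$score), c(-2 * 5 + 3 * 4, -2 * 1 + 3 * 2))

  # single-miRNA panel with weight 1 reduces to that miRNA's log-FPM
  rs1 <- polygenic_score(L, c(a = 1))
  expect_equal(rs1$score, L["a", ])

  expect_equal(unname(polygenic_score(L, c(a = 0, b = 0))$score), c(0, 0))
  expect_error(polygenic_score(L, c(zzz = 1)), "zzz")
})

test_that("score is linear in the weights and AUC invariant to positive scaling", {
  set.seed(41)
  L <- make_logfpm(matrix(runif(5 * 21, 0, 12), nrow = 5), paste0("m", 1:5))
  w <- setNames(rnorm(5), paste0("m", 1:5))
  labels <- rep(c("DR", "NDR"), c(10, 11))
  s1 <- polygenic_score(L, w)$score
  s3 <- polygenic_score(L, 3 * w)$score
  expect_equal(s3, 3 * s1)
  expect_equal(auc(s3, labels, "DR"), auc(s1, labels, "DR"))
})

test_that("midrank AUC equals brute-force pair counting, ties included", {
  expect_equal(auc(c(5, 6, 1, 2), c("c", "c", "n", "n"), "c"), 1)
  expect_equal(auc(rep(2, 6), rep(c("c", "n"), 3), "c"), 0.5)

  set.seed(42)
  for (rep in 1:25) {
    ncase <- sample(2:10, 1)
    nctrl <- sample(2:10, 1)
    s <- c(sample(1:8, ncase, TRUE), sample(1:8, nctrl, TRUE))  # forced ties
    lab <- rep(c("case", "ctrl"), c(ncase, nctrl))
    expect_equal(auc(s, lab, "case"),
                 auc_pairs(s[lab == "case"], s[lab == "ctrl"]))
  }
})

test_that("AUC: label-flip antisymmetry and monotone-transform invariance", {
  set.seed(43)
  s <- rnorm(21)
  lab <- rep(c("DR", "NDR"), c(10, 11))
  expect_equal(auc(s, lab, "DR") + auc(s, lab, "NDR"), 1)
  expect_equal(auc(exp(s), lab, "DR"), auc(s, lab, "DR"))
  expect_equal(auc(rank(s), lab, "DR"), auc(s, lab, "DR"))
  expect_error(auc(s, rep("DR", 21), "DR"), "both classes")
})

test_that("AUC agrees with pROC on random instances", {
  skip_if_not_installed("pROC")
  set.seed(44)
  for (rep in 1:10) {
    s <- round(rnorm(30), 1)
    lab <- sample(c("case", "ctrl"), 30, TRUE, prob = c(0.4, 0.6))
    if (length(unique(lab)) < 2) next
    ref <- suppressMessages(pROC::auc(pROC::roc(
      response = lab, predictor = s, levels = c("ctrl", "case"),
      direction = "<", quiet = TRUE)))
    expect_equal(auc(s, lab, "case"), as.numeric(ref))
  }
})

test_that("ROC curve: endpoints, mirror symmetry, trapezoid = Mann-Whitney", {
  r <- roc_curve(c(2, 1), c("case", "ctrl"), "case")
  expect_true(any(r$points$sensitivity == 1 & r$points$specificity == 1))

  set.seed(45)
  s <- rnorm(21)
  lab <- rep(c("DR", "NDR"), c(10, 11))
  expect_equal(roc_curve(s, lab, "DR")$auc + roc_curve(-s, lab, "DR")$auc, 1)

  for (rep in 1:20) {
    s <- sample(seq(0, 5, 0.5), 21, TRUE)   # with ties
    expect_equal(roc_curve(s, lab, "DR")$auc, auc(s, lab, "DR"),
                 tolerance = 1e-12)
  }

  # curve monotonicity along decreasing thresholds
  r2 <- roc_curve(rnorm(21), lab, "DR")
  expect_true(all(diff(r2$points$sensitivity) >= 0))
  expect_true(all(diff(1 - r2$points$specificity) >= 0))

  # auto orientation records the flip and reports AUC >= 0.5
  s_anti <- c(rnorm(10, 0), rnorm(11, 3))
  r3 <- roc_curve(s_anti, lab, "DR", direction = "auto")
  expect_identical(r3$direction, "case_low")
  expect_gte(r3$auc, 0.5)
  expect_equal(r3$auc, 1 - roc_curve(s_anti, lab, "DR")$auc)
})

test_that("Youden cutoff maximizes J with the documented tie-breaks", {
  r <- roc_curve(c(10, 11, 1, 2), rep(c("case", "ctrl"), each = 2), "case")
  y <- youden_cutoff(r)
  expect_equal(y$J, 1)
  expect_gt(y$cutoff, 2)
  expect_lt(y$cutoff, 10)

  # hand comparison of two candidate operating points
  pts <- data.frame(cutoff = c(-44, -40),
                    sensitivity = c(0.9, 0.8), specificity = c(0.909, 0.95))
  y2 <- youden_cutoff(pts)
  expect_equal(y2$sensitivity, 0.9)
  expect_equal(y2$J, 0.809, tolerance = 1e-12)

  # brute-force oracle over random instances
  set.seed(46)
  for (rep in 1:20) {
    cs <- rnorm(10, 1)
    ct <- rnorm(11)
    r <- roc_curve(c(cs, ct), rep(c("c", "n"), c(10, 11)), "c")
    expect_equal(youden_cutoff(r)$J, youden_bruteforce(cs, ct),
                 tolerance = 1e-12)
  }

  # tie in J and sensitivity resolved toward the lower cutoff
  pts3 <- data.frame(cutoff = c(3, 1), sensitivity = c(0.8, 0.8),
                     specificity = c(0.7, 0.7))
  expect_equal(youden_cutoff(pts3)$cutoff, 1)
})

test_that("DeLong interval: symmetry, narrowing under duplication, oracle", {
  # symmetric null data -> CI symmetric about 0.5
  s <- c(1, 2, 3, 4, 1, 2, 3, 4)
  lab <- rep(c("case", "ctrl"), each = 4)
  ci <- auc_confidence_interval(s, lab, "case")
  expect_equal(ci$auc, 0.5)
  expect_equal(ci$lower + ci$upper, 1, tolerance = 1e-12)

  set.seed(47)
  s2 <- c(rnorm(10, 1.2), rnorm(11))
  lab2 <- rep(c("case", "ctrl"), c(10, 11))
  ci1 <- auc_confidence_interval(s2, lab2, "case")
  ci2 <- auc_confidence_interval(rep(s2, 2), rep(lab2, 2), "case")
  expect_lt(ci2$upper - ci2$lower, ci1$upper - ci1$lower)

  # structural-components oracle on a 6-sample instance, by explicit loops
  cs <- c(3.1, 2.0, 4.5); ct <- c(1.0, 2.0, 3.5)
  psi <- matrix(0, 3, 3)
  for (i in 1:3) for (j in 1:3) {
    psi[i, j] <- (cs[i] > ct[j]) + 0.5 * (cs[i] == ct[j])
  }
  v_hand <- var(rowMeans(psi)) / 3 + var(colMeans(psi)) / 3
  ci3 <- auc_confidence_interval(c(cs, ct), rep(c("c", "n"), each = 3), "c")
  expect_equal(ci3$se^2, v_hand, tolerance = 1e-12)

  # perfectly separated tiny data degenerates; flagged
  ci4 <- auc_confidence_interval(c(10, 11, 12, 1, 2, 3),
                                 rep(c("c", "n"), each = 3), "c")
  expect_true(ci4$widened)
})

test_that("DeLong interval matches pROC and bootstrap is seed-stable", {
  skip_if_not_installed("pROC")
  set.seed(48)
  s <- rnorm(21) + rep(c(1, 0), c(10, 11))
  lab <- rep(c("case", "ctrl"), c(10, 11))
  ci <- auc_confidence_interval(s, lab, "case")
  ref <- suppressWarnings(pROC::ci.auc(pROC::roc(
    response = lab, predictor = s, levels = c("ctrl", "case"),
    direction = "<", quiet = TRUE), method = "delong"))
  expect_equal(c(ci$lower, ci$upper), as.numeric(ref)[c(1, 3)], tolerance = 1e-9)

  b1 <- auc_confidence_interval(s, lab, "case", method = "bootstrap",
                                n_boot = 200, seed = 9)
  b2 <- auc_confidence_interval(s, lab, "case", method = "bootstrap",
                                n_boot = 200, seed = 9)
  expect_identical(b1, b2)
})
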