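test_that("Wald test matches the published serum-miRNA table at printed precision", {
  # (LFC, SE) pairs of the five reported DE miRNAs; p printed to 3 decimals
  lfc <- c(-2.86, -2.60, 4.26, -3.04, -2.84)
  se <- c(1.05, 0.96, 1.58, 1.16, 1.09)
  w <- wald_test(lfc, se)
  expect_equal(round(w$p, 3), c(0.006, 0.007, 0.007, 0.009, 0.009))
  expect_equal(w$z, lfc / se)
})

test_that("Wald p is sign-symmetric, monotone in |z|, and guarded", {
  expect_equal(wald_test(0, 1)$p, 1)
  set.seed(21)
  lfc <- rnorm(50, sd = 3)
  se <- runif(50, 0.2, 2)
  w <- wald_test(lfc, se)
  expect_equal(w$p, wald_test(-lfc, se)$p)
  ord <- order(abs(w$z))
  expect_true(all(diff(w$p[ord]) <= 0))
  expect_error(wald_test(1, 0), "positive")
})

test_that("BH adjustment equals the brute-force step-up definition", {
  expect_equal(bh_adjust(0.037), 0.037)
  expect_equal(bh_adjust(c(0.01, 0.02, 0.03)), c(0.03, 0.03, 0.03))
  set.seed(22)
  for (rep in 1:50) {
    p <- runif(sample(1:40, 1))^sample(1:3, 1)
    expect_equal(bh_adjust(p), bh_bruteforce(p))
  }
  p <- runif(20)
  expect_true(all(bh_adjust(p) >= p & bh_adjust(p) <= 1))
  expect_error(bh_adjust(c(0.5, 1.2)), "\\[0, 1\\]")
})

test_that("DE calling applies raw-p and |LFC| thresholds jointly", {
  tab2 <- data.frame(
    mirna = c("miR-4448", "miR-338-3p", "miR-190a-5p", "miR-485-5p", "miR-9-5p"),
    lfc = c(-2.86, -2.60, 4.26, -3.04, -2.84),
    pvalue = c(0.006, 0.007, 0.007, 0.009, 0.009))
  expect_equal(nrow(call_de(tab2)), 5)

  edge <- data.frame(mirna = "x", lfc = 1.9, pvalue = 0.001)
  expect_equal(nrow(call_de(edge)), 0)
  # boundary: thresholds are inclusive
  expect_equal(nrow(call_de(data.frame(mirna = "y", lfc = -2, pvalue = 0.01))), 1)

  set.seed(23)
  tab <- data.frame(mirna = paste0("m", 1:200),
                    lfc = rnorm(200, sd = 2), pvalue = runif(200))
  got <- call_de(tab, 0.05, 1)
  expect_identical(got$mirna,
                   tab$mirna[tab$pvalue <= 0.05 & abs(tab$lfc) >= 1])
})

test_that("linear fold change is 2^|LFC| and covers the reported range", {
  expect_equal(lfc_to_fold_change(0), 1)
  expect_equal(round(lfc_to_fold_change(-2.60), 1), 6.1)
  expect_gte(lfc_to_fold_change(4.26), 19.1)
  expect_equal(lfc_to_fold_change(c(-3, 3)), c(8, 8))
})

test_that("NB GLM recovers Poisson closed forms as dispersion vanishes", {
  # intercept-only: exp(intercept) is the mean normalized count
  y <- c(12L, 20L, 15L, 9L, 17L, 11L)
  X <- cbind(intercept = rep(1, 6), group = c(0, 0, 0, 1, 1, 1))
  # two-group, unit size factors: LFC = log2 ratio of group means
  fit <- fit_nb_glm(y, X, rep(1, 6), alpha = 1e-8)
  expect_equal(fit$lfc, log2(mean(y[4:6]) / mean(y[1:3])), tolerance = 1e-6)
  expect_equal(2^fit$coefficients[["intercept"]], mean(y[1:3]), tolerance = 1e-5)
  expect_true(fit$converged)
})

test_that("NB GLM agrees with a Poisson GLM in the small-dispersion limit", {
  set.seed(24)
  y <- rpois(21, 40)
  X <- cbind(intercept = 1, group = rep(c(1, 0), c(10, 11)),
             age = c(rnorm(10, 47, 6), rnorm(11, 63, 4)))
  sf <- exp(rnorm(21, 0, 0.2))
  fit <- fit_nb_glm(y, X, sf, alpha = 1e-8)
  ref <- glm(y ~ X[, -1] + offset(log(sf)), family = poisson())
  expect_equal(unname(fit$coefficients * log(2)), unname(coef(ref)),
               tolerance = 1e-4)
})

test_that("NB GLM matches MASS glm(negative.binomial) at fixed dispersion", {
  skip_if_not_installed("MASS")
  set.seed(25)
  alpha <- 0.25
  x <- rep(c(1, 0), c(10, 11))
  age <- c(rnorm(10, 47, 6), rnorm(11, 63, 4))
  sf <- exp(rnorm(21, 0, 0.2))
  y <- rnbinom(21, mu = sf * 100 * 2^(1.5 * x), size = 1 / alpha)
  X <- cbind(intercept = 1, group = x, age = age)
  fit <- fit_nb_glm(y, X, sf, alpha)
  ref <- glm(y ~ x + age + offset(log(sf)),
             family = MASS::negative.binomial(theta = 1 / alpha),
             control = glm.control(epsilon = 1e-12, maxit = 100))
  expect_equal(unname(fit$coefficients * log(2)), unname(coef(ref)),
               tolerance = 1e-6)
  expect_equal(unname(fit$se_all * log(2)),
               unname(summary(ref, dispersion = 1)$coefficients[, 2]),
               tolerance = 1e-5)
})

test_that("dispersion estimator is consistent near Poisson and recovers alpha", {
  set.seed(26)
  y <- rpois(200, 1000)
  X <- cbind(intercept = 1, group = rep(0:1, 100))
  est <- estimate_dispersion(y, X, rep(1, 200))
  expect_identical(est$method, "CR")
  expect_lt(est$alpha, 0.05)

  # alpha = 0.5, 100 per group: estimate within [0.3, 0.7] in >= 90% of reps
  set.seed(27)
  hits <- vapply(1:200, function(i) {
    yy <- rnbinom(200, mu = 1000 * 2^(0.5 * X[, "group"]), size = 2)
    a <- estimate_dispersion(yy, X, rep(1, 200))$alpha
    a >= 0.3 && a <= 0.7
  }, logical(1))
  expect_gte(mean(hits), 0.9)
})

test_that("method-of-moments fallback floors when variance <= mean", {
  y <- rep(10L, 12)
  X <- cbind(intercept = 1, group = rep(0:1, 6))
  est <- estimate_dispersion(y, X, rep(1, 12), method = "mom")
  expect_identical(est$method, "mom")
  expect_equal(est$alpha, 1e-8)
})

test_that("nb_de returns a coherent table with BH over tested features", {
  suppressMessages({
    sim <- simulate_dataset(sim_params(n_features = 60, frac_de = 0.1), seed = 31)
    de <- nb_de(sim$counts, sim$samples)
  })
  expect_identical(de$mirna, rownames(sim$counts))
  tested <- de$converged
  expect_true(all(de$padj[tested] >= de$pvalue[tested]))
  expect_true(all(de$padj[tested] <= 1))
  expect_equal(de$padj[tested], bh_bruteforce(de$pvalue[tested]))
  expect_identical(de$de, de$mirna %in% call_de(de)$mirna)
  expect_true(all(is.na(de$pvalue[!tested])))
})
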