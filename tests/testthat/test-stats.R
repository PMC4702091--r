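test_that("Kruskal-Wallis H matches the brute-force rank formula", {
  g <- list(a = c(1, 2), b = c(3, 4), c = c(5, 6))
  res <- kruskalWallis(g)
  expect_equal(res$statistic, bruteKW(g), tolerance = 1e-12)
  expect_equal(res$statistic, 32 / 7, tolerance = 1e-12) # hand computation
  expect_equal(res$df, 2)
  expect_identical(res$statistic_name, "H")
  # with ties and unequal sizes
  set.seed(4)
  g2 <- list(x = c(1, 1, 2, 5), y = c(2, 3, 3), z = c(4, 4, 6, 7, 8))
  expect_equal(kruskalWallis(g2)$statistic, bruteKW(g2), tolerance = 1e-12)
})

test_that("identical distributions give H = 0, p = 1", {
  res <- kruskalWallis(list(c(1, 2, 3), c(1, 2, 3), c(1, 2, 3)))
  expect_equal(res$statistic, 0)
  expect_equal(res$p, 1)
})

test_that("two-group Kruskal-Wallis equals the squared MWU normal deviate", {
  set.seed(9)
  x <- rnorm(12); y <- rnorm(10) + 0.5
  h <- kruskalWallis(list(x = x, y = y))$statistic
  u <- pairwiseMannWhitney(list(x = x, y = y))$statistic
  n1 <- length(x); n2 <- length(y); n <- n1 + n2
  z <- (u - n1 * n2 / 2) / sqrt(n1 * n2 * (n + 1) / 12)
  expect_equal(h, z^2, tolerance = 1e-10)
})

test_that("Mann-Whitney U and exact p match full enumeration", {
  res <- pairwiseMannWhitney(list(a = c(1, 2, 3), b = c(4, 5, 6)))
  expect_equal(res$statistic, 0)
  expect_equal(res$p, 0.1, tolerance = 1e-12) # 2/20 arrangements
  expect_equal(res$p, bruteMWUP(c(1, 2, 3), c(4, 5, 6)), tolerance = 1e-12)
  set.seed(21)
  for (i in 1:5) {
    x <- sample(100, 5); y <- sample(200, 4) + 0.5
    got <- pairwiseMannWhitney(list(x = x, y = y))
    expect_equal(got$statistic, bruteU(x, y), tolerance = 1e-12)
    expect_equal(got$p, bruteMWUP(x, y), tolerance = 1e-12)
  }
})

test_that("Bonferroni adjustment multiplies and caps at 1", {
  res <- pairwiseMannWhitney(list(a = c(1, 2, 3), b = c(4, 5, 6)),
                             familySize = 3)
  expect_equal(res$p_adj, min(1, res$p * 3), tolerance = 1e-12)
  same <- pairwiseMannWhitney(list(a = c(1, 2, 3), b = c(1, 2, 3)))
  expect_equal(same$p_adj, 1)
  # three groups: family defaults to the 3 pairwise comparisons
  three <- pairwiseMannWhitney(list(a = 1:3, b = 4:6, c = 7:9))
  expect_equal(nrow(three), 3L)
  expect_equal(three$p_adj, pmin(1, three$p * 3), tolerance = 1e-12)
  expect_error(pairwiseMannWhitney(list(a = 1:3, b = numeric(0))), "empty")
})

test_that("Spearman rho matches the rank-difference formula", {
  expect_equal(spearmanCor(1:5, c(2, 1, 4, 3, 5))$rho, 0.8,
               tolerance = 1e-12)
  expect_equal(spearmanCor(1:5, c(2, 1, 4, 3, 5))$rho,
               bruteSpearman(1:5, c(2, 1, 4, 3, 5)), tolerance = 1e-12)
  expect_equal(spearmanCor(1:7, (1:7)^3)$rho, 1)
  expect_equal(spearmanCor(1:7, -(1:7)^3)$rho, -1)
  set.seed(2)
  x <- rnorm(9); y <- rnorm(9)
  expect_equal(spearmanCor(x, y)$rho, bruteSpearman(x, y),
               tolerance = 1e-12)
  expect_error(spearmanCor(rep(1, 5), 1:5), "constant")
  expect_error(spearmanCor(1:2, 1:2), "at least 3")
})

test_that("small-sample Spearman p equals the permutation distribution", {
  set.seed(8)
  x <- rnorm(6); y <- rnorm(6)
  expect_equal(spearmanCor(x, y)$p, bruteSpearmanP(x, y), tolerance = 1e-9)
})

test_that("rank statistics are invariant under strictly monotone transforms", {
  set.seed(31)
  g <- list(a = rnorm(8), b = rnorm(7, 1), c = rnorm(9, 2))
  tr <- function(v) exp(3 * v) - 5
  expect_equal(kruskalWallis(lapply(g, tr)), kruskalWallis(g),
               tolerance = 1e-12)
  expect_equal(pairwiseMannWhitney(lapply(g, tr))$p,
               pairwiseMannWhitney(g)$p, tolerance = 1e-12)
  x <- rnorm(15); y <- rnorm(15)
  expect_equal(spearmanCor(tr(x), tr(y))$rho, spearmanCor(x, y)$rho,
               tolerance = 1e-12)
})

test_that("percent differences reproduce printed worked examples", {
  expect_equal(round(percentDifference(56.0, 65.1), 1), -14.0)
  expect_equal(percentDifference(42, 42), 0)
  expect_equal(percentDifference(50, 100), -50)
  expect_error(percentDifference(1, 0), "nonzero")
})

test_that("noiseless regression interpolates a covariate exactly", {
  set.seed(12)
  coh <- data.frame(age = rnorm(30, 45, 10),
                    sex = sample(c("m", "f"), 30, TRUE),
                    lesion_level = sample(1:25, 30, TRUE),
                    mean_sca = rnorm(30, 65, 5))
  coh$motor <- coh$age
  res <- adjustedRegression(coh, "motor", "mean_sca")
  est <- setNames(res$estimate, res$term)
  expect_equal(unname(est["age"]), 1, tolerance = 1e-9)
  expect_equal(unname(est["mean_sca"]), 0, tolerance = 1e-9)
  expect_equal(unname(est["lesion_level"]), 0, tolerance = 1e-9)
})

test_that("regression errors are explicit for small n and collinearity", {
  coh <- data.frame(age = rnorm(4), sex = c("m", "f", "m", "f"),
                    lesion_level = 1:4, mean_sca = rnorm(4),
                    motor = rnorm(4))
  expect_error(adjustedRegression(coh, "motor", "mean_sca"),
               "too few complete cases")
  set.seed(3)
  coh2 <- data.frame(age = rnorm(30), sex = sample(c("m", "f"), 30, TRUE),
                     lesion_level = sample(1:20, 30, TRUE),
                     mean_sca = rnorm(30))
  coh2$mean_apw <- 2 * coh2$mean_sca # exactly collinear
  coh2$motor <- rnorm(30)
  expect_error(adjustedRegression(coh2, "motor", c("mean_sca", "mean_apw")),
               "collinear.*mean_apw")
  expect_error(adjustedRegression(coh2, "motor", "nope"), "missing columns")
})

test_that("regression recovers a simulated effect without bias", {
  set.seed(77)
  est <- replicate(200, {
    n <- 40
    coh <- data.frame(age = rnorm(n, 45, 10),
                      sex = sample(c("m", "f"), n, TRUE),
                      lesion_level = sample(1:25, n, TRUE),
                      mean_sca = rnorm(n, 65, 6))
    coh$motor <- 10 + 0.5 * coh$mean_sca + 0.3 * coh$age + rnorm(n, 0, 2)
    res <- adjustedRegression(coh, "motor", "mean_sca")
    c(res$estimate[res$term == "mean_sca"], res$se[res$term == "mean_sca"])
  })
  bias <- mean(est[1, ]) - 0.5
  seMean <- sd(est[1, ]) / sqrt(ncol(est))
  expect_lt(abs(bias), 3 * seMean)
  # reported SE consistent with the sampling spread
  expect_equal(mean(est[2, ]), sd(est[1, ]), tolerance = 0.15)
})

test_that("Bonferroni pairwise testing controls family-wise error on nulls", {
  set.seed(123)
  rejections <- vapply(seq_len(1000), function(i) {
    g <- list(a = rnorm(14), b = rnorm(14), c = rnorm(14))
    any(pairwiseMannWhitney(g)$p_adj < 0.05)
  }, logical(1))
  expect_lte(mean(rejections), 0.05 + 0.02)
})

test_that("the cohort report runs the configured battery end to end", {
  ch <- generateCohort(cohortSpec(), seed = 41, phantoms = FALSE)$cohort
  # use generator truth as stand-in measurements for this statistics test
  ch$mean_sca <- ch$true_sca; ch$mean_apw <- ch$true_apw
  ch$mean_lrw <- ch$true_lrw
  rep <- cohortReport(ch)
  expect_s3_class(rep, "cordCohortReport")
  # 3 measures x (H + F) rows, 3 pairwise rows each, 2 pain contrasts
  expect_equal(nrow(rep$groupTests), 6L)
  expect_equal(nrow(rep$pairwise), 9L)
  expect_equal(nrow(rep$painContrasts), 2L)
  expect_true(all(rep$painContrasts$estimable))
  # correlation battery includes the M1/pain link in the NP subset
  expect_true(any(rep$correlations$x == "m1_volume"))
  expect_equal(rep$correlations$p_adj,
               pmin(1, rep$correlations$p * nrow(rep$correlations)),
               tolerance = 1e-12)
  expect_equal(unique(rep$regression$dependent), "motor")
  # strong true group contrast is detected
  expect_lt(rep$groupTests$p[rep$groupTests$comparison == "mean_sca" &
                               rep$groupTests$statistic_name == "H"], 0.001)
})

test_that("a cohort without NP subjects reports pain contrasts not estimable", {
  spec <- cohortSpec()
  for (g in c("pSCI", "tSCI")) spec@groups[[g]]$nNP <- 0L
  ch <- generateCohort(spec, seed = 4, phantoms = FALSE)$cohort
  ch$mean_sca <- ch$true_sca; ch$mean_apw <- ch$true_apw
  ch$mean_lrw <- ch$true_lrw
  rep <- cohortReport(ch)
  expect_false(any(rep$painContrasts$estimable))
  expect_true(any(grepl("not estimable", rep$notes)))
})

test_that("missing required columns are reported by name", {
  expect_error(cohortReport(data.frame(group = "HC", pain = "none")),
               "mean_sca.*mean_apw.*mean_lrw")
})
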