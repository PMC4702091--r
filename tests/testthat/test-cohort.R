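test_that("group calibration: generated true SCA means match configuration", {
  spec <- cohortSpec()
  for (g in c("HC", "tSCI")) {
    gs <- spec@groups[[g]]
    gs$n <- 10000L; gs$nNP <- 0L
    big <- cohortSpec(groups = stats::setNames(list(gs), g))
    ch <- generateCohort(big, seed = 7, phantoms = FALSE, groups = g)
    se <- gs$scaSd / sqrt(gs$n)
    expect_lt(abs(mean(ch$cohort$true_sca) - gs$scaMean), 3 * se)
  }
})

test_that("control-group mean over 10000 draws is within 0.3 mm^2 of target", {
  spec <- cohortSpec()
  gs <- spec@groups$HC
  gs$n <- 10000L
  big <- cohortSpec(groups = list(HC = gs))
  ch <- generateCohort(big, seed = 11, phantoms = FALSE, groups = "HC")
  expect_lt(abs(mean(ch$cohort$true_sca) - 79.2), 0.3)
})

test_that("the paraplegic NP multiplier encodes an exact -11.6% contrast", {
  spec <- cohortSpec()
  gs <- spec@groups$pSCI
  mus <- cordmorph:::subgroupMeans(gs$scaMean, gs$n, gs$nNP,
                                   spec@painMultiplier)
  expect_equal(percentDifference(mus[["np"]], mus[["painFree"]]), -11.6,
               tolerance = 1e-9)
  # pooled mean preserved
  pooled <- ((gs$n - gs$nNP) * mus[["painFree"]] + gs$nNP * mus[["np"]]) /
    gs$n
  expect_equal(pooled, 65.1, tolerance = 1e-9)
})

test_that("zero dependence makes M1 volume and pain intensity independent", {
  spec <- cohortSpec(m1PainDependence = 0)
  gs <- spec@groups$pSCI
  gs$n <- 10000L; gs$nNP <- 10000L
  big <- cohortSpec(groups = list(pSCI = gs), m1PainDependence = 0)
  ch <- generateCohort(big, seed = 3, phantoms = FALSE, groups = "pSCI")
  rho <- spearmanCor(ch$cohort$m1_volume, ch$cohort$pain_intensity)$rho
  expect_lt(abs(rho), 0.02)
})

test_that("the dependence parameter is monotone in the induced correlation", {
  rhoAt <- function(dep) {
    gs <- cohortSpec()@groups$pSCI
    gs$n <- 4000L; gs$nNP <- 4000L
    big <- cohortSpec(groups = list(pSCI = gs), m1PainDependence = dep)
    ch <- generateCohort(big, seed = 17, phantoms = FALSE, groups = "pSCI")
    spearmanCor(ch$cohort$m1_volume, ch$cohort$pain_intensity)$rho
  }
  induced <- vapply(c(0, 0.4, 0.8), rhoAt, numeric(1))
  expect_true(all(diff(induced) > 0))
})

test_that("dependence calibration inverts the exact expectation formula", {
  # finite-n inversion: expectation of the sample coefficient, not the
  # population coefficient, matches the target
  dep <- calibrateDependence(0.637, 13L)
  expect_equal(expectedSpearman(dep, 13L), 0.637, tolerance = 1e-9)
  expect_gt(dep, 2 * sin(pi * 0.637 / 6)) # above the population inversion
  expect_equal(calibrateDependence(0, 13L), 0)
  expect_equal(expectedSpearman(calibrateDependence(-0.5, 9L), 9L), -0.5,
               tolerance = 1e-9)
  expect_error(calibrateDependence(1.2), "< 1")
})

test_that("cohort generation is reproducible and seed-sensitive", {
  spec <- cohortSpec()
  a <- generateCohort(spec, seed = 5, phantoms = TRUE, groups = "tSCI")
  b <- generateCohort(spec, seed = 5, phantoms = TRUE, groups = "tSCI")
  expect_identical(a$cohort, b$cohort)
  expect_identical(a$phantoms[["T01"]]$volume@data,
                   b$phantoms[["T01"]]$volume@data)
  c <- generateCohort(spec, seed = 6, phantoms = FALSE, groups = "tSCI")
  expect_false(identical(a$cohort$true_sca, c$cohort$true_sca))
  # written CSVs are byte-identical under a fixed seed
  f1 <- tempfile(fileext = ".csv"); f2 <- tempfile(fileext = ".csv")
  write.csv(a$cohort, f1, row.names = FALSE)
  write.csv(b$cohort, f2, row.names = FALSE)
  expect_identical(readBin(f1, "raw", file.size(f1)),
                   readBin(f2, "raw", file.size(f2)))
})

test_that("cohort structure matches the configured study design", {
  ch <- generateCohort(cohortSpec(), seed = 2, phantoms = FALSE)$cohort
  expect_equal(table(ch$group)[["HC"]], 31L)
  expect_equal(table(ch$group)[["pSCI"]], 14L)
  expect_equal(table(ch$group)[["tSCI"]], 14L)
  expect_equal(sum(ch$pain == "below_level" & ch$group == "pSCI"), 8L)
  expect_equal(sum(ch$pain == "below_level" & ch$group == "tSCI"), 5L)
  expect_equal(sum(ch$pain == "below_level" & ch$group == "HC"), 0L)
  # pain intensity present iff neuropathic pain
  expect_true(all(is.na(ch$pain_intensity[ch$pain == "none"])))
  expect_true(all(!is.na(ch$pain_intensity[ch$pain != "none"])))
  expect_true(all(ch$pain_intensity >= 0 & ch$pain_intensity <= 10,
                  na.rm = TRUE))
  # lesion levels respect group ranges; HC unlesioned
  expect_true(all(is.na(ch$lesion_level[ch$group == "HC"])))
  expect_true(all(ch$lesion_level[ch$group == "tSCI"] %in% 2:8))
  expect_true(all(ch$lesion_level[ch$group == "pSCI"] %in% 9:23))
  # width ratio model: true widths consistent with drawn area and theta
  expect_true(all(ch$true_lrw > ch$true_apw))
})

test_that("infeasible specifications are rejected", {
  expect_error(cohortSpec(painMultiplier = 0), "painMultiplier")
  expect_error(cohortSpec(painMultiplier = 1.4), "painMultiplier")
  expect_error(cohortSpec(m1PainDependence = 1.5), "m1PainDependence")
  spec <- cohortSpec()
  spec@groups$HC$scaMean <- -10
  expect_error(validObject(spec), "strictly positive")
})
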