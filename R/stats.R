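## Cohort-level statistics on extracted morphometry and clinical covariates:
## Kruskal-Wallis across groups, Bonferroni-corrected pairwise
## Mann-Whitney-U, covariate-adjusted least-squares regression, Spearman
## rank correlations, and percent-difference summaries.

asGroupList <- function(values, groups = NULL) {
  if (is.list(values)) return(values)
  split(values, groups)
}

#' Kruskal-Wallis rank test across groups
#'
#' Tie-corrected H statistic with a chi-square p-value, via
#' [stats::kruskal.test()]. All values identical across groups gives H = 0,
#' p = 1 (not an error).
#'
#' @param values numeric vector, or a list of per-group value vectors.
#' @param groups grouping vector (ignored when `values` is a list).
#' @param label comparison label carried into the result.
#' @return One-row data.frame: `comparison`, `statistic_name` ("H"),
#'   `statistic`, `df`, `p`, `p_adj` (NA here; set by family procedures).
#' @examples
#' kruskalWallis(list(hc = c(1, 2), p = c(3, 4), t = c(5, 6)))
#' @export
kruskalWallis <- function(values, groups = NULL, label = "kruskal-wallis") {
  g <- asGroupList(values, groups)
  if (length(g) < 2L || any(!lengths(g)))
    stop("need at least two nonempty groups")
  if (length(unique(unlist(g))) == 1L) {
    h <- 0; df <- length(g) - 1L; p <- 1
  } else {
    kt <- stats::kruskal.test(g)
    h <- unname(kt$statistic); df <- unname(kt$parameter); p <- kt$p.value
  }
  data.frame(comparison = label, statistic_name = "H", statistic = h,
             df = df, p = p, p_adj = NA_real_)
}

#' Pairwise Mann-Whitney-U tests with Bonferroni correction
#'
#' Runs [stats::wilcox.test()] for every pair of groups (exact p-values for
#' small tie-free samples, normal approximation with continuity and tie
#' correction otherwise) and attaches Bonferroni-adjusted p-values,
#' `p_adj = min(1, p * familySize)`.
#'
#' @param values numeric vector or list of per-group vectors.
#' @param groups grouping vector (ignored when `values` is a list).
#' @param familySize Bonferroni family size; defaults to the number of
#'   pairwise comparisons.
#' @return data.frame, one row per pair: `comparison`, `statistic_name`
#'   ("U"), `statistic`, `df` (NA), `p`, `p_adj`.
#' @export
pairwiseMannWhitney <- function(values, groups = NULL, familySize = NULL) {
  g <- asGroupList(values, groups)
  if (length(g) < 2L) stop("need at least two groups")
  if (any(!lengths(g))) stop("empty group")
  pairs <- utils::combn(names(g), 2, simplify = FALSE)
  if (is.null(familySize)) familySize <- length(pairs)
  rows <- lapply(pairs, function(pr) {
    wt <- suppressWarnings(stats::wilcox.test(g[[pr[1]]], g[[pr[2]]]))
    data.frame(comparison = paste(pr, collapse = " vs "),
               statistic_name = "U", statistic = unname(wt$statistic),
               df = NA_real_, p = wt$p.value,
               p_adj = min(1, wt$p.value * familySize))
  })
  do.call(rbind, rows)
}

#' Spearman rank correlation
#'
#' Average-rank tie handling; p-value by the exact permutation distribution
#' for small tie-free samples and the t approximation otherwise, via
#' [stats::cor.test()]. A constant input vector leaves the coefficient
#' undefined and is an explicit error.
#'
#' @param x,y numeric vectors of equal length >= 3.
#' @return `list(rho, p)`.
#' @examples
#' spearmanCor(1:5, c(2, 1, 4, 3, 5))
#' @export
spearmanCor <- function(x, y) {
  if (length(x) != length(y)) stop("x and y must have equal length")
  ok <- stats::complete.cases(x, y)
  x <- x[ok]; y <- y[ok]
  if (length(x) < 3L) stop("need at least 3 complete pairs")
  if (length(unique(x)) == 1L || length(unique(y)) == 1L)
    stop("Spearman correlation undefined for a constant input vector")
  ct <- suppressWarnings(stats::cor.test(x, y, method = "spearman"))
  list(rho = unname(ct$estimate), p = ct$p.value)
}

#' Covariate-adjusted least-squares regression
#'
#' Fits `dependent ~ independents + covariates` by ordinary least squares on
#' complete cases, with sex coded as an indicator and the lesion level as an
#' ordinal integer. Rank deficiency of the design matrix is an explicit
#' error naming the collinear columns; so is having fewer complete cases
#' than parameters + 1.
#'
#' @param cohort data.frame of subject records.
#' @param dependent name of the dependent (behavioural) variable.
#' @param independents character vector of structural predictors, e.g.
#'   `c("mean_sca", "mean_apw", "mean_lrw")`.
#' @param covariates nuisance covariates, default age, sex, lesion level.
#' @return data.frame, one row per coefficient: `dependent`, `term`,
#'   `estimate`, `se`, `p`, plus the complete-case `n`.
#' @export
adjustedRegression <- function(cohort, dependent, independents,
                               covariates = c("age", "sex", "lesion_level")) {
  vars <- c(dependent, independents, covariates)
  missingCols <- setdiff(vars, names(cohort))
  if (length(missingCols))
    stop("missing columns: ", paste(missingCols, collapse = ", "))
  dat <- cohort[vars]
  if ("sex" %in% names(dat)) dat$sex <- as.integer(dat$sex == "m")
  dat <- dat[stats::complete.cases(dat), , drop = FALSE]
  p <- length(independents) + length(covariates) + 1L
  if (nrow(dat) < p + 1L)
    stop(sprintf("too few complete cases (%d) for %d parameters",
                 nrow(dat), p))
  X <- stats::model.matrix(
    stats::reformulate(c(independents, covariates)), dat)
  qrX <- qr(X)
  if (qrX$rank < ncol(X)) {
    bad <- colnames(X)[-seq_len(qrX$rank)]
    bad <- setdiff(colnames(X), colnames(X)[qrX$pivot[seq_len(qrX$rank)]])
    stop("rank-deficient design; collinear column(s): ",
         paste(bad, collapse = ", "))
  }
  fit <- stats::lm(stats::reformulate(c(independents, covariates),
                                      response = dependent), data = dat)
  sm <- summary(fit)$coefficients
  data.frame(dependent = dependent, term = rownames(sm),
             estimate = sm[, 1], se = sm[, 2], p = sm[, 4],
             n = nrow(dat), row.names = NULL)
}

#' Percent difference between two group means
#'
#' `100 * (meanA - meanB) / meanB`, the relative difference of `meanA` from
#' the reference `meanB`; reported to one decimal in cohort reports.
#'
#' @param meanA,meanB numeric scalars; `meanB` must be nonzero.
#' @return Percent difference (unrounded).
#' @examples
#' round(percentDifference(56.0, 65.1), 1) # tetraplegic vs paraplegic SCA
#' @export
percentDifference <- function(meanA, meanB) {
  if (!is.finite(meanB) || meanB == 0)
    stop("reference mean must be nonzero")
  100 * (meanA - meanB) / meanB
}

#' Full cohort statistical report
#'
#' Runs the study's statistical battery on a cohort table holding measured
#' morphometry (`mean_sca`, `mean_apw`, `mean_lrw`) and clinical covariates:
#'
#' * per measure: Kruskal-Wallis across groups (H), a one-way ANOVA F for
#'   side-by-side comparability, and Bonferroni-corrected pairwise
#'   Mann-Whitney-U tests (family of 3 per measure);
#' * within paraplegics and tetraplegics separately: NP vs pain-free
#'   Mann-Whitney-U on `mean_sca` and the subgroup percent difference
#'   (marked not estimable when a subgroup is empty);
#' * group percent differences of mean SCA/APW/LRW versus healthy controls
#'   and tetraplegic vs paraplegic;
#' * Spearman correlations within the SCI subjects (SCA vs lesion level,
#'   warm perception threshold, motor and sensory scores, time since
#'   injury, age; M1 volume vs pain intensity within NP subjects),
#'   Bonferroni-corrected over the number of correlations run;
#' * covariate-adjusted regression of the behavioural score on the three
#'   cord measures (age, sex, lesion level as covariates).
#'
#' Deterministic given the input table.
#'
#' @param cohort data.frame with columns `group`, `pain`, `mean_sca`,
#'   `mean_apw`, `mean_lrw`, `age`, `sex`, `lesion_level`, and the clinical
#'   covariates used by the correlation battery (missing optional columns
#'   are skipped with a note; missing required columns are an error).
#' @param measures morphometric measures to test across groups.
#' @param behavioural dependent variable of the regression step.
#' @return A list of class `"cordCohortReport"`: `groupTests`,
#'   `pairwise`, `painContrasts`, `percentDifferences`, `correlations`,
#'   `regression`, `notes`.
#' @export
cohortReport <- function(cohort,
                         measures = c("mean_sca", "mean_apw", "mean_lrw"),
                         behavioural = "motor") {
  required <- c("group", "pain", measures)
  missingCols <- setdiff(required, names(cohort))
  if (length(missingCols))
    stop("missing columns: ", paste(missingCols, collapse = ", "))
  notes <- character()

  groupTests <- list(); pairwise <- list()
  for (m in measures) {
    vals <- split(cohort[[m]], cohort$group)
    vals <- lapply(vals, function(v) v[is.finite(v)])
    kw <- kruskalWallis(vals, label = m)
    av <- stats::oneway.test(
      stats::reformulate("group", response = m),
      data = cohort[is.finite(cohort[[m]]), ], var.equal = TRUE)
    fRow <- data.frame(comparison = m, statistic_name = "F",
                       statistic = unname(av$statistic),
                       df = unname(av$parameter[1]), p = av$p.value,
                       p_adj = NA_real_)
    groupTests[[m]] <- rbind(kw, fRow)
    pw <- pairwiseMannWhitney(vals, familySize = 3)
    pw$comparison <- paste(m, pw$comparison, sep = ": ")
    pairwise[[m]] <- pw
  }

  painContrasts <- list()
  for (g in intersect(c("pSCI", "tSCI"), unique(cohort$group))) {
    sub <- cohort[cohort$group == g & is.finite(cohort$mean_sca), ]
    np <- sub$mean_sca[sub$pain != "none"]
    free <- sub$mean_sca[sub$pain == "none"]
    if (!length(np) || !length(free)) {
      painContrasts[[g]] <- data.frame(
        group = g, comparison = "NP vs pain-free mean_sca",
        statistic = NA_real_, p = NA_real_, percent_difference = NA_real_,
        estimable = FALSE)
      notes <- c(notes, sprintf("%s pain contrast not estimable", g))
    } else {
      wt <- suppressWarnings(stats::wilcox.test(np, free))
      painContrasts[[g]] <- data.frame(
        group = g, comparison = "NP vs pain-free mean_sca",
        statistic = unname(wt$statistic), p = wt$p.value,
        percent_difference = round(percentDifference(mean(np), mean(free)),
                                   1),
        estimable = TRUE)
    }
  }

  gm <- function(m, g) mean(cohort[[m]][cohort$group == g], na.rm = TRUE)
  pd <- list()
  for (m in measures) {
    for (g in intersect(c("pSCI", "tSCI"), unique(cohort$group)))
      if ("HC" %in% cohort$group)
        pd[[paste(m, g)]] <- data.frame(
          measure = m, comparison = paste(g, "vs HC"),
          percent_difference = round(percentDifference(gm(m, g),
                                                       gm(m, "HC")), 1))
    if (all(c("pSCI", "tSCI") %in% cohort$group))
      pd[[paste(m, "t-p")]] <- data.frame(
        measure = m, comparison = "tSCI vs pSCI",
        percent_difference = round(percentDifference(gm(m, "tSCI"),
                                                     gm(m, "pSCI")), 1))
  }

  sci <- cohort[cohort$group != "HC", ]
  corSpec <- list(
    c("mean_sca", "lesion_level"),
    c("mean_sca", "warm_perception_threshold"),
    c("mean_sca", "motor"), c("mean_sca", "sensory"),
    c("mean_sca", "time_since_injury"), c("mean_sca", "age"))
  corRows <- list()
  for (cs in corSpec) {
    if (!all(cs %in% names(sci))) {
      notes <- c(notes, sprintf("correlation %s ~ %s skipped: column absent",
                                cs[1], cs[2]))
      next
    }
    res <- tryCatch(spearmanCor(sci[[cs[1]]], sci[[cs[2]]]),
                    error = function(e) NULL)
    if (!is.null(res))
      corRows[[paste(cs, collapse = "~")]] <- data.frame(
        x = cs[1], y = cs[2], subset = "SCI", rho = res$rho, p = res$p)
  }
  npSub <- sci[sci$pain != "none", ]
  if (all(c("m1_volume", "pain_intensity") %in% names(npSub)) &&
      nrow(npSub) >= 3L) {
    res <- tryCatch(spearmanCor(npSub$m1_volume, npSub$pain_intensity),
                    error = function(e) NULL)
    if (!is.null(res))
      corRows[["m1"]] <- data.frame(x = "m1_volume", y = "pain_intensity",
                                    subset = "NP", rho = res$rho, p = res$p)
  } else notes <- c(notes, "M1/pain correlation not estimable")
  correlations <- do.call(rbind, corRows)
  if (!is.null(correlations)) {
    correlations$p_adj <- pmin(1, correlations$p * nrow(correlations))
    rownames(correlations) <- NULL
  }

  regression <- tryCatch(
    adjustedRegression(sci, behavioural, measures),
    error = function(e) {
      notes <<- c(notes, paste("regression skipped:", conditionMessage(e)))
      NULL
    })

  structure(list(groupTests = do.call(rbind, groupTests),
                 pairwise = do.call(rbind, pairwise),
                 painContrasts = do.call(rbind, painContrasts),
                 percentDifferences = do.call(rbind, pd),
                 correlations = correlations,
                 regression = regression, notes = notes),
            class = "cordCohortReport")
}

#' Write a cohort report to CSV and JSON
#'
#' Writes each component table of a [cohortReport()] as a CSV under `dir`
#' and the full report as a single JSON file; byte-identical output for
#' identical input.
#'
#' @param report a `"cordCohortReport"`.
#' @param dir output directory (created if needed).
#' @return Invisibly, the paths written.
#' @export
writeCohortReport <- function(report, dir) {
  stopifnot(inherits(report, "cordCohortReport"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- character()
  for (nm in c("groupTests", "pairwise", "painContrasts",
               "percentDifferences", "correlations", "regression")) {
    tab <- report[[nm]]
    if (is.null(tab)) next
    rn <- rownames(tab)
    p <- file.path(dir, paste0(nm, ".csv"))
    utils::write.csv(tab, p, row.names = FALSE)
    paths <- c(paths, p)
  }
  pj <- file.path(dir, "report.json")
  jsonlite::write_json(unclass(report), pj, auto_unbox = TRUE, digits = NA,
                       na = "null", pretty = TRUE)
  invisible(c(paths, pj))
}

#' @export
print.cordCohortReport <- function(x, ...) {
  cat("Cohort statistical report\n")
  cat("-- group tests --\n"); print(x$groupTests)
  cat("-- pairwise (Bonferroni family of 3 per measure) --\n")
  print(x$pairwise)
  cat("-- pain contrasts --\n"); print(x$painContrasts)
  cat("-- percent differences --\n"); print(x$percentDifferences)
  if (!is.null(x$correlations)) {
    cat("-- Spearman correlations --\n"); print(x$correlations)
  }
  if (!is.null(x$regression)) {
    cat("-- adjusted regression --\n"); print(x$regression)
  }
  if (length(x$notes)) cat("notes:", paste(x$notes, collapse = "; "), "\n")
  invisible(x)
}
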