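## Bundled transcriptions of the published clinical tables of the reference
## SCI morphometry study: the per-subject roster of the 28 spinal-cord-injured
## individuals (14 paraplegic P01-P14, 14 tetraplegic T01-T14) and the
## group-level summary statistics (healthy controls, tSCI, pSCI) that
## calibrate the cohort simulator.

#' Ordinal coding of a neurological lesion level
#'
#' Maps spinal segment labels to a single ordinal scale: C1..C8 = 1..8,
#' Th1..Th12 = 9..20, L1..L5 = 21..25, S1..S5 = 26..30. Two-segment levels
#' such as `"C6/C7"` are coded at the rostral (numerically smaller) level.
#'
#' @param level character vector of levels, e.g. `"Th4"`, `"C6/C7"`.
#' @return Integer vector (NA for missing/unparseable input).
#' @examples
#' parseLesionLevel(c("C2", "C6/C7", "Th12", "L3"))
#' @export
parseLesionLevel <- function(level) {
  one <- function(s) {
    if (is.na(s) || !nzchar(s)) return(NA_integer_)
    s <- trimws(strsplit(s, "/")[[1]][1]) # rostral segment of a split level
    m <- regmatches(s, regexec("^(C|Th|T|L|S)\\s*([0-9]+)$", s))[[1]]
    if (length(m) != 3L) return(NA_integer_)
    n <- as.integer(m[3])
    base <- switch(m[2], C = 0L, Th = 8L, T = 8L, L = 20L, S = 25L)
    base + n
  }
  vapply(as.character(level), one, integer(1), USE.NAMES = FALSE)
}

#' Bundled reference clinical tables
#'
#' Loads the packaged transcription of the reference study's clinical
#' tables: `cohort`, one row per spinal-cord-injured subject (id, age, sex,
#' injury etiology, time since injury in years, neurological lesion level
#' and its ordinal coding, AIS grade, ISNCSCI motor 0-100 and sensory 0-224
#' scores, below-level neuropathic-pain classification) and `summary`, the
#' group-level mean/SD table (SCA, APW, LRW, age, thermal thresholds, ...)
#' for healthy controls and the tetraplegic/paraplegic groups.
#'
#' @return `list(cohort = data.frame, summary = data.frame)`; the cohort
#'   gains `group` (`pSCI`/`tSCI` from the id prefix) and
#'   `lesion_level_ordinal` columns.
#' @examples
#' tab <- referenceTables()
#' sum(tab$cohort$pain == "below_level")
#' @export
referenceTables <- function() {
  coh <- utils::read.csv(system.file("extdata", "reference_cohort.csv",
                                     package = "cordmorph"),
                         stringsAsFactors = FALSE)
  coh$group <- ifelse(substr(coh$id, 1, 1) == "P", "pSCI", "tSCI")
  coh$lesion_level_ordinal <- parseLesionLevel(coh$lesion_level)
  summ <- utils::read.csv(system.file("extdata", "reference_summary.csv",
                                      package = "cordmorph"),
                          stringsAsFactors = FALSE)
  list(cohort = coh, summary = summ)
}

#' Look up a reference group summary value
#'
#' @param parameter row key of the summary table (e.g. `"sca"`, `"apw"`).
#' @param group `"HC"`, `"tSCI"` or `"pSCI"`.
#' @return Named numeric `c(mean, sd)`.
#' @examples
#' referenceSummary("sca", "HC")
#' @export
referenceSummary <- function(parameter, group) {
  summ <- referenceTables()$summary
  row <- summ[summ$parameter == parameter & summ$group == group, ]
  if (nrow(row) != 1L)
    stop("no summary entry for ", parameter, " / ", group)
  c(mean = row$mean, sd = row$sd)
}
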