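# Study-quality scoring: minimum-inclusion-criteria grade, Opinion Scores,
# and the study reliability likelihood lookup.

#' Study quality grade from rule outcomes
#'
#' Grades a toxicity study 1-5 from the outcomes of the sixteen
#' minimum-inclusion-criteria rules. Studies available only as summaries
#' (no underlying records to evaluate) are grade 1 regardless of rule
#' outcomes. Otherwise the grade is set by the number of failed rules:
#' 0 failures -> 5, 1-2 -> 4, 3-4 -> 3, more than 4 -> 2.
#'
#' The texts of the sixteen rules are organisation-specific (study design
#' completeness, dose-group adequacy, reporting of effects per dose level,
#' ...); this function consumes their pass/fail outcomes, which are
#' supplied externally, e.g. via [read_study_records()].
#'
#' @param rule_outcomes logical vector of length 16 (`TRUE` = rule passed),
#'   or a 16-character string of `P`/`F`.
#' @param summary_only logical; `TRUE` when only summary data exist.
#' @return Integer grade in 1..5.
#' @examples
#' minis_grade(rep(TRUE, 16))            # 5
#' minis_grade("PPPPPPPPPPPPPPFF")       # 4
#' minis_grade(rep(TRUE, 16), summary_only = TRUE)  # 1
#' @export
minis_grade <- function(rule_outcomes, summary_only = FALSE) {
  if (is.character(rule_outcomes) && length(rule_outcomes) == 1) {
    ch <- strsplit(toupper(rule_outcomes), "")[[1]]
    if (!all(ch %in% c("P", "F"))) stop("rule string must contain only P/F")
    rule_outcomes <- ch == "P"
  }
  rule_outcomes <- as.logical(rule_outcomes)
  if (length(rule_outcomes) != 16 || anyNA(rule_outcomes)) {
    stop("exactly 16 pass/fail rule outcomes are required")
  }
  if (isTRUE(summary_only)) return(1L)
  failures <- sum(!rule_outcomes)
  if (failures == 0) 5L else if (failures <= 2) 4L else if (failures <= 4) 3L else 2L
}

#' Default study reliability likelihood table
#'
#' The modelled 5 x 5 grid mapping (grade, Opinion Score) to a study
#' reliability likelihood in `[0.5, 1]`. The likelihood increases with
#' either coordinate; a fully compliant study with the strongest expert
#' opinion scores 1.0, and the floor of the default grid is 0.5.
#'
#' @return Numeric 5 x 5 matrix, rows = grade 1..5, columns = opinion 1..5.
#' @export
default_reliability_table <- function() {
  matrix(c(
    0.5, 0.6,  0.65, 0.75, 0.8,   # grade 1 (summary only)
    0.5, 0.6,  0.7,  0.8,  0.85,  # grade 2
    0.6, 0.65, 0.75, 0.85, 0.9,   # grade 3
    0.6, 0.7,  0.8,  0.9,  0.95,  # grade 4
    0.6, 0.75, 0.85, 0.95, 1.0    # grade 5
  ), nrow = 5, byrow = TRUE,
  dimnames = list(grade = 1:5, opinion = 1:5))
}

#' Study reliability likelihood lookup
#'
#' Exact lookup of the reliability likelihood for a (grade, Opinion Score)
#' pair. Opinion Scores are expert judgements of how interpretable the
#' study's conclusion is (5 = fully interpretable, 1 = barely); they are
#' inputs, never computed.
#'
#' @param grade integer grade(s) in 1..5 (see [minis_grade()]).
#' @param opinion integer Opinion Score(s) in 1..5.
#' @param table a 5 x 5 likelihood grid; custom tables should first pass
#'   [validate_reliability_table()].
#' @return Likelihood value(s) in `[0, 1]`.
#' @examples
#' reliability_likelihood(4, 4)  # 0.9
#' @export
reliability_likelihood <- function(grade, opinion, table = default_reliability_table()) {
  grade <- as.integer(grade)
  opinion <- as.integer(opinion)
  if (anyNA(grade) || any(grade < 1 | grade > 5)) stop("grade must be in 1..5")
  if (anyNA(opinion) || any(opinion < 1 | opinion > 5)) stop("opinion must be in 1..5")
  table[cbind(grade, opinion)]
}

#' Validate a custom reliability table
#'
#' Custom grids are permitted (the default is itself a modelled choice),
#' but must be coherent: values in `[0, 1]`, non-decreasing in grade at
#' fixed opinion, and non-decreasing in opinion at fixed grade.
#'
#' @param table numeric 5 x 5 matrix, rows = grade 1..5, columns =
#'   opinion 1..5.
#' @return Character vector of violations; empty when the table is valid.
#' @export
validate_reliability_table <- function(table) {
  out <- character()
  if (!is.matrix(table) || !all(dim(table) == c(5, 5))) {
    return("table must be a 5 x 5 numeric matrix (grade x opinion)")
  }
  if (any(!is.finite(table))) out <- c(out, "non-finite values present")
  bad <- which(table < 0 | table > 1, arr.ind = TRUE)
  for (i in seq_len(nrow(bad))) {
    out <- c(out, sprintf("value out of [0,1] at grade %d, opinion %d: %g",
                          bad[i, 1], bad[i, 2], table[bad[i, 1], bad[i, 2]]))
  }
  for (op in 1:5) {
    d <- diff(table[, op])
    for (g in which(d < 0)) {
      out <- c(out, sprintf(
        "grade monotonicity violated at opinion %d: grade %d (%g) > grade %d (%g)",
        op, g, table[g, op], g + 1, table[g + 1, op]))
    }
  }
  for (g in 1:5) {
    d <- diff(table[g, ])
    for (op in which(d < 0)) {
      out <- c(out, sprintf(
        "opinion monotonicity violated at grade %d: opinion %d (%g) > opinion %d (%g)",
        g, op, table[g, op], op + 1, table[g, op + 1]))
    }
  }
  out
}

#' Read study records
#'
#' Loads a table of toxicity study records and derives, per study, the
#' quality grade and the study reliability likelihood. Expected fields:
#' `study_id`, `compound_id`, `endpoint`, optional design metadata
#' (`species`, `duration`, `route`, `dose_range`), `noael`, `loael`
#' (mg/kg-bw/day; a trailing `"mkd"` unit token is accepted and stripped),
#' `source`, `minis_rules` (16-character `P`/`F` string), `summary_only`,
#' `opinion_score` (1-5).
#'
#' @param x a data frame, or a path to a CSV or JSON file.
#' @param table reliability grid passed to [reliability_likelihood()].
#' @return Data frame of class `study_records` with derived columns
#'   `minis_grade` and `study_reliability` (NA where rule outcomes or
#'   opinion are absent).
#' @export
read_study_records <- function(x, table = default_reliability_table()) {
  if (is.character(x) && length(x) == 1) {
    x <- if (grepl("\\.json$", x, ignore.case = TRUE)) {
      as.data.frame(jsonlite::fromJSON(x))
    } else {
      utils::read.csv(x, check.names = FALSE)
    }
  }
  x <- as.data.frame(x, stringsAsFactors = FALSE)
  stopifnot(all(c("study_id", "compound_id") %in% names(x)))
  parse_dose <- function(v) {
    if (is.null(v)) return(rep(NA_real_, nrow(x)))
    as.numeric(sub("\\s*(mkd|mg/kg-bw/day|mg/kg/day)\\s*$", "",
                   as.character(v), ignore.case = TRUE))
  }
  x$noael <- parse_dose(x$noael)
  x$loael <- parse_dose(x$loael)
  both <- !is.na(x$noael) & !is.na(x$loael)
  if (any(both & x$noael >= x$loael)) {
    stop("invalid study record: NOAEL must be below LOAEL (study ",
         paste(x$study_id[both & x$noael >= x$loael], collapse = ", "), ")")
  }
  if (is.null(x$summary_only)) x$summary_only <- rep(FALSE, nrow(x))
  x$summary_only <- as.logical(x$summary_only)
  x$minis_grade <- rep(NA_integer_, nrow(x))
  if (!is.null(x$minis_rules)) {
    has <- !is.na(x$minis_rules) & nzchar(x$minis_rules)
    x$minis_grade[has] <- vapply(which(has), function(i) {
      minis_grade(x$minis_rules[i], isTRUE(x$summary_only[i]))
    }, integer(1))
  }
  x$study_reliability <- rep(NA_real_, nrow(x))
  ok <- !is.na(x$minis_grade) & !is.null(x$opinion_score) & !is.na(x$opinion_score)
  if (any(ok)) {
    x$study_reliability[ok] <- reliability_likelihood(
      x$minis_grade[ok], x$opinion_score[ok], table)
  }
  class(x) <- c("study_records", "data.frame")
  x
}

#' Grade distribution across study records
#'
#' Histogram of study quality grades; records without a derived grade are
#' counted as `ungraded`.
#'
#' @param records a `study_records` data frame (or any data frame with a
#'   `minis_grade` column).
#' @return Named integer vector with entries `"1"`..`"5"` and `"ungraded"`.
#' @export
grade_distribution <- function(records) {
  g <- if (nrow(records)) records$minis_grade else integer()
  counts <- vapply(1:5, function(k) sum(g == k, na.rm = TRUE), integer(1))
  c(stats::setNames(counts, as.character(1:5)), ungraded = sum(is.na(g)))
}
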