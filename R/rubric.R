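#' Assign a 1-5 sustainability grade from coded criteria
#'
#' Maps a document's coded sustainability criteria to the five-point grading
#' scale used for State Opioid Response (SOR) applications. A plan that meets
#' all three criteria (funding, policies, quality monitoring) receives the top
#' grade of 5; exactly two criteria give a 4 and exactly one a 3. A document
#' that discusses sustainability but meets no criterion -- i.e. it mentions
#' future support without definite plans -- receives a 2, and a document with
#' no mention of sustainability at all receives a 1.
#'
#' A met criterion is itself a discussion of sustainability, so any criterion
#' being `TRUE` while `mentioned` is `FALSE` is an inadmissible coding and is
#' rejected.
#'
#' @param mentioned logical; sustainability discussed at all.
#' @param funding logical; sustainable funding criterion met.
#' @param policies logical; policies/partnerships/regulations criterion met.
#' @param quality_monitoring logical; quality-monitoring criterion met.
#' @return Integer vector of grades in 1..5.
#' @examples
#' score_from_criteria(TRUE, TRUE, TRUE, TRUE)    # 5
#' score_from_criteria(TRUE, TRUE, FALSE, TRUE)   # 4
#' score_from_criteria(TRUE, FALSE, FALSE, FALSE) # 2
#' score_from_criteria(FALSE, FALSE, FALSE, FALSE) # 1
#' @export
score_from_criteria <- function(mentioned, funding, policies, quality_monitoring) {
  args <- list(mentioned, funding, policies, quality_monitoring)
  if (!all(vapply(args, is.logical, TRUE))) {
    stop("all criterion codings must be logical")
  }
  n <- max(lengths(args))
  mentioned <- rep_len(mentioned, n)
  funding <- rep_len(funding, n)
  policies <- rep_len(policies, n)
  quality_monitoring <- rep_len(quality_monitoring, n)
  if (anyNA(mentioned) || anyNA(funding) || anyNA(policies) || anyNA(quality_monitoring)) {
    stop("criterion codings must not be NA")
  }
  n_met <- funding + policies + quality_monitoring
  if (any(n_met > 0L & !mentioned)) {
    stop("inadmissible coding: a criterion is met but sustainability_mentioned is FALSE")
  }
  grade <- ifelse(n_met >= 1L, 2L + n_met, ifelse(mentioned, 2L, 1L))
  as.integer(grade)
}

#' Check coder agreement and form a consensus grade
#'
#' Independent coders rated each document on the 1-5 scale, with disagreements
#' resolved by consensus. When a human consensus grade is supplied it is used
#' as-is; otherwise the median grade is taken, with ties between the two middle
#' values broken toward the *lower* grade (conservative: does not overclaim
#' sustainability), and the result is flagged as an automatic fallback.
#'
#' @param grades integer vector of individual coder grades (1..5), length >= 1.
#' @param consensus optional supplied consensus grade (1..5).
#' @return A list with `within_one` (all grades agree within 1 unit),
#'   `consensus` (the consensus grade) and `fallback` (`TRUE` if the median
#'   fallback was used instead of a supplied consensus).
#' @examples
#' consensus_check(c(4, 4, 5))  # within_one TRUE, consensus 4
#' consensus_check(c(2, 5))     # within_one FALSE, consensus 2 (fallback)
#' @export
consensus_check <- function(grades, consensus = NULL) {
  if (length(grades) < 1L) stop("at least one coder grade is required")
  if (!all(grades %in% 1:5)) stop("grades must be integers in 1..5")
  within_one <- (max(grades) - min(grades)) <= 1L
  if (!is.null(consensus)) {
    if (length(consensus) != 1L || !consensus %in% 1:5) {
      stop("supplied consensus must be a single grade in 1..5")
    }
    return(list(within_one = within_one,
                consensus = as.integer(consensus),
                fallback = FALSE))
  }
  s <- sort(as.integer(grades))
  med <- s[floor((length(s) + 1L) / 2L)]  # lower-middle on even counts
  list(within_one = within_one, consensus = med, fallback = TRUE)
}

#' Summarize a corpus of graded documents
#'
#' Tabulates grade, criterion and sustained-activity counts and percentages
#' over a corpus, in the layout used to report the distribution of
#' sustainability ratings. Percentages are computed on the full document count
#' and kept unrounded internally; rounding to one decimal happens only in the
#' report layer ([format()] / [write_corpus_summary()]).
#'
#' @param ratings data.frame with columns `doc_id`, `grade` (1..5), one row
#'   per document.
#' @param assessments optional data.frame with columns `doc_id`, `mentioned`,
#'   `funding`, `policies`, `quality_monitoring`.
#' @param activities optional data.frame with columns `doc_id`, `moud`,
#'   `overdose`, `prevention`, `maintenance_recovery`,
#'   `implementation_support`. Activity profiles are only defined for
#'   documents graded 2 or higher; supplying one for a grade-1 document is an
#'   error.
#' @return An object of class `corpus_summary`: a list with `n_docs` and
#'   data.frames `grades`, `criteria`, `activities` (columns `n`, `pct`).
#' @export
summarize_corpus <- function(ratings, assessments = NULL, activities = NULL) {
  stopifnot(is.data.frame(ratings), all(c("doc_id", "grade") %in% names(ratings)))
  if (nrow(ratings) == 0L) stop("empty corpus")
  if (anyDuplicated(ratings$doc_id)) stop("duplicate doc_id in ratings")
  if (!all(ratings$grade %in% 1:5)) stop("grades must be in 1..5")
  n <- nrow(ratings)

  grade_n <- vapply(1:5, function(g) sum(ratings$grade == g), 0L)
  grades <- data.frame(grade = 1:5, n = grade_n, pct = 100 * grade_n / n)

  criteria <- NULL
  if (!is.null(assessments)) {
    if (!all(assessments$doc_id %in% ratings$doc_id)) {
      stop("assessments contain doc_ids absent from ratings")
    }
    crit_cols <- c("funding", "policies", "quality_monitoring")
    cn <- vapply(crit_cols, function(v) sum(assessments[[v]]), 0L)
    criteria <- data.frame(criterion = crit_cols, n = cn, pct = 100 * cn / n,
                           row.names = NULL)
  }

  act_tab <- NULL
  if (!is.null(activities)) {
    g <- ratings$grade[match(activities$doc_id, ratings$doc_id)]
    if (anyNA(g)) stop("activities contain doc_ids absent from ratings")
    if (any(g < 2L)) stop("activity profile supplied for a grade-1 document")
    act_cols <- c("moud", "overdose", "prevention", "maintenance_recovery",
                  "implementation_support")
    an <- vapply(act_cols, function(v) sum(activities[[v]]), 0L)
    act_tab <- data.frame(activity = act_cols, n = an, pct = 100 * an / n,
                          row.names = NULL)
  }

  structure(list(n_docs = n, grades = grades, criteria = criteria,
                 activities = act_tab),
            class = "corpus_summary")
}

#' @export
print.corpus_summary <- function(x, digits = 1, ...) {
  cat("Corpus summary:", x$n_docs, "documents\n\nGrades:\n")
  g <- x$grades
  g$pct <- round(g$pct, digits)
  print(g, row.names = FALSE)
  if (!is.null(x$criteria)) {
    cat("\nCriteria:\n")
    cr <- x$criteria
    cr$pct <- round(cr$pct, digits)
    print(cr, row.names = FALSE)
  }
  if (!is.null(x$activities)) {
    cat("\nActivities:\n")
    a <- x$activities
    a$pct <- round(a$pct, digits)
    print(a, row.names = FALSE)
  }
  invisible(x)
}

#' Read human criteria codings
#'
#' Reads a codings CSV with one row per (document, coder): columns `doc_id`,
#' `mentioned`, `funding`, `policies`, `quality_monitoring`, `moud`,
#' `overdose`, `prevention`, `maintenance`, `impl_support`, `coder_id`,
#' `grade`, booleans coded 0/1. Per-document codings (criteria and activity
#' booleans) must agree across coders; grades may differ and are returned one
#' row per coder for consensus resolution.
#'
#' @param path CSV path.
#' @return list with data.frames `assessments` (one row per document),
#'   `activities` (documents graded >= 2 only) and `coders`
#'   (`doc_id`, `coder_id`, `grade`).
#' @export
read_codings <- function(path) {
  d <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("doc_id", "mentioned", "funding", "policies", "quality_monitoring",
            "moud", "overdose", "prevention", "maintenance", "impl_support",
            "coder_id", "grade")
  if (!all(need %in% names(d))) {
    stop("codings file must have columns: ", paste(need, collapse = ", "))
  }
  bool_cols <- c("mentioned", "funding", "policies", "quality_monitoring",
                 "moud", "overdose", "prevention", "maintenance", "impl_support")
  for (v in bool_cols) {
    if (!all(d[[v]] %in% c(0, 1))) stop("column ", v, " must be 0/1")
    d[[v]] <- d[[v]] == 1
  }
  per_doc <- d[!duplicated(d$doc_id), c("doc_id", bool_cols)]
  # codings other than the grade must not vary across coders
  chk <- unique(d[c("doc_id", bool_cols)])
  if (anyDuplicated(chk$doc_id)) stop("criteria/activity codings differ across coders")

  assessments <- per_doc[c("doc_id", "mentioned", "funding", "policies",
                           "quality_monitoring")]
  grade_from_crit <- score_from_criteria(assessments$mentioned,
                                         assessments$funding,
                                         assessments$policies,
                                         assessments$quality_monitoring)
  act <- per_doc[grade_from_crit >= 2L,
                 c("doc_id", "moud", "overdose", "prevention", "maintenance",
                   "impl_support")]
  names(act) <- c("doc_id", "moud", "overdose", "prevention",
                  "maintenance_recovery", "implementation_support")
  list(assessments = assessments,
       activities = act,
       coders = d[c("doc_id", "coder_id", "grade")])
}

#' Write a corpus summary to CSV or JSON
#'
#' @param x a `corpus_summary`.
#' @param path output file path.
#' @param format `"csv"` (long table: section, item, n, pct) or `"json"`.
#' @param digits decimal places for the report-layer percentages.
#' @return `path`, invisibly.
#' @export
write_corpus_summary <- function(x, path, format = c("csv", "json"), digits = 1) {
  stopifnot(inherits(x, "corpus_summary"))
  format <- match.arg(format)
  long <- data.frame(section = "grade", item = as.character(x$grades$grade),
                     n = x$grades$n, pct = round(x$grades$pct, digits))
  if (!is.null(x$criteria)) {
    long <- rbind(long, data.frame(section = "criterion",
                                   item = x$criteria$criterion,
                                   n = x$criteria$n,
                                   pct = round(x$criteria$pct, digits)))
  }
  if (!is.null(x$activities)) {
    long <- rbind(long, data.frame(section = "activity",
                                   item = x$activities$activity,
                                   n = x$activities$n,
                                   pct = round(x$activities$pct, digits)))
  }
  if (format == "csv") {
    utils::write.csv(long, path, row.names = FALSE)
  } else {
    jsonlite::write_json(list(n_docs = x$n_docs, rows = long), path,
                         auto_unbox = TRUE, digits = NA)
  }
  invisible(path)
}
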