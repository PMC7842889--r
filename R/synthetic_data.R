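# Synthetic inputs with the statistical structure the analysis assumes:
# documents whose keyword densities depend on a latent 1-5 sustainability
# grade, state covariate tables with published group moments, one specified
# correlation and a cumulative-logit grade model, and null p-value sets.

#' Default per-token keyword injection rates
#'
#' A categories-by-grades matrix of per-token injection probabilities. Base
#' rates are set so that at the nominal 1500-token document length the
#' expected per-category keyword counts match the published corpus means
#' (education 5.15, prevention 4.56, rescue 1.62, intervention 77.09,
#' implementation 5.5, sustainability 8.62, evaluation 35.82, assistance
#' 5.26, adaptation 0.35, partnership 8.5, education strategies 24.71,
#' consumer engagement 8.35, financial strategies 6.44, infrastructure
#' 3.32). The sustainability category is tilted linearly in the grade
#' (factor 0.55 + 0.15 g: grade 1 gets 70% of the base rate, grade 5 gets
#' 130%), so keyword density carries the grade signal; other categories are
#' grade-independent.
#'
#' @param nominal_length token length at which base rates reproduce the mean
#'   counts.
#' @return matrix (14 categories x 5 grades) of rates in `[0, 1]`.
#' @export
default_injection_rates <- function(nominal_length = 1500) {
  mean_words <- c(education = 5.15, prevention = 4.56, rescue = 1.62,
                  intervention = 77.09, implementation = 5.5,
                  sustainability = 8.62, evaluation = 35.82, assistance = 5.26,
                  adaptation = 0.35, partnership = 8.5,
                  education_strategies = 24.71, consumer_engagement = 8.35,
                  financial_strategies = 6.44, infrastructure = 3.32)
  base <- mean_words / nominal_length
  rates <- matrix(rep(base, 5), ncol = 5,
                  dimnames = list(names(base), paste0("g", 1:5)))
  tilt <- 0.55 + 0.15 * (1:5)
  rates["sustainability", ] <- base["sustainability"] * tilt
  rates
}

#' Synthetic-corpus configuration
#'
#' @param n_docs number of documents.
#' @param grade_probs probability of each grade 1..5; defaults to the
#'   published corpus distribution (3, 8, 11, 10, 2)/34.
#' @param doc_length_mean,doc_length_size negative-binomial document-length
#'   parameters (tokens); negative-binomial lengths avoid a degenerate
#'   equal-length corpus.
#' @param injection_rates categories-by-5 matrix of per-token term-injection
#'   probabilities, as from [default_injection_rates()]. Row names must be
#'   lexicon categories.
#' @param lexicon the `keyword_lexicon` whose terms get injected.
#' @param filler_vocab_size number of distinct filler words.
#' @param activity_probs probability each of the five activities is coded
#'   sustained for documents graded >= 2; defaults to the published activity
#'   shares among the 31 graded-2-or-higher documents.
#' @param seed integer seed (recorded in the output).
#' @return list of class `corpus_config`.
#' @export
corpus_config <- function(n_docs = 34L,
                          grade_probs = c(3, 8, 11, 10, 2) / 34,
                          doc_length_mean = 1500,
                          doc_length_size = 8,
                          injection_rates = default_injection_rates(),
                          lexicon = default_lexicon(),
                          filler_vocab_size = 500L,
                          activity_probs = c(moud = 25, overdose = 16,
                                             prevention = 23,
                                             maintenance_recovery = 23,
                                             implementation_support = 16) / 31,
                          seed = 1L) {
  stopifnot(n_docs >= 1, length(grade_probs) == 5,
            abs(sum(grade_probs) - 1) < 1e-8, all(grade_probs >= 0),
            doc_length_mean > 0, doc_length_size > 0, filler_vocab_size >= 1)
  if (any(injection_rates < 0 | injection_rates > 1)) {
    stop("injection rates must lie in [0,1]")
  }
  if (any(colSums(injection_rates) > 1)) {
    stop("rates imply more than one expected injection per token position")
  }
  if (!all(rownames(injection_rates) %in% names(lexicon))) {
    stop("injection rate rows must name lexicon categories")
  }
  structure(list(n_docs = as.integer(n_docs), grade_probs = grade_probs,
                 doc_length_mean = doc_length_mean,
                 doc_length_size = doc_length_size,
                 injection_rates = injection_rates, lexicon = lexicon,
                 filler_vocab_size = as.integer(filler_vocab_size),
                 activity_probs = activity_probs, seed = as.integer(seed)),
            class = "corpus_config")
}

# inverse of the scoring rubric: draw criteria consistent with a grade
.criteria_from_grade <- function(grade) {
  crit <- c(funding = FALSE, policies = FALSE, quality_monitoring = FALSE)
  if (grade >= 3L) {
    met <- sample(names(crit), grade - 2L)
    crit[met] <- TRUE
  }
  c(mentioned = grade >= 2L, crit)
}

#' Generate a synthetic document corpus
#'
#' Each document draws a grade from `grade_probs` and a negative-binomial
#' token length, fills positions with filler words, then for each lexicon
#' category draws a Binomial(length, rate(category, grade)) number of
#' injections and writes a uniformly chosen term from that category over
#' randomly chosen free positions (multiword terms occupy consecutive
#' positions; an injection that cannot find free room is skipped, which is
#' rare at realistic rates). Sentences of random length (8-20 tokens) are
#' marked with periods. Criteria codings are drawn consistently with the
#' grade via the rubric's inverse (grade g >= 3 means g-2 criteria chosen
#' at random), so applying [score_from_criteria()] to the emitted codings
#' reproduces the drawn grades exactly. Activity profiles are emitted for
#' documents graded >= 2.
#'
#' Identical configuration (including seed) gives byte-identical output.
#'
#' @param config a [corpus_config()].
#' @return list: `documents` (data.frame `doc_id`, `text`), `grades`
#'   (`doc_id`, `grade`), `assessments`, `activities`, `config`.
#' @export
gen_corpus <- function(config = corpus_config()) {
  stopifnot(inherits(config, "corpus_config"))
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old), add = TRUE)
  set.seed(config$seed)
  filler <- sprintf("filler%04d", seq_len(config$filler_vocab_size))
  cats <- rownames(config$injection_rates)
  term_tokens <- lapply(config$lexicon, function(terms) {
    lapply(terms, .tokenize_string)
  })

  docs <- vector("list", config$n_docs)
  grades <- integer(config$n_docs)
  assess <- vector("list", config$n_docs)
  acts <- vector("list", config$n_docs)
  for (d in seq_len(config$n_docs)) {
    g <- sample.int(5L, 1L, prob = config$grade_probs)
    grades[d] <- g
    L <- max(50L, stats::rnbinom(1L, size = config$doc_length_size,
                                 mu = config$doc_length_mean))
    tokens <- sample(filler, L, replace = TRUE)
    free <- rep(TRUE, L)
    for (cat in cats) {
      rate <- config$injection_rates[cat, g]
      k <- stats::rbinom(1L, L, rate)
      if (k == 0L) next
      tt <- term_tokens[[cat]]
      for (inj in seq_len(k)) {
        term <- tt[[sample.int(length(tt), 1L)]]
        len <- length(term)
        starts <- which(free[seq_len(L - len + 1L)])
        # keep only starts whose whole span is free
        if (len > 1L) {
          starts <- starts[vapply(starts, function(s) all(free[s:(s + len - 1L)]), TRUE)]
        }
        if (length(starts) == 0L) next
        s <- starts[sample.int(length(starts), 1L)]
        tokens[s:(s + len - 1L)] <- term
        free[s:(s + len - 1L)] <- FALSE
      }
    }
    # sentence breaks every 8-20 tokens
    text <- character(0)
    i <- 1L
    while (i <= L) {
      j <- min(L, i + sample(8:20, 1L) - 1L)
      text <- c(text, paste0(paste(tokens[i:j], collapse = " "), "."))
      i <- j + 1L
    }
    docs[[d]] <- paste(text, collapse = " ")

    cr <- .criteria_from_grade(g)
    assess[[d]] <- data.frame(doc_id = sprintf("doc%03d", d),
                              mentioned = cr[["mentioned"]],
                              funding = cr[["funding"]],
                              policies = cr[["policies"]],
                              quality_monitoring = cr[["quality_monitoring"]],
                              stringsAsFactors = FALSE)
    if (g >= 2L) {
      ap <- config$activity_probs
      acts[[d]] <- data.frame(doc_id = sprintf("doc%03d", d),
                              moud = stats::runif(1) < ap[["moud"]],
                              overdose = stats::runif(1) < ap[["overdose"]],
                              prevention = stats::runif(1) < ap[["prevention"]],
                              maintenance_recovery = stats::runif(1) < ap[["maintenance_recovery"]],
                              implementation_support = stats::runif(1) < ap[["implementation_support"]],
                              stringsAsFactors = FALSE)
    }
  }
  ids <- sprintf("doc%03d", seq_len(config$n_docs))
  list(documents = data.frame(doc_id = ids,
                              text = unlist(docs), stringsAsFactors = FALSE),
       grades = data.frame(doc_id = ids, grade = grades,
                           stringsAsFactors = FALSE),
       assessments = do.call(rbind, assess),
       activities = if (any(grades >= 2L)) do.call(rbind, acts[grades >= 2L]) else NULL,
       config = config)
}

#' State-table configuration
#'
#' Defaults reproduce the published SOR-state covariate moments (means and
#' SDs of the 34 SOR-providing states), the single published correlation
#' (0.94 between opioid misuse at ages 12+ and 26+; identity elsewhere),
#' and a cumulative-logit grade model whose default thresholds match the
#' published grade distribution at `beta = 0`.
#'
#' `beta` acts on the standardized (latent normal) covariate scores, i.e.
#' it is a per-SD log-odds; this keeps effects comparable across covariates
#' whose raw units differ by orders of magnitude.
#'
#' @param n_states number of states.
#' @param sor_share share of states flagged as having provided an SOR
#'   application (default 34/50).
#' @param covariate_means,covariate_sds named vectors over the continuous
#'   covariates.
#' @param bool_probs named probabilities for the two policy flags.
#' @param correlation positive-semidefinite correlation matrix over all
#'   covariates (continuous then boolean-latent), or `NULL` for the default.
#' @param beta named (or full-length) per-SD effect vector over the
#'   continuous covariates; zero by default.
#' @param theta 4 increasing cumulative-logit thresholds.
#' @param seed integer seed.
#' @return list of class `state_table_config`.
#' @export
state_table_config <- function(n_states = 50L, sor_share = 34 / 50,
                               covariate_means = NULL, covariate_sds = NULL,
                               bool_probs = c(medicaid_expansion = 27 / 34,
                                              moud_covered = 27 / 34),
                               correlation = NULL, beta = NULL,
                               theta = stats::qlogis(c(3, 11, 22, 32) / 34),
                               seed = 1L) {
  def_means <- c(population = 6.9e6, urban_pct = 75.4, minority_pct = 31.2,
                 poverty_pct = 12.9, uninsured_pct = 7.5,
                 opioid_rx_per100 = 59.9, misuse12plus_pct = 4.55,
                 misuse12_17_pct = 3.66, misuse18_25_pct = 8.21,
                 misuse26plus_pct = 4.05, admissions_per100k = 214,
                 deaths_per100k = 19.5, sor_dollars_per_person = 4.29,
                 mm_clinics_per100k = 0.61,
                 misuse_per_mm_center_per100k = 8.12,
                 rx_physicians_per100k = 18.2)
  def_sds <- c(population = 7.6e6, urban_pct = 14, minority_pct = 17.1,
               poverty_pct = 2.95, uninsured_pct = 2.62,
               opioid_rx_per100 = 14.1, misuse12plus_pct = 0.762,
               misuse12_17_pct = 1.14, misuse18_25_pct = 1.62,
               misuse26plus_pct = 0.86, admissions_per100k = 229,
               deaths_per100k = 10.7, sor_dollars_per_person = 3.79,
               mm_clinics_per100k = 0.41, misuse_per_mm_center_per100k = 4.28,
               rx_physicians_per100k = 7.93)
  if (is.null(covariate_means)) covariate_means <- def_means
  if (is.null(covariate_sds)) covariate_sds <- def_sds
  stopifnot(identical(names(covariate_means), names(covariate_sds)),
            all(covariate_sds > 0), n_states >= 4)
  vars <- c(names(covariate_means), names(bool_probs))
  if (is.null(correlation)) {
    correlation <- diag(length(vars))
    dimnames(correlation) <- list(vars, vars)
    pair <- c("misuse12plus_pct", "misuse26plus_pct")
    if (all(pair %in% vars)) {
      correlation[pair[1], pair[2]] <- 0.94
      correlation[pair[2], pair[1]] <- 0.94
    }
  }
  stopifnot(nrow(correlation) == length(vars))
  ev <- eigen(correlation, symmetric = TRUE, only.values = TRUE)$values
  if (min(ev) < -1e-8) stop("correlation matrix is not positive semidefinite")
  b <- stats::setNames(numeric(length(covariate_means)), names(covariate_means))
  if (!is.null(beta)) {
    if (is.null(names(beta))) {
      stopifnot(length(beta) <= length(b))
      b[seq_along(beta)] <- beta
    } else {
      stopifnot(all(names(beta) %in% names(b)))
      b[names(beta)] <- beta
    }
  }
  stopifnot(length(theta) == 4, all(diff(theta) > 0))
  structure(list(n_states = as.integer(n_states), sor_share = sor_share,
                 covariate_means = covariate_means, covariate_sds = covariate_sds,
                 bool_probs = bool_probs, correlation = correlation,
                 beta = b, theta = theta, seed = as.integer(seed)),
            class = "state_table_config")
}

# continuous marginals: lognormal for strictly-positive skewed scales,
# normal (clipped to the admissible range) for percent-like covariates
.lognormal_vars <- c("population", "admissions_per100k", "deaths_per100k",
                     "sor_dollars_per_person", "mm_clinics_per100k",
                     "misuse_per_mm_center_per100k")

#' Generate a synthetic state covariate table
#'
#' Draws covariates from a Gaussian copula with the configured moments and
#' correlation: percent-like covariates get normal marginals (clipped to
#' their admissible range), heavily right-skewed positive covariates
#' (population, admission/death rates, dollars, clinic rates) get lognormal
#' marginals with matching mean and SD, and the two policy flags are the
#' latent normals thresholded at their configured probabilities. The
#' sustainability grade is drawn from the cumulative-logit model
#' `logit P(Y <= j) = theta_j - z'beta` where `z` are the standardized
#' latent covariate scores. Seed-reproducible.
#'
#' @param config a [state_table_config()].
#' @return list: `states` (data.frame with `state_id`, `sor_provided`, all
#'   covariates), `grades` (integer 1..5), `scores` (matrix of latent
#'   standardized covariate scores), `config`.
#' @export
gen_state_table <- function(config = state_table_config()) {
  stopifnot(inherits(config, "state_table_config"))
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old), add = TRUE)
  set.seed(config$seed)
  n <- config$n_states
  cm <- config$covariate_means
  cs <- config$covariate_sds
  vars <- c(names(cm), names(config$bool_probs))
  z <- MASS::mvrnorm(n, mu = rep(0, length(vars)), Sigma = config$correlation)
  colnames(z) <- vars

  states <- data.frame(state_id = sprintf("S%02d", seq_len(n)),
                       stringsAsFactors = FALSE)
  n_sor <- round(n * config$sor_share)
  states$sor_provided <- seq_len(n) %in% sample.int(n, n_sor)
  for (v in names(cm)) {
    if (v %in% .lognormal_vars) {
      sdlog2 <- log(1 + cs[[v]]^2 / cm[[v]]^2)
      x <- stats::qlnorm(stats::pnorm(z[, v]),
                         meanlog = log(cm[[v]]) - sdlog2 / 2,
                         sdlog = sqrt(sdlog2))
    } else {
      x <- cm[[v]] + cs[[v]] * z[, v]
      if (grepl("_pct$", v)) x <- pmin(100, pmax(0, x))
      else x <- pmax(0, x)
    }
    states[[v]] <- x
  }
  for (v in names(config$bool_probs)) {
    states[[v]] <- z[, v] < stats::qnorm(config$bool_probs[[v]])
  }

  eta <- drop(z[, names(cm), drop = FALSE] %*% config$beta)
  cum <- stats::plogis(outer(eta, config$theta, function(e, t) t - e))
  u <- stats::runif(n)
  grades <- rowSums(u > cbind(cum, 1)) + 1L  # category from cumulative probs
  list(states = states, grades = as.integer(grades),
       scores = z[, names(cm), drop = FALSE], config = config)
}

#' Generate a seeded null p-value set
#'
#' `k` independent Uniform(0,1) draws -- the simulated null for the p-p
#' diagnostic.
#'
#' @param k number of draws.
#' @param seed integer seed.
#' @return numeric vector of length `k`.
#' @export
gen_null_pvalues <- function(k, seed = 1L) {
  stopifnot(k >= 1)
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old), add = TRUE)
  set.seed(seed)
  stats::runif(k)
}
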