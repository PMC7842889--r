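small_corpus_config <- function(...) {
  corpus_config(n_docs = 20L, doc_length_mean = 200, ...)
}

test_that("corpus generation is byte-identical under an identical config", {
  c1 <- gen_corpus(small_corpus_config(seed = 5))
  c2 <- gen_corpus(small_corpus_config(seed = 5))
  expect_identical(c1$documents, c2$documents)
  expect_identical(c1$grades, c2$grades)
  expect_identical(c1$assessments, c2$assessments)
  c3 <- gen_corpus(small_corpus_config(seed = 6))
  expect_false(identical(c1$documents$text, c3$documents$text))
})

test_that("zero injection rates produce zero category frequencies", {
  rates <- default_injection_rates()
  rates[] <- 0
  corp <- gen_corpus(small_corpus_config(injection_rates = rates, seed = 2))
  feats <- corpus_features(corp$documents)
  freq_cols <- grep("^freq_", names(feats), value = TRUE)
  expect_true(all(as.matrix(feats[freq_cols]) == 0))
})

test_that("invalid injection configurations are rejected", {
  rates <- default_injection_rates()
  rates[1, 1] <- 1.5
  expect_error(corpus_config(injection_rates = rates), "0,1")
  rates <- default_injection_rates()
  rates[] <- 0.2  # 14 categories x 0.2 > 1 expected injection per position
  expect_error(corpus_config(injection_rates = rates), "expected injection")
  rates <- matrix(0.01, 1, 5, dimnames = list("nonexistent", paste0("g", 1:5)))
  expect_error(corpus_config(injection_rates = rates), "lexicon categories")
})

test_that("observed keyword frequency matches the binomial injection rate", {
  r <- 0.02
  rates <- matrix(r, 1, 5, dimnames = list("sustainability", paste0("g", 1:5)))
  corp <- gen_corpus(corpus_config(n_docs = 100L, doc_length_mean = 300,
                                   injection_rates = rates, seed = 8))
  feats <- corpus_features(corp$documents)
  mean_freq <- mean(feats$freq_sustainability)
  total_tokens <- sum(feats$token_count)
  se <- sqrt(r * (1 - r) / total_tokens)
  expect_lt(abs(mean_freq - r), 3 * se + 1e-4)
})

test_that("emitted criteria invert the rubric exactly", {
  corp <- gen_corpus(small_corpus_config(seed = 11))
  regraded <- score_from_criteria(corp$assessments$mentioned,
                                  corp$assessments$funding,
                                  corp$assessments$policies,
                                  corp$assessments$quality_monitoring)
  expect_identical(regraded, corp$grades$grade)
  # activities only for graded >= 2 documents
  expect_true(all(corp$grades$grade[match(corp$activities$doc_id,
                                          corp$grades$doc_id)] >= 2))
})

test_that("state tables reproduce configured moments, marginals and correlation", {
  cfg <- state_table_config(n_states = 2000, seed = 14)
  st <- gen_state_table(cfg)
  expect_identical(nrow(st$states), 2000L)
  expect_identical(gen_state_table(cfg)$states, st$states)

  # the one specified correlation (0.94) survives the copula
  r <- cor(st$states$misuse12plus_pct, st$states$misuse26plus_pct)
  expect_lt(abs(r - 0.94), 0.03)

  # normal-marginal covariates match their configured moments
  expect_lt(abs(mean(st$states$poverty_pct) - 12.9), 0.25)
  expect_lt(abs(sd(st$states$poverty_pct) - 2.95), 0.25)
  # lognormal marginals match mean and sd too
  expect_lt(abs(mean(st$states$sor_dollars_per_person) - 4.29) / 4.29, 0.1)
  expect_lt(abs(sd(st$states$sor_dollars_per_person) - 3.79) / 3.79, 0.15)
  # percent covariates stay in range, rates stay non-negative
  expect_true(all(st$states$urban_pct >= 0 & st$states$urban_pct <= 100))
  expect_true(all(st$states$population > 0))
  # policy flags near their configured probabilities
  expect_lt(abs(mean(st$states$medicaid_expansion) - 27 / 34), 0.04)

  # null model: grade marginal matches the theta-implied distribution
  implied <- diff(c(0, plogis(cfg$theta), 1))
  obs <- tabulate(st$grades, 5) / 2000
  expect_lt(max(abs(obs - implied)), 0.035)
})

test_that("cumulative-logit effects in the generator are recoverable", {
  st <- gen_state_table(state_table_config(
    n_states = 2000, beta = c(poverty_pct = 1.0), seed = 20))
  # fitting on the standardized latent scores recovers the per-SD effect
  f <- fit_cumulative_logit(st$scores[, "poverty_pct", drop = FALSE],
                            st$grades)
  expect_lt(abs(unname(f$beta) - 1.0), 0.15)
})

test_that("null p-value draws are seeded, bounded uniforms", {
  p1 <- gen_null_pvalues(15, seed = 4)
  expect_identical(p1, gen_null_pvalues(15, seed = 4))
  expect_false(identical(p1, gen_null_pvalues(15, seed = 5)))
  expect_true(all(p1 >= 0 & p1 <= 1))
  big <- gen_null_pvalues(20000, seed = 6)
  expect_lt(abs(mean(big) - 0.5), 3 * sqrt(1 / 12 / 20000))
})

test_that("strong grade separation in the generator yields near-perfect LOOCV", {
  rates <- default_injection_rates()
  rates["sustainability", ] <- c(0.0005, 0.0005, 0.0005, 0.05, 0.05)
  corp <- gen_corpus(corpus_config(n_docs = 60L, doc_length_mean = 300,
                                   injection_rates = rates, seed = 1))
  counts <- corpus_features(corp$documents, counts = TRUE)
  cnt <- as.matrix(counts[grep("^count_", names(counts))])
  cv <- loocv(cnt, dichotomize(corp$grades$grade),
              classifier_spec("multinomial_bayes"))
  expect_gte(cv$accuracy, 0.95)
})
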