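test_that("dichotomization maps every grade", {
  expect_identical(as.character(dichotomize(1:5)),
                   c("low", "low", "low", "high", "high"))
  expect_identical(levels(dichotomize(3)), c("low", "high"))
  expect_error(dichotomize(6), "1..5")
})

test_that("multinomial naive Bayes follows Bayes rule with Laplace smoothing", {
  # one training doc per class with disjoint single-term vocabularies
  tr <- rbind(c(5, 0), c(0, 5))
  lab <- factor(c("low", "high"), levels = c("low", "high"))
  te <- rbind(c(3, 0), c(0, 3))
  pred <- fit_predict_multinomial_bayes(tr, lab, te)
  expect_identical(as.character(pred), c("low", "high"))

  # uniform counts and equal priors: tie broken toward low
  tr2 <- rbind(c(2, 2), c(2, 2))
  te2 <- rbind(c(1, 1))
  expect_identical(as.character(fit_predict_multinomial_bayes(tr2, lab, te2)),
                   "low")

  expect_error(fit_predict_multinomial_bayes(rbind(c(-1, 0)), lab[1],
                                             te2), "non-negative")
})

test_that("naive Bayes matches exact posterior enumeration on small instances", {
  withr::with_seed(99, {
    for (rep in 1:30) {
      n_tr <- sample(2:5, 1)
      n_terms <- sample(2:4, 1)
      tr <- matrix(rpois(n_tr * n_terms, 2), n_tr, n_terms)
      lab <- factor(sample(c("low", "high"), n_tr, replace = TRUE),
                    levels = c("low", "high"))
      if (nlevels(droplevels(lab)) < 2) lab[1] <- setdiff(c("low", "high"),
                                                          as.character(lab[1]))
      te <- matrix(rpois(2 * n_terms, 2), 2, n_terms)
      sm <- sample(c(0.5, 1, 2), 1)
      expect_identical(
        as.character(fit_predict_multinomial_bayes(tr, lab, te, smoothing = sm)),
        unname(oracle_nb_predict(tr, lab, te, smoothing = sm)),
        info = paste("rep", rep))
    }
  })
})

test_that("naive Bayes predictions are stable under training-set duplication", {
  withr::with_seed(4, {
    tr <- matrix(rpois(8 * 5, 3), 8, 5)
    lab <- factor(rep(c("low", "high"), each = 4), levels = c("low", "high"))
    te <- matrix(rpois(6 * 5, 3), 6, 5)
  })
  p1 <- fit_predict_multinomial_bayes(tr, lab, te)
  p2 <- fit_predict_multinomial_bayes(rbind(tr, tr), c(lab, lab), te)
  expect_identical(p1, p2)
})

test_that("LOOCV accuracy is a fold-count multiple and flags one-class folds", {
  # all-equal count features: every score ties, so every prediction is low
  # (the constant classifier) and accuracy equals the majority-class share
  feats <- matrix(1, 10, 3)
  labels <- dichotomize(c(rep(2, 7), rep(5, 3)))
  cv <- loocv(feats, labels, classifier_spec("multinomial_bayes"))
  expect_equal(cv$accuracy, 0.7)
  expect_equal(cv$majority_baseline, 0.7)
  expect_identical(nrow(cv$predictions), 10L)
  expect_true(all(cv$accuracy * cv$n == round(cv$accuracy * cv$n)))

  # a training fold left with a single class predicts that class, flagged
  labels2 <- dichotomize(c(rep(2, 9), 5))
  cv2 <- loocv(feats, labels2, classifier_spec("multinomial_bayes"))
  expect_true(cv2$predictions$flagged[10])
  expect_identical(as.character(cv2$predictions$pred[10]), "low")

  expect_error(loocv(feats[1:2, ], labels[1:2],
                     classifier_spec("multinomial_bayes")), "at least 3")
  expect_error(loocv(feats, rep(factor("low", levels = c("low", "high")), 10),
                     classifier_spec("multinomial_bayes")), "both labels")
})

test_that("the max-margin backend separates separable data and is deterministic", {
  withr::with_seed(31, {
    x <- rbind(matrix(rnorm(20, mean = 0), ncol = 2),
               matrix(rnorm(20, mean = 4), ncol = 2))
  })
  y <- factor(rep(c("low", "high"), each = 10), levels = c("low", "high"))
  pred <- fit_predict_max_margin(x, y, x, kernel = "linear", cost = 1000)
  expect_identical(pred, y)  # zero training errors at large cost

  # reproducible given identical data, kernel and cost
  p2 <- fit_predict_max_margin(x, y, x, kernel = "linear", cost = 1000)
  expect_identical(pred, p2)

  expect_error(fit_predict_max_margin(x, y, x, cost = 0), "positive")
  expect_error(fit_predict_max_margin(x, factor(rep("low", 20),
                                                levels = c("low", "high")), x),
               "both classes")
})

test_that("linear-kernel decisions agree with a brute-force margin maximizer", {
  withr::with_seed(55, {
    for (rep in 1:8) {
      # 4-point separable instance: two points per class, well apart
      shift <- runif(2, 2.5, 4)
      x <- rbind(matrix(rnorm(4, sd = 0.5), 2, 2),
                 sweep(matrix(rnorm(4, sd = 0.5), 2, 2), 2, shift, `+`))
      y <- factor(c("low", "low", "high", "high"), levels = c("low", "high"))
      orc <- oracle_max_margin_2d(x, y)
      # probe points away from the decision boundary
      te <- rbind(colMeans(x[1:2, ]), colMeans(x[3:4, ]),
                  x + matrix(rnorm(8, sd = 0.1), 4, 2))
      dec <- drop(te %*% orc$w) + orc$b
      clear <- abs(dec) > 0.3 * orc$margin
      pred <- fit_predict_max_margin(x, y, te, kernel = "linear", cost = 1e4)
      expect_identical(as.character(pred)[clear],
                       ifelse(dec > 0, "high", "low")[clear],
                       info = paste("rep", rep))
    }
  })
})

test_that("the cost grid search returns the argmax with smallest-cost ties", {
  withr::with_seed(77, {
    x <- rbind(matrix(rnorm(24, 0, 1.5), ncol = 2),
               matrix(rnorm(24, 2, 1.5), ncol = 2))
  })
  labels <- factor(rep(c("low", "high"), each = 12), levels = c("low", "high"))
  grid <- c(0.05, 0.25, 0.5, 1)
  gr <- cost_grid_search(x, labels, kernel = "linear", grid = grid)
  expect_identical(gr$costs, grid)
  expect_equal(gr$best_accuracy, max(gr$accuracies))
  # smallest cost attaining the max
  expect_equal(gr$best_cost, grid[which(gr$accuracies == max(gr$accuracies))[1]])
  # the grid evaluation is its own oracle: recompute independently
  acc2 <- vapply(grid, function(C)
    loocv(x, labels, classifier_spec("max_margin", kernel = "linear",
                                     cost = C))$accuracy, 0)
  expect_identical(gr$accuracies, acc2)
  # single-cost grid
  g1 <- cost_grid_search(x, labels, kernel = "linear", grid = 0.5)
  expect_equal(g1$best_cost, 0.5)
  expect_error(cost_grid_search(x, labels, grid = c(0, 0.5)), "positive")
})

test_that("CV reports serialize to JSON", {
  feats <- matrix(rpois(30, 3), 10, 3)
  labels <- dichotomize(c(rep(2, 6), rep(5, 4)))
  cv <- loocv(feats, labels, classifier_spec("multinomial_bayes"),
              doc_ids = sprintf("d%02d", 1:10))
  f <- withr::local_tempfile(fileext = ".json")
  write_cv_report(cv, f)
  back <- jsonlite::fromJSON(f)
  expect_equal(back$accuracy, cv$accuracy)
  expect_identical(nrow(back$predictions), 10L)
})
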