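# Independent oracles used across tests.

# Phrase-count oracle: enumerate every occurrence of every term first, then
# select non-overlapping matches left to right, longest first at each start.
oracle_count_terms <- function(tokens, terms) {
  term_tok <- lapply(terms, function(t) strsplit(tolower(t), "\\s+")[[1]])
  occ <- do.call(rbind, lapply(term_tok, function(tt) {
    L <- length(tt)
    n <- length(tokens)
    if (n < L) return(NULL)
    starts <- which(vapply(seq_len(n - L + 1L), function(s)
      all(tokens[s:(s + L - 1L)] == tt), TRUE))
    if (length(starts) == 0L) return(NULL)
    data.frame(start = starts, len = L)
  }))
  if (is.null(occ) || nrow(occ) == 0L) return(0L)
  count <- 0L
  pos <- 1L
  n <- length(tokens)
  while (pos <= n) {
    here <- occ[occ$start == pos, , drop = FALSE]
    if (nrow(here) > 0L) {
      count <- count + 1L
      pos <- pos + max(here$len)
    } else {
      pos <- pos + 1L
    }
  }
  count
}

# Exact multinomial naive Bayes posterior by direct enumeration (loops, logs
# avoided where possible): returns predicted label with ties toward "low".
oracle_nb_predict <- function(train_counts, train_labels, test_counts,
                              smoothing = 1) {
  classes <- c("low", "high")
  n <- nrow(train_counts)
  apply(test_counts, 1, function(doc) {
    post <- sapply(classes, function(cl) {
      rows <- which(train_labels == cl)
      if (length(rows) == 0L) return(-Inf)
      tc <- rep(smoothing, ncol(train_counts))
      for (r in rows) tc <- tc + train_counts[r, ]
      theta <- tc / sum(tc)
      lp <- log(length(rows) / n)
      for (j in seq_along(doc)) lp <- lp + doc[j] * log(theta[j])
      lp
    })
    if (post["high"] > post["low"] + 1e-9) "high" else "low"
  })
}

# Maximum-margin oracle for small 2-D separable instances: dense direction
# grid; for each direction the optimal threshold is midway between the
# closest projections of the two classes.
oracle_max_margin_2d <- function(x, y) {
  angles <- seq(0, pi, length.out = 3601)[-3601]
  best <- list(margin = -Inf)
  for (a in angles) {
    w <- c(cos(a), sin(a))
    proj <- drop(x %*% w)
    for (sgn in c(1, -1)) {
      p <- sgn * proj
      hi <- p[y == "high"]; lo <- p[y == "low"]
      m <- (min(hi) - max(lo)) / 2
      if (m > best$margin) {
        best <- list(margin = m, w = sgn * w,
                     b = -(min(hi) + max(lo)) / 2 * 1)
      }
    }
  }
  best  # decision value: x %*% w + b, positive => "high"
}

# simulate ordinal outcomes from logit P(Y <= j) = theta_j - eta
sim_ordinal <- function(eta, theta) {
  cum <- stats::plogis(outer(eta, theta, function(e, t) t - e))
  u <- stats::runif(length(eta))
  as.integer(rowSums(u > cbind(cum, 1)) + 1L)
}
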