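# Cumulative-logit (proportional-odds) regression, fitted by Newton iteration
# with step-halving; standard errors from the inverse observed information.
#
# Parameterization: logit P(Y <= j | x) = theta_j - x'beta, so a positive
# beta means higher covariate values shift mass toward *higher* outcome
# categories.

.cl_loglik <- function(par, x, yi, K) {
  p <- if (is.null(x)) 0L else ncol(x)
  theta <- par[seq_len(K - 1L)]
  beta <- if (p) par[K:(K - 1L + p)] else numeric(0)
  eta <- if (p) drop(x %*% beta) else rep(0, length(yi))
  up <- ifelse(yi == K, 1, stats::plogis(theta[pmin(yi, K - 1L)] - eta))
  lo <- ifelse(yi == 1L, 0, stats::plogis(theta[pmax(yi - 1L, 1L)] - eta))
  pr <- up - lo
  if (any(pr <= 0)) return(-Inf)
  sum(log(pr))
}

.cl_grad <- function(par, x, yi, K) {
  p <- if (is.null(x)) 0L else ncol(x)
  n <- length(yi)
  theta <- par[seq_len(K - 1L)]
  beta <- if (p) par[K:(K - 1L + p)] else numeric(0)
  eta <- if (p) drop(x %*% beta) else rep(0, n)
  up <- ifelse(yi == K, 1, stats::plogis(theta[pmin(yi, K - 1L)] - eta))
  lo <- ifelse(yi == 1L, 0, stats::plogis(theta[pmax(yi - 1L, 1L)] - eta))
  pr <- up - lo
  f_up <- ifelse(yi == K, 0, up * (1 - up))       # logistic density at theta_y - eta
  f_lo <- ifelse(yi == 1L, 0, lo * (1 - lo))      # at theta_{y-1} - eta
  g_theta <- numeric(K - 1L)
  for (j in seq_len(K - 1L)) {
    g_theta[j] <- sum(f_up[yi == j] / pr[yi == j]) -
      sum(f_lo[yi == j + 1L] / pr[yi == j + 1L])
  }
  if (p) {
    w <- (f_lo - f_up) / pr
    c(g_theta, drop(crossprod(x, w)))
  } else {
    g_theta
  }
}

# observed information by central finite differences of the analytic gradient
.cl_hessian <- function(par, x, yi, K) {
  np <- length(par)
  H <- matrix(0, np, np)
  h <- 1e-5 * pmax(1, abs(par))
  for (m in seq_len(np)) {
    up <- par; up[m] <- up[m] + h[m]
    dn <- par; dn[m] <- dn[m] - h[m]
    H[, m] <- (.cl_grad(up, x, yi, K) - .cl_grad(dn, x, yi, K)) / (2 * h[m])
  }
  (H + t(H)) / 2
}

#' Fit a cumulative-logit (proportional-odds) model
#'
#' Maximum-likelihood fit of `logit P(Y <= j | x) = theta_j - x'beta` for an
#' ordinal outcome with K observed categories, by Newton iteration with
#' step-halving (the step is halved until the log-likelihood does not
#' decrease and the thresholds stay strictly increasing). Standard errors
#' come from the inverse observed information at the optimum. Positive
#' coefficients mean higher outcome categories are more likely as the
#' covariate increases.
#'
#' Complete separation (or quasi-separation) is detected heuristically from
#' exploding coefficients or standard errors; when flagged, Wald standard
#' errors are suppressed (set to `NA`) and a likelihood-ratio test should be
#' used instead (see [lr_test()]).
#'
#' @param x numeric matrix or data.frame of covariates (may be `NULL` for an
#'   intercept-only model). Covariates are used in their raw units.
#' @param y ordinal outcome: integer codes or an ordered factor. Unused
#'   levels are dropped; categories are relabeled 1..K in increasing order.
#' @param tol convergence tolerance on the relative log-likelihood change.
#' @param max_iter maximum Newton iterations.
#' @return object of class `cumlogit_fit`: `beta`, `theta`, `se_beta`,
#'   `se_theta`, `vcov`, `loglik`, `loglik_trace`, `converged`, `separation`,
#'   `n_used`, `K`, `levels`, `npar`.
#' @export
fit_cumulative_logit <- function(x, y, tol = 1e-10, max_iter = 100L) {
  if (!is.null(x)) {
    x <- as.matrix(x)
    storage.mode(x) <- "double"
    keep <- stats::complete.cases(x) & !is.na(y)
    x <- x[keep, , drop = FALSE]
    y <- y[keep]
    if (is.null(colnames(x))) colnames(x) <- paste0("x", seq_len(ncol(x)))
  } else {
    y <- y[!is.na(y)]
  }
  lev <- sort(unique(as.numeric(y)))
  K <- length(lev)
  if (K < 2L) stop("outcome must have at least 2 observed categories")
  yi <- match(as.numeric(y), lev)
  n <- length(yi)
  p <- if (is.null(x)) 0L else ncol(x)
  if (n <= K - 1L + p) stop("more parameters than observations")

  cum <- cumsum(tabulate(yi, K))[seq_len(K - 1L)] / n
  par <- c(stats::qlogis(cum), rep(0, p))
  ll <- .cl_loglik(par, x, yi, K)
  trace <- ll
  converged <- FALSE
  for (iter in seq_len(max_iter)) {
    g <- .cl_grad(par, x, yi, K)
    H <- .cl_hessian(par, x, yi, K)
    step <- tryCatch(solve(H, g), error = function(e) NULL)
    if (is.null(step)) {  # singular information: ridge fallback
      step <- solve(H - diag(1e-6, nrow(H)), g)
    }
    step <- -step  # ascent direction for a (negative-definite) Hessian
    lam <- 1
    new_par <- par; new_ll <- -Inf
    for (half in 1:40) {
      cand <- par + lam * step
      th <- cand[seq_len(K - 1L)]
      if (all(diff(th) > 0) || K == 2L) {
        cand_ll <- .cl_loglik(cand, x, yi, K)
        if (is.finite(cand_ll) && cand_ll >= ll - 1e-12) {
          new_par <- cand; new_ll <- cand_ll
          break
        }
      }
      lam <- lam / 2
    }
    if (!is.finite(new_ll)) break
    par <- new_par
    trace <- c(trace, new_ll)
    if (abs(new_ll - ll) < tol * (abs(ll) + 1)) {
      ll <- new_ll
      converged <- TRUE
      break
    }
    ll <- new_ll
  }

  H <- .cl_hessian(par, x, yi, K)
  vc <- tryCatch(solve(-H), error = function(e) matrix(NA_real_, length(par), length(par)))
  se <- suppressWarnings(sqrt(diag(vc)))
  theta <- par[seq_len(K - 1L)]
  beta <- if (p) par[K:(K - 1L + p)] else numeric(0)
  if (p) names(beta) <- colnames(x)
  se_theta <- se[seq_len(K - 1L)]
  se_beta <- if (p) se[K:(K - 1L + p)] else numeric(0)
  if (p) names(se_beta) <- colnames(x)

  separation <- any(!is.finite(se)) || any(abs(beta) > 15) ||
    (p > 0 && any(se_beta > 50, na.rm = TRUE))
  if (separation) {
    se_beta[] <- NA_real_
    se_theta[] <- NA_real_
  }
  structure(list(beta = beta, theta = theta, se_beta = se_beta,
                 se_theta = se_theta, vcov = vc, loglik = ll,
                 loglik_trace = trace, converged = converged,
                 separation = separation, n_used = n, K = K, levels = lev,
                 npar = length(par)),
            class = "cumlogit_fit")
}

#' @export
print.cumlogit_fit <- function(x, ...) {
  cat("Cumulative-logit fit:", x$n_used, "obs,", x$K, "categories; logLik",
      format(x$loglik, digits = 6),
      if (!x$converged) "(NOT converged)" else "", "\n")
  if (length(x$beta)) {
    tab <- data.frame(coef = x$beta, se = x$se_beta,
                      p = wald_test(x$beta, x$se_beta))
    print(tab)
  }
  cat("thresholds:", format(x$theta, digits = 4), "\n")
  if (x$separation) cat("note: separation detected; Wald SEs suppressed\n")
  invisible(x)
}

#' Fitted category probabilities from a cumulative-logit fit
#'
#' @param object a `cumlogit_fit`.
#' @param newdata covariate matrix (same columns as the fit); `NULL` for
#'   intercept-only fits.
#' @param ... unused.
#' @return matrix of per-unit category probabilities (rows sum to 1).
#' @export
predict.cumlogit_fit <- function(object, newdata = NULL, ...) {
  eta <- if (length(object$beta)) {
    drop(as.matrix(newdata)[, names(object$beta), drop = FALSE] %*% object$beta)
  } else {
    rep(0, if (is.null(newdata)) 1L else nrow(as.matrix(newdata)))
  }
  cum <- cbind(0, stats::plogis(outer(eta, object$theta, function(e, t) t - e)), 1)
  pr <- cum[, -1, drop = FALSE] - cum[, -ncol(cum), drop = FALSE]
  colnames(pr) <- object$levels
  pr
}

#' Two-sided Wald test
#'
#' p-value of `z = coef/se` against the standard normal, the univariate test
#' used throughout the regression screens.
#'
#' @param coef coefficient estimate(s).
#' @param se standard error(s), positive.
#' @return two-sided p-value(s).
#' @export
wald_test <- function(coef, se) {
  if (any(se <= 0, na.rm = TRUE)) stop("standard errors must be positive")
  2 * stats::pnorm(-abs(coef / se))
}

#' Fit a binary logistic regression with separation detection
#'
#' Standard maximum-likelihood logistic regression (via [stats::glm()]) for
#' binary outcomes such as individual sustainability criteria, with Wald
#' standard errors. Complete or quasi-complete separation is detected (from
#' boundary fitted probabilities and exploding coefficients); when flagged,
#' Wald SEs are suppressed and a likelihood-ratio test should be used.
#'
#' @param x covariate matrix/data.frame, raw units (or `NULL`).
#' @param y binary outcome (logical, 0/1, or two-level factor).
#' @return object of class `logit_fit`: `beta` (including `(Intercept)`),
#'   `se_beta`, `vcov`, `loglik`, `converged`, `separation`, `n_used`,
#'   `npar`.
#' @export
fit_logistic <- function(x, y) {
  if (is.factor(y)) y <- as.integer(y) - 1L
  y <- as.numeric(y)
  if (!all(y %in% c(0, 1), na.rm = TRUE)) stop("outcome must be binary")
  if (!is.null(x)) {
    x <- as.matrix(x)
    storage.mode(x) <- "double"
    keep <- stats::complete.cases(x) & !is.na(y)
    x <- x[keep, , drop = FALSE]
    y <- y[keep]
    if (is.null(colnames(x))) colnames(x) <- paste0("x", seq_len(ncol(x)))
    df <- data.frame(.y = y, x, check.names = FALSE)
    fml <- stats::as.formula(paste(".y ~", paste(sprintf("`%s`", colnames(x)),
                                                 collapse = " + ")))
  } else {
    y <- y[!is.na(y)]
    df <- data.frame(.y = y)
    fml <- .y ~ 1
  }
  if (length(unique(y)) < 2L) stop("both outcome classes must be present")
  fit <- suppressWarnings(stats::glm(fml, family = stats::binomial(), data = df))
  mu <- stats::fitted(fit)
  separation <- any(abs(stats::coef(fit)) > 15, na.rm = TRUE) ||
    (any(mu < 1e-8 | mu > 1 - 1e-8) && !fit$converged) ||
    all(mu < 1e-8 | mu > 1 - 1e-8)
  se <- sqrt(diag(stats::vcov(fit)))
  if (separation) se[] <- NA_real_
  structure(list(beta = stats::coef(fit), se_beta = se,
                 vcov = stats::vcov(fit),
                 loglik = as.numeric(stats::logLik(fit)),
                 converged = fit$converged, separation = separation,
                 n_used = length(y), npar = length(stats::coef(fit))),
            class = "logit_fit")
}

#' Likelihood-ratio test between nested fits
#'
#' Chi-square test of `2 * (logLik_full - logLik_reduced)` on the
#' parameter-count difference. Used as the fallback when zero cells or
#' separation make Wald tests unusable.
#'
#' @param full,reduced nested fits (`cumlogit_fit` or `logit_fit`) on the
#'   same observations, or raw log-likelihoods (then supply `df`).
#' @param df degrees of freedom; inferred from the fits' parameter counts
#'   when omitted.
#' @return list: `statistic`, `df`, `p_value`.
#' @export
lr_test <- function(full, reduced, df = NULL) {
  ll_f <- if (is.list(full)) full$loglik else full
  ll_r <- if (is.list(reduced)) reduced$loglik else reduced
  if (is.null(df)) {
    if (!is.list(full) || !is.list(reduced)) stop("df required for raw log-likelihoods")
    df <- full$npar - reduced$npar
  }
  if (df < 0) stop("full model has fewer parameters than reduced")
  stat <- max(0, 2 * (ll_f - ll_r))
  p <- if (df == 0L) 1 else stats::pchisq(stat, df, lower.tail = FALSE)
  list(statistic = stat, df = df, p_value = p)
}

#' Univariate regression screen
#'
#' Fits one single-covariate model per covariate (cumulative-logit for
#' ordinal outcomes, logistic for binary) and reports the coefficient, SE
#' and Wald p-value, with significance flags (`*` p < 0.05, `**` p < 0.01).
#' When a fit shows separation, the Wald test is replaced by a
#' likelihood-ratio test against the intercept-only model and noted.
#'
#' @param data data.frame holding outcome and covariates.
#' @param outcome name of the outcome column.
#' @param covariates character vector of covariate names.
#' @param model_kind `"ordinal"` or `"logistic"`.
#' @return data.frame of class `screen_result`: `covariate`, `n`, `coef`,
#'   `se`, `p`, `flag`, `note`.
#' @export
univariate_screen <- function(data, outcome, covariates,
                              model_kind = c("ordinal", "logistic")) {
  model_kind <- match.arg(model_kind)
  y <- data[[outcome]]
  rows <- lapply(covariates, function(v) {
    xv <- data[[v]]
    if (is.logical(xv)) xv <- as.numeric(xv)
    xm <- matrix(xv, ncol = 1, dimnames = list(NULL, v))
    row <- data.frame(covariate = v, n = NA_integer_, coef = NA_real_,
                      se = NA_real_, p = NA_real_, flag = "", note = "",
                      stringsAsFactors = FALSE)
    fit <- tryCatch({
      if (model_kind == "ordinal") fit_cumulative_logit(xm, y)
      else fit_logistic(xm, y)
    }, error = function(e) e)
    if (inherits(fit, "error")) {
      row$note <- conditionMessage(fit)
      return(row)
    }
    cf <- if (model_kind == "ordinal") fit$beta[[v]] else fit$beta[[v]]
    se <- fit$se_beta[[v]]
    row$n <- fit$n_used
    row$coef <- cf
    if (fit$separation || is.na(se)) {
      keep <- !is.na(xv) & !is.na(y)
      null_fit <- if (model_kind == "ordinal") {
        fit_cumulative_logit(NULL, y[keep])
      } else {
        fit_logistic(NULL, y[keep])
      }
      row$p <- lr_test(fit, null_fit)$p_value
      row$note <- "separation: likelihood-ratio test"
    } else {
      row$se <- se
      row$p <- wald_test(cf, se)
    }
    row$flag <- if (is.na(row$p)) "" else if (row$p < 0.01) "**"
      else if (row$p < 0.05) "*" else ""
    row
  })
  res <- do.call(rbind, rows)
  class(res) <- c("screen_result", class(res))
  res
}

#' Prune collinear covariates
#'
#' For every covariate pair with `|Pearson r| > threshold`, keeps the member
#' listed earlier in `priority` and drops the later one. Pairs are resolved
#' greedily in priority order, so in a transitive triple the
#' highest-priority member is kept and every variable too correlated with an
#' already-kept variable is dropped.
#'
#' @param data data.frame containing the covariates.
#' @param covariates covariate names to consider.
#' @param threshold absolute-correlation threshold (default 0.9).
#' @param priority ordering used to break pairs; defaults to `covariates`
#'   order.
#' @return list: `kept` (names), `dropped` (data.frame `dropped`,
#'   `kept_partner`, `r`).
#' @export
collinearity_prune <- function(data, covariates, threshold = 0.9,
                               priority = covariates) {
  stopifnot(all(covariates %in% names(data)), all(covariates %in% priority))
  x <- data[covariates]
  x[] <- lapply(x, function(v) if (is.logical(v)) as.numeric(v) else v)
  r <- stats::cor(as.matrix(x), use = "pairwise.complete.obs")
  kept <- character(0)
  dropped <- data.frame(dropped = character(0), kept_partner = character(0),
                        r = numeric(0), stringsAsFactors = FALSE)
  for (v in priority[priority %in% covariates]) {
    if (v %in% dropped$dropped) next
    if (any(abs(r[v, kept]) > threshold)) {
      partner <- kept[which.max(abs(r[v, kept]))]
      dropped <- rbind(dropped, data.frame(dropped = v, kept_partner = partner,
                                           r = r[v, partner],
                                           stringsAsFactors = FALSE))
    } else {
      kept <- c(kept, v)
    }
  }
  list(kept = kept, dropped = dropped)
}

#' Backward stepwise elimination
#'
#' Starting from the supplied covariate set (typically those passing the
#' univariate screen at p <= 0.20, after collinearity pruning), repeatedly
#' refits the model and removes the covariate with the largest Wald p-value
#' while that p-value exceeds `alpha_stay`. An empty starting set, or
#' elimination of every covariate, yields the intercept-only model.
#'
#' @param data data.frame holding outcome and covariates.
#' @param outcome outcome column name.
#' @param entered covariate names entering the model.
#' @param model_kind `"ordinal"` or `"logistic"`.
#' @param alpha_stay stay-level (default 0.05).
#' @return list of class `stepwise_result`: `entered`, `eliminated`
#'   (data.frame `covariate`, `p_at_removal`, in removal order), `final`
#'   (the final fit), `final_covariates`.
#' @export
backward_stepwise <- function(data, outcome, entered,
                              model_kind = c("ordinal", "logistic"),
                              alpha_stay = 0.05) {
  model_kind <- match.arg(model_kind)
  y <- data[[outcome]]
  current <- entered
  eliminated <- data.frame(covariate = character(0), p_at_removal = numeric(0),
                           stringsAsFactors = FALSE)
  fit_fun <- function(vars) {
    if (length(vars) == 0L) {
      if (model_kind == "ordinal") fit_cumulative_logit(NULL, y)
      else fit_logistic(NULL, y)
    } else {
      x <- data[vars]
      x[] <- lapply(x, function(v) if (is.logical(v)) as.numeric(v) else v)
      if (model_kind == "ordinal") fit_cumulative_logit(as.matrix(x), y)
      else fit_logistic(as.matrix(x), y)
    }
  }
  fit <- fit_fun(current)
  while (length(current) > 0L) {
    ps <- wald_test(fit$beta[current], fit$se_beta[current])
    ps[is.na(ps)] <- 1  # unusable Wald SE (separation): remove that term
    worst <- which.max(ps)
    if (ps[worst] <= alpha_stay) break
    eliminated <- rbind(eliminated,
                        data.frame(covariate = current[worst],
                                   p_at_removal = unname(ps[worst]),
                                   stringsAsFactors = FALSE))
    current <- current[-worst]
    fit <- fit_fun(current)
  }
  structure(list(entered = entered, eliminated = eliminated, final = fit,
                 final_covariates = current),
            class = "stepwise_result")
}

#' Full screening-and-selection procedure
#'
#' The complete multivariable modeling recipe: univariate screen, entry of
#' covariates at p <= `alpha_enter` (default 0.20), collinearity pruning at
#' `|r| > collin_threshold` (default 0.9, keeping the earlier-listed
#' variable), then backward stepwise elimination at `alpha_stay` (default
#' 0.05).
#'
#' @inheritParams univariate_screen
#' @param alpha_enter univariate entry threshold.
#' @param collin_threshold absolute-correlation pruning threshold.
#' @param alpha_stay backward-elimination stay level.
#' @return list: `screen` (the univariate table), `pruned`
#'   (collinearity-prune result), `stepwise` (a `stepwise_result`).
#' @export
stepwise_model <- function(data, outcome, covariates,
                           model_kind = c("ordinal", "logistic"),
                           alpha_enter = 0.20, collin_threshold = 0.9,
                           alpha_stay = 0.05) {
  model_kind <- match.arg(model_kind)
  screen <- univariate_screen(data, outcome, covariates, model_kind)
  passed <- screen$covariate[!is.na(screen$p) & screen$p <= alpha_enter]
  pruned <- if (length(passed) >= 2L) {
    collinearity_prune(data, passed, collin_threshold, priority = passed)
  } else {
    list(kept = passed,
         dropped = data.frame(dropped = character(0),
                              kept_partner = character(0), r = numeric(0)))
  }
  sw <- backward_stepwise(data, outcome, pruned$kept, model_kind, alpha_stay)
  list(screen = screen, pruned = pruned, stepwise = sw)
}
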