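#' Fit a phylogenetic generalized least squares model
#'
#' GLS regression whose error covariance is a Brownian-motion phylogenetic
#' covariance: beta-hat = (X' C^-1 X)^-1 X' C^-1 y, with the residual
#' variance profiled out. The covariance is used on the correlation scale
#' `C* = C / depth` (unit diagonal); the scale is absorbed into the residual
#' variance, so results are invariant to the units of `C`. Estimation is by
#' maximum likelihood (not REML) so that fits with different fixed-effect
#' structures can be compared with likelihood-ratio tests; the maximized
#' log-likelihood is
#' `l = -n/2 log(2 pi s2) - log|C*|/2 - n/2` with `s2` the ML residual
#' variance. Coefficient standard errors and the sequential (type-I) F
#' tests use the unbiased variance `RSS/(n - p)`, matching common GLS
#' software conventions.
#'
#' Categorical predictors are dummy-coded against the alphabetically first
#' level. Changing the reference level changes coefficients but not F or
#' likelihood-ratio statistics.
#'
#' @param data Data frame with one row per clade, containing the response,
#'   the predictors, and a `clade` id column matching the covariance labels.
#' @param formula Model formula, e.g.
#'   `avg_divergence ~ avg_geodist + age + env_het + ecomorph`.
#' @param cov A `cov_spec` from [brownian_covariance()] /
#'   [brownian_covariance_tree()], or a plain covariance matrix with clade
#'   dimnames, or `NULL` for an identity covariance (ordinary least
#'   squares).
#' @param clade_col Name of the id column (default `"clade"`).
#' @return A `pgls_fit` object; see [tidy.pgls_fit()], [glance.pgls_fit()],
#'   [pgls_anova()].
#' @export
pgls_fit <- function(data, formula, cov = NULL, clade_col = "clade") {
  stopifnot(is.data.frame(data))
  n <- nrow(data)
  ids <- as.character(data[[clade_col]])
  if (is.null(ids)) abort(paste("data must have an id column", clade_col))

  if (is.null(cov)) {
    C <- diag(n); dimnames(C) <- list(ids, ids)
    cov <- new_cov_spec(C, method = "identity")
  } else if (is.matrix(cov)) {
    cov <- new_cov_spec(cov, method = "matrix")
  }
  if (!all(ids %in% cov$order)) {
    abort(paste("clades absent from covariance:",
                paste(setdiff(ids, cov$order), collapse = ", ")))
  }
  Cs <- cov$C[ids, ids] / cov$depth  # correlation scale, unit diagonal

  mf <- model.frame(formula, data)
  y <- model.response(mf)
  X <- model.matrix(formula, mf)
  p <- ncol(X)
  if (n <= p) abort("more parameters than observations")

  R <- tryCatch(chol(Cs), error = function(e) {
    inform("covariance not positive definite; adding 1e-10 diagonal jitter")
    chol(Cs + diag(1e-10, n))
  })
  logdet <- 2 * sum(log(diag(R)))
  # whiten: M = R^{-T}, cov(M y) = sigma^2 I
  yw <- backsolve(R, y, transpose = TRUE)
  Xw <- backsolve(R, X, transpose = TRUE)

  qrX <- qr(Xw)
  if (qrX$rank < p) {
    drop <- colnames(X)[qrX$pivot[(qrX$rank + 1):p]]
    abort(paste("design matrix is singular; collinear terms:",
                paste(drop, collapse = ", ")))
  }
  beta <- qr.coef(qrX, yw)
  res <- yw - Xw %*% beta
  rss <- sum(res^2)
  sigma2_ml <- rss / n
  sigma2 <- rss / (n - p)
  XtXinv <- solve(crossprod(Xw))
  vb <- sigma2 * XtXinv
  se <- sqrt(diag(vb))
  tval <- as.numeric(beta) / se
  pval <- 2 * pt(-abs(tval), df = n - p)
  ll <- -n / 2 * log(2 * pi * sigma2_ml) - logdet / 2 - n / 2

  coef_tbl <- tibble::tibble(
    term = colnames(X), estimate = as.numeric(beta), std.error = se,
    statistic = tval, p.value = pval
  )

  # sequential (type-I) F table, terms in formula order, intercept first
  asg <- attr(X, "assign")
  tl <- attr(terms(mf), "term.labels")
  groups <- sort(unique(asg))
  rss_seq <- numeric(length(groups) + 1)
  rss_seq[1] <- sum(yw^2)  # empty model
  for (g in seq_along(groups)) {
    cols <- which(asg <= groups[g])
    rss_seq[g + 1] <- sum(qr.resid(qr(Xw[, cols, drop = FALSE]), yw)^2)
  }
  df_term <- vapply(groups, function(g) sum(asg == g), integer(1))
  Fval <- (rss_seq[-length(rss_seq)] - rss_seq[-1]) / df_term / sigma2
  term_names <- c("(Intercept)", tl)[groups + 1]
  anova_tbl <- tibble::tibble(
    term = term_names, df = df_term, statistic = Fval,
    p.value = pf(Fval, df_term, n - p, lower.tail = FALSE)
  )

  structure(list(
    formula = formula, term_labels = tl, coefficients = coef_tbl,
    anova = anova_tbl, logLik = ll, sigma2 = sigma2_ml, rss = rss,
    tss = sum(yw^2), n = n,
    p = p, df.residual = n - p, vcov = vb, cov = cov, clade_col = clade_col,
    data = data, fitted = as.numeric(X %*% beta),
    residuals = as.numeric(y - X %*% beta), logdet = logdet
  ), class = "pgls_fit")
}

#' @export
print.pgls_fit <- function(x, digits = 4, ...) {
  cat("Phylogenetic GLS (Brownian motion,", x$cov$method, "covariance)\n")
  cat("Formula:", deparse(x$formula), "\n")
  cat(sprintf("n = %d, logLik (ML) = %.4f, sigma^2 = %.6g\n",
              x$n, x$logLik, x$sigma2))
  cat("\nCoefficients:\n")
  print(as.data.frame(x$coefficients), digits = digits, row.names = FALSE)
  cat("\nSequential F tests:\n")
  print(as.data.frame(x$anova), digits = digits, row.names = FALSE)
  invisible(x)
}

#' Tidy a PGLS fit
#' @param x A `pgls_fit`.
#' @param ... Unused.
#' @return Tibble of per-coefficient estimates, standard errors, t and p.
#' @method tidy pgls_fit
#' @export
tidy.pgls_fit <- function(x, ...) x$coefficients

#' One-row model summary of a PGLS fit
#' @param x A `pgls_fit`.
#' @param ... Unused.
#' @return Tibble with logLik, AIC, sigma2, n, df.residual.
#' @method glance pgls_fit
#' @export
glance.pgls_fit <- function(x, ...) {
  tibble::tibble(logLik = x$logLik, AIC = -2 * x$logLik + 2 * (x$p + 1),
                 sigma2 = x$sigma2, n = x$n, df.residual = x$df.residual)
}

#' Sequential (type-I) F table of a PGLS fit
#' @param fit A `pgls_fit`.
#' @return Tibble: term, df, statistic (F), p.value, in formula order with
#'   the intercept first.
#' @export
pgls_anova <- function(fit) {
  stopifnot(inherits(fit, "pgls_fit"))
  fit$anova
}

#' @export
logLik.pgls_fit <- function(object, ...) {
  structure(object$logLik, df = object$p + 1, class = "logLik")
}

#' @export
coef.pgls_fit <- function(object, ...) {
  setNames(object$coefficients$estimate, object$coefficients$term)
}

#' Likelihood-ratio test between nested PGLS fits
#'
#' Both models must be ML fits on the same data and covariance; the reduced
#' model's terms must be a subset of the full model's. The statistic
#' `2 (l_full - l_reduced)` is referred to a chi-square distribution with
#' degrees of freedom equal to the difference in coefficient counts.
#'
#' @param full,reduced `pgls_fit` objects.
#' @return Tibble: statistic, df, p.value.
#' @export
lrt <- function(full, reduced) {
  stopifnot(inherits(full, "pgls_fit"), inherits(reduced, "pgls_fit"))
  if (!all(reduced$term_labels %in% full$term_labels)) {
    abort("models are not nested: reduced terms not a subset of full terms")
  }
  if (full$n != reduced$n ||
      !isTRUE(all.equal(full$cov$C, reduced$cov$C, tolerance = 1e-12))) {
    abort("models must be fitted on identical data and covariance")
  }
  # perfect fits (zero residual variance, e.g. noise-free synthetic chains)
  # have infinite ML log-likelihood; compare residual sums of squares there
  scale_ss <- max(full$tss, reduced$tss, .Machine$double.xmin)
  perfect <- function(f) f$rss <= 1e-14 * scale_ss
  stat <- if (perfect(full) && perfect(reduced)) {
    0
  } else if (perfect(full)) {
    Inf
  } else {
    2 * (full$logLik - reduced$logLik)
  }
  if (stat < -1e-8) abort("negative LRT statistic: models not nested as fitted")
  stat <- max(stat, 0)
  df <- full$p - reduced$p
  p <- if (df == 0) as.numeric(stat < 1e-12) else
    pchisq(stat, df, lower.tail = FALSE)
  tibble::tibble(statistic = stat, df = df, p.value = p)
}
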