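#' Redundancy analysis with supplementary variables
#'
#' Constrained ordination of a multivariate response table by a predictor
#' table: each (standardized) response column is regressed on the predictors
#' by OLS and the fitted-value matrix is eigen-decomposed.  Constrained
#' eigenvalues are expressed as percentages of the *total* response variance
#' (correlation-matrix scaling, as is customary when ordinating water
#' chemistry across mixed units).  Supplementary variables are projected
#' post hoc as correlations with the site scores and have no influence on
#' the eigenstructure.
#'
#' @param Y Data frame / matrix of responses (standardized internally).
#' @param X Data frame / matrix of constraining predictors.
#' @param S Optional data frame of supplementary variables.
#' @param standardize Standardize predictors too (default TRUE).
#' @return An `rda_result` list: `eigenvalues`, `prop_explained` (% of total
#'   response variance per constrained axis), `prop_of_explained`,
#'   `total_variance`, `trace_r2` (sum of constrained eigenvalues over total
#'   variance = average per-response R^2), `site_scores`, `response_scores`,
#'   `predictor_scores` (correlations of predictors with axes),
#'   `supplementary_scores`, `aliased` (dropped predictor columns).
#' @examples
#' set.seed(1)
#' X <- data.frame(a = rnorm(30))
#' Y <- data.frame(y1 = X$a + rnorm(30, sd = .1))
#' rda_ordination(Y, X)$prop_explained
#' @export
rda_ordination <- function(Y, X, S = NULL, standardize = TRUE) {
  Y <- as.matrix(Y); storage.mode(Y) <- "double"
  X <- as.matrix(X); storage.mode(X) <- "double"
  n <- nrow(Y)
  if (nrow(X) != n) stop("Y and X must have the same number of rows")
  if (anyNA(Y) || anyNA(X)) stop("missing values are not allowed")
  if (n < ncol(X) + 2L) stop("need at least ncol(X) + 2 observations")
  Ys <- scale(Y, center = TRUE, scale = TRUE)
  if (any(!is.finite(Ys))) stop("zero-variance response column")
  Xc <- scale(X, center = TRUE, scale = standardize)
  # drop aliased (linearly dependent) predictors
  qrx <- qr(Xc)
  aliased <- character(0)
  if (qrx$rank < ncol(Xc)) {
    keep <- qrx$pivot[seq_len(qrx$rank)]
    aliased <- colnames(Xc)[-keep]
    warning("dropping aliased predictor(s): ", paste(aliased, collapse = ", "))
    Xc <- Xc[, keep, drop = FALSE]
    qrx <- qr(Xc)
  }
  Yhat <- qr.fitted(qrx, Ys)
  sv <- svd(Yhat)
  rank_c <- min(qrx$rank, ncol(Ys))
  d <- sv$d[seq_len(rank_c)]
  eig <- d^2 / (n - 1)
  eig <- eig[eig > max(eig, 0) * 1e-12]       # numerically-zero axes dropped
  k <- length(eig)
  total_var <- sum(apply(Ys, 2L, stats::var))  # = ncol(Y) after scaling
  u <- sv$u[, seq_len(k), drop = FALSE]
  site <- u %*% diag(d[seq_len(k)], k)         # constrained site scores
  resp <- sv$v[, seq_len(k), drop = FALSE]
  rownames(resp) <- colnames(Y)
  pred_cor <- stats::cor(Xc, site)
  colnames(site) <- colnames(resp) <- colnames(pred_cor) <-
    paste0("RDA", seq_len(k))
  supp <- NULL
  if (!is.null(S)) {
    S <- as.matrix(S); storage.mode(S) <- "double"
    if (nrow(S) != n) stop("supplementary table must have n rows")
    supp <- stats::cor(S, site)
    colnames(supp) <- paste0("RDA", seq_len(k))
  }
  structure(list(
    eigenvalues = eig,
    prop_explained = 100 * eig / total_var,
    prop_of_explained = 100 * eig / sum(eig),
    total_variance = total_var,
    trace_r2 = sum(eig) / total_var,
    site_scores = site,
    response_scores = resp,
    predictor_scores = pred_cor,
    supplementary_scores = supp,
    aliased = aliased,
    n = n
  ), class = "rda_result")
}

#' @export
print.rda_result <- function(x, ...) {
  cat("Redundancy analysis:", length(x$eigenvalues), "constrained axes\n")
  cat(sprintf("  axis %% of total variance: %s\n",
              paste(sprintf("%.1f", x$prop_explained), collapse = ", ")))
  cat(sprintf("  total explained: %.1f%%\n", 100 * x$trace_r2))
  invisible(x)
}

#' Multiple linear regression with forward selection
#'
#' Starting from the intercept-only model, repeatedly adds the candidate
#' whose partial F test is most significant, as long as its p-value is
#' below `alpha_enter`; stops otherwise.  May select the empty model.
#'
#' @param y Response vector.
#' @param X_candidates Data frame of candidate predictors.
#' @param alpha_enter Entry threshold on the partial-F p-value (default
#'   0.05).
#' @return A `forward_mlr` list: `selected` (names in entry order), `fit`
#'   (the final `lm`), `coefficients`, `r_squared`, `adj_r_squared`,
#'   `steps` (data frame of entry statistics).
#' @export
forward_mlr <- function(y, X_candidates, alpha_enter = 0.05) {
  X <- as.data.frame(X_candidates)
  stopifnot(length(y) == nrow(X))
  if (anyNA(y) || anyNA(X)) stop("missing values are not allowed")
  n <- length(y)
  selected <- character(0)
  steps <- data.frame(variable = character(0), f = numeric(0), p = numeric(0))
  repeat {
    remaining <- setdiff(names(X), selected)
    if (!length(remaining) || n <= length(selected) + 2L) break
    rss0 <- sum(stats::resid(.ols(y, X[selected]))^2)
    best <- NULL
    for (v in remaining) {
      fit1 <- .ols(y, X[c(selected, v)])
      rss1 <- sum(stats::resid(fit1)^2)
      df2 <- n - length(selected) - 2L
      if (rss1 >= rss0 || df2 <= 0) next
      fstat <- (rss0 - rss1) / (rss1 / df2)
      pval <- stats::pf(fstat, 1, df2, lower.tail = FALSE)
      if (is.null(best) || fstat > best$f) best <- list(v = v, f = fstat, p = pval)
    }
    if (is.null(best) || best$p >= alpha_enter) break
    selected <- c(selected, best$v)
    steps <- rbind(steps, data.frame(variable = best$v, f = best$f, p = best$p))
  }
  fit <- .ols(y, X[selected])
  k <- length(selected)
  r2 <- if (k) 1 - sum(stats::resid(fit)^2) / sum((y - mean(y))^2) else 0
  adj <- if (k) 1 - (1 - r2) * (n - 1) / (n - k - 1) else 0
  structure(list(selected = selected, fit = fit,
                 coefficients = stats::coef(fit),
                 r_squared = r2, adj_r_squared = adj, steps = steps),
            class = "forward_mlr")
}

.ols <- function(y, Xdf) {
  if (!length(Xdf)) return(stats::lm(y ~ 1))
  dat <- cbind(data.frame(.y = y), Xdf)
  stats::lm(stats::as.formula(paste(".y ~", paste(sprintf("`%s`", names(Xdf)),
                                                  collapse = " + "))),
            data = dat)
}

#' @export
print.forward_mlr <- function(x, ...) {
  if (!length(x$selected)) {
    cat("forward selection: no variable entered\n")
  } else {
    cat("forward selection entered:", paste(x$selected, collapse = ", "), "\n")
    cat(sprintf("  R2 = %.3f, adj. R2 = %.3f\n", x$r_squared, x$adj_r_squared))
  }
  invisible(x)
}
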