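#' Parse a plain-text path-model edge list
#'
#' Accepts lines of the form `parent -> child`; blank lines and lines
#' starting with `#` are ignored.
#'
#' @param x Character vector of lines, or a file path to read.
#' @return `data.frame` with columns `from`, `to`.
#' @export
parse_path_edges <- function(x) {
  if (length(x) == 1L && file.exists(x)) x <- readLines(x)
  x <- trimws(x)
  x <- x[nzchar(x) & !startsWith(x, "#")]
  m <- regmatches(x, regexec("^(\\S+)\\s*->\\s*(\\S+)$", x))
  bad <- vapply(m, length, 1L) != 3L
  if (any(bad)) stop("cannot parse edge line(s): ", paste(x[bad], collapse = "; "))
  data.frame(from = vapply(m, `[`, "", 2L), to = vapply(m, `[`, "", 3L))
}

# topological order of a DAG given an edge table; errors on cycles
.topo_order <- function(vars, edges) {
  indeg <- stats::setNames(integer(length(vars)), vars)
  for (v in edges$to) indeg[v] <- indeg[v] + 1L
  out <- character(0)
  avail <- vars[indeg == 0L]
  while (length(avail)) {
    v <- avail[1L]; avail <- avail[-1L]
    out <- c(out, v)
    kids <- edges$to[edges$from == v]
    for (k in kids) {
      indeg[k] <- indeg[k] - 1L
      if (indeg[k] == 0L) avail <- c(avail, k)
    }
  }
  if (length(out) != length(vars)) stop("path model graph is cyclic")
  out
}

#' Fit a recursive path model with ML fit indices
#'
#' Estimates a recursive (acyclic, uncorrelated-errors) structural model by
#' per-equation OLS on standardized data, which coincides with the maximum-
#' likelihood point estimates for such models.  The model-implied covariance
#' is assembled from the structural coefficients and residual variances
#' (exogenous variances and covariances are kept free at their sample
#' values), and the ML discrepancy
#' `F = log det(Sigma) - log det(S) + tr(S Sigma^-1) - p` yields
#' `chi-square = (n - 1) * F`.  CFI and TLI are computed against the
#' independence baseline and clamped to `[0, 1]`;
#' `RMSEA = sqrt(max(0, chi2 - df) / (df * (n - 1)))`.
#'
#' @param data Data frame containing every model variable (numeric).
#' @param edges Edge table (`from`, `to` columns), a character vector of
#'   `"parent -> child"` lines, or a file path ([parse_path_edges()]).
#' @param standardize Standardize variables before fitting (default TRUE),
#'   so coefficients are standardized path coefficients.
#' @return A `path_model` list: `edges` (with `coefficient`, `se`, `p`),
#'   `residual_variances`, `fit` (chi_square, df, p_value, cfi, tli,
#'   rmsea), `implied`, `sample_cov`, `n`, `variables`, `exogenous`.
#' @examples
#' set.seed(1)
#' d <- data.frame(x = rnorm(200))
#' d$m <- 0.8 * d$x + rnorm(200, sd = 0.6)
#' d$y <- 0.5 * d$m + rnorm(200, sd = 0.87)
#' fit_path_model(d, c("x -> m", "m -> y"))
#' @export
fit_path_model <- function(data, edges, standardize = TRUE) {
  if (!is.data.frame(edges)) edges <- parse_path_edges(edges)
  stopifnot(all(c("from", "to") %in% names(edges)))
  vars <- unique(c(edges$from, edges$to))
  missing_vars <- setdiff(vars, names(data))
  if (length(missing_vars)) {
    stop("variables absent from data: ", paste(missing_vars, collapse = ", "))
  }
  ord <- .topo_order(vars, edges)
  dat <- as.data.frame(data)[, ord, drop = FALSE]
  if (anyNA(dat)) stop("missing values are not allowed")
  n <- nrow(dat)
  p <- length(ord)
  if (standardize) dat[] <- lapply(dat, function(v) as.numeric(scale(v)))
  endo <- unique(edges$to)
  exo <- setdiff(ord, endo)
  max_indeg <- max(table(edges$to))
  if (n <= max_indeg + 1L) stop("too few observations for the model")

  S <- stats::cov(dat)
  B <- matrix(0, p, p, dimnames = list(ord, ord))
  psi <- matrix(0, p, p, dimnames = list(ord, ord))
  psi[exo, exo] <- S[exo, exo]
  est <- edges
  est$coefficient <- est$se <- est$p <- NA_real_
  for (child in endo) {
    parents <- edges$from[edges$to == child]
    X <- as.matrix(dat[, parents, drop = FALSE])
    fit <- stats::lm(dat[[child]] ~ X)
    cf <- summary(fit)$coefficients
    if (any(is.na(stats::coef(fit)))) stop("singular parent set for ", child)
    rows <- match(parents, parents) + 1L
    sel <- est$to == child
    est$coefficient[sel] <- cf[rows, 1L][match(est$from[sel], parents)]
    est$se[sel] <- cf[rows, 2L][match(est$from[sel], parents)]
    est$p[sel] <- cf[rows, 4L][match(est$from[sel], parents)]
    B[child, parents] <- est$coefficient[sel][match(parents, est$from[sel])]
    psi[child, child] <- sum(stats::resid(fit)^2) / (n - 1)
  }
  imb <- solve(diag(p) - B)
  sigma <- imb %*% psi %*% t(imb)
  dimnames(sigma) <- dimnames(S)

  f_ml <- function(Sig) {
    as.numeric(determinant(Sig, logarithm = TRUE)$modulus -
                 determinant(S, logarithm = TRUE)$modulus +
                 sum(diag(S %*% solve(Sig))) - p)
  }
  n_free <- nrow(edges) + length(endo) + length(exo) +
    choose(length(exo), 2L)
  df <- p * (p + 1L) / 2L - n_free
  chi2 <- max(0, (n - 1) * f_ml(sigma))
  chi_b <- max(0, (n - 1) * f_ml(diag(diag(S), p)))
  df_b <- p * (p - 1L) / 2L
  num <- max(chi2 - df, 0)
  den <- max(chi_b - df_b, chi2 - df, 0)
  cfi <- if (den == 0) 1 else min(1, max(0, 1 - num / den))
  tli <- if (df == 0L || df_b == 0L || chi_b == 0) {
    1
  } else {
    min(1, max(0, ((chi_b / df_b) - (chi2 / df)) / ((chi_b / df_b) - 1)))
  }
  rmsea <- if (df == 0L) 0 else sqrt(max(0, chi2 - df) / (df * (n - 1)))
  p_chi <- if (df == 0L) 1 else stats::pchisq(chi2, df, lower.tail = FALSE)

  structure(list(
    edges = est,
    residual_variances = stats::setNames(diag(psi)[endo], endo),
    fit = list(chi_square = chi2, df = df, p_value = p_chi,
               cfi = cfi, tli = tli, rmsea = rmsea,
               baseline_chi_square = chi_b, baseline_df = df_b),
    implied = sigma, sample_cov = S, n = n,
    variables = ord, exogenous = exo
  ), class = "path_model")
}

#' @export
print.path_model <- function(x, ...) {
  cat(sprintf("recursive path model: %d variables, %d edges, n = %d\n",
              length(x$variables), nrow(x$edges), x$n))
  print(within(x$edges, {
    coefficient <- round(coefficient, 3)
    se <- round(se, 3); p <- signif(p, 3)
  }), row.names = FALSE)
  f <- x$fit
  cat(sprintf(
    "  chi2 = %.2f (df %d, p = %.3f), CFI = %.3f, TLI = %.3f, RMSEA = %.3f\n",
    f$chi_square, f$df, f$p_value, f$cfi, f$tli, f$rmsea))
  invisible(x)
}

#' Filter path-model edges for display
#'
#' Keeps edges with `|coefficient| > pc_min` and `p < alpha` — the usual
#' convention for drawing only the strong, significant paths while
#' retaining the full model underneath.
#'
#' @param model A fitted [fit_path_model()] object.
#' @param pc_min Minimum absolute path coefficient (default 0.3; a
#'   coefficient of exactly `pc_min` is excluded).
#' @param alpha Significance threshold (default 0.05).
#' @return The subset of the model's edge table.
#' @export
display_filter <- function(model, pc_min = 0.3, alpha = 0.05) {
  stopifnot(inherits(model, "path_model"))
  e <- model$edges
  e[abs(e$coefficient) > pc_min & e$p < alpha, , drop = FALSE]
}

#' Quadratic (unimodal) fit with vertex location
#'
#' OLS fit of `y = b0 + b1 x + b2 x^2`.  The vertex `-b1 / (2 b2)` is
#' reported only when the parabola opens downward (`b2 < 0`); otherwise the
#' fit is flagged as having no interior peak.
#'
#' @param x,y Numeric vectors, `n >= 4`.
#' @return List with `coefficients`, `vertex` (NA when no peak),
#'   `has_peak`, `r_squared`, `fit`.
#' @export
quadratic_peak <- function(x, y) {
  stopifnot(length(x) == length(y))
  if (length(x) < 4L) stop("need at least 4 points for a quadratic fit")
  fit <- stats::lm(y ~ x + I(x^2))
  b <- stats::coef(fit)
  has_peak <- is.finite(b[3L]) && b[3L] < 0
  list(coefficients = b,
       vertex = if (has_peak) unname(-b[2L] / (2 * b[3L])) else NA_real_,
       has_peak = has_peak,
       r_squared = 1 - sum(stats::resid(fit)^2) / sum((y - mean(y))^2),
       fit = fit)
}

#' Pearson correlation with two-sided t-test
#'
#' @param x,y Numeric vectors, `n >= 3`, non-degenerate.
#' @return List with `r`, `p`, `n`.
#' @export
pearson_cor <- function(x, y) {
  stopifnot(length(x) == length(y))
  if (length(x) < 3L) stop("need at least 3 observations")
  if (stats::sd(x) == 0 || stats::sd(y) == 0) stop("zero-variance input")
  ct <- stats::cor.test(x, y, method = "pearson")
  list(r = unname(ct$estimate), p = ct$p.value, n = length(x))
}
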