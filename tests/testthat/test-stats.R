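test_that("RDA recovers a perfectly constrained response", {
  set.seed(1)
  x <- rnorm(30)
  res <- rda_ordination(data.frame(y = x), data.frame(x = x))
  expect_equal(res$prop_explained[1], 100, tolerance = 1e-8)
  expect_equal(res$trace_r2, 1, tolerance = 1e-10)
})

test_that("RDA constrained variance equals the algebraic trace-R2 oracle", {
  set.seed(2)
  n <- 60
  X <- data.frame(a = rnorm(n), b = rnorm(n))
  Y <- data.frame(y1 = X$a + rnorm(n), y2 = -X$b + rnorm(n),
                  y3 = rnorm(n))
  res <- rda_ordination(Y, X)
  # oracle: mean R2 of per-column OLS fits of the standardized responses
  r2 <- vapply(Y, function(y) summary(lm(scale(y) ~ X$a + X$b))$r.squared, 0)
  expect_equal(res$trace_r2, mean(r2), tolerance = 1e-10)
  # site scores orthogonal
  cp <- crossprod(res$site_scores)
  expect_equal(cp[upper.tri(cp)], rep(0, sum(upper.tri(cp))),
               tolerance = 1e-8)
  # eigenvalues non-increasing, non-negative
  expect_true(all(diff(res$eigenvalues) <= 1e-12))
  expect_true(all(res$eigenvalues >= 0))
})

test_that("RDA proportions agree with vegan on a shared fixture", {
  set.seed(3)
  n <- 40
  X <- data.frame(a = rnorm(n), b = rnorm(n))
  Y <- data.frame(y1 = 2 * X$a + rnorm(n), y2 = X$a - X$b + rnorm(n))
  mine <- rda_ordination(Y, X)
  v <- vegan::rda(scale(Y) ~ a + b, data = X)
  expect_equal(unname(mine$prop_explained / 100),
               unname(v$CCA$eig / v$tot.chi), tolerance = 1e-8)
})

test_that("null-response RDA explains almost nothing at large n", {
  set.seed(4)
  n <- 5000
  res <- rda_ordination(data.frame(y = rnorm(n)), data.frame(x = rnorm(n)))
  expect_lt(res$prop_explained[1], 1)
})

test_that("supplementary variables do not influence the eigenstructure", {
  set.seed(5)
  n <- 30
  X <- data.frame(a = rnorm(n))
  Y <- data.frame(y = X$a + rnorm(n))
  S <- data.frame(s = rnorm(n))
  r0 <- rda_ordination(Y, X)
  r1 <- rda_ordination(Y, X, S)
  expect_equal(r0$eigenvalues, r1$eigenvalues)
  expect_equal(dim(r1$supplementary_scores), c(1L, 1L))
})

test_that("forward selection enters true predictors and stops on noise", {
  set.seed(6)
  n <- 50
  x1 <- rnorm(n); x2 <- rnorm(n)
  y <- x1
  sel <- forward_mlr(y, data.frame(x1 = x1, x2 = x2))
  expect_identical(sel$selected, "x1")
  # an exact duplicate never enters second
  sel2 <- forward_mlr(x1 + rnorm(n, 0, .1),
                      data.frame(x1 = x1, dup = x1))
  expect_equal(length(sel2$selected), 1L)
  # pure noise with one candidate: entry rate ~ alpha
  set.seed(7)
  hits <- mean(replicate(2000, {
    length(forward_mlr(rnorm(20), data.frame(x = rnorm(20)))$selected) > 0
  }))
  expect_lt(abs(hits - 0.05), 0.02)
})

test_that("saturated recursive path models reproduce the sample covariance", {
  set.seed(8)
  d <- data.frame(a = rnorm(80))
  d$b <- 0.5 * d$a + rnorm(80)
  d$c <- 0.3 * d$a - 0.4 * d$b + rnorm(80)
  fit <- fit_path_model(d, c("a -> b", "a -> c", "b -> c"))
  expect_equal(fit$fit$chi_square, 0, tolerance = 1e-8)
  expect_equal(fit$fit$df, 0)
  expect_equal(fit$fit$cfi, 1)
  expect_equal(fit$fit$rmsea, 0)
  expect_equal(unname(fit$implied), unname(fit$sample_cov), tolerance = 1e-10)
})

test_that("path coefficients match the normal-equations oracle", {
  set.seed(9)
  n <- 150
  d <- data.frame(x = rnorm(n), w = rnorm(n))
  d$m <- 0.6 * d$x - 0.3 * d$w + rnorm(n, 0, 0.7)
  d$y <- 0.5 * d$m + 0.2 * d$x + rnorm(n, 0, 0.8)
  fit <- fit_path_model(d, c("x -> m", "w -> m", "m -> y", "x -> y"))
  ds <- as.data.frame(scale(d))
  for (child in c("m", "y")) {
    parents <- fit$edges$from[fit$edges$to == child]
    X <- as.matrix(cbind(1, ds[, parents]))
    beta <- solve(crossprod(X), crossprod(X, ds[[child]]))[-1]
    got <- fit$edges$coefficient[fit$edges$to == child]
    expect_equal(got[match(parents, fit$edges$from[fit$edges$to == child])],
                 unname(beta), tolerance = 1e-10)
  }
})

test_that("chain models recover coefficients and flag misspecification", {
  set.seed(10)
  n <- 1e5
  d <- data.frame(x = rnorm(n))
  d$m <- 0.8 * d$x + rnorm(n, 0, 0.6)
  d$y <- 0.5 * d$m + rnorm(n, 0, sqrt(1 - 0.25))
  fit <- fit_path_model(d, c("x -> m", "m -> y"))
  expect_equal(fit$edges$coefficient[fit$edges$to == "m"], 0.8,
               tolerance = 0.01)
  expect_equal(fit$edges$coefficient[fit$edges$to == "y"], 0.5,
               tolerance = 0.01)
  expect_gt(fit$fit$p_value, 0.01)
  # misspecify the chain as a fork (drop the mediation): gross misfit,
  # since the data violate the implied conditional independence of m and y
  bad <- fit_path_model(d, c("x -> m", "x -> y"))
  expect_gt(bad$fit$chi_square, 100)
  expect_gt(bad$fit$rmsea, 0.06)
  expect_error(fit_path_model(d, c("x -> m", "m -> x")), "cyclic")
})

test_that("display filter keeps only strong significant paths", {
  set.seed(11)
  d <- data.frame(a = rnorm(40))
  d$b <- 0.5 * d$a + rnorm(40)
  fit <- fit_path_model(d, "a -> b")
  fake <- fit
  fake$edges <- data.frame(
    from = c("u", "v", "w"), to = c("y", "y", "y"),
    coefficient = c(0.29, 0.63, 0.5), se = 0.1,
    p = c(0.01, 0.01, 0.2))
  kept <- display_filter(fake)
  expect_identical(kept$from, "v")   # 0.29 barely below, 0.5 insignificant
})

test_that("quadratic peak finds vertices and flags monotone fits", {
  x <- seq(1, 17, by = 0.5)
  qp <- quadratic_peak(x, -(x - 9)^2 + 5)
  expect_true(qp$has_peak)
  expect_equal(qp$vertex, 9, tolerance = 1e-9)
  lin <- quadratic_peak(x, 2 * x + 1)
  expect_false(lin$has_peak)
  expect_true(is.na(lin$vertex))
  expect_error(quadratic_peak(1:3, 1:3), "4 points")
})

test_that("pearson correlation and test behave", {
  x <- rnorm(20)
  expect_equal(pearson_cor(x, x)$r, 1)
  expect_equal(pearson_cor(x, -x)$r, -1)
  set.seed(12)
  n <- 1e4
  a <- rnorm(n); b <- 0.5 * a + sqrt(1 - 0.25) * rnorm(n)
  est <- pearson_cor(a, b)
  expect_equal(est$r, 0.5, tolerance = 0.02)
  expect_lt(est$p, 1e-10)
  expect_error(pearson_cor(rep(1, 5), rnorm(5)), "zero-variance")
  expect_error(pearson_cor(1:2, 2:1), "3 observations")
})

test_that("edge lists parse from text", {
  e <- parse_path_edges(c("# comment", "a -> b", "b->c", ""))
  expect_equal(e$from, c("a", "b"))
  expect_equal(e$to, c("b", "c"))
  expect_error(parse_path_edges("a <-> b"), "parse")
})
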