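# Regression battery and variance partitioning.

test_that("an exact affine relationship gives R^2 = 1 and zero residuals", {
  set.seed(1)
  x <- cbind(a = rnorm(30), b = rnorm(30))
  y <- 2 + 3 * x[, 1] - 0.5 * x[, 2]
  fit <- fit_ols(y, x)
  expect_equal(fit$r_squared, 1.0, tolerance = 1e-12)
  expect_equal(unname(fit$coefficients), c(2, 3, -0.5), tolerance = 1e-9)
})

test_that("coefficients match a normal-equations oracle", {
  set.seed(2)
  for (i in 1:20) {
    n <- sample(15:40, 1)
    x <- matrix(rnorm(n * 3), n, dimnames = list(NULL, c("a", "b", "c")))
    y <- rnorm(n)
    fit <- fit_ols(y, x)
    X <- cbind(1, x)
    beta <- solve(t(X) %*% X, t(X) %*% y) # independent solver
    expect_equal(unname(fit$coefficients), as.numeric(beta), tolerance = 1e-9)
    # R^2 from residual sums, independently
    res <- y - X %*% beta
    expect_equal(fit$r_squared, 1 - sum(res^2) / sum((y - mean(y))^2),
                 tolerance = 1e-9)
    expect_equal(fit$adjusted_r_squared,
                 1 - (1 - fit$r_squared) * (n - 1) / (n - 3 - 1),
                 tolerance = 1e-9)
    expect_equal(fit$df_model + fit$df_residual + 1, n)
    expect_lte(fit$adjusted_r_squared, fit$r_squared)
  }
})

test_that("a predictor constructed orthogonal to y gets a near-zero coefficient", {
  set.seed(3)
  n <- 400
  x <- rnorm(n)
  y <- rnorm(n)
  y <- unname(stats::resid(stats::lm(y ~ x))) # exactly orthogonal to {1, x}
  fit <- fit_ols(y, cbind(x = x))
  expect_lt(abs(fit$coefficients["x"]), 1e-9)
  expect_lt(fit$r_squared, 1e-9)
})

test_that("rank deficiency and short data are rejected", {
  x <- cbind(a = 1:10, b = 2 * (1:10))
  expect_error(fit_ols(rnorm(10), x), "rank-deficient|collinear")
  expect_error(fit_ols(rnorm(3), cbind(a = rnorm(3), b = rnorm(3))), "n > p")
})

test_that("variance partition fits exactly 7 models and satisfies the identity", {
  set.seed(4)
  for (i in 1:100) {
    n <- sample(20:60, 1)
    d <- rnorm(n); s <- rnorm(n); v <- rnorm(n)
    y <- rnorm(n, 0.2 * d - 0.1 * s + 0.05 * v)
    part <- variance_partition(y, d, s, v)
    expect_length(part$models, 7)
    total <- part$unique_depth + part$unique_semantic + part$unique_visual +
      part$shared_depth_semantic + part$shared_depth_visual +
      part$shared_semantic_visual + part$shared_all
    expect_equal(total, part$total_r_squared, tolerance = 1e-9)
    # nesting monotonicity: adding predictors never lowers R^2
    r2 <- vapply(part$models, `[[`, numeric(1), "r_squared")
    expect_gte(r2[["depth_semantic_visual"]] + 1e-12, r2[["depth_semantic"]])
    expect_gte(r2[["depth_semantic_visual"]] + 1e-12, r2[["depth_visual"]])
    expect_gte(r2[["depth_semantic_visual"]] + 1e-12, r2[["semantic_visual"]])
    expect_gte(r2[["depth_semantic"]] + 1e-12, max(r2[["depth"]], r2[["semantic"]]))
  }
})

test_that("orthogonal predictors produce zero shared components", {
  # exactly orthogonal columns via QR
  set.seed(5)
  q <- qr.Q(qr(matrix(rnorm(60 * 3), 60)))
  d <- q[, 1]; s <- q[, 2]; v <- q[, 3]
  y <- 0.5 * d - 0.3 * s + 0.1 * v + rnorm(60, sd = 0.2)
  part <- variance_partition(y, d, s, v)
  r2 <- vapply(part$models, `[[`, numeric(1), "r_squared")
  # centered orthogonality is approximate; shared terms should be tiny
  expect_lt(abs(part$shared_depth_semantic), 0.02)
  expect_lt(abs(part$shared_depth_visual), 0.02)
  expect_lt(abs(part$shared_semantic_visual), 0.02)
  expect_equal(part$unique_depth, r2[["depth"]], tolerance = 0.05)
})

test_that("duplicated predictors shift variance from unique to shared", {
  set.seed(6)
  d <- rnorm(50)
  s <- rnorm(50)
  v <- s + rnorm(50, sd = 1e-3) # visual nearly duplicates semantic
  y <- 0.3 * d - 0.4 * s + rnorm(50, sd = 0.3)
  part <- variance_partition(y, d, s, v)
  expect_lt(part$unique_visual, 0.01)
  expect_lt(part$unique_semantic, 0.01)
  expect_gt(part$shared_semantic_visual, 0.1)
})

test_that("per-feature regressions return one simple fit per feature", {
  set.seed(7)
  y <- rnorm(40)
  feats <- data.frame(image_id = sprintf("i%02d", 1:40),
                      f1 = y, f2 = rnorm(40), f3 = sample(y))
  fits <- per_feature_regressions(y, feats)
  expect_named(fits, c("f1", "f2", "f3"))
  expect_equal(fits$f1$r_squared, 1.0, tolerance = 1e-12)
  expect_equal(unname(fits$f1$coefficients), c(0, 1), tolerance = 1e-9)
  expect_lt(fits$f3$r_squared, 0.2) # permutation destroys the signal
})

test_that("feature correlation matrices match the textbook formula", {
  set.seed(8)
  a <- data.frame(image_id = sprintf("i%02d", 1:25), p = rnorm(25), q = rnorm(25))
  b <- data.frame(image_id = sprintf("i%02d", 1:25), r = rnorm(25))
  b$neg_p <- -a$p
  cm <- correlate_features(a, b)
  expect_equal(dim(cm), c(2, 2))
  expect_equal(cm["p", "neg_p"], -1.0, tolerance = 1e-12)
  pearson <- function(x, y) {
    sum((x - mean(x)) * (y - mean(y))) /
      sqrt(sum((x - mean(x))^2) * sum((y - mean(y))^2))
  }
  expect_equal(cm["q", "r"], pearson(a$q, b$r), tolerance = 1e-12)
  expect_equal(correlate_features(a, a)["p", "p"], 1.0, tolerance = 1e-12)
})

test_that("parameter recovery: fitted coefficients stay within 3 SE of truth", {
  # small-scale generative check; the study-scale version is in acceptance
  hits <- 0L
  n_rep <- 40
  for (r in seq_len(n_rep)) {
    cfg <- study_config(n_images = 40, n_participants = 60, seed = 1000 + r)
    st <- generate_study(cfg, components = "responses")
    m <- merge(score_boundary(st$responses), st$covariates, by = "image_id")
    fit <- fit_ols(m$score, m[, c("depth", "semantic_info", "visual_info")])
    truth <- c(0.52, -0.13, -0.03, -0.001)
    ok <- abs(fit$coefficients - truth) <= 3 * fit$std_errors
    hits <- hits + all(ok)
  }
  expect_gte(hits / n_rep, 0.85)
})
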