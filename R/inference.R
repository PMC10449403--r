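# Regression models and variance partitioning for boundary scores.

#' Ordinary least squares with the usual inferential summaries
#'
#' Fits `y ~ X` with an intercept and returns coefficients, R-squared,
#' adjusted R-squared (`1 - (1 - R2)(n - 1)/(n - p - 1)`), the overall F
#' statistic with `(p, n - p - 1)` degrees of freedom, and per-coefficient t
#' and two-sided p values. Predictors are used on the scale supplied, so
#' coefficients stay interpretable in input units.
#'
#' @param y numeric outcome vector (per-image boundary scores, typically).
#' @param x numeric matrix or data.frame of predictors (no intercept column;
#'   one is added).
#' @return an `ols_fit` object (list) with fields `predictor_names`,
#'   `coefficients`, `r_squared`, `adjusted_r_squared`, `f_statistic`,
#'   `f_p_value`, `df_model`, `df_residual`, `t_values`, `p_values`, `n`,
#'   `sigma`, `std_errors`.
#' @export
fit_ols <- function(y, x) {
  x <- as.matrix(x)
  if (is.null(colnames(x))) colnames(x) <- paste0("x", seq_len(ncol(x)))
  if (!is.numeric(y) || length(y) != nrow(x)) {
    stop("'y' must be numeric with one value per row of 'x'")
  }
  n <- length(y); p <- ncol(x)
  if (n <= p + 1) stop("need n > p + 1 observations")
  design <- cbind(`(Intercept)` = 1, x)
  if (qr(design)$rank < ncol(design)) {
    stop("rank-deficient design: predictors are collinear (or constant)")
  }
  dat <- data.frame(.y = y, x, check.names = FALSE)
  fit <- stats::lm(.y ~ ., data = dat)
  # exact fits are legitimate inputs here (noise-free synthetic data)
  s <- withCallingHandlers(summary(fit), warning = function(w) {
    if (grepl("essentially perfect fit", conditionMessage(w))) {
      invokeRestart("muffleWarning")
    }
  })
  ct <- s$coefficients
  structure(list(
    predictor_names = colnames(x),
    coefficients = stats::coef(fit),
    r_squared = s$r.squared,
    adjusted_r_squared = s$adj.r.squared,
    f_statistic = unname(s$fstatistic["value"]),
    f_p_value = unname(stats::pf(s$fstatistic["value"],
                                 s$fstatistic["numdf"], s$fstatistic["dendf"],
                                 lower.tail = FALSE)),
    df_model = p,
    df_residual = n - p - 1,
    t_values = ct[, "t value"],
    p_values = ct[, "Pr(>|t|)"],
    std_errors = ct[, "Std. Error"],
    sigma = s$sigma,
    n = n
  ), class = "ols_fit")
}

#' @export
print.ols_fit <- function(x, ...) {
  cat(sprintf("<ols_fit> n = %d, R^2 = %.3f (adj %.3f), F(%d, %d) = %.2f, p = %.3g\n",
              x$n, x$r_squared, x$adjusted_r_squared, x$df_model,
              x$df_residual, x$f_statistic, x$f_p_value))
  tab <- data.frame(coef = x$coefficients, t = x$t_values, p = x$p_values)
  print(round(tab, 4))
  invisible(x)
}

#' Variance partitioning over depth, semantic, and visual predictors
#'
#' Fits the seven possible regressions of the outcome on the three predictor
#' sets (all three; each pair; each alone) and decomposes the full model's
#' R-squared by inclusion-exclusion (commonality analysis) into variance
#' unique to each predictor, shared by each pair beyond the third, and
#' shared by all three. The identity
#' `sum(uniques) + sum(pairwise) + triple = R2(full)` is enforced to 1e-9.
#' Components can be slightly negative under suppression and are reported
#' unclipped.
#'
#' @param y outcome vector.
#' @param depth,semantic,visual numeric predictor vectors, same length as `y`.
#' @return a `variance_partition` object: `unique_depth`, `unique_semantic`,
#'   `unique_visual`, `shared_depth_semantic`, `shared_depth_visual`,
#'   `shared_semantic_visual`, `shared_all`, `total_r_squared`, and `models`
#'   (the 7 `ols_fit`s, named by predictor set).
#' @export
variance_partition <- function(y, depth, semantic, visual) {
  x <- cbind(depth = depth, semantic = semantic, visual = visual)
  sets <- list(
    depth_semantic_visual = c("depth", "semantic", "visual"),
    depth_semantic = c("depth", "semantic"),
    depth_visual = c("depth", "visual"),
    semantic_visual = c("semantic", "visual"),
    depth = "depth",
    semantic = "semantic",
    visual = "visual"
  )
  models <- lapply(sets, function(s) fit_ols(y, x[, s, drop = FALSE]))
  r2 <- vapply(models, `[[`, numeric(1), "r_squared")
  u_d <- r2[["depth_semantic_visual"]] - r2[["semantic_visual"]]
  u_s <- r2[["depth_semantic_visual"]] - r2[["depth_visual"]]
  u_v <- r2[["depth_semantic_visual"]] - r2[["depth_semantic"]]
  c_ds <- r2[["depth_visual"]] + r2[["semantic_visual"]] -
    r2[["depth_semantic_visual"]] - r2[["visual"]]
  c_dv <- r2[["depth_semantic"]] + r2[["semantic_visual"]] -
    r2[["depth_semantic_visual"]] - r2[["semantic"]]
  c_sv <- r2[["depth_semantic"]] + r2[["depth_visual"]] -
    r2[["depth_semantic_visual"]] - r2[["depth"]]
  c_all <- r2[["depth"]] + r2[["semantic"]] + r2[["visual"]] -
    r2[["depth_semantic"]] - r2[["depth_visual"]] - r2[["semantic_visual"]] +
    r2[["depth_semantic_visual"]]
  total <- r2[["depth_semantic_visual"]]
  resid <- abs(u_d + u_s + u_v + c_ds + c_dv + c_sv + c_all - total)
  if (resid > 1e-9) {
    stop("variance partition identity violated (residual ", format(resid), ")")
  }
  structure(list(
    unique_depth = unname(u_d), unique_semantic = unname(u_s),
    unique_visual = unname(u_v),
    shared_depth_semantic = unname(c_ds), shared_depth_visual = unname(c_dv),
    shared_semantic_visual = unname(c_sv), shared_all = unname(c_all),
    total_r_squared = unname(total),
    models = models
  ), class = "variance_partition")
}

#' @export
print.variance_partition <- function(x, ...) {
  cat("<variance_partition> total R^2 =", round(x$total_r_squared, 4), "\n")
  v <- unlist(x[c("unique_depth", "unique_semantic", "unique_visual",
                  "shared_depth_semantic", "shared_depth_visual",
                  "shared_semantic_visual", "shared_all")])
  print(round(v, 4))
  invisible(x)
}

#' Simple regressions of the outcome on each feature separately
#'
#' @param y outcome vector.
#' @param features data.frame/matrix of feature columns (an `image_id`
#'   column, if present, is ignored).
#' @return named list of `ols_fit`, one per feature column.
#' @export
per_feature_regressions <- function(y, features) {
  x <- drop_id_column(features)
  out <- lapply(colnames(x), function(f) fit_ols(y, x[, f, drop = FALSE]))
  stats::setNames(out, colnames(x))
}

#' Pearson correlation matrix between two feature tables
#'
#' Rows are matched on `image_id` when both tables carry one; otherwise rows
#' are matched positionally.
#'
#' @param table_a,table_b data.frames of numeric columns (optionally with
#'   `image_id`).
#' @return matrix of Pearson correlations, rows = columns of `table_a`,
#'   columns = columns of `table_b`.
#' @export
correlate_features <- function(table_a, table_b) {
  if (is.data.frame(table_a) && is.data.frame(table_b) &&
      "image_id" %in% names(table_a) && "image_id" %in% names(table_b)) {
    common <- intersect(table_a$image_id, table_b$image_id)
    if (length(common) < 3) stop("need >= 3 matched image_ids")
    table_a <- table_a[match(common, table_a$image_id), ]
    table_b <- table_b[match(common, table_b$image_id), ]
  }
  a <- drop_id_column(table_a); b <- drop_id_column(table_b)
  if (nrow(a) != nrow(b)) stop("tables have different numbers of matched rows")
  if (nrow(a) < 3) stop("need >= 3 rows")
  stats::cor(a, b)
}

#' Write a regression or partition result as JSON
#'
#' @param x an `ols_fit` or `variance_partition`.
#' @param path output JSON path.
#' @return `path`, invisibly.
#' @export
write_result_json <- function(x, path) {
  if (inherits(x, "variance_partition")) {
    out <- unclass(x)
    out$models <- lapply(out$models, function(m) unclass(m))
  } else if (inherits(x, "ols_fit")) {
    out <- unclass(x)
  } else {
    stop("expected an 'ols_fit' or 'variance_partition'")
  }
  jsonlite::write_json(out, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}
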