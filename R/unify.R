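# Collapse a triple of information metrics to one score: PCA, first component.

#' Fit a PCA model over an information-feature table
#'
#' Centers (and, by default, z-scores) the feature matrix and computes
#' principal components. The first component's loading vector is the unified
#' information axis; its sign is fixed so that PC1 scores correlate
#' positively with a designated anchor metric ("more information = higher
#' score"), making the score direction stable across runs.
#'
#' @param rows numeric matrix or data.frame of n images x 3 metrics (an
#'   `image_id` column, if present, is set aside automatically). Needs
#'   `n >= 3`, no missing values, and nonzero variance in every column.
#' @param standardize z-score each column before PCA (recommended: the native
#'   scales differ by orders of magnitude).
#' @param anchor column name whose positive direction fixes the PC1 sign;
#'   defaults to the first column.
#' @return an `info_pca` object: `feature_names`, `center`, `scale`,
#'   `loadings` (first-component unit vector), `rotation` (all components),
#'   `variance_explained`, `anchor`, `standardize`.
#' @export
fit_info_pca <- function(rows, standardize = TRUE, anchor = NULL) {
  x <- drop_id_column(rows)
  if (nrow(x) < 3) stop("degenerate input: need at least 3 rows for PCA")
  if (anyNA(x)) stop("degenerate input: missing values in feature matrix")
  sds <- apply(x, 2, stats::sd)
  if (any(sds == 0)) {
    stop("degenerate input: constant feature column(s): ",
         paste(colnames(x)[sds == 0], collapse = ", "))
  }
  if (is.null(anchor)) anchor <- colnames(x)[1]
  if (!anchor %in% colnames(x)) stop("anchor '", anchor, "' is not a feature")
  pc <- stats::prcomp(x, center = TRUE, scale. = standardize)
  ve <- pc$sdev^2 / sum(pc$sdev^2)
  loadings <- pc$rotation[, 1]
  scores <- pc$x[, 1]
  if (stats::cor(scores, x[, anchor]) < 0) {
    loadings <- -loadings
    pc$rotation[, 1] <- loadings
  }
  structure(list(
    feature_names = colnames(x),
    center = pc$center,
    scale = if (standardize) pc$scale else stats::setNames(rep(1, ncol(x)),
                                                           colnames(x)),
    loadings = loadings,
    rotation = pc$rotation,
    variance_explained = ve,
    anchor = anchor,
    standardize = standardize
  ), class = "info_pca")
}

#' @export
print.info_pca <- function(x, ...) {
  cat("<info_pca> features:", paste(x$feature_names, collapse = ", "), "\n")
  cat("  PC1 variance explained:",
      sprintf("%.1f%%", 100 * x$variance_explained[1]),
      "(anchor:", x$anchor, ")\n")
  invisible(x)
}

#' Project images onto the first principal component
#'
#' @param rows feature matrix/data.frame with the model's features (an
#'   `image_id` column is carried through if present).
#' @param model an `info_pca` from [fit_info_pca()].
#' @return if `rows` has an `image_id` column, a data.frame
#'   `image_id, score`; otherwise a numeric score vector. In-sample scores of
#'   the fitted data have mean 0.
#' @export
project_pc1 <- function(rows, model) {
  stopifnot(inherits(model, "info_pca"))
  ids <- if (is.data.frame(rows) && "image_id" %in% names(rows)) {
    as.character(rows$image_id)
  }
  x <- drop_id_column(rows)
  if (!identical(colnames(x), model$feature_names)) {
    if (!all(model$feature_names %in% colnames(x))) {
      stop("feature mismatch: model expects ",
           paste(model$feature_names, collapse = ", "))
    }
    x <- x[, model$feature_names, drop = FALSE]
  }
  z <- sweep(sweep(x, 2, model$center), 2, model$scale, "/")
  scores <- as.numeric(z %*% model$loadings)
  if (is.null(ids)) scores else data.frame(image_id = ids, score = scores,
                                           stringsAsFactors = FALSE)
}

#' Unified information score for a feature table
#'
#' Convenience wrapper: fits the PCA on the feature table and projects the
#' same table onto PC1. The anchor metric defaults to `edge_density` for
#' visual tables and `median_length` for semantic tables.
#'
#' @param features data.frame with `image_id` plus 3 metric columns.
#' @param kind `"visual"` or `"semantic"` (chooses the anchor), or `NULL` to
#'   anchor on the first metric column.
#' @param standardize see [fit_info_pca()].
#' @return list with `scores` (data.frame `image_id, score`) and `model`.
#' @export
unify_scores <- function(features, kind = NULL, standardize = TRUE) {
  anchor <- if (is.null(kind)) NULL else {
    switch(match.arg(kind, c("visual", "semantic")),
           visual = "edge_density", semantic = "median_length")
  }
  model <- fit_info_pca(features, standardize = standardize, anchor = anchor)
  list(scores = project_pc1(features, model), model = model)
}

#' Persist / restore an `info_pca` model as JSON
#'
#' @param model an `info_pca`.
#' @param path JSON path.
#' @return `path` (write) or the restored `info_pca` (read).
#' @export
write_info_pca <- function(model, path) {
  stopifnot(inherits(model, "info_pca"))
  x <- unclass(model)
  x$rotation <- NULL # PC1 is the contract; keep the sidecar minimal
  jsonlite::write_json(x, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_info_pca
#' @export
read_info_pca <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  for (f in c("center", "scale", "loadings", "variance_explained")) {
    x[[f]] <- stats::setNames(as.numeric(x[[f]]), x$feature_names)
  }
  names(x$variance_explained) <- NULL
  x$rotation <- NULL
  structure(x, class = "info_pca")
}

drop_id_column <- function(rows) {
  if (is.data.frame(rows)) {
    rows <- rows[, setdiff(names(rows), "image_id"), drop = FALSE]
    rows <- as.matrix(rows)
  }
  if (!is.numeric(rows)) stop("feature matrix must be numeric")
  if (is.null(colnames(rows))) {
    colnames(rows) <- paste0("f", seq_len(ncol(rows)))
  }
  rows
}
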