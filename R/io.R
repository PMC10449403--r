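# Shared readers/writers and the orchestrating pipeline.

#' Read a per-image depth covariate CSV
#'
#' @param path CSV with columns `image_id,depth`.
#' @return data.frame `image_id, depth`.
#' @export
read_depth <- function(path) {
  if (!file.exists(path)) stop("depth file not found: ", path)
  tab <- utils::read.csv(path, stringsAsFactors = FALSE)
  if (!all(c("image_id", "depth") %in% names(tab))) {
    stop("depth CSV needs columns 'image_id' and 'depth'")
  }
  tab$image_id <- as.character(tab$image_id)
  tab
}

#' Write a table as CSV (round-trip safe)
#'
#' @param x data.frame.
#' @param path output CSV path.
#' @return `path`, invisibly.
#' @export
write_table_csv <- function(x, path) {
  utils::write.csv(x, path, row.names = FALSE)
  invisible(path)
}

#' Write a synthetic study to a directory of plain-text artifacts
#'
#' Writes `depth.csv`, `responses.csv`, `covariates.csv`, `truth.json`
#' (hidden generative parameters, for tests), plus `descriptions.csv` and
#' `embeddings.txt` when the study carries text, and `images/*.png` with an
#' `images/manifest.csv` when it carries images.
#'
#' @param study a `synthetic_study` from [generate_study()].
#' @param dir output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_study <- function(study, dir) {
  stopifnot(inherits(study, "synthetic_study"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write_table_csv(study$covariates[, c("image_id", "depth")],
                  file.path(dir, "depth.csv"))
  write_table_csv(study$covariates, file.path(dir, "covariates.csv"))
  write_table_csv(study$responses, file.path(dir, "responses.csv"))
  jsonlite::write_json(study$truth, file.path(dir, "truth.json"),
                       auto_unbox = TRUE, digits = NA)
  if (!is.null(study$corpus)) {
    desc <- data.frame(
      image_id = rep(names(study$corpus), lengths(study$corpus)),
      description = unlist(study$corpus, use.names = FALSE),
      stringsAsFactors = FALSE
    )
    write_table_csv(desc, file.path(dir, "descriptions.csv"))
    write_embeddings(study$embeddings, file.path(dir, "embeddings.txt"))
  }
  if (!is.null(study$images)) {
    imgdir <- file.path(dir, "images")
    dir.create(imgdir, showWarnings = FALSE)
    for (img in study$images) {
      write_image_png(img, file.path(imgdir, paste0(img$image_id, ".png")))
    }
    write_table_csv(
      data.frame(image_id = names(study$images),
                 path = paste0(names(study$images), ".png"),
                 stringsAsFactors = FALSE),
      file.path(imgdir, "manifest.csv"))
  }
  invisible(dir)
}

#' Load a study directory written by [write_study()]
#'
#' @param dir directory path.
#' @return list with `depth`, `responses`, and (when present) `corpus`,
#'   `embeddings`, `images`, `truth`.
#' @export
load_study_dir <- function(dir) {
  if (!dir.exists(dir)) stop("study directory not found: ", dir)
  out <- list(
    depth = read_depth(file.path(dir, "depth.csv")),
    responses = read_responses(file.path(dir, "responses.csv"))
  )
  dpath <- file.path(dir, "descriptions.csv")
  if (file.exists(dpath)) {
    out$corpus <- read_descriptions(dpath)
    out$embeddings <- read_embeddings(file.path(dir, "embeddings.txt"))
  }
  mpath <- file.path(dir, "images", "manifest.csv")
  if (file.exists(mpath)) out$images <- read_images(manifest = mpath)
  tpath <- file.path(dir, "truth.json")
  if (file.exists(tpath)) out$truth <- jsonlite::read_json(tpath,
                                                           simplifyVector = TRUE)
  out
}

#' Run the full boundary-transformation analysis
#'
#' Orchestrates the stages in order: visual features (from images, if
#' supplied) and semantic features (from a corpus plus embeddings, if
#' supplied) are each unified into a single PC1 information score; forced
#' responses are reduced to per-image boundary-transformation scores; the
#' split-half noise ceiling is estimated; and the regression battery is fit
#' (depth baseline, depth + semantic, depth + visual, all three) along with
#' per-semantic-feature regressions and the seven-model variance partition.
#' Precomputed feature tables or info scores can be supplied directly instead
#' of raw inputs — e.g. `semantic_scores`/`visual_scores` as data.frames
#' `image_id, score` — which is also how external (non-synthetic) unified
#' scores enter the pipeline.
#'
#' @param responses response table (see [score_boundary()]).
#' @param depth data.frame `image_id, depth`.
#' @param images named list of [scene_image()] (optional).
#' @param visual_features precomputed visual feature table (optional).
#' @param corpus named list of description vectors or corpus data.frame
#'   (optional).
#' @param embeddings an [embedding_table()] (required with `corpus`).
#' @param semantic_features precomputed semantic feature table (optional).
#' @param visual_scores,semantic_scores precomputed unified scores,
#'   data.frames `image_id, score` (optional; bypass PCA).
#' @param standardize z-score features before PCA.
#' @param n_iterations,interval,ceiling_seed noise-ceiling settings.
#' @param convention response-coding convention, see [code_response()].
#' @return a `scene_pipeline` list: `visual_features`, `semantic_features`,
#'   `visual` and `semantic` (scores + PCA model), `scores`, `merged`,
#'   `ceiling`, `regressions` (named list of `ols_fit`), `per_feature`,
#'   `partition`, `manifest`.
#' @export
run_pipeline <- function(responses, depth,
                         images = NULL, visual_features = NULL,
                         corpus = NULL, embeddings = NULL,
                         semantic_features = NULL,
                         visual_scores = NULL, semantic_scores = NULL,
                         standardize = TRUE,
                         n_iterations = 1000, interval = 0.95,
                         ceiling_seed = 1,
                         convention = "closer_extension") {
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      stop("[", name, "] ", conditionMessage(e), call. = FALSE)
    })
  }

  visual_model <- NULL
  if (is.null(visual_scores)) {
    if (is.null(visual_features) && !is.null(images)) {
      visual_features <- stage("visual-features", compute_visual_features(images))
    }
    if (!is.null(visual_features)) {
      u <- stage("unify-visual",
                 unify_scores(visual_features, "visual", standardize))
      visual_scores <- u$scores
      visual_model <- u$model
    }
  }
  semantic_model <- NULL
  if (is.null(semantic_scores)) {
    if (is.null(semantic_features) && !is.null(corpus)) {
      if (is.null(embeddings)) stop("[semantic-features] 'embeddings' required with 'corpus'")
      semantic_features <- stage("semantic-features",
                                 compute_semantic_features(corpus, embeddings))
    }
    if (!is.null(semantic_features)) {
      u <- stage("unify-semantic",
                 unify_scores(semantic_features, "semantic", standardize))
      semantic_scores <- u$scores
      semantic_model <- u$model
    }
  }
  if (is.null(visual_scores) || is.null(semantic_scores)) {
    stop("pipeline needs visual and semantic information ",
         "(images/features/scores and corpus/features/scores)")
  }

  scores <- stage("score", score_boundary(responses, convention))
  merged <- stage("merge", {
    m <- merge(scores[, c("image_id", "score")], depth, by = "image_id")
    m <- merge(m, stats::setNames(semantic_scores[, c("image_id", "score")],
                                  c("image_id", "semantic_info")),
               by = "image_id")
    m <- merge(m, stats::setNames(visual_scores[, c("image_id", "score")],
                                  c("image_id", "visual_info")),
               by = "image_id")
    if (nrow(m) < 10) stop("fewer than 10 images with complete data")
    m
  })
  ceiling <- stage("noise-ceiling",
                   noise_ceiling(responses, n_iterations = n_iterations,
                                 interval = interval, seed = ceiling_seed,
                                 convention = convention))
  regressions <- stage("regress", list(
    depth = fit_ols(merged$score, merged[, "depth", drop = FALSE]),
    depth_semantic = fit_ols(merged$score,
                             merged[, c("depth", "semantic_info")]),
    depth_visual = fit_ols(merged$score, merged[, c("depth", "visual_info")]),
    full = fit_ols(merged$score,
                   merged[, c("depth", "semantic_info", "visual_info")])
  ))
  per_feature <- if (!is.null(semantic_features)) {
    stage("per-feature", {
      sf <- semantic_features[match(merged$image_id, semantic_features$image_id), ]
      per_feature_regressions(merged$score, sf)
    })
  }
  partition <- stage("partition",
                     variance_partition(merged$score, merged$depth,
                                        merged$semantic_info,
                                        merged$visual_info))
  manifest <- list(
    package_version = as.character(utils::packageVersion("scenebudget")),
    n_images = nrow(merged),
    n_participants = length(unique(responses$participant_id)),
    standardize = standardize,
    ceiling = list(n_iterations = n_iterations, interval = interval,
                   seed = ceiling_seed),
    convention = convention
  )
  structure(list(visual_features = visual_features,
                 semantic_features = semantic_features,
                 visual = list(scores = visual_scores, model = visual_model),
                 semantic = list(scores = semantic_scores,
                                 model = semantic_model),
                 scores = scores, merged = merged, ceiling = ceiling,
                 regressions = regressions, per_feature = per_feature,
                 partition = partition, manifest = manifest),
            class = "scene_pipeline")
}

#' @export
print.scene_pipeline <- function(x, ...) {
  cat("<scene_pipeline>", x$manifest$n_images, "images,",
      x$manifest$n_participants, "participants\n")
  cat(sprintf("  noise ceiling: R^2 in [%.3f, %.3f]\n",
              x$ceiling$lower, x$ceiling$upper))
  for (nm in names(x$regressions)) {
    r <- x$regressions[[nm]]
    cat(sprintf("  %-15s R^2 = %.3f (adj %.3f)\n", nm, r$r_squared,
                r$adjusted_r_squared))
  }
  cat(sprintf("  partition: unique depth %.3f, semantic %.3f, visual %.3f\n",
              x$partition$unique_depth, x$partition$unique_semantic,
              x$partition$unique_visual))
  invisible(x)
}
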