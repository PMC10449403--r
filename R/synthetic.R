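# Synthetic study generation: procedural images, Zipfian description corpora,
# toy embeddings, and observer responses from a known linear model.

# Derive a stage seed from the master seed so stages can be regenerated
# independently; kept well inside 32-bit integer range.
stage_seed <- function(seed, stage) {
  offsets <- c(covariates = 101L, responses = 202L, corpus = 303L,
               embeddings = 404L, images = 505L)
  if (!stage %in% names(offsets)) stop("unknown stage: ", stage)
  (as.integer(seed) %% 2000000000L) + offsets[[stage]]
}

# Palette of colors whose A*/B* coordinates sit at distinct chromatic
# histogram bin centers (20 bins over [-110, 110]), so palette size maps
# directly onto occupied color bins downstream.
lab_palette <- function(palette_size) {
  if (palette_size < 1) stop("invalid parameter: palette_size must be >= 1")
  centers <- -110 + 11 * (c(5, 7, 9, 11, 13) + 0.5) # in-gamut bin centers
  grid <- expand.grid(a = centers, b = centers)
  # order by distance from neutral so small palettes stay well separated
  grid <- grid[order(abs(grid$a) + abs(grid$b), grid$a, grid$b), ]
  if (palette_size > nrow(grid)) {
    stop("invalid parameter: palette_size must be <= ", nrow(grid))
  }
  # L* varies across entries (luminance contrast drives edge contours);
  # the chromatic bin occupied by each entry depends on A*/B* only.
  Lstar <- 35 + 13 * (seq_len(palette_size) %% 5)
  lab <- cbind(L = Lstar, as.matrix(grid[seq_len(palette_size), ]))
  rgb <- grDevices::convertColor(lab, from = "Lab", to = "sRGB")
  pmin(pmax(rgb, 0), 1)
}

#' Generate a procedural scene image
#'
#' Composes filled ellipses and rectangles over a uniform background, with
#' colors drawn from a palette constructed to occupy distinct chromatic
#' histogram bins. More shapes produce more contours (higher edge density);
#' more palette colors occupy more color bins (higher color entropy). An
#' optional sinusoidal luminance texture adds oriented energy. With
#' `layout = "stripes"` the image is instead divided into `palette_size`
#' equal-width vertical stripes, one per palette color, giving a flat color
#' histogram by construction.
#'
#' @param n_shapes number of shapes to draw (>= 0).
#' @param palette_size number of distinct palette colors (1-25).
#' @param texture_freq spatial frequency (cycles/pixel) of an optional
#'   luminance grating; 0 disables it.
#' @param size image side in pixels.
#' @param seed integer seed; identical seeds give bit-identical images.
#' @param layout `"shapes"` (default) or `"stripes"`.
#' @param image_id identifier for the resulting [scene_image()].
#' @return a [scene_image()].
#' @export
generate_image <- function(n_shapes, palette_size, texture_freq = 0,
                           size = 350, seed = 1, layout = c("shapes", "stripes"),
                           image_id = "synthetic") {
  layout <- match.arg(layout)
  if (n_shapes < 0) stop("invalid parameter: n_shapes must be >= 0")
  if (size < 32) stop("invalid parameter: size must be >= 32")
  pal <- lab_palette(palette_size)
  set.seed(seed)
  px <- array(0, dim = c(size, size, 3))
  if (layout == "stripes") {
    bounds <- round(seq(0, size, length.out = palette_size + 1))
    for (k in seq_len(palette_size)) {
      cols <- (bounds[k] + 1):bounds[k + 1]
      for (ch in 1:3) px[, cols, ch] <- pal[k, ch]
    }
  } else {
    for (ch in 1:3) px[, , ch] <- pal[1, ch] # background = first palette color
    if (n_shapes > 0) {
      xg <- matrix(rep(seq_len(size), each = size), size, size) # column index
      yg <- matrix(rep(seq_len(size), times = size), size, size) # row index
      for (i in seq_len(n_shapes)) {
        col <- pal[(i %% palette_size) + 1, ] # cycles through the palette
        cx <- stats::runif(1, 0.1 * size, 0.9 * size)
        cy <- stats::runif(1, 0.1 * size, 0.9 * size)
        rx <- stats::runif(1, 0.04 * size, 0.16 * size)
        ry <- stats::runif(1, 0.04 * size, 0.16 * size)
        mask <- if (stats::runif(1) < 0.5) {
          ((xg - cx) / rx)^2 + ((yg - cy) / ry)^2 <= 1
        } else {
          abs(xg - cx) <= rx & abs(yg - cy) <= ry
        }
        for (ch in 1:3) {
          plane <- px[, , ch]
          plane[mask] <- col[ch]
          px[, , ch] <- plane
        }
      }
    }
  }
  if (texture_freq > 0) {
    xg <- matrix(rep(seq_len(size), each = size), size, size)
    tex <- 0.06 * sin(2 * pi * texture_freq * xg)
    for (ch in 1:3) px[, , ch] <- pmin(pmax(px[, , ch] + tex, 0), 1)
  }
  scene_image(px * 255, image_id)
}

#' Generate a synthetic description corpus for one image
#'
#' Each describer produces one description: a Poisson-distributed number of
#' words around `target_length`, mixing content words drawn from a Zipfian
#' distribution over a synthetic vocabulary with a fixed proportion of
#' stopwords (so tokenization is exercised downstream). Larger vocabularies
#' and smaller Zipf exponents flatten word use and raise lexical entropy.
#'
#' @param target_length mean description length in words (>= 1).
#' @param vocab_size number of content words available (>= 2 for nonzero
#'   entropy; 1 is allowed and gives entropy 0 downstream).
#' @param zipf_exponent exponent of the Zipfian word-frequency law (> 0).
#' @param n_describers number of descriptions to generate.
#' @param seed integer seed.
#' @param vocabulary optional explicit content vocabulary (overrides
#'   `vocab_size` words generated as `word001`, ...).
#' @param stopword_rate fraction of each description made of stopwords.
#' @return character vector of `n_describers` descriptions.
#' @export
generate_descriptions <- function(target_length, vocab_size,
                                  zipf_exponent = 1.05, n_describers = 100,
                                  seed = 1, vocabulary = NULL,
                                  stopword_rate = 0.3) {
  if (target_length < 1) stop("invalid parameter: target_length must be >= 1")
  if (is.null(vocabulary)) {
    if (vocab_size < 1) stop("invalid parameter: vocab_size must be >= 1")
    vocabulary <- sprintf("word%03d", seq_len(vocab_size))
  } else {
    vocab_size <- length(vocabulary)
  }
  if (zipf_exponent <= 0) stop("invalid parameter: zipf_exponent must be > 0")
  stops <- c("the", "a", "and", "of", "in", "on", "with")
  zipf_p <- (seq_len(vocab_size))^(-zipf_exponent)
  zipf_p <- zipf_p / sum(zipf_p)
  set.seed(seed)
  vapply(seq_len(n_describers), function(i) {
    len <- max(1L, stats::rpois(1, target_length))
    n_stop <- min(len - 1L, round(len * stopword_rate))
    n_content <- len - n_stop
    words <- c(sample(vocabulary, n_content, replace = TRUE, prob = zipf_p),
               sample(stops, n_stop, replace = TRUE))
    paste(sample(words), collapse = " ")
  }, character(1))
}

#' Generate a toy word-embedding table
#'
#' Places unit vectors around `n_clusters` mutually orthogonal centroids
#' (words are assigned to clusters round-robin). Words within a cluster have
#' small pairwise cosine distance, words across clusters have distance near
#' 1, so the mean pairwise distance of a corpus is controlled by how many
#' clusters its words span.
#'
#' @param vocabulary character vector of words.
#' @param dim embedding dimension (>= 2, >= n_clusters).
#' @param n_clusters number of orthogonal cluster centroids (>= 1).
#' @param spread within-cluster dispersion; 0 collapses each cluster to its
#'   centroid exactly.
#' @param seed integer seed.
#' @return an [embedding_table()].
#' @export
generate_embeddings <- function(vocabulary, dim = 50, n_clusters = 5,
                                spread = 0.1, seed = 1) {
  if (dim < 2) stop("invalid parameter: dim must be >= 2")
  if (n_clusters < 1) stop("invalid parameter: n_clusters must be >= 1")
  if (n_clusters > dim) stop("invalid parameter: n_clusters must be <= dim")
  set.seed(seed)
  centroids <- qr.Q(qr(matrix(stats::rnorm(dim * n_clusters), dim)))[, seq_len(n_clusters), drop = FALSE]
  vecs <- t(vapply(seq_along(vocabulary), function(i) {
    v <- centroids[, ((i - 1) %% n_clusters) + 1]
    if (spread > 0) v <- v + spread * stats::rnorm(dim)
    v / sqrt(sum(v^2))
  }, numeric(dim)))
  embedding_table(vecs, vocabulary)
}

#' Configuration of a synthetic boundary-transformation study
#'
#' Defaults mirror the study conditions the pipeline is designed for: 120
#' images, 360 participants, depth on a 1-5 rating scale, unified information
#' scores with a spread of about 1.6 score units, and generative coefficients
#' on the boundary-score scale (intercept 0.52; depth -0.13; semantic -0.03;
#' visual -0.001).
#'
#' @param n_images number of images (>= 10).
#' @param n_participants number of observers (>= 10).
#' @param beta named numeric vector `intercept, depth, semantic, visual` of
#'   generative coefficients on the boundary-score scale.
#' @param noise_sd residual SD of the true per-image scores.
#' @param depth_range range of the uniform per-image depth covariate.
#' @param info_sd named vector `semantic, visual`: SDs of the latent
#'   information scores.
#' @param image_size side of generated images, pixels.
#' @param seed master seed; all stages derive named substreams from it.
#' @return a `study_config` list.
#' @export
study_config <- function(n_images = 120, n_participants = 360,
                         beta = c(intercept = 0.52, depth = -0.13,
                                  semantic = -0.03, visual = -0.001),
                         noise_sd = 0.09, depth_range = c(1, 5),
                         info_sd = c(semantic = 1.6, visual = 1.6),
                         image_size = 350, seed = 1) {
  if (n_images < 10) stop("invalid config: n_images must be >= 10")
  if (n_participants < 10) stop("invalid config: n_participants must be >= 10")
  if (length(beta) != 4) stop("invalid config: beta needs 4 components")
  names(beta) <- c("intercept", "depth", "semantic", "visual")
  if (noise_sd < 0) stop("invalid config: noise_sd must be >= 0")
  if (length(depth_range) != 2 || depth_range[1] >= depth_range[2]) {
    stop("invalid config: depth_range must be an increasing interval")
  }
  names(info_sd) <- c("semantic", "visual")
  structure(list(n_images = n_images, n_participants = n_participants,
                 beta = beta, noise_sd = noise_sd, depth_range = depth_range,
                 info_sd = info_sd, image_size = image_size,
                 seed = as.integer(seed)),
            class = "study_config")
}

clamp <- function(x, lo, hi) pmin(pmax(x, lo), hi)

#' Generate a complete synthetic study
#'
#' Draws per-image depth and latent semantic/visual information, sets each
#' image's true boundary-transformation score
#' `s = clip(b0 + b_d*depth + b_s*sem + b_v*vis + noise, -1, 1)`, and draws
#' every participant's forced-error response as an extension error with
#' probability `(1 + s)/2` — the unique binomial model whose +1/-1-coded mean
#' is `s`. Optionally also emits procedural images, description corpora and
#' a toy embedding table whose measured features increase with the
#' corresponding latent information (via the generator dials), so every
#' pipeline stage has an input.
#'
#' @param cfg a [study_config()].
#' @param components which inputs to generate: `"responses"` is always
#'   produced; add `"text"` for corpora + embeddings and `"images"` for
#'   procedural images.
#' @return a `synthetic_study` list: `covariates` (data.frame `image_id,
#'   depth, semantic_info, visual_info`), `true_scores`, `responses`
#'   (complete participant x image table), `images`, `corpus`, `embeddings`,
#'   `truth` (hidden parameters, for tests), `config`.
#' @export
generate_study <- function(cfg = study_config(),
                           components = c("responses", "text", "images")) {
  stopifnot(inherits(cfg, "study_config"))
  components <- match.arg(components, several.ok = TRUE)
  ids <- sprintf("img%03d", seq_len(cfg$n_images))
  pids <- sprintf("p%03d", seq_len(cfg$n_participants))

  set.seed(stage_seed(cfg$seed, "covariates"))
  depth <- stats::runif(cfg$n_images, cfg$depth_range[1], cfg$depth_range[2])
  sem <- stats::rnorm(cfg$n_images, 0, cfg$info_sd["semantic"])
  vis <- stats::rnorm(cfg$n_images, 0, cfg$info_sd["visual"])
  eps <- stats::rnorm(cfg$n_images, 0, cfg$noise_sd)
  raw <- cfg$beta["intercept"] + cfg$beta["depth"] * depth +
    cfg$beta["semantic"] * sem + cfg$beta["visual"] * vis + eps
  s <- clamp(raw, -1, 1)
  n_clipped <- sum(raw != s)
  if (n_clipped > 0) {
    message("generate_study: ", n_clipped,
            " true score(s) clipped to [-1, 1]")
  }

  set.seed(stage_seed(cfg$seed, "responses"))
  p_ext <- (1 + s) / 2
  ext <- matrix(stats::rbinom(cfg$n_participants * cfg$n_images, 1,
                              rep(p_ext, each = cfg$n_participants)),
                nrow = cfg$n_participants)
  responses <- data.frame(
    participant_id = rep(pids, times = cfg$n_images),
    image_id = rep(ids, each = cfg$n_participants),
    response = ifelse(as.vector(ext) == 1, "closer", "farther"),
    stringsAsFactors = FALSE
  )

  corpus <- NULL; embeddings <- NULL
  if ("text" %in% components) {
    zs <- sem / cfg$info_sd["semantic"]
    tlen <- clamp(round(9 + 3 * zs), 3, 30)
    vsz <- clamp(round(40 + 18 * zs), 4, 150)
    vocabulary <- sprintf("word%03d", seq_len(max(vsz)))
    base <- stage_seed(cfg$seed, "corpus")
    corpus <- lapply(seq_len(cfg$n_images), function(i) {
      generate_descriptions(tlen[i], vsz[i], n_describers = 100,
                            seed = base + i,
                            vocabulary = vocabulary[seq_len(vsz[i])])
    })
    names(corpus) <- ids
    embeddings <- generate_embeddings(vocabulary, dim = 50, n_clusters = 8,
                                      spread = 0.15,
                                      seed = stage_seed(cfg$seed, "embeddings"))
  }

  images <- NULL
  if ("images" %in% components) {
    zv <- vis / cfg$info_sd["visual"]
    nshape <- clamp(round(8 + 4 * zv), 0, 25)
    psize <- clamp(round(5 + 1.5 * zv), 1, 12)
    base <- stage_seed(cfg$seed, "images")
    images <- lapply(seq_len(cfg$n_images), function(i) {
      generate_image(nshape[i], psize[i], texture_freq = 0,
                     size = cfg$image_size, seed = base + i, image_id = ids[i])
    })
    names(images) <- ids
  }

  structure(list(
    covariates = data.frame(image_id = ids, depth = depth,
                            semantic_info = sem, visual_info = vis,
                            stringsAsFactors = FALSE),
    true_scores = stats::setNames(s, ids),
    responses = responses,
    images = images,
    corpus = corpus,
    embeddings = embeddings,
    truth = list(beta = as.list(cfg$beta), noise_sd = cfg$noise_sd,
                 true_scores = unname(s), n_clipped = n_clipped,
                 seed = cfg$seed),
    config = cfg
  ), class = "synthetic_study")
}

#' @export
print.synthetic_study <- function(x, ...) {
  cat("<synthetic_study>", x$config$n_images, "images x",
      x$config$n_participants, "participants; components:",
      paste(c("responses", if (!is.null(x$corpus)) "text",
              if (!is.null(x$images)) "images"), collapse = ", "), "\n")
  invisible(x)
}
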