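# Synthetic study generation: determinism, dials, and the response model.

test_that("generated images are seed-deterministic and validate downstream", {
  i1 <- generate_image(5, 4, seed = 7, size = 96)
  i2 <- generate_image(5, 4, seed = 7, size = 96)
  expect_identical(i1$pixels, i2$pixels)
  i3 <- generate_image(5, 4, seed = 8, size = 96)
  expect_false(identical(i1$pixels, i3$pixels))
  expect_error(generate_image(-1, 4), "n_shapes")
  expect_error(generate_image(3, 0), "palette_size")
})

test_that("a blank canvas has zero edge density and zero color entropy", {
  blank <- generate_image(0, 1, seed = 3, size = 128)
  expect_equal(compute_edge_density(blank), 0)
  expect_equal(compute_color_entropy(blank), 0)
})

test_that("equal-width stripes of k palette colors give log2(k) color entropy", {
  expect_equal(compute_color_entropy(
    generate_image(0, 4, size = 352, layout = "stripes")), 2.0,
    tolerance = 1e-9)
  expect_equal(compute_color_entropy(
    generate_image(0, 8, size = 352, layout = "stripes")), 3.0,
    tolerance = 1e-9)
})

test_that("generator dials move their downstream metrics monotonically", {
  # more shapes -> more edges
  expect_gt(compute_edge_density(generate_image(15, 4, seed = 2, size = 160)),
            compute_edge_density(generate_image(3, 4, seed = 2, size = 160)))
  # more palette colors -> higher color entropy
  expect_gt(compute_color_entropy(generate_image(12, 8, seed = 4, size = 160)),
            compute_color_entropy(generate_image(12, 2, seed = 4, size = 160)))
  # larger vocabulary -> higher lexical entropy
  expect_gt(lexical_entropy(generate_descriptions(9, 80, seed = 2)),
            lexical_entropy(generate_descriptions(9, 10, seed = 2)))
  # more embedding clusters -> larger mean pairwise distance
  vocab <- sprintf("word%03d", 1:40)
  d <- generate_descriptions(9, 40, seed = 5)
  expect_gt(
    mean_pairwise_distance(d, generate_embeddings(vocab, n_clusters = 12,
                                                  spread = 0.1, seed = 1)),
    mean_pairwise_distance(d, generate_embeddings(vocab, n_clusters = 2,
                                                  spread = 0.1, seed = 1)))
})

test_that("description generator hits its length target and entropy limits", {
  short <- generate_descriptions(6, 30, seed = 9)
  long <- generate_descriptions(12, 30, seed = 9)
  med <- function(d) median(vapply(d, description_length, numeric(1)))
  expect_equal(med(long) / med(short), 2, tolerance = 0.25)
  expect_equal(lexical_entropy(generate_descriptions(9, 1, seed = 2)), 0)
  expect_identical(generate_descriptions(8, 20, seed = 4),
                   generate_descriptions(8, 20, seed = 4))
  expect_error(generate_descriptions(0, 10), "target_length")
})

test_that("embedding clusters have the promised geometry", {
  vocab <- c("a1", "a2", "a3", "a4")
  emb0 <- generate_embeddings(vocab, dim = 6, n_clusters = 1, spread = 0,
                              seed = 1)
  expect_equal(mean_pairwise_distance("a1 a2 a3 a4", emb0), 0, tolerance = 1e-12)
  emb2 <- generate_embeddings(vocab, dim = 6, n_clusters = 2, spread = 0,
                              seed = 1)
  # words 1 and 2 land in different (orthogonal) clusters
  expect_equal(1 - sum(emb2["a1", ] * emb2["a2", ]), 1.0, tolerance = 1e-12)
  expect_true(all(abs(sqrt(rowSums(unclass(emb2)^2)) - 1) < 1e-12))
  expect_error(generate_embeddings(vocab, dim = 3, n_clusters = 5), "<= dim")
})

test_that("a degenerate generative model yields unanimous extension", {
  cfg <- study_config(n_images = 10, n_participants = 12,
                      beta = c(1, 0, 0, 0), noise_sd = 0, seed = 2)
  st <- generate_study(cfg, components = "responses")
  expect_true(all(st$true_scores == 1))
  sc <- score_boundary(st$responses)
  expect_true(all(sc$score == 1))
  expect_true(all(st$responses$response == "closer"))
})

test_that("per-image score is an unbiased binomial mean of the true score", {
  cfg <- study_config(n_images = 10, n_participants = 2000, noise_sd = 0.2,
                      seed = 31)
  st <- generate_study(cfg, components = "responses")
  sc <- score_boundary(st$responses)
  s <- st$true_scores[sc$image_id]
  se <- sqrt((1 - s^2) / cfg$n_participants)
  expect_true(all(abs(sc$score - s) <= 3 * pmax(se, 1e-6)))
  # empirical variance of score around truth matches (1 - s^2)/n in aggregate
  z <- (sc$score - s) / pmax(se, 1e-6)
  expect_lt(abs(mean(z)), 1.5)
})

test_that("studies are complete, consistent, and seed-deterministic", {
  cfg <- study_config(n_images = 10, n_participants = 10, image_size = 64,
                      seed = 8)
  st <- generate_study(cfg)
  expect_equal(nrow(st$responses), 100) # every participant x image
  expect_setequal(unique(st$responses$image_id), st$covariates$image_id)
  expect_setequal(names(st$corpus), st$covariates$image_id)
  expect_setequal(names(st$images), st$covariates$image_id)
  expect_true(all(st$true_scores >= -1 & st$true_scores <= 1))
  st2 <- generate_study(cfg)
  expect_identical(st$responses, st2$responses)
  expect_identical(st$corpus, st2$corpus)
  expect_identical(st$images[[1]]$pixels, st2$images[[1]]$pixels)
  expect_error(study_config(n_images = 5), "n_images")
  expect_error(study_config(noise_sd = -1), "noise_sd")
})

test_that("latent information dials surface in measured features", {
  cfg <- study_config(n_images = 15, n_participants = 10, image_size = 96,
                      info_sd = c(semantic = 1.6, visual = 1.6), seed = 21)
  st <- generate_study(cfg)
  vf <- compute_visual_features(st$images)
  vf <- vf[match(st$covariates$image_id, vf$image_id), ]
  expect_gt(cor(vf$edge_density, st$covariates$visual_info), 0.4)
  sf <- compute_semantic_features(st$corpus, st$embeddings)
  sf <- sf[match(st$covariates$image_id, sf$image_id), ]
  expect_gt(cor(sf$lexical_entropy, st$covariates$semantic_info), 0.4)
})
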