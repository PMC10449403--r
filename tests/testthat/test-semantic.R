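# Semantic-information metrics: tokenization, lengths, lexical entropy,
# pairwise embedding distance, per-image aggregation.

test_that("tokenization retains content words and drops stopwords", {
  toks <- tokenize("The quick brown fox jumps over the lazy dog")
  expect_equal(toks, c("quick", "brown", "fox", "jumps", "over", "lazy", "dog"))
  expect_length(toks, 7)
  expect_equal(tokenize(""), character(0))
  expect_equal(tokenize("A dog, a DOG!"), c("dog", "dog"))
  # punctuation splits hyphenated words; order and duplicates preserved
  expect_equal(tokenize("blue-green water, water"),
               c("blue", "green", "water", "water"))
})

test_that("the frozen stopword list behaves as documented", {
  sw <- default_stopwords()
  expect_true(all(c("the", "and", "a", "is") %in% sw))
  expect_false("over" %in% sw) # spatial prepositions are content words here
  expect_true(length(sw) > 100)
})

test_that("description length counts raw words by default", {
  expect_equal(description_length("The quick brown fox jumps over the lazy dog"), 9)
  expect_equal(description_length(""), 0)
  expect_equal(description_length("dog"), 1)
  expect_equal(description_length("  padded   spaces  here "), 3)
  expect_equal(description_length("The quick brown fox jumps over the lazy dog",
                                  after_tokenization = TRUE), 7)
})

test_that("lexical entropy matches hand-computed histograms", {
  expect_equal(lexical_entropy(rep("dog", 100)), 0)
  expect_equal(lexical_entropy(c("cat dog", "dog cat")), 1.0)
  # pooled counts {a:2, b:1, c:1} -> 1.5 bits
  expect_equal(lexical_entropy(c("apple apple", "banana cherry")), 1.5)
  expect_error(lexical_entropy(c("the a an", "of and")), "no tokens")
})

test_that("lexical entropy is order-invariant and rises with new unique tokens", {
  d <- c("red barn door", "old red tractor", "barn with tractor")
  expect_equal(lexical_entropy(d), lexical_entropy(rev(d)))
  # replacing a duplicate with a new type flattens the histogram
  base <- lexical_entropy(c("dog dog cat", "dog bird"))
  flat <- lexical_entropy(c("dog fish cat", "dog bird"))
  expect_gt(flat, base)
})

test_that("pairwise distance follows the pair-count law and embedding geometry", {
  emb <- toy_embeddings()
  # 7 surviving tokens -> choose(7, 2) = 21 pairs, all among identical vectors
  d7 <- paste(rep("dog", 7), collapse = " ")
  expect_equal(mean_pairwise_distance(d7, emb), 0)
  # orthogonal vectors -> distance 1
  expect_equal(mean_pairwise_distance("dog cat", emb), 1.0)
  # opposite vectors -> distance 2 (upper bound)
  expect_equal(mean_pairwise_distance("cat anticat", emb), 2.0)
  # identical-direction vectors -> 0
  expect_equal(mean_pairwise_distance("dog puppy", emb), 0)
})

test_that("pairwise distance equals a brute-force nested-loop oracle", {
  set.seed(11)
  vocab <- sprintf("w%02d", 1:12)
  vecs <- matrix(rnorm(12 * 6), 12, dimnames = list(vocab, NULL))
  emb <- embedding_table(vecs)
  descs <- vapply(1:8, function(i) {
    paste(sample(vocab, sample(2:6, 1), replace = TRUE), collapse = " ")
  }, character(1))
  oracle <- mean(vapply(descs, function(d) {
    toks <- tokenize(d)
    tot <- 0; np <- 0
    for (i in seq_along(toks)) {
      for (j in seq_along(toks)) {
        if (i < j) {
          u <- vecs[toks[i], ]; v <- vecs[toks[j], ]
          tot <- tot + 1 - sum(u * v) / sqrt(sum(u^2) * sum(v^2))
          np <- np + 1
        }
      }
    }
    tot / np
  }, numeric(1)))
  expect_equal(mean_pairwise_distance(descs, emb), oracle, tolerance = 1e-12)
})

test_that("out-of-vocabulary tokens are skipped, never defaulted", {
  emb <- toy_embeddings()
  # "unknownword" pairs are dropped; dog-cat pair remains
  expect_equal(mean_pairwise_distance("dog unknownword cat", emb), 1.0)
  expect_error(mean_pairwise_distance("dog unknownword", emb), "no valid pairs")
  expect_error(lookup_vectors <- scenebudget:::lookup_vectors(emb, "zzz"),
               "out-of-vocabulary")
})

test_that("per-image aggregation computes the documented medians", {
  emb <- toy_embeddings()
  d3 <- c("dog cat mix", "dog cat puppy mix anticat",
          "dog cat mix anticat puppy dog cat") # lengths 3, 5, 7
  f <- aggregate_semantic_features(d3, emb)
  expect_equal(f$median_length, 5)
  d4 <- c(d3, "dog cat mix anticat puppy dog cat mix dog") # + length 9
  expect_equal(aggregate_semantic_features(d4, emb)$median_length, 6)
  expect_true(f$mean_pairwise_distance >= 0 && f$mean_pairwise_distance <= 2)
})

test_that("corpus-level features drop pair-starved images with a warning", {
  emb <- toy_embeddings()
  corpus <- list(good = c("dog cat mix", "puppy anticat dog"),
                 bad = c("unknown thing", "mystery item"))
  expect_warning(tab <- compute_semantic_features(corpus, emb), "dropping")
  expect_equal(tab$image_id, "good")
  expect_equal(names(tab), c("image_id", "median_length", "lexical_entropy",
                             "mean_pairwise_distance"))
})

test_that("semantic features are deterministic", {
  emb <- toy_embeddings()
  corpus <- list(a = c("dog cat over mix", "puppy dog anticat"),
                 b = c("cat cat dog", "mix anticat dog cat"))
  expect_identical(compute_semantic_features(corpus, emb),
                   compute_semantic_features(corpus, emb))
})
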