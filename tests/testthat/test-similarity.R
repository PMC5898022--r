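test_that("cosine similarity matches its closed form and zero conventions", {
  expect_equal(cosine_similarity(c(1, 1, 0), c(1, 1, 0)), 1)
  expect_equal(cosine_similarity(c(1, 1, 0), c(1, 0, 1)), 0.5)
  expect_equal(cosine_similarity(c(1, 0), c(0, 1)), 0)
  expect_equal(cosine_similarity(c(0, 0), c(1, 1)), 0)
})

test_that("jaccard similarity matches its closed form and zero conventions", {
  expect_equal(jaccard_similarity(c(1, 1, 0), c(1, 1, 0)), 1)
  expect_equal(jaccard_similarity(c(1, 1, 0), c(1, 0, 1)), 1 / 3)
  expect_equal(jaccard_similarity(c(1, 0, 0), c(0, 1, 1)), 0)
  expect_equal(jaccard_similarity(c(0, 0), c(0, 0)), 0)
})

test_that("jaccard never exceeds cosine on binary vectors", {
  set.seed(11)
  for (i in 1:200) {
    a <- rbinom(12, 1, runif(1))
    b <- rbinom(12, 1, runif(1))
    expect_gte(cosine_similarity(a, b) + 1e-12, jaccard_similarity(a, b))
  }
})

test_that("local alignment scores match hand-computed and degenerate cases", {
  expect_equal(smith_waterman_score("ACDE", "ACDE"), 8)
  expect_equal(smith_waterman_score("AAAA", "CCCC"), 0)
  expect_equal(smith_waterman_score("ACDE", "AADE"),
               smith_waterman_score("AADE", "ACDE"))
  expect_error(smith_waterman_score("ACDZ1", "ACDE"), "outside the declared")
})

test_that("local alignment agrees with the substring-enumeration oracle", {
  set.seed(23)
  letters4 <- c("A", "C", "D", "E")
  for (i in 1:25) {
    x <- paste(sample(letters4, sample(1:6, 1), replace = TRUE), collapse = "")
    y <- paste(sample(letters4, sample(1:6, 1), replace = TRUE), collapse = "")
    expect_equal(smith_waterman_score(x, y),
                 oracle_local_align(x, y),
                 info = paste(x, y))
  }
})

test_that("sequence-set similarity is a (normalized) mean over cross pairs", {
  expect_equal(sequence_set_similarity("ACDE", "ACDE"), 1)
  # unnormalized: mean of SW(ACDE,AAAA)=2 and SW(ACDE,CCCC)=2
  expect_equal(sequence_set_similarity("ACDE", c("AAAA", "CCCC"),
                                       normalize = FALSE), 2)
  va <- c("ACDEFG", "GHIKL")
  vb <- c("ACDE", "MNPQ", "GHIK")
  expect_equal(sequence_set_similarity(va, vb),
               sequence_set_similarity(vb, va))
  expect_lte(sequence_set_similarity(va, vb), 1)
  expect_error(sequence_set_similarity(character(), "ACDE"), "non-empty")
})

test_that("all measures are symmetric and reach 1 on identical inputs", {
  a <- c(1, 0, 1, 1, 0)
  expect_equal(cosine_similarity(a, a), 1)
  expect_equal(jaccard_similarity(a, a), 1)
  expect_equal(sequence_set_similarity("GHIKLM", "GHIKLM"), 1)
})

test_that("shorthand similarity settings expand to per-source measures", {
  expect_identical(unname(similarity_config("JJS")$measures),
                   c("jaccard", "jaccard", "smith_waterman"))
  expect_identical(names(similarity_config("JJC")$measures),
                   c("chemical", "side_effect", "protein"))
  expect_identical(similarity_config("JJC")$measures[["protein"]], "cosine")
  expect_error(similarity_config("XYZ"), "shorthand")
})

test_that("profiles cover every golden drug except the target", {
  ds <- toy_dataset()
  prof <- build_profiles(ds, "d1", similarity_config("JJJ"))
  expect_setequal(rownames(prof), c("d2", "d3", "d4"))
  expect_equal(prof["d2", "chemical"], 1)
  expect_equal(prof["d3", "chemical"], 0)
  expect_error(build_profiles(ds, "nosuch"), "unknown")
})

test_that("drugs absent from a source get undefined (NA) similarity there", {
  ds <- toy_dataset()
  ds$features$chemical <- feature_matrix(
    unclass(ds$features$chemical)[c("d1", "d2", "d3"), ],
    source_name = "chemical")  # d4 missing from the chemical source
  prof <- build_profiles(ds, "d1", similarity_config("JJJ"))
  expect_true(is.na(prof["d4", "chemical"]))
  expect_false(is.na(prof["d4", "side_effect"]))
})

test_that("planted clusters yield higher within- than between-cluster similarity", {
  spec <- generator_spec(n_drugs = 40, n_diseases = 40, n_clusters = 4,
                         features = c(chemical = 80, protein = 40,
                                      side_effect = 80),
                         signature_features = c(chemical = 8, protein = 1,
                                                side_effect = 6),
                         missingness = c(chemical = 0, protein = 0,
                                         side_effect = 0),
                         seed = 5)
  synth <- generate_dataset(spec)
  sm <- similarity_matrices(synth$dataset, similarity_config("JJJ"))
  cl <- synth$clusters
  same <- outer(cl, cl, "==") & !diag(length(cl))
  expect_gt(mean(sm$chemical[same]), mean(sm$chemical[!same & !diag(length(cl))]))
  expect_gt(mean(sm$side_effect[same]),
            mean(sm$side_effect[!same & !diag(length(cl))]))
})
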