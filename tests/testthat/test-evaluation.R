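test_that("precision/recall/F1 match their closed forms and conventions", {
  expect_equal(precision_recall_f1(confusion_counts(1, 1, 3, 7)),
               c(precision = 0.5, recall = 0.25, f1 = 1 / 3))
  expect_equal(precision_recall_f1(confusion_counts(0, 0, 2, 10, k = 4)),
               c(precision = 0, recall = 0, f1 = 0))
  expect_equal(precision_recall_f1(confusion_counts(3, 0, 0, 9)),
               c(precision = 1, recall = 1, f1 = 1))
  set.seed(3)
  for (i in 1:20) {
    cc <- confusion_counts(sample(1:5, 1), sample(0:5, 1), sample(0:5, 1), 10,
                           k = 10)
    m <- precision_recall_f1(cc)
    if (m["precision"] > 0 && m["recall"] > 0) {
      expect_gte(m[["f1"]], min(m[["precision"]], m[["recall"]]) - 1e-12)
      expect_lte(m[["f1"]], max(m[["precision"]], m[["recall"]]) + 1e-12)
    }
  }
})

test_that("specificity is the true-negative rate over the disease universe", {
  expect_equal(specificity(confusion_counts(0, 1, 0, 9, k = 1)), 0.9)
  expect_equal(specificity(confusion_counts(2, 0, 1, 5, k = 2)), 1)
  expect_error(specificity(confusion_counts(1, 0, 2, 0, k = 1)), "undefined")
  # toy 3-drug x 4-disease golden set, predictions for one target:
  # predicted {A, B}, truth {A, C} over universe of 4 diseases
  tp <- 1; fp <- 1; fn <- 1; tn <- 4 - tp - fp - fn
  expect_equal(tn, 1)
  expect_equal(specificity(confusion_counts(tp, fp, fn, tn, k = 2)), 0.5)
})

test_that("upper bounds behave analytically in both guessing modes", {
  set.seed(7)
  g <- golden_associations(
    matrix(rbinom(200, 1, 0.2), 20, 10,
           dimnames = list(sprintf("d%02d", 1:20), sprintf("x%02d", 1:10))))
  ub <- upper_bounds(g, c(1, 4, 8, 12, 16, 20), allow_guess = FALSE)
  expect_true(all(ub$precision == 1))
  kmax <- max(rowSums(g))
  expect_equal(ub$recall[ub$k >= kmax], rep(1, sum(ub$k >= kmax)))
  ubg <- upper_bounds(g, c(1, 4, 8, 12, 16, 20), allow_guess = TRUE)
  expect_true(all(ubg$precision <= 1))
  expect_equal(ubg$recall, ub$recall)

  # hand-enumerated toy: positives 1/2/5 per target, k = 2, with guessing
  toy <- golden_associations(rbind(
    d1 = c(1, 0, 0, 0, 0), d2 = c(1, 1, 0, 0, 0), d3 = c(1, 1, 1, 1, 1)),
    disease_ids = paste0("c", 1:5))
  tb <- upper_bounds(toy, 2, allow_guess = TRUE)
  expect_equal(tb$precision, mean(c(1 / 2, 1, 1)))
  expect_equal(tb$recall, mean(c(1, 1, 2 / 5)))
  expect_equal(tb$f1, mean(c(2 * 0.5 / 1.5, 1, 2 * 0.4 / 1.4)))
})

test_that("AUC-PR handles perfect, constant and tied rankings", {
  expect_equal(auc_pr(c(5, 4, 3, 2, 1), c(1, 1, 0, 0, 0)), 1)
  expect_equal(auc_pr(rep(1, 10), c(rep(1, 3), rep(0, 7))), 0.3)
  set.seed(13)
  for (i in 1:25) {
    n <- sample(5:20, 1)
    scores <- sample(1:6, n, replace = TRUE)
    labels <- rbinom(n, 1, 0.4)
    if (sum(labels) %in% c(0, n)) next
    expect_equal(auc_pr(scores, labels), oracle_auc_pr(scores, labels),
                 info = i)
  }
  expect_error(auc_pr(1:3, c(1, 1, 1)), "at least one positive and one negative")
})

test_that("AUC-ROC equals Mann-Whitney pair counting", {
  expect_equal(auc_roc(c(5, 4, 3, 2, 1), c(1, 1, 0, 0, 0)), 1)
  expect_equal(auc_roc(rep(2, 8), c(1, 0, 1, 0, 0, 0, 1, 0)), 0.5)
  set.seed(17)
  for (i in 1:25) {
    n <- sample(4:20, 1)
    scores <- sample(1:5, n, replace = TRUE)
    labels <- rbinom(n, 1, 0.5)
    if (sum(labels) %in% c(0, n)) next
    expect_equal(auc_roc(scores, labels), oracle_auc_roc(scores, labels),
                 info = i)
  }
})

test_that("leave-one-out recovers duplicated drugs perfectly", {
  ds <- toy_dataset()  # every drug has an identical twin
  rep <- leave_one_out(ds, similarity_config("JJJ"), mot = "ND", n = 1,
                       ist = "WSUM", k = 2)
  expect_equal(unname(rep$summary[c("precision", "recall", "f1")]),
               c(1, 1, 1))
})

test_that("a single-target run equals that target's row of the aggregate", {
  ds <- toy_dataset()
  all_rep <- leave_one_out(ds, similarity_config("JJJ"), mot = "ND", n = 1,
                           k = 2)
  one <- leave_one_out(ds, similarity_config("JJJ"), mot = "ND", n = 1,
                       k = 2, targets = "d3")
  expect_equal(one$per_target,
               all_rep$per_target[all_rep$per_target$target == "d3", ],
               ignore_attr = TRUE)
  expect_equal(unname(one$summary["precision"]), one$per_target$precision)
})

test_that("the withheld golden row is never consulted during prediction", {
  ds <- toy_dataset()
  corrupted <- ds
  g <- unclass(ds$golden)
  g["d1", ] <- 1L  # garbage in the target's own row
  corrupted$golden <- golden_associations(g)
  p0 <- predict_indications(ds, "d1", similarity_config("JJJ"), k = 4)
  p1 <- predict_indications(corrupted, "d1", similarity_config("JJJ"), k = 4)
  expect_identical(as.data.frame(p0), as.data.frame(p1))
})

test_that("targets without positives are skipped with a warning", {
  ds <- toy_dataset()
  g <- unclass(ds$golden)
  g["d4", ] <- 0L
  ds$golden <- golden_associations(g)
  expect_warning(rep <- leave_one_out(ds, similarity_config("JJJ"),
                                      targets = c("d1", "d4"), n = 1, k = 2),
                 "skipping")
  expect_identical(rep$per_target$target, "d1")
})

test_that("method metrics never exceed the no-guess upper bound", {
  spec <- generator_spec(n_drugs = 40, n_diseases = 40, n_clusters = 4,
                         features = c(chemical = 80, side_effect = 80),
                         signature_features = c(chemical = 8, side_effect = 6),
                         within_prob = c(chemical = 0.85, side_effect = 0.85),
                         background_prob = c(chemical = 0.05,
                                             side_effect = 0.02),
                         missingness = c(chemical = 0.1, side_effect = 0.1),
                         seed = 19)
  ds <- generate_dataset(spec)$dataset
  cfg <- similarity_config(c(chemical = "jaccard", side_effect = "jaccard"))
  for (k in c(1, 4)) {
    rep <- leave_one_out(ds, cfg, mot = "ND", n = 4, k = k)
    ub <- upper_bounds(ds$golden, k, allow_guess = FALSE)
    expect_lte(rep$summary[["precision"]], ub$precision + 1e-12)
    expect_lte(rep$summary[["recall"]], ub$recall + 1e-12)
    expect_lte(rep$summary[["f1"]], ub$f1 + 1e-12)
  }
})

test_that("pooled AUC pooling mode returns a single pooled ranking value", {
  ds <- toy_dataset()
  rep <- leave_one_out(ds, similarity_config("JJJ"), mot = "ND", n = 1, k = 2,
                       auc_pooling = "pooled")
  expect_true(rep$summary[["auc_pr"]] >= 0 && rep$summary[["auc_pr"]] <= 1)
  expect_true(is.na(rep$per_target$auc_pr[1]))
})
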