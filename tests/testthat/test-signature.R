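test_that("featurize produces ternary tables and honours variance provenance", {
  X <- toy_matrix(6, 5, seed = 2)
  pairs <- data.frame(gene_a = c("g1", "g3"), gene_b = c("g2", "g5"))
  f <- featurize(X, pairs, a = 1)
  expect_identical(dim(f), c(5L, 2L))
  expect_true(all(f %in% c(-1L, 0L, 1L)))
  expect_identical(colnames(f), c("g1|g2", "g3|g5"))

  # frozen vs per-cohort stats coincide on an affine batch-shifted copy
  Y <- expression_matrix(2.5 * unclass(X) + 7, "shifted")
  st <- gene_stddev(X)
  f_frozen <- featurize(X, pairs, a = 1, stats_mode = "frozen",
                        gene_stats = st)
  f_per <- featurize(Y, pairs, a = 1)
  expect_identical(unname(f_frozen), unname(f_per))

  expect_error(featurize(X, data.frame(gene_a = "nope", gene_b = "g1"),
                         a = 1), "nope")
})

test_that("fitting is deterministic and separates a separable fixture", {
  fx <- separable_features(n = 30, k = 3)
  sig <- fit_signature(fx$features, fx$labels, method = "rf", a = 2,
                       seed = 0, cv = FALSE)
  prob <- predict_proba(sig, fx$features)
  expect_equal(auc(prob[, "R"], fx$labels), 1)
  expect_equal(unname(rowSums(prob)), rep(1, nrow(prob)), tolerance = 1e-12)

  sig2 <- fit_signature(fx$features, fx$labels, method = "rf", a = 2,
                        seed = 0, cv = FALSE)
  expect_identical(predict_proba(sig2, fx$features), prob)

  one_class <- label_map(setNames(rep("R", 4), paste0("s0", 1:4)),
                         c("R", "NR"))
  expect_error(fit_signature(fx$features[1:4, ], one_class),
               "single class")
})

test_that("every classifier kind trains and predicts valid probabilities", {
  fx <- separable_features(n = 30, k = 3)
  for (method in c("rf", "lr", "svm", "knn", "nb", "mlp", "xgb")) {
    sig <- fit_signature(fx$features, fx$labels, method = method, a = 0,
                         seed = 3, cv = FALSE)
    prob <- predict_proba(sig, fx$features)
    expect_identical(colnames(prob), c("R", "NR"))
    expect_equal(unname(rowSums(prob)), rep(1, nrow(prob)),
                 tolerance = 1e-12)
    expect_gte(auc(prob[, "R"], fx$labels), 0.9)
  }
})

test_that("prediction aligns feature columns by pair name", {
  fx <- separable_features(n = 20, k = 4)
  sig <- fit_signature(fx$features, fx$labels, seed = 1, cv = FALSE)
  shuffled <- fx$features[, c(3, 1, 4, 2)]
  expect_identical(predict_proba(sig, shuffled),
                   predict_proba(sig, fx$features))
  expect_error(predict_proba(sig, fx$features[, 1:2]), "lacks signature")
})

test_that("zero-importance pruning filters and refits correctly", {
  # 3 informative pairs + constant (never used) pairs
  fx <- separable_features(n = 40, k = 3)
  noise <- matrix(0L, nrow(fx$features), 2,
                  dimnames = list(rownames(fx$features),
                                  c("nA1|nB1", "nA2|nB2")))
  feats <- cbind(fx$features, noise)
  sig <- fit_signature(feats, fx$labels, method = "rf", a = 2, seed = 0,
                       cv = FALSE)
  expect_true(any(sig$pairs$importance == 0))
  pruned <- prune_zero_importance(sig, feats, fx$labels)
  expect_lt(nrow(pruned$pairs), nrow(sig$pairs))
  expect_true(all(pruned$pairs$importance > 0))
  expect_false(any(grepl("^n", pruned$pairs$gene_a)))

  # all-positive importances leave the pair set unchanged
  sig_pos <- fit_signature(fx$features, fx$labels, method = "rf", seed = 0,
                           cv = FALSE)
  if (all(sig_pos$pairs$importance > 0)) {
    expect_identical(prune_zero_importance(sig_pos, fx$features,
                                           fx$labels)$pairs$gene_a,
                     sig_pos$pairs$gene_a)
  }
  expect_error(prune_zero_importance(
    fit_signature(feats, fx$labels, method = "lr", cv = FALSE),
    feats, fx$labels), "random-forest")
})

test_that("pruning on a noisy synthetic signature keeps informative pairs", {
  spec <- synthetic_spec(m = 60, n = 120, k = 10, delta = 3)
  cos <- generate_cohorts(spec, 2, seed = 0)
  train <- cos[[1]]
  scr <- screen_cohort(train$X, train$labels, a = 0)
  top <- select_top(scr, 50)
  sig <- train_signature(train$X, train$labels, top, a = 0, seed = 0,
                         cv = FALSE)
  pruned <- prune_zero_importance(
    sig, featurize(train$X, sig$pairs, 0), train$labels)
  expect_lt(nrow(pruned$pairs), 50)

  # held-out AUC of the pruned signature stays within 0.05 of unpruned
  test_co <- cos[[2]]
  auc_full <- auc(predict_cohort(sig, test_co$X)[, "class1"],
                  test_co$labels)
  auc_pruned <- auc(predict_cohort(pruned, test_co$X)[, "class1"],
                    test_co$labels)
  expect_gte(auc_pruned, auc_full - 0.05)
})

test_that("coefficient tuning picks from the grid deterministically", {
  spec <- synthetic_spec(m = 40, n = 60, k = 5, delta = 3)
  cos <- generate_cohorts(spec, 3, seed = 1)
  labels <- label_map(
    unlist(lapply(cos, function(co) setNames(as.character(co$labels),
                                             names(co$labels)))),
    levels(cos[[1]]$labels))
  cs <- intersect_genes(setNames(lapply(cos, `[[`, "X"),
                                 c("d", "t", "v")),
                        roles = c(d = "discovery", t = "training",
                                  v = "test"))
  single <- tune_coefficient(cs, labels, grid = 0, x = 10, seed = 1,
                             cv = FALSE)
  expect_equal(single$best_a, 0)
  dup <- tune_coefficient(cs, labels, grid = c(0, 0, 0), x = 10, seed = 1,
                          cv = FALSE)
  expect_equal(dup$best_a, single$best_a)
  expect_equal(nrow(dup$table), 1)

  no_val <- intersect_genes(setNames(lapply(cos[1:2], `[[`, "X"),
                                     c("d", "t")),
                            roles = c(d = "discovery", t = "training"))
  expect_error(tune_coefficient(no_val, labels, grid = 0, x = 5),
               "test")
})
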