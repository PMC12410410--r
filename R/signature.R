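#' Featurize a cohort on a fixed set of gene pairs
#'
#' Applies the ternary adaptive coding to the selected pairs only, returning
#' a samples x pairs feature table (entries in -1/0/+1, columns named
#' `"geneA|geneB"`). Variance provenance: with `stats_mode = "per-cohort"`
#' (default) the per-gene standard deviations are recomputed on `X`; with
#' `"frozen"` the supplied `gene_stats` (typically stored in a trained
#' signature) are reused, which supports single-sample deployment.
#'
#' @param X Expression matrix containing every gene referenced by `pairs`.
#' @param pairs Two-column data.frame (`gene_a`, `gene_b`), e.g. from
#'   [select_top()] or a signature's `pairs`.
#' @param a Non-negative adaptive coefficient.
#' @param stats_mode `"per-cohort"` or `"frozen"`.
#' @param gene_stats `gene_stats` object required when `stats_mode =
#'   "frozen"`.
#' @return Integer matrix samples x pairs.
#' @export
featurize <- function(X, pairs, a, stats_mode = c("per-cohort", "frozen"),
                      gene_stats = NULL) {
  stats_mode <- match.arg(stats_mode)
  need <- unique(c(pairs$gene_a, pairs$gene_b))
  missing <- setdiff(need, rownames(X))
  if (length(missing) > 0L) {
    stop("gene(s) absent from cohort '", cohort_name(X), "': ",
         paste(missing, collapse = ", "), call. = FALSE)
  }
  stats <- if (stats_mode == "frozen") {
    if (is.null(gene_stats)) {
      stop("frozen stats_mode requires gene_stats", call. = FALSE)
    }
    gene_stats
  } else {
    gene_stddev(X)
  }
  P <- build_pair_matrix(X, a, stats = stats,
                         pairs = cbind(pairs$gene_a, pairs$gene_b))
  t(P$values)
}

pairs_from_features <- function(features) {
  sp <- strsplit(colnames(features), "|", fixed = TRUE)
  data.frame(gene_a = vapply(sp, `[`, "", 1L),
             gene_b = vapply(sp, `[`, "", 2L),
             stringsAsFactors = FALSE)
}

#' Fit a gene-pair signature classifier
#'
#' Trains the discriminative model on a ternary feature table. The default
#' model is a random forest; hyperparameters are chosen by 3-fold
#' cross-validation within a small documented grid (random forest: 100 or
#' 500 trees, unlimited or depth-8 trees), selected on pooled out-of-fold
#' AUC (binary) or accuracy (multiclass). With `cv = FALSE` (appropriate
#' when samples are plentiful) the grid's default entry is used directly.
#' Fits are deterministic given `(features, labels, seed)`.
#'
#' @param features Samples x pairs ternary matrix (see [featurize()]),
#'   rownames = sample IDs.
#' @param labels Named factor of class labels.
#' @param method One of `"rf"`, `"knn"`, `"lr"`, `"svm"`, `"mlp"`, `"xgb"`,
#'   `"nb"`.
#' @param a Adaptive coefficient the features were coded with (stored for
#'   deployment).
#' @param seed Integer seed controlling every stochastic component.
#' @param cv Use cross-validated hyperparameter selection?
#' @param cv_folds Number of CV folds (default 3).
#' @param gene_stats Optional training-cohort `gene_stats` stored for frozen
#'   featurization at deployment.
#' @param pair_info Optional screening info (`p_value`, `direction`) to carry
#'   in the signature's pair table.
#' @return Object of class `aigps_signature`.
#' @export
fit_signature <- function(features, labels, method = "rf", a = NA_real_,
                          seed = 1L, cv = TRUE, cv_folds = 3L,
                          gene_stats = NULL, pair_info = NULL) {
  if (is.null(rownames(features))) {
    stop("feature table needs sample rownames", call. = FALSE)
  }
  missing <- setdiff(rownames(features), names(labels))
  if (length(missing) > 0L) {
    stop("unlabeled sample(s): ", paste(missing, collapse = ", "),
         call. = FALSE)
  }
  y <- droplevels(labels[rownames(features)])
  fit <- fit_classifier(features, y, method, seed, cv, cv_folds)
  pairs <- pairs_from_features(features)
  pairs$direction <- NA_integer_
  pairs$p_value <- NA_real_
  if (!is.null(pair_info)) {
    key <- paste(pair_info$gene_a, pair_info$gene_b, sep = "|")
    hit <- match(paste(pairs$gene_a, pairs$gene_b, sep = "|"), key)
    pairs$direction <- pair_info$direction[hit]
    pairs$p_value <- pair_info$p_value[hit]
  }
  imp <- classifier_importance(fit)
  pairs$importance <- if (is.null(imp)) NA_real_ else unname(imp)
  structure(list(pairs = pairs, coefficient_a = a, method = method,
                 fit = fit, class_order = levels(y), seed = seed,
                 cv = cv, cv_folds = cv_folds, gene_stats = gene_stats),
            class = "aigps_signature")
}

#' @export
print.aigps_signature <- function(x, ...) {
  cat("aigps_signature:", nrow(x$pairs), "pairs |", x$method,
      "| a =", x$coefficient_a, "| classes:",
      paste(x$class_order, collapse = ", "), "\n")
  invisible(x)
}

#' Train a signature end-to-end on a cohort
#'
#' Convenience wrapper: featurizes the training cohort on the selected
#' pairs, fits the classifier, records training-cohort gene statistics for
#' frozen deployment, and optionally prunes zero-importance pairs.
#'
#' @param X Training expression matrix.
#' @param labels Named factor of class labels.
#' @param pairs Selected pairs (e.g. [select_top()] output); screening
#'   columns `p_value`/`direction`, when present, are carried along.
#' @param a Adaptive coefficient.
#' @inheritParams fit_signature
#' @param prune Remove zero-importance pairs and refit (random forest only)?
#' @return An `aigps_signature`.
#' @export
train_signature <- function(X, labels, pairs, a, method = "rf", seed = 1L,
                            cv = TRUE, cv_folds = 3L, prune = FALSE) {
  features <- featurize(X, pairs, a)
  gs <- gene_stddev(X)
  keep <- unique(c(pairs$gene_a, pairs$gene_b))
  gs$sd <- gs$sd[keep]
  pair_info <- if (all(c("p_value", "direction") %in% names(pairs))) pairs
               else NULL
  sig <- fit_signature(features, labels, method = method, a = a, seed = seed,
                       cv = cv, cv_folds = cv_folds, gene_stats = gs,
                       pair_info = pair_info)
  if (prune) sig <- prune_zero_importance(sig, features, labels)
  sig
}

#' Remove zero-importance pairs from a random-forest signature
#'
#' Drops every pair whose random-forest impurity importance is exactly 0 and
#' refits the model on the reduced pair set with the same seed and settings.
#' If the refit introduces new zero-importance pairs, pruning is applied once
#' more (at most two rounds). Pruning never increases the pair count.
#'
#' @param sig An `aigps_signature` with `method = "rf"`.
#' @param features The training feature table the signature was fitted on.
#' @param labels Named factor of training labels.
#' @return The pruned (refitted) signature.
#' @export
prune_zero_importance <- function(sig, features, labels) {
  if (sig$method != "rf") {
    stop("zero-importance pruning requires a random-forest signature",
         call. = FALSE)
  }
  for (round in 1:2) {
    imp <- sig$pairs$importance
    if (all(imp == 0)) stop("all pair importances are zero", call. = FALSE)
    keep <- imp > 0
    if (all(keep)) break
    features <- features[, keep, drop = FALSE]
    pair_info <- sig$pairs[keep, , drop = FALSE]
    sig <- fit_signature(features, labels, method = sig$method,
                         a = sig$coefficient_a, seed = sig$seed,
                         cv = sig$cv, cv_folds = sig$cv_folds,
                         gene_stats = sig$gene_stats, pair_info = pair_info)
  }
  sig
}

#' Predict class probabilities from a signature
#'
#' Columns of `features` are aligned to the signature's pairs by name, so a
#' permuted feature table yields identical output. Probability rows sum to 1.
#'
#' @param sig An `aigps_signature`.
#' @param features Samples x pairs ternary matrix whose columns cover the
#'   signature's pairs.
#' @return Numeric matrix samples x classes.
#' @export
predict_proba <- function(sig, features) {
  want <- paste(sig$pairs$gene_a, sig$pairs$gene_b, sep = "|")
  missing <- setdiff(want, colnames(features))
  if (length(missing) > 0L) {
    stop("feature table lacks signature pair(s): ",
         paste(missing, collapse = ", "), call. = FALSE)
  }
  predict_one(sig$fit, features[, want, drop = FALSE])
}

#' Featurize and predict a cohort in one step
#'
#' @param sig An `aigps_signature`.
#' @param X Expression matrix containing the signature's genes.
#' @param stats_mode Variance provenance for featurization: recompute on `X`
#'   (`"per-cohort"`, default) or reuse the signature's stored training
#'   statistics (`"frozen"`).
#' @return Numeric matrix samples x classes.
#' @export
predict_cohort <- function(sig, X, stats_mode = c("per-cohort", "frozen")) {
  stats_mode <- match.arg(stats_mode)
  features <- featurize(X, sig$pairs, sig$coefficient_a,
                        stats_mode = stats_mode, gene_stats = sig$gene_stats)
  predict_proba(sig, features)
}

#' Grid-search the adaptive coefficient
#'
#' For every candidate `a` in the grid (default 0 to 5 in 0.5 steps, the
#' duplicate-free grid is used), pairs are screened on the discovery
#' cohort(s), the top `x` pairs are used to train the classifier on the
#' training cohort(s), and the signature is evaluated on every test cohort
#' (AUC for two classes, accuracy otherwise). The winning coefficient
#' maximizes the median score across test cohorts, with ties broken by lower
#' score variance and then by smaller `a`.
#'
#' @param cohorts A `cohort_set` with roles assigned (needs at least one
#'   discovery, one training and one test cohort).
#' @param labels Named factor covering all samples of all cohorts.
#' @param grid Candidate coefficients.
#' @param x Number of top pairs to carry into training.
#' @param method Classifier kind.
#' @param seed Seed.
#' @param cv Cross-validated hyperparameter selection during training?
#' @return List with `best_a` and `table` (one row per coefficient: median
#'   and variance of the per-cohort scores, plus each cohort's score).
#' @export
tune_coefficient <- function(cohorts, labels, grid = seq(0, 5, by = 0.5),
                             x = 50L, method = "rf", seed = 1L, cv = TRUE) {
  stopifnot(inherits(cohorts, "cohort_set"))
  if (length(grid) == 0L) stop("empty coefficient grid", call. = FALSE)
  grid <- sort(unique(grid))
  roles <- cohorts$roles
  if (is.null(roles)) stop("cohort roles must be assigned", call. = FALSE)
  disc <- names(roles)[roles == "discovery"]
  trn <- names(roles)[roles == "training"]
  tst <- names(roles)[roles == "test"]
  if (length(disc) == 0L) stop("no discovery cohort", call. = FALSE)
  if (length(trn) == 0L) stop("no training cohort", call. = FALSE)
  if (length(tst) == 0L) stop("no test (validation) cohort", call. = FALSE)
  bind <- function(nms) {
    do.call(cbind, unname(cohorts$cohorts[nms]))
  }
  Xd <- bind(disc); Xt <- bind(trn)
  rows <- lapply(grid, function(a) {
    scr <- screen_cohort(Xd, labels, a)
    top <- select_top(scr, x)
    sig <- train_signature(Xt, labels, top, a, method = method, seed = seed,
                           cv = cv)
    scores <- vapply(tst, function(nm) {
      Xv <- cohorts$cohorts[[nm]]
      prob <- predict_cohort(sig, Xv)
      yv <- droplevels(labels[colnames(Xv)])
      if (nlevels(yv) == 2L) {
        auc(prob[, levels(yv)[1L]], yv)
      } else {
        pred <- colnames(prob)[max.col(prob, ties.method = "first")]
        mean(pred == as.character(yv))
      }
    }, numeric(1L))
    c(a = a, median = stats::median(scores),
      variance = if (length(scores) > 1L) stats::var(scores) else 0,
      scores)
  })
  tab <- as.data.frame(do.call(rbind, rows))
  ord <- order(-tab$median, tab$variance, tab$a)
  list(best_a = tab$a[ord[1L]], table = tab)
}
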