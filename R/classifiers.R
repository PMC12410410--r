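# Internal classifier layer: uniform fit/predict over the supported model
# kinds, each delegated to its established implementation (ranger, e1071,
# nnet, class, xgboost, stats::glm). All randomness is controlled by a single
# seed so fits are reproducible.

classifier_grid <- function(method) {
  switch(method,
    rf  = expand.grid(num_trees = c(100L, 500L), max_depth = c(0L, 8L)),
    knn = data.frame(k = c(3L, 5L, 11L)),
    svm = data.frame(cost = c(0.1, 1, 10)),
    lr  = data.frame(.default = TRUE),
    nb  = data.frame(laplace = c(0, 1)),
    mlp = data.frame(size = c(4L, 8L)),
    xgb = data.frame(nrounds = c(50L, 200L)),
    stop("unknown classifier kind: ", method, call. = FALSE))
}

classifier_default <- function(method) classifier_grid(method)[1L, , drop = FALSE]

fit_one <- function(x, y, method, params, seed) {
  df <- as.data.frame(x)
  model <- switch(method,
    rf = ranger::ranger(x = df, y = y, probability = TRUE,
                        num.trees = params$num_trees,
                        max.depth = params$max_depth,
                        importance = "impurity",
                        seed = seed, num.threads = 1L),
    lr = {
      set.seed(seed)
      if (nlevels(y) == 2L) {
        stats::glm(y ~ ., data = cbind(df, y = y), family = stats::binomial())
      } else {
        nnet::multinom(y ~ ., data = cbind(df, y = y), trace = FALSE,
                       maxit = 300L)
      }
    },
    svm = {
      set.seed(seed)
      e1071::svm(x = as.matrix(x), y = y, probability = TRUE,
                 cost = params$cost, kernel = "radial")
    },
    knn = list(train_x = as.matrix(x), train_y = y, k = params$k),
    nb = e1071::naiveBayes(x = df, y = y, laplace = params$laplace),
    mlp = {
      set.seed(seed)
      nnet::nnet(y ~ ., data = cbind(df, y = y), size = params$size,
                 decay = 0.01, maxit = 300L, trace = FALSE, MaxNWts = 10000L)
    },
    xgb = {
      lab <- as.integer(y) - 1L
      obj <- if (nlevels(y) == 2L) "binary:logistic" else "multi:softprob"
      pars <- list(objective = obj, nthread = 1L, seed = seed,
                   max_depth = 4L, eta = 0.1)
      if (nlevels(y) > 2L) pars$num_class <- nlevels(y)
      dtrain <- xgboost::xgb.DMatrix(as.matrix(x), label = lab)
      xgboost::xgb.train(params = pars, data = dtrain,
                         nrounds = params$nrounds, verbose = 0L)
    })
  list(model = model, method = method, params = params,
       levels = levels(y), seed = seed,
       feature_names = colnames(x))
}

predict_one <- function(fit, x) {
  x <- as.matrix(x)
  lev <- fit$levels
  prob <- switch(fit$method,
    rf = {
      p <- stats::predict(fit$model, data = as.data.frame(x))$predictions
      p[, lev, drop = FALSE]
    },
    lr = {
      if (length(lev) == 2L) {
        p2 <- stats::predict(fit$model, newdata = as.data.frame(x),
                             type = "response")
        cbind(1 - p2, p2)
      } else {
        p <- stats::predict(fit$model, newdata = as.data.frame(x),
                            type = "probs")
        if (is.null(dim(p))) p <- matrix(p, nrow = nrow(x),
                                         dimnames = list(NULL, lev[-1L]))
        p[, lev, drop = FALSE]
      }
    },
    svm = {
      pr <- stats::predict(fit$model, x, probability = TRUE)
      attr(pr, "probabilities")[, lev, drop = FALSE]
    },
    knn = knn_proba(fit$model, x),
    nb = stats::predict(fit$model, as.data.frame(x), type = "raw")[, lev,
                                                                   drop = FALSE],
    mlp = {
      p <- stats::predict(fit$model, as.data.frame(x), type = "raw")
      if (ncol(p) == 1L) cbind(1 - p[, 1L], p[, 1L]) else p[, lev, drop = FALSE]
    },
    xgb = {
      p <- stats::predict(fit$model, xgboost::xgb.DMatrix(x))
      if (length(lev) == 2L) cbind(1 - p, p)
      else if (is.matrix(p)) p
      else matrix(p, ncol = length(lev), byrow = TRUE)
    })
  prob <- matrix(as.numeric(prob), nrow = nrow(x),
                 dimnames = list(rownames(x), lev))
  prob / rowSums(prob)
}

knn_proba <- function(model, x) {
  # deterministic k-NN vote fractions (Euclidean); ties at the k-th distance
  # are resolved by training-sample order
  tr <- model$train_x; k <- model$k
  lev <- levels(model$train_y)
  out <- matrix(0, nrow(x), length(lev), dimnames = list(NULL, lev))
  for (s in seq_len(nrow(x))) {
    d <- sqrt(colSums((t(tr) - x[s, ])^2))
    nn <- order(d)[seq_len(min(k, length(d)))]
    votes <- table(factor(model$train_y[nn], levels = lev))
    out[s, ] <- as.numeric(votes) / sum(votes)
  }
  out
}

cv_score <- function(x, y, method, params, seed, folds) {
  set.seed(seed)
  fold <- sample(rep_len(seq_len(folds), length(y)))
  pooled <- matrix(NA_real_, length(y), nlevels(y),
                   dimnames = list(NULL, levels(y)))
  for (f in seq_len(folds)) {
    tr <- fold != f
    if (nlevels(droplevels(y[tr])) < nlevels(y)) return(NA_real_)
    fit <- fit_one(x[tr, , drop = FALSE], y[tr], method, params, seed + f)
    pooled[!tr, ] <- predict_one(fit, x[!tr, , drop = FALSE])
  }
  if (nlevels(y) == 2L) {
    auc(pooled[, levels(y)[1L]], y)
  } else {
    mean(levels(y)[max.col(pooled, ties.method = "first")] == as.character(y))
  }
}

fit_classifier <- function(x, y, method, seed, cv = TRUE, cv_folds = 3L) {
  y <- droplevels(y)
  if (nlevels(y) < 2L) stop("labels contain a single class", call. = FALSE)
  if (nrow(x) == 0L || ncol(x) == 0L) stop("empty feature table", call. = FALSE)
  grid <- classifier_grid(method)
  chosen <- grid[1L, , drop = FALSE]
  if (cv && nrow(grid) > 1L) {
    scores <- vapply(seq_len(nrow(grid)), function(g) {
      cv_score(x, y, method, grid[g, , drop = FALSE], seed, cv_folds)
    }, numeric(1L))
    if (!all(is.na(scores))) {
      chosen <- grid[which.max(scores), , drop = FALSE]
    }
  }
  fit <- fit_one(x, y, method, chosen, seed)
  fit$cv <- cv
  fit$cv_folds <- cv_folds
  fit
}

classifier_importance <- function(fit) {
  if (fit$method != "rf") return(NULL)
  imp <- fit$model$variable.importance
  imp[fit$feature_names]
}
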