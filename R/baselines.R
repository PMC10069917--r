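## Regressor comparison harness: 5-fold cross-validated fits of standard
## models (linear regression, decision tree, random forest, SVM, Gaussian
## process) and the shallow ANN on the reference database, across the 3 /
## 5 / 8 input feature subsets, reported as R2 and RMSE per model.

BASELINE_MODELS <- c("lr", "dt", "rf", "svm", "gpr", "ann")

fit_predict_one <- function(model, Xtr, ytr, Xte, hidden_units = 20L) {
  tr <- as.data.frame(Xtr); tr$y <- ytr
  te <- as.data.frame(Xte)
  switch(model,
    lr = {
      fit <- stats::lm(y ~ ., data = tr)
      predict(fit, te)
    },
    dt = {
      fit <- rpart::rpart(y ~ ., data = tr,
                          control = rpart::rpart.control(cp = 1e-4, xval = 0))
      predict(fit, te)
    },
    rf = {
      fit <- randomForest::randomForest(Xtr, ytr, ntree = 100)
      predict(fit, Xte)
    },
    svm = {
      fit <- e1071::svm(Xtr, ytr, kernel = "radial", scale = TRUE)
      predict(fit, Xte)
    },
    gpr = {
      fit <- kernlab::gausspr(Xtr, ytr, kernel = "rbfdot", variance.model = FALSE)
      as.vector(kernlab::predict(fit, Xte))
    },
    ann = {
      nw <- (ncol(Xtr) + 1) * hidden_units + (hidden_units + 1)
      fit <- nnet::nnet(Xtr, ytr, size = hidden_units, linout = TRUE,
                        trace = FALSE, maxit = 300, MaxNWts = nw + 10)
      as.vector(predict(fit, Xte))
    },
    stopf("unknown baseline model: %s", model))
}

#' Cross-validated comparison of baseline regressors on a reference db
#'
#' For each model and each feature subset (3, 5, 8 inputs), fits the model
#' to predict the min-max normalized band-mean DN with 5-fold
#' cross-validation and reports pooled out-of-fold R2 and RMSE.
#' Deterministic given the seed. The heavier models see at most `max_rows`
#' subsampled rows.
#'
#' @param db an 8-feature [build_reference_db()] database
#' @param models subset of lr, dt, rf, svm, gpr, ann
#' @param feature_sets input subsets to compare (default 3, 5, 8)
#' @param folds cross-validation folds (default 5)
#' @param seed RNG seed
#' @param max_rows row cap (subsampled once, shared by all models)
#' @return data.frame: model, feature_set, r2, rmse
#' @export
fit_baseline_regressors <- function(db, models = BASELINE_MODELS,
                                    feature_sets = c(3L, 5L, 8L),
                                    folds = 5L, seed = 1L, max_rows = 2000L) {
  if (db$feature_set != 8L)
    stopf("feature-set comparison needs the 8-feature database")
  bad <- setdiff(models, BASELINE_MODELS)
  if (length(bad)) stopf("unknown model(s): %s", paste(bad, collapse = ", "))
  Xall <- normalize_features(db, db$features)
  y <- rowMeans(db$dn)
  y <- (y - min(y)) / max(max(y) - min(y), 1e-12)
  res <- with_seed(seed, {
    idx <- if (nrow(Xall) > max_rows) sample.int(nrow(Xall), max_rows)
           else seq_len(nrow(Xall))
    Xs <- Xall[idx, , drop = FALSE]; ys <- y[idx]
    fold <- sample(rep(seq_len(folds), length.out = length(ys)))
    rows <- list()
    for (fs in feature_sets) {
      cols <- match(c("d_i", "d_v", "theta_i", "theta_v", "theta",
                      "x", "y", "z")[feature_subset_cols(fs)], db$channels)
      Xf <- Xs[, cols, drop = FALSE]
      for (mdl in models) {
        pred <- rep(NA_real_, length(ys))
        ok <- TRUE
        for (f in seq_len(folds)) {
          tr <- fold != f; te <- fold == f
          p <- tryCatch(
            fit_predict_one(mdl, Xf[tr, , drop = FALSE], ys[tr],
                            Xf[te, , drop = FALSE]),
            error = function(e) NULL)
          if (is.null(p)) { ok <- FALSE; break }
          pred[te] <- p
        }
        if (!ok) {
          warning(sprintf("model '%s' unavailable/failed; skipped", mdl))
          next
        }
        m <- regression_metrics(pred, ys)
        rows[[length(rows) + 1]] <- data.frame(
          model = mdl, feature_set = fs, r2 = m$r2, rmse = m$rmse)
      }
    }
    do.call(rbind, rows)
  })
  rownames(res) <- NULL
  res
}
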