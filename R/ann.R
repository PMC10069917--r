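## Shallow neural network mapping light-field features to reference DN
## spectra: F inputs -> 20 sigmoid hidden units -> B linear outputs,
## trained on min-max normalized inputs and outputs with a 70/15/15
## train/validation/test split and selection of the training stage with
## the best validation MSE (nnet's BFGS optimizer, warm-restarted in
## stages so validation can be monitored).

#' Train the reference reflectance ANN
#'
#' @param db a [build_reference_db()] database (N >= 100)
#' @param hidden_units hidden layer size (default 20)
#' @param split train/validation/test fractions (default 0.70/0.15/0.15);
#'   validation and test must be nonempty
#' @param epochs total optimizer iterations, spent in `stages` equal
#'   chunks with validation checks between chunks
#' @param stages number of validation checkpoints
#' @param decay optional L2 weight decay of the optimizer (default 0; the
#'   500-iteration budget itself acts as the regularizer — the validation
#'   split only sees reference-surface features, so it cannot guard
#'   against off-manifold oscillation that longer optimization induces)
#' @param seed RNG seed (split + weight init); same seed, same model
#' @param split_mode "pixel" (random over rows) or "frame" (whole frames
#'   held out, the honest generalization split)
#' @param max_rows optional row subsample cap (training cost control)
#' @return object of class `reflectance_model` with weights, normalization
#'   stats and a training report (split sizes, per-stage validation MSE,
#'   test R2/RMSE)
#' @export
train_ann <- function(db, hidden_units = 20L, split = c(0.70, 0.15, 0.15),
                      epochs = 500L, stages = 10L, decay = 0, seed = 1L,
                      split_mode = c("pixel", "frame"), max_rows = 60000L) {
  split_mode <- match.arg(split_mode)
  if (length(split) != 3 || any(split < 0) || !isTRUE(all.equal(sum(split), 1)))
    stopf("split must be three nonnegative fractions summing to 1")
  if (split[2] <= 0 || split[3] <= 0)
    stopf("validation and test sets must be nonempty")
  N <- nrow(db$features)
  if (N < 100) stopf("at least 100 reference rows are required, got %d", N)
  X <- normalize_features(db, db$features)
  Y <- db$dn
  ymin <- apply(Y, 2, min); ymax <- apply(Y, 2, max)
  yrng <- pmax(ymax - ymin, 1e-12)
  Yn <- sweep(sweep(Y, 2, ymin), 2, yrng, "/")
  out <- with_seed(seed, {
    idx <- seq_len(N)
    if (!is.null(max_rows) && N > max_rows) idx <- sort(sample.int(N, max_rows))
    if (split_mode == "pixel") {
      sh <- sample(idx)
      n_tr <- round(split[1] * length(sh)); n_va <- round(split[2] * length(sh))
      tr <- sh[seq_len(n_tr)]
      va <- sh[n_tr + seq_len(n_va)]
      te <- sh[(n_tr + n_va + 1):length(sh)]
    } else {
      fr <- db$frame[idx]
      uf <- sample(unique(fr))
      n_tr <- max(1, round(split[1] * length(uf)))
      n_va <- max(1, round(split[2] * length(uf)))
      tr <- idx[fr %in% uf[seq_len(n_tr)]]
      va <- idx[fr %in% uf[n_tr + seq_len(n_va)]]
      te <- idx[fr %in% uf[(n_tr + n_va + 1):length(uf)]]
      if (!length(va) || !length(te)) stopf("frame split left an empty set")
    }
    per_stage <- max(10L, ceiling(epochs / stages))
    nw <- (ncol(X) + 1) * hidden_units + (hidden_units + 1) * ncol(Yn)
    wts <- NULL; best <- NULL; val_trace <- numeric(0)
    for (st in seq_len(stages)) {
      fit <- if (is.null(wts)) {
        nnet::nnet(X[tr, , drop = FALSE], Yn[tr, , drop = FALSE],
                   size = hidden_units, linout = TRUE, trace = FALSE,
                   maxit = per_stage, MaxNWts = nw + 10, rang = 0.5,
                   decay = decay)
      } else {
        nnet::nnet(X[tr, , drop = FALSE], Yn[tr, , drop = FALSE],
                   size = hidden_units, linout = TRUE, trace = FALSE,
                   maxit = per_stage, MaxNWts = nw + 10, Wts = wts,
                   decay = decay)
      }
      if (!all(is.finite(fit$wts))) stopf("ANN training diverged (non-finite loss)")
      wts <- fit$wts
      pv <- predict(fit, X[va, , drop = FALSE])
      vmse <- mean((pv - Yn[va, , drop = FALSE])^2)
      val_trace <- c(val_trace, vmse)
      if (is.null(best) || vmse < best$vmse) best <- list(fit = fit, vmse = vmse)
    }
    pt <- predict(best$fit, X[te, , drop = FALSE])
    test_metrics <- regression_metrics(as.vector(pt), as.vector(Yn[te, , drop = FALSE]))
    list(fit = best$fit, val_trace = val_trace,
         report = list(n_train = length(tr), n_val = length(va),
                       n_test = length(te), val_mse = best$vmse,
                       test_r2 = test_metrics$r2, test_rmse = test_metrics$rmse))
  })
  structure(list(net = out$fit, hidden_units = as.integer(hidden_units),
                 feature_set = db$feature_set, channels = db$channels,
                 fmin = db$fmin, fmax = db$fmax,
                 ymin = ymin, yrng = yrng,
                 val_trace = out$val_trace, report = out$report),
            class = "reflectance_model")
}

#' @export
print.reflectance_model <- function(x, ...) {
  cat(sprintf("<reflectance_model %d-%d-%d, test R2 %.3f RMSE %.4f>\n",
              length(x$fmin), x$hidden_units, length(x$ymin),
              x$report$test_r2, x$report$test_rmse))
  invisible(x)
}

#' Predict reference DN spectra for plant pixels
#'
#' Masked pixels' features are normalized with the training statistics and
#' pushed through the network; predictions for pixels whose features fall
#' outside the training min-max hull are returned but flagged in an
#' extrapolation mask.
#'
#' @param model a [train_ann()] model
#' @param features H x W x 8 feature array
#' @param mask H x W logical; FALSE pixels are skipped
#' @return list: `dn` (H x W x B predicted reference DN, NA outside the
#'   mask), `extrapolated` (H x W logical), `n_extrapolated`
#' @export
predict_reference_dn <- function(model, features, mask) {
  fm <- frame_feature_matrix(features, mask, model$feature_set)
  h <- dim(features)[1]; w <- dim(features)[2]
  B <- length(model$ymin)
  out <- array(NA_real_, c(h, w, B))
  extra <- matrix(FALSE, h, w)
  if (length(fm$idx)) {
    db_stats <- list(fmin = model$fmin, fmax = model$fmax)
    Xn <- normalize_features(db_stats, fm$X)
    pred_n <- predict(model$net, Xn)
    pred <- sweep(sweep(pred_n, 2, model$yrng, "*"), 2, model$ymin, "+")
    for (b in seq_len(B)) {
      m <- matrix(NA_real_, h, w); m[fm$idx] <- pred[, b]
      out[, , b] <- m
    }
    extra[fm$idx] <- extrapolation_rows(db_stats, fm$X)
  }
  list(dn = out, extrapolated = extra, n_extrapolated = sum(extra))
}
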