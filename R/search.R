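## Search-based reference DN lookup: exact nearest neighbours in min-max
## normalized feature space under a family of distance metrics (Euclidean,
## weighted Euclidean, Cosine, Mahalanobis, Chebychev, PCA-Cosine, weighted
## Mahalanobis; v1/v2 = descending/ascending weight assignment). Metrics
## that are monotone transforms of a Euclidean distance in a linearly
## transformed space share one vectorized exact scan; exactness against a
## brute-force linear scan is the contract.

SEARCH_METRICS <- c("euclidean", "weighted_euclidean_v1", "weighted_euclidean_v2",
                    "cosine", "mahalanobis", "chebychev", "pca_cosine",
                    "weighted_mahalanobis_v1", "weighted_mahalanobis_v2")

#' Precompute search statistics for a reference database
#'
#' Feature-importance weights for the weighted Euclidean metrics come from
#' a random forest predicting the band-mean DN from the features (relative
#' importance, normalized so the top feature gets weight 1); the PCA basis
#' and per-component variance contributions (normalized so the top
#' component gets 1) drive the PCA-Cosine and weighted Mahalanobis
#' metrics; the regularized feature covariance drives Mahalanobis.
#'
#' @param db a [build_reference_db()] database
#' @param seed RNG seed for the forest (and row subsampling)
#' @param max_rows row cap for the forest fit
#' @return list of class `search_stats`
#' @export
db_search_stats <- function(db, seed = 1L, max_rows = 5000L) {
  X <- normalize_features(db, db$features)
  F <- ncol(X)
  with_seed(seed, {
    idx <- if (nrow(X) > max_rows) sample.int(nrow(X), max_rows) else seq_len(nrow(X))
    y <- rowMeans(db$dn)[idx]
    rf <- randomForest::randomForest(X[idx, , drop = FALSE], y,
                                     ntree = 100, importance = FALSE)
    imp <- randomForest::importance(rf)[, 1]
    imp <- pmax(imp, 0)
    rf_w <- if (max(imp) > 0) imp / max(imp) else rep(1, F)
    ctr <- colMeans(X)
    Xc <- sweep(X, 2, ctr)
    eg <- eigen(stats::cov(Xc), symmetric = TRUE)
    lam <- pmax(eg$values, 0)
    pc_w <- if (max(lam) > 0) lam / max(lam) else rep(1, F)
    S <- stats::cov(X)
    S <- S + diag(1e-6 * sum(diag(S)) / F, F)
    structure(list(rf_weights = rf_w, pca_center = ctr,
                   pca_rotation = eg$vectors, pca_values = lam,
                   pc_weights = pc_w, cov = S, cov_inv = solve(S)),
              class = "search_stats")
  })
}

## ascending variant: the same multiset of weights assigned in reverse
## rank order (least important gets the largest weight)
reverse_weights <- function(w) {
  out <- w
  out[order(w, decreasing = TRUE)] <- sort(w, decreasing = FALSE)
  out
}

## linear map L such that the metric equals (monotone in) the Euclidean
## distance between q %*% L and x %*% L; NULL for non-transform metrics
metric_transform <- function(metric, stats) {
  F <- length(stats$rf_weights)
  switch(metric,
    euclidean = diag(F),
    weighted_euclidean_v1 = diag(sqrt(stats$rf_weights), F),
    weighted_euclidean_v2 = diag(sqrt(reverse_weights(stats$rf_weights)), F),
    mahalanobis = t(chol(stats$cov_inv)),   # row transform: (q-x) R' R (q-x)'
    weighted_mahalanobis_v1 = ,
    weighted_mahalanobis_v2 = {
      w <- stats$pc_weights
      if (metric == "weighted_mahalanobis_v2") w <- reverse_weights(w)
      lam <- pmax(stats$pca_values, 1e-12)
      stats$pca_rotation %*% diag(sqrt(w / lam), F)
    },
    NULL)
}

## exact distances between query rows Q and db rows X under a metric;
## returns the |Q| x |X| matrix (used by tests and small-scale search)
metric_distances <- function(metric, Q, X, stats) {
  switch(metric,
    cosine = {
      1 - normalize_rows(Q) %*% t(normalize_rows(X))
    },
    pca_cosine = {
      Qp <- sweep(Q, 2, stats$pca_center) %*% stats$pca_rotation
      Xp <- sweep(X, 2, stats$pca_center) %*% stats$pca_rotation
      1 - normalize_rows(Qp) %*% t(normalize_rows(Xp))
    },
    chebychev = {
      d <- matrix(0, nrow(Q), nrow(X))
      for (f in seq_len(ncol(Q)))
        d <- pmax(d, abs(outer(Q[, f], X[, f], "-")))
      d
    },
    {
      L <- metric_transform(metric, stats)
      if (is.null(L)) stopf("unknown metric: %s", metric)
      Qt <- Q %*% L; Xt <- X %*% L
      d2 <- pmax(outer(rowSums(Qt^2), rowSums(Xt^2), "+") - 2 * Qt %*% t(Xt), 0)
      sqrt(d2)
    })
}

## nearest k db rows for each query row; exact, chunked over queries
nn_search <- function(metric, Q, X, stats, k = 1L, chunk = 512L) {
  nq <- nrow(Q)
  idx <- matrix(0L, nq, k); dd <- matrix(0, nq, k)
  i <- 1L
  while (i <= nq) {
    j <- min(i + chunk - 1L, nq)
    D <- metric_distances(metric, Q[i:j, , drop = FALSE], X, stats)
    if (k == 1L) {
      best <- max.col(-D)
      idx[i:j, 1] <- best
      dd[i:j, 1] <- D[cbind(seq_len(nrow(D)), best)]
    } else {
      for (r in seq_len(nrow(D))) {
        o <- order(D[r, ])[seq_len(k)]
        idx[i + r - 1L, ] <- o
        dd[i + r - 1L, ] <- D[r, o]
      }
    }
    i <- j + 1L
  }
  list(idx = idx, dist = dd)
}

#' Look up reference DN spectra by nearest-neighbour search
#'
#' Each masked pixel's normalized feature vector is matched against the
#' database under the chosen metric; the matched row's DN spectrum (k = 1)
#' or the inverse-distance-weighted mean of the k nearest rows is
#' returned. The search is exact (verified against a brute-force linear
#' scan).
#'
#' @param db a [build_reference_db()] database
#' @param features H x W x 8 feature array
#' @param mask H x W logical
#' @param metric one of euclidean, weighted_euclidean_v1/v2, cosine,
#'   mahalanobis, chebychev, pca_cosine, weighted_mahalanobis_v1/v2
#' @param k neighbours to average (default 1)
#' @param stats optional [db_search_stats()] (computed on demand)
#' @param max_db_rows optional db row subsample cap (deterministic,
#'   evenly spaced) to bound the scan cost
#' @return list: `dn` (H x W x B), `distance` (H x W), `stats`
#' @export
search_reference_dn <- function(db, features, mask, metric = "euclidean",
                                k = 1L, stats = NULL, max_db_rows = NULL) {
  if (!metric %in% SEARCH_METRICS)
    stopf("unknown metric '%s'; choose one of: %s", metric,
          paste(SEARCH_METRICS, collapse = ", "))
  if (is.null(stats)) stats <- db_search_stats(db)
  X <- normalize_features(db, db$features)
  Y <- db$dn
  if (!is.null(max_db_rows) && nrow(X) > max_db_rows) {
    sel <- unique(round(seq(1, nrow(X), length.out = max_db_rows)))
    X <- X[sel, , drop = FALSE]; Y <- Y[sel, , drop = FALSE]
  }
  fm <- frame_feature_matrix(features, mask, db$feature_set)
  h <- dim(features)[1]; w <- dim(features)[2]
  B <- ncol(Y)
  out <- array(NA_real_, c(h, w, B))
  dmap <- matrix(NA_real_, h, w)
  if (length(fm$idx)) {
    Qn <- normalize_features(db, fm$X)
    nn <- nn_search(metric, Qn, X, stats, k)
    pred <- if (k == 1L) {
      Y[nn$idx[, 1], , drop = FALSE]
    } else {
      wts <- 1 / pmax(nn$dist, 1e-12)
      wts <- wts / rowSums(wts)
      p <- matrix(0, nrow(nn$idx), B)
      for (kk in seq_len(k)) p <- p + wts[, kk] * Y[nn$idx[, kk], , drop = FALSE]
      p
    }
    for (b in seq_len(B)) {
      m <- matrix(NA_real_, h, w); m[fm$idx] <- pred[, b]
      out[, , b] <- m
    }
    dmap[fm$idx] <- nn$dist[, 1]
  }
  list(dn = out, distance = dmap, stats = stats)
}
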