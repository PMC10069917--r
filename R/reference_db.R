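## Reference spectra database: per-pixel light-field features of the
## hemisphere reference frames paired with their observed DN spectra, plus
## min-max normalization statistics, PCA basis and feature weights used by
## the search metrics.

feature_subset_cols <- function(feature_set) {
  switch(as.character(feature_set),
         "3" = 6:8,           # x, y, z
         "5" = 1:5,           # d_i, d_v, theta_i, theta_v, theta
         "8" = 1:8,
         stopf("feature_set must be 3, 5 or 8"))
}

#' Build a reference DN spectra database from hemisphere frames
#'
#' One row per valid masked pixel across all frames: the chosen light-field
#' feature subset as independent variables and the B-band DN spectrum as
#' dependent variables. Min-max statistics are pooled over all rows
#' (feature scales are heterogeneous, so models train on min-max normalized
#' features).
#'
#' @param frames list of frames, each a list with `features` (H x W x 8),
#'   `dn` (H x W x B) and `mask` (H x W logical)
#' @param feature_set 3 (x, y, z), 5 (distances + angles) or 8 (all)
#' @param max_angle_deg optionally drop pixels whose incidence or viewing
#'   angle exceeds this; default Inf (keep all — trimming the grazing rim
#'   also trims the feature coverage the plant pixels query into)
#' @return object of class `reference_db`: `features` (N x F), `dn`
#'   (N x B), `frame` (row origin), normalization stats, channel names
#' @export
build_reference_db <- function(frames, feature_set = 8L, max_angle_deg = Inf) {
  if (!length(frames)) stopf("at least one reference frame is required")
  cols <- feature_subset_cols(feature_set)
  ch_names <- c("d_i", "d_v", "theta_i", "theta_v", "theta", "x", "y", "z")[cols]
  amax <- max_angle_deg * pi / 180
  feat_rows <- list(); dn_rows <- list(); frame_id <- list()
  for (i in seq_along(frames)) {
    fr <- frames[[i]]
    mask <- fr$mask & apply(is.finite(fr$features), c(1, 2), all)
    if (is.finite(amax))
      mask <- mask & !(fr$features[, , 3] > amax) & !(fr$features[, , 4] > amax)
    idx <- which(mask)
    if (!length(idx)) next
    fm <- sapply(cols, function(ch) fr$features[, , ch][idx])
    if (is.null(dim(fm))) fm <- matrix(fm, nrow = 1)
    B <- dim(fr$dn)[3]
    dm <- sapply(seq_len(B), function(b) fr$dn[, , b][idx])
    if (is.null(dim(dm))) dm <- matrix(dm, nrow = 1)
    feat_rows[[length(feat_rows) + 1]] <- fm
    dn_rows[[length(dn_rows) + 1]] <- dm
    frame_id[[length(frame_id) + 1]] <- rep(i, length(idx))
  }
  if (!length(feat_rows)) stopf("no valid reference pixels found")
  X <- do.call(rbind, feat_rows)
  Y <- do.call(rbind, dn_rows)
  colnames(X) <- ch_names
  fmin <- apply(X, 2, min); fmax <- apply(X, 2, max)
  const <- fmax - fmin <= 0
  if (any(const))
    stopf("constant feature column(s): %s", paste(ch_names[const], collapse = ", "))
  structure(list(features = X, dn = Y, frame = unlist(frame_id),
                 fmin = fmin, fmax = fmax, channels = ch_names,
                 feature_set = as.integer(feature_set)),
            class = "reference_db")
}

#' @export
print.reference_db <- function(x, ...) {
  cat(sprintf("<reference_db %d rows, %d features (%s), %d bands>\n",
              nrow(x$features), ncol(x$features),
              paste(x$channels, collapse = ","), ncol(x$dn)))
  invisible(x)
}

## min-max normalize a feature matrix with db statistics
normalize_features <- function(db, X) {
  sweep(sweep(X, 2, db$fmin), 2, db$fmax - db$fmin, "/")
}

## rows whose features fall outside the training min-max hull
extrapolation_rows <- function(db, X) {
  lo <- sweep(X, 2, db$fmin, "<"); hi <- sweep(X, 2, db$fmax, ">")
  rowSums(lo | hi) > 0
}

## collect per-pixel feature matrix for a plant frame (masked pixels only)
frame_feature_matrix <- function(features, mask, feature_set) {
  cols <- feature_subset_cols(feature_set)
  finite <- apply(is.finite(features), c(1, 2), all)
  idx <- which(mask & finite)
  if (!length(idx)) return(list(X = matrix(0, 0, length(cols)), idx = idx))
  X <- sapply(cols, function(ch) features[, , ch][idx])
  if (is.null(dim(X))) X <- matrix(X, nrow = length(idx))
  list(X = X, idx = idx)
}
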